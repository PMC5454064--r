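# Small in-code lexicon used across tests (independent of the bundled one).
test_lexicon <- function() {
  lexicon(
    entries = tibble::tibble(
      token = c("happy", "joyful", "sad", "lonely", "angry", "furious",
                "gross", "vile", "scared", "worried", "stress", "good",
                "bad", "work", "job", "exam", "sleep", "friend"),
      valence = c(0.6, 0.8, -0.6, -0.6, -0.7, -0.8, -0.6, -0.8, -0.6, -0.5,
                  -0.5, 0.5, -0.5, 0, 0, 0, 0, 0),
      emotions = list(
        "joy", "joy", "sadness", "sadness", "anger", "anger",
        "disgust", "disgust", "fear", "fear", character(0), character(0),
        character(0), character(0), character(0), character(0),
        character(0), character(0))
    ),
    stopwords = c("the", "a", "an", "my", "i", "is", "am", "about", "and"),
    negators = c("not", "no", "never")
  )
}

# Minimal hand-built catalog: 3 steps + 2 actions, known structure.
test_catalog <- function() {
  catalog(tibble::tibble(
    id = c("s1", "s2", "s3", "a1", "a2"),
    kind = c("step", "step", "step", "action", "action"),
    title = c("Zen Garden", "apple picking", "Mango Tango",
              "Brave Talk", "Quiet Walk"),
    valence = c("positive", "negative", "either", "either", "positive"),
    anger = c(0, 0.2, 0.1, 0.3, 0),
    disgust = c(0, 0.1, 0.1, 0, 0),
    fear = c(0, 0.3, 0.1, 0.4, 0.1),
    joy = c(0.8, 0, 0.3, 0.1, 0.6),
    sadness = c(0, 0.5, 0.1, 0.1, 0),
    keywords = list(c("calm", "garden"), c("stress", "work"),
                    c("dance", "fun"), c("courage", "talk"),
                    c("walk", "calm")),
    subtags = list("Wellbeing with Mindfulness", "Work and Study",
                   "Making Happiness", "Overcoming Conflict",
                   c("Wellbeing with Mindfulness", "Making Happiness")),
    strengths = list(character(0), character(0), character(0),
                     "Courage", c("Discretion", "Curiosity")),
    related_ids = list(c("s2", "s3"), character(0), "s1",
                       character(0), character(0))
  ))
}

# Seeded random problem instance for the oracle-equivalence properties.
random_instance <- function(seed, lex) {
  withr::with_seed(seed, {
    n_steps <- sample(0:25, 1)
    n_actions <- sample(0:25, 1)
    post_words <- sample(c(lex$entries$token, lex$stopwords, "zzz", "qqq"),
                         sample(0:25, 1), replace = TRUE)
    alpha <- round(stats::runif(1, 0.55, 1), 2)
  })
  list(
    cat = generate_catalog(
      generation_spec(seed = seed + 1L, n_steps = n_steps,
                      n_actions = n_actions), lex),
    post = paste(post_words, collapse = " "),
    cfg = scoring_config(alpha = alpha, seed = seed)
  )
}
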