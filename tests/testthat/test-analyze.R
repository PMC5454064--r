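lex <- test_lexicon()

test_that("tokenizer lowercases, strips punctuation, keeps in-word apostrophes", {
  expect_equal(tokenize("I can't sleep."), c("i", "can't", "sleep"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize(NA_character_), character(0))
  expect_equal(tokenize("HELLO hello"), c("hello", "hello"))
  expect_equal(tokenize("well-being, truly!"), c("well", "being", "truly"))
})

test_that("sentiment is the clipped mean of matched valences", {
  expect_identical(sentiment_score(tokenize("nothing matches here"), lex), 0)
  expect_identical(sentiment_score(character(0), lex), 0)
  expect_equal(sentiment_score(tokenize("so happy"), lex), 0.6)
  expect_equal(sentiment_score(tokenize("happy but sad"), lex), 0)
  expect_equal(sentiment_score(tokenize("happy and joyful"), lex), 0.7)
})

test_that("negators flip the next matched token within a one-token window", {
  expect_equal(sentiment_score(tokenize("not happy"), lex), -0.6)
  expect_equal(sentiment_score(tokenize("never sad"), lex), 0.6)
  # window is one token: an intervening token breaks the flip
  expect_equal(sentiment_score(tokenize("not very happy"), lex), 0.6)
})

test_that("emotion scores are densities over content tokens", {
  expect_equal(unname(emotion_scores(character(0), lex)), rep(0, 5))
  # 4 content tokens, 2 carrying joy -> joy 0.5, rest 0
  sc <- emotion_scores(c("happy", "joyful", "work", "sleep"), lex)
  expect_equal(sc[["joy"]], 0.5)
  expect_equal(unname(sc[c("anger", "disgust", "fear", "sadness")]), rep(0, 4))
  # all content tokens carry sadness -> 1; stopwords don't count
  expect_equal(emotion_scores(c("the", "sad", "lonely"), lex)[["sadness"]], 1)
})

test_that("keywords rank by frequency then first occurrence, capped at k", {
  expect_equal(extract_keywords(tokenize("the a my"), lex, 10), character(0))
  expect_equal(extract_keywords(c("work", "work", "stress"), lex, 10),
               c("work", "stress"))
  expect_equal(extract_keywords(c("exam", "sleep", "sleep", "exam", "work"),
                                lex, 10),
               c("exam", "sleep", "work"))
  expect_equal(extract_keywords(c("work", "work", "stress"), lex, 1), "work")
})

test_that("analyze_post composes the parts deterministically", {
  empty <- analyze_post("", lex)
  expect_identical(empty$sentiment, 0)
  expect_equal(unname(empty$emotions), rep(0, 5))
  expect_equal(empty$keywords, character(0))

  a1 <- analyze_post("happy joyful work, not bad!", lex)
  a2 <- analyze_post("happy joyful work, not bad!", lex)
  expect_equal(a1[c("sentiment", "emotions", "keywords")],
               a2[c("sentiment", "emotions", "keywords")])
  expect_gt(a1$sentiment, 0)
  expect_equal(names(which.max(a1$emotions)), "joy")
})

test_that("analyzer output always respects its ranges", {
  pool <- c(lex$entries$token, lex$stopwords, lex$negators, "xyz", "blorp")
  for (s in 1:300) {
    toks <- withr::with_seed(s, sample(pool, sample(0:12, 1), replace = TRUE))
    sent <- sentiment_score(toks, lex)
    emo <- emotion_scores(toks, lex)
    expect_true(sent >= -1 && sent <= 1)
    expect_true(all(emo >= 0 & emo <= 1))
    expect_equal(anyDuplicated(extract_keywords(toks, lex, 10)), 0)
  }
})

test_that("appending a +1-valence token never decreases sentiment", {
  strong <- lexicon(
    entries = dplyr::bind_rows(test_lexicon()$entries,
                               tibble::tibble(token = "superb", valence = 1,
                                              emotions = list(character(0)))),
    stopwords = test_lexicon()$stopwords, negators = test_lexicon()$negators)
  pool <- c(strong$entries$token, strong$stopwords, "zzz")
  for (s in 1:100) {
    toks <- withr::with_seed(s, sample(pool, sample(1:10, 1), replace = TRUE))
    expect_gte(sentiment_score(c(toks, "superb"), strong),
               sentiment_score(toks, strong))
  }
})

test_that("tidy and glance summarize an analysis", {
  a <- analyze_post("happy happy work", lex)
  td <- tidy(a)
  expect_equal(td$emotion, c("anger", "disgust", "fear", "joy", "sadness"))
  expect_equal(sum(td$score > 0), 1)
  g <- glance(a)
  expect_equal(g$top_emotion, "joy")
  expect_equal(g$sentiment_class, "positive")
})
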