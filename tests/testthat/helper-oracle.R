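# Independent brute-force reference for the suggestion pipeline.
# Re-derives partition, scoring and argmax with plain loops and its own
# text normalization; only the documented tie-break primitive (one uniform
# draw over the sorted tie set, steps under cfg seed, actions under seed+1)
# is shared by contract.
oracle_normalize <- function(phrases, stopwords) {
  toks <- unlist(strsplit(tolower(paste(phrases, collapse = " ")),
                          "[^a-z0-9']+"))
  toks <- gsub("^'+|'+$", "", toks)
  unique(toks[nzchar(toks) & !toks %in% stopwords])
}

oracle_dice <- function(a, b) {
  if (length(a) + length(b) == 0) return(0)
  2 * sum(a %in% b) / (length(a) + length(b))
}

oracle_pick <- function(ids, scores, tau, seed) {
  if (length(ids) == 0) return(NA_character_)
  best <- max(scores)
  if (best < tau) return(NA_character_)
  tied <- sort(ids[scores >= best - 1e-9])
  if (length(tied) == 1) return(tied)
  withr::with_seed(seed, tied[sample.int(length(tied), 1)])
}

oracle_suggest <- function(post_text, cat, cfg, lex) {
  an <- analyze_post(post_text, lex)
  post_kw <- oracle_normalize(an$keywords, lex$stopwords)
  pick_kind <- function(kind, seed) {
    ids <- character(0); scores <- numeric(0)
    for (i in seq_len(nrow(cat$items))) {
      it <- cat$items[i, ]
      if (it$kind != kind) next
      admitted <- if (an$sentiment > 0) it$valence != "negative"
        else if (an$sentiment < 0) it$valence != "positive"
        else TRUE
      if (!admitted) next
      sim <- oracle_dice(post_kw, oracle_normalize(it$keywords[[1]], lex$stopwords))
      emo <- c(it$anger, it$disgust, it$fear, it$joy, it$sadness)
      cong <- 1 - sum(abs(unname(an$emotions) - emo)) / 5
      ids <- c(ids, it$id)
      scores <- c(scores, cfg$alpha * sim + (1 - cfg$alpha) * cong)
    }
    oracle_pick(ids, scores, cfg$tau, seed)
  }
  list(step = pick_kind("step", cfg$seed),
       action = pick_kind("action", cfg$seed + 1L))
}
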