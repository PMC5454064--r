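#' Generation spec for synthetic fixtures
#'
#' Controls the seeded synthetic-data generator used in testing: how many
#' posts/steps/actions to produce, which emotion or sentiment sign generated
#' posts should exhibit, and how long posts are (bounds on content tokens
#' before stopword padding).
#'
#' @param seed Integer seed; identical specs produce identical output.
#' @param n_posts,n_steps,n_actions Non-negative sizes.
#' @param target_emotion One of anger/disgust/fear/joy/sadness, or `NULL`.
#' @param target_sentiment_sign "+", "-", "0", or `NULL` (unconstrained).
#' @param token_min,token_max Positive bounds on content tokens per post.
#' @return A `generation_spec` object.
#' @export
generation_spec <- function(seed = 1L, n_posts = 0L, n_steps = 0L,
                            n_actions = 0L, target_emotion = NULL,
                            target_sentiment_sign = NULL,
                            token_min = 30L, token_max = 45L) {
  stopifnot(n_posts >= 0, n_steps >= 0, n_actions >= 0,
            token_min >= 1, token_max >= token_min)
  if (!is.null(target_emotion)) {
    stopifnot(target_emotion %in% emotion_names())
  }
  if (!is.null(target_sentiment_sign)) {
    stopifnot(target_sentiment_sign %in% c("+", "-", "0"))
  }
  structure(
    list(seed = as.integer(seed), n_posts = as.integer(n_posts),
         n_steps = as.integer(n_steps), n_actions = as.integer(n_actions),
         target_emotion = target_emotion,
         target_sentiment_sign = target_sentiment_sign,
         token_min = as.integer(token_min), token_max = as.integer(token_max)),
    class = "generation_spec"
  )
}

lexicon_strata <- function(lex) {
  e <- lex$entries
  has_emo <- lengths(e$emotions) > 0
  list(
    by_emotion = stats::setNames(purrr::map(emotion_names(), function(em) {
      e$token[purrr::map_lgl(e$emotions, ~ em %in% .x)]
    }), emotion_names()),
    positive = e$token[e$valence > 0],
    negative = e$token[e$valence < 0],
    neutral = e$token[e$valence == 0 & !has_emo]
  )
}

#' Generate synthetic posts
#'
#' Samples posts from lexicon strata so that the analyzer's verdicts are
#' knowable in advance: posts targeting an emotion draw a majority (60%) of
#' their content tokens from that emotion's stratum and the rest from the
#' neutral stratum; posts targeting a sentiment sign draw the majority from
#' tokens of that sign. Stopwords are interleaved as padding. Generation is
#' fully seeded: the same spec always yields the identical posts.
#'
#' @param spec A [generation_spec()] with `n_posts` set.
#' @param lex A `lexicon` object carrying at least one token per emotion and
#'   per sentiment sign (the bundled [default_lexicon()] qualifies).
#' @return Character vector of `n_posts` posts.
#' @export
generate_posts <- function(spec, lex = default_lexicon()) {
  strata <- lexicon_strata(lex)
  needed <- c(purrr::map_int(strata$by_emotion, length),
              positive = length(strata$positive),
              negative = length(strata$negative),
              neutral = length(strata$neutral))
  if (any(needed == 0)) {
    rlang::abort(sprintf("lexicon lacks required stratum/strata: %s",
                         paste(names(needed)[needed == 0], collapse = ", ")),
                 class = "steprec_config_error")
  }
  if (spec$n_posts == 0) return(character(0))

  target_pool <- if (!is.null(spec$target_emotion)) {
    pool <- strata$by_emotion[[spec$target_emotion]]
    if (!is.null(spec$target_sentiment_sign)) {
      signed <- switch(spec$target_sentiment_sign,
                       "+" = strata$positive, "-" = strata$negative,
                       "0" = strata$neutral)
      both <- intersect(pool, signed)
      if (length(both)) pool <- both   # emotion wins when incompatible
    }
    pool
  } else if (!is.null(spec$target_sentiment_sign)) {
    switch(spec$target_sentiment_sign,
           "+" = strata$positive, "-" = strata$negative, "0" = strata$neutral)
  } else {
    c(strata$positive, strata$negative, strata$neutral)
  }

  withr::with_seed(spec$seed, {
    purrr::map_chr(seq_len(spec$n_posts), function(i) {
      n_content <- sample(spec$token_min:spec$token_max, 1L)
      n_target <- ceiling(0.6 * n_content)
      toks <- c(
        sample(target_pool, n_target, replace = TRUE),
        sample(strata$neutral, n_content - n_target, replace = TRUE)
      )
      toks <- sample(toks)  # shuffle target/filler order
      if (length(lex$stopwords)) {
        pad <- sample(lex$stopwords, max(1L, round(0.3 * n_content)),
                      replace = TRUE)
        toks <- sample(c(toks, pad))
      }
      paste(toks, collapse = " ")
    })
  })
}

#' Generate a synthetic catalog
#'
#' Builds a validation-clean catalog of `n_steps` steps and `n_actions`
#' actions under the canonical taxonomy and strengths: seeded random
#' valences, emotion-relevance vectors with one dominant emotion, keywords
#' drawn from the lexicon's content vocabulary, 1-2 sub-tags each, strengths
#' on actions, and resolvable related-step links.
#'
#' @param spec A [generation_spec()] with `n_steps`/`n_actions` set.
#' @param lex Lexicon supplying the keyword vocabulary.
#' @return A `catalog` object that passes full validation.
#' @export
generate_catalog <- function(spec, lex = default_lexicon()) {
  tax <- canonical_taxonomy()
  strengths <- canonical_strengths()
  strata <- lexicon_strata(lex)
  vocab <- unique(c(strata$neutral, unlist(strata$by_emotion)))
  n <- spec$n_steps + spec$n_actions
  if (n == 0) return(new_catalog(empty_items(), tax, strengths))

  withr::with_seed(spec$seed, {
    kinds <- c(rep("step", spec$n_steps), rep("action", spec$n_actions))
    ids <- sprintf("%s%03d", ifelse(kinds == "step", "s", "a"),
                   c(seq_len(spec$n_steps), seq_len(spec$n_actions)))
    step_ids <- ids[kinds == "step"]
    items <- purrr::map(seq_len(n), function(i) {
      dominant <- sample(emotion_names(), 1L)
      emo <- round(stats::runif(5, 0, 0.3), 3)
      names(emo) <- emotion_names()
      emo[dominant] <- round(stats::runif(1, 0.5, 1), 3)
      kws <- sample(vocab, sample(2:5, 1L))
      rel <- if (kinds[i] == "step" && length(step_ids) > 1L) {
        others <- setdiff(step_ids, ids[i])
        sample(others, min(length(others), sample(0:2, 1L)))
      } else character(0)
      tibble::tibble(
        id = ids[i], kind = kinds[i],
        title = paste(tools::toTitleCase(paste(kws[1:2], collapse = " and ")),
                      sprintf("(%s)", ids[i])),
        valence = sample(valence_levels(), 1L),
        anger = emo[["anger"]], disgust = emo[["disgust"]],
        fear = emo[["fear"]], joy = emo[["joy"]], sadness = emo[["sadness"]],
        keywords = list(kws),
        subtags = list(sample(tax$subtag, sample(1:2, 1L))),
        strengths = list(if (kinds[i] == "action")
          sample(strengths, sample(0:3, 1L)) else character(0)),
        related_ids = list(rel)
      )
    }) |> purrr::list_rbind()
    catalog(items, tax, strengths)
  })
}

#' Fixtures reproducing the published usage counts
#'
#' Deterministically builds the bundled accounting fixtures whose summary
#' statistics equal the counts reported for the live system:
#' * a 701-record moderator-suggestion ledger with 211 completed,
#'   21 client-dismissed, 304 moderator-dismissed and 165 pending;
#' * a 100-event log over the four "Steps People are Taking" links split
#'   48 / 14 / 11 / 27;
#' * a 100-event tracked-visit log split 39 (moderator suggestion) /
#'   5 (post-step related list) / 9 (newsfeed suggestion) / 47 (other);
#' * the canonical 3x3 tag taxonomy and the 24-strength list.
#'
#' Event logs are scaled to 100 events so the published integer percentages
#' are reproduced exactly rather than approximately. No randomness is
#' involved; output is byte-stable.
#'
#' @return Named list: `ledger`, `four_link_events`, `tracked_events`,
#'   `taxonomy`, `strengths`.
#' @export
build_reference_fixtures <- function() {
  statuses <- rep(c("completed", "client_dismissed", "moderator_dismissed",
                    "pending"),
                  times = c(211L, 21L, 304L, 165L))
  n <- length(statuses)
  ledger <- tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    moderator_id = sprintf("m%d", (seq_len(n) - 1L) %% 8L + 1L),
    user_id = sprintf("u%03d", (seq_len(n) - 1L) %% 60L + 1L),
    item_id = sprintf("s%03d", (seq_len(n) - 1L) %% 20L + 1L),
    status = statuses
  )

  t0 <- as.POSIXct("2017-01-01 00:00:00", tz = "UTC")
  mk_events <- function(paths, kinds) {
    m <- length(paths)
    tibble::tibble(
      user_id = sprintf("u%03d", (seq_len(m) - 1L) %% 40L + 1L),
      item_id = sprintf("%s%03d", ifelse(kinds == "step", "s", "a"),
                        (seq_len(m) - 1L) %% 15L + 1L),
      item_kind = kinds,
      access_path = paths,
      timestamp = t0 + 3600 * seq_len(m)
    )
  }
  four_paths <- rep(four_link_paths(), times = c(48L, 14L, 11L, 27L))
  four_link_events <- mk_events(four_paths, rep("step", 100L))

  tracked_paths <- rep(c("moderator_suggestion", "related_after_step",
                         "newsfeed_suggestion", "other"),
                       times = c(39L, 5L, 9L, 47L))
  tracked_kinds <- rep(c("step", "action"), length.out = 100L)
  tracked_events <- mk_events(tracked_paths, tracked_kinds)

  list(
    ledger = ledger,
    four_link_events = four_link_events,
    tracked_events = tracked_events,
    taxonomy = canonical_taxonomy(),
    strengths = canonical_strengths()
  )
}

#' Write all fixtures to a directory
#'
#' Writes the reference-count fixtures of [build_reference_fixtures()] (plus the
#' bundled catalog) as plain-text files in the formats their consuming
#' modules read.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly the vector of files written.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- build_reference_fixtures()
  paths <- c(
    ledger = file.path(dir, "suggestion_ledger.csv"),
    four_link = file.path(dir, "four_link_events.csv"),
    tracked = file.path(dir, "tracked_events.csv"),
    catalog = file.path(dir, "catalog.json")
  )
  write_ledger(fx$ledger, paths[["ledger"]])
  write_events(fx$four_link_events, paths[["four_link"]])
  write_events(fx$tracked_events, paths[["tracked"]])
  save_catalog(example_catalog(), paths[["catalog"]])
  invisible(paths)
}
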