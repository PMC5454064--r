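#' Scoring configuration
#'
#' Parameters of the combined suggestion score. Keyword similarity is the
#' decisive factor and emotion congruence the balancing one, so the combined
#' score is the convex combination `alpha * similarity + (1 - alpha) *
#' congruence` with `alpha` constrained to (0.5, 1]. `tau` is the minimum
#' combined score below which no suggestion is emitted (default 0: always
#' suggest). `seed` drives the uniform random choice among exact ties.
#'
#' @param alpha Similarity weight in (0.5, 1]; default 0.7.
#' @param tau Minimum combined score in \[0, 1\]; default 0.
#' @param seed Integer seed for tie-breaking; default 1.
#' @return A `scoring_config` object.
#' @export
scoring_config <- function(alpha = 0.7, tau = 0, seed = 1L) {
  if (!(alpha > 0.5 && alpha <= 1)) {
    rlang::abort("alpha must lie in (0.5, 1]")
  }
  if (!(tau >= 0 && tau <= 1)) {
    rlang::abort("tau must lie in [0, 1]")
  }
  structure(list(alpha = alpha, tau = tau, seed = as.integer(seed)),
            class = "scoring_config")
}

#' User profile
#'
#' @param user_id Identifier.
#' @param chosen_strengths Up to 5 distinct strength names.
#' @param steps_taken Step ids the user has taken.
#' @param bookmarked_actions Action ids the user has bookmarked.
#' @return A `user_profile` object.
#' @export
user_profile <- function(user_id = "user", chosen_strengths = character(0),
                         steps_taken = character(0),
                         bookmarked_actions = character(0)) {
  chosen_strengths <- unique(as.character(chosen_strengths))
  if (length(chosen_strengths) > 5L) {
    rlang::abort("a profile carries at most 5 chosen strengths")
  }
  structure(
    list(user_id = user_id, chosen_strengths = chosen_strengths,
         steps_taken = as.character(steps_taken),
         bookmarked_actions = as.character(bookmarked_actions)),
    class = "user_profile"
  )
}

#' Valence partition of suggestion candidates
#'
#' Positive posts reduce the candidate pool to items suitable for positive
#' posts, negative posts to those suitable for negative posts; a neutral post
#' imposes no reduction. Items marked `either` are admitted for both signed
#' classes, since they are by construction suitable for any post.
#'
#' @param items Tibble of catalog items.
#' @param sentiment Post sentiment in \[-1, 1\].
#' @return The admitted rows of `items`, original order preserved.
#' @export
partition_candidates <- function(items, sentiment) {
  if (sentiment > 0) {
    dplyr::filter(items, .data$valence %in% c("positive", "either"))
  } else if (sentiment < 0) {
    dplyr::filter(items, .data$valence %in% c("negative", "either"))
  } else {
    items
  }
}

normalize_keywords <- function(kws, lex) {
  toks <- unlist(purrr::map(kws, tokenize))
  unique(toks[!toks %in% lex$stopwords])
}

#' Keyword similarity
#'
#' Dice coefficient `2|a intersect b| / (|a| + |b|)` on normalized keyword
#' token sets (lowercased, phrases split into tokens, stopwords removed).
#' Both sets empty gives 0.
#'
#' @param a,b Character vectors of normalized keyword tokens.
#' @return A number in \[0, 1\].
#' @export
semantic_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Emotion congruence
#'
#' Closeness of a post's five-emotion vector to an item's emotion-relevance
#' vector: one minus the mean absolute difference over the five emotions,
#' `1 - mean(|p - r|)`. Identical vectors give 1; maximally distant give 0.
#'
#' @param p,r Numeric vectors over (anger, disgust, fear, joy, sadness), each
#'   component in \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
emotion_congruence <- function(p, r) {
  stopifnot(length(p) == 5, length(r) == 5)
  1 - mean(abs(as.numeric(p) - as.numeric(r)))
}

#' Combined suggestion score of one item
#'
#' `alpha * similarity + (1 - alpha) * congruence`. Similarity dominates
#' (alpha > 0.5), while congruence splits similarity ties and can downgrade a
#' keyword-similar but emotionally inappropriate item.
#'
#' @param analysis A `post_analysis`.
#' @param item One-row tibble of a catalog item.
#' @param cfg A [scoring_config()].
#' @param lex Lexicon used to normalize the item's keywords.
#' @return A number in \[0, 1\].
#' @export
score_item <- function(analysis, item, cfg = scoring_config(),
                       lex = default_lexicon()) {
  sim <- semantic_similarity(
    normalize_keywords(analysis$keywords, lex),
    normalize_keywords(item$keywords[[1]], lex)
  )
  cong <- emotion_congruence(analysis$emotions,
                             as.numeric(item[1, emotion_names()]))
  cfg$alpha * sim + (1 - cfg$alpha) * cong
}

# one uniform draw among sorted tied ids under a fixed seed
tie_break <- function(ids, seed) {
  ids <- sort(ids)
  if (length(ids) == 1L) return(ids)
  withr::with_seed(seed, ids[sample.int(length(ids), 1L)])
}

select_from_pool <- function(audit_pool, tau, seed) {
  adm <- dplyr::filter(audit_pool, .data$admitted)
  if (nrow(adm) == 0 || max(adm$combined) < tau) {
    return(list(id = NA_character_, tie_broken = FALSE))
  }
  top <- adm$id[adm$combined >= max(adm$combined) - 1e-9]
  list(id = tie_break(top, seed), tie_broken = length(top) > 1L)
}

#' Suggest a step and an action for a post
#'
#' The four-stage automated suggestion pipeline applied to one newsfeed post:
#' (1) the post is analyzed for sentiment, the five emotions and keywords;
#' (2) candidate steps and candidate actions are each reduced by the valence
#' partition (positive posts keep positively-suited items, negative posts
#' negatively-suited ones, neutral posts keep everything); (3) every admitted
#' candidate is scored by keyword similarity with the post combined with
#' emotion congruence; (4) per kind, the highest-scoring candidate is
#' selected, exact ties (within 1e-9) resolved uniformly at random under the
#' configured seed. Steps and actions are scored as separate pools, so the
#' result carries one step and one action. A post without extractable
#' keywords has similarity 0 everywhere and selection rides on congruence.
#'
#' @param post_text Free text of the post.
#' @param cat A `catalog` object.
#' @param profile Optional [user_profile()]; carried into the audit trail.
#' @param cfg A [scoring_config()].
#' @param lex A `lexicon` object.
#' @return A `suggestion_result`: selected `step` and `action` ids (or `NA`),
#'   the post `analysis`, `sentiment_class`, `tie_broken` flag, and an
#'   `audit` tibble with one row per candidate (id, kind, admitted flag,
#'   similarity, congruence, combined score).
#' @export
#' @examples
#' res <- suggest("Feeling stressed about my new job", example_catalog())
#' res$step
suggest <- function(post_text, cat, profile = NULL, cfg = scoring_config(),
                    lex = default_lexicon()) {
  analysis <- analyze_post(post_text, lex)
  s_class <- sentiment_class(analysis$sentiment)

  if (nrow(cat$items) == 0) {
    return(new_suggestion_result(NA_character_, NA_character_, analysis,
                                 s_class, FALSE, empty_audit()))
  }

  post_kw <- normalize_keywords(analysis$keywords, lex)
  admitted_ids <- partition_candidates(cat$items, analysis$sentiment)$id
  audit <- cat$items |>
    dplyr::mutate(
      admitted = .data$id %in% admitted_ids,
      similarity = purrr::map_dbl(
        .data$keywords, ~ semantic_similarity(post_kw, normalize_keywords(.x, lex))),
      congruence = 1 - (abs(analysis$emotions[["anger"]] - .data$anger) +
                        abs(analysis$emotions[["disgust"]] - .data$disgust) +
                        abs(analysis$emotions[["fear"]] - .data$fear) +
                        abs(analysis$emotions[["joy"]] - .data$joy) +
                        abs(analysis$emotions[["sadness"]] - .data$sadness)) / 5,
      combined = cfg$alpha * .data$similarity + (1 - cfg$alpha) * .data$congruence
    ) |>
    dplyr::select("id", "kind", "title", "valence", "admitted",
                  "similarity", "congruence", "combined")

  step_sel <- select_from_pool(dplyr::filter(audit, .data$kind == "step"),
                               cfg$tau, cfg$seed)
  act_sel <- select_from_pool(dplyr::filter(audit, .data$kind == "action"),
                              cfg$tau, cfg$seed + 1L)

  new_suggestion_result(step_sel$id, act_sel$id, analysis, s_class,
                        step_sel$tie_broken || act_sel$tie_broken, audit)
}

empty_audit <- function() {
  tibble::tibble(
    id = character(0), kind = character(0), title = character(0),
    valence = character(0), admitted = logical(0), similarity = numeric(0),
    congruence = numeric(0), combined = numeric(0)
  )
}

new_suggestion_result <- function(step, action, analysis, s_class, tie_broken,
                                  audit) {
  structure(
    list(step = step, action = action, analysis = analysis,
         sentiment_class = s_class, tie_broken = tie_broken, audit = audit),
    class = "suggestion_result"
  )
}

#' @export
print.suggestion_result <- function(x, ...) {
  cat(sprintf("<suggestion_result: post is %s>\n", x$sentiment_class))
  cat("  step:  ", if (is.na(x$step)) "(none)" else x$step, "\n")
  cat("  action:", if (is.na(x$action)) "(none)" else x$action, "\n")
  if (x$tie_broken) cat("  (tie broken at random under the configured seed)\n")
  invisible(x)
}

#' Tidy a suggestion result
#'
#' The per-candidate audit trail: one row per catalog item with its
#' admission flag, similarity, congruence and combined score, plus a
#' `selected` flag.
#'
#' @param x A `suggestion_result`.
#' @param ... Unused.
#' @return A tibble sorted by combined score within kind.
#' @exportS3Method generics::tidy
tidy.suggestion_result <- function(x, ...) {
  x$audit |>
    dplyr::mutate(selected = .data$id %in% stats::na.omit(c(x$step, x$action))) |>
    dplyr::arrange(.data$kind, dplyr::desc(.data$combined))
}

#' Glance at a suggestion result
#'
#' @param x A `suggestion_result`.
#' @param ... Unused.
#' @return One-row tibble: selections, sentiment, candidate counts.
#' @exportS3Method generics::glance
glance.suggestion_result <- function(x, ...) {
  tibble::tibble(
    step = x$step, action = x$action,
    sentiment = x$analysis$sentiment,
    sentiment_class = x$sentiment_class,
    tie_broken = x$tie_broken,
    n_candidates = nrow(x$audit),
    n_admitted = sum(x$audit$admitted)
  )
}

#' Plot a suggestion result
#'
#' Combined scores of all candidates, faceted by kind; excluded (valence
#' non-admitted) candidates are greyed out and the selected items outlined.
#'
#' @param object A `suggestion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.suggestion_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$id, .data$combined), y = .data$combined,
      fill = .data$admitted, colour = .data$selected)) +
    ggplot2::geom_col(linewidth = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey80")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA)) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "combined score") +
    ggplot2::theme_minimal()
}

#' Related steps of a step
#'
#' The "You might also be interested in" list shown after a step: the
#' step-to-step links pre-set by the content author, resolved in stored
#' order.
#'
#' @param step_id A step id present in the catalog.
#' @param cat A `catalog` object.
#' @return Tibble of the linked steps in stored order.
#' @export
related_steps <- function(step_id, cat) {
  row <- dplyr::filter(cat$items, .data$id == step_id, .data$kind == "step")
  if (nrow(row) == 0) {
    rlang::abort(sprintf("unknown step id: '%s'", step_id),
                 class = "steprec_domain_error")
  }
  rel <- row$related_ids[[1]]
  cat$items[match(rel, cat$items$id), ]
}

#' Action suggestions for the newsfeed
#'
#' Personalized action placements inserted into a user's newsfeed, driven by
#' the user's chosen strengths and the steps they have taken: candidate
#' actions share at least one strength with the profile or at least one
#' sub-tag with a taken step, are ranked by the total overlap count
#' (shared strengths + shared sub-tags, descending), and already-bookmarked
#' actions are excluded. Rank ties are ordered uniformly at random under
#' `seed`.
#'
#' @param profile A [user_profile()].
#' @param cat A `catalog` object.
#' @param n Maximum number of suggestions (default 10).
#' @param seed Integer seed for tie ordering.
#' @return Tibble of up to `n` actions with an `overlap` column.
#' @export
feed_action_suggestions <- function(profile, cat, n = 10L, seed = 1L) {
  taken_tags <- unique(unlist(
    cat$items$subtags[cat$items$id %in% profile$steps_taken]))
  cand <- cat$items |>
    dplyr::filter(.data$kind == "action",
                  !.data$id %in% profile$bookmarked_actions) |>
    dplyr::mutate(
      shared_strengths = purrr::map_int(
        .data$strengths, ~ length(intersect(.x, profile$chosen_strengths))),
      shared_subtags = purrr::map_int(
        .data$subtags, ~ length(intersect(.x, taken_tags))),
      overlap = .data$shared_strengths + .data$shared_subtags
    ) |>
    dplyr::filter(.data$shared_strengths > 0 | .data$shared_subtags > 0)
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$overlap, withr::with_seed(seed, stats::runif(nrow(cand)))), ]
  utils::head(cand, n)
}

#' Actions on the strengths page
#'
#' The "Powered by your Strengths" page: exactly the actions connected to at
#' least one of the user's chosen strengths, sorted by title.
#'
#' @param profile A [user_profile()].
#' @param cat A `catalog` object.
#' @return Tibble of matching actions.
#' @export
strengths_page_actions <- function(profile, cat) {
  cat$items |>
    dplyr::filter(.data$kind == "action",
                  purrr::map_lgl(.data$strengths,
                                 ~ length(intersect(.x, profile$chosen_strengths)) > 0)) |>
    dplyr::arrange(tolower(.data$title), .data$id)
}
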