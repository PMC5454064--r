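#' Tokenize free text
#'
#' Lowercases and splits text into word tokens, stripping punctuation but
#' keeping apostrophes inside words (so "can't" stays one token).
#'
#' @param text A character scalar (free text); `NA` is treated as empty.
#' @return Character vector of tokens in order of occurrence.
#' @export
#' @examples
#' tokenize("I can't sleep.")
tokenize <- function(text) {
  if (length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  m <- stringr::str_extract_all(tolower(text), "[a-z0-9]+(?:'[a-z0-9]+)*")[[1]]
  m[nzchar(m)]
}

#' Sentiment score of a token stream
#'
#' The mean valence of the tokens matched in the lexicon, clipped to
#' \[-1, 1\]. A score of 0 is neutral, positive scores positive, negative
#' scores negative. Negators ("not", "never", ...) flip the sign of the next
#' matched token within a one-token window. With no matched token the score
#' is exactly 0.
#'
#' @param tokens Character vector from [tokenize()].
#' @param lex A `lexicon` object.
#' @return A number in \[-1, 1\].
#' @export
sentiment_score <- function(tokens, lex) {
  if (length(tokens) == 0) return(0)
  idx <- match(tokens, lex$entries$token)
  vals <- lex$entries$valence[idx]
  if (length(tokens) > 1) {
    negated <- c(FALSE, tokens[-length(tokens)] %in% lex$negators)
    vals <- ifelse(negated, -vals, vals)
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  min(1, max(-1, mean(vals)))
}

#' Five-emotion scores of a token stream
#'
#' For each of anger, disgust, fear, joy and sadness, the share of content
#' (non-stopword) tokens carrying that emotion in the lexicon:
#' `count(tokens with e) / max(1, content tokens)`, clipped to \[0, 1\].
#' The denominator is the content-token count, so each score reads as the
#' density of that emotion in the post.
#'
#' @inheritParams sentiment_score
#' @return Named numeric vector over the five emotions, each in \[0, 1\].
#' @export
emotion_scores <- function(tokens, lex) {
  out <- stats::setNames(numeric(5), emotion_names())
  content <- tokens[!tokens %in% lex$stopwords]
  if (length(content) == 0) return(out)
  emo <- lex$entries$emotions[match(content, lex$entries$token)]
  for (e in emotion_names()) {
    n_e <- sum(purrr::map_lgl(emo, ~ !is.null(.x) && e %in% .x))
    out[[e]] <- min(1, max(0, n_e / max(1, length(content))))
  }
  out
}

#' Extract keywords from a token stream
#'
#' Content (non-stopword) tokens ranked by frequency, ties broken by first
#' occurrence; at most `k` distinct tokens returned.
#'
#' @inheritParams sentiment_score
#' @param k Maximum number of keywords (default 10).
#' @return Character vector of up to `k` keywords, duplicate-free.
#' @export
extract_keywords <- function(tokens, lex, k = 10L) {
  stopifnot(k >= 1)
  content <- tokens[!tokens %in% lex$stopwords]
  if (length(content) == 0) return(character(0))
  first <- match(unique(content), content)
  freq <- table(factor(content, levels = unique(content)))
  ord <- order(-as.integer(freq), first)
  utils::head(unique(content)[ord], k)
}

#' Analyze a post
#'
#' The full linguistic analysis applied to every newsfeed post: a sentiment
#' score in \[-1, 1\] (0 neutral), a score in \[0, 1\] for each of the five
#' emotions anger, disgust, fear, joy and sadness, and the post's ranked
#' keywords. Deterministic: the same text and lexicon always produce the
#' identical analysis. Any backend returning the same structure (e.g. a
#' remote text-analysis service) can stand in for this local analyzer
#' wherever a `post_analysis` is consumed.
#'
#' @param text Free text of the post.
#' @param lex A `lexicon` object (default [default_lexicon()]).
#' @param k Maximum number of keywords (default 10).
#' @return A `post_analysis` object: `sentiment`, `emotions` (named numeric),
#'   `keywords`, plus the tokenization used.
#' @export
#' @examples
#' analyze_post("Feeling stressed about my new job")
analyze_post <- function(text, lex = default_lexicon(), k = 10L) {
  tokens <- tokenize(text)
  structure(
    list(
      text = if (length(text) && !is.na(text)) text else "",
      tokens = tokens,
      sentiment = sentiment_score(tokens, lex),
      emotions = emotion_scores(tokens, lex),
      keywords = extract_keywords(tokens, lex, k)
    ),
    class = "post_analysis"
  )
}

#' Sentiment class of a score
#'
#' @param sentiment Number in \[-1, 1\].
#' @return "positive", "neutral" or "negative".
#' @export
sentiment_class <- function(sentiment) {
  if (sentiment > 0) "positive" else if (sentiment < 0) "negative" else "neutral"
}

#' @export
print.post_analysis <- function(x, ...) {
  cat(sprintf("<post_analysis: sentiment %+.3f (%s)>\n",
              x$sentiment, sentiment_class(x$sentiment)))
  cat("  emotions:", paste(sprintf("%s %.2f", names(x$emotions), x$emotions),
                           collapse = ", "), "\n")
  cat("  keywords:", if (length(x$keywords)) paste(x$keywords, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a post analysis
#'
#' One row per emotion with its score.
#'
#' @param x A `post_analysis` object.
#' @param ... Unused.
#' @return A tibble with columns `emotion`, `score`.
#' @exportS3Method generics::tidy
tidy.post_analysis <- function(x, ...) {
  tibble::tibble(emotion = names(x$emotions), score = unname(x$emotions))
}

#' Glance at a post analysis
#'
#' @param x A `post_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: `sentiment`, `sentiment_class`, `top_emotion`,
#'   `n_tokens`, `n_keywords`.
#' @exportS3Method generics::glance
glance.post_analysis <- function(x, ...) {
  tibble::tibble(
    sentiment = x$sentiment,
    sentiment_class = sentiment_class(x$sentiment),
    top_emotion = if (any(x$emotions > 0)) names(which.max(x$emotions)) else NA_character_,
    n_tokens = length(x$tokens),
    n_keywords = length(x$keywords)
  )
}

#' Plot a post analysis
#'
#' Bar chart of the five emotion scores, annotated with the sentiment class.
#'
#' @param object A `post_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.post_analysis <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$emotion, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("Post analysis (sentiment %+.2f, %s)",
                      object$sentiment, sentiment_class(object$sentiment)),
      x = NULL, y = "emotion score"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
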