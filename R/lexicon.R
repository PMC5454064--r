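#' Read a sentiment/emotion lexicon
#'
#' The analyzer is powered by a plain-text lexicon: one token per line,
#' tab-separated as `token<TAB>valence<TAB>emotion1;emotion2;...`, where
#' valence is in \[-1, 1\] and the (possibly empty) emotion field lists
#' memberships among anger, disgust, fear, joy, sadness. Stopwords and
#' negators are separate one-token-per-line files. All files are UTF-8 and
#' tokens are lowercase.
#'
#' @param path Lexicon TSV path.
#' @param stopwords_path,negators_path One-token-per-line list files.
#' @return A `lexicon` object: `entries` tibble (`token`, `valence`,
#'   `emotions` list-column), `stopwords` and `negators` character vectors.
#' @export
read_lexicon <- function(path, stopwords_path, negators_path) {
  entries <- readr::read_tsv(
    path,
    col_names = c("token", "valence", "emotions"),
    col_types = readr::cols(
      token = readr::col_character(),
      valence = readr::col_double(),
      emotions = readr::col_character()
    ),
    na = character(0), progress = FALSE
  )
  entries$emotions <- purrr::map(entries$emotions, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  lex <- structure(
    list(
      entries = entries,
      stopwords = readr::read_lines(stopwords_path, progress = FALSE),
      negators = readr::read_lines(negators_path, progress = FALSE)
    ),
    class = "lexicon"
  )
  validate_lexicon(lex)
  lex
}

validate_lexicon <- function(lex) {
  bad_val <- lex$entries$valence < -1 | lex$entries$valence > 1
  if (any(bad_val)) {
    rlang::abort(sprintf(
      "lexicon validation failed: valence outside [-1,1] for token(s): %s",
      paste(lex$entries$token[bad_val], collapse = ", ")),
      class = "steprec_validation_error")
  }
  not_lower <- lex$entries$token != tolower(lex$entries$token)
  if (any(not_lower)) {
    rlang::abort(sprintf(
      "lexicon validation failed: token(s) not lowercase: %s",
      paste(lex$entries$token[not_lower], collapse = ", ")),
      class = "steprec_validation_error")
  }
  unknown <- setdiff(unique(unlist(lex$entries$emotions)), emotion_names())
  if (length(unknown)) {
    rlang::abort(sprintf(
      "lexicon validation failed: unknown emotion name(s): %s",
      paste(unknown, collapse = ", ")),
      class = "steprec_validation_error")
  }
  invisible(lex)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d entries, %d stopwords, %d negators>\n",
              nrow(x$entries), length(x$stopwords), length(x$negators)))
  invisible(x)
}

#' Bundled default lexicon
#'
#' A small hand-curated English lexicon shipped with the package, sufficient
#' for the bundled examples and the synthetic-post generator. Larger lexicons
#' in the same format can be plugged into every analysis function.
#'
#' @return A `lexicon` object.
#' @export
default_lexicon <- function() {
  dir <- system.file("extdata", "lexicon", package = "steprec")
  read_lexicon(
    file.path(dir, "lexicon.tsv"),
    file.path(dir, "stopwords.txt"),
    file.path(dir, "negators.txt")
  )
}

#' Construct a lexicon in code
#'
#' @param entries Tibble with columns `token`, `valence`, `emotions`
#'   (list-column of character vectors).
#' @param stopwords,negators Character vectors.
#' @return A `lexicon` object.
#' @export
lexicon <- function(entries, stopwords = character(0), negators = character(0)) {
  lex <- structure(
    list(entries = tibble::as_tibble(entries),
         stopwords = stopwords, negators = negators),
    class = "lexicon"
  )
  validate_lexicon(lex)
  lex
}
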