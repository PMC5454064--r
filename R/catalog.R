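#' Canonical tag taxonomy
#'
#' The therapy-content tag taxonomy: three parent tags (Coping, Connecting,
#' Enhancing), each with three sub-tags. Steps and actions are tagged with one
#' or more sub-tags, and users browse or search content through them.
#'
#' @return A tibble with columns `parent` and `subtag` (9 rows).
#' @export
#' @examples
#' canonical_taxonomy()
canonical_taxonomy <- function() {
  tibble::tibble(
    parent = rep(c("Coping", "Connecting", "Enhancing"), each = 3L),
    subtag = c(
      "Solving Problems", "Kicking the Habit", "Beating Sadness and Worries",
      "Overcoming Conflict", "Boosting Relationships", "Stories Like Yours",
      "Making Happiness", "Wellbeing with Mindfulness", "Work and Study"
    )
  )
}

#' Canonical character strengths
#'
#' The 24 character strengths from which each user selects the 5 that best
#' apply to them. Actions are connected to strengths so that users can find
#' activities that exercise them. Four names (Courage, Discretion, Creativity,
#' Curiosity) come from the deployed system; the remaining twenty are
#' synthetic placeholders, since the full deployed list is not public.
#'
#' @return A character vector of 24 distinct strength names.
#' @export
canonical_strengths <- function() {
  c(
    "Courage", "Discretion", "Creativity", "Curiosity",
    # synthetic placeholders below
    "Kindness", "Honesty", "Humor", "Gratitude", "Hope", "Perseverance",
    "Teamwork", "Leadership", "Forgiveness", "Humility", "Prudence",
    "Self-Control", "Fairness", "Love of Learning", "Perspective", "Zest",
    "Social Awareness", "Appreciation", "Open-Mindedness", "Patience"
  )
}

emotion_names <- function() c("anger", "disgust", "fear", "joy", "sadness")
valence_levels <- function() c("positive", "negative", "either")

new_catalog <- function(items, taxonomy, strengths) {
  structure(
    list(items = items, taxonomy = taxonomy, strengths = strengths),
    class = "catalog"
  )
}

#' Build a catalog from its parts
#'
#' Assembles and validates a therapy-content catalog. `items` must carry one
#' row per step/action with the per-item fields described in
#' [load_catalog()]; list-columns hold the set-valued fields.
#'
#' @param items Tibble of items (see [load_catalog()] for columns).
#' @param taxonomy Tibble with columns `parent`, `subtag`; defaults to
#'   [canonical_taxonomy()].
#' @param strengths Character vector of strength names; defaults to
#'   [canonical_strengths()].
#' @return A validated `catalog` object.
#' @export
catalog <- function(items, taxonomy = canonical_taxonomy(),
                    strengths = canonical_strengths()) {
  cat <- new_catalog(tibble::as_tibble(items), tibble::as_tibble(taxonomy),
                     strengths)
  validate_catalog(cat)
  cat
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf(
    "<catalog: %d steps, %d actions, %d parent tags / %d sub-tags, %d strengths>\n",
    sum(x$items$kind == "step"), sum(x$items$kind == "action"),
    dplyr::n_distinct(x$taxonomy$parent), nrow(x$taxonomy),
    length(x$strengths)
  ))
  invisible(x)
}

catalog_violations <- function(cat) {
  items <- cat$items
  tax <- cat$taxonomy
  v <- character(0)
  add <- function(msgs) v <<- c(v, msgs)

  if (anyDuplicated(tax$subtag)) {
    add(sprintf("taxonomy: duplicated sub-tag name(s): %s",
                paste(unique(tax$subtag[duplicated(tax$subtag)]), collapse = ", ")))
  }
  if (anyDuplicated(cat$strengths)) {
    add("strengths: duplicated strength name(s)")
  }
  if (nrow(items) == 0) return(v)

  if (anyDuplicated(items$id)) {
    add(sprintf("items: duplicated id(s): %s",
                paste(unique(items$id[duplicated(items$id)]), collapse = ", ")))
  }
  bad_kind <- !items$kind %in% c("step", "action")
  if (any(bad_kind)) {
    add(sprintf("item '%s': kind '%s' not one of step/action",
                items$id[bad_kind], items$kind[bad_kind]))
  }
  bad_val <- !items$valence %in% valence_levels()
  if (any(bad_val)) {
    add(sprintf("item '%s': valence '%s' not one of positive/negative/either",
                items$id[bad_val], items$valence[bad_val]))
  }
  for (e in emotion_names()) {
    x <- items[[e]]
    bad <- is.na(x) | x < 0 | x > 1
    if (any(bad)) {
      add(sprintf("item '%s': %s relevance %s outside the unit interval [0,1]",
                  items$id[bad], e, format(x[bad])))
    }
  }
  no_kw <- lengths(items$keywords) == 0
  if (any(no_kw)) add(sprintf("item '%s': keywords must be non-empty", items$id[no_kw]))
  no_tag <- lengths(items$subtags) == 0
  if (any(no_tag)) add(sprintf("item '%s': subtags must be non-empty", items$id[no_tag]))

  for (i in seq_len(nrow(items))) {
    unknown_tag <- setdiff(items$subtags[[i]], tax$subtag)
    if (length(unknown_tag)) {
      add(sprintf("item '%s': unknown sub-tag(s): %s", items$id[i],
                  paste(unknown_tag, collapse = ", ")))
    }
    unknown_str <- setdiff(items$strengths[[i]], cat$strengths)
    if (length(unknown_str)) {
      add(sprintf("item '%s': unknown strength(s): %s", items$id[i],
                  paste(unknown_str, collapse = ", ")))
    }
  }

  step_ids <- items$id[items$kind == "step"]
  for (i in seq_len(nrow(items))) {
    rel <- items$related_ids[[i]]
    if (length(rel) && items$kind[i] != "step") {
      add(sprintf("item '%s': related_ids only allowed on steps", items$id[i]))
    }
    dangling <- setdiff(rel, step_ids)
    if (length(dangling)) {
      add(sprintf("item '%s': related_ids reference missing step(s): %s",
                  items$id[i], paste(dangling, collapse = ", ")))
    }
  }
  v
}

#' Validate a catalog
#'
#' Checks every catalog invariant (unique ids, valence and unit-interval
#' emotion bounds, sub-tag/strength membership, resolvable related links) and
#' reports every violation at once rather than stopping at the first.
#'
#' @param cat A `catalog` object.
#' @return Invisibly `cat`; errors with the full violation list otherwise.
#' @export
validate_catalog <- function(cat) {
  v <- catalog_violations(cat)
  if (length(v)) {
    rlang::abort(c("catalog validation failed:", stats::setNames(v, rep("x", length(v)))),
                 class = "steprec_validation_error")
  }
  invisible(cat)
}

item_from_record <- function(rec, where) {
  need <- c("id", "kind", "title", "valence", "emotion_relevance", "keywords", "subtags")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    rlang::abort(sprintf("catalog format error at %s: missing field(s) %s",
                         where, paste(missing, collapse = ", ")),
                 class = "steprec_format_error")
  }
  emo <- rec$emotion_relevance
  tibble::tibble(
    id = as.character(rec$id),
    kind = as.character(rec$kind),
    title = as.character(rec$title),
    valence = as.character(rec$valence),
    anger = as.numeric(emo$anger %||% NA_real_),
    disgust = as.numeric(emo$disgust %||% NA_real_),
    fear = as.numeric(emo$fear %||% NA_real_),
    joy = as.numeric(emo$joy %||% NA_real_),
    sadness = as.numeric(emo$sadness %||% NA_real_),
    keywords = list(as.character(unlist(rec$keywords))),
    subtags = list(as.character(unlist(rec$subtags))),
    strengths = list(as.character(unlist(rec$strengths))),
    related_ids = list(as.character(unlist(rec$related_ids)))
  )
}

#' Read a catalog file
#'
#' Reads a UTF-8 JSON catalog with top-level keys `taxonomy` (object mapping
#' parent tag to its sub-tags), `strengths` (array) and `items` (array of
#' records with `id`, `kind`, `title`, `valence`,
#' `emotion_relevance{anger,disgust,fear,joy,sadness}`, `keywords[]`,
#' `subtags[]`, `strengths[]`, `related_ids[]`). The loaded catalog is fully
#' validated; all invariant violations are reported together.
#'
#' @param path Path to a catalog JSON file.
#' @return A `catalog` object.
#' @seealso [save_catalog()], [example_catalog()]
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("catalog file not found: %s", path))
  }
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      rlang::abort(sprintf("catalog format error in %s: %s", path, conditionMessage(e)),
                   class = "steprec_format_error")
    }
  )
  for (key in c("taxonomy", "strengths", "items")) {
    if (is.null(raw[[key]])) {
      rlang::abort(sprintf("catalog format error in %s: missing top-level key '%s'",
                           path, key), class = "steprec_format_error")
    }
  }
  taxonomy <- purrr::imap(raw$taxonomy, function(subs, parent) {
    tibble::tibble(parent = parent, subtag = as.character(unlist(subs)))
  }) |> purrr::list_rbind()
  items <- purrr::imap(raw$items, function(rec, i) {
    item_from_record(rec, sprintf("items[%d]", i))
  }) |> purrr::list_rbind()
  if (is.null(items) || nrow(items) == 0) {
    items <- empty_items()
  }
  cat <- new_catalog(items, taxonomy, as.character(unlist(raw$strengths)))
  validate_catalog(cat)
  cat
}

empty_items <- function() {
  tibble::tibble(
    id = character(0), kind = character(0), title = character(0),
    valence = character(0), anger = numeric(0), disgust = numeric(0),
    fear = numeric(0), joy = numeric(0), sadness = numeric(0),
    keywords = list(), subtags = list(), strengths = list(),
    related_ids = list()
  )
}

#' Write a catalog file
#'
#' Serializes a catalog back to the JSON format read by [load_catalog()];
#' `load(save(load(f)))` reproduces `load(f)` field-for-field.
#'
#' @param cat A `catalog` object.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
save_catalog <- function(cat, path) {
  items <- purrr::map(seq_len(nrow(cat$items)), function(i) {
    it <- cat$items[i, ]
    list(
      id = it$id, kind = it$kind, title = it$title, valence = it$valence,
      emotion_relevance = as.list(stats::setNames(
        as.numeric(it[1, emotion_names()]), emotion_names())),
      keywords = as.list(it$keywords[[1]]),
      subtags = as.list(it$subtags[[1]]),
      strengths = as.list(it$strengths[[1]]),
      related_ids = as.list(it$related_ids[[1]])
    )
  })
  tax <- split(cat$taxonomy$subtag, cat$taxonomy$parent)
  tax <- tax[unique(cat$taxonomy$parent)]  # keep parent order
  out <- list(
    taxonomy = purrr::map(tax, as.list),
    strengths = as.list(cat$strengths),
    items = items
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Bundled example catalog
#'
#' Loads the small catalog shipped with the package: the canonical 3x3 tag
#' taxonomy, the 24 strengths, and a handful of synthetic steps and actions
#' (item-to-tag and item-to-strength assignments are invented, not taken from
#' any deployed site).
#'
#' @return A `catalog` object.
#' @export
example_catalog <- function() {
  load_catalog(system.file("extdata", "catalog.json", package = "steprec"))
}

#' Validate a user's strength selection
#'
#' Users choose exactly 5 of the 24 canonical strengths. The verdict is
#' accept only for 5 distinct canonical names; anything else is rejected with
#' reasons (never an error).
#'
#' @param chosen Character vector of chosen strength names.
#' @param cat A `catalog` object supplying the canonical strengths list.
#' @return A list with `ok` (logical) and `reasons` (character, empty when
#'   accepted).
#' @export
#' @examples
#' cat <- example_catalog()
#' validate_strength_selection(canonical_strengths()[1:5], cat)$ok
validate_strength_selection <- function(chosen, cat) {
  chosen <- as.character(chosen)
  reasons <- character(0)
  if (length(unique(chosen)) != 5L) {
    reasons <- c(reasons, sprintf(
      "cardinality: exactly 5 distinct strengths required, got %d",
      length(unique(chosen))))
  }
  unknown <- setdiff(chosen, cat$strengths)
  if (length(unknown)) {
    reasons <- c(reasons, sprintf("unknown strength: %s",
                                  paste(unknown, collapse = ", ")))
  }
  list(ok = length(reasons) == 0L, reasons = reasons)
}

#' Items carrying a sub-tag
#'
#' @param cat A `catalog` object.
#' @param subtag A sub-tag name from the catalog's taxonomy.
#' @return Tibble of items whose `subtags` contain `subtag`, sorted by title.
#' @export
items_by_subtag <- function(cat, subtag) {
  if (!subtag %in% cat$taxonomy$subtag) {
    rlang::abort(sprintf("unknown sub-tag: '%s'", subtag),
                 class = "steprec_domain_error")
  }
  cat$items |>
    dplyr::filter(purrr::map_lgl(.data$subtags, ~ subtag %in% .x)) |>
    dplyr::arrange(tolower(.data$title), .data$id)
}
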