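#' Basic text search over the catalog
#'
#' Case-insensitive substring match of the query against item titles,
#' keywords and sub-tags. Results are ranked by where the match occurred —
#' title matches first, then keyword matches, then tag matches — with ties
#' ordered alphabetically by title.
#'
#' @param query Search term; must be non-empty after trimming.
#' @param cat A `catalog` object.
#' @return Tibble of matching items with a `matched_via` column
#'   ("title", "keyword" or "subtag").
#' @export
search_catalog <- function(query, cat) {
  q <- tolower(trimws(query))
  if (!nzchar(q)) {
    rlang::abort("search query must be non-empty", class = "steprec_usage_error")
  }
  hit <- function(x) any(stringr::str_detect(tolower(x), stringr::fixed(q)))
  res <- cat$items |>
    dplyr::mutate(
      tier = dplyr::case_when(
        stringr::str_detect(tolower(.data$title), stringr::fixed(q)) ~ 1L,
        purrr::map_lgl(.data$keywords, hit) ~ 2L,
        purrr::map_lgl(.data$subtags, hit) ~ 3L,
        TRUE ~ NA_integer_
      )
    ) |>
    dplyr::filter(!is.na(.data$tier)) |>
    dplyr::arrange(.data$tier, tolower(.data$title), .data$id) |>
    dplyr::mutate(matched_via = c("title", "keyword", "subtag")[.data$tier]) |>
    dplyr::select(-"tier")
  res
}

#' All steps, alphabetically
#'
#' The browsable grid of every step, ordered case-insensitively by title
#' (ties stably by id).
#'
#' @param cat A `catalog` object.
#' @return Tibble of all steps.
#' @export
all_steps <- function(cat) {
  cat$items |>
    dplyr::filter(.data$kind == "step") |>
    dplyr::arrange(tolower(.data$title), .data$id)
}

rank_entries <- function(df, key_col, desc, k) {
  key <- df[[key_col]]
  ord <- if (desc) order(-xtfrm(key), df$step_id) else order(xtfrm(key), df$step_id)
  out <- df[ord, c("step_id", key_col)]
  names(out) <- c("step_id", "key")
  utils::head(tibble::as_tibble(out), k)
}

#' The four "Steps People are Taking" rankings
#'
#' Builds the four discovery lists from the visit log and Talking Point
#' comment counts:
#' * `recently_taken` — steps by latest visit timestamp, newest first;
#' * `got_people_talking` — steps by Talking Point comment count, most first;
#' * `taken_most_often` — steps by visit count, most first;
#' * `hidden_treasures` — steps by visit count, fewest first, including
#'   never-visited steps (count 0) ahead of everything — a modest counter to
#'   the informational cascade by which popular content stays popular.
#'
#' Ties are broken by step id; each list is truncated to `k` entries.
#'
#' @param events Tibble of usage events (see [read_events()]); step visits
#'   must reference catalog steps.
#' @param comments Tibble with columns `step_id`, `n_comments`.
#' @param cat A `catalog` object.
#' @param k Entries per list (default 10).
#' @return Named list of four tibbles (`step_id`, `key`), class
#'   `ranked_lists`.
#' @export
steps_people_are_taking <- function(events, comments, cat, k = 10L) {
  step_ids <- cat$items$id[cat$items$kind == "step"]
  ev <- dplyr::filter(tibble::as_tibble(events), .data$item_kind == "step")
  unknown <- setdiff(unique(ev$item_id), step_ids)
  if (length(unknown)) {
    rlang::abort(sprintf("event(s) reference unknown step(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "steprec_validation_error")
  }

  visited <- if (nrow(ev) == 0) {
    tibble::tibble(step_id = character(0),
                   latest = as.POSIXct(character(0), tz = "UTC"),
                   n_visits = integer(0))
  } else {
    ev |>
      dplyr::group_by(step_id = .data$item_id) |>
      dplyr::summarise(latest = max(.data$timestamp), n_visits = dplyr::n(),
                       .groups = "drop")
  }
  counts <- tibble::tibble(step_id = step_ids) |>
    dplyr::left_join(visited, by = "step_id") |>
    dplyr::mutate(n_visits = tidyr::replace_na(.data$n_visits, 0L))

  talking <- tibble::as_tibble(comments)
  names(talking)[1:2] <- c("step_id", "n_comments")
  talking <- dplyr::filter(talking, .data$n_comments > 0,
                           .data$step_id %in% step_ids)

  structure(list(
    recently_taken = rank_entries(
      dplyr::select(dplyr::filter(counts, .data$n_visits > 0),
                    "step_id", "latest"),
      "latest", TRUE, k),
    got_people_talking = rank_entries(talking, "n_comments", TRUE, k),
    taken_most_often = rank_entries(
      dplyr::filter(counts, .data$n_visits > 0), "n_visits", TRUE, k),
    hidden_treasures = rank_entries(counts, "n_visits", FALSE, k)
  ), class = "ranked_lists")
}

#' @export
print.ranked_lists <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":", if (nrow(x[[nm]])) paste(x[[nm]]$step_id, collapse = ", ")
        else "(empty)", "\n")
  }
  invisible(x)
}

#' Tidy ranked discovery lists
#'
#' @param x A `ranked_lists` object.
#' @param ... Unused.
#' @return Long tibble with columns `link_kind`, `rank`, `step_id`, `key`.
#' @exportS3Method generics::tidy
tidy.ranked_lists <- function(x, ...) {
  purrr::imap(x, function(df, nm) {
    tibble::tibble(link_kind = nm, rank = seq_len(nrow(df)),
                   step_id = df$step_id, key = as.numeric(df$key))
  }) |> purrr::list_rbind()
}
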