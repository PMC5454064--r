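access_paths <- function() {
  c("search", "menu", "tag_browse", "steps_recent", "steps_talking",
    "steps_often", "hidden_treasures", "strengths_page",
    "moderator_suggestion", "related_after_step", "newsfeed_suggestion",
    "post_suggestion", "other")
}

four_link_paths <- function() {
  c("steps_recent", "steps_talking", "steps_often", "hidden_treasures")
}

ledger_statuses <- function() {
  c("pending", "completed", "client_dismissed", "moderator_dismissed")
}

#' Read a usage-event log
#'
#' Tracked content visits, one per row, as CSV with header
#' `user_id,item_id,item_kind,access_path,timestamp` (ISO-8601 timestamps).
#' `access_path` records which site feature led to the visit (search, menu,
#' tag browse, the four "Steps People are Taking" links, the strengths page,
#' a moderator suggestion, the post-step related list, a newsfeed
#' suggestion, a post-triggered suggestion, or other). Unknown paths or
#' kinds are a validation error.
#'
#' @param path CSV file path.
#' @return Tibble of events with parsed timestamps.
#' @export
read_events <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  need <- c("user_id", "item_id", "item_kind", "access_path", "timestamp")
  missing <- setdiff(need, hdr)
  if (length(missing)) {
    rlang::abort(sprintf("event log format error: missing column(s) %s",
                         paste(missing, collapse = ", ")),
                 class = "steprec_format_error")
  }
  ev <- readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(),
    item_id = readr::col_character(),
    item_kind = readr::col_character(),
    access_path = readr::col_character(),
    timestamp = readr::col_datetime(format = "")
  ), progress = FALSE)
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  bad_path <- !ev$access_path %in% access_paths()
  bad_kind <- !ev$item_kind %in% c("step", "action")
  bad_ts <- is.na(ev$timestamp)
  msgs <- c(
    if (any(bad_path)) sprintf("row %d: unknown access_path '%s'",
                               which(bad_path), ev$access_path[bad_path]),
    if (any(bad_kind)) sprintf("row %d: unknown item_kind '%s'",
                               which(bad_kind), ev$item_kind[bad_kind]),
    if (any(bad_ts)) sprintf("row %d: unparseable timestamp", which(bad_ts))
  )
  if (length(msgs)) {
    rlang::abort(c("event log validation failed:",
                   stats::setNames(msgs, rep("x", length(msgs)))),
                 class = "steprec_validation_error")
  }
  invisible(ev)
}

#' Write a usage-event log
#'
#' @param events Tibble of events.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' Read a moderator-suggestion ledger
#'
#' One row per moderator-to-user content suggestion, as CSV with header
#' `record_id,moderator_id,user_id,item_id,status`. A suggestion is
#' `completed` when the user did the suggested content (recorded
#' automatically), `client_dismissed` or `moderator_dismissed` when either
#' party dismissed it, and `pending` otherwise.
#'
#' @param path CSV file path.
#' @return Tibble of ledger records.
#' @export
read_ledger <- function(path) {
  led <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("record_id", "moderator_id", "user_id", "item_id", "status")
  missing <- setdiff(need, names(led))
  if (length(missing)) {
    rlang::abort(sprintf("ledger format error: missing column(s) %s",
                         paste(missing, collapse = ", ")),
                 class = "steprec_format_error")
  }
  bad <- !led$status %in% ledger_statuses()
  if (any(bad)) {
    rlang::abort(sprintf("ledger validation failed: row %s has unknown status '%s'",
                         paste(which(bad), collapse = ","),
                         paste(unique(led$status[bad]), collapse = ",")),
                 class = "steprec_validation_error")
  }
  led
}

#' Write a moderator-suggestion ledger
#'
#' @param ledger Tibble of ledger records.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_csv(ledger, path, progress = FALSE)
  invisible(path)
}

#' Moderator-suggestion outcomes
#'
#' Tallies a suggestion ledger into one count per outcome status plus the
#' total and the completion fraction (`completed / total`, 0 for an empty
#' ledger). The counts always partition the ledger.
#'
#' @param ledger Tibble of ledger records (see [read_ledger()]).
#' @return One-row tibble: `total`, `completed`, `client_dismissed`,
#'   `moderator_dismissed`, `pending`, `completion_fraction`.
#' @export
suggestion_outcomes <- function(ledger) {
  bad <- !ledger$status %in% ledger_statuses()
  if (any(bad)) {
    rlang::abort(sprintf("unknown status value(s): %s",
                         paste(unique(ledger$status[bad]), collapse = ", ")),
                 class = "steprec_validation_error")
  }
  n <- nrow(ledger)
  cnt <- function(s) sum(ledger$status == s)
  tibble::tibble(
    total = n,
    completed = cnt("completed"),
    client_dismissed = cnt("client_dismissed"),
    moderator_dismissed = cnt("moderator_dismissed"),
    pending = cnt("pending"),
    completion_fraction = if (n == 0) 0 else cnt("completed") / n
  )
}

#' Shares of the four "Steps People are Taking" links
#'
#' Among all step visits arriving through the four discovery links, the
#' percentage arriving through each. Shares are reported both as exact
#' percentages and rounded to the nearest integer; they sum to 100 up to
#' rounding.
#'
#' @param events Tibble of usage events.
#' @return Tibble with one row per link: `access_path`, `n`, `share`
#'   (exact percent), `percent` (nearest integer).
#' @export
four_link_share <- function(events) {
  ev <- dplyr::filter(tibble::as_tibble(events),
                      .data$access_path %in% four_link_paths())
  if (nrow(ev) == 0) {
    rlang::abort("no events on any of the four discovery links: shares undefined",
                 class = "steprec_domain_error")
  }
  tibble::tibble(access_path = four_link_paths()) |>
    dplyr::left_join(dplyr::count(ev, .data$access_path), by = "access_path") |>
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      share = 100 * .data$n / sum(.data$n),
      percent = round(.data$share)
    )
}

#' Share of all tracked visits from one access path
#'
#' The percentage of all tracked step/action visit events attributed to a
#' given access path: `100 * count(path) / count(all events)`. The
#' denominator can be restricted to step visits or action visits via `kind`.
#'
#' @param events Tibble of usage events.
#' @param path One access-path name.
#' @param kind "both" (default), "step" or "action".
#' @return A single percentage (numeric).
#' @export
tracked_visit_share <- function(events, path, kind = c("both", "step", "action")) {
  kind <- match.arg(kind)
  stopifnot(path %in% access_paths())
  ev <- tibble::as_tibble(events)
  if (kind != "both") ev <- dplyr::filter(ev, .data$item_kind == kind)
  if (nrow(ev) == 0) {
    rlang::abort("empty event log: share undefined",
                 class = "steprec_domain_error")
  }
  100 * sum(ev$access_path == path) / nrow(ev)
}
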