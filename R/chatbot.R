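chat_replies <- function() {
  yaml::read_yaml(system.file("extdata", "chatbot_replies.yaml",
                              package = "steprec"))
}

#' Start a conversational search session
#'
#' The assistant is a deterministic slot-filling finite-state machine over
#' the phases greet -> elicit_mood -> elicit_topic -> confirm -> done. It
#' elicits how the user feels and what they want help with, then hands the
#' concatenated text to the suggestion engine exactly as if it were a
#' newsfeed post. A blank reply in an eliciting phase triggers a reprompt;
#' after two reprompts the phase is skipped with an empty slot, so every
#' dialog terminates in a bounded number of turns.
#'
#' @return A fresh `chat_state`.
#' @export
chat_state <- function() {
  structure(
    list(
      phase = "greet",
      slots = list(mood_text = "", topic_text = ""),
      reprompt_count = 0L,
      transcript = tibble::tibble(speaker = character(0), text = character(0))
    ),
    class = "chat_state"
  )
}

#' @export
print.chat_state <- function(x, ...) {
  cat(sprintf("<chat_state: phase %s, %d turns>\n", x$phase, nrow(x$transcript)))
  invisible(x)
}

log_turn <- function(state, speaker, text) {
  state$transcript <- dplyr::bind_rows(
    state$transcript, tibble::tibble(speaker = speaker, text = text))
  state
}

elicit <- function(state, utterance, slot, next_phase, r, reprompt_key, next_key) {
  if (nzchar(trimws(utterance))) {
    state$slots[[slot]] <- trimws(utterance)
    state$phase <- next_phase
    state$reprompt_count <- 0L
    return(list(state = state, reply = r[[next_key]]))
  }
  if (state$reprompt_count < 2L) {
    state$reprompt_count <- state$reprompt_count + 1L
    return(list(state = state, reply = r[[reprompt_key]]))
  }
  # reprompt cap reached: skip the phase with an empty slot
  state$phase <- next_phase
  state$reprompt_count <- 0L
  list(state = state, reply = paste(r$skipped, r[[next_key]]))
}

#' Advance the chat by one user turn
#'
#' Applies the FSM transition table to one user utterance and returns the
#' next state plus the assistant's reply. All inputs are handled
#' conversationally; there are no error conditions.
#'
#' @param state A `chat_state`.
#' @param utterance The user's text for this turn (may be blank).
#' @return List with elements `state` (next `chat_state`) and `reply`.
#' @export
#' @examples
#' s <- chat_state()
#' turn <- chat_step(s, "hello")
#' turn$state$phase
chat_step <- function(state, utterance) {
  stopifnot(inherits(state, "chat_state"))
  r <- chat_replies()
  state <- log_turn(state, "user", utterance)
  out <- switch(
    state$phase,
    greet = {
      state$phase <- "elicit_mood"
      list(state = state, reply = r$greet)
    },
    elicit_mood = elicit(state, utterance, "mood_text", "elicit_topic", r,
                         "reprompt_mood", "elicit_topic"),
    elicit_topic = elicit(state, utterance, "topic_text", "confirm", r,
                          "reprompt_topic", "confirm"),
    confirm = {
      state$phase <- "done"
      list(state = state, reply = r$done)
    },
    done = list(state = state, reply = r$done)
  )
  out$state <- log_turn(out$state, "bot", out$reply)
  out
}

#' Finish a chat and build the pre-chat profile
#'
#' Once the dialog reaches the `done` phase, the elicited mood and topic
#' text are concatenated into a pseudo-post and routed through the standard
#' analysis and suggestion pipeline — the bot is a front-end to the same
#' scoring path as a newsfeed post, never a second one. The result is the
#' pre-chat profile a human moderator sees before accepting the chat.
#'
#' @param state A `chat_state` in phase `done`.
#' @param cat A `catalog` object.
#' @param cfg A [scoring_config()].
#' @param lex A `lexicon` object.
#' @return A `pre_chat_profile`: the pseudo-post `text`, its `analysis`, the
#'   `suggestion` result, and the full `transcript`.
#' @export
finish_chat <- function(state, cat, cfg = scoring_config(),
                        lex = default_lexicon()) {
  if (!identical(state$phase, "done")) {
    rlang::abort(sprintf("chat not finished: phase is '%s', not 'done'", state$phase),
                 class = "steprec_state_error")
  }
  text <- trimws(paste(state$slots$mood_text, state$slots$topic_text))
  structure(
    list(
      text = text,
      analysis = analyze_post(text, lex),
      suggestion = suggest(text, cat, cfg = cfg, lex = lex),
      transcript = state$transcript
    ),
    class = "pre_chat_profile"
  )
}

#' @export
print.pre_chat_profile <- function(x, ...) {
  cat("<pre_chat_profile>\n")
  cat(sprintf("  elicited text: %s\n",
              if (nzchar(x$text)) x$text else "(none)"))
  step <- if (is.na(x$suggestion$step)) "(none)" else x$suggestion$step
  act <- if (is.na(x$suggestion$action)) "(none)" else x$suggestion$action
  cat(sprintf("  sentiment %+.3f (%s); suggested step %s, action %s\n",
              x$analysis$sentiment, sentiment_class(x$analysis$sentiment),
              step, act))
  invisible(x)
}

#' Glance at a pre-chat profile
#'
#' @param x A `pre_chat_profile`.
#' @param ... Unused.
#' @return One-row tibble summarizing the elicited analysis and suggestion.
#' @exportS3Method generics::glance
glance.pre_chat_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(text = x$text),
    glance(x$suggestion),
    tibble::tibble(n_turns = nrow(x$transcript))
  )
}
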