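#' Start an adaptive screening session
#'
#' A session walks a respondent through the battery tier by tier: Tier 1 is
#' the distress gateway (negative outcome terminates), a positive outcome
#' presents all Tier-2 short forms together, and each positive Tier-2 gate
#' opens its full scale in Tier 3 minus the items already answered in Tier 2
#' (their responses carry over into the full-scale score). Sessions are
#' immutable: [submit_responses()] returns an advanced copy and appends to an
#' append-only event log, so any session can be audited and replayed.
#'
#' @param battery An `itap_battery`.
#' @param session_id Optional identifier stored in the session log.
#' @return An `itap_session` at Tier 1; [pending_items()] lists the items to
#'   administer next.
#' @export
start_session <- function(battery, session_id = "session-1") {
  if (!inherits(battery, "itap_battery"))
    stop("start_session requires an itap_battery")
  structure(list(
    session_id = session_id,
    battery = battery,
    tier = "tier1",
    responses = stats::setNames(numeric(0), character(0)),
    administered = character(0),
    gated = character(0),
    tier_outcomes = list(),
    termination_reason = NULL,
    events = list()
  ), class = "itap_session")
}

#' Items pending at the session's current tier
#'
#' @param session An `itap_session`.
#' @return Character vector of item ids (empty when the session is done).
#' @export
pending_items <- function(session) {
  b <- session$battery
  switch(session$tier,
    tier1 = b$scales[[b$tier1]]$item_ids,
    tier2 = unlist(lapply(b$scales[b$tier2], `[[`, "item_ids"),
                   use.names = FALSE),
    tier3 = unlist(lapply(session$gated, remainder_items, battery = b),
                   use.names = FALSE),
    done = character(0))
}

#' Submit responses for the pending items and advance the session
#'
#' Responses must cover exactly the pending items (in any order) and respect
#' each item's ordinal range. Tier outcomes are dichotomised at the
#' configured cutoffs; a negative Tier-1 outcome or a negative outcome on
#' all four Tier-2 gates terminates the session.
#'
#' @param session An `itap_session` that is not done.
#' @param responses Named numeric vector or list, names are item ids.
#' @return The advanced `itap_session`.
#' @export
submit_responses <- function(session, responses) {
  if (session$tier == "done")
    stop("session is finished (", session$termination_reason,
         "); no further responses accepted")
  responses <- unlist(responses)
  pending <- pending_items(session)
  extra <- setdiff(names(responses), pending)
  missing <- setdiff(pending, names(responses))
  if (length(extra))
    stop("responses for items not pending: ", paste(extra, collapse = ", "))
  if (length(missing))
    stop("missing responses for pending items: ",
         paste(missing, collapse = ", "))

  b <- session$battery
  info <- b$items[match(pending, b$items$item_id), ]
  vals <- responses[pending]
  bad <- which(is.na(vals) | vals < info$min | vals > info$max |
                 vals != round(vals))
  if (length(bad))
    stop("out-of-range response for item ", pending[bad[1]], ": ",
         vals[bad[1]])

  tier_no <- match(session$tier, c("tier1", "tier2", "tier3"))
  session$responses <- c(session$responses, vals)
  session$administered <- c(session$administered, pending)
  session$events <- c(session$events, lapply(pending, function(id)
    list(tier = tier_no, item_id = id, value = unname(vals[id]))))

  advance(session)
}

advance <- function(session) {
  b <- session$battery
  if (session$tier == "tier1") {
    s <- b$scales[[b$tier1]]
    score <- score_scale(session$responses, s)
    pos <- classify(score, s$cutoff)
    session$tier_outcomes[[b$tier1]] <- list(score = score, positive = pos)
    if (pos) {
      session$tier <- "tier2"
    } else {
      session$tier <- "done"
      session$termination_reason <- "tier1_negative"
    }
  } else if (session$tier == "tier2") {
    gated <- character(0)
    for (sid in b$tier2) {
      s <- b$scales[[sid]]
      score <- score_scale(session$responses, s)
      pos <- classify(score, s$cutoff)
      session$tier_outcomes[[sid]] <- list(score = score, positive = pos)
      if (pos) gated <- c(gated, s$parent)
    }
    if (length(gated)) {
      session$gated <- gated
      session$tier <- "tier3"
    } else {
      session$tier <- "done"
      session$termination_reason <- "tier2_all_negative"
    }
  } else if (session$tier == "tier3") {
    for (sid in session$gated) {
      s <- b$scales[[sid]]
      score <- score_scale(session$responses, s)  # includes tier-2 carry-over
      session$tier_outcomes[[sid]] <- list(score = score,
                                           positive = classify(score, s$cutoff))
    }
    session$tier <- "done"
    session$termination_reason <- "completed"
  }
  session
}

#' Full-scale score including Tier-2 carry-over
#'
#' The score of a Tier-3 full scale computed over the union of the Tier-2
#' short-form responses and the Tier-3 remainder responses; identical to
#' scoring a non-adaptive administration of the same item values.
#'
#' @param session An `itap_session` in which the scale's items have all been
#'   answered.
#' @param full_scale_id A tier-3 scale id.
#' @return Integer score.
#' @export
full_score_with_carryover <- function(session, full_scale_id) {
  s <- session$battery$scales[[full_scale_id]]
  if (is.null(s) || s$tier != 3) stop("not a tier-3 full scale: ", full_scale_id)
  if (!all(s$item_ids %in% names(session$responses)))
    stop("scale ", full_scale_id, " not fully administered in this session")
  score_scale(session$responses, s)
}

#' Finalise a completed session into a screening result
#'
#' A disorder screens positive only when all three tiers agree: Tier 1
#' positive, its Tier-2 gate positive, and the full-scale score at or above
#' the Tier-3 cutoff.
#'
#' @param session A finished `itap_session`.
#' @return An `itap_result`: per disorder the gate and full-scale scores and
#'   the screen flag, plus the distress score, items administered and
#'   termination reason.
#' @export
finalize <- function(session) {
  if (session$tier != "done")
    stop("session not finished; current tier: ", session$tier)
  b <- session$battery
  t1 <- session$tier_outcomes[[b$tier1]]
  rows <- lapply(seq_along(b$tier3), function(i) {
    full_id <- b$tier3[i]; gate_id <- b$tier2[i]
    gate <- session$tier_outcomes[[gate_id]]
    full <- session$tier_outcomes[[full_id]]
    data.frame(
      disorder = b$scales[[full_id]]$disorder,
      gate_scale = gate_id, full_scale = full_id,
      gate_score = if (is.null(gate)) NA_integer_ else gate$score,
      gate_positive = if (is.null(gate)) FALSE else gate$positive,
      full_score = if (is.null(full)) NA_integer_ else full$score,
      screen_positive = t1$positive &&
        !is.null(gate) && gate$positive &&
        !is.null(full) && full$positive,
      stringsAsFactors = FALSE)
  })
  structure(list(
    disorders = do.call(rbind, rows),
    distress_score = t1$score,
    tier1_positive = t1$positive,
    items_administered = length(session$administered),
    termination_reason = session$termination_reason,
    session_id = session$session_id
  ), class = "itap_result")
}

#' @export
print.itap_result <- function(x, ...) {
  cat("<itap_result>", x$session_id, "-", x$termination_reason, "\n")
  cat("  distress score:", x$distress_score,
      if (x$tier1_positive) "(positive)" else "(negative)", "\n")
  cat("  items administered:", x$items_administered, "\n")
  print(x$disorders, row.names = FALSE)
  invisible(x)
}

#' @export
print.itap_session <- function(x, ...) {
  cat("<itap_session>", x$session_id, "- at", x$tier, "\n")
  cat("  administered:", length(x$administered), "items;",
      length(pending_items(x)), "pending\n")
  invisible(x)
}

#' Administer a complete response vector adaptively
#'
#' Feeds a full 56-item response set through the engine on demand, exactly
#' as an interactive respondent would experience it. Items the tiers never
#' open are left unasked.
#'
#' @param battery An `itap_battery`.
#' @param responses Named numeric vector/list covering (at least) every item
#'   the adaptive procedure requests.
#' @param session_id Identifier for the session log.
#' @return The finalised `itap_result`.
#' @export
administer_complete <- function(battery, responses, session_id = "replay") {
  responses <- unlist(responses)
  session <- start_session(battery, session_id)
  while (session$tier != "done") {
    pending <- pending_items(session)
    session <- submit_responses(session, responses[pending])
  }
  finalize(session)
}

#' Write / read / replay a session event log
#'
#' The log is JSON with a stable field order:
#' `{session_id, battery_fingerprint, termination_reason, events: [...]}`.
#' `replay_session()` re-feeds the logged events through the engine against
#' a battery and returns the reconstructed session, which is identical in
#' state to the one that produced the log.
#'
#' @param session A finished or in-progress `itap_session`.
#' @param path File path for the JSON log.
#' @return `write_session_log()` the path, invisibly; `read_session_log()`
#'   the parsed log; `replay_session()` an `itap_session`.
#' @export
write_session_log <- function(session, path) {
  log <- list(
    session_id = session$session_id,
    battery_fingerprint = session$battery$fingerprint,
    termination_reason = if (is.null(session$termination_reason)) NA
                         else session$termination_reason,
    events = session$events)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' @rdname write_session_log
#' @param log A parsed session log (from [read_session_log()]).
#' @param battery The battery the log was recorded against.
#' @export
replay_session <- function(log, battery) {
  if (!identical(log$battery_fingerprint, battery$fingerprint))
    stop("session log was recorded against a different battery (fingerprint ",
         log$battery_fingerprint, " != ", battery$fingerprint, ")")
  session <- start_session(battery, log$session_id)
  tiers <- vapply(log$events, `[[`, numeric(1), "tier")
  for (tno in sort(unique(tiers))) {
    ev <- log$events[tiers == tno]
    vals <- stats::setNames(
      vapply(ev, `[[`, numeric(1), "value"),
      vapply(ev, `[[`, character(1), "item_id"))
    session <- submit_responses(session, vals)
  }
  session
}
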