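#' Round half away from zero
#'
#' Reporting convention for percentages and kappa: round-half-up (ties away
#' from zero), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Apply the tiered screening logic to a complete response dataset
#'
#' Retrospective simulation: every respondent answered every item, and the
#' tier gates are applied to the recorded scores to determine what an
#' adaptive administration would have asked and concluded. Implemented as a
#' vectorised computation over the score matrix; it is guaranteed (and
#' property-tested) to agree exactly with feeding each row through the
#' adaptive engine.
#'
#' @param dataset Wide response data frame: `id` plus one column per battery
#'   item, complete.
#' @param battery An `itap_battery`.
#' @param strict If `TRUE` (default) a respondent with any missing item is an
#'   error; otherwise such rows are dropped with a warning.
#' @return A data frame of class `itap_results`, one row per respondent:
#'   tier-1 score/flag, per-disorder gate and full scores and screen flags,
#'   `items_administered`, `termination_reason`.
#' @export
simulate_tiered <- function(dataset, battery, strict = TRUE) {
  item_cols <- battery$items$item_id
  missing_cols <- setdiff(item_cols, names(dataset))
  if (length(missing_cols))
    stop("dataset lacks item columns: ", paste(missing_cols, collapse = ", "))
  incomplete <- rowSums(is.na(dataset[, item_cols])) > 0
  if (any(incomplete)) {
    if (strict)
      stop("incomplete responses for respondent(s): ",
           paste(dataset$id[incomplete], collapse = ", "))
    warning("dropping ", sum(incomplete), " respondent(s) with missing items")
    dataset <- dataset[!incomplete, , drop = FALSE]
  }

  t1 <- battery$scales[[battery$tier1]]
  n_tier2 <- sum(lengths(lapply(battery$scales[battery$tier2], `[[`, "item_ids")))
  out <- data.frame(id = dataset$id)
  out$tier1_score <- as.integer(rowSums(dataset[, t1$item_ids, drop = FALSE]))
  out$tier1_positive <- classify(out$tier1_score, t1$cutoff)

  items_admin <- length(t1$item_ids) + ifelse(out$tier1_positive, n_tier2, 0L)
  any_gate <- rep(FALSE, nrow(dataset))
  for (i in seq_along(battery$tier3)) {
    full <- battery$scales[[battery$tier3[i]]]
    gate <- battery$scales[[battery$tier2[i]]]
    d <- full$disorder
    gate_score <- as.integer(rowSums(dataset[, gate$item_ids, drop = FALSE]))
    full_score <- as.integer(rowSums(dataset[, full$item_ids, drop = FALSE]))
    gate_pos <- out$tier1_positive & classify(gate_score, gate$cutoff)
    out[[paste0("gate_score_", d)]] <- gate_score
    out[[paste0("gate_positive_", d)]] <- gate_pos
    out[[paste0("full_score_", d)]] <- full_score
    out[[paste0("screen_", d)]] <- gate_pos & classify(full_score, full$cutoff)
    items_admin <- items_admin +
      ifelse(gate_pos, length(remainder_items(battery, full$scale_id)), 0L)
    any_gate <- any_gate | gate_pos
  }
  out$items_administered <- as.integer(items_admin)
  out$termination_reason <- ifelse(!out$tier1_positive, "tier1_negative",
                            ifelse(!any_gate, "tier2_all_negative", "completed"))
  class(out) <- c("itap_results", "data.frame")
  out
}

#' Item burden and its reduction against full-scale administration
#'
#' `item_burden()` is the number of items a respondent answered.
#' `burden_reduction()` expresses it as a percentage reduction relative to
#' administering all Tier-3 full scales non-adaptively (43 items in the
#' default battery; the Tier-1 gateway scale is not part of the baseline, so
#' a respondent who completes everything has a negative reduction, i.e. an
#' increased burden). Reported to one decimal, round-half-up.
#'
#' @param result An `itap_result` (engine), an `itap_results` data frame
#'   (tier simulation), or a plain count of administered items.
#' @param battery Battery defining the full-scale baseline.
#' @return `item_burden()`: integer vector; `burden_reduction()`: numeric
#'   percentage(s), one decimal.
#' @export
item_burden <- function(result) {
  if (inherits(result, "itap_result")) return(result$items_administered)
  if (inherits(result, "itap_results")) return(result$items_administered)
  as.integer(result)
}

#' @rdname item_burden
#' @export
burden_reduction <- function(result, battery = default_battery()) {
  baseline <- sum(vapply(battery$scales[battery$tier3],
                         function(s) length(s$item_ids), integer(1)))
  round_half_up((1 - item_burden(result) / baseline) * 100, 1)
}

#' Per-tier culling report
#'
#' Characterises each tier's continuation decision against reference
#' diagnosis labels: who continues, who is terminated, and the TP/FP/TN/FN
#' of that decision per disorder and for "any" diagnosis (a terminated case
#' is a false negative of the continuation decision). At every tier the four
#' cells sum to the respondents entering that tier.
#'
#' @param dataset Complete wide response data frame.
#' @param battery An `itap_battery`.
#' @param labels Reference labels: data frame `id` + 0/1 or logical columns
#'   per disorder (see [read_labels()]).
#' @return A `culling_report` list: per tier the entering/continuing/
#'   terminated counts and a decision data frame with sensitivity and
#'   specificity (proportions in \[0, 1\]).
#' @export
culling_report <- function(dataset, battery, labels) {
  res <- simulate_tiered(dataset, battery)
  lab <- align_labels(labels, res$id)
  disorders <- disorder_names(battery)
  lab$any <- Reduce(`|`, lab[disorders])

  decision_df <- function(continues, entering) {
    rows <- lapply(c(disorders, "any"), function(d) {
      y <- lab[[d]][entering]; x <- continues[entering]
      data.frame(disorder = d,
                 tp = sum(x & y), fp = sum(x & !y),
                 fn = sum(!x & y), tn = sum(!x & !y))
    })
    df <- do.call(rbind, rows)
    df$sensitivity <- ifelse(df$tp + df$fn > 0, df$tp / (df$tp + df$fn), NA)
    df$specificity <- ifelse(df$tn + df$fp > 0, df$tn / (df$tn + df$fp), NA)
    df
  }

  n <- nrow(res)
  entering1 <- rep(TRUE, n)
  cont1 <- res$tier1_positive
  entering2 <- cont1
  cont2_any <- res$termination_reason == "completed"

  tiers <- list(
    tier1 = list(entering = n, continuing = sum(cont1),
                 terminated = n - sum(cont1),
                 decisions = decision_df(cont1, entering1)),
    tier2 = list(entering = sum(entering2), continuing = sum(cont2_any),
                 terminated = sum(entering2) - sum(cont2_any),
                 decisions = decision_df(cont2_any, entering2)))

  # tier-3 decision per disorder among respondents whose gate opened
  rows <- lapply(disorders, function(d) {
    entering <- res[[paste0("gate_positive_", d)]]
    x <- res[[paste0("screen_", d)]][entering]; y <- lab[[d]][entering]
    data.frame(disorder = d, entering = sum(entering),
               tp = sum(x & y), fp = sum(x & !y),
               fn = sum(!x & y), tn = sum(!x & !y))
  })
  tiers$tier3 <- list(decisions = do.call(rbind, rows))

  structure(list(n = n, baseline_items = sum(vapply(
    battery$scales[battery$tier3], function(s) length(s$item_ids),
    integer(1))), tiers = tiers), class = "culling_report")
}

#' @export
print.culling_report <- function(x, ...) {
  cat("<culling_report> N =", x$n, "\n")
  for (t in c("tier1", "tier2")) {
    ti <- x$tiers[[t]]
    cat(sprintf("  %s: %d entering, %d continue, %d terminated\n",
                t, ti$entering, ti$continuing, ti$terminated))
  }
  cat("  tier1 continuation decisions:\n")
  print(x$tiers$tier1$decisions, row.names = FALSE)
  invisible(x)
}

disorder_names <- function(battery)
  vapply(battery$scales[battery$tier3], function(s) s$disorder, character(1),
         USE.NAMES = FALSE)

# order label rows by ids, coerce disorder columns to logical
align_labels <- function(labels, ids) {
  if (!"id" %in% names(labels)) stop("labels need an 'id' column")
  idx <- match(ids, labels$id)
  if (anyNA(idx))
    stop("labels missing for respondent(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  lab <- labels[idx, , drop = FALSE]
  for (col in setdiff(names(lab), "id")) lab[[col]] <- as.logical(lab[[col]])
  lab
}
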