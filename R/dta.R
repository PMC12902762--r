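#' Construct a 2x2 confusion table
#'
#' Index-test positives against reference-standard positives.
#'
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be non-negative integers")
  n <- sum(cells)
  if (n == 0) stop("empty confusion table")
  structure(as.list(c(cells, n = n)), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> n =", x$n, "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("ref+", "ref-")))
  print(t(m))
  invisible(x)
}

#' Cross-classify index-test flags against reference labels
#'
#' @param test_flags Logical vector, or a results data frame (`id` +
#'   `screen_<disorder>` columns as produced by [simulate_tiered()], or
#'   plain `<disorder>` columns).
#' @param labels Logical vector aligned with `test_flags`, or a labels data
#'   frame (`id` + disorder columns) aligned by `id`.
#' @param disorder Disorder name, required for the data-frame form.
#' @return A `confusion_table`.
#' @export
confusion <- function(test_flags, labels, disorder = NULL) {
  if (is.data.frame(test_flags)) {
    if (is.null(disorder))
      stop("disorder must be named when passing data frames")
    lab <- align_labels(labels, test_flags$id)
    col <- if (paste0("screen_", disorder) %in% names(test_flags))
      paste0("screen_", disorder) else disorder
    if (!col %in% names(test_flags))
      stop("no test flags for disorder ", disorder)
    test_flags <- as.logical(test_flags[[col]])
    labels <- lab[[disorder]]
  }
  if (length(test_flags) == 0) stop("empty input")
  if (length(test_flags) != length(labels))
    stop("test flags and labels differ in length")
  confusion_table(tp = sum(test_flags & labels),
                  fp = sum(test_flags & !labels),
                  fn = sum(!test_flags & labels),
                  tn = sum(!test_flags & !labels))
}

#' Reconstruct a confusion table from published marginals
#'
#' Given the sample size, the number of reference-standard positives, the
#' number of index-test positives and the number of concordant positives,
#' the remaining cells are determined: `fp = test_pos - tp`,
#' `fn = ref_pos - tp`, `tn = n - tp - fp - fn`.
#'
#' @param n Sample size.
#' @param ref_pos Reference-standard positives.
#' @param test_pos Index-test positives.
#' @param tp Concordant (true) positives.
#' @return A `confusion_table`.
#' @export
confusion_from_margins <- function(n, ref_pos, test_pos, tp) {
  confusion_table(tp = tp, fp = test_pos - tp, fn = ref_pos - tp,
                  tn = n - test_pos - ref_pos + tp)
}

#' Diagnostic test accuracy metrics with Wald confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, and accuracy, each as a percentage with a 95% Wald
#' interval `p +- 1.96 sqrt(p(1-p)/m)` over its own denominator `m`, clipped
#' to \[0, 100\]. Cohen's kappa is attached. A metric whose denominator is
#' zero is flagged undefined (`NA`), the others are still computed; nothing
#' is silently reported as 0 or 100.
#'
#' Point estimates and bounds are kept at full precision; rounding (1
#' decimal for percentages, 2 for kappa, half-up) happens only in the
#' reporting layer ([write_report()]).
#'
#' @param table A `confusion_table`.
#' @param z Normal quantile for the interval (default 1.96 for 95%).
#' @return A `dta_report`: data frame `metrics` (metric, percent, lower,
#'   upper, defined), `kappa`, `n_pos_index` = tp+fp, and the input table.
#' @export
dta_metrics <- function(table, z = 1.96) {
  stopifnot(inherits(table, "confusion_table"))
  wald <- function(num, den) {
    if (den == 0)
      return(data.frame(percent = NA_real_, lower = NA_real_,
                        upper = NA_real_, defined = FALSE))
    p <- num / den
    half <- z * sqrt(p * (1 - p) / den)
    data.frame(percent = 100 * p,
               lower = max(0, 100 * (p - half)),
               upper = min(100, 100 * (p + half)),
               defined = TRUE)
  }
  metrics <- rbind(
    sensitivity = wald(table$tp, table$tp + table$fn),
    specificity = wald(table$tn, table$tn + table$fp),
    ppv         = wald(table$tp, table$tp + table$fp),
    npv         = wald(table$tn, table$tn + table$fn),
    accuracy    = wald(table$tp + table$tn, table$n))
  metrics <- cbind(metric = rownames(metrics), metrics)
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 kappa = cohen_kappa(table),
                 n_pos_index = table$tp + table$fp,
                 table = table),
            class = "dta_report")
}

#' @export
print.dta_report <- function(x, ...) {
  cat("<dta_report> n =", x$table$n, " index positives =", x$n_pos_index,
      " kappa =", format_kappa(x$kappa), "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$defined[i])
      cat(sprintf("  %-12s %5.1f (%.1f-%.1f)\n", m$metric[i],
                  round_half_up(m$percent[i], 1),
                  round_half_up(m$lower[i], 1), round_half_up(m$upper[i], 1)))
    else
      cat(sprintf("  %-12s undefined (zero denominator)\n", m$metric[i]))
  }
  invisible(x)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (tp+tn)/n} and expected agreement from the
#' marginals \eqn{p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn))/n^2}.
#'
#' @param table A `confusion_table`.
#' @return Kappa in \[-1, 1\]; `NA` with a warning when the expected
#'   agreement is 1 (kappa undefined).
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$n
  po <- (table$tp + table$tn) / n
  pe <- ((table$tp + table$fp) * (table$tp + table$fn) +
         (table$fn + table$tn) * (table$fp + table$tn)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Any-disorder flag
#'
#' Logical OR over the four disorder flags per respondent; works on a
#' results data frame (`screen_*` columns), a labels data frame, or a
#' logical matrix.
#'
#' @param x Flags or labels.
#' @param disorders Disorder names (default: depression, anxiety, ptsd,
#'   insomnia).
#' @return Logical vector.
#' @export
any_disorder <- function(x, disorders = c("depression", "anxiety",
                                          "ptsd", "insomnia")) {
  if (is.data.frame(x)) {
    cols <- if (all(paste0("screen_", disorders) %in% names(x)))
      paste0("screen_", disorders) else disorders
    if (!all(cols %in% names(x)))
      stop("flags for ", paste(setdiff(cols, names(x)), collapse = ", "),
           " not found")
    x <- sapply(x[cols], as.logical)
  }
  x <- as.matrix(x)
  rowSums(x) > 0
}

#' Per-individual correctness of the screen
#'
#' For each respondent, the number of the four disorder calls (positive or
#' negative) that agree with the reference standard, 0 to 4; plus, among the
#' discordant calls, the share that are false positives.
#'
#' @param results Results data frame ([simulate_tiered()]) or flags.
#' @param labels Reference labels data frame.
#' @param disorders Disorder names.
#' @return List: `histogram` (named counts over 0..4), `proportions`,
#'   `n_failed_calls`, `failed_fp_share` (proportion of discordant calls
#'   that are false positives), `per_respondent` data frame.
#' @export
per_individual_correctness <- function(results, labels,
                                       disorders = c("depression", "anxiety",
                                                     "ptsd", "insomnia")) {
  lab <- align_labels(labels, results$id)
  flags <- sapply(paste0("screen_", disorders),
                  function(c) as.logical(results[[c]]))
  truth <- sapply(disorders, function(d) lab[[d]])
  correct <- flags == truth
  n_correct <- rowSums(correct)
  fp_calls <- flags & !truth
  hist <- table(factor(n_correct, levels = 0:4))
  n_failed <- sum(!correct)
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       proportions = as.numeric(hist) / nrow(flags),
       n_failed_calls = n_failed,
       failed_fp_share = if (n_failed > 0) sum(fp_calls) / n_failed else NA_real_,
       per_respondent = data.frame(id = results$id, n_correct = n_correct))
}

#' Pooled positive identification across disorders
#'
#' Percentage of all reference-standard positive cases, pooled over the
#' disorders, that the index test identified: `sum(tp) / sum(tp + fn) * 100`.
#'
#' @param tables List of `confusion_table`s, one per disorder.
#' @return Percentage (full precision; round at reporting).
#' @export
pooled_positive_identification <- function(tables) {
  if (length(tables) == 0) stop("no confusion tables supplied")
  tp <- sum(vapply(tables, `[[`, numeric(1), "tp"))
  pos <- tp + sum(vapply(tables, `[[`, numeric(1), "fn"))
  if (pos == 0) stop("no reference-standard positives in pooled tables")
  100 * tp / pos
}

#' Sweep candidate cutoffs for one scale
#'
#' Scores the scale for every respondent, dichotomises at each candidate
#' cutoff and evaluates against the reference labels for the scale's
#' disorder. Used e.g. to compare the proposed insomnia severity cutoffs
#' (8, 11, 14).
#'
#' @param dataset Complete wide response data frame.
#' @param labels Reference labels data frame.
#' @param battery An `itap_battery`.
#' @param scale_id A tier-1 or tier-3 scale id.
#' @param cutoffs Integer vector of candidate cutoffs.
#' @param disorder Label column to evaluate against; defaults to the scale's
#'   configured disorder.
#' @return Data frame, one row per cutoff (sorted): cutoff, cells, percent
#'   metrics, kappa.
#' @export
cutoff_sweep <- function(dataset, labels, battery, scale_id, cutoffs,
                         disorder = battery$scales[[scale_id]]$disorder) {
  if (length(cutoffs) == 0) stop("empty cutoff list")
  scores <- scale_scores(dataset, battery, scale_id)[[scale_id]]
  lab <- align_labels(labels, dataset$id)[[disorder]]
  rows <- lapply(sort(cutoffs), function(cut) {
    tab <- confusion(classify(scores, cut), lab)
    rep <- dta_metrics(tab)
    m <- stats::setNames(rep$metrics$percent, rep$metrics$metric)
    data.frame(cutoff = cut, tp = tab$tp, fp = tab$fp, fn = tab$fn,
               tn = tab$tn, sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], ppv = m[["ppv"]],
               npv = m[["npv"]], accuracy = m[["accuracy"]],
               kappa = rep$kappa)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prevalence and comorbidity tables
#'
#' Per-disorder positive counts and percentages for the index test and the
#' reference standard (plus "any"), pairwise comorbidity counts among the
#' reference diagnoses, and the multimorbidity distribution (number of
#' respondents with 0..4 diagnoses).
#'
#' @param results Results data frame ([simulate_tiered()]).
#' @param labels Reference labels data frame.
#' @param disorders Disorder names.
#' @return List: `prevalence` data frame, `comorbidity` symmetric count
#'   matrix, `multimorbidity` named counts over 0..4, `n_ge2` and
#'   `pct_ge2` (respondents with two or more diagnoses).
#' @export
prevalence_and_comorbidity <- function(results, labels,
                                       disorders = c("depression", "anxiety",
                                                     "ptsd", "insomnia")) {
  lab <- align_labels(labels, results$id)
  n <- nrow(lab)
  truth <- sapply(disorders, function(d) lab[[d]])
  flags <- sapply(paste0("screen_", disorders),
                  function(c) as.logical(results[[c]]))
  colnames(flags) <- disorders

  prev <- data.frame(
    disorder = c(disorders, "any"),
    reference_n = c(colSums(truth), sum(any_disorder(truth))),
    test_n = c(colSums(flags), sum(any_disorder(flags))))
  prev$reference_pct <- 100 * prev$reference_n / n
  prev$test_pct <- 100 * prev$test_n / n

  comorbidity <- t(truth) %*% truth
  diag(comorbidity) <- colSums(truth)

  k <- rowSums(truth)
  multi <- table(factor(k, levels = 0:length(disorders)))
  list(prevalence = prev,
       comorbidity = comorbidity,
       multimorbidity = stats::setNames(as.integer(multi), names(multi)),
       n_ge2 = sum(k >= 2),
       pct_ge2 = 100 * sum(k >= 2) / n)
}

format_kappa <- function(k) {
  if (is.na(k)) "NA" else sprintf("%.2f", round_half_up(k, 2))
}
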