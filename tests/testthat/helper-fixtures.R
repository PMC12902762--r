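# Fixtures built in code: random response vectors with varied severities so
# property tests exercise every tier path, and a hand-constructed cohort
# whose Tier-1 continuation decision has known operating characteristics.

the_battery <- default_battery()

# one random complete response vector; severity drawn per respondent so the
# tier gates open for some and not for others
random_responses <- function(battery = the_battery) {
  p <- stats::runif(1, 0, 0.6)
  stats::setNames(stats::rbinom(nrow(battery$items), battery$items$max, p),
                  battery$items$item_id)
}

random_dataset <- function(n, battery = the_battery) {
  rows <- t(vapply(seq_len(n), function(i) random_responses(battery),
                   numeric(nrow(battery$items))))
  cbind(data.frame(id = sprintf("r%03d", seq_len(n))), as.data.frame(rows))
}

# N = 70 cohort: 50 distress-positive (3 items at 4 -> RHS-13 = 12), 20
# distress-negative (all zero). 36 respondents carry a depression diagnosis:
# 35 among the distress-positives, 1 among the negatives. Tier-1
# continuation vs any diagnosis: tp 35, fn 1, tn 19, fp 15.
tier1_culling_cohort <- function(battery = the_battery) {
  zero <- stats::setNames(rep(0, nrow(battery$items)), battery$items$item_id)
  pos <- zero; pos[c("rhs13_1", "rhs13_2", "rhs13_3")] <- 4
  rows <- rbind(
    matrix(rep(pos, 50), nrow = 50, byrow = TRUE),
    matrix(rep(zero, 20), nrow = 20, byrow = TRUE))
  colnames(rows) <- names(zero)
  dataset <- cbind(data.frame(id = sprintf("c%02d", 1:70)), as.data.frame(rows))
  labels <- data.frame(id = dataset$id,
                       depression = c(rep(1, 35), rep(0, 15), 1, rep(0, 19)),
                       anxiety = 0, ptsd = 0, insomnia = 0)
  list(dataset = dataset, labels = labels)
}

# published concordance marginals: reference positives, index-test
# positives and concordant positives per disorder, N = 70
table4_margins <- list(
  depression = c(ref = 20, test = 33, tp = 19),
  anxiety    = c(ref = 17, test = 25, tp = 13),
  ptsd       = c(ref = 20, test = 27, tp = 16),
  insomnia   = c(ref = 26, test = 32, tp = 21))

table4_tables <- function() {
  lapply(table4_margins, function(m)
    confusion_from_margins(70, m[["ref"]], m[["test"]], m[["tp"]]))
}

metric_pct <- function(report, metric) {
  report$metrics$percent[report$metrics$metric == metric]
}
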