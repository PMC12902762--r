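test_that("confusion tables cross-classify flags against labels", {
  flags <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  tab <- confusion(flags, flags)
  expect_equal(c(tab$fp, tab$fn), c(0, 0))
  expect_equal(tab$tp, 3)
  expect_error(confusion(logical(0), logical(0)), "empty")
  expect_error(confusion_table(-1, 0, 0, 5), "non-negative")
  # data-frame form aligns by id even when rows are scrambled
  res <- data.frame(id = c("a", "b", "c"),
                    screen_depression = c(TRUE, FALSE, TRUE))
  lab <- data.frame(id = c("c", "a", "b"), depression = c(1, 1, 0))
  tab2 <- confusion(res, lab, "depression")
  expect_equal(c(tab2$tp, tab2$fp, tab2$fn, tab2$tn), c(2, 0, 0, 1))
  expect_error(confusion(res, lab[-1, ], "depression"), "missing for")
})

test_that("published marginals reconstruct the depression table", {
  tab <- confusion_from_margins(70, ref_pos = 20, test_pos = 33, tp = 19)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(19, 14, 1, 36))
})

test_that("accuracy metrics carry Wald intervals over their own denominators", {
  tab <- confusion_from_margins(70, 20, 33, 19)
  rep <- dta_metrics(tab)
  expect_equal(round_half_up(metric_pct(rep, "accuracy"), 1), 78.6)
  expect_equal(round_half_up(metric_pct(rep, "ppv"), 1), 57.6)
  m <- rep$metrics
  expect_true(all(m$lower <= m$percent & m$percent <= m$upper))
  expect_true(all(m$lower >= 0 & m$upper <= 100))
  expect_equal(rep$n_pos_index, 33)
  # perfect 2x2: all metrics 100
  perfect <- dta_metrics(confusion_table(1, 0, 0, 1))
  expect_equal(perfect$metrics$percent, rep(100, 5))
  # undefined metrics are flagged, not silently 0 or 100
  norefpos <- dta_metrics(confusion_table(0, 5, 0, 15))
  sens_row <- norefpos$metrics[norefpos$metrics$metric == "sensitivity", ]
  ppv_row <- norefpos$metrics[norefpos$metrics$metric == "ppv", ]
  expect_false(sens_row$defined)
  expect_true(is.na(sens_row$percent))
  expect_true(ppv_row$defined)
  expect_equal(ppv_row$percent, 0)
})

test_that("metric identities hold on random tables", {
  set.seed(88)
  for (i in 1:200) {
    cells <- stats::rmultinom(1, size = sample(20:200, 1),
                              prob = stats::runif(4, 0.05, 1))[, 1]
    if (sum(cells) == 0) next
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    rep <- dta_metrics(tab)
    acc <- metric_pct(rep, "accuracy") / 100
    expect_equal(acc * tab$n, tab$tp + tab$tn)
    sens <- metric_pct(rep, "sensitivity") / 100
    spec <- metric_pct(rep, "specificity") / 100
    ppv <- metric_pct(rep, "ppv") / 100
    prev <- (tab$tp + tab$fn) / tab$n
    if (!anyNA(c(sens, spec, ppv))) {
      bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
      if (!is.nan(bayes)) expect_equal(ppv, bayes)
    }
  }
})

test_that("kappa matches a brute-force agreement recount", {
  expect_equal(cohen_kappa(confusion_table(10, 0, 0, 12)), 1)
  expect_equal(round_half_up(cohen_kappa(confusion_from_margins(70, 20, 33, 19)), 2),
               0.56)
  # cells proportional to the margins: chance-level agreement, kappa 0
  expect_equal(cohen_kappa(confusion_table(6, 14, 9, 21)), 0)
  # random tables against an independent recount from expanded vectors
  set.seed(13)
  for (i in 1:100) {
    cells <- stats::rmultinom(1, 60, stats::runif(4, 0.05, 1))[, 1] + 1
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    test <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    ref <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    n <- length(test)
    po <- mean(test == ref)
    pe <- mean(test) * mean(ref) + mean(!test) * mean(!ref)
    expect_equal(cohen_kappa(tab), (po - pe) / (1 - pe))
    expect_lte(cohen_kappa(tab), po)
  }
  expect_warning(k <- cohen_kappa(confusion_table(9, 0, 0, 0)), "undefined")
  expect_true(is.na(k))
})

test_that("any-disorder is the logical OR of the four flags", {
  expect_false(any_disorder(matrix(c(FALSE, FALSE, FALSE, FALSE), 1)))
  expect_true(any_disorder(matrix(c(FALSE, TRUE, FALSE, FALSE), 1)))
  lab <- data.frame(id = 1:3, depression = c(1, 0, 0), anxiety = 0,
                    ptsd = c(0, 0, 1), insomnia = 0)
  expect_equal(any_disorder(lab), c(TRUE, FALSE, TRUE))
})

test_that("per-individual correctness recounts concordant calls", {
  lab <- data.frame(id = c("a", "b"),
                    depression = c(1, 0), anxiety = 0, ptsd = 0, insomnia = 0)
  res <- data.frame(id = c("a", "b"),
                    screen_depression = FALSE, screen_anxiety = FALSE,
                    screen_ptsd = FALSE, screen_insomnia = FALSE)
  pic <- per_individual_correctness(res, lab)
  expect_equal(pic$histogram, c(`0` = 0L, `1` = 0L, `2` = 0L, `3` = 1L,
                                `4` = 1L))
  expect_equal(pic$n_failed_calls, 1)
  expect_equal(pic$failed_fp_share, 0)  # the single failure is a miss
  # fully concordant cohort: everyone at 4/4
  res2 <- res
  res2$screen_depression <- c(TRUE, FALSE)
  pic2 <- per_individual_correctness(res2, lab)
  expect_equal(unname(pic2$histogram[5]), 2L)
  expect_true(is.na(pic2$failed_fp_share))
  # random cohort against a brute-force per-row recount
  set.seed(555)
  n <- 60
  disorders <- c("depression", "anxiety", "ptsd", "insomnia")
  lab3 <- cbind(data.frame(id = seq_len(n)),
                as.data.frame(matrix(stats::runif(n * 4) < 0.3, n,
                                     dimnames = list(NULL, disorders))))
  res3 <- cbind(data.frame(id = seq_len(n)),
                as.data.frame(matrix(stats::runif(n * 4) < 0.4, n,
                                     dimnames = list(NULL, paste0("screen_", disorders)))))
  pic3 <- per_individual_correctness(res3, lab3)
  brute <- vapply(seq_len(n), function(i)
    sum(vapply(disorders, function(d)
      res3[i, paste0("screen_", d)] == lab3[i, d], logical(1))), numeric(1))
  expect_equal(pic3$per_respondent$n_correct, brute)
  expect_equal(unname(pic3$histogram),
               as.integer(table(factor(brute, levels = 0:4))))
})

test_that("pooled identification pools true positives over disorders", {
  tabs <- list(confusion_table(5, 2, 0, 10), confusion_table(8, 1, 0, 4))
  expect_equal(pooled_positive_identification(tabs), 100)
  one <- confusion_from_margins(70, 20, 33, 19)
  expect_equal(pooled_positive_identification(list(one)),
               metric_pct(dta_metrics(one), "sensitivity"))
  expect_error(pooled_positive_identification(list()), "no confusion")
})

test_that("cutoff sweeps behave monotonically in the cutoff", {
  b <- the_battery
  set.seed(321)
  dat <- random_dataset(80, b)
  scores <- scale_scores(dat, b)
  labels <- data.frame(id = dat$id, depression = 0, anxiety = 0, ptsd = 0,
                       insomnia = as.integer(scores$isi7 >= 10))
  # flip some labels so both classes and both error types occur
  labels$insomnia[1:10] <- 1 - labels$insomnia[1:10]
  sweep <- cutoff_sweep(dat, labels, b, "isi7", c(14, 8, 11))
  expect_equal(sweep$cutoff, c(8, 11, 14))
  expect_true(all(diff(sweep$sensitivity) <= 0))
  expect_true(all(diff(sweep$specificity) >= 0))
  # degenerate cutoffs: everyone positive / everyone negative
  lo <- cutoff_sweep(dat, labels, b, "isi7", 0)
  expect_equal(c(lo$sensitivity, lo$specificity), c(100, 0))
  hi <- cutoff_sweep(dat, labels, b, "isi7", 28)
  if (hi$tp + hi$fn > 0) expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 100)
  expect_error(cutoff_sweep(dat, labels, b, "isi7", integer(0)), "empty")
})

test_that("prevalence and comorbidity tables count diagnoses correctly", {
  n <- 70
  disorders <- c("depression", "anxiety", "ptsd", "insomnia")
  lab <- cbind(data.frame(id = seq_len(n)),
               as.data.frame(matrix(0L, n, 4, dimnames = list(NULL, disorders))))
  # 23 respondents with two or more diagnoses
  lab$depression[1:23] <- 1
  lab$insomnia[1:23] <- 1
  lab$ptsd[1:8] <- 1
  lab$anxiety[24:30] <- 1
  res <- cbind(data.frame(id = seq_len(n)),
               stats::setNames(as.data.frame(matrix(FALSE, n, 4)),
                               paste0("screen_", disorders)))
  pc <- prevalence_and_comorbidity(res, lab)
  expect_equal(pc$n_ge2, 23)
  expect_equal(round_half_up(pc$pct_ge2, 1), 32.9)
  expect_equal(pc$comorbidity["depression", "insomnia"], 23)
  expect_true(isSymmetric(pc$comorbidity))
  off <- pc$comorbidity; diag(off) <- 0
  expect_true(all(off <= diag(pc$comorbidity)[col(off)]))
  expect_true(all(off <= diag(pc$comorbidity)[row(off)]))
  expect_equal(sum(pc$multimorbidity), n)
  # an all-negative cohort yields all-zero counts
  lab0 <- lab; lab0[disorders] <- 0L
  pc0 <- prevalence_and_comorbidity(res, lab0)
  expect_true(all(pc0$prevalence$reference_n == 0))
  expect_equal(pc0$n_ge2, 0)
})

test_that("Wald intervals reach near-nominal coverage at n = 70", {
  set.seed(2024)
  n <- 70; p <- 0.8; reps <- 2000
  covered <- vapply(seq_len(reps), function(i) {
    x <- stats::rbinom(1, n, p)
    phat <- x / n
    half <- 1.96 * sqrt(phat * (1 - phat) / n)
    p >= phat - half && p <= phat + half
  }, logical(1))
  cov <- mean(covered)
  expect_gte(cov, 0.90)  # Wald undercoverage tolerated
  expect_lte(cov, 0.97)
})
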