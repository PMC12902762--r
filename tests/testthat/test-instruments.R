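test_that("default battery matches the published tier structure", {
  b <- the_battery
  expect_equal(nrow(b$items), 56)
  expect_false(anyDuplicated(b$items$item_id) > 0)
  # full-scale baseline (the four tier-3 instruments) and tier-2 gate total
  tier3_items <- vapply(b$scales[b$tier3], function(s) length(s$item_ids),
                        integer(1))
  expect_equal(sum(tier3_items), 43)
  expect_equal(unname(tier3_items), c(9, 7, 20, 7))
  tier2_items <- vapply(b$scales[b$tier2], function(s) length(s$item_ids),
                        integer(1))
  expect_equal(sum(tier2_items), 9)
  # every short form is a subset of its parent, and score ranges are sums
  for (sid in b$tier2) {
    s <- b$scales[[sid]]
    expect_true(all(s$item_ids %in% b$scales[[s$parent]]$item_ids))
  }
  for (s in b$scales) {
    expect_equal(s$score_min, sum(s$item_min))
    expect_equal(s$score_max, sum(s$item_max))
    expect_true(s$cutoff >= s$score_min && s$cutoff <= s$score_max)
  }
})

test_that("invalid battery configurations are rejected", {
  base <- yaml::read_yaml(system.file("extdata", "itap_default.yaml",
                                      package = "tierscreen"))
  write_cfg <- function(cfg) {
    path <- withr::local_tempfile(fileext = ".yaml",
                                  .local_envir = parent.frame(2))
    yaml::write_yaml(cfg, path)
    path
  }
  # short-form item outside its parent scale
  bad <- base
  bad$short_forms[[3]]$items <- c("pcl5_1", "phq9_1")
  expect_error(load_battery(write_cfg(bad)), "not in its parent")
  # cutoff outside the score range
  bad <- base
  bad$scales[[2]]$cutoff <- 99
  expect_error(load_battery(write_cfg(bad)), "outside score range")
  # duplicate item ids across scales
  bad <- base
  bad$scales[[3]]$items$prefix <- "phq9"
  expect_error(load_battery(write_cfg(bad)), "duplicate item ids")
  expect_error(tierscreen:::build_battery(list(scales = list())), "no scales")
})

test_that("scale scoring is a validated plain sum", {
  b <- the_battery
  phq9 <- b$scales$phq9
  zeros <- stats::setNames(rep(0, 9), phq9$item_ids)
  expect_equal(score_scale(zeros, phq9), 0L)
  vals <- stats::setNames(c(2, 1, 1, 3, 0, 1, 1, 0, 1), phq9$item_ids)
  expect_equal(score_scale(vals, phq9), 10L)
  pcl5 <- b$scales$pcl5
  expect_equal(score_scale(stats::setNames(rep(4, 20), pcl5$item_ids), pcl5),
               80L)
  expect_error(score_scale(zeros[-1], phq9), "missing responses")
  bad <- zeros; bad["phq9_3"] <- 9
  expect_error(score_scale(bad, phq9), "out-of-range.*phq9_3")
  expect_true(classify(11, 11))
  expect_false(classify(10, 11))
})

test_that("short-form scores are consistent with their parent items", {
  b <- the_battery
  set.seed(41)
  for (rep in 1:20) {
    r <- random_responses(b)
    for (sid in b$tier2) {
      s <- b$scales[[sid]]
      expect_equal(score_scale(r, s), as.integer(sum(r[s$item_ids])))
      expect_true(score_scale(r, s) >= s$score_min)
      expect_true(score_scale(r, s) <= s$score_max)
    }
  }
})

test_that("cronbach alpha matches a direct formula evaluation", {
  # duplicated column: perfectly correlated pair
  x <- c(1, 4, 2, 5, 3)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # 4x3 toy matrix against a spreadsheet-style computation
  m <- matrix(c(1, 2, 0,
                3, 3, 2,
                0, 1, 1,
                2, 3, 3), nrow = 4, byrow = TRUE)
  svar <- function(v) sum((v - mean(v))^2) / (length(v) - 1)
  alpha_direct <- 3 / 2 * (1 - (svar(m[, 1]) + svar(m[, 2]) + svar(m[, 3])) /
                             svar(rowSums(m)))
  expect_equal(cronbach_alpha(m), alpha_direct)
  # independent items: alpha near zero
  set.seed(7)
  big <- matrix(stats::rnorm(5000 * 6), ncol = 6)
  expect_lt(abs(cronbach_alpha(big)), 0.1)
  # degenerate input is flagged, not silently scored
  expect_warning(a <- cronbach_alpha(matrix(1, 4, 3)), "undefined")
  expect_true(is.na(a))
  expect_error(cronbach_alpha(matrix(1:4, 4, 1)), "2 items")
})

test_that("scale correlations reproduce the brute-force Pearson formula", {
  b <- the_battery
  set.seed(42)
  dat <- random_dataset(5, b)
  r <- scale_correlations(dat, b)
  expect_equal(dim(r), c(5, 5))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r, t(r))
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  sc <- scale_scores(dat, b)
  expect_equal(r["phq9", "gad7"], pearson(sc$phq9, sc$gad7))
  expect_equal(r["rhs13", "isi7"], pearson(sc$rhs13, sc$isi7))
  # a constant scale yields flagged NA entries
  dat0 <- dat
  dat0[, b$scales$isi7$item_ids] <- 0
  expect_warning(r0 <- scale_correlations(dat0, b), "zero-variance")
  expect_true(all(is.na(r0["isi7", ])))
  expect_false(anyNA(r0["phq9", c("rhs13", "gad7", "pcl5")]))
})
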