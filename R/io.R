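#' Read a wide item-response CSV
#'
#' Canonical exchange format: one row per respondent, an `id` column plus
#' one column per battery item (e.g. `rhs13_1..rhs13_13, phq9_1..`).
#'
#' @param path CSV path.
#' @param battery Battery whose items the file must cover.
#' @param strict If `TRUE` (default), a missing item column, a duplicated
#'   id, or an out-of-range value is an error (with coordinates); if
#'   `FALSE`, respondents with invalid values are dropped with a warning.
#' @return Validated wide data frame.
#' @export
read_wide_responses <- function(path, battery = default_battery(),
                                strict = TRUE) {
  dat <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(dat)) stop("responses file needs an 'id' column: ", path)
  if (anyDuplicated(dat$id))
    stop("duplicated respondent id(s): ",
         paste(unique(dat$id[duplicated(dat$id)]), collapse = ", "))
  item_cols <- battery$items$item_id
  missing_cols <- setdiff(item_cols, names(dat))
  if (length(missing_cols)) {
    if (strict) stop("missing item column(s): ",
                     paste(missing_cols, collapse = ", "))
    warning("missing item column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(dat), c("id", item_cols))
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))

  present <- intersect(item_cols, names(dat))
  info <- battery$items[match(present, battery$items$item_id), ]
  bad_rows <- logical(nrow(dat))
  for (j in seq_along(present)) {
    v <- dat[[present[j]]]
    bad <- which(!is.na(v) & (v < info$min[j] | v > info$max[j] | v != round(v)))
    if (length(bad)) {
      msg <- paste0("value ", v[bad[1]], " out of range [", info$min[j], ", ",
                    info$max[j], "] at row ", bad[1], ", column ", present[j])
      if (strict) stop(msg)
      warning(msg, "; dropping affected respondent(s)")
      bad_rows[bad] <- TRUE
    }
  }
  dat <- dat[!bad_rows, c("id", present), drop = FALSE]
  dat
}

#' @rdname read_wide_responses
#' @param dataset Wide data frame to write.
#' @export
write_wide_responses <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference diagnosis labels
#'
#' CSV `id` + one 0/1 column per disorder. The column `mdd` is accepted as
#' an alias for `depression` (anxiety is always the single collapsed
#' anxiety-disorder flag).
#'
#' @param path CSV path.
#' @return Data frame `id` + logical disorder columns.
#' @export
read_labels <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(lab)) stop("labels file needs an 'id' column: ", path)
  names(lab)[names(lab) == "mdd"] <- "depression"
  for (col in setdiff(names(lab), "id")) lab[[col]] <- as.logical(lab[[col]])
  lab
}

#' @rdname read_labels
#' @param labels Labels data frame.
#' @export
write_labels <- function(labels, path) {
  out <- labels
  for (col in setdiff(names(out), "id")) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render diagnostic-accuracy reports
#'
#' Renders one or more [dta_metrics()] reports (a named list, names =
#' disorders) as JSON (full precision, the canonical machine format),
#' Markdown (a concordance table: n positives, kappa to 2 decimals, each
#' metric as `% (95% CI)` to 1 decimal, round-half-up), or CSV (long, full
#' precision). Undefined metrics are rendered as explicit `undefined`
#' flags, never as 0 or 100.
#'
#' @param reports A `dta_report` or named list of them.
#' @param format One of `"json"`, `"markdown"`, `"csv"`.
#' @param path Optional output file.
#' @return The rendered document as a character string, invisibly if
#'   written to `path`.
#' @export
write_report <- function(reports, format = c("json", "markdown", "csv"),
                         path = NULL) {
  format <- match.arg(format)
  if (inherits(reports, "dta_report")) reports <- list(report = reports)
  if (!length(reports)) {
    txt <- switch(format, json = "{}",
                  markdown = "(empty report)\n",
                  csv = "disorder,metric,percent,lower,upper,defined\n")
  } else {
    txt <- switch(format,
                  json = render_json(reports),
                  markdown = render_markdown(reports),
                  csv = render_csv(reports))
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

render_json <- function(reports) {
  obj <- lapply(reports, function(r) {
    m <- r$metrics
    metrics <- stats::setNames(lapply(seq_len(nrow(m)), function(i)
      list(percent = m$percent[i], lower = m$lower[i], upper = m$upper[i],
           defined = m$defined[i])), m$metric)
    list(n = r$table$n, n_pos_index = r$n_pos_index, kappa = r$kappa,
         cells = list(tp = r$table$tp, fp = r$table$fp,
                      fn = r$table$fn, tn = r$table$tn),
         metrics = metrics)
  })
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

render_markdown <- function(reports) {
  fmt_ci <- function(m, i) {
    if (!m$defined[i]) return("undefined")
    sprintf("%.1f (%.1f-%.1f)", round_half_up(m$percent[i], 1),
            round_half_up(m$lower[i], 1), round_half_up(m$upper[i], 1))
  }
  header <- paste("| Diagnosis | n_pos | Cohen k | Sensitivity, % (95% CI) |",
                  "Specificity, % (95% CI) | PPV, % (95% CI) |",
                  "NPV, % (95% CI) | Accuracy, % (95% CI) |")
  sep <- paste(c("|", rep("---|", 8)), collapse = " ")
  rows <- vapply(names(reports), function(nm) {
    r <- reports[[nm]]; m <- r$metrics
    cells <- vapply(seq_len(nrow(m)), function(i) fmt_ci(m, i), character(1))
    paste("|", nm, "|", r$n_pos_index, "|", format_kappa(r$kappa), "|",
          paste(cells, collapse = " | "), "|")
  }, character(1))
  paste(c(header, sep, rows, ""), collapse = "\n")
}

render_csv <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    m <- reports[[nm]]$metrics
    cbind(disorder = nm, m)
  })
  df <- do.call(rbind, rows)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  paste(c(out, ""), collapse = "\n")
}

#' Evaluate a tiered screen against reference labels
#'
#' Convenience wrapper tying the modules together: simulate the tiers over a
#' complete dataset, cross-classify each disorder (and "any") against the
#' labels, and return the full set of accuracy reports plus the culling
#' report and pooled identification.
#'
#' @param dataset Complete wide response data frame.
#' @param labels Reference labels data frame.
#' @param battery An `itap_battery`.
#' @return List: `results` (per-respondent), `reports` (named list of
#'   `dta_report`, incl. "any"), `pooled_identification` (%),
#'   `culling` (a `culling_report`).
#' @export
evaluate_screen <- function(dataset, labels, battery = default_battery()) {
  results <- simulate_tiered(dataset, battery)
  lab <- align_labels(labels, results$id)
  disorders <- disorder_names(battery)
  tables <- lapply(disorders, function(d) confusion(results, lab, d))
  names(tables) <- disorders
  any_tab <- confusion(any_disorder(results), any_disorder(lab))
  reports <- c(lapply(tables, dta_metrics), list(any = dta_metrics(any_tab)))
  list(results = results,
       reports = reports,
       pooled_identification = pooled_positive_identification(tables),
       culling = culling_report(dataset, battery, labels))
}
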