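#' Load a screening battery from a YAML configuration
#'
#' A battery describes the instruments of a tiered screening procedure: the
#' Tier-1 distress gateway scale, the Tier-3 full symptom scales, and the
#' Tier-2 short forms whose items are subsets of the full scales (so that a
#' response given in Tier 2 is never asked again in Tier 3).
#'
#' The configuration declares, per scale: `scale_id`, `tier` (1 or 3),
#' `disorder`, `cutoff` and its items, either compactly as
#' `{prefix, count, min, max}` (items named `<prefix>_1 .. <prefix>_count`)
#' or as an explicit list of `{id, min, max}`. Short forms declare their
#' parent scale, gateway cutoff and the parent items they reuse.
#'
#' @param path Path to a YAML battery configuration.
#' @return An object of class `itap_battery`.
#' @seealso [default_battery()] for the shipped default configuration.
#' @export
load_battery <- function(path) {
  if (!file.exists(path)) stop("battery config not found: ", path)
  cfg <- yaml::read_yaml(path)
  build_battery(cfg)
}

#' The default screening battery
#'
#' Five validated scales, 56 distinct items: RHS-13 (13 items, 0-4,
#' cutoff >= 11) as the Tier-1 gateway; PHQ-9 (9 items, 0-3, >= 10),
#' GAD-7 (7 items, 0-3, >= 10), PCL-5 (20 items, 0-4, >= 32) and
#' ISI-7 (7 items, 0-4, >= 11) as Tier-3 full scales; PHQ-2 (>= 2),
#' GAD-2 (>= 2), a 4-item PCL-5 short form (>= 5) and ISI item 7 (>= 2)
#' as Tier-2 gates.
#'
#' @return An `itap_battery`.
#' @export
default_battery <- function() {
  load_battery(system.file("extdata", "itap_default.yaml",
                           package = "tierscreen", mustWork = TRUE))
}

build_battery <- function(cfg) {
  if (is.null(cfg$scales) || length(cfg$scales) == 0)
    stop("battery config declares no scales")

  scales <- list()
  for (sc in cfg$scales) {
    it <- expand_items(sc$items, sc$scale_id)
    scales[[sc$scale_id]] <- make_scale(
      scale_id = sc$scale_id, tier = sc$tier, disorder = sc$disorder,
      cutoff = sc$cutoff, item_ids = it$id,
      item_min = it$min, item_max = it$max, parent = NA_character_)
  }

  full_ids <- names(scales)
  items <- do.call(rbind, lapply(scales, function(s)
    data.frame(item_id = s$item_ids, scale_id = s$scale_id,
               min = s$item_min, max = s$item_max,
               stringsAsFactors = FALSE)))
  rownames(items) <- NULL
  if (anyDuplicated(items$item_id))
    stop("duplicate item ids across scales: ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))

  for (sf in cfg$short_forms) {
    parent <- scales[[sf$parent]]
    if (is.null(parent)) stop("short form ", sf$scale_id,
                              " names unknown parent scale ", sf$parent)
    unknown <- setdiff(unlist(sf$items), parent$item_ids)
    if (length(unknown))
      stop("short form ", sf$scale_id, " uses items not in its parent ",
           sf$parent, ": ", paste(unknown, collapse = ", "))
    idx <- match(unlist(sf$items), parent$item_ids)
    scales[[sf$scale_id]] <- make_scale(
      scale_id = sf$scale_id, tier = 2, disorder = parent$disorder,
      cutoff = sf$cutoff, item_ids = parent$item_ids[idx],
      item_min = parent$item_min[idx], item_max = parent$item_max[idx],
      parent = sf$parent)
  }

  tier1 <- full_ids[vapply(scales[full_ids], function(s) s$tier == 1, logical(1))]
  tier3 <- full_ids[vapply(scales[full_ids], function(s) s$tier == 3, logical(1))]
  tier2 <- vapply(cfg$short_forms, function(sf) sf$scale_id, character(1))
  if (length(tier1) != 1)
    stop("battery must declare exactly one tier-1 gateway scale")
  parents <- vapply(scales[tier2], function(s) s$parent, character(1))
  if (!setequal(parents, tier3) || anyDuplicated(parents))
    stop("tier-2 short forms must map one-to-one onto the tier-3 full scales")
  # short forms ordered as their parents so tier presentation follows config
  tier2 <- tier2[match(tier3, parents)]

  battery <- structure(list(
    name = if (is.null(cfg$name)) "unnamed battery" else cfg$name,
    scales = scales,
    tier1 = tier1, tier2 = tier2, tier3 = tier3,
    items = items
  ), class = "itap_battery")
  battery$fingerprint <- battery_fingerprint(battery)
  battery
}

expand_items <- function(spec, scale_id) {
  if (!is.null(spec$prefix)) {
    data.frame(id = paste0(spec$prefix, "_", seq_len(spec$count)),
               min = rep(spec$min, spec$count),
               max = rep(spec$max, spec$count), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(spec, function(x)
      data.frame(id = x$id, min = x$min, max = x$max, stringsAsFactors = FALSE)))
  }
}

make_scale <- function(scale_id, tier, disorder, cutoff,
                       item_ids, item_min, item_max, parent) {
  if (any(item_min >= item_max))
    stop("scale ", scale_id, ": item ordinal_min must be < ordinal_max")
  score_min <- sum(item_min); score_max <- sum(item_max)
  if (cutoff < score_min || cutoff > score_max)
    stop("scale ", scale_id, ": cutoff ", cutoff, " outside score range [",
         score_min, ", ", score_max, "]")
  structure(list(scale_id = scale_id, tier = tier, disorder = disorder,
                 cutoff = cutoff, item_ids = item_ids,
                 item_min = item_min, item_max = item_max,
                 score_min = score_min, score_max = score_max,
                 parent = parent),
            class = "itap_scale")
}

# deterministic text fingerprint of the battery structure, for session logs
battery_fingerprint <- function(battery) {
  parts <- vapply(battery$scales, function(s)
    paste0(s$scale_id, ":", s$tier, ":", s$cutoff, ":",
           paste(s$item_ids, collapse = ",")), character(1))
  txt <- paste(parts, collapse = ";")
  # 31-ary polynomial hash mod 2^31-1 over the canonical description
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.itap_battery <- function(x, ...) {
  cat("<itap_battery>", x$name, "\n")
  cat("  items:", nrow(x$items), " fingerprint:", x$fingerprint, "\n")
  for (id in c(x$tier1, x$tier2, x$tier3)) {
    s <- x$scales[[id]]
    cat(sprintf("  tier %d  %-8s %-10s %2d items  cutoff >= %d\n",
                s$tier, s$scale_id, s$disorder, length(s$item_ids), s$cutoff))
  }
  invisible(x)
}

#' Items a tier-2 short form leaves unanswered in its parent full scale
#'
#' @param battery An `itap_battery`.
#' @param full_scale_id A tier-3 scale id.
#' @return Character vector of item ids, in parent-scale order.
#' @export
remainder_items <- function(battery, full_scale_id) {
  full <- battery$scales[[full_scale_id]]
  short_id <- battery$tier2[match(full_scale_id,
    vapply(battery$scales[battery$tier2], function(s) s$parent, character(1)))]
  setdiff(full$item_ids, battery$scales[[short_id]]$item_ids)
}

#' Score a scale by summing its item responses
#'
#' Plain sum scoring; none of the instruments reverse-score. Every item of
#' the scale must be present and within its ordinal range.
#'
#' @param responses Named numeric vector (or list) of item responses,
#'   names are item ids.
#' @param scale An `itap_scale` (an element of `battery$scales`).
#' @return Integer sum score.
#' @export
score_scale <- function(responses, scale) {
  responses <- unlist(responses)
  missing <- setdiff(scale$item_ids, names(responses))
  if (length(missing))
    stop("missing responses for scale ", scale$scale_id, ": ",
         paste(missing, collapse = ", "))
  vals <- responses[scale$item_ids]
  bad <- which(is.na(vals) | vals < scale$item_min | vals > scale$item_max |
                 vals != round(vals))
  if (length(bad))
    stop("out-of-range response for ", scale$scale_id, " item ",
         scale$item_ids[bad[1]], ": ", vals[bad[1]])
  as.integer(sum(vals))
}

#' Dichotomise a score at a gateway cutoff
#'
#' Positive if and only if `score >= cutoff`; all cutoffs in the battery use
#' this ">=" convention. Vectorised.
#'
#' @param score Numeric score(s).
#' @param cutoff Cutoff value.
#' @return Logical.
#' @export
classify <- function(score, cutoff) score >= cutoff

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s^2_i / s^2_{tot})}, where the item and
#' total-score variances are sample variances (denominator n-1).
#'
#' @param mat Numeric matrix or data frame, respondents in rows, the items of
#'   one scale in columns. At least 2 items and 2 respondents.
#' @return Alpha in (-Inf, 1]; `NA` with a warning if the total score has
#'   zero variance (alpha undefined).
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("alpha needs at least 2 items")
  if (nrow(mat) < 2) stop("alpha needs at least 2 respondents")
  k <- ncol(mat)
  var_tot <- stats::var(rowSums(mat))
  if (var_tot == 0) {
    warning("total score variance is zero; alpha undefined")
    return(NA_real_)
  }
  item_vars <- apply(mat, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / var_tot)
}

#' Full-scale sum scores for every respondent
#'
#' @param dataset Wide response data frame: an `id` column plus one column
#'   per battery item.
#' @param battery An `itap_battery`.
#' @param scale_ids Scales to score; defaults to Tier 1 + all Tier-3 scales.
#' @return Data frame `id` + one integer score column per scale.
#' @export
scale_scores <- function(dataset, battery,
                         scale_ids = c(battery$tier1, battery$tier3)) {
  out <- data.frame(id = dataset$id)
  for (sid in scale_ids) {
    s <- battery$scales[[sid]]
    out[[sid]] <- as.integer(rowSums(dataset[, s$item_ids, drop = FALSE]))
  }
  out
}

#' Pearson correlations between full-scale scores
#'
#' @inheritParams scale_scores
#' @return Symmetric correlation matrix over Tier-1 + Tier-3 scale scores,
#'   unit diagonal; a zero-variance scale yields `NA` entries with a warning.
#' @export
scale_correlations <- function(dataset, battery) {
  sc <- scale_scores(dataset, battery)
  m <- as.matrix(sc[, -1, drop = FALSE])
  degenerate <- apply(m, 2, stats::var) == 0
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  if (any(degenerate)) {
    warning("zero-variance scale(s): ",
            paste(colnames(m)[degenerate], collapse = ", "),
            "; correlation undefined")
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
  }
  diag(r) <- ifelse(degenerate, NA_real_, 1)
  r
}
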