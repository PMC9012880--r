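#' ROUT outlier detection for a single sample (constant model)
#'
#' Robust regression and outlier removal specialized to a constant model:
#' the robust center is fit by iteratively reweighted least squares with
#' Lorentzian weights `1 / (1 + (r / RSDR)^2)`; the robust scale (RSDR) is
#' the 68.27th percentile of absolute residuals with the small-sample
#' correction `n / (n - 1)`. Each point's t-like ratio
#' `|residual| / RSDR` is converted to a two-tailed P value (t
#' distribution, `n - 1` df) and tested outward-in at false-discovery
#' level `Q`: points are ranked by decreasing ratio and the i-th most
#' extreme is compared with the Benjamini-Hochberg-style threshold
#' `Q * (n - i + 1) / n`, stopping at the first non-significant point.
#'
#' @param values Numeric sample, `n >= 10`.
#' @param Q False-discovery level, in (0, 0.1] (default 0.01, i.e. 1%).
#' @return Logical mask of flagged outliers with attributes `center`,
#'   `rsdr` and `Q`.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 10) stop("rout_outliers: need n >= 10 for a robust scale")
  if (!(Q > 0 && Q <= 0.1)) stop("rout_outliers: Q must be in (0, 0.1]")
  center <- stats::median(values)
  rsdr <- robust_sdr(values - center, n)
  for (i in 1:100) {
    r <- values - center
    w <- 1 / (1 + (r / max(rsdr, .Machine$double.eps))^2)
    new_center <- sum(w * values) / sum(w)
    rsdr <- robust_sdr(values - new_center, n)
    if (abs(new_center - center) < 1e-12 * (1 + abs(center))) {
      center <- new_center; break
    }
    center <- new_center
  }
  tratio <- abs(values - center) / max(rsdr, .Machine$double.eps)
  pvals <- 2 * stats::pt(-tratio, df = n - 1)
  ord <- order(pvals)                       # most extreme first
  thresh <- Q * (n - seq_len(n) + 1) / n    # Q at i = 1 down to Q/n
  fails <- which(pvals[ord] >= thresh)
  k <- if (length(fails)) fails[1] - 1L else n
  mask <- logical(n)
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  structure(mask, center = center, rsdr = rsdr, Q = Q)
}

# 68.27th percentile of |residuals| with small-n correction; a robust
# analogue of the residual SD.
robust_sdr <- function(residuals, n) {
  stats::quantile(abs(residuals), 0.6827, names = FALSE) * n / (n - 1)
}

#' Assemble a cohort table
#'
#' Standard long-format table used by the statistical tail: one row per
#' (field of view, imaging period) with its animal, group and metric
#' value.
#'
#' @param fov_id,animal_id,group_label,imaging_period,value Equal-length
#'   vectors; `group_label` must be `"control"` or `"FIP"`.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(fov_id, animal_id, group_label, imaging_period,
                         value) {
  if (!all(group_label %in% c("control", "FIP")))
    stop("cohort_table: group_label must be 'control' or 'FIP'")
  tab <- data.frame(fov_id = fov_id, animal_id = animal_id,
                    group_label = group_label,
                    imaging_period = as.integer(imaging_period),
                    value = as.numeric(value), stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("fov_id", "imaging_period")]))
    stop("cohort_table: duplicated (fov_id, imaging_period)")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Matched-field outlier exclusion
#'
#' Applies per-period outlier masks and removes every field of view that
#' is flagged in any imaging period from all periods, preserving data
#' matching across time. If no masks are given, [rout_outliers()] is run
#' within each (imaging period, group) cell — outliers are judged against
#' their own group's distribution, as in a per-column outlier analysis —
#' falling back to the pooled period when a group has fewer than 10
#' values.
#'
#' @param table [cohort_table()] spanning the imaging periods.
#' @param masks Optional named list (by period) of logical vectors aligned
#'   with that period's rows (in table order).
#' @param Q FDR level for [rout_outliers()] when masks are computed here.
#' @return Filtered table with attributes `excluded_fovs` and
#'   `removed_per_period` (rows removed per period).
#' @export
matched_field_exclusion <- function(table, masks = NULL, Q = 0.01) {
  periods <- sort(unique(table$imaging_period))
  flagged <- character(0)
  for (p in periods) {
    rows <- which(table$imaging_period == p)
    mask <- if (!is.null(masks)) {
      m <- masks[[as.character(p)]]
      if (is.null(m) || length(m) != length(rows))
        stop("matched_field_exclusion: mask for period ", p,
             " missing or misaligned")
      m
    } else {
      groups <- table$group_label[rows]
      if (all(table(groups) >= 10)) {
        m <- logical(length(rows))
        for (g in unique(groups)) {
          sel <- groups == g
          m[sel] <- as.logical(rout_outliers(table$value[rows][sel], Q = Q))
        }
        m
      } else {
        as.logical(rout_outliers(table$value[rows], Q = Q))
      }
    }
    flagged <- union(flagged, table$fov_id[rows][mask])
  }
  keep <- !(table$fov_id %in% flagged)
  removed <- vapply(periods, function(p)
    sum(!keep & table$imaging_period == p), numeric(1))
  out <- table[keep, , drop = FALSE]
  attr(out, "excluded_fovs") <- flagged
  attr(out, "removed_per_period") <- stats::setNames(removed, periods)
  out
}

#' Two-way ANOVA (group x imaging period) with Bonferroni post-hoc
#'
#' Fixed-effects two-factor ANOVA of the metric on group, period and
#' their interaction, using type-III sums of squares with sum-to-zero
#' contrasts (robust to unbalanced tables; identical to the textbook
#' partition when balanced). The post-hoc compares groups within each
#' period using the pooled residual mean square, multiplying each raw P by
#' the number of periods (Bonferroni) and capping at 1.
#'
#' @param table [cohort_table()] with both groups and >= 2 periods.
#' @return Object of class `anova_result`: `effects` (data.frame with F,
#'   df and P for group, period, interaction), `posthoc` (per-period group
#'   contrast with raw and adjusted P), `cell_summary` (mean/SEM/n per
#'   group x period).
#' @export
two_way_anova <- function(table) {
  d <- data.frame(value = table$value,
                  group = factor(table$group_label),
                  period = factor(table$imaging_period))
  if (nlevels(d$group) < 2 || nlevels(d$period) < 2)
    stop("two_way_anova: need both groups and >= 2 periods")
  counts <- table(d$group, d$period)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("two_way_anova: empty cell (",
         rownames(counts)[empty[1]], ", period ",
         colnames(counts)[empty[2]], ")")
  }
  if (stats::var(d$value) == 0) {
    # a constant table carries no effects: F = 0, P = 1 throughout
    effects <- data.frame(term = c("group", "period", "interaction"),
                          F = 0, df = c(1, nlevels(d$period) - 1,
                                        nlevels(d$period) - 1), P = 1,
                          stringsAsFactors = FALSE)
    cs <- summarize_cells(d)
    posthoc <- data.frame(imaging_period = levels(d$period),
                          contrast = paste(levels(d$group)[2], "-",
                                           levels(d$group)[1]),
                          estimate = 0, t = 0,
                          df = nrow(d) - 2 * nlevels(d$period),
                          p_raw = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(structure(list(effects = effects, posthoc = posthoc,
                          cell_summary = cs, mse = 0),
                     class = "anova_result"))
  }
  # fit on a unit-scale response: F and P are scale-invariant and this
  # keeps very small metrics (e.g. Power ~ 1e-8) numerically well-posed
  s <- stats::sd(d$value)
  d$z <- (d$value - mean(d$value)) / s
  fit <- stats::lm(z ~ group * period, data = d,
                   contrasts = list(group = "contr.sum",
                                    period = "contr.sum"))
  at <- car::Anova(fit, type = 3, singular.ok = FALSE)
  pick <- function(term) {
    i <- match(term, rownames(at))
    f <- at[i, "F value"]; p <- at[i, "Pr(>F)"]
    ss <- at[i, "Sum Sq"]
    if (!is.finite(f) && isTRUE(all.equal(ss, 0))) { f <- 0; p <- 1 }
    c(F = f, df = at[i, "Df"], P = p)
  }
  eff <- rbind(group = pick("group"), period = pick("period"),
               interaction = pick("group:period"))
  effects <- data.frame(term = rownames(eff), F = eff[, "F"],
                        df = eff[, "df"], P = eff[, "P"],
                        row.names = NULL, stringsAsFactors = FALSE)

  mse <- s^2 * sum(stats::residuals(fit)^2) / fit$df.residual
  cs <- summarize_cells(d)
  n_comp <- nlevels(d$period)
  posthoc <- do.call(rbind, lapply(levels(d$period), function(p) {
    v1 <- d$value[d$group == levels(d$group)[1] & d$period == p]
    v2 <- d$value[d$group == levels(d$group)[2] & d$period == p]
    diffm <- mean(v2) - mean(v1)
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tstat <- if (se > 0) diffm / se else 0
    praw <- if (se > 0) 2 * stats::pt(-abs(tstat), df = fit$df.residual)
    else 1
    data.frame(imaging_period = p,
               contrast = paste(levels(d$group)[2], "-", levels(d$group)[1]),
               estimate = diffm, t = tstat, df = fit$df.residual,
               p_raw = praw, p_adj = min(1, praw * n_comp),
               stringsAsFactors = FALSE)
  }))
  structure(list(effects = effects, posthoc = posthoc, cell_summary = cs,
                 mse = mse), class = "anova_result")
}

# Per-cell mean/SEM for the internal (group, period) factor frame.
summarize_cells <- function(d) {
  do.call(rbind, lapply(levels(d$period), function(p) {
    do.call(rbind, lapply(levels(d$group), function(g) {
      v <- d$value[d$group == g & d$period == p]
      data.frame(group_label = g, imaging_period = p, n = length(v),
                 mean = mean(v),
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                 else NA_real_, stringsAsFactors = FALSE)
    }))
  }))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> two-way ANOVA (group x period), type III\n")
  print(x$effects, row.names = FALSE)
  cat("Bonferroni post-hoc (group contrast per period):\n")
  print(x$posthoc[, c("imaging_period", "contrast", "estimate", "p_adj")],
        row.names = FALSE)
  invisible(x)
}

#' Group mean and SEM per (group, period) cell
#'
#' @param table [cohort_table()].
#' @return data.frame `group_label, imaging_period, n, mean, sem`; cells
#'   with a single observation report `sem = NA` with a warning.
#' @export
summarize_groups <- function(table) {
  out <- do.call(rbind, lapply(split(
    table, list(table$group_label, table$imaging_period), drop = TRUE),
    function(d) data.frame(
      group_label = d$group_label[1], imaging_period = d$imaging_period[1],
      n = nrow(d), mean = mean(d$value),
      sem = if (nrow(d) > 1) stats::sd(d$value) / sqrt(nrow(d)) else NA_real_,
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (any(is.na(out$sem)))
    warning("summarize_groups: cells with n = 1 have no SEM")
  out[order(out$group_label, out$imaging_period), ]
}

#' Power heat-map matrix (fields of view x imaging periods)
#'
#' Arranges per-field band-peak Power into a matrix with one row per
#' field of view (grouped by animal, then field id) and one column per
#' imaging period; missing cells are `NA`.
#'
#' @param table data.frame with `fov_id, animal_id, imaging_period,
#'   value` (e.g. peak Power per field and period).
#' @param periods Column order (default `1:3`).
#' @return Numeric matrix with `fov_id` rownames and an `animal_id`
#'   attribute giving each row's animal.
#' @export
power_heatmap_table <- function(table, periods = 1:3) {
  if (anyDuplicated(table[, c("fov_id", "imaging_period")]))
    stop("power_heatmap_table: duplicate (fov_id, imaging_period)")
  key <- unique(table[, c("animal_id", "fov_id")])
  key <- key[order(key$animal_id, key$fov_id), ]
  m <- matrix(NA_real_, nrow(key), length(periods),
              dimnames = list(key$fov_id, paste0("period", periods)))
  for (i in seq_len(nrow(table))) {
    j <- match(table$imaging_period[i], periods)
    if (!is.na(j)) m[table$fov_id[i], j] <- table$value[i]
  }
  attr(m, "animal_id") <- key$animal_id
  m
}
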