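#' Summarize projection dimensions per group
#'
#' Sample mean, standard deviation (n-1 denominator) and standard error of the
#' mean of one dimension column, per group.
#'
#' @param records Data frame of projection records (e.g. from
#'   [gen_morphometry()]).
#' @param field Dimension column to summarize, `"short_axis_nm"` or
#'   `"long_axis_nm"` (any numeric column is accepted).
#' @param group_by Name of the grouping column; default `"condition"`.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `sem`. Groups
#'   with no finite values are skipped with a warning.
#' @export
summarize_dimensions <- function(records, field = "short_axis_nm",
                                 group_by = "condition") {
  stopifnot(is.data.frame(records), field %in% names(records),
            group_by %in% names(records))
  groups <- unique(records[[group_by]])
  rows <- list()
  for (g in groups) {
    x <- records[[field]][records[[group_by]] == g]
    x <- x[is.finite(x)]
    if (length(x) == 0L) {
      warning(sprintf("group '%s' has no finite values; skipped", g))
      next
    }
    n <- length(x)
    s <- if (n > 1) stats::sd(x) else 0
    rows[[length(rows) + 1L]] <-
      data.frame(group = g, n = n, mean = mean(x), sd = s, sem = s / sqrt(n),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify projections as nanoscale bridges or lamellipodia
#'
#' A projection is a nanoscale bridge iff its short axis is below the width
#' threshold AND its aspect ratio (long/short) is at least the aspect
#' threshold; otherwise it is a lamellipodium. The default thresholds (width
#' < 1 um, aspect >= 10) sit between the two published population means
#' (bridges: 290 nm x 30.7 um; lamellipodia: 4.99 um x 12.9 um).
#'
#' @param short_axis_nm,long_axis_nm Numeric vectors of axis lengths in nm.
#' @param width_threshold_nm Maximum short axis for a bridge (exclusive).
#' @param aspect_threshold Minimum long/short ratio for a bridge (inclusive).
#' @return Character vector of `"nanobridge"` / `"lamellipodium"`, with `NA`
#'   where either axis is missing (unclassifiable).
#' @export
#' @examples
#' classify_projection_kind(c(290, 4990), c(30690, 12900))
classify_projection_kind <- function(short_axis_nm, long_axis_nm,
                                     width_threshold_nm = 1000,
                                     aspect_threshold = 10) {
  if (length(short_axis_nm) != length(long_axis_nm))
    stop("axis vectors must have equal length", call. = FALSE)
  ok <- is.finite(short_axis_nm) & is.finite(long_axis_nm)
  if (any(short_axis_nm[ok] <= 0))
    stop("axes must be positive", call. = FALSE)
  out <- rep(NA_character_, length(short_axis_nm))
  bridge <- short_axis_nm < width_threshold_nm &
    long_axis_nm / short_axis_nm >= aspect_threshold
  out[ok] <- ifelse(bridge[ok], "nanobridge", "lamellipodium")
  out
}

#' Per-class intercellular connection statistics
#'
#' For each connection class (homotypic epithelial-epithelial, heterotypic
#' epithelial-endothelial, ...), the percentage of cells with at least one
#' connection of that class and the mean (+/- s.e.m.) number of connections
#' per cell, with zero-connection cells included in the denominator.
#'
#' @param records Data frame with one row per connection; must contain
#'   `cell_id` and `connection_class`.
#' @param cells Vector of all cell ids in the population (so that cells with
#'   zero connections count); defaults to the cells present in `records`.
#' @return Data frame with `connection_class`, `pct_cells_with_connection`,
#'   `mean_per_cell`, `sem_per_cell`, `n_cells`.
#' @export
connection_stats <- function(records, cells = unique(records$cell_id)) {
  stopifnot(is.data.frame(records),
            all(c("cell_id", "connection_class") %in% names(records)))
  cells <- unique(cells)
  n_cells <- length(cells)
  if (n_cells == 0L) stop("no cells supplied", call. = FALSE)
  classes <- unique(records$connection_class)
  rows <- lapply(classes, function(cl) {
    sub <- records[records$connection_class == cl, , drop = FALSE]
    counts <- table(factor(sub$cell_id, levels = cells))
    counts <- as.numeric(counts)
    s <- if (n_cells > 1) stats::sd(counts) else 0
    data.frame(connection_class = cl,
               pct_cells_with_connection = 100 * mean(counts >= 1),
               mean_per_cell = mean(counts),
               sem_per_cell = s / sqrt(n_cells),
               n_cells = n_cells,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peak window of a kinetics series
#'
#' Smooths the per-timepoint means with a centered moving average and returns
#' the window of timepoints whose smoothed value is within 5% of the peak,
#' measured relative to the smoothed range (`>= max - rel_tol * (max - min)`).
#' The range-based criterion makes the window invariant to adding a constant
#' to all means. A flat series returns the full time range flagged `flat`.
#'
#' @param timepoint_h Numeric vector of at least 3 increasing timepoints (h).
#' @param value Mean measurement per timepoint (length, percentage, ...).
#' @param smoothing_window Odd moving-average window width; default 3.
#' @param rel_tol Fraction of the smoothed range defining the peak window.
#' @return A list of class `"kinetics_peak"`: `interval` (`c(earliest,
#'   latest)` h), `argmax_h`, `flat` and `smoothed`.
#' @export
kinetics_peak <- function(timepoint_h, value, smoothing_window = 3,
                          rel_tol = 0.05) {
  if (length(timepoint_h) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (length(value) != length(timepoint_h))
    stop("'value' and 'timepoint_h' must have equal length", call. = FALSE)
  if (is.unsorted(timepoint_h, strictly = TRUE))
    stop("'timepoint_h' must be strictly increasing", call. = FALSE)
  w <- max(1L, as.integer(smoothing_window))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(value)
  sm <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(value[idx])
  }, numeric(1))
  rng <- max(sm) - min(sm)
  if (rng <= .Machine$double.eps * max(1, abs(max(sm)))) {
    out <- list(interval = range(timepoint_h), argmax_h = timepoint_h[1L],
                flat = TRUE, smoothed = sm)
  } else {
    keep <- sm >= max(sm) - rel_tol * rng
    out <- list(interval = range(timepoint_h[keep]),
                argmax_h = timepoint_h[which.max(sm)],
                flat = FALSE, smoothed = sm)
  }
  class(out) <- "kinetics_peak"
  out
}

#' @export
print.kinetics_peak <- function(x, ...) {
  if (x$flat)
    cat("Flat series: peak window is the full range",
        sprintf("[%g, %g] h\n", x$interval[1], x$interval[2]))
  else
    cat(sprintf("Peak window: [%g, %g] h (argmax %g h)\n",
                x$interval[1], x$interval[2], x$argmax_h))
  invisible(x)
}

#' Compare measurement groups by one-way ANOVA with Bonferroni post hoc
#'
#' The comparison used throughout the pipeline: a one-way analysis of variance
#' followed by pairwise pooled-SD t tests with Bonferroni adjustment
#' (`p_adj = min(1, m * p_raw)` over the m pairs). Alternatively plain
#' pairwise Student t tests.
#'
#' @param values Numeric vector of measurements.
#' @param group Grouping vector (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @param method `"anova_bonferroni"` (default) or `"t_test"`.
#' @return An object of class `"group_comparison"`: list with `anova`
#'   (`f`, `p`, `df`), `pairs` (data frame with `group1`, `group2`,
#'   `mean_diff`, `cohens_d`, `p_raw`, `p_adj`), `method`, `m` (number of
#'   pairs).
#' @export
compare_groups <- function(values, group,
                           method = c("anova_bonferroni", "t_test")) {
  method <- match.arg(method)
  group <- factor(group)
  if (length(values) != length(group))
    stop("'values' and 'group' must have equal length", call. = FALSE)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  tab <- table(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs at least 2 observations", call. = FALSE)
  vars <- tapply(values, group, stats::var)
  if (all(vars == 0))
    stop("degenerate: zero within-group variance in all groups", call. = FALSE)

  fit <- stats::aov(values ~ group)
  an <- stats::anova(fit)
  lev <- levels(group)
  pairs_idx <- utils::combn(lev, 2L, simplify = FALSE)
  m <- length(pairs_idx)

  if (method == "anova_bonferroni") {
    raw <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
  } else {
    raw <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                                  pool.sd = FALSE, var.equal = TRUE)$p.value
  }
  pairs <- do.call(rbind, lapply(pairs_idx, function(pr) {
    g1 <- pr[1]; g2 <- pr[2]
    x1 <- values[group == g1]; x2 <- values[group == g2]
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                  (length(x2) - 1) * stats::var(x2)) /
                 (length(x1) + length(x2) - 2))
    p_raw <- if (!is.na(raw[g2, g1])) raw[g2, g1] else raw[g1, g2]
    data.frame(group1 = g1, group2 = g2,
               mean_diff = mean(x1) - mean(x2),
               cohens_d = if (sp > 0) (mean(x1) - mean(x2)) / sp else NA_real_,
               p_raw = p_raw,
               p_adj = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  }))
  structure(list(anova = list(f = an$`F value`[1], p = an$`Pr(>F)`[1],
                              df = an$Df),
                 pairs = pairs, method = method, m = m),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$f, x$anova$p))
  cat(sprintf("Pairwise comparisons (%s; Bonferroni m = %d):\n",
              x$method, x$m))
  print(format(x$pairs, digits = digits), row.names = FALSE)
  invisible(x)
}
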