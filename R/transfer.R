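# Gated quantification of intercellular cargo transfer from flow-cytometry
# event tables: endothelial gating by DiI/PECAM dual positivity, cargo-positive
# percentage with background subtraction, condition differences and kinetics.

#' Inverse-hyperbolic-sine transform of cytometry intensities
#'
#' Standard display/gating transform for flow data: `asinh(x / cofactor)`.
#'
#' @param x Linear-scale intensities.
#' @param cofactor Transform cofactor; default 150.
#' @return Transformed intensities.
#' @export
asinh_transform <- function(x, cofactor = 150) asinh(x / cofactor)

#' Gate specification
#'
#' Per-channel thresholds on the asinh scale, either fixed or derived from a
#' negative control at a percentile (see [derive_gate()]).
#'
#' @param thresholds Named numeric vector of asinh-scale thresholds, e.g.
#'   `c(diI = 3.2, pecam = 3.1, cfse = 3.3)`.
#' @param rule `"fixed"` or `"percentile_of_control"`.
#' @param cofactor asinh cofactor the thresholds refer to.
#' @param percentile Percentile used (informational, for the control rule).
#' @return An object of class `"gate_spec"`.
#' @export
gate_spec <- function(thresholds, rule = c("fixed", "percentile_of_control"),
                      cofactor = 150, percentile = NA_real_) {
  rule <- match.arg(rule)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("'thresholds' must be a named vector", call. = FALSE)
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite", call. = FALSE)
  if (!is.na(percentile) && (percentile <= 50 || percentile >= 100))
    stop("'percentile' must lie in (50, 100)", call. = FALSE)
  structure(list(thresholds = thresholds, rule = rule, cofactor = cofactor,
                 percentile = percentile),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("Gate (%s%s, asinh cofactor %g):\n", x$rule,
              if (!is.na(x$percentile)) sprintf(" @ %g%%", x$percentile) else "",
              x$cofactor))
  print(round(x$thresholds, 3))
  invisible(x)
}

#' Derive gate thresholds from a negative control
#'
#' Places each channel's threshold at a high percentile (default 99.5) of the
#' negative-control events on the asinh scale, the conventional way of fixing
#' positivity gates when the experiment provides an unstained control.
#'
#' @param control_events Event table of the negative (unstained) control.
#' @param channels Channels to derive thresholds for.
#' @param percentile Percentile of the control distribution; default 99.5.
#' @param cofactor asinh cofactor.
#' @return A [gate_spec()] with rule `"percentile_of_control"`.
#' @export
derive_gate <- function(control_events, channels = c("diI", "pecam", "cfse"),
                        percentile = 99.5, cofactor = 150) {
  if (is.null(control_events) || !is.data.frame(control_events) ||
      nrow(control_events) == 0L)
    stop("percentile gating requires a non-empty control condition", call. = FALSE)
  missing_ch <- setdiff(channels, names(control_events))
  if (length(missing_ch))
    stop("control table lacks channels: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  thr <- vapply(channels, function(ch) {
    stats::quantile(asinh_transform(control_events[[ch]], cofactor),
                    probs = percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  gate_spec(thr, rule = "percentile_of_control", cofactor = cofactor,
            percentile = percentile)
}

#' Gate endothelial events by DiI/PECAM dual positivity
#'
#' Retains events above threshold in BOTH endothelial marker channels.
#'
#' @param events Event table with `diI` and `pecam` columns (linear scale).
#' @param gate A [gate_spec()] containing `diI` and `pecam` thresholds.
#' @return The endothelial subset of `events`.
#' @export
gate_endothelial <- function(events, gate) {
  stopifnot(is.data.frame(events), inherits(gate, "gate_spec"))
  need <- c("diI", "pecam")
  if (!all(need %in% names(events)))
    stop("event table lacks diI/pecam channels", call. = FALSE)
  if (!all(need %in% names(gate$thresholds)))
    stop("gate lacks diI/pecam thresholds", call. = FALSE)
  keep <- asinh_transform(events$diI, gate$cofactor) > gate$thresholds[["diI"]] &
    asinh_transform(events$pecam, gate$cofactor) > gate$thresholds[["pecam"]]
  events[keep, , drop = FALSE]
}

#' Cargo-positive percentage with background subtraction
#'
#' Raw percentage of gated events above the cargo-channel threshold; the
#' background percentage is measured identically on the gated cargo-free
#' control, and the corrected percentage is `max(0, raw - background)`
#' (percentage-point subtraction with clipping at zero). A normal-approximation
#' standard error and confidence interval for the corrected percentage are
#' propagated from the two binomial proportions.
#'
#' @param gated Gated endothelial event table of the condition of interest.
#' @param control_gated Gated event table of the cargo-free control.
#' @param gate A [gate_spec()] with a threshold for `channel`.
#' @param channel Cargo channel; default `"cfse"`.
#' @param conf_level Confidence level for the interval; default 0.95.
#' @return An object of class `"transfer_result"`: list with `pct_raw`,
#'   `pct_background`, `pct_corrected`, `se`, `ci`, `n_gated`, `n_control`,
#'   `channel` and the gate thresholds used.
#' @export
percent_positive <- function(gated, control_gated, gate, channel = "cfse",
                             conf_level = 0.95) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!is.data.frame(gated) || nrow(gated) == 0L)
    stop("empty gated event set: percentage undefined", call. = FALSE)
  if (!is.data.frame(control_gated) || nrow(control_gated) == 0L)
    stop("empty gated control set: background undefined", call. = FALSE)
  if (!channel %in% names(gate$thresholds))
    stop(sprintf("gate lacks a '%s' threshold", channel), call. = FALSE)
  thr <- gate$thresholds[[channel]]
  pos <- function(tab)
    mean(asinh_transform(tab[[channel]], gate$cofactor) > thr)
  p_raw <- pos(gated)
  p_bg <- pos(control_gated)
  corrected <- max(0, p_raw - p_bg)
  se <- sqrt(p_raw * (1 - p_raw) / nrow(gated) +
               p_bg * (1 - p_bg) / nrow(control_gated))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(100, pmax(0, 100 * c(p_raw - p_bg - z * se, p_raw - p_bg + z * se)))
  structure(list(pct_raw = 100 * p_raw, pct_background = 100 * p_bg,
                 pct_corrected = 100 * corrected, se = 100 * se, ci = ci,
                 n_gated = nrow(gated), n_control = nrow(control_gated),
                 channel = channel, thresholds = gate$thresholds,
                 conf_level = conf_level),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("%s+ among %d gated events: raw %.2f%%, background %.2f%%\n",
              x$channel, x$n_gated, x$pct_raw, x$pct_background))
  cat(sprintf("corrected %.2f%% (%.0f%% CI %.2f-%.2f)\n", x$pct_corrected,
              100 * x$conf_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Conduit-attributable transfer: co-culture minus baseline
#'
#' Difference in corrected cargo-positive percentages between the contact
#' (co-culture) condition and the contact-free (Boyden dual-culture) baseline,
#' isolating the component of transfer attributable to membrane conduits from
#' the basal exosome/gap-junction component. Normal-approximation CI from the
#' two results' standard errors.
#'
#' @param co,dual [percent_positive()] results for the two conditions.
#' @param conf_level Confidence level; default 0.95.
#' @return List with `difference_pp` (percentage points), `se`, `ci`.
#' @export
conduit_attributable_transfer <- function(co, dual, conf_level = 0.95) {
  stopifnot(inherits(co, "transfer_result"), inherits(dual, "transfer_result"))
  diff <- co$pct_corrected - dual$pct_corrected
  se <- sqrt(co$se^2 + dual$se^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(difference_pp = diff, se = se, ci = c(diff - z * se, diff + z * se))
}

#' Peak window of transfer kinetics
#'
#' Applies the [kinetics_peak()] contract to corrected cargo-positive
#' percentages measured over time.
#'
#' @param timepoint_h Increasing vector of at least 3 timepoints (h).
#' @param results List of [percent_positive()] results, or a numeric vector of
#'   corrected percentages, one per timepoint.
#' @param ... Passed to [kinetics_peak()].
#' @return A `"kinetics_peak"` object.
#' @export
transfer_kinetics <- function(timepoint_h, results, ...) {
  vals <- if (is.numeric(results)) results
  else vapply(results, function(r) {
    stopifnot(inherits(r, "transfer_result"))
    r$pct_corrected
  }, numeric(1))
  kinetics_peak(timepoint_h, vals, ...)
}
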