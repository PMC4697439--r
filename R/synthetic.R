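# Seeded generators for every input the analysis pipelines consume:
# projection-dimension tables, growth-kinetics series, cytometry event tables,
# composition labels and qPCR Ct tables. Every generator takes a mandatory
# seed and leaves the caller's RNG state untouched.

with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Population parameters reported as mean +/- s.e.m.
#'
#' Captures a published population summary (mean, standard error, reported n)
#' and the distribution family used to emulate it. The population standard
#' deviation is recovered as `sem * sqrt(n_reported)`.
#'
#' @param mean Population mean (any positive measurement unit).
#' @param sem Standard error of the mean, same unit.
#' @param n_reported Sample size behind the published s.e.m.; default 300.
#' @param distribution `"lognormal"` (default; required when the implied
#'   coefficient of variation exceeds what a positive-support normal allows)
#'   or `"truncated_normal"`.
#' @return An object of class `"population_params"`.
#' @export
#' @examples
#' # nanoscale-bridge short axis: 290 +/- 20 nm at n = 300
#' population_params(290, 20)
population_params <- function(mean, sem, n_reported = 300,
                              distribution = c("lognormal", "truncated_normal")) {
  distribution <- match.arg(distribution)
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(sem) || length(sem) != 1L || sem <= 0)
    stop("'sem' must be a single positive number", call. = FALSE)
  if (!is.numeric(n_reported) || length(n_reported) != 1L || n_reported < 2)
    stop("'n_reported' must be at least 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n_reported = n_reported,
                 sd = sem * sqrt(n_reported), distribution = distribution),
            class = "population_params")
}

# moment-matched lognormal: E = mean, SD = sd
lognormal_from_moments <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog2 <- log1p(cv2)
  if (!is.finite(sdlog2)) stop("infeasible moment match", call. = FALSE)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

draw_population <- function(p, n) {
  if (p$distribution == "lognormal") {
    if (p$sd == 0) return(rep(p$mean, n))
    lp <- lognormal_from_moments(p$mean, p$sd)
    stats::rlnorm(n, lp$meanlog, lp$sdlog)
  } else {
    x <- stats::rnorm(n, p$mean, p$sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), p$mean, p$sd)
    x
  }
}

#' Generate a synthetic projection-morphometry table
#'
#' Draws `n` membrane projections whose short- and long-axis populations are
#' moment-matched (lognormal by default) to the requested mean +/- s.e.m.
#' summaries. The defaults are the published nanoscale-bridge dimensions
#' (short axis 290 +/- 20 nm, long axis 30.69 +/- 2.43 um, n_reported = 300).
#'
#' @param short_axis,long_axis [population_params()] for the two axes, in nm.
#' @param n Number of projections to draw.
#' @param seed Mandatory integer seed.
#' @param kind_label True kind label stored with every record
#'   (`"nanobridge"` or `"lamellipodium"`).
#' @param condition Condition label.
#' @param timepoint_h Optional timepoint in hours (recycled).
#' @return A data frame with columns `structure_id`, `cell_id`, `condition`,
#'   `timepoint_h`, `short_axis_nm`, `long_axis_nm`, `kind_label`.
#' @export
#' @examples
#' head(gen_morphometry(n = 5, seed = 1))
gen_morphometry <- function(short_axis = population_params(290, 20, 300),
                            long_axis = population_params(30690, 2430, 300),
                            n, seed,
                            kind_label = "nanobridge",
                            condition = "co_culture",
                            timepoint_h = NA_real_) {
  stopifnot(inherits(short_axis, "population_params"),
            inherits(long_axis, "population_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be at least 1", call. = FALSE)
  with_local_seed(seed, {
    data.frame(
      structure_id = sprintf("s%05d", seq_len(n)),
      cell_id = sprintf("c%04d", sample.int(max(1L, as.integer(ceiling(n / 3))),
                                            n, replace = TRUE)),
      condition = condition,
      timepoint_h = rep_len(timepoint_h, n),
      short_axis_nm = draw_population(short_axis, n),
      long_axis_nm = draw_population(long_axis, n),
      kind_label = kind_label,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic projection growth-kinetics series
#'
#' Mean projection length over time follows a logistic rise toward `plateau_nm`
#' reaching ~97.5% of the plateau at `t_peak_h`, followed by a slow post-peak
#' relaxation (`decay_per_h`), so that the population peaks in a genuine
#' interior window around `t_peak_h` (the published window is 15-20 h).
#' Additive Gaussian noise perturbs the per-timepoint means.
#'
#' @param plateau_nm Plateau mean length in nm.
#' @param t_peak_h Time of peak mean length, hours; must lie inside the range
#'   of `timepoints_h`.
#' @param rate_per_h Logistic growth rate (1/h).
#' @param timepoints_h Increasing vector of at least 3 sampling times (h).
#' @param n_per_t Number of structures measured per timepoint (reported only).
#' @param noise_sd_nm Standard deviation of additive noise on each mean (nm).
#' @param seed Mandatory integer seed.
#' @param decay_per_h Post-peak relaxation rate (1/h); default 0.05. With the
#'   default rise rate this puts the noiseless smoothed peak window at 16-19 h,
#'   inside the published 15-20 h window.
#' @return Data frame with `timepoint_h`, `mean_length_nm`, `sem_nm`, `n`.
#' @export
gen_kinetics <- function(plateau_nm = 25000, t_peak_h = 17.5, rate_per_h = 0.6,
                         timepoints_h = 0:24, n_per_t = 6, noise_sd_nm = 500,
                         seed, decay_per_h = 0.05) {
  if (length(timepoints_h) < 3L)
    stop("need at least 3 timepoints", call. = FALSE)
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("'timepoints_h' must be strictly increasing", call. = FALSE)
  if (t_peak_h < min(timepoints_h) || t_peak_h > max(timepoints_h))
    stop("'t_peak_h' must lie within the timepoint range", call. = FALSE)
  if (plateau_nm <= 0 || rate_per_h <= 0 || noise_sd_nm < 0 || decay_per_h < 0)
    stop("invalid kinetics parameters", call. = FALSE)
  t_mid <- t_peak_h - stats::qlogis(0.975) / rate_per_h
  mu <- plateau_nm * stats::plogis(rate_per_h * (timepoints_h - t_mid)) *
    exp(-decay_per_h * pmax(0, timepoints_h - t_peak_h))
  with_local_seed(seed, {
    noisy <- mu + stats::rnorm(length(mu), 0, noise_sd_nm)
    data.frame(timepoint_h = timepoints_h,
               mean_length_nm = noisy,
               sem_nm = noise_sd_nm / sqrt(max(1, n_per_t)),
               n = n_per_t)
  })
}

default_channel_params <- function() {
  list(diI   = list(neg_median = 100, pos_median = 3000, sdlog = 0.5),
       pecam = list(neg_median = 100, pos_median = 3000, sdlog = 0.5),
       cfse  = list(neg_median = 100, pos_median = 3000, sdlog = 0.5))
}

#' Generate a synthetic flow-cytometry event table
#'
#' Events are a mixture of endothelial and cancer cells. Endothelial events are
#' high in the DiI-Ac-LDL and PECAM-1 channels; a `true_transfer_fraction` of
#' them carry high cargo (CFSE) signal, and an additional `background_rate`
#' are spuriously cargo-high in every condition (the condition-independent
#' exosome/autofluorescence baseline). Cancer events are cargo-loaded (high
#' CFSE) unless `condition = "unstained"`, in which case every channel of every
#' event is drawn from its negative population (the threshold-setting control).
#' Intensities are lognormal on a linear scale with >= 10x median separation
#' between negative and positive populations; ground-truth labels are retained
#' for oracle-based testing.
#'
#' @param condition One of `"co_culture"`, `"dual_culture"`, `"inhibitor"`,
#'   `"control"` (cargo-free stained control), `"unstained"`.
#' @param true_transfer_fraction Fraction of endothelial events that truly
#'   received cargo.
#' @param background_rate Fraction of endothelial events spuriously cargo-high.
#' @param endo_fraction Fraction of events that are endothelial.
#' @param channel_params Per-channel list of `neg_median`, `pos_median`,
#'   `sdlog`; see `nanobridge:::default_channel_params()`.
#' @param n_events Number of events (>= 1000 for quantification use).
#' @param seed Mandatory integer seed.
#' @return Data frame with columns `event_id`, `condition`, `diI`, `pecam`,
#'   `cfse`, `true_endothelial`, `true_cfse_class` (one of `transfer`,
#'   `background`, `negative`, `cancer_load`). If positive/negative medians of
#'   any channel are separated by less than 10x, attribute
#'   `"separation_warning"` is set to `TRUE`.
#' @export
gen_facs_events <- function(condition = c("co_culture", "dual_culture",
                                          "inhibitor", "control", "unstained"),
                            true_transfer_fraction = 0,
                            background_rate = 0.03,
                            endo_fraction = 0.5,
                            channel_params = default_channel_params(),
                            n_events = 50000, seed) {
  condition <- match.arg(condition)
  for (p in c(true_transfer_fraction, background_rate, endo_fraction))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
  if (true_transfer_fraction + background_rate > 1)
    stop("transfer fraction plus background rate exceeds 1", call. = FALSE)
  if (n_events < 1000)
    stop("'n_events' must be at least 1000", call. = FALSE)

  sep_warn <- any(vapply(channel_params,
                         function(ch) ch$pos_median / ch$neg_median < 10,
                         logical(1)))

  draw <- function(ch, positive) {
    med <- ifelse(positive, ch$pos_median, ch$neg_median)
    stats::rlnorm(length(positive), meanlog = log(med), sdlog = ch$sdlog)
  }

  out <- with_local_seed(seed, {
    endo <- stats::runif(n_events) < endo_fraction
    cls <- rep("cancer_load", n_events)
    u <- stats::runif(n_events)
    cls[endo] <- ifelse(u[endo] < true_transfer_fraction, "transfer",
                        ifelse(u[endo] < true_transfer_fraction + background_rate,
                               "background", "negative"))
    stained <- condition != "unstained"
    cfse_hi <- if (stained) cls %in% c("transfer", "background", "cancer_load")
               else rep(FALSE, n_events)
    data.frame(
      event_id = seq_len(n_events),
      condition = condition,
      diI = draw(channel_params$diI, stained & endo),
      pecam = draw(channel_params$pecam, stained & endo),
      cfse = draw(channel_params$cfse, cfse_hi),
      true_endothelial = endo,
      true_cfse_class = cls,
      stringsAsFactors = FALSE
    )
  })
  attr(out, "separation_warning") <- sep_warn
  out
}

#' Generate synthetic cytoskeletal composition labels
#'
#' Independent Bernoulli draws of whether each nanoscale bridge contains both
#' actin and tubulin (probability `p_dual`, published value ~0.70) or actin
#' only.
#'
#' @param p_dual Probability of dual actin+tubulin composition.
#' @param n Number of structures.
#' @param seed Mandatory integer seed.
#' @return Data frame with `structure_id` and `composition`
#'   (`"actin_plus_tubulin"` or `"actin_only"`).
#' @export
gen_composition_labels <- function(p_dual = 0.7, n, seed) {
  if (!is.numeric(p_dual) || p_dual < 0 || p_dual > 1)
    stop("'p_dual' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("'n' must be at least 1", call. = FALSE)
  with_local_seed(seed, {
    dual <- stats::rbinom(n, 1L, p_dual) == 1L
    data.frame(structure_id = sprintf("s%05d", seq_len(n)),
               composition = ifelse(dual, "actin_plus_tubulin", "actin_only"),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic qPCR Ct table with embedded fold changes
#'
#' For each condition, the target-gene Ct is shifted by `-log2(fold)` relative
#' to the base target Ct, so a noiseless table recovers the embedded folds
#' exactly under delta-delta-Ct quantification against the fold-1 calibrator;
#' the reference gene is constant up to noise.
#'
#' @param fold_changes Named numeric vector of expression folds per condition
#'   (relative to the calibrator, which should carry fold 1). All > 0.
#' @param base_ct_target,base_ct_reference Baseline threshold cycles.
#' @param noise_sd Gaussian Ct noise s.d. (cycles).
#' @param replicates Technical replicates per (condition, gene); >= 2.
#' @param seed Mandatory integer seed.
#' @return Data frame with `sample_id`, `condition`, `gene` (`"target"` or
#'   `"reference"`), `replicate`, `ct`.
#' @export
#' @examples
#' gen_ct_table(c(recipient = 5, control_mirna = 1), noise_sd = 0,
#'              replicates = 2, seed = 1)
gen_ct_table <- function(fold_changes = c(recipient = 5, antagomir = 1 / 26,
                                          control_mirna = 1),
                         base_ct_target = 24, base_ct_reference = 20,
                         noise_sd = 0.1, replicates = 3, seed) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes))))
    stop("'fold_changes' must be a named vector", call. = FALSE)
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    stop("fold changes must be strictly positive", call. = FALSE)
  if (replicates < 2) stop("'replicates' must be at least 2", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  conds <- names(fold_changes)
  with_local_seed(seed, {
    rows <- lapply(conds, function(cond) {
      ct_t <- base_ct_target - log2(fold_changes[[cond]]) +
        stats::rnorm(replicates, 0, noise_sd)
      ct_r <- base_ct_reference + stats::rnorm(replicates, 0, noise_sd)
      data.frame(sample_id = paste0(cond, "_1"),
                 condition = cond,
                 gene = rep(c("target", "reference"), each = replicates),
                 replicate = rep(seq_len(replicates), 2L),
                 ct = c(ct_t, ct_r),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
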