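#' Filament class: geometric and mechanical properties of one cytoskeletal polymer
#'
#' Describes a single filament species (actin microfilament or microtubule) by
#' its cross-sectional radius and thermal persistence length. These are the two
#' properties the composite-bundle mechanics needs: the radius sets the packed
#' footprint, the persistence length sets the flexural rigidity per filament
#' (`B_i = kT * L_p,i`).
#'
#' @param name Identifier, e.g. `"actin"` or `"tubulin"`.
#' @param radius_nm Filament radius in nm (actin ~3.5 nm; a microtubule ~14 nm,
#'   i.e. 4x the actin radius).
#' @param persistence_length_nm Persistence length in nm (actin ~17.7 um;
#'   microtubule ~5.2 mm).
#' @return An object of class `"filament_class"` (a named list).
#' @seealso [bundle_model()]
#' @export
#' @examples
#' filament_class("actin", 3.5, 17700)
filament_class <- function(name, radius_nm, persistence_length_nm) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L || radius_nm <= 0)
    stop("'radius_nm' must be a single positive number", call. = FALSE)
  if (!is.numeric(persistence_length_nm) || length(persistence_length_nm) != 1L ||
      persistence_length_nm <= 0)
    stop("'persistence_length_nm' must be a single positive number", call. = FALSE)
  structure(list(name = name, radius_nm = radius_nm,
                 persistence_length_nm = persistence_length_nm),
            class = "filament_class")
}

#' Physical constants of the projection-buckling model
#'
#' @param thermal_energy_pNnm Thermal energy kT in pN nm. Default 4.28
#'   (T = 310 K, body temperature).
#' @param load_force_pN Axial load F the projection must withstand, in pN.
#' @param packing_fraction Areal fraction phi of the bundle cross-section
#'   occupied by filaments; default 0.9069 (hexagonal close packing of discs).
#' @param boundary_factor Non-dimensional Euler buckling prefactor I; default
#'   `pi^2/4` (clamped-free column). Must lie in `[pi^2/4, 4*pi^2]`, the span
#'   from clamped-free to clamped-clamped boundary conditions.
#' @param coupling_exponent Exponent gamma in the bundle-rigidity law
#'   `B = kT * N^(gamma-1) * sum(n_i * L_p,i)`. The default 1 is the uncoupled
#'   (independent-filament) bundle; 2 corresponds to fully cross-linked.
#' @return An object of class `"mech_constants"`.
#' @export
mech_constants <- function(thermal_energy_pNnm = 4.28,
                           load_force_pN = 10,
                           packing_fraction = 0.9069,
                           boundary_factor = pi^2 / 4,
                           coupling_exponent = 1) {
  for (nm in c("thermal_energy_pNnm", "load_force_pN", "packing_fraction",
               "boundary_factor", "coupling_exponent")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (packing_fraction > 1)
    stop("'packing_fraction' must lie in (0, 1]", call. = FALSE)
  if (boundary_factor < pi^2 / 4 - 1e-12 || boundary_factor > 4 * pi^2 + 1e-12)
    stop("'boundary_factor' must lie in [pi^2/4, 4*pi^2]", call. = FALSE)
  structure(list(thermal_energy_pNnm = thermal_energy_pNnm,
                 load_force_pN = load_force_pN,
                 packing_fraction = packing_fraction,
                 boundary_factor = boundary_factor,
                 coupling_exponent = coupling_exponent),
            class = "mech_constants")
}

#' Composite actin/microtubule bundle mechanics model
#'
#' Constructs the mechanical model of a membrane projection supported by a
#' bundle of `n_actin` actin filaments and `n_tubulin` microtubules. The model
#' treats the bundle as an Euler column of additive flexural rigidity
#' `B = kT * (n_a * L_p,a + n_t * L_p,t)` packed hexagonally inside the
#' projection, so that a projection of length L buckles under axial force
#' `F_b = I * B / L^2`, the longest load-bearing projection is
#' `L_max = sqrt(I * B / F)`, and the smallest circumscribing diameter is
#' `D_min = 2 * sqrt((n_a r_a^2 + n_t r_t^2) / phi)`.
#'
#' All downstream mechanics functions ([bundle_rigidity()], [buckling_force()],
#' [buckling_length()], [min_diameter()], [feasibility_curve()],
#' [classify_feasibility()]) take this object as their first argument.
#'
#' @param actin,tubulin [filament_class()] objects for the two species.
#' @param constants A [mech_constants()] object.
#' @return An object of class `"bundle_model"`.
#' @export
#' @examples
#' m <- bundle_model()
#' m
#' # the longest actin-only projection that fits a 290-nm-wide bridge
#' b <- max_filaments_for_diameter(m, 290, tubulin_fraction = 0)
#' buckling_length(m, b$n_actin, b$n_tubulin)
bundle_model <- function(actin = filament_class("actin", 3.5, 17700),
                         tubulin = filament_class("tubulin", 14, 5.2e6),
                         constants = mech_constants()) {
  stopifnot(inherits(actin, "filament_class"),
            inherits(tubulin, "filament_class"),
            inherits(constants, "mech_constants"))
  structure(list(actin = actin, tubulin = tubulin, constants = constants),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  cat("Composite filament-bundle buckling model\n")
  cat(sprintf("  %-8s r = %6.1f nm, L_p = %.4g nm\n", x$actin$name,
              x$actin$radius_nm, x$actin$persistence_length_nm))
  cat(sprintf("  %-8s r = %6.1f nm, L_p = %.4g nm\n", x$tubulin$name,
              x$tubulin$radius_nm, x$tubulin$persistence_length_nm))
  con <- x$constants
  cat(sprintf("  kT = %.3g pN nm, load F = %.3g pN, phi = %.4f, I = %.4f\n",
              con$thermal_energy_pNnm, con$load_force_pN,
              con$packing_fraction, con$boundary_factor))
  if (con$coupling_exponent != 1)
    cat(sprintf("  coupling exponent = %.3g\n", con$coupling_exponent))
  invisible(x)
}

check_counts <- function(n_actin, n_tubulin) {
  if (any(n_actin < 0) || any(n_tubulin < 0))
    stop("filament counts must be non-negative", call. = FALSE)
  if (any(n_actin + n_tubulin < 1))
    stop("bundle must contain at least one filament", call. = FALSE)
  invisible(NULL)
}

#' Flexural rigidity of a mixed filament bundle
#'
#' Additive (uncoupled) bundle rigidity `B = kT * (n_a L_p,a + n_t L_p,t)`,
#' in pN nm^2. With a coupling exponent gamma != 1 the sum is multiplied by
#' `N^(gamma-1)`. The equivalent bundle persistence length is `B / kT`.
#'
#' @param model A [bundle_model()].
#' @param n_actin,n_tubulin Filament counts (vectorized).
#' @return Flexural rigidity in pN nm^2.
#' @export
bundle_rigidity <- function(model, n_actin, n_tubulin = 0) {
  stopifnot(inherits(model, "bundle_model"))
  check_counts(n_actin, n_tubulin)
  con <- model$constants
  n_tot <- n_actin + n_tubulin
  base <- n_actin * model$actin$persistence_length_nm +
    n_tubulin * model$tubulin$persistence_length_nm
  con$thermal_energy_pNnm * n_tot^(con$coupling_exponent - 1) * base
}

#' Euler buckling force of a projection
#'
#' Critical axial force `F_b = I * B / L^2` (pN) above which a projection of
#' length `length_nm` supported by the given bundle bows.
#'
#' @inheritParams bundle_rigidity
#' @param length_nm Projection length L in nm; must be strictly positive
#'   (the force diverges as L -> 0).
#' @return Buckling force in pN.
#' @export
buckling_force <- function(model, n_actin, n_tubulin = 0, length_nm) {
  stopifnot(inherits(model, "bundle_model"))
  if (any(!is.finite(length_nm)) || any(length_nm <= 0))
    stop("'length_nm' must be strictly positive", call. = FALSE)
  B <- bundle_rigidity(model, n_actin, n_tubulin)
  model$constants$boundary_factor * B / length_nm^2
}

#' Buckling length: the longest projection that withstands a given load
#'
#' `L_max = sqrt(I * B / F)` in nm; inverse of [buckling_force()] at force
#' `load_force_pN`.
#'
#' @inheritParams bundle_rigidity
#' @param load_force_pN Axial load in pN; defaults to the model constant.
#' @return Maximum sustainable projection length in nm.
#' @export
buckling_length <- function(model, n_actin, n_tubulin = 0,
                            load_force_pN = model$constants$load_force_pN) {
  stopifnot(inherits(model, "bundle_model"))
  if (any(!is.finite(load_force_pN)) || any(load_force_pN <= 0))
    stop("'load_force_pN' must be strictly positive", call. = FALSE)
  B <- bundle_rigidity(model, n_actin, n_tubulin)
  sqrt(model$constants$boundary_factor * B / load_force_pN)
}

#' Minimum packed diameter of a bundle
#'
#' Smallest circumscribing diameter `D_min = 2 * sqrt((n_a r_a^2 + n_t r_t^2)
#' / phi)` (nm) at areal packing fraction phi. The same formula is applied down
#' to a single filament for continuity (slightly above `2r` there).
#'
#' @inheritParams bundle_rigidity
#' @return Minimum diameter in nm.
#' @export
min_diameter <- function(model, n_actin, n_tubulin = 0) {
  stopifnot(inherits(model, "bundle_model"))
  check_counts(n_actin, n_tubulin)
  area <- n_actin * model$actin$radius_nm^2 +
    n_tubulin * model$tubulin$radius_nm^2
  2 * sqrt(area / model$constants$packing_fraction)
}

#' Largest bundle of a given composition that packs inside a diameter
#'
#' Inverts the packed-diameter relation: finds the largest total filament count
#' N whose bundle, split between actin and tubulin at a tubulin number fraction
#' as close as possible to `tubulin_fraction`, has `min_diameter` at most
#' `diameter_nm`. Counts are integers; composition rounding ties resolve toward
#' fewer microtubules (conservative feasibility).
#'
#' @param model A [bundle_model()].
#' @param diameter_nm Available diameter in nm.
#' @param tubulin_fraction Target tubulin number fraction in `[0, 1]`.
#' @return A list with `n_actin`, `n_tubulin`, `n_total`, `tubulin_fraction`
#'   (achieved) and `min_diameter_nm`.
#' @export
max_filaments_for_diameter <- function(model, diameter_nm, tubulin_fraction = 0) {
  stopifnot(inherits(model, "bundle_model"))
  if (!is.numeric(diameter_nm) || length(diameter_nm) != 1L || diameter_nm <= 0)
    stop("'diameter_nm' must be a single positive number", call. = FALSE)
  if (!is.numeric(tubulin_fraction) || length(tubulin_fraction) != 1L ||
      tubulin_fraction < 0 || tubulin_fraction > 1)
    stop("'tubulin_fraction' must lie in [0, 1]", call. = FALSE)
  r_a <- model$actin$radius_nm
  r_t <- model$tubulin$radius_nm
  phi <- model$constants$packing_fraction
  budget <- phi * (diameter_nm / 2)^2  # allowed sum of n_i r_i^2

  split <- function(N) {
    # tie (f*N exactly half-integer) resolves toward fewer microtubules
    n_t <- ceiling(tubulin_fraction * N - 0.5)
    n_t <- max(0L, min(N, as.integer(n_t)))
    c(n_a = N - n_t, n_t = n_t)
  }
  fits <- function(N) {
    s <- split(N)
    s[["n_a"]] * r_a^2 + s[["n_t"]] * r_t^2 <= budget + 1e-9
  }
  if (!fits(1L))
    stop("zero capacity: diameter smaller than one filament's packed footprint",
         call. = FALSE)
  # descend from an upper bound computed with the composition's mean footprint
  a_mix <- (1 - tubulin_fraction) * r_a^2 + tubulin_fraction * r_t^2
  N <- as.integer(floor(budget / min(a_mix, r_a^2))) + 2L
  while (N > 1L && !fits(N)) N <- N - 1L
  s <- split(N)
  list(n_actin = as.integer(s[["n_a"]]), n_tubulin = as.integer(s[["n_t"]]),
       n_total = as.integer(N),
       tubulin_fraction = s[["n_t"]] / N,
       min_diameter_nm = min_diameter(model, s[["n_a"]], s[["n_t"]]))
}

#' Feasibility curve: maximum projection length versus minimum diameter
#'
#' For each diameter on the grid, packs the largest bundle of the requested
#' tubulin fraction into that diameter and evaluates its buckling length at the
#' model's load force. Points to the upper-left of the curve (longer and
#' thinner) are mechanically infeasible at that composition.
#'
#' @param model A [bundle_model()].
#' @param tubulin_fraction Tubulin number fraction of the bundles.
#' @param diameter_grid_nm Strictly increasing vector of diameters in nm; each
#'   must pack at least one filament.
#' @return A data frame of class `"feasibility_curve"` with columns
#'   `diameter_nm`, `max_length_nm`, `n_actin`, `n_tubulin`; the model is
#'   attached as attribute `"model"` and the composition as
#'   `"tubulin_fraction"`.
#' @export
feasibility_curve <- function(model, tubulin_fraction, diameter_grid_nm) {
  stopifnot(inherits(model, "bundle_model"))
  if (length(diameter_grid_nm) == 0L)
    stop("'diameter_grid_nm' must be non-empty", call. = FALSE)
  if (is.unsorted(diameter_grid_nm, strictly = TRUE))
    stop("'diameter_grid_nm' must be strictly increasing", call. = FALSE)
  rows <- lapply(diameter_grid_nm, function(d) {
    b <- max_filaments_for_diameter(model, d, tubulin_fraction)
    data.frame(diameter_nm = d,
               max_length_nm = buckling_length(model, b$n_actin, b$n_tubulin),
               n_actin = b$n_actin, n_tubulin = b$n_tubulin)
  })
  out <- do.call(rbind, rows)
  attr(out, "tubulin_fraction") <- tubulin_fraction
  attr(out, "model") <- model
  class(out) <- c("feasibility_curve", "data.frame")
  out
}

#' @export
plot.feasibility_curve <- function(x, ..., log = "y",
                                   xlab = "minimum diameter (nm)",
                                   ylab = "maximum length (nm)") {
  graphics::plot(x$diameter_nm, x$max_length_nm, type = "l", log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Classify a projection geometry as mechanically feasible or not
#'
#' A projection of the given length and diameter is feasible at a composition
#' iff its length does not exceed the buckling length of the largest bundle of
#' that composition packable within the diameter.
#'
#' @param model A [bundle_model()].
#' @param length_nm Projection length in nm (>= 0).
#' @param diameter_nm Projection diameter in nm (> 0).
#' @param tubulin_fraction Tubulin number fraction of the supporting bundle.
#' @return `"feasible"` or `"infeasible"`.
#' @export
#' @examples
#' m <- bundle_model()
#' # the observed mean bridge geometry cannot be actin-only at a 10 pN load
#' classify_feasibility(m, length_nm = 30690, diameter_nm = 290,
#'                      tubulin_fraction = 0)
classify_feasibility <- function(model, length_nm, diameter_nm,
                                 tubulin_fraction = 0) {
  stopifnot(inherits(model, "bundle_model"))
  if (!is.numeric(length_nm) || length_nm < 0)
    stop("'length_nm' must be non-negative", call. = FALSE)
  b <- max_filaments_for_diameter(model, diameter_nm, tubulin_fraction)
  lmax <- buckling_length(model, b$n_actin, b$n_tubulin)
  if (length_nm <= lmax) "feasible" else "infeasible"
}

#' Predicted maximum length for projection geometries
#'
#' `predict()` on a [bundle_model()] evaluates, for each row of `newdata`, the
#' buckling length of the largest bundle of the requested composition that
#' packs inside the given diameter.
#'
#' @param object A [bundle_model()].
#' @param newdata Data frame with columns `diameter_nm` and (optionally)
#'   `tubulin_fraction` (default 0).
#' @param ... Unused.
#' @return Numeric vector of maximum lengths in nm.
#' @export
predict.bundle_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), "diameter_nm" %in% names(newdata))
  f <- if ("tubulin_fraction" %in% names(newdata)) newdata$tubulin_fraction
       else rep(0, nrow(newdata))
  vapply(seq_len(nrow(newdata)), function(i) {
    b <- max_filaments_for_diameter(object, newdata$diameter_nm[i], f[i])
    buckling_length(object, b$n_actin, b$n_tubulin)
  }, numeric(1))
}

#' Optimal tubulin fraction of a composite bundle
#'
#' Maximizes the flexural performance `P(f) = L_max(f) / D_min(f)^2` of a
#' bundle at fixed total filament count over its tubulin number fraction f,
#' where q is the squared tubulin/actin radius ratio and rho the
#' tubulin/actin persistence-length ratio. On the continuous relaxation,
#' `P(f)` is proportional to `sqrt(1 + f(rho-1)) / (1 + f(q-1))`, giving the
#' closed-form optimum `f* = 1/(q-1) - 2/(rho-1)`. An interior optimum exists
#' only for `rho > 2q - 1`; otherwise the boundary `f = 0` is returned with
#' `boundary = TRUE`.
#'
#' With the 4x microtubule/actin radius ratio (q = 16) and a stiff-microtubule
#' persistence-length ratio rho = 3000, the optimum is 6.6%.
#'
#' @param lp_ratio rho = L_p,tubulin / L_p,actin (> 1).
#' @param radius_ratio_sq q = (r_tubulin / r_actin)^2 (> 1).
#' @param method `"closed_form"` (default) or `"numeric"` (1-D maximization of
#'   P(f) by [stats::optimize()] on `[0, 0.5]`).
#' @return A list with `fraction` (the optimal tubulin number fraction),
#'   `boundary` (TRUE if no interior optimum exists) and `method`.
#' @export
#' @examples
#' optimal_tubulin_fraction(lp_ratio = 3000, radius_ratio_sq = 16)
optimal_tubulin_fraction <- function(lp_ratio, radius_ratio_sq,
                                     method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  if (!is.numeric(lp_ratio) || length(lp_ratio) != 1L || lp_ratio <= 1)
    stop("'lp_ratio' must be a single number > 1", call. = FALSE)
  if (!is.numeric(radius_ratio_sq) || length(radius_ratio_sq) != 1L ||
      radius_ratio_sq <= 1)
    stop("'radius_ratio_sq' must be a single number > 1", call. = FALSE)
  q <- radius_ratio_sq
  rho <- lp_ratio
  if (rho <= 2 * q - 1)
    return(list(fraction = 0, boundary = TRUE, method = method))
  f_star <- 1 / (q - 1) - 2 / (rho - 1)
  if (method == "numeric") {
    perf <- function(f) sqrt(1 + f * (rho - 1)) / (1 + f * (q - 1))
    opt <- stats::optimize(perf, interval = c(0, 0.5), maximum = TRUE,
                           tol = 1e-10)
    f_star <- opt$maximum
  }
  list(fraction = f_star, boundary = FALSE, method = method)
}
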