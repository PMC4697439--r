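# Composite-bundle buckling mechanics: closed-form values, scaling laws,
# round-trip identities and the tubulin-fraction optimum.

test_that("bundle rigidity matches hand-computed values and is additive", {
  m <- default_model
  # single-filament identity B = kT * L_p
  expect_equal(bundle_rigidity(m, 1, 0), 4.28 * 17700)
  # hand sum: kT * (10 * 17,700 + 1 * 5,200,000)
  expect_equal(bundle_rigidity(m, 10, 1), 4.28 * (177000 + 5200000))
  # linearity / additivity over random splits
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(0:50, 2)
    n2 <- sample(0:50, 2)
    if (sum(n1) == 0) n1[1] <- 1
    if (sum(n2) == 0) n2[1] <- 1
    expect_equal(bundle_rigidity(m, n1[1] + n2[1], n1[2] + n2[2]),
                 bundle_rigidity(m, n1[1], n1[2]) +
                   bundle_rigidity(m, n2[1], n2[2]))
  }
  expect_equal(bundle_rigidity(m, 2, 4), 2 * bundle_rigidity(m, 1, 2))
  expect_error(bundle_rigidity(m, 0, 0), "at least one filament")
})

test_that("buckling force follows I*B/L^2 with inverse-square length scaling", {
  m <- default_model
  # closed form: (pi^2/4) * 75,756 / 1e8
  expect_equal(buckling_force(m, 1, 0, 1e4), (pi^2 / 4) * 4.28 * 17700 / 1e8)
  expect_equal(buckling_force(m, 1, 0, 2e4), buckling_force(m, 1, 0, 1e4) / 4)
  # linear in filament number: 100 actin at 10 um
  expect_equal(buckling_force(m, 100, 0, 1e4),
               100 * buckling_force(m, 1, 0, 1e4))
  expect_error(buckling_force(m, 1, 0, 0), "positive")
})

test_that("buckling force and buckling length round-trip exactly", {
  m <- default_model
  # inversion of the single-actin example
  f1 <- buckling_force(m, 1, 0, 1e4)
  expect_equal(buckling_length(m, 1, 0, load_force_pN = f1), 1e4,
               tolerance = 1e-9)
  # quadrupling the load halves L_max
  expect_equal(buckling_length(m, 5, 2, load_force_pN = 40),
               buckling_length(m, 5, 2, load_force_pN = 10) / 2)
  # round-trip property over random bundles and lengths
  set.seed(7)
  for (i in 1:25) {
    na <- sample(1:2000, 1); nt <- sample(0:100, 1)
    L <- stats::runif(1, 100, 5e4)
    f <- buckling_force(m, na, nt, L)
    expect_equal(buckling_length(m, na, nt, load_force_pN = f), L,
                 tolerance = 1e-9)
    # F_b * L^2 / B is the boundary factor for every bundle and length
    expect_equal(f * L^2 / bundle_rigidity(m, na, nt),
                 m$constants$boundary_factor, tolerance = 1e-12)
  }
  expect_error(buckling_length(m, 1, 0, load_force_pN = -1), "positive")
})

test_that("minimum packed diameter matches the hexagonal-packing closed form", {
  m <- default_model
  expect_equal(min_diameter(m, 19, 0), 2 * sqrt(19 * 3.5^2 / 0.9069))
  expect_equal(min_diameter(m, 19, 0), 32.04, tolerance = 1e-3)
  # 1,556 actin filaments fill the observed 290-nm mean width
  expect_equal(min_diameter(m, 1556, 0), 290, tolerance = 1e-3)
  # swapping one actin for one tubulin adds (q - 1) = 15 actin footprints
  a1 <- min_diameter(m, 10, 0)^2
  a2 <- min_diameter(m, 9, 1)^2
  expect_equal((a2 - a1) * 0.9069 / 4, 15 * 3.5^2)
})

test_that("packing inversion finds the largest feasible bundle", {
  m <- default_model
  b <- max_filaments_for_diameter(m, 290, 0)
  expect_identical(b$n_actin, 1556L)
  expect_identical(b$n_tubulin, 0L)
  expect_lte(b$min_diameter_nm, 290)
  # adding one more filament must not fit
  expect_gt(min_diameter(m, 1557, 0), 290)
  # below a single filament's packed footprint: zero capacity
  d_one <- 2 * 3.5 / sqrt(0.9069)
  expect_error(max_filaments_for_diameter(m, d_one * 0.99, 0), "zero capacity")
  # round-trip property sweep across diameters and compositions
  for (d in c(30, 50, 150, 290, 600)) {
    for (f in c(0, 0.066, 0.3, 1)) {
      b <- max_filaments_for_diameter(m, d, f)
      expect_lte(b$min_diameter_nm, d + 1e-9)
    }
  }
})

test_that("feasibility curves are monotone and tubulin shifts them upward", {
  m <- default_model
  grid <- c(50, 100, 200, 290, 400, 600)
  actin_only <- feasibility_curve(m, 0, grid)
  expect_true(all(diff(actin_only$max_length_nm) >= 0))
  expect_true(all(diff(actin_only$diameter_nm) > 0))
  # actin-only point at the observed width: L_max ~ 5.39 um
  expect_equal(actin_only$max_length_nm[actin_only$diameter_nm == 290],
               5393, tolerance = 1e-3)
  # a near-optimal tubulin fraction beats actin-only at fixed diameter
  mixed <- feasibility_curve(m, 0.066, grid)
  expect_true(all(mixed$max_length_nm >= actin_only$max_length_nm))
  expect_gt(mixed$max_length_nm[mixed$diameter_nm == 290],
            actin_only$max_length_nm[actin_only$diameter_nm == 290])
  # a grid of one diameter packing exactly one filament: single-filament length
  d_one <- 2 * 3.5 / sqrt(0.9069)
  one <- feasibility_curve(m, 0, d_one * 1.001)
  expect_equal(one$max_length_nm, buckling_length(m, 1, 0))
  expect_error(feasibility_curve(m, 0, numeric(0)), "non-empty")
})

test_that("observed mean bridge geometry is infeasible for actin alone", {
  m <- default_model
  expect_identical(classify_feasibility(m, 30690, 290, 0), "infeasible")
  expect_identical(classify_feasibility(m, 0, 290, 0), "feasible")
  expect_identical(classify_feasibility(m, 5000, 290, 0), "feasible")
  # tubulin at the optimum roughly triples the attainable length at 290 nm
  b <- max_filaments_for_diameter(m, 290, 0.066)
  expect_gt(buckling_length(m, b$n_actin, b$n_tubulin),
            3 * predict(m, data.frame(diameter_nm = 290)))
})

test_that("optimal tubulin fraction: closed form, asymptote and grid search", {
  o <- optimal_tubulin_fraction(3000, 16)
  expect_equal(o$fraction, 1 / 15 - 2 / 2999, tolerance = 1e-12)
  expect_equal(o$fraction, 0.0660, tolerance = 1e-3)
  expect_false(o$boundary)
  # numeric maximization agrees with the closed form
  on <- optimal_tubulin_fraction(3000, 16, method = "numeric")
  expect_equal(on$fraction, o$fraction, tolerance = 1e-6)
  # stiff-microtubule asymptote 1/15
  expect_equal(optimal_tubulin_fraction(1e12, 16)$fraction, 1 / 15,
               tolerance = 1e-6)
  # physiological persistence-length ratio 5.2 mm / 17.7 um
  expect_equal(optimal_tubulin_fraction(294, 16)$fraction, 0.0598,
               tolerance = 1e-3)
  # no interior optimum below rho = 2q - 1
  b <- optimal_tubulin_fraction(20, 16)
  expect_true(b$boundary)
  expect_identical(b$fraction, 0)
})

test_that("closed-form optimum equals brute-force grid maximization", {
  grid <- seq(0, 0.5, by = 1e-5)
  set.seed(11)
  for (i in 1:20) {
    q <- stats::runif(1, 4, 25)
    rho <- stats::runif(1, 2 * q + 5, 5000)
    perf <- sqrt(1 + grid * (rho - 1)) / (1 + grid * (q - 1))
    f_grid <- grid[which.max(perf)]
    f_closed <- optimal_tubulin_fraction(rho, q)$fraction
    expect_lt(abs(f_closed - f_grid), 1e-5)
  }
})

test_that("dimensionless outputs are invariant to expressing lengths in um", {
  # nm model vs the same physics expressed in um (kT in pN*um)
  m_nm <- default_model
  m_um <- bundle_model(
    actin = filament_class("actin", 3.5e-3, 17.7),
    tubulin = filament_class("tubulin", 14e-3, 5200),
    constants = mech_constants(thermal_energy_pNnm = 4.28e-3,
                               load_force_pN = 10)
  )
  expect_identical(classify_feasibility(m_um, 30.69, 0.290, 0),
                   classify_feasibility(m_nm, 30690, 290, 0))
  expect_identical(classify_feasibility(m_um, 5.0, 0.290, 0),
                   classify_feasibility(m_nm, 5000, 290, 0))
  # L_max scales by exactly 1e-3
  b_nm <- max_filaments_for_diameter(m_nm, 290, 0)
  b_um <- max_filaments_for_diameter(m_um, 0.290, 0)
  expect_identical(b_nm$n_actin, b_um$n_actin)
  expect_equal(buckling_length(m_um, b_um$n_actin, 0) * 1e3,
               buckling_length(m_nm, b_nm$n_actin, 0))
})

test_that("constructor validation rejects non-physical parameters", {
  expect_error(filament_class("x", -1, 100), "positive")
  expect_error(filament_class("x", 3.5, 0), "positive")
  expect_error(mech_constants(packing_fraction = 1.2), "0, 1")
  expect_error(mech_constants(boundary_factor = 1), "pi")
  expect_error(mech_constants(load_force_pN = 0), "positive")
})
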