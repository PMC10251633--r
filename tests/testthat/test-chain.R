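test_that("contour lengths convert monomer counts at the field's per-unit lengths", {
  expect_equal(contour_length(10, "rna"), 5.5)
  expect_equal(contour_length(10, "peptide"), 3.8)
  expect_equal(contour_length(1, "rna"), 0.55)
  expect_equal(contour_length(8, "rna", chain_constants(nm_per_nt = 0.6)), 4.8)
  expect_error(contour_length(0, "rna"), "positive")
  expect_error(contour_length(-3, "peptide"), "positive")
})

test_that("particle-in-a-sphere concentration is one molecule per sphere volume", {
  # oracle: 1 nm radius -> V = 4/3*pi*1e-24 L; c = 1/(N_A * V)
  v_litre <- 4 / 3 * pi * 1e-24
  expect_equal(c_sphere(1)$value, 1 / (6.02214076e23 * v_litre),
               tolerance = 1e-12)
  expect_equal(c_sphere(2)$value, c_sphere(1)$value / 8, tolerance = 1e-12)
  ls <- c(1, 2, 5, 10, 50)
  vals <- vapply(ls, function(l) c_sphere(l)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(c_sphere(1e4)$value, 1e-12)
  expect_error(c_sphere(0), "positive")
})

test_that("end-to-end variance follows the long-chain Gaussian law", {
  ch <- chain_segment(5.5, 2.7, "rna")
  expect_equal(end_to_end_variance(ch), 2 * 2.7 * 5.5 / 3)  # 9.9 nm^2
  ch2 <- chain_segment(11, 2.7, "rna")
  expect_equal(end_to_end_variance(ch2), 2 * end_to_end_variance(ch))
  soft <- chain_segment(5.5, 1e-6, "rna")
  expect_lt(end_to_end_variance(soft), 1e-5)
  # Kratky-Porod correction is smaller and converges for long chains
  expect_lt(end_to_end_variance(ch, exact = TRUE), end_to_end_variance(ch))
  long <- chain_segment(5000, 2.7, "rna")
  expect_equal(end_to_end_variance(long, exact = TRUE),
               end_to_end_variance(long), tolerance = 1e-3)
})

test_that("rigid-linkage WLC effective concentration matches direct Gaussian evaluation", {
  # oracle: sigma^2 = 9.9 nm^2, density (2*pi*s2)^-1.5 * exp(-d^2/(2 s2)),
  # 1 nm^-3 = 1e24/N_A M; frozen value
  cc <- suppressWarnings(c_eff_rigid(rna_linker(10), d_nm = 2))
  expect_equal(cc$value, 2.765606e-3, tolerance = 1e-6)
  # mode at d = 0, strictly decreasing in d
  ds <- seq(0, 6, by = 1)
  vals <- vapply(ds, function(d)
    c_eff_rigid(rna_linker(60), d_nm = d)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the implied number density integrates to one molecule", {
  ch <- rna_linker(70)
  dens_nm3 <- function(r) vapply(r, function(ri)
    molar_to_nm3(c_eff_rigid(ch, ri, warn = FALSE)$value), numeric(1))
  # upper limit far in the Gaussian tail (sigma ~ 8.3 nm)
  total <- stats::integrate(function(r) 4 * pi * r^2 * dens_nm3(r),
                            0, 100)$value
  expect_equal(total, 1, tolerance = 0.01)
})

test_that("molar/number-density unit conversion round-trips to machine precision", {
  x <- c(1e-9, 3.7e-4, 0.26, 12)
  expect_equal(molar_to_nm3(nm3_to_molar(x)), x, tolerance = 1e-15)
  s2 <- end_to_end_variance(rna_linker(70))
  cc <- c_eff_rigid(rna_linker(70), 1.5)
  expect_equal(molar_to_nm3(cc$value),
               (2 * pi * s2)^(-1.5) * exp(-1.5^2 / (2 * s2)),
               tolerance = 1e-15)
})

test_that("WLC concentration exceeds the sphere model for long chains and decays as l^-3/2", {
  lp <- chain_constants()$lp_rna_nm
  l <- 20 * lp
  wlc <- c_eff_rigid(chain_segment(l, lp, "rna"), 0)$value
  expect_gt(wlc, c_sphere(l)$value)
  # d = 0: wlc ~ l^-1.5 vs sphere ~ l^-3
  wlc2 <- c_eff_rigid(chain_segment(2 * l, lp, "rna"), 0)$value
  expect_equal(wlc2 / wlc, 2^-1.5, tolerance = 1e-10)
  expect_equal(c_sphere(2 * l)$value / c_sphere(l)$value, 2^-3,
               tolerance = 1e-10)
})

test_that("flexible linkage convolves variances of independent chains", {
  rna <- rna_linker(70)
  # empty peptide list degenerates to the rigid-linkage case
  expect_equal(c_eff_flexible(rna, list(), 1.2)$value,
               c_eff_rigid(rna, 1.2)$value)
  # an identical second chain doubles the variance: mode scales by 2^-1.5
  twin <- chain_segment(rna$contour_length_nm, rna$persistence_length_nm,
                        "peptide")
  expect_equal(c_eff_flexible(rna, list(twin), 0)$value,
               c_eff_rigid(rna, 0)$value * 2^-1.5, tolerance = 1e-12)
  # any added peptide widens the Gaussian and lowers the mode
  expect_lt(c_eff_flexible(rna, list(peptide_linker(10)), 0)$value,
            c_eff_rigid(rna, 0)$value)
  expect_lt(c_eff_flexible(rna, list(peptide_linker(10),
                                     peptide_linker(30)), 0)$value,
            c_eff_flexible(rna, list(peptide_linker(10)), 0)$value)
})

test_that("chains outside the Gaussian regime warn but still compute", {
  short <- rna_linker(10)    # l/(2 l_p) = 1.02 < 5.6
  expect_warning(c_eff_rigid(short, 1), "Gaussian regime")
  expect_silent(c_eff_rigid(rna_linker(60), 1))
  v <- suppressWarnings(c_eff_rigid(short, 1)$value)
  expect_gt(v, 0)
})
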