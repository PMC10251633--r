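two_site <- function(kd = c(1e-5, 1e-5), d = 2, linker = 10) {
  list(rbp = rbp_model(kd = kd, geometry = rigid_geometry(d, n = 2)),
       rna = rna_target(linker))
}

test_that("configuration enumeration covers all 2^n bitstrings in stable order", {
  expect_equal(enumerate_configurations(1), c("0", "1"))
  expect_equal(enumerate_configurations(2), c("00", "10", "01", "11"))
  expect_length(enumerate_configurations(3), 8)
  expect_setequal(nchar(enumerate_configurations(4)), 4)
  expect_error(enumerate_configurations(17), "capacity")
  expect_error(enumerate_configurations(0), "positive integer")
})

test_that("configuration weights follow stepwise mass action", {
  m <- two_site(kd = c(1e-5, 4e-5))
  c12 <- pair_effective_concentration(m$rbp, m$rna, 1, 2, warn = FALSE)$value
  expect_equal(configuration_weight(m$rbp, m$rna, "10"), 1e5)
  expect_equal(configuration_weight(m$rbp, m$rna, "01"), 2.5e4)
  expect_equal(configuration_weight(m$rbp, m$rna, "11"), 1e5 * c12 * 2.5e4)
  expect_error(configuration_weight(m$rbp, m$rna, "00"), "reference")
  expect_error(configuration_weight(m$rbp, m$rna, "1"), "bitstring")
})

test_that("a skipped site combines the intervening linkers and uses the direct d_ij", {
  rbp <- rbp_model(kd = rep(1e-5, 3),
                   geometry = rigid_geometry(c(2, 3), n = 3))
  rna <- rna_target(c(12, 20), motif_footprint_nt = 4)
  # oracle: tether = l_12 + footprint_2 + l_23 = 36 nt; d_13 = 5 nm
  s2 <- 2 * 2.7 * (36 * 0.55) / 3
  expected <- (2 * pi * s2)^(-1.5) * exp(-25 / (2 * s2)) *
    1e24 / 6.02214076e23
  c13 <- pair_effective_concentration(rbp, rna, 1, 3, warn = FALSE)
  expect_equal(c13$value, expected, tolerance = 1e-12)
  w101 <- configuration_weight(rbp, rna, "101")
  expect_equal(w101, 1e5 * expected * 1e5, tolerance = 1e-12)
})

test_that("pair effective concentration is symmetric in its end points", {
  m <- generate_synthetic_model(4, seed = 42)
  for (ij in list(c(1, 2), c(2, 4), c(1, 4))) {
    expect_equal(
      pair_effective_concentration(m$rbp, m$rna, ij[1], ij[2], warn = FALSE)$value,
      pair_effective_concentration(m$rbp, m$rna, ij[2], ij[1], warn = FALSE)$value)
  }
  expect_error(pair_effective_concentration(m$rbp, m$rna, 2, 2), "distinct")
})

test_that("exact avidity reduces correctly at the edges of the model", {
  # single domain: K_av is the bare association constant
  expect_equal(avidity_exact(rbp_model(ka = 1e5), rna_target(numeric(0)))$k_av,
               1e5)
  # huge linker: domains bind independently, K_av -> sum of K_a
  m <- two_site(kd = c(1e-5, 4e-5), linker = 5e5)
  expect_equal(avidity_exact(m$rbp, m$rna)$k_av, 1e5 + 2.5e4,
               tolerance = 1e-4)
  expect_error(avidity_exact(m$rbp, rna_target(c(5, 5))), "sites")
})

test_that("exact avidity equals the printed two-site closed form", {
  m <- two_site(kd = c(1e-5, 4e-5), d = 2.5, linker = 14)
  c12 <- pair_effective_concentration(m$rbp, m$rna, 1, 2, warn = FALSE)$value
  res <- suppressWarnings(avidity_exact(m$rbp, m$rna))
  expect_equal(res$k_av, 1e5 + 2.5e4 + 1e5 * c12 * 2.5e4)
  expect_equal(res$k_av, sum(unlist(res$weights)))
  # the printed worked example: equal 1e5 affinities at c12 = 1e-3 M
  closed_form <- avidity_fuzzy_two_site(diag(c(1e5, 1e5)), 1e-3)
  expect_equal(closed_form$k_av, 1.02e7)
})

test_that("exact avidity agrees with the brute-force reaction-network oracle", {
  for (seed in 1:25) {
    n <- 1 + (seed %% 5)
    m <- generate_synthetic_model(n, seed = seed)
    expect_equal(avidity_exact(m$rbp, m$rna, warn = FALSE)$k_av,
                 oracle_kav(m$rbp, m$rna),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("avidity is monotone in every affinity and bounded below by the independent sum", {
  for (seed in c(3, 17, 29)) {
    m <- generate_synthetic_model(3, seed = seed)
    base <- avidity_exact(m$rbp, m$rna, warn = FALSE)$k_av
    expect_gte(base, sum(m$rbp$ka))
    for (i in 1:3) {
      ka_up <- m$rbp$ka; ka_up[i] <- ka_up[i] * 3
      up <- rbp_model(ka = ka_up, geometry = m$rbp$geometry)
      expect_gt(avidity_exact(up, m$rna, warn = FALSE)$k_av, base)
    }
    # smaller inter-domain distances raise every c_ij
    closer <- rbp_model(ka = m$rbp$ka,
                        geometry = rigid_geometry(
                          m$rbp$geometry$distances_nm * 0.8))
    expect_gt(avidity_exact(closer, m$rna, warn = FALSE)$k_av, base)
  }
})

test_that("the fully bound weight does not depend on the direction of the path", {
  m <- generate_synthetic_model(4, seed = 9)
  # right-to-left product, written out independently of configuration_weight
  ka <- m$rbp$ka
  w <- ka[4]
  for (i in 3:1) {
    cc <- pair_effective_concentration(m$rbp, m$rna, i + 1, i, warn = FALSE)
    w <- w * cc$value * ka[i]
  }
  expect_equal(configuration_weight(m$rbp, m$rna, "1111"), w,
               tolerance = 1e-12)
})

test_that("the dominant-path approximation converges to the exact avidity", {
  # strong binders on short tethers: every step factor Ka*c >> 1
  m <- two_site(kd = c(1e-8, 1e-8), d = 1, linker = 8)
  ex <- suppressWarnings(avidity_exact(m$rbp, m$rna))
  ap <- suppressWarnings(avidity_approx(m$rbp, m$rna))
  step <- pair_effective_concentration(m$rbp, m$rna, 1, 2, warn = FALSE)$value * 1e8
  expect_gt(step, 1e4)
  expect_equal(ex$k_av / ap$k_av, 1, tolerance = 3 / step)
  # n = 1 degenerate product
  expect_equal(avidity_approx(rbp_model(ka = 2e4), rna_target(numeric(0)))$k_av,
               2e4)
  # weak step emits the validity warning
  weak <- two_site(kd = c(1e-3, 1e-3), d = 4, linker = 40)
  expect_warning(avidity_approx(weak$rbp, weak$rna), "validity")
})

test_that("same-specificity (fuzzy) two-site binding adds the swapped assignments", {
  m <- two_site(kd = c(1e-5, 4e-5))
  c12 <- pair_effective_concentration(m$rbp, m$rna, 1, 2, warn = FALSE)$value
  specific <- suppressWarnings(avidity_exact(m$rbp, m$rna))$k_av
  # off-diagonal zero reduces exactly to the strictly matched model
  expect_equal(avidity_fuzzy_two_site(diag(c(1e5, 2.5e4)), c12)$k_av,
               specific)
  # fully symmetric affinities strictly exceed the specific-binding avidity
  ka_sym <- matrix(c(1e5, 1e5, 2.5e4, 2.5e4), 2, 2)
  expect_gt(avidity_fuzzy_two_site(ka_sym, c12)$k_av, specific)
  # one domain dead: the other binds either site independently
  ka_dead <- matrix(c(0, 0, 3e4, 5e4), 2, 2, byrow = TRUE)
  expect_equal(avidity_fuzzy_two_site(ka_dead, c12)$k_av, 3e4 + 5e4)
  expect_error(avidity_fuzzy_two_site(matrix(1, 3, 3), c12), "2 x 2")
})

test_that("register multiplicity scales the association constant linearly", {
  expect_equal(register_adjusted_ka(2e4, 3), 6e4)
  expect_equal(register_adjusted_ka(7e5, 1), 7e5)
  ns <- 1:6
  expect_true(all(diff(vapply(ns, function(k)
    register_adjusted_ka(1e4, k), numeric(1))) > 0))
  expect_error(register_adjusted_ka(1e4, 0), "integer")
})

test_that("occupancy is the standard binding isotherm", {
  expect_equal(occupancy(1e7, 1e-7), 0.5)
  expect_equal(occupancy(2e4, 5e-5), 0.5)
  expect_gt(occupancy(1e7, 1e-2), 0.9999)
  expect_lt(occupancy(1e7, 1e-12), 1e-4)
  expect_error(occupancy(-1, 1e-7), "positive")
  expect_error(occupancy(1e7, 0), "positive")
})
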