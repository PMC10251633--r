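settings_for <- function(protein_conc, ...) {
  sim_settings(protein_conc = protein_conc, t_end = 100, replicates = 6,
               seed = 1, ...)
}

test_that("the reaction network has the hypercube shape", {
  m1 <- list(rbp = rbp_model(ka = 1e5), rna = rna_target(numeric(0)))
  net1 <- build_network(m1$rbp, m1$rna, settings_for(1e-5))
  expect_length(net1$configs, 2)
  expect_length(net1$rate, 2)
  m2 <- generate_synthetic_model(2, seed = 4)
  net2 <- build_network(m2$rbp, m2$rna, settings_for(1e-5))
  expect_length(net2$configs, 4)
  expect_length(net2$rate, 8)       # 4 undirected edges, both directions
  big <- rbp_model(ka = rep(1e5, 11), geometry = rigid_geometry(2, n = 11))
  expect_error(build_network(big, rna_target(rep(10, 10)),
                             settings_for(1e-5)),
               "n <= 10")
})

test_that("detailed balance holds edge-by-edge (hence on every cycle) for both rate splits", {
  m <- generate_synthetic_model(3, seed = 21)
  for (split in c("uniform", "balanced")) {
    st <- settings_for(2e-6, rate_split = split)
    net <- build_network(m$rbp, m$rna, st)
    # stationary measure: 1 for the free state, w(S) * c for bound states
    pi_meas <- net$weights
    pi_meas[net$bound] <- pi_meas[net$bound] * st$protein_conc
    for (k in seq_along(net$rate)) {
      rev <- which(net$from == net$to[k] & net$to == net$from[k])
      expect_equal(unname(pi_meas[net$from[k]] * net$rate[k]),
                   unname(pi_meas[net$to[k]] * net$rate[rev]),
                   tolerance = 1e-10)
    }
  }
})

test_that("network rates reproduce the analytic avidity through the stationary distribution", {
  for (seed in c(2, 12)) {
    m <- generate_synthetic_model(3, seed = seed)
    ex <- avidity_exact(m$rbp, m$rna, warn = FALSE)$k_av
    st <- settings_for(1 / ex, rate_split = "balanced", kon_scale = 1)
    net <- build_network(m$rbp, m$rna, st)
    expect_equal(network_kav_stationary(net, st$protein_conc), ex,
                 tolerance = 1e-6)
  }
})

test_that("single-site simulation recovers the closed-form equilibrium", {
  rbp <- rbp_model(ka = 1e5); rna <- rna_target(numeric(0))
  st <- sim_settings(protein_conc = 1e-5, t_end = 400, replicates = 8,
                     seed = 3)
  est <- run_and_estimate(build_network(rbp, rna, st))
  expect_equal(est$bound_fraction, 0.5, tolerance = 0.1)
  expect_lt(abs(est$k_av_hat - 1e5), 3 * est$stderr)
})

test_that("trajectories and estimates are reproducible under a fixed seed", {
  m <- generate_synthetic_model(2, seed = 6)
  st <- sim_settings(protein_conc = 1e-5, t_end = 50, replicates = 3,
                     seed = 99, rate_split = "balanced", kon_scale = 1)
  net <- build_network(m$rbp, m$rna, st)
  e1 <- run_and_estimate(net)
  e2 <- run_and_estimate(net)
  expect_identical(e1$replicates$bound_fraction, e2$replicates$bound_fraction)
  expect_identical(e1$k_av_hat, e2$k_av_hat)
  st2 <- st; st2$seed <- 100L
  e3 <- run_and_estimate(net, st2)
  expect_false(identical(e1$replicates$bound_fraction,
                         e3$replicates$bound_fraction))
})

test_that("the equilibrium estimate does not depend on the overall rate scale", {
  rbp <- rbp_model(ka = 1e5); rna <- rna_target(numeric(0))
  ests <- lapply(c(1e6, 2e5), function(kon) {
    st <- sim_settings(protein_conc = 1e-5, t_end = 2e7 / kon,
                       replicates = 6, seed = 11, kon_scale = kon)
    run_and_estimate(build_network(rbp, rna, st))
  })
  z <- abs(ests[[1]]$k_av_hat - ests[[2]]$k_av_hat) /
    sqrt(ests[[1]]$stderr^2 + ests[[2]]$stderr^2)
  expect_lt(z, 3)
})

test_that("two-site simulation agrees with the exact avidity", {
  m <- generate_synthetic_model(2, seed = 11)
  ex <- avidity_exact(m$rbp, m$rna, warn = FALSE)$k_av
  st <- sim_settings(protein_conc = 1 / ex, t_end = 10, replicates = 6,
                     seed = 5, rate_split = "balanced", kon_scale = 1)
  net <- build_network(m$rbp, m$rna, st)
  st$t_end <- 3000 / min(net$rate); st$burn_in <- 0.1 * st$t_end
  est <- run_and_estimate(net, st)
  expect_lt(abs(est$k_av_hat - ex), 3 * est$stderr)
})

test_that("a degenerate estimator (all replicates stuck) is reported as an error", {
  rbp <- rbp_model(ka = 1e5); rna <- rna_target(numeric(0))
  # protein at 1e6-fold below the midpoint: nothing ever binds in t_end
  st <- sim_settings(protein_conc = 1e-11, t_end = 1, replicates = 3,
                     seed = 8)
  expect_error(run_and_estimate(build_network(rbp, rna, st)),
               "degenerate")
})
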