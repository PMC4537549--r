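test_that("deterministic simulation matches closed-form solutions", {
  bd <- make_birth_death(10, 1)
  tr <- simulate_network(bd, x0 = c(X = 0), t_end = 5)
  expect_equal(unname(tr$conc[nrow(tr$conc), "X"]), 10 * (1 - exp(-5)),
               tolerance = 1e-7)
  # full closed form along the grid
  expect_equal(unname(tr$conc[, "X"]), 10 * (1 - exp(-tr$time)),
               tolerance = 1e-6)

  chain <- make_linear_chain(4, 2, 1)
  tr_c <- simulate_network(chain, x0 = c(A = 0, B = 0), t_end = 40)
  expect_equal(unname(tr_c$conc[nrow(tr_c$conc), ]), c(2, 4),
               tolerance = 1e-6)
})

test_that("a verified stationary state stays constant under simulation", {
  net <- make_random_network(4, 6, 0.5, seed = 2)
  st <- find_stationary_state(net)
  tr <- simulate_network(net, x0 = st$state, t_end = 50)
  drift <- apply(abs(sweep(tr$conc, 2, st$state)), 2, max)
  expect_lt(max(drift / (1 + st$state)), 1e-6)
})

test_that("stationary-state finder reaches fixed points of the flow", {
  bd <- make_birth_death(10, 1)
  st <- find_stationary_state(bd)
  expect_equal(unname(st$state), 10, tolerance = 1e-10)
  expect_lt(st$residual, 1e-10)
  chain <- make_linear_chain(4, 2, 1)
  st_c <- find_stationary_state(chain)
  expect_equal(unname(st_c$state), c(2, 4), tolerance = 1e-10)
  # fixed point over a fresh horizon
  tr <- simulate_network(chain, x0 = st_c$state, t_end = 123)
  expect_equal(unname(tr$conc[nrow(tr$conc), ]), unname(st_c$state),
               tolerance = 1e-7)
})

test_that("divergence detection reports first crossings", {
  bd <- make_birth_death(10, 1)
  tr <- simulate_network(bd, x0 = c(X = 0), t_end = 20)
  expect_equal(nrow(detect_divergence(tr, threshold = 100)), 0)

  pure <- reaction_network(
    species = tibble::tibble(id = "X", compartment = "c",
                             initial_concentration = 0),
    reactions = list(rxn("in", to = c(X = 1), law = mal(1))))
  tr_p <- simulate_network(pure, x0 = c(X = 0),
                           grid = seq(0, 20, by = 0.01))
  hits <- detect_divergence(tr_p, threshold = 10)
  expect_equal(hits$species, "X")
  expect_equal(hits$first_crossing, 10, tolerance = 0.02)
  expect_error(detect_divergence(tr_p, threshold = -1), "exceed")
})

test_that("time-rescaling: doubled rates at halved time reproduce paths", {
  chain <- make_linear_chain(4, 2, 1)
  fast <- make_linear_chain(8, 4, 2)
  grid <- seq(0, 10, length.out = 51)
  tr1 <- simulate_network(chain, x0 = c(A = 0, B = 0), grid = grid)
  tr2 <- simulate_network(fast, x0 = c(A = 0, B = 0), grid = grid / 2)
  expect_equal(tr1$conc, tr2$conc, tolerance = 1e-6)
})

test_that("SSA reproduces the Poisson law of the birth-death process", {
  bd <- make_birth_death(10, 1)
  n_paths <- 10000
  ens <- ssa_simulate(bd, c(X = 0), t_end = 20, n_paths = n_paths, seed = 7)
  xf <- ssa_final_states(ens)
  se_mean <- sqrt(10 / n_paths)
  expect_lt(abs(mean(xf) - 10), 3 * se_mean)
  # sampling error of the variance of a Poisson(10) sample
  se_var <- sqrt((10 + 2 * 100) / n_paths)
  expect_lt(abs(stats::var(xf) - 10), 4 * se_var)
  # reproducibility
  ens2 <- ssa_simulate(bd, c(X = 0), t_end = 20, n_paths = 5, seed = 7)
  ens3 <- ssa_simulate(bd, c(X = 0), t_end = 20, n_paths = 5, seed = 7)
  expect_identical(ens2$states, ens3$states)
})

test_that("SSA on the chain matches the product-Poisson stationary law", {
  chain <- make_linear_chain(4, 2, 1)
  ens <- ssa_simulate(chain, c(A = 0, B = 0), t_end = 15, n_paths = 10000,
                      seed = 11)
  xf <- ssa_final_states(ens)
  expect_lt(abs(mean(xf[, "A"]) - 2), 3 * sqrt(2 / 1e4))
  expect_lt(abs(mean(xf[, "B"]) - 4), 3 * sqrt(4 / 1e4))
  expect_lt(abs(stats::var(xf[, "A"]) - 2), 4 * sqrt((2 + 2 * 4) / 1e4))
  expect_lt(abs(stats::cov(xf[, "A"], xf[, "B"])), 4 * sqrt(8 / 1e4))
})

test_that("zero-propensity networks absorb and stay constant", {
  net <- reaction_network(
    species = tibble::tibble(id = "X", compartment = "c",
                             initial_concentration = 0),
    reactions = list(rxn("d", from = c(X = 1), law = mal(1))))
  ens <- ssa_simulate(net, c(X = 0), t_end = 5, n_paths = 3, seed = 1,
                      record_times = c(1, 5))
  expect_true(all(ens$states == 0))
})

test_that("SSA ensemble mean tracks the deterministic solution", {
  bd <- make_birth_death(10, 1)
  ens <- ssa_simulate(bd, c(X = 0), t_end = 2, n_paths = 4000, seed = 3)
  det <- 10 * (1 - exp(-2))
  expect_lt(abs(mean(ssa_final_states(ens)) - det), 3 * sqrt(det / 4000))
})
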