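test_that("LNA operators match the defining formulas on the birth-death net", {
  bd <- make_birth_death(10, 1)
  ops <- lna_operators(bd, c(X = 10))
  expect_equal(unname(ops$A), matrix(-1), tolerance = 1e-12)
  expect_equal(unname(ops$D), matrix(20), tolerance = 1e-12)
  expect_equal(unname(ops$Dj[["birth"]]), matrix(10), tolerance = 1e-12)
  expect_equal(unname(ops$Dj[["death"]]), matrix(10), tolerance = 1e-12)
})

test_that("chain drift matrix is lower triangular with rate diagonal", {
  chain <- make_linear_chain(4, 2, 1)
  ops <- lna_operators(chain, c(A = 2, B = 4))
  expect_equal(unname(ops$A), matrix(c(-2, 0, 2, -1), 2, byrow = TRUE),
               tolerance = 1e-12)
  # zero-flux reaction contributes a zero diffusion piece
  tiny <- reaction_network(
    species = chain$species,
    reactions = c(chain$reactions,
                  list(rxn("eps", from = c(A = 1), law = mal(1e-300)))))
  ops2 <- lna_operators(tiny, c(A = 2, B = 4))
  expect_equal(max(abs(ops2$Dj[["eps"]])), 0, tolerance = 1e-290)
})

test_that("stationary covariance solves the Lyapunov equation", {
  bd <- make_birth_death(10, 1)
  S <- stationary_covariance(lna_operators(bd, c(X = 10)))
  expect_equal(unname(S), matrix(10), tolerance = 1e-10)

  chain <- make_linear_chain(4, 2, 1)
  S_c <- stationary_covariance(lna_operators(chain, c(A = 2, B = 4)))
  expect_equal(unname(S_c), diag(c(2, 4)), tolerance = 1e-8)

  # isotropic case A = -I, D = 2I -> identity covariance
  ops <- structure(list(A = -diag(3), D = 2 * diag(3)),
                   class = "lna_operators")
  expect_equal(unname(stationary_covariance(ops)), diag(3),
               tolerance = 1e-10)

  unstable <- structure(list(A = matrix(1), D = matrix(2)),
                        class = "lna_operators")
  expect_error(stationary_covariance(unstable), "not Hurwitz")
})

test_that("variance decomposition is additive with PSD components", {
  for (net in list(make_birth_death(10, 1), make_linear_chain(4, 2, 1),
                   make_random_network(4, 6, 0.5, seed = 4))) {
    st <- find_stationary_state(net)
    ops <- lna_operators(net, st$state)
    dec <- decompose_variance(ops)
    total <- Reduce(`+`, dec$Sigma_j)
    expect_lt(max(abs(dec$Sigma - total)), 1e-12 * max(1, max(abs(dec$Sigma))))
    expect_equal(dec$Sigma, stationary_covariance(ops), tolerance = 1e-8)
    for (Sj in dec$Sigma_j) {
      expect_gte(min(eigen((Sj + t(Sj)) / 2, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})

test_that("birth-death variance splits equally across the two reactions", {
  bd <- make_birth_death(10, 1)
  dec <- decompose_variance(lna_operators(bd, c(X = 10)))
  expect_equal(unname(dec$Sigma_j[["birth"]]), matrix(5), tolerance = 1e-10)
  expect_equal(unname(dec$Sigma_j[["death"]]), matrix(5), tolerance = 1e-10)
})

test_that("LNA covariance matches SSA sampling on first-order networks", {
  bd <- make_birth_death(10, 1)
  ens <- ssa_simulate(bd, c(X = 0), t_end = 20, n_paths = 10000, seed = 5)
  v <- stats::var(ssa_final_states(ens))
  expect_lt(abs(v - 10), 4 * sqrt((10 + 2 * 100) / 1e4))

  chain <- make_linear_chain(4, 2, 1)
  ens_c <- ssa_simulate(chain, c(A = 0, B = 0), t_end = 15,
                        n_paths = 10000, seed = 6)
  xf <- ssa_final_states(ens_c)
  S <- stationary_covariance(lna_operators(chain, c(A = 2, B = 4)))
  expect_lt(abs(stats::var(xf[, "A"]) - S["A", "A"]),
            4 * sqrt((2 + 2 * 4) / 1e4))
  expect_lt(abs(stats::var(xf[, "B"]) - S["B", "B"]),
            4 * sqrt((4 + 2 * 16) / 1e4))
  expect_lt(abs(stats::cov(xf[, "A"], xf[, "B"]) - S["A", "B"]),
            4 * sqrt(8 / 1e4))
})

test_that("rate rescaling leaves the birth-death stationary variance fixed", {
  for (c_scale in c(0.5, 1, 4)) {
    bd <- make_birth_death(10 * c_scale, 1 * c_scale)
    S <- stationary_covariance(lna_operators(bd, c(X = 10)))
    expect_equal(unname(S), matrix(10), tolerance = 1e-9)
  }
})

test_that("the 110 percent rule flags only dominant components", {
  dec <- structure(
    list(components = tibble::tibble(
      species = "X", reaction = c("r1", "r2", "r3"),
      component = c(1, 1, 4))),
    class = "variance_decomposition")
  fl <- flag_components(dec)
  expect_equal(fl$threshold, rep(2.2, 3))
  expect_equal(fl$flag, c(FALSE, FALSE, TRUE))
  # all-equal components: nothing exceeds 110 percent of the mean
  dec2 <- structure(
    list(components = tibble::tibble(
      species = "X", reaction = c("r1", "r2"), component = c(3, 3))),
    class = "variance_decomposition")
  expect_false(any(flag_components(dec2)$flag))
})
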