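test_that("forward sensitivities match the closed-form birth-death result", {
  bd <- make_birth_death(10, 1)
  grid <- seq(0, 1, by = 0.01)
  # from the stationary start: dx/dk1 = (1 - exp(-k2 t)) / k2
  s <- forward_sensitivities(bd, x0 = c(X = 10), grid = grid,
                             method = "ode")
  expect_equal(s$sens[101, "X", "birth.k"], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(unname(s$sens[, "X", "birth.k"]), 1 - exp(-grid),
               tolerance = 1e-6)
  # the lti route agrees exactly (state is stationary)
  s_lti <- forward_sensitivities(bd, x0 = c(X = 10), grid = grid,
                                 method = "lti")
  expect_equal(s$sens, s_lti$sens, tolerance = 1e-7)
})

test_that("expstep propagation converges to the ode route off equilibrium", {
  chain <- make_linear_chain(4, 2, 1)
  grid <- seq(0, 5, by = 0.1)
  s_ode <- forward_sensitivities(chain, x0 = c(A = 1, B = 0.5), grid = grid,
                                 method = "ode")
  s_exp <- forward_sensitivities(chain, x0 = c(A = 1, B = 0.5), grid = grid,
                                 method = "expstep", n_substeps = 8)
  expect_lt(max(abs(s_ode$sens - s_exp$sens)), 2e-4)
})

test_that("forward sensitivities agree with central finite differences", {
  for (net in list(make_birth_death(10, 1), make_linear_chain(4, 2, 1),
                   make_random_network(4, 6, 0.5, seed = 3))) {
    x0 <- initial_state(net) + 0.5
    grid <- seq(0, 4, by = 0.2)
    fwd <- forward_sensitivities(net, x0 = x0, grid = grid, method = "ode")
    fd <- fd_sensitivities(net, x0, grid)
    scale <- max(abs(fd))
    expect_lt(max(abs(fwd$sens - fd)) / scale, 1e-4)
  }
})

test_that("long-time sensitivities converge to the implicit stationary derivative", {
  chain <- make_linear_chain(4, 2, 1)
  st <- find_stationary_state(chain)
  cn <- sphingokin:::compile_network(chain)
  M <- stoichiometry_matrix(chain)
  theta <- unname(chain$params)
  A <- M %*% sphingokin:::flux_jac_state_compiled(cn, unname(st$state), theta)
  B <- M %*% sphingokin:::flux_jac_theta_compiled(cn, unname(st$state), theta)
  d_stat <- -solve(A, B) # implicit differentiation of M v(x, theta) = 0
  s <- forward_sensitivities(chain, x0 = st$state, grid = c(0, 50, 100))
  expect_equal(unname(s$sens[3, , ]), unname(d_stat), tolerance = 1e-6)
})

test_that("integrated indices match analytic integrals and converge in grid", {
  bd <- make_birth_death(10, 1)
  grid <- seq(0, 10, by = 0.005)
  s <- forward_sensitivities(bd, x0 = c(X = 10), grid = grid)
  idx <- sensitivity_indices(s)
  got <- idx$index[idx$species == "X" & idx$parameter == "birth.k"]
  expect_equal(got, 10 - (1 - exp(-10)), tolerance = 1e-4)
  # parameter absent from a species' dynamics: zero column integrates to 0
  chain <- make_linear_chain(4, 2, 1)
  s_c <- forward_sensitivities(chain, x0 = c(A = 2, B = 4),
                               grid = seq(0, 5, by = 0.05))
  idx_c <- sensitivity_indices(s_c)
  # A never depends on the outflow rate of B
  expect_equal(idx_c$index[idx_c$species == "A" &
                             idx_c$parameter == "outflow.k"], 0,
               tolerance = 1e-10)
  # quadrature self-consistency: doubled resolution changes results < 1e-3
  s_half <- forward_sensitivities(bd, x0 = c(X = 10),
                                  grid = seq(0, 10, by = 0.01))
  idx_half <- sensitivity_indices(s_half)
  expect_equal(idx_half$index[1], got, tolerance = 1e-3)
})

test_that("indices are invariant to adding a negligible-rate reaction", {
  chain <- make_linear_chain(4, 2, 1)
  aug <- reaction_network(
    species = chain$species,
    reactions = c(chain$reactions,
                  list(rxn("eps", from = c(A = 1), law = mal(1e-12)))),
    metadata = chain$metadata)
  grid <- seq(0, 5, by = 0.1)
  i1 <- sensitivity_indices(
    forward_sensitivities(chain, x0 = c(A = 1, B = 1), grid = grid))
  i2 <- sensitivity_indices(
    forward_sensitivities(aug, x0 = c(A = 1, B = 1), grid = grid))
  merged <- merge(i1, i2, by = c("species", "parameter"))
  expect_equal(merged$index.x, merged$index.y, tolerance = 1e-8)
})

test_that("parameter ranking sorts by summed index with lexicographic ties", {
  idx <- tibble::tibble(
    species = c("X", "X", "Y", "Y"),
    parameter = c("b", "a", "b", "a"),
    index = c(1, 2, 1, 2))
  r <- rank_parameters(idx, c("X", "Y"))
  expect_equal(r$parameter, c("a", "b"))
  tie <- tibble::tibble(species = "X", parameter = c("z", "a"),
                        index = c(1, 1))
  expect_equal(rank_parameters(tie, "X")$parameter, c("a", "z"))
  expect_error(rank_parameters(idx, character()), "empty")
  expect_error(rank_parameters(idx, "Q"), "unknown species")
})
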