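# Finite-difference sensitivity oracle: central differences in parameter
# space around the registry values, using the plain ODE solver. Independent
# of the forward (variational) implementation.
fd_sensitivities <- function(net, x0, grid, parameters = names(net$params),
                             rel_step = 1e-6) {
  out <- array(0, dim = c(length(grid), nrow(net$species),
                          length(parameters)),
               dimnames = list(NULL, net$species$id, parameters))
  for (p in parameters) {
    h <- net$params[[p]] * rel_step
    up <- net$params; up[[p]] <- up[[p]] + h
    dn <- net$params; dn[[p]] <- dn[[p]] - h
    tr_up <- simulate_network(net, x0 = x0, grid = grid, params = up,
                              rtol = 1e-10, atol = 1e-13)
    tr_dn <- simulate_network(net, x0 = x0, grid = grid, params = dn,
                              rtol = 1e-10, atol = 1e-13)
    out[, , p] <- (tr_up$conc - tr_dn$conc) / (2 * h)
  }
  out
}

# Mutual information between two blocks of a zero-mean Gaussian with
# covariance C, in nats: -1/2 log(det(C) / (det(C_AA) det(C_BB))).
gaussian_block_mi <- function(C, A, B) {
  -0.5 * log(det(C[c(A, B), c(A, B)]) /
               (det(C[A, A, drop = FALSE]) * det(C[B, B, drop = FALSE])))
}

# random symmetric positive-definite matrix
random_spd <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * n), n)
  crossprod(X) + diag(n) * 0.5
}

expect_rel_equal <- function(object, expected, rtol = 1e-6) {
  expect_lt(max(abs(object - expected)) /
              max(abs(expected), .Machine$double.eps), rtol)
}
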