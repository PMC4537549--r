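#' Linear Noise Approximation operators
#'
#' At an evaluation state `Phi` (normally a stationary state) builds the
#' drift matrix `A` with `A_ik = sum_j m_ij df_j/dPhi_k` and the diffusion
#' matrix `D = sum_j D^(j)` with the rank-one per-reaction pieces
#' `D^(j) = m_j m_j' f_j(Phi)`. Under the unit-volume convention the
#' macroscopic fluxes `f_j` equal the propensities, so concentration-scale
#' and copy-number-scale operators coincide.
#'
#' @param net a `reaction_network`.
#' @param phi evaluation state (named or in species order).
#' @return an `lna_operators` object: `A`, `D`, list `Dj`, fluxes `f`, and
#'   `phi`.
#' @export
lna_operators <- function(net, phi) {
  cn <- compile_network(net)
  theta <- unname(net$params)
  M <- stoichiometry_matrix(net)
  x <- if (!is.null(names(phi))) unname(phi[net$species$id]) else unname(phi)
  f <- flux_vector_compiled(cn, x, theta)
  A <- M %*% flux_jac_state_compiled(cn, x, theta)
  Dj <- lapply(seq_len(cn$R), function(j) {
    mj <- M[, j]
    tcrossprod(mj) * f[j]
  })
  names(Dj) <- names(net$reactions)
  D <- Reduce(`+`, Dj)
  dimnames(A) <- list(net$species$id, net$species$id)
  dimnames(D) <- dimnames(A)
  structure(list(A = A, D = D, Dj = Dj,
                 f = stats::setNames(f, names(net$reactions)),
                 phi = stats::setNames(x, net$species$id)),
            class = "lna_operators")
}

#' @export
print.lna_operators <- function(x, ...) {
  cat("<lna_operators> N =", nrow(x$A), " R =", length(x$Dj), "\n")
  invisible(x)
}

lyapunov_factor <- function(A) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= -1e-12)) {
    stop("no stable stationary state: drift matrix is not Hurwitz",
         call. = FALSE)
  }
  lu <- qr(K)
  function(D) {
    S <- matrix(qr.coef(lu, -as.vector(D)), n, n)
    (S + t(S)) / 2
  }
}

#' Stationary covariance of the LNA
#'
#' Solves the stationary Lyapunov equation `A S + S A' + D = 0` (the fixed
#' point of the covariance evolution equation `dS/dt = A S + S A' + D`).
#'
#' @param ops an `lna_operators` object (with Hurwitz `A`).
#' @return symmetric positive-semidefinite covariance matrix.
#' @export
stationary_covariance <- function(ops) {
  solver <- lyapunov_factor(ops$A)
  S <- solver(ops$D)
  dimnames(S) <- dimnames(ops$A)
  S
}

#' Per-reaction variance decomposition
#'
#' Decomposes the stationary covariance additively into per-reaction
#' components by solving one Lyapunov equation per rank-one diffusion piece:
#' `A S^(j) + S^(j) A' + D^(j) = 0`, so that `S = sum_j S^(j)` exactly
#' (linearity of the Lyapunov equation in `D`). The per-species component
#' table holds `diag(S^(j))`; [flag_components()] applies the
#' 110-percent-of-mean threshold rule.
#'
#' @param ops an `lna_operators` object.
#' @return a `variance_decomposition`: total `Sigma`, list `Sigma_j`, and a
#'   tidy per-(species, reaction) component table.
#' @export
decompose_variance <- function(ops) {
  solver <- lyapunov_factor(ops$A)
  Sigma_j <- lapply(ops$Dj, solver)
  Sigma <- Reduce(`+`, Sigma_j)
  dimnames(Sigma) <- dimnames(ops$A)
  sp <- rownames(ops$A)
  comp <- purrr::imap_dfr(Sigma_j, function(S, rid) {
    tibble(species = sp, reaction = rid, component = diag(S))
  })
  structure(list(Sigma = Sigma, Sigma_j = Sigma_j, components = comp),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition> N =", nrow(x$Sigma),
      " reactions =", length(x$Sigma_j), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variance_decomposition <- function(x, ...) flag_components(x)

#' Flag dominant noise components
#'
#' For each species, computes the mean variance component over all reactions
#' and flags the components exceeding 110 percent of that mean — the rule
#' used to single out distinctive noise-generating reactions.
#'
#' @param decomp a `variance_decomposition`.
#' @param factor threshold multiplier on the per-species mean (default 1.1).
#' @return tibble: `species`, `reaction`, `component`, `mean_component`,
#'   `threshold`, `flag`.
#' @export
flag_components <- function(decomp, factor = 1.1) {
  decomp$components |>
    group_by(.data$species) |>
    mutate(mean_component = mean(.data$component),
           threshold = factor * .data$mean_component,
           flag = .data$component > .data$threshold) |>
    ungroup()
}

#' Variance-decomposition bar plot
#'
#' One panel per species: variance components by reaction, the per-species
#' mean as a horizontal reference line, flagged components highlighted.
#'
#' @param object a `variance_decomposition`.
#' @param species optional subset of species to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.variance_decomposition <- function(object, species = NULL, ...) {
  d <- flag_components(object)
  if (!is.null(species)) d <- filter(d, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(.data$reaction, .data$component,
                                  fill = .data$flag)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mean_component),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "red")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5)) +
    ggplot2::labs(x = "reaction", y = "variance component", fill = "> 110%")
}
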