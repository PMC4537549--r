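#' Synthetic toy networks
#'
#' Small reaction networks with known analytic behaviour, used throughout the
#' test-suite as oracles for the simulation, sensitivity, noise-decomposition
#' and identifiability machinery.
#'
#' `make_birth_death()` builds the linear birth-death process
#' `0 -> X` (rate `k1`), `X -> 0` (rate `k2 X`): stationary mean and
#' stationary copy-number variance are both `k1/k2` (Poisson law).
#'
#' `make_linear_chain()` builds `0 -> A -> B -> 0` with rates
#' `k0`, `k1 A`, `k2 B`: stationary state `(k0/k1, k0/k2)` and product-Poisson
#' stationary law (diagonal covariance `diag(k0/k1, k0/k2)`).
#'
#' `make_redundant_pair()` builds a birth-death network whose production flux
#' is the product `ka * kb`, so the pair `(ka, kb)` is structurally
#' non-identifiable: their log-scale sensitivity columns are proportional and
#' the Fisher information matrix is rank-deficient on that pair.
#'
#' @param k1,k2,k0,ka,kb positive rate constants.
#' @return a `reaction_network`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_birth_death <- function(k1 = 10, k2 = 1) {
  reaction_network(
    species = tibble(id = "X", compartment = "cell",
                     initial_concentration = 0),
    reactions = list(
      rxn("birth", to = c(X = 1), law = mal(k1)),
      rxn("death", from = c(X = 1), law = mal(k2))
    ),
    metadata = list(scenario = "birth_death")
  )
}

#' @rdname fixtures
#' @export
make_linear_chain <- function(k0 = 4, k1 = 2, k2 = 1) {
  reaction_network(
    species = tibble(id = c("A", "B"), compartment = "cell",
                     initial_concentration = 0),
    reactions = list(
      rxn("inflow", to = c(A = 1), law = mal(k0)),
      rxn("conv", from = c(A = 1), to = c(B = 1), law = mal(k1)),
      rxn("outflow", from = c(B = 1), law = mal(k2))
    ),
    metadata = list(scenario = "linear_chain")
  )
}

#' @rdname fixtures
#' @export
make_redundant_pair <- function(ka = 2, kb = 5, k2 = 1) {
  reaction_network(
    species = tibble(id = "X", compartment = "cell",
                     initial_concentration = 0),
    reactions = list(
      rxn("birth", to = c(X = 1),
          law = opaque_law(quote(ka * kb), c(ka = ka, kb = kb))),
      rxn("death", from = c(X = 1), law = mal(k2))
    ),
    metadata = list(scenario = "redundant_pair")
  )
}

#' Random mass-action / Michaelis-Menten network
#'
#' Generates a connected open reaction network with a guaranteed inflow and
#' outflow, first-order mass-action transport between species and a fraction
#' of saturating Michaelis-Menten conversions. `Vmax/Km` ratios are bounded
#' so the deterministic system is dissipative; draws whose Jacobian at the
#' stabilized state is not Hurwitz are rejected and re-sampled.
#'
#' @param n_species,n_reactions network size (`n_reactions >= n_species + 1`
#'   so every species can be reached and drained).
#' @param mm_fraction fraction of conversion reactions using MM kinetics.
#' @param seed integer seed; the same seed reproduces the same network.
#' @return a `reaction_network` whose metadata records the seed and the
#'   number of rejected draws.
#' @export
make_random_network <- function(n_species = 5, n_reactions = 8,
                                mm_fraction = 0.5, seed = 1) {
  stopifnot(n_species >= 1, mm_fraction >= 0, mm_fraction <= 1)
  if (n_reactions < n_species + 1) {
    stop("need at least n_species + 1 reactions for inflow, chain and outflow",
         call. = FALSE)
  }
  rejections <- 0L
  for (attempt in 1:25) {
    rng <- local({
      set.seed(seed + 1000L * rejections)
      NULL
    })
    ids <- paste0("S", seq_len(n_species))
    reactions <- list(
      rxn("r_in", to = stats::setNames(1, ids[1]),
          law = mal(stats::runif(1, 1, 5))),
      rxn("r_out", from = stats::setNames(1, ids[n_species]),
          law = mal(stats::runif(1, 0.5, 2)))
    )
    # spanning chain keeps the network connected
    k <- 3L
    for (i in seq_len(n_species - 1)) {
      reactions[[k]] <- conv_rxn(sprintf("r_chain%d", i), ids[i], ids[i + 1],
                                 mm_fraction)
      k <- k + 1L
    }
    extra <- n_reactions - length(reactions)
    for (i in seq_len(extra)) {
      pair <- sample(n_species, 2)
      reactions[[k]] <- conv_rxn(sprintf("r_x%d", i), ids[pair[1]],
                                 ids[pair[2]], mm_fraction)
      k <- k + 1L
    }
    net <- reaction_network(
      species = tibble(id = ids, compartment = "cell",
                       initial_concentration = stats::runif(n_species, 0.5, 2)),
      reactions = reactions,
      metadata = list(scenario = "random_mal_mm", seed = seed,
                      rejections = rejections)
    )
    st <- try(find_stationary_state(net), silent = TRUE)
    if (!inherits(st, "try-error")) {
      A <- lna_operators(net, st$state)$A
      if (all(Re(eigen(A, only.values = TRUE)$values) < -1e-10)) return(net)
    }
    rejections <- rejections + 1L
  }
  stop("could not draw a stable random network for this seed", call. = FALSE)
}

conv_rxn <- function(id, from, to, mm_fraction) {
  if (stats::runif(1) < mm_fraction) {
    rxn(id, from = stats::setNames(1, from), to = stats::setNames(1, to),
        law = mm(Vmax = stats::runif(1, 1, 3), Km = stats::runif(1, 0.5, 2)),
        transport = FALSE)
  } else {
    rxn(id, from = stats::setNames(1, from), to = stats::setNames(1, to),
        law = mal(stats::runif(1, 0.3, 1.5)))
  }
}
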