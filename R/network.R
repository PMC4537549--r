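#' @useDynLib sphingokin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

LAW_FORMS <- c("MASS_ACTION", "MICHAELIS_MENTEN", "MM_INHIBITED", "OPAQUE")

#' Kinetic law constructors
#'
#' A kinetic law is a tagged union over the rate-law forms used in the model:
#' mass action (transport and inflow reactions), Michaelis-Menten (enzymatic
#' reactions), Michaelis-Menten with non-competitive inhibition, and an opaque
#' form carrying an arbitrary rate expression (used when importing SBML files
#' whose math matches none of the closed forms).
#'
#' Inhibition is multiplicative and non-competitive: each inhibitor `I` with
#' constant `Ki` scales the flux by `1 / (1 + [I]/Ki)`. Any law form may carry
#' inhibitors; `mm_inh()` is Michaelis-Menten plus a non-empty inhibitor list.
#'
#' @param k,Vmax,Km positive rate parameters.
#' @param inhibitors named numeric vector: names are inhibitor species ids,
#'   values are the inhibition constants `Ki` (> 0).
#' @param expr an R expression (as produced by `quote()`) in species ids and
#'   parameter symbols.
#' @param params named numeric vector of the parameter symbols appearing in
#'   `expr`, with their values.
#' @return an object of class `kinetic_law`.
#' @export
mal <- function(k, inhibitors = NULL) {
  new_law("MASS_ACTION", list(k = k), inhibitors)
}

#' @rdname mal
#' @export
mm <- function(Vmax, Km, inhibitors = NULL) {
  form <- if (length(inhibitors)) "MM_INHIBITED" else "MICHAELIS_MENTEN"
  new_law(form, list(Vmax = Vmax, Km = Km), inhibitors)
}

#' @rdname mal
#' @export
mm_inh <- function(Vmax, Km, inhibitors) {
  stopifnot(length(inhibitors) >= 1)
  mm(Vmax, Km, inhibitors)
}

#' @rdname mal
#' @export
opaque_law <- function(expr, params = numeric()) {
  l <- new_law("OPAQUE", as.list(params), NULL)
  l$expr <- expr
  l
}

new_law <- function(form, params, inhibitors) {
  form <- match.arg(form, LAW_FORMS)
  vals <- unlist(params)
  if (length(vals) && any(!is.finite(vals) | vals <= 0)) {
    stop("kinetic-law parameters must be positive and finite", call. = FALSE)
  }
  if (!is.null(inhibitors)) {
    stopifnot(is.numeric(inhibitors), !is.null(names(inhibitors)),
              all(inhibitors > 0))
  }
  structure(list(form = form, params = params,
                 inhibitors = inhibitors), class = "kinetic_law")
}

#' Define a reaction
#'
#' @param id short unique identifier.
#' @param from named integer vector of substrate stoichiometric coefficients
#'   (names are species ids); empty for a pure inflow.
#' @param to named integer vector of product coefficients; empty for a pure
#'   outflow / degradation.
#' @param law a [kinetic_law][mal] object.
#' @param modifiers character vector of catalyzing enzyme names (annotations:
#'   modifiers are not consumed and contribute no stoichiometry; enzyme
#'   concentrations are absorbed into `Vmax`).
#' @param transport logical; `TRUE` for molecular transport, `FALSE` for
#'   biochemical transformation.
#' @param name display name.
#' @return an object of class `reaction`.
#' @export
rxn <- function(id, from = NULL, to = NULL, law, modifiers = character(),
                transport = is(law, "kinetic_law") && law$form == "MASS_ACTION",
                name = id) {
  as_side <- function(x) {
    if (is.null(x) || !length(x)) {
      return(tibble(species = character(), coef = integer()))
    }
    if (is.null(names(x))) stop("substrates/products must be named", call. = FALSE)
    stopifnot(all(x >= 1), all(x == round(x)))
    tibble(species = names(x), coef = as.integer(x))
  }
  sub <- as_side(from); prod <- as_side(to)
  if (nrow(sub) + nrow(prod) == 0) {
    stop("reaction '", id, "' needs at least one substrate or product",
         call. = FALSE)
  }
  stopifnot(inherits(law, "kinetic_law"))
  if (law$form %in% c("MICHAELIS_MENTEN", "MM_INHIBITED") && nrow(sub) < 1) {
    stop("MM law in reaction '", id, "' requires a rate-limiting substrate",
         call. = FALSE)
  }
  structure(list(id = id, name = name, substrates = sub, products = prod,
                 modifiers = modifiers, law = law,
                 is_transport = isTRUE(transport)), class = "reaction")
}

#' Assemble a reaction network
#'
#' The network is the single source of truth from which the stoichiometry
#' matrix, deterministic rate laws and stochastic propensities are built.
#' Kinetic parameters given inside each reaction's law are hoisted into a
#' parameter registry keyed `"<reaction id>.<symbol>"` (inhibition constants
#' as `"<reaction id>.Ki_<inhibitor id>"`), which guarantees key uniqueness.
#'
#' @param species a tibble/data.frame with columns `id`, `compartment`, and
#'   optionally `name`, `initial_concentration` (default 0), `is_enzyme`
#'   (default `FALSE`) and `explicit_initial` (default `TRUE`; species whose
#'   initial value is derived rather than tabulated carry `FALSE`).
#' @param reactions list of [rxn()] objects.
#' @param compartments a tibble/data.frame with columns `id` and optionally
#'   `name` and `volume` (default 1). If omitted, compartments are inferred
#'   from the species table.
#' @param metadata named list (scenario label etc.).
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, compartments = NULL,
                             metadata = list()) {
  species <- as_tibble(species)
  if (!"name" %in% names(species)) species$name <- species$id
  if (!"initial_concentration" %in% names(species)) {
    species$initial_concentration <- 0
  }
  if (!"is_enzyme" %in% names(species)) species$is_enzyme <- FALSE
  if (!"explicit_initial" %in% names(species)) species$explicit_initial <- TRUE
  if (is.null(compartments)) {
    compartments <- tibble(id = unique(species$compartment))
  }
  compartments <- as_tibble(compartments)
  if (!"name" %in% names(compartments)) compartments$name <- compartments$id
  if (!"volume" %in% names(compartments)) compartments$volume <- 1
  if (!is.null(names(reactions)) && !all(names(reactions) == "")) {
    names(reactions) <- NULL
  }
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  params <- numeric()
  for (r in reactions) {
    for (sym in names(r$law$params)) {
      params[[paste0(r$id, ".", sym)]] <- r$law$params[[sym]]
    }
    if (!is.null(r$law$inhibitors)) {
      for (inh in names(r$law$inhibitors)) {
        params[[paste0(r$id, ".Ki_", inh)]] <- r$law$inhibitors[[inh]]
      }
    }
  }

  net <- structure(list(compartments = compartments, species = species,
                        reactions = reactions, params = params,
                        metadata = metadata), class = "reaction_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks id uniqueness, positive volumes, non-negative initial
#' concentrations, resolvable cross-references (compartments, substrates,
#' products, inhibitors) and exact coverage of every rate symbol by the
#' parameter registry. Called by [reaction_network()]; exported so imported
#' models can be re-checked.
#'
#' @param net a `reaction_network`.
#' @return `net`, invisibly; errors name the offending reaction or species.
#' @export
validate_network <- function(net) {
  sp <- net$species
  if (anyDuplicated(sp$id)) stop("duplicate species ids", call. = FALSE)
  if (anyDuplicated(net$compartments$id)) {
    stop("duplicate compartment ids", call. = FALSE)
  }
  if (any(net$compartments$volume <= 0)) {
    stop("compartment volumes must be > 0", call. = FALSE)
  }
  if (any(sp$initial_concentration < 0)) {
    stop("negative initial concentration", call. = FALSE)
  }
  bad <- setdiff(sp$compartment, net$compartments$id)
  if (length(bad)) stop("unknown compartment: ", bad[1], call. = FALSE)
  if (nrow(sp) == 0) stop("network has no species", call. = FALSE)
  if (length(net$reactions) == 0) stop("network has no reactions", call. = FALSE)
  if (anyDuplicated(names(net$reactions))) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  for (r in net$reactions) {
    refs <- c(r$substrates$species, r$products$species,
              names(r$law$inhibitors))
    dangling <- setdiff(refs, sp$id)
    if (length(dangling)) {
      stop("reaction '", r$id, "' references unknown species '",
           dangling[1], "'", call. = FALSE)
    }
    syms <- law_symbols(r)
    keys <- paste0(r$id, ".", syms)
    missing <- setdiff(keys, names(net$params))
    if (length(missing)) {
      stop("parameter registry misses ", missing[1], call. = FALSE)
    }
  }
  invisible(net)
}

law_symbols <- function(r) {
  base <- switch(r$law$form,
    MASS_ACTION = "k",
    MICHAELIS_MENTEN = c("Vmax", "Km"),
    MM_INHIBITED = c("Vmax", "Km"),
    OPAQUE = names(r$law$params))
  c(base, if (!is.null(r$law$inhibitors))
    paste0("Ki_", names(r$law$inhibitors)))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>",
      if (!is.null(x$metadata$scenario)) paste0(" [", x$metadata$scenario, "]"),
      "\n", sep = "")
  cat("  compartments: ", nrow(x$compartments),
      "  species: ", nrow(x$species),
      "  reactions: ", length(x$reactions),
      "  parameters: ", length(x$params), "\n", sep = "")
  invisible(x)
}

#' Network stoichiometry matrix
#'
#' Net stoichiometry `s_nj = products_nj - substrates_nj` as an integer
#' species-by-reaction matrix; column `j` is the state-change vector `m_j` of
#' reaction `j`. Modifiers contribute zero.
#'
#' @param net a `reaction_network`.
#' @return integer matrix with species ids as row names and reaction ids as
#'   column names.
#' @export
stoichiometry_matrix <- function(net) {
  sp_ids <- net$species$id
  M <- matrix(0L, nrow = length(sp_ids), ncol = length(net$reactions),
              dimnames = list(sp_ids, names(net$reactions)))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (i in seq_len(nrow(r$substrates))) {
      M[r$substrates$species[i], j] <- M[r$substrates$species[i], j] -
        r$substrates$coef[i]
    }
    for (i in seq_len(nrow(r$products))) {
      M[r$products$species[i], j] <- M[r$products$species[i], j] +
        r$products$coef[i]
    }
  }
  M
}

inhibition_factor <- function(law, state, r_id, params) {
  if (is.null(law$inhibitors)) return(1)
  fac <- 1
  for (inh in names(law$inhibitors)) {
    ki <- params[[paste0(r_id, ".Ki_", inh)]]
    fac <- fac / (1 + state[[inh]] / ki)
  }
  fac
}

#' Flux of a single reaction
#'
#' Macroscopic reaction flux at a concentration state: mass action
#' `k * prod([S]^coef)`, Michaelis-Menten `Vmax [S] / (Km + [S])` on the
#' rate-limiting (first listed) substrate, each multiplied by the
#' non-competitive inhibition factor `prod(1 / (1 + [I]/Ki))` when the law
#' carries inhibitors. The flux is zero whenever a required substrate is zero.
#'
#' @param reaction a [rxn()] object.
#' @param state named non-negative numeric vector of concentrations.
#' @param params parameter registry (named numeric vector keyed
#'   `"<reaction id>.<symbol>"`).
#' @return a single non-negative number.
#' @export
reaction_flux <- function(reaction, state, params) {
  need <- unique(c(reaction$substrates$species,
                   names(reaction$law$inhibitors)))
  if (any(state[need] < 0)) {
    stop("negative concentration supplied to reaction '", reaction$id, "'",
         call. = FALSE)
  }
  law <- reaction$law
  base <- switch(law$form,
    MASS_ACTION = {
      k <- params[[paste0(reaction$id, ".k")]]
      v <- k
      for (i in seq_len(nrow(reaction$substrates))) {
        v <- v * state[[reaction$substrates$species[i]]]^
          reaction$substrates$coef[i]
      }
      v
    },
    MICHAELIS_MENTEN = ,
    MM_INHIBITED = {
      Vmax <- params[[paste0(reaction$id, ".Vmax")]]
      Km <- params[[paste0(reaction$id, ".Km")]]
      s <- state[[reaction$substrates$species[1]]]
      Vmax * s / (Km + s)
    },
    OPAQUE = {
      env <- as.list(state)
      for (sym in names(law$params)) {
        env[[sym]] <- params[[paste0(reaction$id, ".", sym)]]
      }
      eval(law$expr, env)
    })
  unname(base * inhibition_factor(law, state, reaction$id, params))
}

# ---- compiled evaluators ----------------------------------------------------
# Index-based closures over the network: flux vector, and analytic Jacobians
# with respect to state and parameters. Opaque laws are differentiated
# symbolically with stats::D at compile time.

compile_network <- function(net) {
  sp_ids <- net$species$id
  p_keys <- names(net$params)
  R <- length(net$reactions)
  comp <- vector("list", R)
  for (j in seq_len(R)) {
    r <- net$reactions[[j]]
    law <- r$law
    entry <- list(form = law$form,
                  sub_idx = match(r$substrates$species, sp_ids),
                  sub_coef = r$substrates$coef)
    if (law$form == "MASS_ACTION") {
      entry$k_idx <- match(paste0(r$id, ".k"), p_keys)
    } else if (law$form %in% c("MICHAELIS_MENTEN", "MM_INHIBITED")) {
      entry$vmax_idx <- match(paste0(r$id, ".Vmax"), p_keys)
      entry$km_idx <- match(paste0(r$id, ".Km"), p_keys)
      entry$s_idx <- entry$sub_idx[1]
    } else { # OPAQUE
      psyms <- names(law$params)
      entry$opq_syms <- psyms
      entry$opq_pidx <- match(paste0(r$id, ".", psyms), p_keys)
      vars <- intersect(all.vars(law$expr), c(sp_ids, psyms))
      entry$expr <- law$expr
      entry$d_state <- lapply(intersect(vars, sp_ids),
                              function(v) stats::D(law$expr, v))
      entry$d_state_idx <- match(intersect(vars, sp_ids), sp_ids)
      entry$d_par <- lapply(intersect(vars, psyms),
                            function(v) stats::D(law$expr, v))
      entry$d_par_idx <- entry$opq_pidx[match(intersect(vars, psyms), psyms)]
    }
    if (!is.null(law$inhibitors)) {
      entry$inh_idx <- match(names(law$inhibitors), sp_ids)
      entry$ki_idx <- match(paste0(r$id, ".Ki_", names(law$inhibitors)),
                            p_keys)
    }
    comp[[j]] <- entry
  }
  list(entries = comp, sp_ids = sp_ids, p_keys = p_keys, R = R,
       N = length(sp_ids), L = length(p_keys))
}

opq_env <- function(e, x, theta, sp_ids) {
  env <- as.list(stats::setNames(x, sp_ids))
  env[e$opq_syms] <- as.list(theta[e$opq_pidx])
  env
}

flux_vector_compiled <- function(cn, x, theta) {
  out <- numeric(cn$R)
  for (j in seq_len(cn$R)) {
    e <- cn$entries[[j]]
    base <- switch(e$form,
      MASS_ACTION = {
        v <- theta[e$k_idx]
        if (length(e$sub_idx)) v <- v * prod(x[e$sub_idx]^e$sub_coef)
        v
      },
      MICHAELIS_MENTEN = ,
      MM_INHIBITED = {
        s <- x[e$s_idx]
        theta[e$vmax_idx] * s / (theta[e$km_idx] + s)
      },
      OPAQUE = eval(e$expr, opq_env(e, x, theta, cn$sp_ids)))
    if (!is.null(e$inh_idx)) {
      base <- base * prod(1 / (1 + x[e$inh_idx] / theta[e$ki_idx]))
    }
    out[j] <- base
  }
  out
}

# d flux / d state, R x N dense matrix
flux_jac_state_compiled <- function(cn, x, theta) {
  J <- matrix(0, cn$R, cn$N)
  for (j in seq_len(cn$R)) {
    e <- cn$entries[[j]]
    inh_fac <- 1
    if (!is.null(e$inh_idx)) {
      inh_fac <- prod(1 / (1 + x[e$inh_idx] / theta[e$ki_idx]))
    }
    base <- 0
    if (e$form == "MASS_ACTION") {
      k <- theta[e$k_idx]
      base <- k
      if (length(e$sub_idx)) base <- base * prod(x[e$sub_idx]^e$sub_coef)
      for (s in seq_along(e$sub_idx)) {
        others <- k * prod(x[e$sub_idx[-s]]^e$sub_coef[-s])
        J[j, e$sub_idx[s]] <- others * e$sub_coef[s] *
          x[e$sub_idx[s]]^(e$sub_coef[s] - 1) * inh_fac
      }
    } else if (e$form %in% c("MICHAELIS_MENTEN", "MM_INHIBITED")) {
      s <- x[e$s_idx]; Vmax <- theta[e$vmax_idx]; Km <- theta[e$km_idx]
      base <- Vmax * s / (Km + s)
      J[j, e$s_idx] <- J[j, e$s_idx] + Vmax * Km / (Km + s)^2 * inh_fac
    } else {
      env <- opq_env(e, x, theta, cn$sp_ids)
      base <- eval(e$expr, env)
      for (q in seq_along(e$d_state)) {
        J[j, e$d_state_idx[q]] <- J[j, e$d_state_idx[q]] +
          eval(e$d_state[[q]], env) * inh_fac
      }
    }
    if (!is.null(e$inh_idx)) {
      for (q in seq_along(e$inh_idx)) {
        ii <- e$inh_idx[q]
        J[j, ii] <- J[j, ii] -
          base * inh_fac / (theta[e$ki_idx[q]] + x[ii])
      }
    }
  }
  J
}

# d flux / d theta, R x L dense matrix
flux_jac_theta_compiled <- function(cn, x, theta) {
  J <- matrix(0, cn$R, cn$L)
  for (j in seq_len(cn$R)) {
    e <- cn$entries[[j]]
    inh_fac <- 1
    if (!is.null(e$inh_idx)) {
      inh_fac <- prod(1 / (1 + x[e$inh_idx] / theta[e$ki_idx]))
    }
    if (e$form == "MASS_ACTION") {
      base_over_k <- 1
      if (length(e$sub_idx)) {
        base_over_k <- prod(x[e$sub_idx]^e$sub_coef)
      }
      J[j, e$k_idx] <- base_over_k * inh_fac
      base <- theta[e$k_idx] * base_over_k
    } else if (e$form %in% c("MICHAELIS_MENTEN", "MM_INHIBITED")) {
      s <- x[e$s_idx]; Vmax <- theta[e$vmax_idx]; Km <- theta[e$km_idx]
      base <- Vmax * s / (Km + s)
      J[j, e$vmax_idx] <- s / (Km + s) * inh_fac
      J[j, e$km_idx] <- -base / (Km + s) * inh_fac
    } else {
      env <- opq_env(e, x, theta, cn$sp_ids)
      base <- eval(e$expr, env)
      for (q in seq_along(e$d_par)) {
        J[j, e$d_par_idx[q]] <- eval(e$d_par[[q]], env) * inh_fac
      }
    }
    if (!is.null(e$inh_idx)) {
      for (q in seq_along(e$inh_idx)) {
        ki <- theta[e$ki_idx[q]]; xi <- x[e$inh_idx[q]]
        J[j, e$ki_idx[q]] <- base * inh_fac * xi / (ki * (ki + xi))
      }
    }
  }
  J
}

#' Deterministic right-hand side of the ODE system
#'
#' Returns the function `dS/dt = M v(S)` where `M` is the stoichiometry matrix
#' and `v` stacks [reaction_flux()] over all reactions.
#'
#' @param net a `reaction_network`.
#' @return `function(state, t = 0, params = net$params)` returning the named
#'   derivative vector.
#' @export
build_rhs <- function(net) {
  cn <- compile_network(net)
  M <- stoichiometry_matrix(net)
  theta0 <- unname(net$params)
  sp_ids <- net$species$id
  function(state, t = 0, params = NULL) {
    theta <- if (is.null(params)) theta0 else unname(params[cn$p_keys])
    x <- unname(state[sp_ids])
    stats::setNames(drop(M %*% flux_vector_compiled(cn, x, theta)), sp_ids)
  }
}

#' Stochastic propensities
#'
#' Under the unit-volume convention used throughout (all compartment volumes
#' are 1, so copy numbers and concentrations share one scale), the propensity
#' of each reaction numerically equals its macroscopic flux evaluated at the
#' state.
#'
#' @param net a `reaction_network`.
#' @return `function(state)` returning the length-R propensity vector (named
#'   by reaction id).
#' @export
build_propensities <- function(net) {
  cn <- compile_network(net)
  theta0 <- unname(net$params)
  sp_ids <- net$species$id
  r_ids <- names(net$reactions)
  function(state) {
    x <- unname(state[sp_ids])
    if (any(x < 0)) stop("negative state in propensity evaluation",
                         call. = FALSE)
    stats::setNames(flux_vector_compiled(cn, x, theta0), r_ids)
  }
}

#' Tidy per-reaction summary of a network
#'
#' @param x a `reaction_network`.
#' @param ... unused.
#' @return a tibble with one row per reaction: id, name, law form, transport
#'   flag, substrate/product/modifier summaries and parameter count.
#' @exportS3Method generics::tidy
tidy.reaction_network <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(r) {
    tibble(reaction = r$id, name = r$name, form = r$law$form,
           transport = r$is_transport,
           substrates = paste(r$substrates$species, collapse = "+"),
           products = paste(r$products$species, collapse = "+"),
           modifiers = paste(r$modifiers, collapse = "+"),
           n_parameters = length(law_symbols(r)))
  })
}

#' One-line model summary
#'
#' @param x a `reaction_network`.
#' @param ... unused.
#' @return a one-row tibble of structural counts: compartments, species,
#'   reactions, enzymes (distinct modifiers), parameters and explicit initial
#'   concentrations.
#' @exportS3Method generics::glance
glance.reaction_network <- function(x, ...) {
  tibble(
    n_compartments = nrow(x$compartments),
    n_species = nrow(x$species),
    n_reactions = length(x$reactions),
    n_enzymes = length(unique(unlist(lapply(x$reactions, `[[`, "modifiers")))),
    n_parameters = length(x$params),
    n_explicit_initials = sum(x$species$explicit_initial)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Initial state vector of a network
#'
#' @param net a `reaction_network`.
#' @return named numeric vector of initial concentrations in species order.
#' @export
initial_state <- function(net) {
  stats::setNames(net$species$initial_concentration, net$species$id)
}

#' @importFrom methods is
NULL
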