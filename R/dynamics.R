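#' Deterministic time-course simulation
#'
#' Integrates `dS/dt = M v(S)` with a stiff-capable implicit solver
#' (`deSolve::lsoda`). Tolerances default to `rtol = 1e-8`, `atol = 1e-12`:
#' the stabilized state feeds the noise and identifiability analyses, so
#' stationarity residuals must be clean.
#'
#' @param net a `reaction_network`.
#' @param x0 named initial state; defaults to the network's tabulated initial
#'   concentrations.
#' @param t_end final time (> 0); ignored when `grid` is given.
#' @param grid strictly increasing time grid starting at 0.
#' @param params optional parameter registry overriding `net$params`.
#' @param rtol,atol solver tolerances.
#' @return a `trajectory` object: time grid, time-by-species concentration
#'   matrix and solver metadata. `tidy()` returns it in long form.
#' @export
simulate_network <- function(net, x0 = initial_state(net), t_end = NULL,
                             grid = NULL, params = NULL,
                             rtol = 1e-8, atol = 1e-12) {
  if (is.null(grid)) {
    stopifnot(!is.null(t_end), t_end > 0)
    grid <- seq(0, t_end, length.out = 201)
  }
  stopifnot(all(diff(grid) > 0), all(x0 >= 0))
  cn <- compile_network(net)
  M <- stoichiometry_matrix(net)
  theta <- if (is.null(params)) unname(net$params) else
    unname(params[cn$p_keys])
  x0 <- x0[net$species$id]
  f <- function(t, y, p) {
    list(drop(M %*% flux_vector_compiled(cn, pmax(y, 0), theta)))
  }
  sol <- deSolve::lsoda(y = unname(x0), times = grid, func = f, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed at t = ", max(sol[, 1]), call. = FALSE)
  }
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- net$species$id
  if (min(conc) < -10 * atol - 1e-12) {
    warning("trajectory dips below -10*atol; check stiffness settings")
  }
  structure(list(time = sol[, 1], conc = conc,
                 scenario = net$metadata$scenario %||% "unnamed",
                 rtol = rtol, atol = atol), class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$scenario, ": ", length(x$time), " time points x ",
      ncol(x$conc), " species, t in [", min(x$time), ", ", max(x$time),
      "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trajectory <- function(x, ...) {
  as_tibble(as.data.frame(x$conc)) |>
    mutate(time = x$time, scenario = x$scenario) |>
    tidyr::pivot_longer(cols = -c("time", "scenario"),
                        names_to = "species", values_to = "concentration")
}

#' Plot a trajectory
#'
#' @param object a `trajectory`.
#' @param species optional character vector restricting the species drawn.
#' @param ... unused.
#' @return a ggplot object: concentration versus time, one line per species.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory <- function(object, species = NULL, ...) {
  d <- tidy(object)
  if (!is.null(species)) d <- filter(d, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$concentration,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stationary state of the deterministic system
#'
#' Long integration with plateau detection (`max |dx/dt| <
#' 1e-9 * (1 + max|x|)` sustained over 10 percent of the current horizon),
#' followed by Newton polishing on `M v(x) = 0` using the analytic flux
#' Jacobian. The horizon doubles until the plateau criterion holds.
#'
#' @param net a `reaction_network`.
#' @param x0 starting state (non-negative).
#' @param horizon initial integration horizon.
#' @param max_horizon give up beyond this horizon.
#' @param params optional parameter override.
#' @param polish run Newton refinement after the plateau is reached.
#' @return a `stationary_state`: `state`, `residual` (`max|M v|`), `horizon`
#'   reached and `method` tag.
#' @export
find_stationary_state <- function(net, x0 = initial_state(net),
                                  horizon = 100, max_horizon = 1e6,
                                  params = NULL, polish = TRUE) {
  cn <- compile_network(net)
  M <- stoichiometry_matrix(net)
  theta <- if (is.null(params)) unname(net$params) else
    unname(params[cn$p_keys])
  x <- unname(x0[net$species$id])
  h <- horizon
  repeat {
    grid <- seq(0, h, length.out = 101)
    f <- function(t, y, p) {
      list(drop(M %*% flux_vector_compiled(cn, pmax(y, 0), theta)))
    }
    sol <- deSolve::lsoda(x, grid, f, NULL, rtol = 1e-10, atol = 1e-12,
                          maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed while stabilizing (t = ", max(sol[, 1]), ")",
           call. = FALSE)
    }
    conc <- sol[, -1, drop = FALSE]
    # plateau: derivative criterion over the last 10% of the horizon
    tail_idx <- which(sol[, 1] >= 0.9 * h)
    ok <- all(vapply(tail_idx, function(i) {
      xi <- pmax(conc[i, ], 0)
      dx <- drop(M %*% flux_vector_compiled(cn, xi, theta))
      max(abs(dx)) < 1e-9 * (1 + max(abs(xi)))
    }, TRUE))
    x <- pmax(conc[nrow(conc), ], 0)
    if (ok) break
    h <- h * 4
    if (h > max_horizon) {
      stop("no stationary plateau before horizon ", max_horizon,
           "; max |dx/dt| = ",
           signif(max(abs(drop(M %*% flux_vector_compiled(cn, x, theta)))), 3),
           call. = FALSE)
    }
  }
  method <- "integration"
  if (polish) {
    for (it in 1:20) {
      v <- flux_vector_compiled(cn, x, theta)
      res <- drop(M %*% v)
      if (max(abs(res)) < 1e-13 * (1 + max(abs(x)))) break
      J <- M %*% flux_jac_state_compiled(cn, x, theta)
      step <- try(solve(J, -res), silent = TRUE)
      if (inherits(step, "try-error")) break
      x_new <- x + step
      if (any(x_new < 0)) break # keep the integrated iterate instead
      x <- x_new
      method <- "integration+newton"
    }
  }
  residual <- max(abs(drop(M %*% flux_vector_compiled(cn, x, theta))))
  structure(list(state = stats::setNames(x, net$species$id),
                 residual = residual, horizon = h, method = method),
            class = "stationary_state")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat("<stationary_state> residual ", format(x$residual, digits = 3),
      " (", x$method, ", horizon ", x$horizon, ")\n", sep = "")
  invisible(x)
}

#' Detect diverging species in a trajectory
#'
#' @param traj a `trajectory`.
#' @param threshold concentration threshold; defaults to `1e6` times the
#'   largest initial concentration (or 1e6 if the trajectory starts at zero).
#' @return tibble with columns `species` and `first_crossing` (time of first
#'   exceedance); zero rows when the trajectory is bounded.
#' @export
detect_divergence <- function(traj, threshold = NULL) {
  x0max <- max(traj$conc[1, ])
  if (is.null(threshold)) threshold <- 1e6 * max(x0max, 1)
  if (threshold <= x0max) {
    stop("threshold must exceed the largest initial concentration",
         call. = FALSE)
  }
  hits <- purrr::map_dfr(colnames(traj$conc), function(sp) {
    i <- which(traj$conc[, sp] > threshold)
    if (!length(i)) return(tibble())
    tibble(species = sp, first_crossing = traj$time[min(i)])
  })
  if (!nrow(hits)) {
    return(tibble(species = character(), first_crossing = numeric()))
  }
  arrange(hits, .data$first_crossing)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the jump process whose propensities come from
#' [build_propensities()] and whose state-change vectors are the stoichiometry
#' columns. Runs in compiled code; reproducibility is governed by `seed`
#' (paths are drawn sequentially from one seeded stream). Opaque rate laws are
#' supported only when they do not depend on the state (they are frozen to
#' constant propensities); state-dependent opaque laws are rejected.
#'
#' @param net a `reaction_network`.
#' @param x0_counts named non-negative integer initial copy numbers.
#' @param t_end end time.
#' @param n_paths number of independent paths.
#' @param seed integer seed.
#' @param record_times times at which the state is recorded (default
#'   `t_end` only).
#' @return an `ssa_ensemble`: array `[path, time, species]` plus metadata.
#' @export
ssa_simulate <- function(net, x0_counts = round(initial_state(net)),
                         t_end, n_paths = 1, seed = 1,
                         record_times = t_end) {
  stopifnot(n_paths >= 1, all(x0_counts >= 0),
            all(x0_counts == round(x0_counts)))
  enc <- encode_for_ssa(net)
  set.seed(seed)
  out <- ssa_run(enc$stoich, enc$type, enc$p1, enc$p2, enc$sub_off,
                 enc$sub_idx, enc$sub_coef, enc$inh_off, enc$inh_idx,
                 enc$inh_ki, unname(x0_counts[net$species$id]),
                 record_times, as.integer(n_paths))
  dim(out) <- c(n_paths, length(record_times), nrow(net$species))
  dimnames(out) <- list(NULL, NULL, net$species$id)
  structure(list(states = out, record_times = record_times, seed = seed,
                 scenario = net$metadata$scenario %||% "unnamed"),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  d <- dim(x$states)
  cat("<ssa_ensemble> ", d[1], " paths x ", d[2], " record times x ",
      d[3], " species (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Final-time ensemble states
#'
#' @param ens an `ssa_ensemble`.
#' @return matrix paths-by-species at the last recorded time.
#' @export
ssa_final_states <- function(ens) {
  nt <- length(ens$record_times)
  ens$states[, nt, , drop = TRUE]
}

encode_for_ssa <- function(net) {
  cn <- compile_network(net)
  theta <- unname(net$params)
  R <- cn$R
  type <- integer(R); p1 <- numeric(R); p2 <- numeric(R)
  sub_idx <- integer(); sub_coef <- integer(); sub_off <- integer(R + 1)
  inh_idx <- integer(); inh_ki <- numeric(); inh_off <- integer(R + 1)
  for (j in seq_len(R)) {
    e <- cn$entries[[j]]
    sub_off[j] <- length(sub_idx)
    inh_off[j] <- length(inh_idx)
    if (e$form == "MASS_ACTION") {
      type[j] <- 0L; p1[j] <- theta[e$k_idx]
      sub_idx <- c(sub_idx, e$sub_idx - 1L)
      sub_coef <- c(sub_coef, e$sub_coef)
    } else if (e$form %in% c("MICHAELIS_MENTEN", "MM_INHIBITED")) {
      type[j] <- 1L; p1[j] <- theta[e$vmax_idx]; p2[j] <- theta[e$km_idx]
      sub_idx <- c(sub_idx, e$s_idx - 1L); sub_coef <- c(sub_coef, 1L)
    } else {
      # opaque laws admissible only when state-independent
      if (length(e$d_state_idx)) {
        stop("state-dependent opaque rate law in reaction '",
             names(net$reactions)[j], "' cannot be simulated stochastically",
             call. = FALSE)
      }
      env <- opq_env(e, rep(0, cn$N), theta, cn$sp_ids)
      type[j] <- 0L; p1[j] <- eval(e$expr, env)
    }
    if (!is.null(e$inh_idx)) {
      inh_idx <- c(inh_idx, e$inh_idx - 1L)
      inh_ki <- c(inh_ki, theta[e$ki_idx])
    }
  }
  sub_off[R + 1] <- length(sub_idx)
  inh_off[R + 1] <- length(inh_idx)
  list(stoich = stoichiometry_matrix(net), type = type, p1 = p1, p2 = p2,
       sub_off = sub_off, sub_idx = sub_idx, sub_coef = sub_coef,
       inh_off = inh_off, inh_idx = inh_idx, inh_ki = inh_ki)
}
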