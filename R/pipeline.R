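#' Pipeline configuration
#'
#' @param model `"homeostasis"`, `"ad"`, `"ad_uncorrected"`, an SBML file
#'   path, or a `reaction_network`.
#' @param horizon simulation/stabilization horizon.
#' @param t_end comparison time for scenario fold changes (defaults to
#'   `horizon`).
#' @param delta,zeta identifiability thresholds.
#' @param seed integer seed echoed to stochastic stages.
#' @param divergence_threshold forwarded to [detect_divergence()].
#' @param stages subset of `c("structure", "stationary", "sensitivity",
#'   "noise", "clustering")` to run (simulation always runs).
#' @return a `pipeline_config` (a named list, echoed into the run report).
#' @export
pipeline_config <- function(model = "homeostasis", horizon = 400,
                            t_end = NULL, delta = 1e-6, zeta = 1e-3,
                            seed = 1, divergence_threshold = NULL,
                            stages = c("structure", "stationary",
                                       "sensitivity", "noise",
                                       "clustering")) {
  stopifnot(horizon > 0, delta > 0, delta < 1, zeta > 0)
  structure(list(model = model, horizon = horizon,
                 t_end = t_end %||% horizon, delta = delta, zeta = zeta,
                 seed = seed, divergence_threshold = divergence_threshold,
                 stages = stages),
            class = "pipeline_config")
}

resolve_model <- function(model) {
  if (inherits(model, "reaction_network")) return(model)
  if (is.character(model) && file.exists(model)) return(read_sbml(model))
  switch(model,
    homeostasis = build_homeostasis_model(),
    ad = build_ad_model(corrected = TRUE),
    ad_uncorrected = build_ad_model(corrected = FALSE),
    stop("unknown model source '", model, "'", call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: model resolution, deterministic simulation with
#' divergence detection, stationary-state stabilization, time-integrated
#' local sensitivity indices, LNA variance decomposition with the
#' 110-percent flagging rule, and redundancy-based parameter clustering
#' with identifiability filtering. A failing stage is recorded and the
#' stages depending on it are skipped; everything is deterministic given
#' the configuration.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` with one element per stage plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = unclass(config), failed = character())
  net <- resolve_model(config$model)
  report$model <- glance(net)
  report$scenario <- net$metadata$scenario %||% "model"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failed <<- c(report$failed, name)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  traj <- stage("simulate", simulate_network(net, t_end = config$horizon))
  report$trajectory <- traj
  if (!is.null(traj)) {
    report$divergence <- detect_divergence(traj,
                                           config$divergence_threshold)
    report$final_state <- traj$conc[nrow(traj$conc), ]
  }

  st <- NULL
  if ("stationary" %in% config$stages &&
      (is.null(report$divergence) || nrow(report$divergence) == 0)) {
    st <- stage("stationary",
                find_stationary_state(net, horizon = config$horizon))
    report$stationary <- st
  }

  if ("sensitivity" %in% config$stages && !is.null(st)) {
    report$sensitivity <- stage("sensitivity", {
      grid <- c(0, exp(seq(log(config$horizon / 1e3), log(config$horizon),
                           length.out = 50)))
      sens <- forward_sensitivities(net, x0 = st$state, grid = grid)
      list(result = sens, indices = sensitivity_indices(sens),
           indices_log = sensitivity_indices(sens, normalize = "log"))
    })
  }

  if ("noise" %in% config$stages && !is.null(st)) {
    report$noise <- stage("noise", {
      ops <- lna_operators(net, st$state)
      dec <- decompose_variance(ops)
      list(decomposition = dec, flags = flag_components(dec))
    })
  }

  if ("clustering" %in% config$stages && !is.null(st)) {
    report$clustering <- stage("clustering", {
      fim <- fisher_information(net, horizon = config$horizon)
      tree <- cluster_parameters(fim, delta = config$delta,
                                 zeta = config$zeta)
      list(fim = fim, tree = tree, summary = glance(tree))
    })
  }

  report$summary <- tibble(
    scenario = report$scenario,
    n_species = report$model$n_species,
    n_reactions = report$model$n_reactions,
    n_compartments = report$model$n_compartments,
    n_diverging = if (is.null(report$divergence)) NA_integer_ else
      nrow(report$divergence),
    stationary_residual = if (is.null(st)) NA_real_ else st$residual,
    n_flagged_components = if (is.null(report$noise)) NA_integer_ else
      sum(report$noise$flags$flag),
    n_unidentifiable = if (is.null(report$clustering)) NA_integer_ else
      report$clustering$summary$n_unidentifiable,
    n_clusters = if (is.null(report$clustering)) NA_integer_ else
      report$clustering$summary$n_clusters,
    failed_stages = paste(report$failed, collapse = ";"))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> scenario:", x$scenario, "\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.run_report <- function(x, ...) x$summary

#' Final-time fold changes between two runs
#'
#' @param report_a,report_b `run_report`s over the same species inventory
#'   (a: reference, e.g. homeostasis; b: perturbed, e.g. AD).
#' @return tibble: `species`, final concentrations `a` and `b`, `ratio`
#'   (b/a) and a `direction` label (`"up"`, `"down"`, `"unchanged"` at a
#'   2 percent margin).
#' @export
compare_scenarios <- function(report_a, report_b) {
  a <- report_a$final_state; b <- report_b$final_state
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("species inventories differ: ",
         paste(symdiff(names(a), names(b)), collapse = ", "), call. = FALSE)
  }
  b <- b[names(a)]
  tibble(species = names(a), a = unname(a), b = unname(b),
         ratio = unname(b / a)) |>
    mutate(direction = dplyr::case_when(
      .data$ratio > 1.02 ~ "up",
      .data$ratio < 0.98 ~ "down",
      TRUE ~ "unchanged"))
}

symdiff <- function(x, y) c(setdiff(x, y), setdiff(y, x))
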