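#' Fisher information matrix from forward sensitivities
#'
#' Builds `FIM = sum_e sum_t S_e(t)' S_e(t)` where `S_e(t)` is the
#' observed-species by parameter sensitivity matrix of (simulated)
#' experiment `e` on the design grid, under unit observation noise.
#'
#' The default design is a perturb-and-relax protocol: the model is
#' stabilized, the stationary state is displaced by a small set of
#' multiplicative perturbation patterns (global up, global down, and two
#' alternating patterns), and each relaxation back to equilibrium is
#' observed at `n_times` log-spaced time points for all non-enzyme species.
#' Observing only the unperturbed stationary state would make the
#' information matrix rank-deficient by construction (all sensitivity
#' trajectories then factor through a common linear map of dimension at most
#' the species count), so the excitation is what renders most parameters
#' identifiable. Parameters enter on the log scale by default (column `i`
#' multiplied by `theta_i`) and the matrix is normalized by its largest
#' diagonal entry so identifiability thresholds are scale-free.
#'
#' @param net a `reaction_network`.
#' @param x0 optional explicit initial state for a single-experiment design;
#'   when `NULL` (default) the perturb-and-relax protocol around the
#'   stabilized state is used.
#' @param horizon design horizon; defaults to the stabilization horizon.
#' @param n_times number of log-spaced design times per experiment.
#' @param observed character vector of observed species ids (default: all
#'   non-enzyme species).
#' @param scale `"log"` (default) or `"raw"` parameter scale.
#' @param normalize divide by the largest diagonal entry (default `TRUE`).
#' @param perturbations list of multiplicative perturbation vectors (length
#'   N or scalars) applied to the stabilized state; used only when `x0` is
#'   `NULL`.
#' @param sens_method forwarded to [forward_sensitivities()].
#' @return a `fisher_information`: matrix `F` over parameters, evaluation
#'   point and design metadata.
#' @export
fisher_information <- function(net, x0 = NULL, horizon = NULL, n_times = 50,
                               observed = NULL, scale = c("log", "raw"),
                               normalize = TRUE, perturbations = NULL,
                               sens_method = NULL) {
  scale <- match.arg(scale)
  starts <- list()
  if (is.null(x0)) {
    st <- find_stationary_state(net)
    if (is.null(horizon)) horizon <- st$horizon
    N <- nrow(net$species)
    if (is.null(perturbations)) {
      perturbations <- list(rep(1.3, N), rep(0.7, N),
                            ifelse(seq_len(N) %% 2 == 1, 1.5, 0.8),
                            ifelse(seq_len(N) %% 2 == 0, 1.5, 0.8))
    }
    starts <- lapply(perturbations, function(p) p * st$state)
  } else {
    starts <- list(x0[net$species$id])
  }
  if (is.null(horizon)) horizon <- 100
  if (is.null(observed)) {
    observed <- net$species$id[!net$species$is_enzyme]
  }
  grid <- c(0, exp(seq(log(horizon / 1e3), log(horizon),
                       length.out = n_times)))
  theta <- net$params
  l <- length(theta)
  F <- matrix(0, l, l, dimnames = list(names(theta), names(theta)))
  for (start in starts) {
    sens <- forward_sensitivities(net, x0 = start, grid = grid,
                                  method = sens_method %||% "auto")
    obs_idx <- match(observed, dimnames(sens$sens)[[2]])
    for (ti in seq_along(sens$time)) {
      S <- matrix(sens$sens[ti, obs_idx, , drop = TRUE],
                  nrow = length(obs_idx), ncol = l)
      if (scale == "log") S <- sweep(S, 2, unname(theta), `*`)
      F <- F + crossprod(S)
    }
  }
  if (normalize && max(diag(F)) > 0) F <- F / max(diag(F))
  structure(list(F = F, theta = theta,
                 design = list(horizon = horizon, n_times = n_times,
                               observed = observed, scale = scale,
                               normalize = normalize,
                               n_experiments = length(starts))),
            class = "fisher_information")
}

#' @export
print.fisher_information <- function(x, ...) {
  cat("<fisher_information> ", nrow(x$F), " parameters (", x$design$scale,
      " scale, ", x$design$n_experiments, " experiments)\n", sep = "")
  invisible(x)
}

fim_matrix <- function(fim) {
  if (inherits(fim, "fisher_information")) fim$F else as.matrix(fim)
}

# symmetric pseudo-inverse square root; eigendirections below `tol` times the
# reference scale (largest FIM diagonal) are treated as carrying no
# information
psqrt_inv <- function(S, tol = 1e-10, ref = NULL) {
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  cutoff <- tol * max(if (is.null(ref)) eg$values[1] else ref,
                      .Machine$double.xmin)
  keep <- eg$values > cutoff
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  V <- eg$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(eg$values[keep]))
}

#' Canonical correlations between two parameter blocks
#'
#' Computes the canonical correlations of the blocks `A` and `B` under the
#' Fisher-information inner product: the singular values of
#' `F_AA^{-1/2} F_AB F_BB^{-1/2}`, with pseudo-inversion of rank-deficient
#' blocks (eigendirections below `tol` times the largest FIM diagonal are
#' dropped). Values are clipped to `[0, 1]` and returned in decreasing
#' order.
#'
#' @param fim a `fisher_information` or a symmetric PSD matrix.
#' @param A,B disjoint non-empty index vectors (names or positions).
#' @param tol relative eigenvalue cutoff for the block pseudo-inverses.
#' @return numeric vector of length `min(|A|, |B|)`.
#' @export
canonical_correlations <- function(fim, A, B, tol = 1e-10) {
  F <- fim_matrix(fim)
  A <- resolve_idx(F, A); B <- resolve_idx(F, B)
  if (!length(A) || !length(B)) stop("empty block", call. = FALSE)
  if (length(intersect(A, B))) stop("blocks overlap", call. = FALSE)
  ref <- max(diag(F))
  Wa <- psqrt_inv(F[A, A, drop = FALSE], tol = tol, ref = ref)
  Wb <- psqrt_inv(F[B, B, drop = FALSE], tol = tol, ref = ref)
  Mab <- Wa %*% F[A, B, drop = FALSE] %*% Wb
  s <- svd(Mab, nu = 0, nv = 0)$d
  rho <- sort(pmin(pmax(s, 0), 1), decreasing = TRUE)
  length(rho) <- min(length(A), length(B))
  rho[is.na(rho)] <- 0
  rho
}

resolve_idx <- function(F, idx) {
  if (is.character(idx)) {
    out <- match(idx, rownames(F))
    if (anyNA(out)) stop("unknown parameter: ", idx[which(is.na(out))[1]],
                         call. = FALSE)
    out
  } else as.integer(idx)
}

#' Functional redundancy between parameter blocks
#'
#' `I(theta_A, theta_B | theta*) = -1/2 sum_j ln(1 - rho_j^2)` over the
#' canonical correlations `rho_j` (natural logarithm, so the measure is in
#' nats and equals the Gaussian mutual information between the blocks).
#' A canonical correlation of 1 (confounded blocks) yields `Inf`, a sentinel
#' ordered above every finite redundancy.
#'
#' @inheritParams canonical_correlations
#' @return non-negative number, possibly `Inf`.
#' @export
functional_redundancy <- function(fim, A, B, tol = 1e-10) {
  rho <- canonical_correlations(fim, A, B, tol = tol)
  if (any(rho >= 1 - 1e-9)) return(Inf)
  -0.5 * sum(log1p(-rho^2))
}

#' (delta, zeta)-identifiability filter
#'
#' A parameter `theta_i` is (delta, zeta)-identifiable if its Fisher
#' information diagonal exceeds `zeta` and its multiple correlation with all
#' remaining parameters — the single canonical correlation between `{i}` and
#' its complement — stays below `1 - delta`. The complement block is
#' pseudo-inverted with eigenvalue cutoff `zeta` as well: information below
#' the floor cannot confound.
#'
#' The package defaults `(delta, zeta) = (1e-6, 1e-3)` come from a
#' documented sweep on the sphingolipid model (see the methods vignette);
#' both are freely sweepable.
#'
#' @param fim a `fisher_information` or matrix.
#' @param delta in (0, 1); collinearity margin.
#' @param zeta positive information floor (applied to the normalized FIM).
#' @param within optional index set restricting the analysis universe.
#' @return list with `identifiable` (parameter names) and `removed`
#'   (tibble: `parameter`, `reason` in `"zeta"`/`"delta"`, and the measured
#'   `value`).
#' @export
identifiability_filter <- function(fim, delta = 1e-6, zeta = 1e-3,
                                   within = NULL) {
  stopifnot(delta > 0, delta < 1, zeta > 0)
  F <- fim_matrix(fim)
  univ <- if (is.null(within)) seq_len(nrow(F)) else resolve_idx(F, within)
  nm <- rownames(F) %||% as.character(seq_len(nrow(F)))
  removed <- tibble(parameter = character(), reason = character(),
                    value = numeric())
  ident <- character()
  for (i in univ) {
    if (F[i, i] <= zeta) {
      removed <- add_row(removed, parameter = nm[i], reason = "zeta",
                         value = F[i, i])
      next
    }
    rest <- setdiff(univ, i)
    rho <- if (length(rest)) {
      canonical_correlations(F, i, rest, tol = zeta)[1]
    } else 0
    if (rho >= 1 - delta) {
      removed <- add_row(removed, parameter = nm[i], reason = "delta",
                         value = rho)
    } else {
      ident <- c(ident, nm[i])
    }
  }
  list(identifiable = ident, removed = removed)
}

#' Redundancy-based hierarchical parameter clustering
#'
#' Agglomerative merge-and-remove loop: starting from the identifiable
#' singletons, each iteration merges the two current sets with the largest
#' functional redundancy and (in the default `"per_iteration"` mode)
#' re-applies the (delta, zeta) filter on the shrinking active universe,
#' removing parameters that fail it from further analysis. The loop ends
#' with one set or when every remaining pairwise redundancy is zero.
#'
#' The cluster count is derived from the merge-height profile: the cut is
#' placed at the largest relative drop between consecutive finite merge
#' heights, and clusters are the groups present just before that drop
#' (singletons still unmerged at the cut count as their own cluster).
#'
#' @param fim a `fisher_information` or matrix.
#' @param delta,zeta identifiability thresholds, see
#'   [identifiability_filter()].
#' @param removal `"per_iteration"` (default) or `"upfront"`.
#' @return a `redundancy_tree`: `merges` (step, members, height), `removed`,
#'   `clusters` (parameter to cluster id at the gap cut), `n_clusters`,
#'   and the active leaf set.
#' @export
cluster_parameters <- function(fim, delta = 1e-6, zeta = 1e-3,
                               removal = c("per_iteration", "upfront")) {
  removal <- match.arg(removal)
  F <- fim_matrix(fim)
  nm <- rownames(F) %||% as.character(seq_len(nrow(F)))
  rownames(F) <- colnames(F) <- nm

  flt <- identifiability_filter(F, delta, zeta)
  removed <- mutate(flt$removed, step = 0L)
  active <- flt$identifiable
  if (!length(active)) {
    stop("model fully non-identifiable under (delta, zeta)", call. = FALSE)
  }
  sets <- lapply(active, identity)
  merges <- tibble(step = integer(), set_a = list(), set_b = list(),
                   height = numeric())
  step <- 0L
  red <- function(a, b) functional_redundancy(F, a, b, tol = zeta)
  Rm <- matrix(NA_real_, length(sets), length(sets))
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    Rm[i, j] <- red(sets[[i]], sets[[j]])
  }
  repeat {
    if (length(sets) <= 1L) break
    best <- which(Rm == max(Rm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    h <- Rm[best[1], best[2]]
    if (!is.na(h) && h <= 0) break
    i <- max(best); j <- min(best)
    step <- step + 1L
    merges <- add_row(merges, step = step, set_a = list(sets[[i]]),
                      set_b = list(sets[[j]]), height = h)
    merged <- c(sets[[i]], sets[[j]])
    sets[[j]] <- merged
    sets[[i]] <- NULL
    Rm <- Rm[-i, -i, drop = FALSE]
    for (q in seq_along(sets)) {
      if (q == j) next
      val <- red(sets[[q]], sets[[j]])
      if (q > j) Rm[q, j] <- val else Rm[j, q] <- val
    }
    if (removal == "per_iteration") {
      univ <- unlist(sets)
      flt_it <- identifiability_filter(F, delta, zeta, within = univ)
      drop_par <- setdiff(univ, flt_it$identifiable)
      if (length(drop_par)) {
        removed <- bind_rows(removed,
                             mutate(filter(flt_it$removed,
                                           .data$parameter %in% drop_par),
                                    step = step))
        keep <- rep(TRUE, length(sets))
        for (q in seq_along(sets)) {
          sets[[q]] <- setdiff(sets[[q]], drop_par)
          if (!length(sets[[q]])) keep[q] <- FALSE
        }
        sets <- sets[keep]
        Rm <- matrix(NA_real_, length(sets), length(sets))
        for (ii in seq_along(sets)) for (jj in seq_len(ii - 1L)) {
          Rm[ii, jj] <- red(sets[[ii]], sets[[jj]])
        }
      }
    }
  }
  leaves <- unlist(sets)
  tree <- structure(list(merges = merges, removed = removed,
                         leaves = leaves, sets = sets,
                         delta = delta, zeta = zeta),
                    class = "redundancy_tree")
  cut <- cut_by_gap(tree)
  tree$clusters <- cut$clusters
  tree$n_clusters <- cut$n_clusters
  tree
}

# Largest relative drop between consecutive finite merge heights decides the
# cut; partitions are replayed from the merge list.
cut_by_gap <- function(tree) {
  merges <- tree$merges
  params <- unique(c(unlist(merges$set_a), unlist(merges$set_b),
                     tree$leaves))
  partition_after <- function(s) {
    sets <- lapply(params, identity)
    if (s > 0) for (q in seq_len(s)) {
      a <- merges$set_a[[q]]; b <- merges$set_b[[q]]
      ia <- which(vapply(sets, function(x) all(a %in% x), TRUE))[1]
      ib <- which(vapply(sets, function(x) all(b %in% x), TRUE))[1]
      sets[[ia]] <- c(sets[[ia]], sets[[ib]])
      sets[[ib]] <- NULL
    }
    sets
  }
  h <- merges$height
  fin <- which(is.finite(h))
  cut_step <- nrow(merges)
  if (length(fin) >= 2) {
    hf <- h[fin]
    drops <- (hf[-length(hf)] - hf[-1]) / (abs(hf[-length(hf)]) + 1e-12)
    cut_step <- fin[which.max(drops)]
  }
  sets <- partition_after(cut_step)
  sets <- sets[order(-vapply(sets, length, 1L))]
  clusters <- purrr::imap_dfr(sets, function(s, i) {
    tibble(parameter = s, cluster = i)
  })
  clusters <- filter(clusters, .data$parameter %in% tree$leaves)
  list(clusters = clusters,
       n_clusters = length(unique(clusters$cluster)))
}

#' @export
print.redundancy_tree <- function(x, ...) {
  cat("<redundancy_tree> ", length(x$leaves), " clustered parameters, ",
      nrow(x$removed), " removed, ", x$n_clusters,
      " clusters at the gap cut\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.redundancy_tree <- function(x, ...) {
  left_join(tibble(parameter = c(x$leaves, x$removed$parameter)),
            x$clusters, by = "parameter") |>
    left_join(select(x$removed, "parameter", removal_reason = "reason"),
              by = "parameter") |>
    mutate(identifiable = is.na(.data$removal_reason))
}

#' @exportS3Method generics::glance
glance.redundancy_tree <- function(x, ...) {
  tibble(n_parameters = length(x$leaves) + nrow(x$removed),
         n_identifiable = length(x$leaves),
         n_unidentifiable = nrow(x$removed),
         n_clusters = x$n_clusters,
         n_merges = nrow(x$merges),
         delta = x$delta, zeta = x$zeta)
}

#' Convert a redundancy tree to hclust / Newick
#'
#' Merge heights are redundancies (similarities); for dendrogram export they
#' are mapped to the dissimilarity `1/(1 + I)` and made monotone with a
#' cumulative maximum, which preserves merge order. Parameters removed as
#' non-identifiable are not part of the tree.
#'
#' @param tree a `redundancy_tree` whose merge history reaches a single set.
#' @return `as_hclust()` returns an `hclust`; `write_newick()` writes a
#'   Newick file via [ape::write.tree()] and returns the path invisibly.
#' @export
as_hclust <- function(tree) {
  merges <- tree$merges
  leaves <- sort(tree$leaves)
  n <- length(leaves)
  if (nrow(merges) != n - 1 ||
      !setequal(unique(c(unlist(merges$set_a), unlist(merges$set_b))),
                leaves)) {
    stop("tree is not a complete merge history over its leaves ",
         "(removals or early stop)", call. = FALSE)
  }
  merge_m <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  set_of <- stats::setNames(-seq_len(n), leaves) # negative: leaf index
  for (s in seq_len(n - 1)) {
    a <- merges$set_a[[s]][1]; b <- merges$set_b[[s]][1]
    merge_m[s, ] <- c(set_of[[a]], set_of[[b]])
    h <- merges$height[s]
    heights[s] <- 1 / (1 + ifelse(is.finite(h), h, 1e12))
    members <- c(merges$set_a[[s]], merges$set_b[[s]])
    set_of[members] <- s
  }
  heights <- cummax(heights)
  structure(list(merge = merge_m, height = heights,
                 order = hclust_order(merge_m), labels = leaves,
                 method = "functional_redundancy"),
            class = "hclust")
}

hclust_order <- function(merge_m) {
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge_m[i, 1]), walk(merge_m[i, 2]))
  }
  walk(nrow(merge_m))
}

#' @rdname as_hclust
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  hc <- as_hclust(tree)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cluster assignment at a fixed number of clusters
#'
#' Cuts the (monotonized) dendrogram at `k` groups, as one would cut a
#' plotted dendrogram by eye, independent of the automatic gap rule.
#'
#' @param tree a complete `redundancy_tree`.
#' @param k number of clusters.
#' @return tibble with `parameter` and `cluster`.
#' @export
cut_redundancy_tree <- function(tree, k) {
  hc <- as_hclust(tree)
  ct <- stats::cutree(hc, k = k)
  tibble(parameter = names(ct), cluster = unname(ct))
}
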