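#' Parameters for interval MDS fitting
#'
#' @param n_dims Number of dimensions of the solution (must be smaller than
#'   the number of items).
#' @param n_starts Number of random starting configurations (default 1000);
#'   the lowest-stress solution is kept.
#' @param max_iter Majorization iteration cap per start (default 1000).
#' @param conv_tol Relative stress-change convergence tolerance
#'   (default 1e-6).
#' @param seed Integer seed for the random starts (optional; when `NULL`
#'   the current RNG stream is used).
#' @param weight_mode `"uniform"` (default, the primary analysis),
#'   `"evidence"` (use the record's accumulated evidence weights) or
#'   `"familiarity"` (see [familiarity_pair_weights()]).
#' @return A list of class `fit_params`.
#' @export
fit_params <- function(n_dims = 2L, n_starts = 1000L, max_iter = 1000L,
                       conv_tol = 1e-6, seed = NULL,
                       weight_mode = c("uniform", "evidence",
                                       "familiarity")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(n_dims >= 1, n_starts >= 1, max_iter >= 1, conv_tol > 0)
  structure(list(n_dims = as.integer(n_dims),
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 conv_tol = conv_tol, seed = seed,
                 weight_mode = weight_mode),
            class = "fit_params")
}

resolve_weights <- function(record, params, items = NULL) {
  W <- switch(params$weight_mode,
    uniform = {
      w <- matrix(1, nrow(record$D), ncol(record$D))
      diag(w) <- 0
      w
    },
    evidence = record$W,
    familiarity = {
      if (is.null(items)) {
        abort("weight_mode = 'familiarity' needs an item manifest")
      }
      familiarity_pair_weights(items)[record$item_ids, record$item_ids]
    }
  )
  # pairs never co-presented carry no information regardless of mode
  W[record$W == 0] <- 0
  diag(W) <- 0
  if (all(W == 0)) abort("all pair weights are zero")
  W
}

#' Fit an interval MDS solution by SMACOF majorization
#'
#' Fits a `n_dims`-dimensional configuration to a dissimilarity record by
#' majorization (SMACOF), with interval disparities `dhat = a + b * D`
#' (`b >= 0`, negative disparities clamped to zero) re-estimated by weighted
#' least squares at every sweep. Each random start draws coordinates
#' uniformly in \[-1, 1\]^k; the lowest-stress solution across starts is
#' returned, centred.
#'
#' @param record A `dissimilarity_record` (or a bare symmetric matrix,
#'   which is wrapped via [dissimilarity_record()]).
#' @param params A [fit_params()] object.
#' @param items Item manifest; only needed for familiarity weighting.
#' @return An object of class `mds_config`: list with `item_ids`, `X`
#'   (n_items x n_dims matrix, centred), `stress1` (Kruskal stress-1),
#'   `spp` (stress-per-point percentages), `disparity` (`a`, `b`),
#'   `stress_trace` (per-iteration normalized stress of the winning start),
#'   `converged`, `start_index`, `weights`.
#' @export
fit_interval_mds <- function(record, params = fit_params(), items = NULL) {
  if (!inherits(record, "dissimilarity_record")) {
    record <- dissimilarity_record(record, normalize = FALSE)
  }
  n <- length(record$item_ids)
  if (params$n_dims >= n) abort("n_dims must be smaller than the item count")
  if (any(!is.finite(record$D))) abort("dissimilarities must be finite")
  W <- resolve_weights(record, params, items)

  starts <- with_optional_seed(params$seed, {
    lapply(seq_len(params$n_starts), function(i) {
      matrix(runif(n * params$n_dims, -1, 1), n, params$n_dims)
    })
  })
  best <- .smacof_multistart(record$D, W, starts,
                             max_iter = params$max_iter,
                             tol = params$conv_tol)
  X <- best$X
  dimnames(X) <- list(record$item_ids, paste0("dim", seq_len(params$n_dims)))
  config <- structure(
    list(item_ids = record$item_ids, X = X, stress1 = best$stress1,
         disparity = c(a = best$a, b = best$b),
         stress_trace = best$trace, converged = best$converged,
         start_index = best$start_index, weights = W,
         n_dims = params$n_dims),
    class = "mds_config"
  )
  config$spp <- stress_per_point(config, record)
  config
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.mds_config <- function(x, ...) {
  cat("<mds_config>", length(x$item_ids), "items in", x$n_dims,
      "dimension(s); stress-1 =", format(x$stress1, digits = 4),
      if (isTRUE(x$converged)) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @describeIn fit_interval_mds Tidy a configuration into one row per item
#'   (`item_id`, `dim1..dimK`, `spp`).
#' @param x An `mds_config`.
#' @param ... Unused.
#' @export
tidy.mds_config <- function(x, ...) {
  out <- tibble::as_tibble(x$X)
  out <- dplyr::bind_cols(tibble::tibble(item_id = x$item_ids), out)
  if (!is.null(x$spp)) out$spp <- unname(x$spp[x$item_ids])
  out
}

#' @describeIn fit_interval_mds One-row fit summary (`stress1`, `n_items`,
#'   `n_dims`, `converged`, `start_index`, disparity coefficients).
#' @export
glance.mds_config <- function(x, ...) {
  tibble::tibble(stress1 = x$stress1, n_items = length(x$item_ids),
                 n_dims = x$n_dims, converged = x$converged,
                 start_index = x$start_index,
                 disparity_a = unname(x$disparity["a"]),
                 disparity_b = unname(x$disparity["b"]))
}

config_matrix <- function(config) {
  if (inherits(config, "mds_config")) return(config$X)
  if (is.matrix(config)) return(config)
  if (is.data.frame(config)) {
    X <- as.matrix(config[, grep("^dim", names(config)), drop = FALSE])
    rownames(X) <- config$item_id
    return(X)
  }
  abort("cannot interpret `config` as a spatial configuration")
}

#' Kruskal stress-1
#'
#' `sqrt(sum w (d(X) - dhat)^2 / sum w d(X)^2)` over weighted pairs, where
#' `d(X)` are configuration distances and `dhat` the disparities.
#'
#' @param X Coordinate matrix (n x k).
#' @param disparities Symmetric matrix of disparities.
#' @param weights Optional symmetric weight matrix (default uniform).
#' @return Stress-1 value (non-negative scalar).
#' @export
stress1 <- function(X, disparities, weights = NULL) {
  X <- config_matrix(X)
  n <- nrow(X)
  if (is.null(weights)) {
    weights <- matrix(1, n, n)
    diag(weights) <- 0
  }
  stopifnot(nrow(disparities) == n, nrow(weights) == n)
  d <- as.matrix(dist(X))
  ut <- upper.tri(d)
  den <- sum(weights[ut] * d[ut]^2)
  if (den <= 0) abort("degenerate configuration: all distances zero")
  sqrt(sum(weights[ut] * (d[ut] - disparities[ut])^2) / den)
}

#' Stress-per-point decomposition
#'
#' Splits total stress into per-item percentage contributions: each pair's
#' weighted squared residual is attributed half to each endpoint. A
#' perfectly fitting configuration returns uniform shares.
#'
#' @param config An `mds_config` (uses its fitted disparities and weights).
#' @param record The `dissimilarity_record` the configuration was fit to.
#' @return Named numeric vector of percentages summing to 100.
#' @export
stress_per_point <- function(config, record) {
  X <- config_matrix(config)
  n <- nrow(X)
  a <- config$disparity["a"]
  b <- config$disparity["b"]
  dhat <- pmax(a + b * record$D, 0)
  diag(dhat) <- 0
  W <- config$weights
  d <- as.matrix(dist(X))
  R <- W * (d - dhat)^2
  diag(R) <- 0
  tot <- sum(R) / 2
  scale_ref <- sum(W * d^2) / 2
  if (tot <= 1e-12 * max(scale_ref, .Machine$double.xmin)) {
    # numerically perfect fit: uniform-share convention
    return(setNames(rep(100 / n, n), config$item_ids))
  }
  shares <- rowSums(R) / 2
  setNames(100 * shares / tot, config$item_ids)
}

#' Familiarity-based pair weights
#'
#' Dissimilarities involving poorly known experiences are less reliable;
#' this maps per-item familiarity ratings `f in [1, 5]` to pair weights
#' `w_ij = f_i * f_j / 25` in (0, 1\].
#'
#' @param items Item manifest with familiarity ratings (missing ratings for
#'   non-common roles default to 5).
#' @return Symmetric weight matrix with zero diagonal, named by item id.
#' @export
familiarity_pair_weights <- function(items) {
  items <- item_manifest(items)
  f <- items$familiarity
  if (anyNA(f)) abort("familiarity ratings missing for some common items")
  if (any(f < 1 | f > 5)) abort("familiarity ratings must lie in [1, 5]")
  w <- outer(f, f) / 25
  diag(w) <- 0
  dimnames(w) <- list(items$item_id, items$item_id)
  w
}

#' Permutation benchmark for an MDS solution
#'
#' Tests whether a fitted stress value is lower than expected for
#' structureless data by refitting MDS to matrices whose off-diagonal
#' upper-triangle entries are randomly permuted (and mirrored back to
#' symmetry). The permutation p-value is `(1 + #{null <= observed}) /
#' (n_perm + 1)`, and the solution passes when the observed stress falls
#' below the 5th percentile of the null stresses (one-sided alpha = 0.05).
#'
#' @param record A `dissimilarity_record`.
#' @param params [fit_params()] controlling the observed fit.
#' @param n_perm Number of permutations (default 500).
#' @param perm_starts Random starts per permutation refit (default 10; a
#'   reduced budget keeps the benchmark tractable).
#' @param alpha One-sided significance level (default 0.05).
#' @param observed Optionally, an already fitted `mds_config` for the
#'   record, to avoid refitting.
#' @return A list of class `permutation_report` with `observed_stress`,
#'   `null_stresses`, `p_value`, `passes`, `n_perm`, `alpha`.
#' @export
mds_permutation_test <- function(record, params = fit_params(),
                                 n_perm = 500L, perm_starts = 10L,
                                 alpha = 0.05, observed = NULL) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (n_perm < 20) warn("fewer than 20 permutations: unstable percentile")
  if (is.null(observed)) observed <- fit_interval_mds(record, params)
  n <- length(record$item_ids)
  perm_params <- fit_params(n_dims = params$n_dims, n_starts = perm_starts,
                            max_iter = params$max_iter,
                            conv_tol = params$conv_tol,
                            weight_mode = params$weight_mode)
  null_stresses <- with_optional_seed(params$seed, {
    vapply(seq_len(n_perm), function(i) {
      ut <- upper.tri(record$D)
      p <- sample.int(sum(ut))
      Dp <- record$D
      Wp <- record$W
      Dp[ut] <- record$D[ut][p]
      Wp[ut] <- record$W[ut][p] # evidence weight travels with its value
      Dp[lower.tri(Dp)] <- t(Dp)[lower.tri(Dp)]
      Wp[lower.tri(Wp)] <- t(Wp)[lower.tri(Wp)]
      rec_p <- structure(list(item_ids = record$item_ids, D = Dp, W = Wp,
                              n_trials_used = record$n_trials_used,
                              converged = TRUE),
                         class = "dissimilarity_record")
      fit_interval_mds(rec_p, perm_params)$stress1
    }, numeric(1))
  })
  p_value <- (1 + sum(null_stresses <= observed$stress1)) / (n_perm + 1)
  passes <- observed$stress1 <
    stats::quantile(null_stresses, alpha, names = FALSE)
  structure(list(observed_stress = observed$stress1,
                 null_stresses = null_stresses, p_value = p_value,
                 passes = passes, n_perm = as.integer(n_perm),
                 alpha = alpha),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("<permutation_report> observed stress",
      format(x$observed_stress, digits = 4), "vs", x$n_perm,
      "permuted refits; p =", format(x$p_value, digits = 4),
      if (x$passes) "(passes)" else "(fails)", "\n")
  invisible(x)
}

#' @describeIn mds_permutation_test One-row summary of a permutation
#'   benchmark.
#' @param x A `permutation_report`.
#' @param ... Unused.
#' @export
glance.permutation_report <- function(x, ...) {
  tibble::tibble(observed_stress = x$observed_stress, p_value = x$p_value,
                 passes = x$passes, n_perm = x$n_perm, alpha = x$alpha,
                 null_q05 = stats::quantile(x$null_stresses, 0.05,
                                            names = FALSE))
}
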