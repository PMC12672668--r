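#' Parameters for inverse-MDS dissimilarity estimation
#'
#' @param evidence_exponent Evidence utility exponent applied to per-pair
#'   evidence deficits when scoring candidate stimuli for the next trial
#'   (default 10; high values concentrate selection on the least-determined
#'   pairs).
#' @param evidence_target Target per-pair evidence weight; the session may
#'   stop once the worst pair exceeds it (default 0.5).
#' @param max_trials Maximum number of arrangements per session (default 12).
#' @param min_subset,max_subset Bounds on adaptive subset size; `max_subset
#'   = NULL` means the full item set.
#' @param scale_iterations Sweeps of the alternating trial-scale /
#'   dissimilarity update (default 1000; convergence is linear, so tight
#'   tolerances need on the order of a hundred sweeps).
#' @param scale_tol Convergence tolerance on the maximum absolute change of
#'   the unit-RMS-scaled dissimilarities (default 1e-6).
#' @return A list of class `imds_params`.
#' @export
imds_params <- function(evidence_exponent = 10, evidence_target = 0.5,
                        max_trials = 12L, min_subset = 3L,
                        max_subset = NULL, scale_iterations = 1000L,
                        scale_tol = 1e-6) {
  stopifnot(evidence_exponent > 0, evidence_target > 0,
            min_subset >= 3, max_trials >= 1, scale_iterations >= 1,
            scale_tol > 0)
  if (!is.null(max_subset) && max_subset < min_subset) {
    abort("max_subset must be >= min_subset")
  }
  structure(list(evidence_exponent = evidence_exponent,
                 evidence_target = evidence_target,
                 max_trials = as.integer(max_trials),
                 min_subset = as.integer(min_subset),
                 max_subset = max_subset,
                 scale_iterations = as.integer(scale_iterations),
                 scale_tol = scale_tol),
            class = "imds_params")
}

#' Pairwise on-screen distances of one arrangement trial
#'
#' Euclidean distances between all items co-presented in the trial;
#' pairs involving absent items are `NA`.
#'
#' @param trial Tibble with columns `item_id`, `x`, `y` (one arrangement),
#'   e.g. from [session_trial()].
#' @param item_ids Full item-id vector defining matrix order.
#' @return A symmetric `length(item_ids)` square matrix with zero diagonal
#'   for present items and `NA` for absent pairs.
#' @export
trial_distance_matrix <- function(trial, item_ids) {
  n <- length(item_ids)
  out <- matrix(NA_real_, n, n, dimnames = list(item_ids, item_ids))
  idx <- match(trial$item_id, item_ids)
  if (anyNA(idx)) abort("trial contains item ids absent from `item_ids`")
  d <- as.matrix(dist(cbind(trial$x, trial$y)))
  out[idx, idx] <- d
  out
}

#' Per-pair evidence weights of one arrangement trial
#'
#' Widely separated pairs are measured with better signal-to-noise than
#' cramped ones, so each co-presented pair receives evidence
#' `w = (d / d_max)^2` where `d_max` is the trial's largest inter-item
#' distance; values lie in \[0, 1\] and absent pairs are `NA`.
#'
#' @inheritParams trial_distance_matrix
#' @return Symmetric matrix of evidence weights (`NA` for absent pairs,
#'   zero diagonal).
#' @export
trial_evidence <- function(trial, item_ids) {
  d <- trial_distance_matrix(trial, item_ids)
  dmax <- max(d, na.rm = TRUE)
  if (dmax <= 0) abort("degenerate arrangement: all items coincident")
  w <- (d / dmax)^2
  diag(w)[!is.na(diag(w))] <- 0
  w
}

#' Estimate a dissimilarity matrix from multiple arrangements
#'
#' Statistically combines the evidence from all arrangements of a session
#' into a single representational dissimilarity matrix (RDM). Trials are
#' free to use different zoom levels, so each trial's distances enter
#' through a non-negative per-trial scale fitted by evidence-weighted least
#' squares; the scales and the combined estimate are alternated until the
#' estimate stabilizes, and the result is normalized to unit root mean
#' square over defined pairs.
#'
#' @param session An [arrangement_session()].
#' @param items Item manifest defining matrix order.
#' @param params An [imds_params()] object.
#' @return An object of class `dissimilarity_record`: list with `item_ids`,
#'   `D` (estimated dissimilarities, RMS 1), `W` (accumulated evidence
#'   weights; 0 marks pairs never co-presented, whose `D` entry is an
#'   undefined placeholder 0), `n_trials_used`, `converged`.
#' @export
estimate_rdm <- function(session, items, params = imds_params()) {
  items <- item_manifest(items)
  ids <- items$item_id
  n <- length(ids)
  idx <- sort(unique(session$trials$trial_index))
  if (length(idx) < 1) abort("session has no trials")

  # vectorized over the upper triangle: one entry per item pair
  ut <- upper.tri(matrix(0, n, n))
  trials_v <- lapply(idx, function(t) {
    d <- trial_distance_matrix(session_trial(session, t), ids)[ut]
    pres <- which(!is.na(d))
    dv <- d[pres]
    dmax <- max(dv)
    if (dmax <= 0) abort("degenerate arrangement: all items coincident")
    list(pix = pres, d = dv, w = (dv / dmax)^2)
  })

  wsum <- rep(0, sum(ut))
  for (tv in trials_v) wsum[tv$pix] <- wsum[tv$pix] + tv$w
  defined <- wsum > 0

  # initialize from trial 1 (the full-set trial), unit RMS
  Dh <- rep(0, sum(ut))
  Dh[trials_v[[1]]$pix] <- trials_v[[1]]$d
  Dh <- Dh / sqrt(mean(Dh[defined]^2))

  converged <- FALSE
  for (sweep in seq_len(params$scale_iterations)) {
    prev <- Dh
    num <- rep(0, length(Dh))
    for (tv in trials_v) {
      # non-negative per-trial scale by weighted least squares
      s_t <- max(0, sum(tv$w * tv$d * Dh[tv$pix]) / sum(tv$w * tv$d^2))
      num[tv$pix] <- num[tv$pix] + tv$w * s_t * tv$d
    }
    Dh[defined] <- num[defined] / wsum[defined]
    Dh <- Dh / sqrt(mean(Dh[defined]^2))
    # Dh is RMS-normalized to 1, so absolute change is already relative to
    # the matrix scale
    if (max(abs(Dh[defined] - prev[defined])) < params$scale_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("dissimilarity estimate did not converge within scale_iterations")
  }

  Dhat <- matrix(0, n, n, dimnames = list(ids, ids))
  Dhat[ut] <- Dh
  Dhat <- Dhat + t(Dhat)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[ut] <- wsum
  W <- W + t(W)
  structure(list(item_ids = ids, D = Dhat, W = W,
                 n_trials_used = length(idx), converged = converged),
            class = "dissimilarity_record")
}

rms_normalize <- function(D, defined = NULL) {
  if (is.null(defined)) {
    defined <- matrix(TRUE, nrow(D), ncol(D))
    diag(defined) <- FALSE
  }
  r <- sqrt(mean(D[defined]^2))
  if (!is.finite(r) || r <= 0) abort("cannot RMS-normalize a zero matrix")
  D / r
}

#' Build a dissimilarity record from a precomputed matrix
#'
#' Wraps an externally supplied (or averaged) dissimilarity matrix in the
#' container used throughout the package; weights default to 1 for every
#' off-diagonal pair.
#'
#' @param D Symmetric non-negative matrix with zero diagonal; row names are
#'   used as item ids when present.
#' @param W Optional symmetric evidence-weight matrix.
#' @param item_ids Item ids (defaults to `rownames(D)` or `item_1..n`).
#' @param normalize RMS-normalize `D` to 1 over weighted pairs
#'   (default TRUE).
#' @return A `dissimilarity_record`.
#' @export
dissimilarity_record <- function(D, W = NULL, item_ids = NULL,
                                 normalize = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) abort("D must be square")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  D <- (D + t(D)) / 2
  if (any(D < 0) || any(diag(D) != 0)) {
    abort("D must be non-negative with zero diagonal")
  }
  if (is.null(item_ids)) {
    item_ids <- rownames(D)
    if (is.null(item_ids)) item_ids <- paste0("item_", seq_len(n))
  }
  if (is.null(W)) {
    W <- matrix(1, n, n)
    diag(W) <- 0
  } else {
    W <- as.matrix(W)
    if (max(abs(W - t(W))) > 1e-8) abort("W must be symmetric")
    W <- (W + t(W)) / 2
  }
  dimnames(D) <- dimnames(W) <- list(item_ids, item_ids)
  defined <- W > 0
  diag(defined) <- FALSE
  if (normalize) D <- rms_normalize(D, defined)
  structure(list(item_ids = item_ids, D = D, W = W,
                 n_trials_used = NA_integer_, converged = TRUE),
            class = "dissimilarity_record")
}

#' @export
print.dissimilarity_record <- function(x, ...) {
  cat("<dissimilarity_record>", length(x$item_ids), "items,",
      x$n_trials_used, "trial(s); min evidence",
      format(min(x$W[upper.tri(x$W)]), digits = 3), "\n")
  invisible(x)
}

#' @describeIn estimate_rdm Tidy a dissimilarity record into one row per
#'   item pair with columns `item_a`, `item_b`, `dissimilarity`, `evidence`.
#' @param x A `dissimilarity_record`.
#' @param ... Unused.
#' @export
tidy.dissimilarity_record <- function(x, ...) {
  ut <- upper.tri(x$D)
  tibble::tibble(
    item_a = rownames(x$D)[row(x$D)[ut]],
    item_b = colnames(x$D)[col(x$D)[ut]],
    dissimilarity = x$D[ut],
    evidence = x$W[ut]
  )
}

#' Adaptive choice of the next arrangement subset
#'
#' Greedy evidence-driven selection: each pair has deficit
#' `u_ij = max(0, 1 - W_ij / evidence_target)`; each candidate stimulus
#' scores `U_s = sum_j u_sj ^ E` against the current subset. The subset is
#' seeded with the maximum-deficit pair (ties broken lexicographically) and
#' grown by the highest-utility stimulus while per-trial efficiency
#' `sum_{i<j in S} u_ij / |S|` does not decrease, subject to the size
#' bounds.
#'
#' @param record A `dissimilarity_record` of the trials so far.
#' @param params An [imds_params()].
#' @return Character vector of item ids (empty when every pair has reached
#'   the evidence target, signalling the caller to stop).
#' @export
select_next_subset <- function(record, params = imds_params()) {
  ids <- record$item_ids
  n <- length(ids)
  max_subset <- if (is.null(params$max_subset)) n else
    min(params$max_subset, n)
  U <- matrix(pmax(0, 1 - record$W / params$evidence_target), n, n)
  diag(U) <- 0
  if (all(U == 0)) return(character(0))

  # seed with the maximum-deficit pair, lexicographic tie-break on ids
  ut <- which(upper.tri(U), arr.ind = TRUE)
  vals <- U[upper.tri(U)]
  best <- max(vals)
  cand <- ut[vals >= best - 1e-15, , drop = FALSE]
  pair_key <- apply(cand, 1, function(rc) {
    paste(sort(c(ids[rc[1]], ids[rc[2]])), collapse = "\r")
  })
  seed <- cand[order(pair_key)[1], ]
  S <- sort(seed)

  eff <- function(S) {
    if (length(S) < 2) return(0)
    sum(U[S, S][upper.tri(U[S, S])]) / length(S)
  }

  repeat {
    if (length(S) >= max_subset) break
    rest <- setdiff(seq_len(n), S)
    if (length(rest) == 0) break
    util <- vapply(rest, function(s) {
      sum(U[s, S]^params$evidence_exponent)
    }, numeric(1))
    ord <- order(-util, ids[rest])
    add <- rest[ord[1]]
    if (length(S) >= params$min_subset && eff(c(S, add)) < eff(S)) break
    S <- c(S, add)
  }
  ids[sort(S)]
}

#' Session termination rule
#'
#' A session stops once the pair with the lowest accumulated evidence
#' exceeds the evidence target, or after the maximum number of
#' arrangements, whichever comes first.
#'
#' @param record A `dissimilarity_record`.
#' @param params An [imds_params()].
#' @return A list with `stop` (logical) and `reason` (`"evidence"`,
#'   `"max_trials"` or `NA`).
#' @export
should_terminate <- function(record, params = imds_params()) {
  min_w <- min(record$W[upper.tri(record$W)])
  if (min_w > params$evidence_target) {
    list(stop = TRUE, reason = "evidence")
  } else if (!is.na(record$n_trials_used) &&
             record$n_trials_used >= params$max_trials) {
    list(stop = TRUE, reason = "max_trials")
  } else {
    list(stop = FALSE, reason = NA_character_)
  }
}
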