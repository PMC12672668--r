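#' Rotate a 2-D configuration
#'
#' Standard counter-clockwise rotation about the centroid; all pairwise
#' distances are preserved.
#'
#' @param config An `mds_config`, coordinate matrix, or tidy configuration
#'   tibble (2-D).
#' @param angle_degrees Rotation angle in degrees.
#' @return A coordinate matrix with the same dimnames as the input.
#' @export
rotate_config <- function(config, angle_degrees) {
  X <- config_matrix(config)
  if (ncol(X) != 2) abort("rotation is defined for 2-D configurations")
  ctr <- colMeans(X)
  th <- angle_degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- sweep(sweep(X, 2, ctr) %*% R, 2, ctr, `+`)
  dimnames(out) <- dimnames(X)
  out
}

#' Baseline-anchored rotation of a configuration
#'
#' Searches rotation angles on a grid and returns the one minimizing the
#' sum over dimensions of the min-max-normalized coordinates of the
#' no-ownership baseline item. Anchoring the empty-glove item at the joint
#' minimum makes dimensions interpretable (low values = less embodiment /
#' stimulation) and comparable across solutions.
#'
#' @param config 2-D configuration containing the baseline item.
#' @param baseline_none_id Item id of the no-ownership baseline.
#' @param grid_step Grid resolution in degrees (default 5).
#' @return List with `angle` (degrees; smallest angle on ties) and
#'   `config` (the rotated coordinate matrix).
#' @export
baseline_anchor_rotation <- function(config, baseline_none_id,
                                     grid_step = 5) {
  X <- config_matrix(config)
  if (!baseline_none_id %in% rownames(X)) {
    abort(paste0("baseline item '", baseline_none_id,
                 "' absent from configuration"))
  }
  angles <- seq(0, 360 - grid_step, by = grid_step)
  obj <- vapply(angles, function(a) {
    Xr <- rotate_config(X, a)
    sum(vapply(seq_len(ncol(Xr)), function(k) {
      normalize_dimension(Xr, k)[baseline_none_id]
    }, numeric(1)))
  }, numeric(1))
  best <- angles[which.min(obj)] # which.min takes the first = smallest angle
  list(angle = best, config = rotate_config(X, best))
}

#' Min-max normalization of one configuration dimension
#'
#' Maps coordinates on a dimension linearly to \[0, 1\]: the item at the
#' dimension minimum scores 0, the maximum scores 1. Used for ownership /
#' stimulation scores and for clustering.
#'
#' @param config Configuration (matrix, `mds_config`, or tidy tibble).
#' @param dim Dimension index (column).
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
normalize_dimension <- function(config, dim) {
  X <- config_matrix(config)
  x <- X[, dim]
  rng <- range(x)
  if (rng[1] == rng[2]) abort("degenerate dimension: all coordinates equal")
  setNames((x - rng[1]) / (rng[2] - rng[1]), rownames(X))
}

#' Normalize every dimension of a configuration
#'
#' @inheritParams normalize_dimension
#' @return Matrix of min-max-normalized coordinates.
#' @export
normalize_config <- function(config) {
  X <- config_matrix(config)
  out <- vapply(seq_len(ncol(X)), function(k) normalize_dimension(X, k),
                numeric(nrow(X)))
  dimnames(out) <- dimnames(X)
  out
}

centroid_size <- function(X) sqrt(sum(sweep(X, 2, colMeans(X))^2))

#' Procrustes alignment of two configurations
#'
#' Least-squares Procrustes superimposition of `source` onto `target`:
#' both configurations are centred and scaled to unit centroid size
#' ("Procrustes normalized units"), then the optimal orthogonal map
#' (rotation, and reflection when allowed) is obtained by singular value
#' decomposition, with an optimal scale factor when allowed. The target is
#' left untouched apart from its own normalization.
#'
#' @param source,target Configurations over the same items and
#'   dimensionality (matrices, `mds_config`s, or tidy tibbles). Rows are
#'   matched by item id when rownames are present.
#' @param allow_scaling Fit an optimal scale factor (default TRUE).
#' @param allow_reflection Permit an orientation-reversing map
#'   (default TRUE).
#' @return An object of class `procrustes_alignment`: list with `aligned`
#'   (source coordinates in the target's normalized frame), `target`
#'   (normalized target), `rotation`, `scale`, `residual_ss`, the
#'   similarity coefficients `congruence`, `coord_correlation`,
#'   `alienation`, and `landmarks` (per-item displacements, sorted
#'   descending).
#' @export
procrustes_align <- function(source, target, allow_scaling = TRUE,
                             allow_reflection = TRUE) {
  Xs <- config_matrix(source)
  Xt <- config_matrix(target)
  if (!is.null(rownames(Xs)) && !is.null(rownames(Xt))) {
    common <- intersect(rownames(Xt), rownames(Xs))
    if (length(common) < nrow(Xt)) {
      abort("source and target must share the same item set")
    }
    Xs <- Xs[rownames(Xt), , drop = FALSE]
  }
  if (!all(dim(Xs) == dim(Xt))) {
    abort("source and target must have identical dimensions")
  }
  if (nrow(Xs) < 3) abort("need at least 3 common items to align")

  # both to centred unit centroid size
  Xs <- sweep(Xs, 2, colMeans(Xs))
  Xt <- sweep(Xt, 2, colMeans(Xt))
  ss <- centroid_size(Xs)
  st <- centroid_size(Xt)
  if (ss == 0 || st == 0) abort("degenerate configuration: zero size")
  Xs <- Xs / ss
  Xt <- Xt / st

  sv <- svd(crossprod(Xt, Xs))
  R <- sv$v %*% t(sv$u)
  d <- sv$d
  if (!allow_reflection && det(R) < 0) {
    k <- ncol(Xs)
    flip <- diag(k)
    flip[k, k] <- -1
    R <- sv$v %*% flip %*% t(sv$u)
    d[k] <- -d[k]
  }
  scale <- if (allow_scaling) sum(d) / sum(Xs^2) else 1
  aligned <- scale * Xs %*% R
  dimnames(aligned) <- dimnames(Xt)
  residual_ss <- sum((aligned - Xt)^2)

  coefs <- similarity_coefficients(aligned, Xt)
  disp <- sqrt(rowSums((aligned - Xt)^2))
  landmarks <- tibble::tibble(item_id = rownames(Xt), distance = disp)
  landmarks <- dplyr::arrange(landmarks, dplyr::desc(.data$distance))

  structure(list(aligned = aligned, target = Xt, rotation = R,
                 scale = scale, residual_ss = residual_ss,
                 congruence = coefs[["congruence"]],
                 coord_correlation = coefs[["coord_correlation"]],
                 alienation = coefs[["alienation"]],
                 landmarks = landmarks,
                 allow_scaling = allow_scaling,
                 allow_reflection = allow_reflection),
            class = "procrustes_alignment")
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat("<procrustes_alignment>", nrow(x$aligned), "landmarks; c =",
      format(x$congruence, digits = 4), "r =",
      format(x$coord_correlation, digits = 4), "a =",
      format(x$alienation, digits = 4), "\n")
  invisible(x)
}

#' @describeIn procrustes_align Per-item landmark displacements as a tidy
#'   tibble (sorted descending).
#' @param x A `procrustes_alignment`.
#' @param ... Unused.
#' @export
tidy.procrustes_alignment <- function(x, ...) x$landmarks

#' @describeIn procrustes_align One-row alignment summary (congruence,
#'   coordinate correlation, alienation, scale, residual sum of squares).
#' @export
glance.procrustes_alignment <- function(x, ...) {
  tibble::tibble(congruence = x$congruence,
                 coord_correlation = x$coord_correlation,
                 alienation = x$alienation, scale = x$scale,
                 residual_ss = x$residual_ss)
}

#' Configurational similarity coefficients
#'
#' For two configurations over the same items: the congruence coefficient
#' `c` of corresponding pairwise distances, the Pearson correlation `r` of
#' stacked corresponding coordinates, and the alienation coefficient
#' `a = sqrt(1 - c^2)`.
#'
#' @param aligned,target Configurations (typically from
#'   [procrustes_align()]).
#' @return Named numeric vector with `congruence`, `coord_correlation`,
#'   `alienation`.
#' @export
similarity_coefficients <- function(aligned, target) {
  Xa <- config_matrix(aligned)
  Xt <- config_matrix(target)
  d1 <- as.matrix(dist(Xa))[upper.tri(diag(nrow(Xa)))]
  d2 <- as.matrix(dist(Xt))[upper.tri(diag(nrow(Xt)))]
  if (all(d1 == 0) || all(d2 == 0)) {
    abort("degenerate configuration: all distances zero")
  }
  cc <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
  r <- stats::cor(as.vector(Xa), as.vector(Xt))
  c(congruence = cc, coord_correlation = r,
    alienation = sqrt(max(0, 1 - cc^2)))
}

#' Null benchmark for Procrustes similarity coefficients
#'
#' Aligns pairs of random configurations (points uniform in the unit
#' square) to build null distributions of the congruence, coordinate
#' correlation and alienation coefficients, against which observed values
#' can be compared (an observed congruence above the null maximum indicates
#' far-better-than-chance configurational similarity).
#'
#' @param n_items Number of landmarks per configuration.
#' @param n_dims Dimensionality (default 2).
#' @param n_sims Number of simulated random pairs (default 500).
#' @param seed Optional integer seed.
#' @return A tibble with one row per simulation and columns `congruence`,
#'   `coord_correlation`, `alienation`.
#' @export
procrustes_null_benchmark <- function(n_items, n_dims = 2L, n_sims = 500L,
                                      seed = NULL) {
  if (n_sims < 20) warn("fewer than 20 simulations: unstable percentiles")
  sims <- with_optional_seed(seed, {
    purrr::map(seq_len(n_sims), function(i) {
      A <- matrix(runif(n_items * n_dims), n_items, n_dims)
      B <- matrix(runif(n_items * n_dims), n_items, n_dims)
      al <- procrustes_align(A, B)
      tibble::tibble(congruence = al$congruence,
                     coord_correlation = al$coord_correlation,
                     alienation = al$alienation)
    })
  })
  dplyr::bind_rows(sims)
}

#' Compare observed similarity coefficients against a null benchmark
#'
#' @param alignment A `procrustes_alignment`.
#' @param null Null tibble from [procrustes_null_benchmark()].
#' @return One-row tibble with observed values, null extremes, and
#'   `exceeds_benchmark` (TRUE when the observed congruence exceeds the
#'   null maximum and the observed alienation falls below the null
#'   minimum).
#' @export
benchmark_alignment <- function(alignment, null) {
  tibble::tibble(
    congruence = alignment$congruence,
    coord_correlation = alignment$coord_correlation,
    alienation = alignment$alienation,
    null_c_max = max(null$congruence),
    null_r_max = max(null$coord_correlation),
    null_a_min = min(null$alienation),
    exceeds_benchmark = alignment$congruence > max(null$congruence) &
      alignment$alienation < min(null$alienation)
  )
}

#' Displacements of homologous landmarks between aligned configurations
#'
#' Euclidean distance of each item between the two configurations of an
#' alignment, in Procrustes normalized units; large displacements flag
#' items whose position in the space changed between conditions.
#'
#' @param aligned,target Configurations over the same items (row order of
#'   `target` is used).
#' @return Tibble with `item_id` and `distance`, sorted descending.
#' @export
landmark_displacements <- function(aligned, target) {
  Xa <- config_matrix(aligned)
  Xt <- config_matrix(target)
  if (!is.null(rownames(Xa)) && !is.null(rownames(Xt))) {
    Xa <- Xa[rownames(Xt), , drop = FALSE]
  }
  disp <- sqrt(rowSums((Xa - Xt)^2))
  out <- tibble::tibble(item_id = rownames(Xt), distance = disp)
  dplyr::arrange(out, dplyr::desc(.data$distance))
}
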