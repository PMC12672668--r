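#' k-means partition of a normalized bodily-space configuration
#'
#' Lloyd-style k-means (best of `n_init` seeded initializations) on
#' min-max-normalized configuration dimensions, with the percentage of
#' variance explained (between-cluster sum of squares over total).
#'
#' @param config_normalized Matrix of normalized coordinates (see
#'   [normalize_config()]); a raw configuration is normalized on the fly.
#' @param k Number of clusters (`2 <= k < n_items`).
#' @param n_init Number of random initializations (default 100).
#' @param seed Optional integer seed.
#' @return Object of class `cluster_solution`: list with `k`, `assignments`
#'   (tibble `item_id`, `cluster`), `centroids`, `variance_explained`,
#'   `totss`, `withinss`.
#' @export
kmeans_fit <- function(config_normalized, k, n_init = 100L, seed = NULL) {
  X <- config_matrix(config_normalized)
  if (max(X) > 1 + 1e-9 || min(X) < -1e-9) X <- normalize_config(X)
  n <- nrow(X)
  if (k < 2 || k >= n) abort("k must satisfy 2 <= k < n_items")
  km <- with_optional_seed(seed, {
    kmeans(X, centers = k, nstart = n_init, iter.max = 100)
  })
  ve <- 100 * km$betweenss / km$totss
  structure(
    list(k = as.integer(k),
         assignments = tibble::tibble(item_id = rownames(X),
                                      cluster = unname(km$cluster)),
         centroids = km$centers,
         variance_explained = ve,
         totss = km$totss,
         withinss = sum(km$withinss)),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k =", x$k, "|",
      format(x$variance_explained, digits = 4), "% variance explained\n")
  invisible(x)
}

#' @describeIn kmeans_fit Tidy cluster assignments (one row per item).
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @export
tidy.cluster_solution <- function(x, ...) x$assignments

#' @describeIn kmeans_fit One-row summary (`k`, `variance_explained`,
#'   `withinss`).
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, variance_explained = x$variance_explained,
                 withinss = x$withinss)
}

# --- cluster-count validity indices --------------------------------------
# Each index maps a candidate partition (or the within-SS profile) to a
# preferred k; the panel votes and the modal k wins (ties -> smaller k).

ch_index <- function(X, cl) {
  n <- nrow(X)
  k <- length(unique(cl))
  gm <- colMeans(X)
  bss <- sum(vapply(split(seq_len(n), cl), function(ix) {
    length(ix) * sum((colMeans(X[ix, , drop = FALSE]) - gm)^2)
  }, numeric(1)))
  wss <- sum(vapply(split(seq_len(n), cl), function(ix) {
    sum(sweep(X[ix, , drop = FALSE], 2,
              colMeans(X[ix, , drop = FALSE]))^2)
  }, numeric(1)))
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

db_index <- function(X, cl) {
  ks <- sort(unique(cl))
  cent <- t(vapply(ks, function(g) colMeans(X[cl == g, , drop = FALSE]),
                   numeric(ncol(X))))
  s <- vapply(ks, function(g) {
    mean(sqrt(rowSums(sweep(X[cl == g, , drop = FALSE], 2,
                            cent[which(ks == g), ])^2)))
  }, numeric(1))
  k <- length(ks)
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

dunn_index <- function(X, cl) {
  d <- as.matrix(dist(X))
  same <- outer(cl, cl, `==`)
  diag(same) <- NA
  between <- min(d[!is.na(same) & !same])
  within <- max(d[!is.na(same) & same], 0)
  if (within == 0) return(Inf)
  between / within
}

c_index <- function(X, cl) {
  d <- as.matrix(dist(X))
  ut <- upper.tri(d)
  same <- outer(cl, cl, `==`)[ut]
  dv <- d[ut]
  sw <- sum(dv[same])
  nw <- sum(same)
  if (nw == 0) return(NA_real_)
  sorted <- sort(dv)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  if (smax == smin) return(NA_real_)
  (sw - smin) / (smax - smin)
}

point_biserial <- function(X, cl) {
  d <- as.matrix(dist(X))
  ut <- upper.tri(d)
  same <- outer(cl, cl, `==`)[ut]
  dv <- d[ut]
  if (all(same) || !any(same)) return(NA_real_)
  -stats::cor(dv, as.numeric(same)) # larger = tighter clusters
}

#' Majority-vote selection of the cluster count
#'
#' Fits k-means for every k in `k_range` and lets a panel of eight cluster
#' validity indices vote: mean silhouette width, Calinski-Harabasz,
#' Davies-Bouldin (minimized), Dunn, gap statistic (uniform reference
#' sets), elbow (second difference of within-SS), C-index (minimized) and
#' point-biserial correlation. The modal k wins; ties go to the smaller k.
#'
#' @inheritParams kmeans_fit
#' @param k_range Candidate cluster counts (default 2:6).
#' @param n_init Initializations per k (default 100).
#' @param gap_refs Uniform reference sets for the gap statistic
#'   (default 50).
#' @param seed Optional integer seed.
#' @return List with `k` (winning count), `votes` (tibble `index`, `k`),
#'   and `solution` (the [kmeans_fit()] at the winning k).
#' @export
select_k_majority <- function(config_normalized, k_range = 2:6,
                              n_init = 100L, gap_refs = 50L, seed = NULL) {
  X <- config_matrix(config_normalized)
  if (max(X) > 1 + 1e-9 || min(X) < -1e-9) X <- normalize_config(X)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0) abort("k_range contains no valid cluster count")

  with_optional_seed(seed, {
    fits <- lapply(k_range, function(k) {
      kmeans(X, centers = k, nstart = n_init, iter.max = 100)
    })
    d <- dist(X)
    wss <- vapply(fits, function(f) sum(f$withinss), numeric(1))

    sil <- vapply(seq_along(k_range), function(i) {
      mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
    }, numeric(1))
    ch <- vapply(seq_along(k_range), function(i) {
      ch_index(X, fits[[i]]$cluster)
    }, numeric(1))
    db <- vapply(seq_along(k_range), function(i) {
      db_index(X, fits[[i]]$cluster)
    }, numeric(1))
    dunn <- vapply(seq_along(k_range), function(i) {
      dunn_index(X, fits[[i]]$cluster)
    }, numeric(1))
    cind <- vapply(seq_along(k_range), function(i) {
      c_index(X, fits[[i]]$cluster)
    }, numeric(1))
    pb <- vapply(seq_along(k_range), function(i) {
      point_biserial(X, fits[[i]]$cluster)
    }, numeric(1))

    gap <- cluster::clusGap(
      X, FUN = function(x, k) kmeans(x, k, nstart = 25, iter.max = 100),
      K.max = max(k_range), B = gap_refs, verbose = FALSE
    )
    gtab <- gap$Tab[k_range, , drop = FALSE]
    gap_k <- k_range[cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                                    method = "Tibs2001SEmax")]

    # elbow on the within-SS profile over the k grid (needs interior points)
    elbow_k <- if (length(k_range) >= 3) {
      d2 <- diff(diff(wss)) # second difference; max curvature = elbow
      k_range[which.max(d2) + 1]
    } else {
      k_range[which.min(wss)]
    }

    pick <- function(vals, maximize = TRUE) {
      if (all(is.na(vals))) return(NA_integer_)
      if (maximize) k_range[which.max(vals)] else k_range[which.min(vals)]
    }
    votes <- tibble::tibble(
      index = c("silhouette", "calinski_harabasz", "davies_bouldin",
                "dunn", "gap", "elbow", "c_index", "point_biserial"),
      k = c(pick(sil), pick(ch), pick(db, maximize = FALSE), pick(dunn),
            gap_k, elbow_k, pick(cind, maximize = FALSE), pick(pb))
    )
    tab <- table(votes$k[!is.na(votes$k)])
    if (length(tab) == 0) abort("all validity indices were undefined")
    winners <- as.integer(names(tab)[tab == max(tab)])
    k_win <- min(winners) # ties -> smaller k
    list(k = k_win, votes = votes,
         solution = kmeans_fit(X, k_win, n_init = n_init))
  })
}
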