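# Shared fixtures: all built in code, no stored data.

items13 <- default_item_manifest()

# latent space with well-spread structure (items on a circle): evidence
# accumulates fast, sessions stop by the evidence rule
make_easy_latent <- function() {
  lat <- default_latent_space(items13)
  ang <- 2 * pi * (seq_len(13) - 1) / 13
  coords <- cbind(dim1 = cos(ang), dim2 = sin(ang))
  rownames(coords) <- items13$item_id
  lat$coords <- coords
  lat
}

# a well-formed minimal session: full-set first trial on a circle, then two
# 3-item subset trials
make_valid_session <- function() {
  ang <- 2 * pi * (seq_len(13) - 1) / 13
  t1 <- tibble::tibble(trial_index = 1L, item_id = items13$item_id,
                       x = 0.9 * cos(ang), y = 0.9 * sin(ang))
  t2 <- tibble::tibble(trial_index = 2L,
                       item_id = c("hand", "normal_body", "empty_glove"),
                       x = c(0, 0.5, -0.5), y = c(0, 0.3, 0.2))
  t3 <- tibble::tibble(trial_index = 3L,
                       item_id = c("cold_hands", "dead_hand", "swelling"),
                       x = c(0.1, -0.2, 0.4), y = c(-0.1, 0.6, -0.5))
  arrangement_session("P01", "sync", dplyr::bind_rows(t1, t2, t3))
}

# n points drawn in the plane whose pairwise distances embed exactly
make_planted_record <- function(n = 13, seed = 42, noise_sd = 0) {
  set.seed(seed)
  X <- matrix(runif(n * 2), n, 2)
  rownames(X) <- if (n == 13) items13$item_id else paste0("i", seq_len(n))
  D <- as.matrix(dist(X))
  if (noise_sd > 0) {
    E <- matrix(rnorm(n * n, 0, noise_sd), n, n)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    D <- D * exp(E) # multiplicative noise keeps D positive
  }
  list(record = dissimilarity_record(D), X = X)
}

# interval-disparity stress-1 for a fixed 1-D configuration: the same
# regression the fitter uses, evaluated directly (independent arithmetic)
interval_stress_1d <- function(x, D) {
  d <- as.matrix(dist(x))
  ut <- upper.tri(D)
  dv <- d[ut]
  Dv <- D[ut]
  den <- sum((Dv - mean(Dv))^2)
  b <- if (den > 0) sum((Dv - mean(Dv)) * (dv - mean(dv))) / den else 0
  b <- max(b, 0)
  a <- mean(dv) - b * mean(Dv)
  dhat <- pmax(a + b * Dv, 0)
  sqrt(sum((dv - dhat)^2) / sum(dv^2))
}

# exhaustive 1-D grid oracle for 3 points (first point pinned at 0; stress
# is translation-invariant)
grid_oracle_1d_3pt <- function(D, step = 0.01, lim = 1) {
  g <- seq(-lim, lim, by = step)
  best <- Inf
  for (u in g) {
    for (v in g) {
      x <- c(0, u, v)
      if (u == 0 || v == 0 || u == v) next # degenerate layouts
      s <- interval_stress_1d(x, D)
      if (s < best) best <- s
    }
  }
  best
}
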