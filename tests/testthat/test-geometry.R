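random_config <- function(n = 13, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(2 * n), n, 2)
  rownames(X) <- if (n == 13) items13$item_id else paste0("i", seq_len(n))
  colnames(X) <- c("dim1", "dim2")
  X
}

test_that("rotation is an isometry with the expected identities", {
  X <- random_config(seed = 2)
  expect_equal(rotate_config(X, 0), X)
  expect_equal(rotate_config(X, 360), X, tolerance = 1e-12)
  Xr <- rotate_config(X, 137)
  expect_lt(max(abs(dist(Xr) - dist(X))), 1e-10)
  expect_equal(rotate_config(rotate_config(X, 90), 270), X,
               tolerance = 1e-12)
  expect_error(rotate_config(X[, 1, drop = FALSE], 10), "2-D")
})

test_that("baseline anchoring finds the grid-optimal angle", {
  X <- random_config(seed = 3)
  res <- baseline_anchor_rotation(X, "empty_glove")

  # brute force over all 72 grid angles
  objective <- function(ang) {
    Xr <- rotate_config(X, ang)
    normalize_dimension(Xr, 1)["empty_glove"] +
      normalize_dimension(Xr, 2)["empty_glove"]
  }
  all_angles <- seq(0, 355, by = 5)
  objs <- vapply(all_angles, objective, numeric(1))
  expect_equal(res$angle, all_angles[which.min(objs)])

  # anchored config is unchanged by re-anchoring (0 is already optimal)
  res2 <- baseline_anchor_rotation(res$config, "empty_glove")
  expect_equal(res2$angle, 0)

  # pre-rotating by +90 degrees is undone by 270
  res3 <- baseline_anchor_rotation(rotate_config(res$config, 90),
                                   "empty_glove")
  expect_equal(res3$angle, 270)

  expect_error(baseline_anchor_rotation(X, "phantom"), "absent")
})

test_that("dimension normalization is exact min-max", {
  X <- cbind(dim1 = c(0, 2, 10), dim2 = c(1, 1, 2))
  rownames(X) <- c("a", "b", "c")
  sc <- normalize_dimension(X, 1)
  expect_equal(unname(sc), c(0, 0.2, 1))
  expect_equal(unname(sc["a"]), 0) # minimum item scores 0
  expect_equal(unname(sc["c"]), 1) # maximum item scores 1
  expect_error(normalize_dimension(cbind(c(1, 1, 1)), 1), "degenerate")
})

test_that("procrustes recovers an exact similarity transform", {
  X <- random_config(seed = 4)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 1.9 * X %*% R + matrix(rep(c(5, -3), each = 13), 13)
  rownames(Y) <- rownames(X)
  al <- procrustes_align(Y, X)
  expect_lt(al$residual_ss, 1e-20)
  expect_equal(al$congruence, 1, tolerance = 1e-12)
  expect_equal(al$coord_correlation, 1, tolerance = 1e-12)
  expect_equal(al$alienation, 0, tolerance = 1e-6)
  expect_lt(max(al$landmarks$distance), 1e-10)
})

test_that("reflection handling obeys the allow_reflection switch", {
  X <- random_config(seed = 5)
  Y <- X %*% diag(c(-1, 1)) # mirrored copy
  rownames(Y) <- rownames(X)
  al_free <- procrustes_align(Y, X, allow_reflection = TRUE)
  expect_lt(al_free$residual_ss, 1e-20)
  al_rot <- procrustes_align(Y, X, allow_reflection = FALSE)
  expect_gt(al_rot$residual_ss, 0.01)
  expect_equal(det(al_rot$rotation), 1, tolerance = 1e-12)
})

test_that("procrustes residual matches the vegan oracle on noisy pairs", {
  X <- random_config(seed = 6)
  set.seed(7)
  Y <- X + matrix(rnorm(26, 0, 0.08), 13, 2)
  rownames(Y) <- rownames(X)
  ours <- procrustes_align(Y, X)
  ref <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(ours$residual_ss, ref$ss, tolerance = 1e-6)
  # protest reports the same coordinate correlation structure
  pt <- vegan::protest(X, Y, permutations = 99)
  expect_equal(sqrt(1 - ours$residual_ss), pt$t0, tolerance = 1e-6)
})

test_that("similarity coefficients satisfy their algebraic identities", {
  X <- random_config(seed = 8)
  co <- similarity_coefficients(X, X)
  expect_equal(unname(co["congruence"]), 1)
  expect_equal(unname(co["coord_correlation"]), 1)
  expect_equal(unname(co["alienation"]), 0)

  # a = sqrt(1 - c^2) across random pairs
  for (s in 1:5) {
    set.seed(s)
    Y <- X + matrix(rnorm(26, 0, 0.3), 13, 2)
    rownames(Y) <- rownames(X)
    co <- similarity_coefficients(Y, X)
    expect_equal(unname(co["alienation"]),
                 sqrt(1 - unname(co["congruence"])^2), tolerance = 1e-9)
  }

  # closed-form values at reported congruence levels
  expect_equal(round(sqrt(1 - 0.964^2), 3), 0.266)
  expect_equal(round(sqrt(1 - 0.984^2), 3), 0.178)

  expect_error(similarity_coefficients(X * 0, X), "degenerate")
})

test_that("alignment residual is invariant to source pre-transforms", {
  X <- random_config(seed = 9)
  set.seed(10)
  Y <- X + matrix(rnorm(26, 0, 0.1), 13, 2)
  rownames(Y) <- rownames(X)
  base <- procrustes_align(Y, X)$residual_ss
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y2 <- 0.31 * Y %*% R + matrix(rep(c(-2, 7), each = 13), 13)
  rownames(Y2) <- rownames(Y)
  expect_equal(procrustes_align(Y2, X)$residual_ss, base,
               tolerance = 1e-8)
})

test_that("self-alignment is the identity map", {
  X <- random_config(seed = 11)
  al <- procrustes_align(X, X)
  expect_equal(al$scale, 1, tolerance = 1e-12)
  expect_equal(al$rotation, diag(2), tolerance = 1e-12)
  expect_lt(al$residual_ss, 1e-20)
})

test_that("the null benchmark is stable across seeds and shifts with n", {
  null_a <- procrustes_null_benchmark(13, 2, n_sims = 150, seed = 1)
  null_b <- procrustes_null_benchmark(13, 2, n_sims = 150, seed = 2)
  expect_equal(nrow(null_a), 150)
  q_a <- stats::quantile(null_a$congruence, 0.95, names = FALSE)
  q_b <- stats::quantile(null_b$congruence, 0.95, names = FALSE)
  expect_lt(abs(q_a - q_b), 0.05)

  # fewer landmarks produce higher chance congruence
  null_small <- procrustes_null_benchmark(5, 2, n_sims = 150, seed = 1)
  expect_gt(median(null_small$congruence), median(null_a$congruence))

  expect_warning(procrustes_null_benchmark(5, 2, n_sims = 5, seed = 1),
                 "unstable")
})

test_that("observed coefficients are compared against the null extremes", {
  X <- random_config(seed = 12)
  set.seed(13)
  Y <- X + matrix(rnorm(26, 0, 0.03), 13, 2)
  rownames(Y) <- rownames(X)
  al <- procrustes_align(Y, X)
  null <- procrustes_null_benchmark(13, 2, n_sims = 100, seed = 3)
  bm <- benchmark_alignment(al, null)
  expect_true(bm$exceeds_benchmark)
  expect_gt(bm$congruence, bm$null_c_max)
  expect_lt(bm$alienation, bm$null_a_min)
})

test_that("landmark displacements rank moved items first", {
  X <- random_config(seed = 14)
  expect_equal(max(landmark_displacements(X, X)$distance), 0)

  Y <- X
  Y["hand", ] <- Y["hand", ] + c(0.4, 0)
  ld <- landmark_displacements(Y, X)
  expect_equal(ld$item_id[1], "hand")
  expect_true(all(diff(ld$distance) <= 0)) # sorted descending

  # a planted shift of the experimental item survives alignment noise
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    A <- X + matrix(rnorm(26, 0, 0.02), 13, 2)
    B <- X + matrix(rnorm(26, 0, 0.02), 13, 2)
    B["hand", ] <- B["hand", ] + c(0.3, 0.2)
    rownames(A) <- rownames(B) <- rownames(X)
    al <- procrustes_align(B, A)
    ld <- landmark_displacements(al$aligned, al$target)
    hand_d <- ld$distance[ld$item_id == "hand"]
    if (hand_d > median(ld$distance)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
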