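test_that("perfectly embeddable distances are recovered with zero stress", {
  set.seed(3)
  X <- matrix(runif(8), 4, 2)
  rownames(X) <- paste0("i", 1:4)
  rec <- dissimilarity_record(as.matrix(dist(X)), normalize = FALSE)
  fit <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 20,
                                          seed = 1))
  expect_lte(fit$stress1, 1e-6)
  expect_equal(colMeans(fit$X), c(dim1 = 0, dim2 = 0), tolerance = 1e-9)
})

test_that("an equilateral triple in 1-D matches the grid-search oracle", {
  D <- matrix(1, 3, 3) - diag(3)
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  rec <- dissimilarity_record(D, normalize = FALSE)
  fit <- fit_interval_mds(rec, fit_params(n_dims = 1, n_starts = 100,
                                          seed = 2))
  expect_gt(fit$stress1, 0)
  oracle <- grid_oracle_1d_3pt(rec$D, step = 0.01)
  expect_equal(fit$stress1, oracle, tolerance = 1e-3)
  expect_lte(fit$stress1, oracle + 1e-9) # never worse than the grid
})

test_that("a scalene 1-D triple also matches the grid oracle", {
  D <- matrix(c(0, 1, 2.4, 1, 0, 1.1, 2.4, 1.1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  rec <- dissimilarity_record(D, normalize = FALSE)
  fit <- fit_interval_mds(rec, fit_params(n_dims = 1, n_starts = 100,
                                          seed = 4))
  oracle <- grid_oracle_1d_3pt(rec$D, step = 0.01)
  expect_equal(fit$stress1, oracle, tolerance = 1e-3)
})

test_that("more random starts never yield a worse best stress", {
  rec <- make_planted_record(13, seed = 5, noise_sd = 0.3)$record
  f_small <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 5,
                                              seed = 99))
  f_big <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 50,
                                            seed = 99))
  expect_lte(f_big$stress1, f_small$stress1)
})

test_that("majorization stress is non-increasing within a start", {
  for (sd in c(0.1, 0.4)) {
    rec <- make_planted_record(13, seed = 6, noise_sd = sd)$record
    fit <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 5,
                                            seed = 3))
    expect_true(all(diff(fit$stress_trace) <= 1e-10))
  }
})

test_that("stress1 matches direct arithmetic on a hand-built case", {
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1))
  disp <- matrix(c(0, 1.2, 0.8, 1.2, 0, 1.5, 0.8, 1.5, 0), 3, 3)
  d <- c(1, 1, sqrt(2)) # ab, ac, bc
  dh <- c(1.2, 0.8, 1.5)
  by_hand <- sqrt(sum((d - dh)^2) / sum(d^2))
  expect_equal(stress1(X, disp), by_hand, tolerance = 1e-12)

  # perfect fit and rotation invariance
  expect_equal(stress1(X, as.matrix(dist(X))), 0)
  Xr <- rotate_config(X, 73)
  expect_lt(stress1(Xr, as.matrix(dist(X))), 1e-10)

  expect_error(stress1(X * 0, disp), "degenerate")
})

test_that("stress-per-point localizes misfit and conserves 100%", {
  pl <- make_planted_record(13, seed = 8)
  fit <- fit_interval_mds(pl$record, fit_params(n_dims = 2, n_starts = 20,
                                                seed = 5))
  # perfect fit: uniform convention
  expect_equal(unname(fit$spp), rep(100 / 13, 13), tolerance = 1e-6)

  # displace one item's dissimilarities: that item carries the most stress
  D <- pl$record$D
  D["hand", ] <- D["hand", ] * 1.6
  D[, "hand"] <- t(D["hand", , drop = FALSE])
  diag(D) <- 0
  rec2 <- dissimilarity_record(D)
  fit2 <- fit_interval_mds(rec2, fit_params(n_dims = 2, n_starts = 20,
                                            seed = 5))
  expect_equal(sum(fit2$spp), 100, tolerance = 1e-6)
  expect_equal(names(which.max(fit2$spp)), "hand")

  rec3 <- make_planted_record(13, seed = 9, noise_sd = 0.2)$record
  fit3 <- fit_interval_mds(rec3, fit_params(n_dims = 2, n_starts = 20,
                                            seed = 5))
  expect_equal(sum(fit3$spp), 100, tolerance = 1e-6)
})

test_that("fits are invariant to a positive rescaling of dissimilarities", {
  rec <- make_planted_record(13, seed = 10, noise_sd = 0.2)$record
  rec_scaled <- dissimilarity_record(3.7 * rec$D, rec$W, normalize = FALSE)
  f1 <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 30,
                                         seed = 21))
  f2 <- fit_interval_mds(rec_scaled, fit_params(n_dims = 2, n_starts = 30,
                                                seed = 21))
  expect_equal(f1$stress1, f2$stress1, tolerance = 1e-8)
  al <- procrustes_align(f2, f1)
  expect_lt(al$alienation, 1e-6)
})

test_that("planted noisy 13-item spaces are recovered accurately", {
  pl <- make_planted_record(13, seed = 12, noise_sd = 0.05)
  fit <- fit_interval_mds(pl$record, fit_params(n_dims = 2, n_starts = 50,
                                                seed = 31))
  expect_lt(fit$stress1, 0.1)
  al <- procrustes_align(fit, pl$X)
  expect_gt(al$coord_correlation, 0.98)
})

test_that("familiarity weights follow the normalized product rule", {
  items <- default_item_manifest()
  items$familiarity[items$role == "common"] <-
    c(5, 1, 3, 4, 2, 5, 3, 2, 4, 1)
  w <- familiarity_pair_weights(items)
  expect_true(isSymmetric(w))
  expect_equal(unname(diag(w)), rep(0, 13))
  expect_equal(w["hand", "normal_body"], 1) # both familiarity 5
  expect_equal(w["hand", "dead_hand"], 5 * 1 / 25) # 5 against 1
  expect_true(all(w[upper.tri(w)] > 0 & w[upper.tri(w)] <= 1))

  bad <- items
  bad$familiarity[4] <- 0.5
  expect_error(familiarity_pair_weights(bad), "\\[1, 5\\]")
})

test_that("familiarity weighting changes the fit but keeps it valid", {
  items <- default_item_manifest()
  items$familiarity[items$role == "common"] <-
    c(5, 1, 3, 4, 2, 5, 3, 2, 4, 1)
  rec <- make_planted_record(13, seed = 14, noise_sd = 0.3)$record
  f_u <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 20,
                                          seed = 1))
  f_w <- fit_interval_mds(rec, fit_params(n_dims = 2, n_starts = 20,
                                          seed = 1,
                                          weight_mode = "familiarity"),
                          items = items)
  expect_false(isTRUE(all.equal(f_u$X, f_w$X)))
  expect_true(is.finite(f_w$stress1))
})

test_that("strong planted structure saturates the permutation benchmark", {
  rec <- make_planted_record(13, seed = 15, noise_sd = 0.02)$record
  rep1 <- mds_permutation_test(rec, fit_params(n_dims = 2, n_starts = 20,
                                               seed = 8),
                               n_perm = 50, perm_starts = 5)
  expect_equal(rep1$p_value, 1 / 51)
  expect_true(rep1$passes)
  # deterministic given the seed
  rep2 <- mds_permutation_test(rec, fit_params(n_dims = 2, n_starts = 20,
                                               seed = 8),
                               n_perm = 50, perm_starts = 5)
  expect_identical(rep1$null_stresses, rep2$null_stresses)
})

test_that("degenerate permutation requests hit the error/warning paths", {
  rec <- make_planted_record(6, seed = 16)$record
  expect_error(mds_permutation_test(rec, fit_params(n_dims = 2,
                                                    n_starts = 5, seed = 1),
                                    n_perm = 0), "n_perm")
  expect_warning(mds_permutation_test(rec, fit_params(n_dims = 2,
                                                      n_starts = 5,
                                                      seed = 1),
                                      n_perm = 5, perm_starts = 2),
                 "unstable")
})

test_that("fit rejects impossible requests", {
  rec <- make_planted_record(4, seed = 17)$record
  expect_error(fit_interval_mds(rec, fit_params(n_dims = 4, n_starts = 2)),
               "smaller than the item count")
  bad <- rec
  bad$D[1, 2] <- bad$D[2, 1] <- Inf
  expect_error(fit_interval_mds(bad, fit_params(n_dims = 2, n_starts = 2)),
               "finite")
})
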