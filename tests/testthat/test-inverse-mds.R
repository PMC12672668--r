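test_that("trial distances are plain Euclidean with missing absent pairs", {
  tr <- tibble::tibble(item_id = c("hand", "normal_body", "empty_glove"),
                       x = c(0, 1, 0), y = c(0, 0, 1))
  d <- trial_distance_matrix(tr, items13$item_id)
  expect_equal(d["hand", "normal_body"], 1)
  expect_equal(d["hand", "empty_glove"], 1)
  expect_equal(d["normal_body", "empty_glove"], sqrt(2))
  ut <- upper.tri(d)
  expect_equal(sum(!is.na(d[ut])), 3)
  expect_equal(sum(is.na(d[ut])), 75)

  full <- session_trial(make_valid_session(), 1)
  dfull <- trial_distance_matrix(full, items13$item_id)
  expect_equal(sum(!is.na(dfull[upper.tri(dfull)])), choose(13, 2))
})

test_that("evidence is squared relative distance, 1 at the farthest pair", {
  tr <- tibble::tibble(item_id = c("hand", "normal_body", "empty_glove"),
                       x = c(0, 2, 1), y = c(0, 0, 0))
  w <- trial_evidence(tr, items13$item_id)
  expect_equal(w["hand", "normal_body"], 1)    # the trial's farthest pair
  expect_equal(w["hand", "empty_glove"], 0.25) # half the max distance
  expect_true(is.na(w["hand", "dead_hand"]))   # absent pair

  coincident <- tibble::tibble(item_id = c("hand", "normal_body",
                                           "empty_glove"),
                               x = c(0.2, 0.2, 0.2), y = c(0.1, 0.1, 0.1))
  expect_error(trial_evidence(coincident, items13$item_id), "degenerate")
})

test_that("a single full-set trial yields its own distances at unit RMS", {
  s <- make_valid_session()
  s1 <- arrangement_session("P01", "sync",
                            s$trials[s$trials$trial_index == 1, ])
  rec <- estimate_rdm(s1, items13)
  d <- trial_distance_matrix(session_trial(s1, 1), items13$item_id)
  ut <- upper.tri(d)
  expect_equal(sqrt(mean(rec$D[ut]^2)), 1, tolerance = 1e-12)
  expect_equal(stats::cor(rec$D[ut], d[ut]), 1, tolerance = 1e-12)
  # proportionality, not just correlation
  expect_lt(max(abs(rec$D[ut] / d[ut] - mean(rec$D[ut] / d[ut]))), 1e-9)
})

test_that("repeating an identical trial doubles evidence, not dissimilarity", {
  s <- make_valid_session()
  t1 <- s$trials[s$trials$trial_index == 1, ]
  t1b <- t1
  t1b$trial_index <- 2L
  s2 <- arrangement_session("P01", "sync", dplyr::bind_rows(t1, t1b))
  s1 <- arrangement_session("P01", "sync", t1)
  r1 <- estimate_rdm(s1, items13)
  r2 <- estimate_rdm(s2, items13)
  expect_equal(r2$D, r1$D, tolerance = 1e-9)
  expect_equal(r2$W, 2 * r1$W, tolerance = 1e-12)
})

test_that("noiseless trials at different zooms recover planted distances", {
  lat <- default_latent_space(items13)
  td <- as.matrix(dist(lat$coords))
  ut <- upper.tri(td)
  set.seed(7)
  s <- simulate_session(lat, "sync", "P01", noise_model(0, 0.4))
  rec <- estimate_rdm(s, items13)
  expect_gte(stats::cor(rec$D[ut], td[ut]), 1 - 1e-9)
})

test_that("the estimate is invariant to a global coordinate rescaling", {
  set.seed(11)
  s <- simulate_session(default_latent_space(items13), "sync", "P01",
                        noise_model(0.05, 0.1))
  s_scaled <- s
  s_scaled$trials$x <- 0.37 * s$trials$x
  s_scaled$trials$y <- 0.37 * s$trials$y
  r1 <- estimate_rdm(s, items13)
  r2 <- estimate_rdm(s_scaled, items13)
  expect_lt(max(abs(r1$D - r2$D)), 1e-10)
})

test_that("evidence accumulates monotonically as trials are added", {
  set.seed(13)
  s <- simulate_session(default_latent_space(items13), "sync", "P01",
                        noise_model(0.08, 0.1))
  n_tr <- max(s$trials$trial_index)
  W_prev <- NULL
  for (k in 2:n_tr) {
    sk <- arrangement_session("P01", "sync",
                              s$trials[s$trials$trial_index <= k, ])
    W <- estimate_rdm(sk, items13)$W
    if (!is.null(W_prev)) expect_true(all(W - W_prev >= -1e-12))
    W_prev <- W
  }
})

test_that("subset selection targets the only under-determined pair", {
  ids <- items13$item_id
  n <- length(ids)
  W <- matrix(0.5, n, n, dimnames = list(ids, ids))
  diag(W) <- 0
  W["hand", "swelling"] <- W["swelling", "hand"] <- 0.1
  rec <- structure(list(item_ids = ids, D = NULL, W = W,
                        n_trials_used = 3L, converged = TRUE),
                   class = "dissimilarity_record")
  sub <- select_next_subset(rec)
  expect_true(all(c("hand", "swelling") %in% sub))
  expect_gte(length(sub), 3)
})

test_that("with no evidence at all, the full set is selected", {
  ids <- items13$item_id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  rec <- structure(list(item_ids = ids, D = NULL, W = W,
                        n_trials_used = 0L, converged = TRUE),
                   class = "dissimilarity_record")
  expect_setequal(select_next_subset(rec), ids)
})

test_that("saturated evidence yields an empty selection", {
  ids <- items13$item_id
  W <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  diag(W) <- 0
  rec <- structure(list(item_ids = ids, D = NULL, W = W,
                        n_trials_used = 5L, converged = TRUE),
                   class = "dissimilarity_record")
  expect_length(select_next_subset(rec), 0)
})

test_that("greedy selection matches exhaustive search on a 4-item table", {
  ids <- c("a", "b", "c", "d")
  # deficit structure: (a,b) worst, c tied to both, d nearly saturated
  W <- matrix(c(0.00, 0.05, 0.20, 0.45,
                0.05, 0.00, 0.25, 0.48,
                0.20, 0.25, 0.00, 0.40,
                0.45, 0.48, 0.40, 0.00), 4, 4,
              dimnames = list(ids, ids))
  rec <- structure(list(item_ids = ids, D = NULL, W = W,
                        n_trials_used = 2L, converged = TRUE),
                   class = "dissimilarity_record")
  params <- imds_params()
  sub <- select_next_subset(rec, params)

  # brute force: per-trial efficiency over all subsets of size >= 3
  U <- matrix(pmax(0, 1 - W / params$evidence_target), 4, 4,
              dimnames = dimnames(W))
  diag(U) <- 0
  best_eff <- -Inf
  best_sub <- NULL
  for (size in 3:4) {
    combs <- utils::combn(4, size, simplify = FALSE)
    for (S in combs) {
      eff <- sum(U[S, S][upper.tri(U[S, S])]) / length(S)
      if (eff > best_eff + 1e-12) {
        best_eff <- eff
        best_sub <- ids[S]
      }
    }
  }
  expect_setequal(sub, best_sub)
})

test_that("termination honors the evidence target and the trial cap", {
  ids <- items13$item_id
  n <- length(ids)
  mk <- function(min_w, trials) {
    W <- matrix(1, n, n, dimnames = list(ids, ids))
    diag(W) <- 0
    W[1, 2] <- W[2, 1] <- min_w
    structure(list(item_ids = ids, D = NULL, W = W,
                   n_trials_used = as.integer(trials), converged = TRUE),
              class = "dissimilarity_record")
  }
  t1 <- should_terminate(mk(0.51, 3))
  expect_true(t1$stop)
  expect_equal(t1$reason, "evidence")
  t2 <- should_terminate(mk(0.10, 12))
  expect_true(t2$stop)
  expect_equal(t2$reason, "max_trials")
  t3 <- should_terminate(mk(0.10, 5))
  expect_false(t3$stop)
})

test_that("tidy() flattens a record to one row per pair", {
  rec <- make_planted_record(5)$record
  td <- tidy(rec)
  expect_equal(nrow(td), choose(5, 2))
  expect_named(td, c("item_a", "item_b", "dissimilarity", "evidence"))
})
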