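#' Latent bodily space for synthetic participants
#'
#' A latent space holds the ground-truth 2-D coordinates every simulated
#' participant shares, plus optional per-condition displacements of the
#' experimental item (only the experimental item moves between conditions
#' by default, mirroring how an illusion manipulation should act).
#'
#' @param items Item manifest.
#' @param coords n_items x 2 matrix of true coordinates (rownames must be
#'   the item ids); dimension 1 is the embodiment axis by construction.
#' @param condition_shifts Named list mapping condition labels to length-2
#'   displacement vectors added to the experimental item's coordinates.
#' @return Object of class `latent_space`.
#' @export
latent_space <- function(items, coords, condition_shifts = list()) {
  items <- item_manifest(items)
  coords <- as.matrix(coords)
  if (!all(items$item_id %in% rownames(coords))) {
    abort("coords must have one named row per item")
  }
  coords <- coords[items$item_id, , drop = FALSE]
  if (any(!is.finite(coords))) abort("latent coordinates must be finite")
  structure(list(items = items, coords = coords,
                 condition_shifts = condition_shifts),
            class = "latent_space")
}

#' Default latent bodily space
#'
#' Ground-truth coordinates emulating the empirically reported structure of
#' the bodily space: an embodiment axis (dimension 1) anchored by the empty
#' glove at the bottom and normal body feelings near the top, a stimulation
#' axis (dimension 2), and three groupings (de-embodiment experiences low
#' on both axes, artificial-stimulation experiences high on stimulation,
#' normal bodily feelings high on embodiment). The experimental hand item
#' sits at moderate embodiment and low stimulation, matching reported
#' ownership/stimulation scores for the illusion condition.
#'
#' @param items Item manifest (default [default_item_manifest()]).
#' @param condition_shifts Passed to [latent_space()].
#' @return A `latent_space`.
#' @export
default_latent_space <- function(items = default_item_manifest(),
                                 condition_shifts = list()) {
  coords <- rbind(
    hand          = c(0.60, 0.25),
    normal_body   = c(0.88, 0.45),
    empty_glove   = c(0.02, 0.35),
    cold_hands    = c(0.20, 0.55),
    dead_hand     = c(0.10, 0.15),
    anesthesia    = c(0.15, 0.08),
    inebriation   = c(0.28, 0.22),
    muscle_cramp  = c(0.40, 0.92),
    pinched_nerve = c(0.33, 0.83),
    workout       = c(0.52, 0.80),
    swelling      = c(0.45, 0.72),
    crossed_legs  = c(0.72, 0.52),
    relaxation    = c(0.92, 0.38)
  )
  colnames(coords) <- c("dim1", "dim2")
  latent_space(items, coords, condition_shifts)
}

#' Displacement vector toward another item
#'
#' Convenience for planting condition effects: the vector that moves the
#' experimental item `magnitude` units along the straight line toward a
#' target item (e.g. toward the empty glove to weaken ownership).
#'
#' @param latent A `latent_space`.
#' @param target_item Item id to move toward.
#' @param magnitude Displacement length in latent units.
#' @return Length-2 numeric displacement vector.
#' @export
shift_toward <- function(latent, target_item, magnitude) {
  exp_id <- latent$items$item_id[latent$items$role == "experimental"]
  v <- latent$coords[target_item, ] - latent$coords[exp_id, ]
  magnitude * v / sqrt(sum(v^2))
}

condition_coords <- function(latent, condition) {
  coords <- latent$coords
  shift <- latent$condition_shifts[[condition]]
  if (!is.null(shift)) {
    exp_id <- latent$items$item_id[latent$items$role == "experimental"]
    coords[exp_id, ] <- coords[exp_id, ] + shift
  }
  coords
}

#' Noise model for simulated arrangements
#'
#' @param placement_sd Isotropic Gaussian placement noise, in arena units
#'   (>= 0).
#' @param zoom_jitter_sd SD of the per-trial log-normal zoom factor (>= 0);
#'   emulates participants using different overall spreads across trials.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(placement_sd = 0.05, zoom_jitter_sd = 0.1) {
  stopifnot(placement_sd >= 0, zoom_jitter_sd >= 0)
  structure(list(placement_sd = placement_sd,
                 zoom_jitter_sd = zoom_jitter_sd),
            class = "noise_model")
}

#' Simulate one arrangement trial
#'
#' Takes the true coordinates of the requested subset, applies a random
#' rotation and (with probability 1/2) a reflection, a log-normal per-trial
#' zoom, adds isotropic Gaussian placement noise, and rescales the trial to
#' fit the unit-disk arena (maximum radius 0.95). Consumes the current R
#' RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param coords True coordinate matrix (rownames = item ids).
#' @param subset Character vector of item ids to present (size >= 3).
#' @param noise A [noise_model()].
#' @return Tibble with `item_id`, `x`, `y`.
#' @export
simulate_arrangement <- function(coords, subset, noise = noise_model()) {
  if (length(subset) < 3) abort("arrangement subsets need at least 3 items")
  X <- coords[subset, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (runif(1) < 0.5) R[, 2] <- -R[, 2]
  zoom <- exp(rnorm(1, 0, noise$zoom_jitter_sd))
  X <- zoom * X %*% R
  X <- X + matrix(rnorm(length(X), 0, noise$placement_sd), nrow(X), 2)
  X <- sweep(X, 2, colMeans(X))
  rmax <- max(sqrt(rowSums(X^2)))
  if (rmax > 0) X <- X * (0.95 / rmax)
  tibble::new_tibble(list(item_id = subset, x = unname(X[, 1]),
                          y = unname(X[, 2])), nrow = length(subset))
}

#' Simulate a full adaptive arrangement session
#'
#' Runs the closed loop a real participant would produce: a full-set first
#' trial, then adaptively selected subsets (see [select_next_subset()])
#' until the evidence-based termination rule fires or the trial cap is
#' reached.
#'
#' @param latent A `latent_space`.
#' @param condition Condition label (selects a planted shift when one is
#'   registered in the latent space).
#' @param participant_id Participant identifier.
#' @param noise A [noise_model()].
#' @param params An [imds_params()].
#' @param seed Optional integer seed.
#' @return An [arrangement_session()] with attribute `"termination"`
#'   (`"evidence"` or `"max_trials"`).
#' @export
simulate_session <- function(latent, condition = "baseline",
                             participant_id = "sim", noise = noise_model(),
                             params = imds_params(), seed = NULL) {
  coords <- condition_coords(latent, condition)
  items <- latent$items
  with_optional_seed(seed, {
    trials <- list()
    t1 <- simulate_arrangement(coords, items$item_id, noise)
    t1$trial_index <- 1L
    trials[[1]] <- t1
    # the adaptive controller only needs accumulated evidence, so W is
    # tracked incrementally; the full dissimilarity estimate is not required
    # during the loop
    W <- trial_evidence(t1, items$item_id)
    W[is.na(W)] <- 0
    reason <- "max_trials"
    repeat {
      state <- structure(list(item_ids = items$item_id, D = NULL, W = W,
                              n_trials_used = length(trials),
                              converged = TRUE),
                         class = "dissimilarity_record")
      term <- should_terminate(state, params)
      if (term$stop) {
        reason <- term$reason
        break
      }
      subset <- select_next_subset(state, params)
      if (length(subset) == 0) {
        reason <- "evidence"
        break
      }
      t_new <- simulate_arrangement(coords, subset, noise)
      t_new$trial_index <- length(trials) + 1L
      trials[[length(trials) + 1]] <- t_new
      w_new <- trial_evidence(t_new, items$item_id)
      w_new[is.na(w_new)] <- 0
      W <- W + w_new
    }
    session <- arrangement_session(participant_id, condition,
                                   dplyr::bind_rows(trials))
    attr(session, "termination") <- reason
    session
  })
}

#' Simulate a cohort of participants across conditions
#'
#' Generates, per participant x condition, a full adaptive session, a
#' questionnaire mean (an affine map of the latent ownership score to the
#' -3..3 agreement scale plus Gaussian response noise, clipped to the scale
#' bounds), and per-item familiarity ratings drawn from a fixed discrete
#' distribution on 1..5 (common items) with the experimental and baseline
#' items pinned at 5. Fully reproducible from the seed; the ground truth is
#' retained for recovery scoring.
#'
#' @param latent A `latent_space` (register condition shifts there).
#' @param n_participants Number of participants (>= 2).
#' @param conditions Character vector of condition labels.
#' @param noise A [noise_model()].
#' @param questionnaire_sd SD of questionnaire response noise in scale
#'   points (default 0.8).
#' @param seed Integer seed.
#' @return Object of class `cohort`: list with `sessions` (list of
#'   sessions), `questionnaire` (tibble `participant_id`, `condition`,
#'   `mean_rating`), `familiarity` (tibble `participant_id`, `item_id`,
#'   `familiarity`), `items`, `truth` (per-condition true coordinates),
#'   `seed`.
#' @export
simulate_cohort <- function(latent, n_participants, conditions,
                            noise = noise_model(), questionnaire_sd = 0.8,
                            seed = 1L) {
  if (n_participants < 2) abort("need at least 2 participants")
  items <- latent$items
  exp_id <- items$item_id[items$role == "experimental"]
  truth <- lapply(setNames(conditions, conditions), function(cn) {
    condition_coords(latent, cn)
  })
  with_optional_seed(seed, {
    sessions <- list()
    quest <- list()
    famil <- list()
    for (p in seq_len(n_participants)) {
      pid <- sprintf("P%02d", p)
      fam <- ifelse(items$role == "common",
                    sample(1:5, nrow(items), replace = TRUE,
                           prob = c(0.05, 0.10, 0.20, 0.30, 0.35)),
                    5L)
      famil[[length(famil) + 1]] <-
        tibble::tibble(participant_id = pid, item_id = items$item_id,
                       familiarity = as.numeric(fam))
      for (cn in conditions) {
        sessions[[paste(pid, cn, sep = ".")]] <-
          simulate_session(latent, cn, pid, noise)
        # questionnaire: latent ownership mapped to the -3..3 scale
        os_true <- normalize_dimension(truth[[cn]], 1)[exp_id]
        m <- -3 + 6 * os_true + rnorm(1, 0, questionnaire_sd)
        quest[[length(quest) + 1]] <-
          tibble::tibble(participant_id = pid, condition = cn,
                         mean_rating = min(3, max(-3, m)))
      }
    }
    structure(list(sessions = sessions,
                   questionnaire = dplyr::bind_rows(quest),
                   familiarity = dplyr::bind_rows(famil),
                   items = items, truth = truth, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", dplyr::n_distinct(x$questionnaire$participant_id),
      "participants x", dplyr::n_distinct(x$questionnaire$condition),
      "condition(s),", length(x$sessions), "sessions\n")
  invisible(x)
}
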