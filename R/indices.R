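#' Identify the embodiment dimension of a rotated configuration
#'
#' By convention the embodiment dimension is the one on which the
#' no-ownership baseline (empty glove) attains its minimal normalized
#' coordinate after baseline-anchored rotation; an explicit dimension index
#' overrides the convention.
#'
#' @param config Configuration (matrix, `mds_config` or tidy tibble).
#' @param items Item manifest (locates the baseline item).
#' @param dim Optional explicit dimension index.
#' @return Integer dimension index.
#' @export
embodiment_dimension <- function(config, items, dim = NULL) {
  if (!is.null(dim)) return(as.integer(dim))
  items <- item_manifest(items)
  X <- config_matrix(config)
  glove <- items$item_id[items$role == "baseline_none"]
  sc <- vapply(seq_len(ncol(X)), function(k) {
    normalize_dimension(X, k)[glove]
  }, numeric(1))
  which.min(sc)
}

#' MDS ownership score of an item
#'
#' The min-max-normalized coordinate of an item on the embodiment
#' dimension of a (rotated) configuration; 0 at the dimension minimum
#' (typically anchored at the empty-glove baseline), 1 at the maximum.
#' With `dim` pointing at a stimulation dimension the same normalization
#' yields a stimulation score.
#'
#' @param config Configuration (rotated so dimensions are interpretable).
#' @param dim Dimension index carrying the embodiment interpretation.
#' @param item_id Item whose score is requested.
#' @return Score in \[0, 1\].
#' @export
ownership_score <- function(config, dim, item_id) {
  sc <- normalize_dimension(config, dim)
  if (!item_id %in% names(sc)) {
    abort(paste0("item '", item_id, "' absent from configuration"))
  }
  unname(sc[item_id])
}

#' Baseline-anchored distance indices of illusion strength
#'
#' Euclidean distances between the experimental item and the two canonical
#' baselines in an aligned configuration (Procrustes normalized units).
#' For multisensory (RHI-type) conditions the distance to the full-ownership
#' baseline is the embodiment index (inversely related to illusion
#' strength) and the distance to the no-ownership baseline is the
#' de-objectification index (proportional to illusion strength). For
#' suggestion-type conditions the same two distances are read in the
#' opposite direction: distance to the full-ownership baseline measures
#' de-embodiment and distance to the no-ownership baseline (inversely)
#' measures objectification.
#'
#' @param config Aligned configuration (matrix, `mds_config` or tidy
#'   tibble).
#' @param items Item manifest (locates the experimental and baseline
#'   items).
#' @param condition_type `"rhi"` (default) or `"suggestion"`; selects the
#'   index labels.
#' @return One-row tibble with the two named distance indices.
#' @export
distance_indices <- function(config, items,
                             condition_type = c("rhi", "suggestion")) {
  condition_type <- match.arg(condition_type)
  items <- item_manifest(items)
  X <- config_matrix(config)
  need <- c(experimental = items$item_id[items$role == "experimental"],
            baseline_full = items$item_id[items$role == "baseline_full"],
            baseline_none = items$item_id[items$role == "baseline_none"])
  missing_items <- setdiff(need, rownames(X))
  if (length(missing_items) > 0) {
    abort(paste0("configuration lacks required item(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  d_full <- sqrt(sum((X[need["experimental"], ] -
                        X[need["baseline_full"], ])^2))
  d_none <- sqrt(sum((X[need["experimental"], ] -
                        X[need["baseline_none"], ])^2))
  if (condition_type == "rhi") {
    tibble::tibble(embodiment_dist = d_full, deobjectification_dist = d_none)
  } else {
    tibble::tibble(deembodiment_dist = d_full, objectification_dist = d_none)
  }
}

#' Ownership-loss index
#'
#' Quantifies how much ownership a suggestion removed, from a normalized
#' ownership score. Without a baseline the maximum score 1 is the implicit
#' baseline and the loss is `1 - os`; with the full-ownership baseline's
#' own score `b` as the true baseline the loss is rescaled to
#' `(b - os) / b`.
#'
#' @param os Normalized ownership score in \[0, 1\].
#' @param baseline_os Optional baseline ownership score in (0, 1\].
#' @return Ownership-loss index.
#' @examples
#' ownership_loss(0.641)        # 0.359
#' ownership_loss(0.641, 0.846) # 0.242
#' @export
ownership_loss <- function(os, baseline_os = NULL) {
  if (os < 0 || os > 1) abort("ownership score must lie in [0, 1]")
  if (is.null(baseline_os)) return(1 - os)
  if (baseline_os <= 0 || baseline_os > 1) {
    abort("baseline ownership score must lie in (0, 1]")
  }
  (baseline_os - os) / baseline_os
}

#' Normalize a questionnaire mean to the unit interval
#'
#' Maps a mean agreement rating from a bounded response scale (default the
#' 7-point scale from -3 "strongly disagree" to 3 "strongly agree")
#' linearly to \[0, 1\], making questionnaire-based ownership estimates
#' comparable with MDS ownership scores.
#'
#' @param mean_rating Mean rating within the scale bounds.
#' @param scale_min,scale_max Scale endpoints (defaults -3 and 3).
#' @return Normalized score in \[0, 1\].
#' @examples
#' questionnaire_normalize(1.250)  # 0.708...
#' questionnaire_normalize(-1.361) # 0.273...
#' @export
questionnaire_normalize <- function(mean_rating, scale_min = -3,
                                    scale_max = 3) {
  if (scale_min >= scale_max) abort("scale_min must be below scale_max")
  if (any(mean_rating < scale_min | mean_rating > scale_max)) {
    abort("mean rating outside scale bounds")
  }
  (mean_rating - scale_min) / (scale_max - scale_min)
}

#' Full set of illusion indices for one rotated, aligned configuration
#'
#' Convenience wrapper computing the ownership score (embodiment
#' dimension), stimulation score (the other dimension, 2-D solutions),
#' baseline-anchored distance indices and ownership-loss variants in one
#' call.
#'
#' @param config Rotated, aligned 2-D configuration.
#' @param items Item manifest.
#' @param condition_type `"rhi"` or `"suggestion"` (see
#'   [distance_indices()]).
#' @param dim Optional override of the embodiment dimension.
#' @return One-row tibble with `os_mds`, `ss_mds` (NA for 1-D input),
#'   `baseline_full_os`, the two distance indices, `ownership_loss_max`
#'   and `ownership_loss_rescaled`.
#' @export
illusion_indices <- function(config, items,
                             condition_type = c("rhi", "suggestion"),
                             dim = NULL) {
  condition_type <- match.arg(condition_type)
  items <- item_manifest(items)
  X <- config_matrix(config)
  emb <- embodiment_dimension(X, items, dim)
  exp_id <- items$item_id[items$role == "experimental"]
  full_id <- items$item_id[items$role == "baseline_full"]
  os <- ownership_score(X, emb, exp_id)
  os_full <- ownership_score(X, emb, full_id)
  ss <- if (ncol(X) >= 2) {
    stim <- setdiff(seq_len(ncol(X)), emb)[1]
    ownership_score(X, stim, exp_id)
  } else {
    NA_real_
  }
  dplyr::bind_cols(
    tibble::tibble(
      os_mds = os, ss_mds = ss, baseline_full_os = os_full,
      ownership_loss_max = ownership_loss(os),
      ownership_loss_rescaled = if (os_full > 0) {
        ownership_loss(os, os_full)
      } else {
        NA_real_
      }
    ),
    distance_indices(X, items, condition_type)
  )
}
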