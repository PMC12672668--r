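#' Run the full measurement pipeline on a cohort
#'
#' Executes the complete analysis sequence on a (simulated or loaded)
#' two-condition cohort: per-session dissimilarity estimation, interval MDS
#' fits with stress diagnostics, group-level solutions on averaged
#' dissimilarity matrices with permutation benchmarks, stress-per-point,
#' baseline-anchored rotation, per-participant Procrustes alignment across
#' conditions, baseline-anchored distance indices, paired hypothesis tests,
#' questionnaire correlations, and k-means structure analysis of the group
#' solution. Sessions whose solution stress exceeds `stress_threshold` are
#' flagged (with a written rationale) but never silently dropped; exclusion
#' is an analyst decision.
#'
#' @param cohort A `cohort` (see [simulate_cohort()]) or a list with the
#'   same fields built from files.
#' @param n_dims Solution dimensionality (default 2).
#' @param n_starts Random starts per individual fit (default 100).
#' @param group_starts Random starts for group fits (default equal to
#'   `n_starts`).
#' @param n_perm Permutations for the group-solution benchmark
#'   (default 100).
#' @param perm_starts Starts per permutation refit (default 10).
#' @param stress_threshold Rule-of-thumb acceptability cutoff for stress-1
#'   (default 0.2).
#' @param imds An [imds_params()].
#' @param seed Integer seed controlling fits and permutations.
#' @param out_dir Optional directory for artifacts (configs, RDMs, summary
#'   JSON).
#' @return A list of class `pipeline_result` with `summary` (provenance,
#'   group diagnostics, comparisons, correlations, clusters), `records`,
#'   `configs`, `group` (per-condition group record/config/report),
#'   `indices` (per participant x condition tibble), `comparisons`,
#'   `flags`.
#' @export
pipeline_run <- function(cohort, n_dims = 2L, n_starts = 100L,
                         group_starts = n_starts, n_perm = 100L,
                         perm_starts = 10L, stress_threshold = 0.2,
                         imds = imds_params(), seed = 1L, out_dir = NULL) {
  items <- item_manifest(cohort$items)
  conditions <- unique(vapply(cohort$sessions, function(s) s$condition,
                              character(1)))
  params_used <- list(n_dims = n_dims, n_starts = n_starts,
                      group_starts = group_starts, n_perm = n_perm,
                      perm_starts = perm_starts,
                      stress_threshold = stress_threshold, seed = seed)

  # --- per-session estimation and fits ------------------------------------
  records <- list()
  configs <- list()
  flags <- list()
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    key <- names(cohort$sessions)[i]
    if (is.null(key) || key == "") {
      key <- paste(s$participant_id, s$condition, sep = ".")
    }
    v <- validate_session(s, items, max_trials = imds$max_trials,
                          min_subset = imds$min_subset)
    if (nrow(v) > 0) {
      abort(paste0("pipeline stage validate: session ", key, ": ",
                   v$rule[1]))
    }
    records[[key]] <- estimate_rdm(s, items, imds)
    configs[[key]] <- fit_interval_mds(
      records[[key]],
      fit_params(n_dims = n_dims, n_starts = n_starts,
                 seed = (seed + i) %% .Machine$integer.max)
    )
    if (configs[[key]]$stress1 > stress_threshold) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        session = key, stress1 = configs[[key]]$stress1,
        rationale = paste0("stress-1 exceeds the rule-of-thumb cutoff ",
                           stress_threshold,
                           "; inspect the solution before inclusion")
      )
    }
  }
  flags <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble::tibble(session = character(), stress1 = numeric(),
                   rationale = character())

  # --- group solutions per condition ---------------------------------------
  glove <- items$item_id[items$role == "baseline_none"]
  group <- lapply(setNames(conditions, conditions), function(cn) {
    keys <- names(records)[vapply(cohort$sessions, function(s) {
      s$condition == cn
    }, logical(1))]
    Ds <- lapply(records[keys], `[[`, "D")
    Dm <- Reduce(`+`, Ds) / length(Ds)
    Wm <- Reduce(`+`, lapply(records[keys], `[[`, "W"))
    rec <- dissimilarity_record(Dm, Wm, items$item_id)
    fp <- fit_params(n_dims = n_dims, n_starts = group_starts,
                     seed = (seed + 1000 + match(cn, conditions)) %%
                       .Machine$integer.max)
    cfg <- fit_interval_mds(rec, fp)
    perm <- mds_permutation_test(rec, fp, n_perm = n_perm,
                                 perm_starts = perm_starts,
                                 observed = cfg)
    rot <- if (n_dims == 2) {
      baseline_anchor_rotation(cfg, glove)
    } else {
      list(angle = NA_real_, config = cfg$X)
    }
    list(record = rec, config = cfg, permutation = perm,
         rotation_angle = rot$angle, rotated = rot$config)
  })

  # --- per-participant alignment and distance indices ----------------------
  participants <- unique(vapply(cohort$sessions, function(s) {
    s$participant_id
  }, character(1)))
  indices <- list()
  alignments <- list()
  if (length(conditions) == 2) {
    c1 <- conditions[1]
    c2 <- conditions[2]
    for (p in participants) {
      k1 <- paste(p, c1, sep = ".")
      k2 <- paste(p, c2, sep = ".")
      if (!k1 %in% names(configs) || !k2 %in% names(configs)) next
      # rotation/reflection-only alignment of unit-size configurations:
      # optimal scaling would shrink the source and bias paired distance
      # comparisons toward the target condition
      al <- procrustes_align(configs[[k2]], configs[[k1]],
                             allow_scaling = FALSE)
      alignments[[p]] <- al
      d1 <- distance_indices(al$target, items)
      d2 <- distance_indices(al$aligned, items)
      indices[[length(indices) + 1]] <- dplyr::bind_rows(
        dplyr::mutate(d1, participant_id = p, condition = c1, .before = 1),
        dplyr::mutate(d2, participant_id = p, condition = c2, .before = 1)
      )
    }
  }
  indices <- if (length(indices)) dplyr::bind_rows(indices) else NULL

  # --- paired comparisons and questionnaire correlations -------------------
  comparisons <- NULL
  correlations <- NULL
  if (!is.null(indices) && length(conditions) == 2 &&
      length(participants) >= 3) {
    wide <- tidyr::pivot_wider(
      indices, id_cols = "participant_id", names_from = "condition",
      values_from = c("embodiment_dist", "deobjectification_dist")
    )
    c1 <- conditions[1]
    c2 <- conditions[2]
    emb1 <- wide[[paste0("embodiment_dist_", c1)]]
    emb2 <- wide[[paste0("embodiment_dist_", c2)]]
    deo1 <- wide[[paste0("deobjectification_dist_", c1)]]
    deo2 <- wide[[paste0("deobjectification_dist_", c2)]]
    # same-index contrasts across conditions, plus the mixed-direction
    # contrasts used when the second condition works in the opposite
    # direction (suggestion designs): "starts to be" compares the
    # experimental-to-full-baseline distance in condition 1 against the
    # experimental-to-none-baseline distance in condition 2, and
    # "ceases to be" the converse pair
    comparisons <- dplyr::bind_rows(
      dplyr::mutate(paired_test(emb1, emb2, alternative = "less"),
                    effect = "embodiment", .before = 1),
      dplyr::mutate(paired_test(deo1, deo2, alternative = "greater"),
                    effect = "deobjectification", .before = 1),
      dplyr::mutate(paired_test(emb1, deo2, alternative = "less"),
                    effect = "starts_to_be", .before = 1),
      dplyr::mutate(paired_test(deo1, emb2, alternative = "greater"),
                    effect = "ceases_to_be", .before = 1)
    )
    if (!is.null(cohort$questionnaire)) {
      q1 <- dplyr::filter(cohort$questionnaire, .data$condition == c1)
      q1 <- q1$mean_rating[match(wide$participant_id, q1$participant_id)]
      if (sum(!is.na(q1)) >= 4 && stats::sd(q1, na.rm = TRUE) > 0) {
        ok <- !is.na(q1)
        correlations <- dplyr::bind_rows(
          dplyr::mutate(pearson_r(emb1[ok], q1[ok]),
                        measure = "embodiment_dist", .before = 1),
          dplyr::mutate(pearson_r(deo1[ok], q1[ok]),
                        measure = "deobjectification_dist", .before = 1)
        )
      }
    }
  }

  # --- clustering of the first condition's rotated group solution ----------
  clusters <- NULL
  if (n_dims == 2) {
    sel <- select_k_majority(normalize_config(group[[1]]$rotated),
                             seed = (seed + 77) %% .Machine$integer.max)
    clusters <- list(k = sel$k, votes = sel$votes,
                     assignments = sel$solution$assignments,
                     variance_explained = sel$solution$variance_explained)
  }

  summary <- list(
    seed = seed,
    config_hash = config_hash(params_used),
    params = params_used,
    conditions = conditions,
    n_participants = length(participants),
    group = lapply(group, function(g) {
      list(stress1 = g$config$stress1,
           stress_ok = g$config$stress1 < stress_threshold,
           permutation_p = g$permutation$p_value,
           permutation_passes = g$permutation$passes,
           rotation_angle = g$rotation_angle,
           spp = as.list(g$config$spp))
    }),
    flags = flags,
    comparisons = comparisons,
    correlations = correlations,
    clusters = if (!is.null(clusters)) {
      list(k = clusters$k, variance_explained = clusters$variance_explained)
    } else {
      NULL
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(records)) {
      write_matrix_csv(records[[key]]$D,
                       file.path(out_dir, paste0("rdm_", key, ".csv")))
      write_config_csv(configs[[key]],
                       file.path(out_dir, paste0("config_", key, ".csv")))
    }
    for (cn in conditions) {
      write_config_csv(group[[cn]]$rotated,
                       file.path(out_dir,
                                 paste0("group_config_", cn, ".csv")))
    }
    write_report_json(summary, file.path(out_dir, "summary.json"))
  }

  structure(list(summary = summary, records = records, configs = configs,
                 group = group, alignments = alignments, indices = indices,
                 comparisons = comparisons, correlations = correlations,
                 clusters = clusters, flags = flags),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$summary$n_participants, "participants,",
      length(x$summary$conditions), "condition(s)\n")
  for (cn in names(x$group)) {
    g <- x$summary$group[[cn]]
    cat("  ", cn, ": group stress-1 =", format(g$stress1, digits = 3),
        "| permutation p =", format(g$permutation_p, digits = 3), "\n")
  }
  if (!is.null(x$comparisons)) {
    print(x$comparisons)
  }
  invisible(x)
}
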