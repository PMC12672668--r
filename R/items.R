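#' Item manifests for multi-arrangement bodily-space experiments
#'
#' An item manifest is a tibble with one row per item and columns
#' `item_id` (short stable token, unique), `label` (human-readable name),
#' `role` (one of `"experimental"`, `"baseline_full"`, `"baseline_none"`,
#' `"common"`) and `familiarity` (rating in \[1, 5\]; may be `NA` for
#' `common` items, and defaults to the maximum of 5 for every other role,
#' since the experimental and canonical baseline experiences are assumed
#' fully familiar).
#'
#' A valid manifest has at least 4 items, exactly one `experimental` item
#' (the hand whose ownership is being probed), exactly one `baseline_full`
#' item (normal body feelings, the canonical case of full ownership) and
#' exactly one `baseline_none` item (an empty glove, the canonical case of
#' no ownership).
#'
#' @param items A data frame of items with at least `item_id`, `label`,
#'   `role`; `familiarity` is optional.
#' @return `item_manifest()` returns a validated item tibble.
#' @export
item_manifest <- function(items) {
  items <- tibble::as_tibble(items)
  required <- c("item_id", "label", "role")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("item manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"familiarity" %in% names(items)) items$familiarity <- NA_real_
  items$item_id <- as.character(items$item_id)
  items$label <- as.character(items$label)
  items$role <- as.character(items$role)
  items$familiarity <- as.numeric(items$familiarity)

  roles <- c("experimental", "baseline_full", "baseline_none", "common")
  bad_role <- setdiff(unique(items$role), roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown item role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (anyDuplicated(items$item_id)) abort("item_id values must be unique")
  if (nrow(items) < 4) abort("an item set needs at least 4 items")
  for (r in c("experimental", "baseline_full", "baseline_none")) {
    if (sum(items$role == r) != 1) {
      abort(paste0("item set must contain exactly one '", r, "' item"))
    }
  }
  # canonical and experimental experiences are assumed fully familiar
  fill <- is.na(items$familiarity) & items$role != "common"
  items$familiarity[fill] <- 5
  ok <- is.na(items$familiarity) |
    (items$familiarity >= 1 & items$familiarity <= 5)
  if (!all(ok)) abort("familiarity ratings must lie in [1, 5]")
  items
}

#' Default 13-item bodily-experience manifest
#'
#' The packaged item set used for rubber-hand-illusion measurement: the
#' experimental hand item, the two canonical baselines (normal body
#' feelings, empty glove), and ten common experiences of altered or partial
#' body ownership.
#'
#' @return A 13-row item tibble (see [item_manifest()] for the schema).
#' @examples
#' default_item_manifest()
#' @export
default_item_manifest <- function() {
  item_manifest(tibble::tribble(
    ~item_id,         ~label,                 ~role,
    "hand",           "experimental hand",    "experimental",
    "normal_body",    "normal body feelings", "baseline_full",
    "empty_glove",    "empty glove",          "baseline_none",
    "cold_hands",     "cold hands",           "common",
    "dead_hand",      "dead hand",            "common",
    "anesthesia",     "anesthesia",           "common",
    "inebriation",    "inebriation",          "common",
    "muscle_cramp",   "muscle cramp",         "common",
    "pinched_nerve",  "pinched nerve",        "common",
    "workout",        "workout fatigue",      "common",
    "swelling",       "swelling",             "common",
    "crossed_legs",   "sitting cross-legged", "common",
    "relaxation",     "deep relaxation",      "common"
  ))
}

#' Construct an arrangement session
#'
#' A session is one participant x condition block of arrangement trials.
#' Each trial places a subset of the items inside a circular arena
#' (the closed unit disk centred at the origin); trial 1 must show the full
#' item set, later trials at least 3 items, and a session has at most
#' `max_trials` (12) arrangements.
#'
#' @param participant_id Participant identifier.
#' @param condition Free condition label (e.g. `"synchronous"`).
#' @param trials A tibble in long format with columns `trial_index`,
#'   `item_id`, `x`, `y` (one row per placed item).
#' @return An object of class `arrangement_session`.
#' @export
arrangement_session <- function(participant_id, condition, trials) {
  trials <- tibble::as_tibble(trials)
  required <- c("trial_index", "item_id", "x", "y")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("session trials are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  trials$trial_index <- as.integer(trials$trial_index)
  trials$item_id <- as.character(trials$item_id)
  trials$x <- as.numeric(trials$x)
  trials$y <- as.numeric(trials$y)
  structure(
    list(participant_id = as.character(participant_id),
         condition = as.character(condition),
         trials = trials[order(trials$trial_index), ]),
    class = "arrangement_session"
  )
}

#' @export
print.arrangement_session <- function(x, ...) {
  cat("<arrangement_session> participant", x$participant_id,
      "| condition", x$condition,
      "|", dplyr::n_distinct(x$trials$trial_index), "trial(s)\n")
  invisible(x)
}

#' Extract one trial's placements from a session
#'
#' @param session An [arrangement_session()].
#' @param trial One trial index.
#' @return Tibble with columns `item_id`, `x`, `y`.
#' @export
session_trial <- function(session, trial) {
  tr <- session$trials
  tr[tr$trial_index == trial, c("item_id", "x", "y")]
}

#' Validate an arrangement session against an item manifest
#'
#' Checks every structural rule a session must satisfy before dissimilarity
#' estimation: known item ids, consecutive trial indices starting at 1, the
#' full item set in trial 1, at least 3 items per later trial, at most 12
#' trials, all coordinates inside the closed unit-disk arena, no duplicated
#' item within a trial and no two items placed at identical coordinates
#' (zero distances carry no evidence).
#'
#' @param session An [arrangement_session()].
#' @param items An item manifest (see [item_manifest()]).
#' @param max_trials Maximum allowed number of arrangements (default 12).
#' @param min_subset Minimum subset size for trials after the first
#'   (default 3).
#' @return A tibble of violations with columns `trial` (NA for
#'   session-level rules) and `rule`; zero rows if the session is valid.
#' @export
validate_session <- function(session, items, max_trials = 12L,
                             min_subset = 3L) {
  items <- item_manifest(items)
  if (!inherits(session, "arrangement_session")) {
    abort("`session` must be an arrangement_session")
  }
  tr <- session$trials
  viol <- list()
  add <- function(trial, rule) {
    viol[[length(viol) + 1]] <<- tibble::tibble(trial = as.integer(trial),
                                                rule = rule)
  }

  idx <- sort(unique(tr$trial_index))
  if (length(idx) == 0) {
    add(NA, "session has no trials")
  } else {
    if (!identical(idx, seq_along(idx))) {
      add(NA, "trial indices must be consecutive from 1")
    }
    if (length(idx) > max_trials) {
      add(NA, paste0("session exceeds ", max_trials, " arrangements"))
    }
  }

  unknown <- setdiff(unique(tr$item_id), items$item_id)
  if (length(unknown) > 0) {
    add(NA, paste0("unknown item_id(s): ", paste(unknown, collapse = ", ")))
  }

  for (t in idx) {
    one <- tr[tr$trial_index == t, ]
    if (anyDuplicated(one$item_id)) {
      add(t, "item placed more than once in trial")
    }
    if (t == 1) {
      if (!setequal(one$item_id, items$item_id) ||
          nrow(one) != nrow(items)) {
        add(t, "first trial must show full set")
      }
    } else if (nrow(one) < min_subset) {
      add(t, paste0("trial has fewer than ", min_subset, " items"))
    }
    r <- sqrt(one$x^2 + one$y^2)
    if (any(!is.finite(r)) || any(r > 1 + 1e-12)) {
      add(t, "coordinate outside arena")
    }
    if (nrow(one) > 1) {
      dd <- as.matrix(dist(cbind(one$x, one$y)))
      if (any(dd[upper.tri(dd)] == 0)) {
        add(t, "duplicate placement (two items at identical coordinates)")
      }
    }
  }

  if (length(viol) == 0) {
    tibble::tibble(trial = integer(), rule = character())
  } else {
    dplyr::bind_rows(viol)
  }
}
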