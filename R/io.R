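#' Read and write item manifests (TSV)
#'
#' Tab-separated with header row and columns `item_id`, `label`, `role`,
#' `familiarity`.
#'
#' @param items Item manifest tibble.
#' @param path File path.
#' @return `read_items()` returns a validated item tibble;
#'   `write_items()` returns `path` invisibly.
#' @export
write_items <- function(items, path) {
  items <- item_manifest(items)
  readr::write_tsv(items, path)
  invisible(path)
}

#' @rdname write_items
#' @export
read_items <- function(path) {
  items <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("item_id", "label", "role")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("items file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  item_manifest(items)
}

#' Read and write arrangement sessions (JSON)
#'
#' Sessions are stored as JSON objects with fields `participant_id`,
#' `condition`, `arena` (`cx`, `cy`, `r`, declaring the circle the
#' coordinates live in) and `trials` (each with `trial_index`, `items`,
#' `coords` as an array of `[x, y]` pairs). On read, coordinates are
#' converted to the canonical unit-disk arena via `(x - cx) / r`,
#' `(y - cy) / r`, so files may use raw pixel coordinates.
#'
#' @param session An [arrangement_session()].
#' @param path File path.
#' @return `read_session()` returns an `arrangement_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  trials <- lapply(sort(unique(session$trials$trial_index)), function(t) {
    one <- session_trial(session, t)
    list(trial_index = t, items = one$item_id,
         coords = unname(as.matrix(one[, c("x", "y")])))
  })
  obj <- list(participant_id = session$participant_id,
              condition = session$condition,
              arena = list(cx = 0, cy = 0, r = 1),
              trials = trials)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (f in c("participant_id", "condition", "trials")) {
    if (is.null(obj[[f]])) {
      abort(paste0("session file ", path, " lacks field '", f, "'"))
    }
  }
  arena <- obj$arena
  if (is.null(arena)) arena <- list(cx = 0, cy = 0, r = 1)
  if (is.null(arena$r) || arena$r <= 0) {
    abort("session arena radius must be positive")
  }
  trials <- dplyr::bind_rows(lapply(obj$trials, function(tr) {
    if (is.null(tr$trial_index) || is.null(tr$items) ||
        is.null(tr$coords)) {
      abort(paste0("malformed trial record in ", path,
                   ": needs trial_index, items, coords"))
    }
    coords <- tr$coords
    if (!is.matrix(coords)) {
      coords <- do.call(rbind, lapply(coords, unlist))
    }
    if (nrow(coords) != length(tr$items) || ncol(coords) != 2) {
      abort(paste0("trial ", tr$trial_index, " in ", path,
                   ": coords must be one [x, y] pair per item"))
    }
    tibble::tibble(trial_index = as.integer(tr$trial_index),
                   item_id = as.character(tr$items),
                   x = (coords[, 1] - arena$cx) / arena$r,
                   y = (coords[, 2] - arena$cy) / arena$r)
  }))
  arrangement_session(obj$participant_id, obj$condition, trials)
}

#' Read and write square matrices (CSV)
#'
#' Full (not triangular) square matrices with an `item_id` header column
#' and one column per item, written with 12 significant digits and exact
#' symmetry. On read, matrices with asymmetry above `1e-8` are rejected;
#' smaller asymmetries are averaged away.
#'
#' @param m Square matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_csv()` returns a symmetric named matrix;
#'   `write_matrix_csv()` returns `path` invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  m <- (m + t(m)) / 2 # exact symmetry on write
  df <- tibble::as_tibble(signif(m, 12))
  df <- dplyr::bind_cols(tibble::tibble(item_id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"item_id" %in% names(df)) {
    abort(paste0("matrix file ", path, " is missing column: item_id"))
  }
  ids <- as.character(df$item_id)
  m <- as.matrix(df[, setdiff(names(df), "item_id"), drop = FALSE])
  if (!identical(colnames(m), ids)) {
    abort(paste0("matrix file ", path,
                 ": column order must match the item_id column"))
  }
  rownames(m) <- ids
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    abort(paste0("matrix in ", path, " is asymmetric (max |m - t(m)| = ",
                 format(asym), ")"))
  }
  (m + t(m)) / 2
}

#' Read and write spatial configurations (CSV)
#'
#' `item_id` plus `dim1..dimK` columns.
#'
#' @param config Configuration (matrix with rownames, `mds_config`, or
#'   tidy tibble).
#' @param path File path.
#' @return `read_config_csv()` returns a coordinate matrix;
#'   `write_config_csv()` returns `path` invisibly.
#' @export
write_config_csv <- function(config, path) {
  X <- config_matrix(config)
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  df <- dplyr::bind_cols(tibble::tibble(item_id = rownames(X)),
                         tibble::as_tibble(signif(X, 12)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_config_csv
#' @export
read_config_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"item_id" %in% names(df)) {
    abort(paste0("config file ", path, " is missing column: item_id"))
  }
  dims <- grep("^dim[0-9]+$", names(df), value = TRUE)
  if (length(dims) == 0) {
    abort(paste0("config file ", path, " has no dim columns"))
  }
  X <- as.matrix(df[, dims, drop = FALSE])
  rownames(X) <- as.character(df$item_id)
  X
}

#' Write a report object as JSON
#'
#' @param report A list (nested tibbles are converted to data frames).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}

# order-independent FNV-style hash of a parameter list, for provenance
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)),
             collapse = "\n")
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h), b) * 31) %% 2147483647
  sprintf("%08x", as.integer(h))
}
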