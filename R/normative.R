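NORMDB_SCHEMA <- "ppasym-normdb-1"

#' Build a normative asymmetry database from a reference cohort
#'
#' For every layer and every corresponding cell pair, stores the 2.5th and
#' 97.5th percentiles of the per-eye asymmetries (inferior minus superior)
#' across the cohort, together with the pair's mean, SD and the reference n
#' for auditability. A complete database over the ten layers has
#' 10 x 32 = 320 entries.
#'
#' @param cohort A `ppa_cohort`; every eye must contain every requested
#'   layer.
#' @param layers Layers to include (default all ten).
#' @param description Free-text provenance note.
#' @return An object of class `normative_db`: list with `schema_version`,
#'   `provenance` (list: `description`, `n_eyes`, `created`) and `entries`
#'   (data.frame with columns `layer`, `inf_row`, `inf_col`, `n_reference`,
#'   `mean_diff_um`, `sd_diff_um`, `p2_5_um`, `p97_5_um`).
#' @export
build_normative_database <- function(cohort, layers = layer_ids(),
                                     description = "") {
  if (!inherits(cohort, "ppa_cohort") || !length(cohort$eyes)) {
    stop("cohort must be a non-empty ppa_cohort", call. = FALSE)
  }
  for (l in layers) assert_layer(l)
  missing_by_eye <- lapply(cohort$eyes, function(e) {
    setdiff(layers, names(e$grids))
  })
  has_missing <- vapply(missing_by_eye, length, 1L) > 0L
  if (any(has_missing)) {
    msg <- vapply(which(has_missing), function(i) {
      sprintf("%s: %s", cohort$eyes[[i]]$subject_id,
              paste(missing_by_eye[[i]], collapse = ", "))
    }, character(1L))
    stop("incomplete layer coverage (eye: missing layers) - ",
         paste(msg, collapse = "; "), call. = FALSE)
  }
  entries <- do.call(rbind, lapply(layers, function(l) {
    d <- pair_difference_matrix(cohort, l)
    p <- cell_pairs()
    ranges <- apply(d, 2L, percentile_range)
    data.frame(layer = l, inf_row = p$inf_row, inf_col = p$inf_col,
               n_reference = nrow(d),
               mean_diff_um = colMeans(d),
               sd_diff_um = apply(d, 2L, stats::sd),
               p2_5_um = ranges["p2_5", ],
               p97_5_um = ranges["p97_5", ])
  }))
  rownames(entries) <- NULL
  structure(list(
    schema_version = NORMDB_SCHEMA,
    provenance = list(
      description = if (nzchar(description)) description else cohort$provenance,
      n_eyes = length(cohort$eyes),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    entries = entries), class = "normative_db")
}

#' @export
print.normative_db <- function(x, ...) {
  cat(sprintf("Normative asymmetry database (%d entries, %d layers, n = %s)\n",
              nrow(x$entries), length(unique(x$entries$layer)),
              x$provenance$n_eyes %||% "?"))
  invisible(x)
}

#' Classify an eye's asymmetries against a normative database
#'
#' Each inferior-superior cell-pair difference of the eye is compared with
#' the database's reference range for that (layer, pair). Bounds are
#' inclusive: a value exactly at either percentile is within normal limits.
#' Values strictly below the 2.5th percentile or strictly above the 97.5th
#' percentile are flagged as likely pathological.
#'
#' @param eye An `eye_record`.
#' @param db A `normative_db` covering every requested layer.
#' @param layers Layers to classify (default: the eye's layers).
#' @return A data.frame with one row per (layer, inferior cell): `layer`,
#'   `inf_row`, `inf_col`, `observed_diff_um`, `p2_5_um`, `p97_5_um`,
#'   `verdict` in {below_p2_5, within_normal, above_p97_5}.
#' @export
classify_eye <- function(eye, db, layers = names(eye$grids)) {
  if (!inherits(db, "normative_db")) {
    stop("db must be a normative_db", call. = FALSE)
  }
  if (!inherits(eye, "eye_record")) {
    stop("eye must be an eye_record", call. = FALSE)
  }
  layers <- intersect(layer_ids(), layers)
  out <- do.call(rbind, lapply(layers, function(l) {
    d <- cell_pair_differences(eye, l)
    ent <- db$entries[db$entries$layer == l, , drop = FALSE]
    key_obs <- paste(d$inf_row, d$inf_col)
    key_db <- paste(ent$inf_row, ent$inf_col)
    idx <- match(key_obs, key_db)
    if (anyNA(idx)) {
      miss <- key_obs[is.na(idx)][1L]
      stop("normative database has no entry for layer ", l, ", inferior cell ",
           sub(" ", ".", miss), call. = FALSE)
    }
    lo <- ent$p2_5_um[idx]
    hi <- ent$p97_5_um[idx]
    verdict <- ifelse(d$diff_um < lo, "below_p2_5",
                      ifelse(d$diff_um > hi, "above_p97_5", "within_normal"))
    data.frame(layer = l, inf_row = d$inf_row, inf_col = d$inf_col,
               observed_diff_um = d$diff_um, p2_5_um = lo, p97_5_um = hi,
               verdict = verdict)
  }))
  rownames(out) <- NULL
  out
}

#' Save a normative database to JSON
#'
#' @param db A `normative_db`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  if (!inherits(db, "normative_db")) {
    stop("db must be a normative_db", call. = FALSE)
  }
  jsonlite::write_json(
    list(schema_version = db$schema_version,
         provenance = db$provenance,
         entries = db$entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a normative database from JSON
#'
#' Round-trips the format written by [save_database()]. Rejects files with a
#' mismatched schema version or duplicated (layer, cell) keys; a database
#' with an empty entry list loads with a warning.
#'
#' @param path JSON file path.
#' @return A `normative_db`.
#' @export
load_database <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed database file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(raw$schema_version) || !identical(raw$schema_version,
                                                NORMDB_SCHEMA)) {
    stop("schema version mismatch in ", path, ": expected '", NORMDB_SCHEMA,
         "', found '", raw$schema_version %||% "<absent>", "'", call. = FALSE)
  }
  entries <- raw$entries
  if (is.null(entries) || !NROW(entries)) {
    warning("normative database ", path, " contains no entries")
    entries <- data.frame(layer = character(), inf_row = integer(),
                          inf_col = integer(), n_reference = integer(),
                          mean_diff_um = numeric(), sd_diff_um = numeric(),
                          p2_5_um = numeric(), p97_5_um = numeric())
  } else {
    entries <- as.data.frame(entries)
    need <- c("layer", "inf_row", "inf_col", "n_reference", "mean_diff_um",
              "sd_diff_um", "p2_5_um", "p97_5_um")
    miss <- setdiff(need, names(entries))
    if (length(miss)) {
      stop("database entries are missing fields: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    key <- paste(entries$layer, entries$inf_row, entries$inf_col)
    if (anyDuplicated(key)) {
      stop("duplicated (layer, cell) keys in ", path, ": ",
           paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    }
    bad_layer <- setdiff(unique(entries$layer), layer_ids())
    if (length(bad_layer)) {
      stop("unknown layer labels in database: ",
           paste(bad_layer, collapse = ", "), call. = FALSE)
    }
    entries$inf_row <- as.integer(entries$inf_row)
    entries$inf_col <- as.integer(entries$inf_col)
    entries$n_reference <- as.integer(entries$n_reference)
  }
  structure(list(schema_version = raw$schema_version,
                 provenance = as.list(raw$provenance),
                 entries = entries),
            class = "normative_db")
}

#' Export a normative database's entries as CSV
#'
#' Spreadsheet-friendly flat export with the same columns as the JSON
#' entries array.
#'
#' @param db A `normative_db`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_database_csv <- function(db, path) {
  if (!inherits(db, "normative_db")) {
    stop("db must be a normative_db", call. = FALSE)
  }
  utils::write.csv(db$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
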