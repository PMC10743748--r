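#' Write a cohort as a long-format grid CSV
#'
#' The grid CSV dialect mirrors a flattened posterior-pole export: one row
#' per cell with columns `subject_id`, `laterality` (R/L), `layer`, `row`
#' (1-8), `col` (1-8), `thickness_um`. UTF-8, comma-separated, header
#' required. Rows are written in a deterministic order (eyes in cohort
#' order, layers in [layer_ids()] order, cells row-major).
#'
#' @param x A `ppa_cohort` or a single `eye_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(x, path) {
  if (inherits(x, "eye_record")) x <- cohort(list(x))
  if (!inherits(x, "ppa_cohort")) {
    stop("x must be a ppa_cohort or eye_record", call. = FALSE)
  }
  df <- cohort_to_long(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_to_long <- function(cohort) {
  per_eye <- lapply(cohort$eyes, function(e) {
    layers <- intersect(layer_ids(), names(e$grids))
    per_layer <- lapply(layers, function(l) {
      v <- e$grids[[l]]$values
      data.frame(subject_id = e$subject_id,
                 laterality = if (e$laterality == "right") "R" else "L",
                 layer = l,
                 row = rep(1:8, each = 8L),
                 col = rep(1:8, times = 8L),
                 thickness_um = as.vector(t(v)))
    })
    do.call(rbind, per_layer)
  })
  do.call(rbind, per_eye)
}

#' Read a cohort from a long-format grid CSV
#'
#' Parses the dialect written by [write_grid_csv()], validates every
#' eye-layer block with [validate_grid()], and assembles `eye_record`s.
#'
#' @param path CSV file path.
#' @param provenance Provenance string to attach to the cohort; defaults to
#'   the file name.
#' @return A `ppa_cohort`.
#' @export
read_grid_csv <- function(path, provenance = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "laterality", "layer", "row", "col", "thickness_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("grid CSV ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_layer <- setdiff(unique(df$layer), layer_ids())
  if (length(bad_layer)) {
    stop("grid CSV ", path, " contains unknown layer labels: ",
         paste(bad_layer, collapse = ", "), call. = FALSE)
  }
  if (!all(df$laterality %in% c("R", "L"))) {
    stop("laterality column must contain only 'R' or 'L'", call. = FALSE)
  }
  eyes <- lapply(split(df, df$subject_id), function(sub) {
    lat <- unique(sub$laterality)
    if (length(lat) != 1L) {
      stop("subject ", sub$subject_id[1L],
           " has inconsistent laterality entries", call. = FALSE)
    }
    laterality <- if (lat == "R") "right" else "left"
    grids <- lapply(split(sub, sub$layer), function(block) {
      rep_ <- validate_grid(block[, c("row", "col", "thickness_um")])
      if (!rep_$ok) {
        stop("invalid grid for subject ", block$subject_id[1L], ", layer ",
             block$layer[1L], ": ", paste(rep_$problems, collapse = "; "),
             call. = FALSE)
      }
      m <- matrix(NA_real_, 8L, 8L)
      m[cbind(block$row, block$col)] <- block$thickness_um
      thickness_grid(block$subject_id[1L], block$layer[1L], laterality, m)
    })
    eye_record(sub$subject_id[1L], laterality, grids)
  })
  # split() orders by factor level; restore input file order of subjects
  eyes <- eyes[unique(df$subject_id)]
  cohort(unname(eyes),
         provenance = provenance %||% paste("read from", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort manifest
#'
#' A manifest lists the grid CSV files of a cohort plus optional per-eye
#' metadata columns (e.g. `age_years`, `sex`). Paths are stored relative to
#' the manifest's directory.
#'
#' @param files Character vector of grid CSV paths.
#' @param path Manifest CSV output path.
#' @param metadata Optional data.frame with one row per file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, path, metadata = NULL) {
  df <- data.frame(file = files, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (nrow(metadata) != length(files)) {
      stop("metadata must have one row per file", call. = FALSE)
    }
    df <- cbind(df, metadata)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort via a manifest
#'
#' Reads every grid CSV listed in the manifest (paths resolved relative to
#' the manifest location), merges the eyes into one cohort and attaches any
#' metadata columns to the matching eye records.
#'
#' @param path Manifest CSV path.
#' @return A `ppa_cohort`.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"file" %in% names(mf) || !nrow(mf)) {
    stop("manifest must be a non-empty CSV with a 'file' column",
         call. = FALSE)
  }
  base <- dirname(path)
  meta_cols <- setdiff(names(mf), "file")
  eyes <- list()
  for (i in seq_len(nrow(mf))) {
    f <- mf$file[i]
    full <- if (file.exists(f)) f else file.path(base, f)
    co <- read_grid_csv(full)
    for (e in co$eyes) {
      if (length(meta_cols)) {
        e$metadata <- utils::modifyList(e$metadata,
                                        as.list(mf[i, meta_cols, drop = FALSE]))
      }
      eyes[[length(eyes) + 1L]] <- e
    }
  }
  cohort(eyes, provenance = paste("manifest", basename(path)))
}
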