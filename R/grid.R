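#' Macular layer identifiers
#'
#' The ten layer segmentations exported by the posterior pole protocol:
#' seven individual layers (RNFL, GCL, IPL, INL, OPL, ONL, RPE) and three
#' composites (INNER = RNFL..ONL, OUTER = photoreceptors + RPE, RETINA =
#' complete retina).
#'
#' @return Character vector of the 10 admissible layer labels, in fixed
#'   display order.
#' @export
layer_ids <- function() {
  c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "RPE",
    "INNER", "OUTER", "RETINA")
}

assert_layer <- function(layer) {
  if (length(layer) != 1L || !is.character(layer) || !(layer %in% layer_ids())) {
    stop("unknown layer '", paste(layer, collapse = ","),
         "'; must be one of: ", paste(layer_ids(), collapse = ", "),
         call. = FALSE)
  }
  invisible(layer)
}

assert_laterality <- function(laterality) {
  if (length(laterality) != 1L || !(laterality %in% c("right", "left"))) {
    stop("laterality must be 'right' or 'left'", call. = FALSE)
  }
  invisible(laterality)
}

assert_address <- function(row, col) {
  ok <- length(row) == length(col) &&
    all(is.finite(row)) && all(is.finite(col)) &&
    all(row == as.integer(row)) && all(col == as.integer(col)) &&
    all(row >= 1 & row <= 8) && all(col >= 1 & col <= 8)
  if (!ok) {
    stop("invalid cell address: row and col must be integers in 1..8 ",
         "(row 1 = most inferior, col 1 = most temporal)", call. = FALSE)
  }
  invisible(NULL)
}

#' Corresponding cell across the horizontal midline
#'
#' The posterior pole grid numbers rows 1..8 from inferior to superior, so
#' the cell anatomically mirrored across the horizontal midline sits at row
#' `9 - row` in the same column: cell 1.1 corresponds to cell 8.1, and the
#' map is an involution.
#'
#' @param row,col Integer vectors in 1..8 (recycled to common length is not
#'   supported; lengths must match).
#' @return A data.frame with columns `row` and `col` giving the partner cell
#'   of each input address.
#' @examples
#' corresponding_cell(1, 1)  # row 8, col 1
#' @export
corresponding_cell <- function(row, col) {
  assert_address(row, col)
  data.frame(row = 9L - as.integer(row), col = as.integer(col))
}

#' Hemisphere of a grid cell
#'
#' Rows 1-4 form the inferior hemisphere and rows 5-8 the superior one, so
#' each hemisphere contains exactly 32 cells.
#'
#' @inheritParams corresponding_cell
#' @return Character vector, `"inferior"` or `"superior"` per address.
#' @export
hemisphere_of <- function(row, col) {
  assert_address(row, col)
  ifelse(row <= 4, "inferior", "superior")
}

#' Inferior-hemisphere pair index
#'
#' Enumerates the 32 corresponding cell pairs in row-major order over the
#' inferior hemisphere (rows 1..4, columns 1..8).
#'
#' @return A data.frame with columns `inf_row`, `inf_col`, `sup_row`,
#'   `sup_col` (32 rows).
#' @export
cell_pairs <- function() {
  inf_row <- rep(1:4, each = 8L)
  inf_col <- rep(1:8, times = 4L)
  data.frame(inf_row = inf_row, inf_col = inf_col,
             sup_row = 9L - inf_row, sup_col = inf_col)
}

#' Construct a thickness grid for one eye and one layer
#'
#' @param subject_id Opaque subject identifier (scalar).
#' @param layer One of [layer_ids()].
#' @param laterality `"right"` or `"left"`.
#' @param values Either an 8x8 numeric matrix indexed `[row, col]` with row 1
#'   the most inferior row and column 1 the most temporal column, or a
#'   length-64 numeric vector in row-major order starting at row 1. Values
#'   are thicknesses in microns; all must be finite and non-negative.
#' @return An object of class `thickness_grid`: a list with fields
#'   `subject_id`, `layer`, `laterality` and `values` (8x8 matrix).
#' @export
thickness_grid <- function(subject_id, layer, laterality, values) {
  assert_layer(layer)
  assert_laterality(laterality)
  if (is.matrix(values)) {
    if (!all(dim(values) == c(8L, 8L))) {
      stop("values matrix must be 8x8", call. = FALSE)
    }
    m <- values
  } else {
    if (length(values) != 64L) {
      stop("values must be an 8x8 matrix or a length-64 vector", call. = FALSE)
    }
    m <- matrix(as.numeric(values), nrow = 8L, ncol = 8L, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(row = as.character(1:8), col = as.character(1:8))
  g <- structure(
    list(subject_id = as.character(subject_id)[1L], layer = layer,
         laterality = laterality, values = m),
    class = "thickness_grid")
  rep_ <- validate_grid(g)
  if (!rep_$ok) {
    stop("invalid thickness grid: ", paste(rep_$problems, collapse = "; "),
         call. = FALSE)
  }
  g
}

#' Validate grid cell data
#'
#' Checks the completeness and sanity of one eye-layer set of cell values:
#' each of the 64 addresses present exactly once, all thicknesses finite and
#' non-negative. Accepts either a `thickness_grid` or a long data.frame with
#' columns `row`, `col`, `thickness_um` (as read from a grid CSV).
#'
#' @param x A `thickness_grid` or a data.frame of cells for a single
#'   eye-layer combination.
#' @return A list with `ok` (logical) and `problems` (character vector of
#'   human-readable findings, empty when `ok`).
#' @export
validate_grid <- function(x) {
  problems <- character()
  if (inherits(x, "thickness_grid")) {
    v <- x$values
    if (!is.matrix(v) || !all(dim(v) == c(8L, 8L))) {
      problems <- c(problems, "values is not an 8x8 matrix")
    } else {
      bad <- which(!is.finite(v) | v < 0, arr.ind = TRUE)
      if (nrow(bad)) {
        problems <- c(problems, sprintf(
          "non-finite or negative thickness at cell %d.%d",
          bad[, 1L], bad[, 2L]))
      }
    }
    if (!x$laterality %in% c("right", "left")) {
      problems <- c(problems, "laterality must be 'right' or 'left'")
    }
  } else if (is.data.frame(x)) {
    need <- c("row", "col", "thickness_um")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      problems <- c(problems, paste("missing columns:",
                                    paste(miss, collapse = ", ")))
    } else {
      key <- paste(x$row, x$col, sep = ".")
      all_key <- paste(rep(1:8, each = 8L), rep(1:8, times = 8L), sep = ".")
      dup <- unique(key[duplicated(key)])
      if (length(dup)) {
        problems <- c(problems, sprintf("duplicate address at cell %s", dup))
      }
      absent <- setdiff(all_key, key)
      if (length(absent)) {
        problems <- c(problems, sprintf("missing cell %s", absent))
      }
      extra <- setdiff(key, all_key)
      if (length(extra)) {
        problems <- c(problems, sprintf("address out of range: %s", extra))
      }
      bad <- !is.finite(x$thickness_um) | x$thickness_um < 0
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "non-finite or negative thickness at cell %s", key[bad]))
      }
    }
  } else {
    problems <- "input is neither a thickness_grid nor a data.frame"
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Orient grid values for rendering
#'
#' The grid nomenclature is specular between eyes (cell 1.1 is
#' inferior-temporal in both), so stored addresses never change with
#' laterality. For display, left-eye maps are conventionally shown in
#' right-eye format, which amounts to mirroring the horizontal (column) axis
#' of the rendering only. Row order is kept as stored (row 1 = inferior);
#' plotting code places higher row numbers towards the top of the image.
#'
#' @param x A `thickness_grid`, or an 8x8 matrix together with `laterality`.
#' @param laterality Used only when `x` is a bare matrix.
#' @return An 8x8 matrix of display values: identical to storage for right
#'   eyes, column-mirrored for left eyes.
#' @export
display_orientation <- function(x, laterality = NULL) {
  if (inherits(x, "thickness_grid")) {
    m <- x$values
    laterality <- x$laterality
  } else if (is.matrix(x) && all(dim(x) == c(8L, 8L))) {
    m <- x
    if (is.null(laterality)) {
      stop("laterality is required when passing a bare matrix", call. = FALSE)
    }
  } else {
    stop("x must be a thickness_grid or an 8x8 matrix", call. = FALSE)
  }
  assert_laterality(laterality)
  if (laterality == "left") m <- m[, 8:1, drop = FALSE]
  dimnames(m) <- list(row = as.character(1:8), col = as.character(1:8))
  m
}

#' Construct an eye record
#'
#' Container for all layer grids of a single eye, plus optional metadata
#' (age in years, sex, axial length in mm, ...).
#'
#' @param subject_id Scalar identifier.
#' @param laterality `"right"` or `"left"`.
#' @param grids Named list of `thickness_grid` objects, names being layer
#'   ids; every grid must share `subject_id` and `laterality` with the
#'   record, and at most one grid per layer is allowed.
#' @param metadata Optional named list.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(subject_id, laterality, grids, metadata = list()) {
  assert_laterality(laterality)
  subject_id <- as.character(subject_id)[1L]
  if (!is.list(grids) || is.null(names(grids)) || any(names(grids) == "")) {
    stop("grids must be a named list keyed by layer id", call. = FALSE)
  }
  if (anyDuplicated(names(grids))) {
    stop("at most one grid per layer is allowed", call. = FALSE)
  }
  for (nm in names(grids)) {
    g <- grids[[nm]]
    if (!inherits(g, "thickness_grid")) {
      stop("grids[['", nm, "']] is not a thickness_grid", call. = FALSE)
    }
    if (g$layer != nm) {
      stop("grid stored under '", nm, "' is labelled '", g$layer, "'",
           call. = FALSE)
    }
    if (g$subject_id != subject_id || g$laterality != laterality) {
      stop("grid for layer ", nm,
           " does not match the record's subject_id/laterality",
           call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, laterality = laterality,
                 grids = grids, metadata = metadata),
            class = "eye_record")
}

#' Construct a cohort
#'
#' @param eyes List of `eye_record` objects, one eye per subject.
#' @param provenance Free-text description of the cohort's origin.
#' @return An object of class `ppa_cohort`.
#' @export
cohort <- function(eyes, provenance = "") {
  if (!length(eyes)) stop("cohort must contain at least one eye", call. = FALSE)
  if (!all(vapply(eyes, inherits, logical(1L), "eye_record"))) {
    stop("all cohort elements must be eye_record objects", call. = FALSE)
  }
  ids <- vapply(eyes, function(e) e$subject_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("at most one eye per subject: duplicated subject_id ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(eyes = eyes, provenance = provenance), class = "ppa_cohort")
}

#' @export
print.ppa_cohort <- function(x, ...) {
  lat <- vapply(x$eyes, function(e) e$laterality, character(1L))
  cat(sprintf("Posterior pole cohort: %d eyes (%d right, %d left)\n",
              length(x$eyes), sum(lat == "right"), sum(lat == "left")))
  if (nzchar(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf("8x8 thickness grid: subject %s, %s eye, layer %s\n",
              x$subject_id, x$laterality, x$layer))
  print(round(x$values, 1))
  invisible(x)
}
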