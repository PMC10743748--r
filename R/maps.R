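#' Build a significance-masked deviation map from pair summaries
#'
#' Converts the 32 pair summaries of one layer into a cell-wise map in which
#' each corresponding pair's mean difference d (inferior minus superior) is
#' attributed half to each member: +d/2 at the inferior cell and -d/2 at the
#' superior cell, so the map is exactly antisymmetric across the horizontal
#' midline and each hemisphere shows its own thickness excess. The mask
#' marks pairs without a significant paired-test difference; masked pairs
#' are drawn in black.
#'
#' @param summaries A 32-row data.frame as returned by
#'   [pairwise_summary_table()] for a single layer.
#' @return An object of class `deviation_map`: list with `layer`, `values`
#'   (8x8 matrix of signed half-differences, microns) and `mask` (8x8
#'   logical matrix, `TRUE` = significant).
#' @export
deviation_map <- function(summaries) {
  need <- c("layer", "inf_row", "inf_col", "sup_row", "sup_col",
            "mean_diff_um", "significant")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries))) {
    stop("summaries must be a pairwise_summary_table data.frame",
         call. = FALSE)
  }
  key <- paste(summaries$inf_row, summaries$inf_col)
  p <- cell_pairs()
  if (nrow(summaries) != 32L ||
      !setequal(key, paste(p$inf_row, p$inf_col)) ||
      length(unique(summaries$layer)) != 1L) {
    stop("summaries must contain exactly the 32 pairs of one layer",
         call. = FALSE)
  }
  values <- matrix(0, 8L, 8L)
  mask <- matrix(FALSE, 8L, 8L)
  half <- summaries$mean_diff_um / 2
  values[cbind(summaries$inf_row, summaries$inf_col)] <- half
  values[cbind(summaries$sup_row, summaries$sup_col)] <- -half
  mask[cbind(summaries$inf_row, summaries$inf_col)] <- summaries$significant
  mask[cbind(summaries$sup_row, summaries$sup_col)] <- summaries$significant
  structure(list(layer = summaries$layer[1L], values = values, mask = mask),
            class = "deviation_map")
}

# Long-format display data for an 8x8 matrix: x = display column, y = row
# (1 = bottom/inferior, 8 = top/superior).
display_df <- function(values, laterality = "right", mask = NULL) {
  disp <- display_orientation(values, laterality)
  df <- data.frame(x = rep(1:8, each = 8L), y = rep(1:8, times = 8L),
                   value = as.vector(disp))
  if (!is.null(mask)) {
    dm <- display_orientation(mask * 1, laterality)
    df$masked <- as.vector(dm) == 0
  }
  df
}

#' Render a significance-masked asymmetry heatmap
#'
#' 8x8 tile raster: red = thickening, blue = thinning (colour scale
#' symmetric about zero), non-significant pairs black, and a green line on
#' the horizontal midline between rows 4 and 5. Left-eye data are mirrored
#' into right-eye display format.
#'
#' @param map A [deviation_map()].
#' @param path Optional output file (PNG/SVG, chosen by extension); when
#'   `NULL` the plot object is returned without writing.
#' @param laterality Display laterality of the underlying data.
#' @param overlay Print the signed deviation (microns) in each unmasked
#'   cell.
#' @param limit Colour-scale limit in microns; default: max absolute
#'   deviation (minimum 1) so equal magnitudes get equal saturation.
#' @param width,height Device size in inches when writing to `path`.
#' @return The ggplot object, invisibly.
#' @export
render_heatmap <- function(map, path = NULL, laterality = "right",
                           overlay = FALSE, limit = NULL,
                           width = 4, height = 4) {
  if (!inherits(map, "deviation_map")) {
    stop("map must be a deviation_map", call. = FALSE)
  }
  df <- display_df(map$values, laterality, mask = map$mask)
  limit <- limit %||% max(1, max(abs(df$value)))
  df$fill_value <- ifelse(df$masked, NA_real_, df$value)
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = fill_value),
                       colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, limits = c(-limit, limit),
                                  na.value = "black",
                                  name = "half diff (µm)") +
    ggplot2::geom_hline(yintercept = 4.5, colour = "green", linewidth = 1.5) +
    ggplot2::coord_fixed() +
    ggplot2::scale_x_continuous(breaks = 1:8, expand = c(0, 0)) +
    ggplot2::scale_y_continuous(breaks = 1:8, expand = c(0, 0)) +
    ggplot2::labs(title = paste0(map$layer, " superior-inferior asymmetry"),
                  x = "column (temporal → nasal, right-eye format)",
                  y = "row (inferior → superior)") +
    ggplot2::theme_minimal()
  if (overlay) {
    df$lab <- ifelse(df$masked, "", sprintf("%.1f", df$value))
    plt <- plt + ggplot2::geom_text(ggplot2::aes(label = lab), size = 2.6,
                                    data = df)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, plt, width = width, height = height, dpi = 150)
  }
  invisible(plt)
}

#' Per-eye pair asymmetry magnitudes on the device's 30-micron scale
#'
#' For one eye and layer, computes |inferior - superior| for each
#' corresponding pair and assigns the magnitude to both member cells,
#' clamped at the device display ceiling (30 um by default): differences at
#' or beyond the ceiling render at full scale.
#'
#' @param eye An `eye_record`.
#' @param layer One of [layer_ids()].
#' @param clamp_um Display ceiling in microns.
#' @return 8x8 numeric matrix of clamped absolute pair differences.
#' @export
device_asymmetry <- function(eye, layer, clamp_um = 30) {
  d <- cell_pair_differences(eye, layer)
  a <- pmin(abs(d$diff_um), clamp_um)
  m <- matrix(0, 8L, 8L)
  m[cbind(d$inf_row, d$inf_col)] <- a
  m[cbind(d$sup_row, d$sup_col)] <- a
  m
}

#' Render a device-style grayscale asymmetry map for one eye
#'
#' Emulates the instrument's per-eye asymmetry display: a grayscale 8x8 map
#' of absolute corresponding-cell differences on a linear 0-30 um ramp
#' (white = no asymmetry, black = 30 um or more), shown in right-eye format.
#'
#' @inheritParams device_asymmetry
#' @param path Optional output image path.
#' @param width,height Device size in inches when writing to `path`.
#' @return The ggplot object, invisibly.
#' @export
device_style_map <- function(eye, layer, path = NULL, clamp_um = 30,
                             width = 4, height = 4) {
  m <- device_asymmetry(eye, layer, clamp_um)
  df <- display_df(m, eye$laterality)
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = value), colour = "grey70") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, clamp_um),
                                 name = "|diff| (µm)") +
    ggplot2::geom_hline(yintercept = 4.5, colour = "green", linewidth = 1) +
    ggplot2::coord_fixed() +
    ggplot2::scale_x_continuous(breaks = 1:8, expand = c(0, 0)) +
    ggplot2::scale_y_continuous(breaks = 1:8, expand = c(0, 0)) +
    ggplot2::labs(title = sprintf("%s asymmetry, subject %s (%s eye)",
                                  layer, eye$subject_id, eye$laterality),
                  x = "column (right-eye format)", y = "row") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, plt, width = width, height = height, dpi = 150)
  }
  invisible(plt)
}
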