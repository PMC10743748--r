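# Machine-readable run log: enough to reproduce a run byte-identically.
write_run_log <- function(out_dir, step, params) {
  log <- c(list(step = step,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package_version = as.character(utils::packageVersion("ppasym")),
                r_version = as.character(getRversion())),
           params)
  jsonlite::write_json(log, file.path(out_dir, paste0(step, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()]: writes the cohort as a single long-format grid
#' CSV plus a manifest, lesion ground-truth labels (when lesions are
#' configured) and a JSON run log recording the seed and calibration.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the generated `cohort` and the written
#'   file paths.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  co <- generate_cohort(config)
  grid_file <- file.path(out_dir, "cohort_grids.csv")
  write_grid_csv(co, grid_file)
  manifest_file <- file.path(out_dir, "manifest.csv")
  write_manifest("cohort_grids.csv", manifest_file)
  files <- list(grids = grid_file, manifest = manifest_file)
  labels <- attr(co, "lesion_labels")
  if (!is.null(labels)) {
    files$lesion_labels <- file.path(out_dir, "lesion_labels.csv")
    utils::write.csv(labels, files$lesion_labels, row.names = FALSE,
                     quote = FALSE)
  }
  write_run_log(out_dir, "simulate",
                list(n_eyes = config$n_eyes, seed = config$seed,
                     right_fraction = config$right_fraction,
                     spatial_profile = config$spatial_profile,
                     calibration = config$calibration,
                     n_lesions = length(config$lesions)))
  invisible(list(cohort = co, files = files))
}

#' Run the asymmetry analysis over a cohort
#'
#' For every requested layer: the 32-pair summary table (one CSV per layer),
#' the hemisphere-level summary (one CSV over all layers, two rows per
#' layer with the paired hemisphere test's p-value), and a
#' significance-masked asymmetry heatmap (PNG per layer).
#'
#' @param x A `ppa_cohort`, or a path to a manifest or grid CSV.
#' @param out_dir Output directory.
#' @param layers Layers to analyse (default all present in every eye).
#' @param alpha Two-sided significance level.
#' @param adjust Multiple-comparison adjustment across each layer's 32
#'   pairs: "none", "holm" or "bh".
#' @param render Write heatmap PNGs (default TRUE).
#' @return Invisibly, a list with `pair_tables` (named by layer),
#'   `hemispheres` (data.frame) and the output paths.
#' @export
run_analyze <- function(x, out_dir, layers = NULL, alpha = 0.05,
                        adjust = "none", render = TRUE) {
  co <- as_cohort_input(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  present <- Reduce(intersect, lapply(co$eyes, function(e) names(e$grids)))
  layers <- layers %||% intersect(layer_ids(), present)
  missing <- setdiff(layers, present)
  if (length(missing)) {
    culprit <- Find(function(e) !all(layers %in% names(e$grids)), co$eyes)
    stop("layer(s) ", paste(missing, collapse = ", "),
         " not present in every eye (e.g. eye ", culprit$subject_id, ")",
         call. = FALSE)
  }
  pair_tables <- list()
  hemi <- list()
  for (l in layers) {
    tab <- pairwise_summary_table(co, l, alpha = alpha, adjust = adjust)
    pair_tables[[l]] <- tab
    utils::write.csv(tab, file.path(out_dir, sprintf("pairs_%s.csv", l)),
                     row.names = FALSE, quote = FALSE)
    hs <- hemisphere_summary(co, l)
    ht <- attr(hs, "paired_test")
    hs$p_hemisphere <- if (is.null(ht)) NA_real_ else ht$p_value
    hemi[[l]] <- hs
    if (render) {
      render_heatmap(deviation_map(tab),
                     path = file.path(out_dir, sprintf("heatmap_%s.png", l)))
    }
  }
  hemispheres <- do.call(rbind, hemi)
  rownames(hemispheres) <- NULL
  utils::write.csv(hemispheres, file.path(out_dir, "hemispheres.csv"),
                   row.names = FALSE, quote = FALSE)
  write_run_log(out_dir, "analyze",
                list(n_eyes = length(co$eyes), layers = layers, alpha = alpha,
                     adjust = adjust, render = render))
  invisible(list(pair_tables = pair_tables, hemispheres = hemispheres,
                 out_dir = out_dir))
}

#' Build and save a normative database from a cohort
#'
#' @param x A `ppa_cohort`, or a path to a manifest or grid CSV.
#' @param out_file Output JSON path for the database.
#' @param layers Layers to include (default all ten).
#' @return Invisibly, the `normative_db`.
#' @export
run_build_norms <- function(x, out_file, layers = layer_ids()) {
  co <- as_cohort_input(x)
  db <- build_normative_database(co, layers = layers)
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  save_database(db, out_file)
  write_run_log(dirname(out_file), "build_norms",
                list(n_eyes = length(co$eyes), layers = layers,
                     out_file = out_file))
  invisible(db)
}

#' Classify eyes against a normative database
#'
#' @param x A `ppa_cohort`, an `eye_record`, or a path to a manifest or grid
#'   CSV containing the eyes to classify.
#' @param db A `normative_db` or a path to a database JSON.
#' @param out_file Optional CSV path for the combined report.
#' @return A data.frame: one row per (eye, layer, inferior cell) with a
#'   `subject_id` column prepended to the [classify_eye()] columns.
#' @export
run_classify <- function(x, db, out_file = NULL) {
  if (is.character(db)) db <- load_database(db)
  if (inherits(x, "eye_record")) x <- cohort(list(x))
  co <- as_cohort_input(x)
  report <- do.call(rbind, lapply(co$eyes, function(e) {
    layers <- intersect(names(e$grids), unique(db$entries$layer))
    cbind(subject_id = e$subject_id, classify_eye(e, db, layers = layers))
  }))
  rownames(report) <- NULL
  if (!is.null(out_file)) {
    dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, out_file, row.names = FALSE, quote = FALSE)
  }
  report
}

as_cohort_input <- function(x) {
  if (inherits(x, "ppa_cohort")) return(x)
  if (is.character(x) && length(x) == 1L) {
    header <- names(utils::read.csv(x, nrows = 1L))
    if ("file" %in% header) return(read_manifest(x))
    return(read_grid_csv(x))
  }
  stop("expected a ppa_cohort or a path to a manifest/grid CSV",
       call. = FALSE)
}
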