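# Hemisphere-level pooled mean +/- SD (microns) per layer in a healthy adult
# reference population; the calibration source for the simulator.
table1_reference <- function() {
  data.frame(
    layer = c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "RPE",
              "INNER", "OUTER", "RETINA"),
    superior_mean = c(38.76, 33.05, 27.79, 31.61, 26.20, 55.54, 13.03,
                      215.92, 78.61, 294.53),
    inferior_mean = c(46.33, 32.89, 26.77, 31.43, 27.14, 51.98, 12.57,
                      216.62, 77.00, 293.61),
    superior_sd = c(25.03, 10.34, 8.21, 5.88, 5.12, 11.08, 2.49,
                    33.27, 3.65, 34.46),
    inferior_sd = c(30.36, 10.88, 8.66, 6.39, 6.26, 11.74, 2.22,
                    33.58, 3.81, 34.96))
}

#' Default layer calibration for the cohort simulator
#'
#' Hemisphere means are taken from published healthy-adult reference values
#' for the ten layers. The published SDs pool between-subject and spatial
#' (cell-to-cell) variation, which the publication does not decompose; the
#' simulator therefore splits each layer's mean printed SD into derived
#' settings: a between-subject random-effect scale (`subject_sd`, 20% of the
#' printed SD), an independent per-cell noise scale (`cell_sd`, 35%), and a
#' deterministic smooth spatial gradient carrying the remainder
#' (`spatial_sd`). The spatial component is additionally capped at 35% of
#' the smaller hemisphere mean so that a Gaussian thickness model cannot
#' produce negative base thicknesses; the cap only binds for RNFL, whose
#' true spatial distribution is strongly right-skewed.
#'
#' @param subject_frac,noise_frac Fractions of the printed SD assigned to
#'   the subject random effect and to per-cell noise.
#' @return A data.frame with one row per layer: `layer`, `superior_mean`,
#'   `inferior_mean`, `subject_sd`, `cell_sd`, `spatial_sd` (all microns).
#' @export
default_calibration <- function(subject_frac = 0.20, noise_frac = 0.35) {
  ref <- table1_reference()
  sd_bar <- (ref$superior_sd + ref$inferior_sd) / 2
  subject_sd <- subject_frac * sd_bar
  cell_sd <- noise_frac * sd_bar
  spatial_sd <- sqrt(pmax(sd_bar^2 - subject_sd^2 - cell_sd^2, 0))
  spatial_sd <- pmin(spatial_sd, 0.35 * pmin(ref$superior_mean,
                                             ref$inferior_mean))
  data.frame(layer = ref$layer,
             superior_mean = ref$superior_mean,
             inferior_mean = ref$inferior_mean,
             subject_sd = subject_sd,
             cell_sd = cell_sd,
             spatial_sd = spatial_sd)
}

#' Specify a focal lesion for simulation
#'
#' A lesion adds a fixed thickness offset (negative = thinning) to a set of
#' cells of one layer in a random subset of eyes, providing ground truth for
#' classifier evaluation.
#'
#' @param layer Target layer.
#' @param cells data.frame with columns `row`, `col` (addresses in 1..8).
#' @param delta_um Thickness change in microns (may be negative).
#' @param affected_fraction Fraction of eyes to lesion, in `[0, 1]`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(layer, cells, delta_um, affected_fraction) {
  assert_layer(layer)
  if (!is.data.frame(cells) || !all(c("row", "col") %in% names(cells))) {
    stop("cells must be a data.frame with columns row and col", call. = FALSE)
  }
  assert_address(cells$row, cells$col)
  if (!is.finite(delta_um)) stop("delta_um must be finite", call. = FALSE)
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop("affected_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(layer = layer, cells = cells[, c("row", "col")],
                 delta_um = delta_um, affected_fraction = affected_fraction),
            class = "lesion_spec")
}

#' Cohort simulation configuration
#'
#' @param n_eyes Number of eyes (one per subject), default 300.
#' @param right_fraction Fraction of right eyes, default 0.51.
#' @param calibration Per-layer means/variance components as returned by
#'   [default_calibration()]; a subset of layers is allowed.
#' @param spatial_profile `"smooth-gradient"` (default) adds a deterministic
#'   pericentral thickness mound, standardised to zero mean and exactly
#'   `spatial_sd` within each hemisphere so hemisphere-level calibration is
#'   unaffected; `"flat"` omits it.
#' @param noise_sd Optional global override (microns) of the per-layer
#'   `cell_sd`; `NULL` (default) uses the calibration values.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @param lesions Optional list of [lesion_spec()] objects.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 300L, right_fraction = 0.51,
                          calibration = default_calibration(),
                          spatial_profile = c("smooth-gradient", "flat"),
                          noise_sd = NULL, seed = 1L, lesions = NULL) {
  spatial_profile <- match.arg(spatial_profile)
  if (!is.numeric(n_eyes) || n_eyes < 1L || n_eyes != as.integer(n_eyes)) {
    stop("n_eyes must be a positive integer", call. = FALSE)
  }
  if (right_fraction < 0 || right_fraction > 1) {
    stop("right_fraction must be in [0, 1]", call. = FALSE)
  }
  need <- c("layer", "superior_mean", "inferior_mean", "subject_sd",
            "cell_sd", "spatial_sd")
  if (!is.data.frame(calibration) || !all(need %in% names(calibration))) {
    stop("calibration must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (l in calibration$layer) assert_layer(l)
  if (anyDuplicated(calibration$layer)) {
    stop("duplicated layer in calibration", call. = FALSE)
  }
  with(calibration, {
    if (any(superior_mean <= 0) || any(inferior_mean <= 0)) {
      stop("calibration means must be positive", call. = FALSE)
    }
    if (any(subject_sd < 0) || any(cell_sd < 0) || any(spatial_sd < 0)) {
      stop("calibration SD components must be non-negative", call. = FALSE)
    }
  })
  if (!is.null(noise_sd) && (!is.finite(noise_sd) || noise_sd < 0)) {
    stop("noise_sd must be a non-negative number or NULL", call. = FALSE)
  }
  if (!is.null(lesions)) {
    if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
    if (!all(vapply(lesions, inherits, logical(1L), "lesion_spec"))) {
      stop("lesions must be a list of lesion_spec objects", call. = FALSE)
    }
  }
  structure(list(n_eyes = as.integer(n_eyes),
                 right_fraction = right_fraction,
                 calibration = calibration,
                 spatial_profile = spatial_profile,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 lesions = lesions),
            class = "cohort_config")
}

# Evaluate expr under a fixed seed, leaving the caller's RNG state intact.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic pericentral mound, standardised within each hemisphere to
# mean 0 and sample SD 1 over its 32 cells. Midline-symmetric by
# construction, so it cancels exactly in corresponding-cell differences.
spatial_pattern <- function() {
  r <- matrix(rep(1:8, times = 8L), 8L, 8L)
  c_ <- matrix(rep(1:8, each = 8L), 8L, 8L)
  p <- exp(-((r - 4.5)^2 + (c_ - 4.5)^2) / 18)
  for (rows in list(1:4, 5:8)) {
    block <- p[rows, ]
    p[rows, ] <- (block - mean(block)) / stats::sd(as.vector(block))
  }
  p
}

#' Generate a synthetic posterior-pole cohort
#'
#' Simulates `n_eyes` eyes with all calibrated layers. For eye e, layer l
#' and cell a: value = hemisphere mean of l + optional spatial gradient
#' (zero mean within each hemisphere) + subject effect b_el ~ N(0,
#' subject_sd^2) + cell noise ~ N(0, cell_sd^2), floored at 0 um (the floor
#' is essentially never hit under the default calibration). The expected
#' pooled hemisphere mean equals the calibration mean. Identical
#' configurations (including seed) generate identical cohorts; lesions are
#' drawn from a separate seed sub-stream so toggling them does not perturb
#' base thicknesses.
#'
#' @param config A [cohort_config()].
#' @return A `ppa_cohort`. When the config contains lesions, the lesion
#'   ground truth is attached as attribute `lesion_labels` (see
#'   [inject_lesions()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  cal <- config$calibration
  n <- config$n_eyes
  grad <- if (config$spatial_profile == "smooth-gradient") spatial_pattern()
          else matrix(0, 8L, 8L)
  id_width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("S%0", id_width, "d"), seq_len(n))

  co <- with_seed(config$seed, {
    n_right <- round(config$right_fraction * n)
    lat <- sample(c(rep("right", n_right), rep("left", n - n_right)))
    layer_values <- list()
    for (i in seq_len(nrow(cal))) {
      l <- cal$layer[i]
      base <- matrix(0, 8L, 8L)
      base[1:4, ] <- cal$inferior_mean[i]
      base[5:8, ] <- cal$superior_mean[i]
      base <- base + cal$spatial_sd[i] * grad
      cell_sd <- config$noise_sd %||% cal$cell_sd[i]
      b <- stats::rnorm(n, 0, cal$subject_sd[i])
      noise <- matrix(stats::rnorm(n * 64L, 0, cell_sd), nrow = 64L)
      vals <- as.vector(base) + rep(b, each = 64L) + as.vector(noise)
      layer_values[[l]] <- matrix(pmax(vals, 0), nrow = 64L)
    }
    eyes <- lapply(seq_len(n), function(e) {
      grids <- lapply(cal$layer, function(l) {
        m <- matrix(layer_values[[l]][, e], 8L, 8L)
        thickness_grid(ids[e], l, lat[e], m)
      })
      names(grids) <- cal$layer
      eye_record(ids[e], lat[e], grids)
    })
    cohort(eyes, provenance = sprintf(
      "synthetic cohort: n=%d, seed=%d, profile=%s", n, config$seed,
      config$spatial_profile))
  })

  if (!is.null(config$lesions)) {
    lesioned <- inject_lesions(co, config$lesions,
                               seed = (config$seed + 1000003L) %% .Machine$integer.max)
    co <- lesioned$cohort
    attr(co, "lesion_labels") <- lesioned$labels
  }
  co
}

#' Inject focal lesions into a cohort
#'
#' Adds each lesion's thickness offset to the specified cells of a randomly
#' chosen `round(affected_fraction * n)` eyes (thickness floored at 0), and
#' returns per-eye, per-cell ground truth for classifier evaluation.
#'
#' @param cohort A `ppa_cohort`.
#' @param lesions A [lesion_spec()] or list thereof.
#' @param seed Integer seed for the eye-selection draw.
#' @return A list with `cohort` (the modified cohort) and `labels`, a
#'   data.frame with columns `subject_id`, `layer`, `row`, `col`,
#'   `delta_um`, one row per lesioned cell of each affected eye (zero rows
#'   when no eye is affected).
#' @export
inject_lesions <- function(cohort, lesions, seed = 1L) {
  if (!inherits(cohort, "ppa_cohort")) {
    stop("cohort must be a ppa_cohort", call. = FALSE)
  }
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (!all(vapply(lesions, inherits, logical(1L), "lesion_spec"))) {
    stop("lesions must be lesion_spec objects", call. = FALSE)
  }
  n <- length(cohort$eyes)
  labels <- list()
  cohort <- with_seed(seed, {
    for (spec_ in lesions) {
      n_aff <- round(spec_$affected_fraction * n)
      affected <- sort(sample.int(n, n_aff))
      for (e in affected) {
        eye <- cohort$eyes[[e]]
        if (is.null(eye$grids[[spec_$layer]])) {
          stop("eye ", eye$subject_id, " has no grid for lesion layer ",
               spec_$layer, call. = FALSE)
        }
        v <- eye$grids[[spec_$layer]]$values
        idx <- cbind(spec_$cells$row, spec_$cells$col)
        v[idx] <- pmax(v[idx] + spec_$delta_um, 0)
        cohort$eyes[[e]]$grids[[spec_$layer]]$values <- v
        labels[[length(labels) + 1L]] <- data.frame(
          subject_id = eye$subject_id, layer = spec_$layer,
          row = spec_$cells$row, col = spec_$cells$col,
          delta_um = spec_$delta_um)
      }
    }
    cohort
  })
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(subject_id = character(), layer = character(),
               row = integer(), col = integer(), delta_um = numeric())
  list(cohort = cohort, labels = labels)
}

#' Read a cohort configuration from JSON or YAML
#'
#' The file mirrors [cohort_config()]'s arguments: scalar fields `n_eyes`,
#' `right_fraction`, `spatial_profile`, `noise_sd`, `seed`; an optional
#' `calibration` array of per-layer records (defaults to
#' [default_calibration()]); and an optional `lesions` array of records with
#' fields `layer`, `delta_um`, `affected_fraction` and `cells` (array of
#' `{row, col}`). YAML support requires the yaml package.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `cohort_config`.
#' @export
cohort_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("config file must be .json, .yml or .yaml", call. = FALSE)
  }
  args <- list()
  for (f in c("n_eyes", "right_fraction", "spatial_profile", "noise_sd",
              "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$calibration)) {
    args$calibration <- as.data.frame(raw$calibration)
  }
  if (!is.null(raw$lesions)) {
    lesions <- raw$lesions
    if (is.data.frame(lesions)) lesions <- split(lesions, seq_len(nrow(lesions)))
    args$lesions <- lapply(lesions, function(ls) {
      ls <- as.list(ls)
      cells <- as.data.frame(ls$cells)
      if (is.list(ls$cells) && !is.data.frame(ls$cells) &&
          !is.null(ls$cells[[1L]])) {
        cells <- do.call(rbind, lapply(ls$cells, as.data.frame))
      }
      lesion_spec(ls$layer, cells, ls$delta_um, ls$affected_fraction)
    })
  }
  do.call(cohort_config, args)
}
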