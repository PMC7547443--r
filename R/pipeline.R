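#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list: E-state switches
#' (`perturbation_sign`, `distance_power`), reduction switches
#' (`ring_mode`, `centroid`), matching parameters (`u`, `cutoff`),
#' screening `thresholds`, and I/O paths. The list serialises losslessly
#' to YAML via [write_config()] / [read_config()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    input = NULL, activity = NULL, output_dir = ".",
    u = 0.95, cutoff = 0.15,
    ring_mode = "fused_system", centroid = "mass",
    perturbation_sign = "difference", distance_power = 2,
    thresholds = c(0.90, 0.80, 0.70),
    matrix_digits = 6
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg
}

#' @rdname default_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full similarity pipeline
#'
#' Reads the structures, computes the per-atom Sstate3D table, the reduced
#' descriptor-center graphs, and the all-against-all similarity matrix;
#' when an activity table is supplied, adds the threshold screening table.
#' Artifacts are written under `config$output_dir` as `estate.csv`,
#' `reduced.json`, `matrix.csv` and `screening.csv`. Re-running with the
#' same config and inputs reproduces identical outputs.
#'
#' @param config list as from [default_config()] (or a YAML path); must at
#'   least set `input`.
#' @return invisibly, a named list of the written file paths plus the
#'   in-memory results (`mols`, `estates`, `reduced`, `matrix`,
#'   `screening`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  if (is.null(config$input)) abort("config$input must name an SDF file")
  if (!file.exists(config$input)) {
    abort(sprintf("input not found: %s", config$input))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  mols <- read_sdf(config$input)
  if (length(mols) == 0) abort("no molecules in input")

  estates <- sstate3d_table(mols, config$perturbation_sign,
                            config$distance_power)
  estate_path <- file.path(config$output_dir, "estate.csv")
  readr::write_csv(dplyr::mutate(estates, dplyr::across(
    c("i", "di", "sstate3d"), ~ round(.x, 6))), estate_path)

  reduced <- lapply(mols, function(m)
    reduce_graph(m, sstate3d(m, config$perturbation_sign,
                             config$distance_power),
                 config$ring_mode, config$centroid))
  reduced_path <- file.path(config$output_dir, "reduced.json")
  jsonlite::write_json(lapply(reduced, function(rg) list(
    molecule_id = rg$molecule_id,
    dcs = tidy(rg),
    dist = round(unclass(rg$dist), 6)
  )), reduced_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  mat <- mcphd_matrix(mols, u = config$u, cutoff = config$cutoff,
                      ring_mode = config$ring_mode,
                      centroid = config$centroid,
                      perturbation_sign = config$perturbation_sign,
                      distance_power = config$distance_power)
  matrix_path <- file.path(config$output_dir, "matrix.csv")
  mat_df <- as.data.frame(round(unclass(mat), config$matrix_digits))
  readr::write_csv(dplyr::bind_cols(tibble(id = rownames(mat)), mat_df),
                   matrix_path)

  out <- list(estate = estate_path, reduced = reduced_path,
              matrix = matrix_path, mols = mols, estates = estates,
              reduced_graphs = reduced, matrix_values = mat)

  if (!is.null(config$activity)) {
    act <- read_activity_table(config$activity)
    scr <- screening_table(mat, act, config$thresholds)
    screening_path <- file.path(config$output_dir, "screening.csv")
    readr::write_csv(scr, screening_path)
    out$screening <- screening_path
    out$screening_values <- scr
  }
  invisible(out)
}
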