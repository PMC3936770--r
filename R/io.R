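# Configuration, fixtures and output writers: the reproducibility shell
# around the simulator.

CONFIG_DEFAULTS <- list(
  L = 80, N_t = 100, generations = 100, attempt_mode = "fixed",
  island_L = 80, sea_L = 240, island_spacing = 1, sea_spacing = 10,
  alpha = 20, restrict_demethylation = TRUE,
  lower = 0.4, upper = 0.6, seed = NULL
)

#' Load a run configuration
#'
#' Reads a flat JSON configuration file and applies flag-style overrides
#' on top (overrides win). Unknown keys are rejected; unspecified keys
#' fall back to the model's defaults (island of 80 CpGs, 100 attempts per
#' CpG per generation, spacings 1/10, alpha 20, 240 sea CpGs).
#'
#' @param path Path to a JSON config file, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file.
#' @return Named list of resolved parameters (class `run_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- CONFIG_DEFAULTS
  fill <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(CONFIG_DEFAULTS))
    if (length(unknown))
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path))
    cfg <- fill(cfg, jsonlite::read_json(path, simplifyVector = TRUE),
                paste0("file '", path, "'"))
  cfg <- fill(cfg, overrides, "overrides")
  if (cfg$L < 2) stop("config error at key L: need at least 2 sites")
  if (cfg$N_t <= 0) stop("config error at key N_t: must be positive")
  if (cfg$generations < 0)
    stop("config error at key generations: must be non-negative")
  if (!(cfg$lower >= 0 && cfg$lower < cfg$upper && cfg$upper <= 1))
    stop("config error at keys lower/upper: need 0 <= lower < upper <= 1")
  structure(cfg, class = "run_config")
}

#' Ready-to-run fixture bundles
#'
#' Named preset bundles of scheme, initial states and (for the spatial
#' fixture) geometry:
#' \describe{
#'   \item{fig1b_standard}{standard scheme with strong maintenance
#'     (`h+ = 0.9`), de novo at the floor (`u+ = 1e-4`) and weak
#'     demethylation noise; converges to a mixed state from either init.}
#'   \item{fig1e_collab}{full-feedback scheme (collaborative methylation
#'     0.2, collaborative demethylation 0.05, noise floors); bistable over
#'     at least 1000 generations.}
#'   \item{fig4_spatial}{the spatial default scheme with the 80-island /
#'     240-sea geometry and island-restricted demethylation.}
#' }
#'
#' @param name Fixture name.
#' @return List with `scheme`, `init_m`, `init_u`, `config`, and for the
#'   spatial fixture `geometry` and `rules`.
#' @export
fixtures <- function(name = c("fig1b_standard", "fig1e_collab",
                              "fig4_spatial")) {
  name <- match.arg(name)
  if (name == "fig4_spatial") {
    g <- build_geometry()
    return(list(scheme = preset_scheme("spatial_default"), geometry = g,
                rules = spatial_rules(),
                init_m = spatial_state(g, island = "m", sea = "m"),
                init_u = spatial_state(g, island = "u", sea = "m"),
                config = sim_config(L = length(g$coords),
                                    record_full = TRUE)))
  }
  scheme <- switch(name,
    fig1b_standard = preset_scheme("standard"),
    fig1e_collab = preset_scheme("full_feedback")
  )
  list(scheme = scheme, init_m = island_state(80, "m"),
       init_u = island_state(80, "u"), config = sim_config())
}

#' Write a trajectory as TSV
#'
#' One row per generation: `generation`, `n_u`, `n_h`, `n_m`, `attempts`,
#' one completion-count column per reaction id, and the time-averaged
#' densities. Byte-stable for identical trajectory objects.
#'
#' @param trajectory A `cpg_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory$records, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write results with a manifest
#'
#' Writes the result's tables plus a `manifest.json` echoing the resolved
#' scheme rates, configuration, seed and package version. Trajectories
#' produce `trajectory.tsv` (plus `spacetime.txt` and `positional.tsv`
#' when full states were recorded); scans produce `scan.tsv` and
#' `summary.json`.
#'
#' @param results A `cpg_trajectory` or `cpg_scan`.
#' @param directory Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  manifest <- list(package = "cpgcollab",
                   version = as.character(utils::packageVersion("cpgcollab")))
  if (inherits(results, "cpg_trajectory")) {
    f <- file.path(directory, "trajectory.tsv")
    write_trajectory(results, f)
    files <- c(files, f)
    if (!is.null(results$full_states)) {
      f2 <- file.path(directory, "spacetime.txt")
      writeLines(results$full_states, f2)
      f3 <- file.path(directory, "positional.tsv")
      utils::write.table(positional_averages(results), f3, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f2, f3)
    }
    manifest$scheme <- as.list(results$scheme$rates)
    manifest$motif <- results$scheme$motif
    manifest$config <- results$config[c("L", "N_t", "generations",
                                        "attempt_mode")]
    manifest$seed <- results$config$seed
  } else if (inherits(results, "cpg_scan")) {
    f <- file.path(directory, "scan.tsv")
    utils::write.table(results$schemes, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    f2 <- file.path(directory, "summary.json")
    jsonlite::write_json(
      list(n_samples = results$config$n_samples,
           motif = results$config$motif$name,
           horizon = results$config$horizon,
           pass_fraction = results$pass_fraction),
      f2, auto_unbox = TRUE, digits = NA)
    files <- c(files, f2)
    manifest$config <- results$config[c("n_samples", "horizon",
                                        "replicates", "L", "N_t")]
    manifest$seed <- results$config$seed
  } else {
    stop("unsupported results object")
  }
  fm <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fm))
}
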