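# Island-in-a-sea geometry and spatially restricted collaboration.
#
# CpG coordinates are in DNA-distance units: spacing 1 between island CpGs,
# 10 between sea CpGs (reflecting the lower CpG density outside islands).
# Collaborative methylation acts locally (nearest-neighbour mediator);
# collaborative demethylation acts globally with a contact probability that
# decays as 1/(x + alpha), with mediators optionally restricted to the
# island (density-dependent recruitment of demethylases).

#' Build an island-plus-sea geometry
#'
#' Lays out `island_L` island CpGs at spacing `island_spacing` followed by
#' `sea_L` sea CpGs at spacing `sea_spacing`; the gap between the last
#' island site and the first sea site equals `sea_spacing`.
#'
#' @param island_L Number of island CpG sites.
#' @param sea_L Number of sea (non-island) CpG sites.
#' @param island_spacing DNA distance between adjacent island CpGs
#'   (default 1).
#' @param sea_spacing DNA distance between adjacent sea CpGs (default 10).
#' @param alpha Minimal distance factor in the contact kernel
#'   `1/(x + alpha)`; roughly one nucleosome spacing (default 20).
#' @return An object of class `cpg_geometry`: list with `coords`
#'   (strictly increasing site coordinates), `island` (logical membership
#'   flag per site), the spacings and `alpha`.
#' @examples
#' g <- build_geometry(80, 240)
#' length(g$coords)            # 320
#' diff(g$coords[79:81])       # 1 within the island, 10 at the boundary
#' @export
build_geometry <- function(island_L = 80, sea_L = 240, island_spacing = 1,
                           sea_spacing = 10, alpha = 20) {
  if (island_L < 0 || sea_L < 0 || island_L + sea_L < 2)
    stop("need at least 2 sites in total")
  if (island_spacing <= 0 || sea_spacing <= 0)
    stop("spacings must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  island_coords <- if (island_L > 0)
    seq(0, by = island_spacing, length.out = island_L) else numeric(0)
  last <- if (island_L > 0) island_coords[island_L] else -sea_spacing
  sea_coords <- if (sea_L > 0)
    last + seq(sea_spacing, by = sea_spacing, length.out = sea_L)
  else numeric(0)
  structure(list(coords = c(island_coords, sea_coords),
                 island = rep(c(TRUE, FALSE), c(island_L, sea_L)),
                 island_spacing = island_spacing,
                 sea_spacing = sea_spacing, alpha = alpha),
            class = "cpg_geometry")
}

#' Spatial collaboration rules
#'
#' Collaborative methylation reactions use nearest-neighbour mediators;
#' collaborative demethylation reactions draw a uniform-random mediator
#' (as in the global model) whose interaction with the target succeeds
#' with the contact probability `alpha/(x + alpha)` -- the `1/(x + alpha)`
#' looping-contact decay normalized to 1 at zero separation -- so that
#' completion keeps scaling with mediator density. With
#' `restrict_demethylation = TRUE` (the default) demethylation mediators
#' must additionally lie inside the island, modelling
#' CpG-density-dependent recruitment of demethylating enzymes.
#'
#' @param restrict_demethylation Restrict demethylation mediators to the
#'   island.
#' @return List of class `spatial_rules`.
#' @export
spatial_rules <- function(restrict_demethylation = TRUE) {
  structure(list(restrict_demethylation = restrict_demethylation),
            class = "spatial_rules")
}

#' Nearest-neighbour mediator
#'
#' Returns the left or right adjacent CpG with probability 1/2 each; a
#' chain-end target returns its unique neighbour.
#'
#' @param geometry A `cpg_geometry` (only the chain length is used).
#' @param target Target site index (1-based).
#' @return A mediator site index.
#' @export
neighbor_mediator <- function(geometry, target) {
  L <- length(geometry$coords)
  if (L < 2) stop("chain must have at least 2 sites")
  if (target == 1L) return(2L)
  if (target == L) return(L - 1L)
  if (stats::runif(1) < 0.5) target - 1L else target + 1L
}

#' Distance-weighted mediator
#'
#' Draws a mediator from `eligible` with probability proportional to
#' `1/(|coord(j) - coord(target)| + alpha)`. Eligibility filtering happens
#' before weight normalization, so any non-empty eligible set yields a
#' mediator; an empty set returns `NA` (the attempt then fails).
#'
#' @param geometry A `cpg_geometry`.
#' @param target Target site index (1-based).
#' @param eligible Integer vector of candidate mediator indices (must
#'   exclude the target).
#' @return A mediator site index, or `NA_integer_` if `eligible` is empty.
#' @examples
#' g <- build_geometry(80, 240)
#' distance_weighted_mediator(g, 1, c(10, 50))
#' @export
distance_weighted_mediator <- function(geometry, target, eligible) {
  eligible <- setdiff(as.integer(eligible), as.integer(target))
  if (length(eligible) == 0) return(NA_integer_)
  w <- 1 / (abs(geometry$coords[eligible] - geometry$coords[target]) +
              geometry$alpha)
  if (length(eligible) == 1L) return(eligible)
  sample(eligible, 1L, prob = w)
}

#' Initial state over an island-plus-sea geometry
#'
#' @param geometry A `cpg_geometry`.
#' @param island State for island sites (default `"u"`).
#' @param sea State for sea sites (default `"m"`, the hypermethylated
#'   open sea).
#' @return Island state vector over all sites.
#' @export
spatial_state <- function(geometry, island = "u", sea = "m") {
  ifelse(geometry$island, match.arg(island, SITE_STATES),
         match.arg(sea, SITE_STATES))
}

#' Simulate a spatially restricted trajectory
#'
#' As [run_trajectory()], but collaborative methylation mediators are
#' nearest neighbours on the DNA and collaborative demethylation mediators
#' are drawn with the `1/(x + alpha)` contact kernel over eligible sites
#' (matching state, and inside the island when the restriction is on).
#' Full per-site states are recorded by default for space-time output.
#'
#' @param init Initial state over all sites (see [spatial_state()]).
#' @param scheme A `reaction_scheme`.
#' @param config A [sim_config()]; its `L` is taken from the geometry.
#' @param geometry A [build_geometry()] object.
#' @param rules A [spatial_rules()] object.
#' @param thresholds Classification thresholds (island flips are judged on
#'   the whole-state level only if `stop_on_flip`; default no stopping).
#' @return A `cpg_trajectory` with `full_states` and a `geometry` field.
#' @export
run_spatial_trajectory <- function(init, scheme, config = sim_config(),
                                   geometry = build_geometry(),
                                   rules = spatial_rules(),
                                   thresholds = class_thresholds()) {
  stopifnot(inherits(scheme, "reaction_scheme"),
            inherits(geometry, "cpg_geometry"))
  if (length(init) != length(geometry$coords))
    stop("init length must match the geometry")
  cfg <- config
  cfg$L <- length(geometry$coords)
  if (is.null(cfg$record_full) || !cfg$record_full) cfg$record_full <- TRUE
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- run_core(init, scheme, cfg, geometry = geometry, rules = rules,
                  thresholds = thresholds)
  structure(list(records = res$records, init = init, scheme = scheme,
                 config = cfg, geometry = geometry, rules = rules,
                 full_states = res$full_states,
                 final_state = res$final_state, termination = "horizon"),
            class = c("cpg_spatial_trajectory", "cpg_trajectory"))
}
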