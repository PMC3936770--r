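# Stochastic simulation engine.
#
# A cell generation = one round of semiconservative DNA replication followed
# by N_t * L reaction attempts over the island. Each attempt (i) draws one
# of the 12 reactions (or a no-op) according to the per-attempt selection
# probabilities, (ii) draws a uniform-random target CpG, (iii) for
# collaborative reactions draws a mediator CpG, and completes if and only
# if target (and mediator) states match the reaction.

STATE_CODES <- c(u = 0L, h = 1L, m = 2L)

#' Create an island state
#'
#' @param L Number of CpG sites (default 80, roughly a 1 kb island).
#' @param fill Either a single state (`"u"`, `"h"`, `"m"`) used for every
#'   site, or a character vector of length `L` of per-site states.
#' @return A character vector of site states.
#' @examples
#' island_state(80, "m")
#' @export
island_state <- function(L = 80, fill = "u") {
  if (length(fill) == 1L) {
    fill <- match.arg(fill, SITE_STATES)
    rep(fill, L)
  } else {
    if (length(fill) != L) stop("fill must have length 1 or L")
    if (!all(fill %in% SITE_STATES)) stop("states must be u, h or m")
    fill
  }
}

state_to_int <- function(state) {
  if (is.integer(state)) return(state)
  if (!all(state %in% SITE_STATES)) stop("states must be u, h or m")
  unname(STATE_CODES[state])
}

int_to_state <- function(code) SITE_STATES[code + 1L]

#' Count sites per state
#'
#' @param state Island state vector.
#' @return Named integer vector `c(u=, h=, m=)`; the counts always sum to
#'   the island size.
#' @export
state_counts <- function(state) {
  c(u = sum(state == "u"), h = sum(state == "h"), m = sum(state == "m"))
}

#' Semiconservative DNA replication
#'
#' Replication maps each parental site independently: a `u` site remains
#' `u`, an `m` site becomes `h` (the new strand is unmethylated), and an
#' `h` site becomes `h` or `u` with probability 1/2 each, depending on
#' which strand the followed daughter inherits. The returned daughter
#' state therefore never contains `m` sites and never loses `u` sites.
#'
#' @param state Island state vector.
#' @return The daughter island state.
#' @examples
#' set.seed(1)
#' replicate_island(island_state(10, "m")) # all "h"
#' @export
replicate_island <- function(state) {
  out <- state
  out[state == "m"] <- "h"
  hs <- which(state == "h")
  if (length(hs))
    out[hs] <- ifelse(stats::runif(length(hs)) < 0.5, "h", "u")
  out
}

#' Simulation configuration
#'
#' @param L Island size (number of CpG sites); default 80.
#' @param N_t Mean number of reaction attempts per CpG per generation;
#'   default 100.
#' @param generations Number of generations to simulate.
#' @param attempt_mode `"fixed"` (exactly `N_t * L` attempts per
#'   generation) or `"poisson"` (Poisson-distributed with that mean). The
#'   distinction is immaterial at the default attempt budget of 8000.
#' @param record_full Record the full per-site state at the end of every
#'   generation (needed for space-time output and positional averages).
#' @param track_time_average Accumulate within-generation time-averaged
#'   u/h/m densities (attempt-weighted), alongside the end-of-generation
#'   snapshot counts.
#' @param seed Optional integer seed; when non-`NULL` the run is fully
#'   reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 80, N_t = 100, generations = 100,
                       attempt_mode = c("fixed", "poisson"),
                       record_full = FALSE, track_time_average = TRUE,
                       seed = NULL) {
  attempt_mode <- match.arg(attempt_mode)
  if (L < 2) stop("L must be at least 2")
  if (N_t <= 0) stop("N_t must be positive")
  if (generations < 0) stop("generations must be non-negative")
  structure(list(L = L, N_t = N_t, generations = generations,
                 attempt_mode = attempt_mode, record_full = record_full,
                 track_time_average = track_time_average, seed = seed),
            class = "sim_config")
}

#' Draw one reaction event
#'
#' Selects reaction `r` with probability `rate(r)` and a no-op with the
#' remaining probability `1 - sum(rates)` (the Gillespie-style discrete
#' selection among reaction channels used by each attempt).
#'
#' @param scheme A `reaction_scheme`.
#' @param n Number of independent draws.
#' @return Character vector of reaction ids, with `"noop"` for unassigned
#'   attempts.
#' @export
choose_event <- function(scheme, n = 1) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  p <- c(scheme$rates, noop = 1 - sum(scheme$rates))
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Perform a single reaction attempt
#'
#' Reference R implementation of the attempt step, independent of the
#' compiled generation loop: draws an event via [choose_event()], a
#' uniform-random target site, and (for collaborative reactions) a mediator
#' site via `mediator_sampler`; the target changes if and only if the
#' reaction applies.
#'
#' @param state Island state vector.
#' @param scheme A `reaction_scheme`.
#' @param mediator_sampler Function `(state, target)` returning a mediator
#'   site index; the default draws uniformly over all sites excluding the
#'   target (the non-spatial rule).
#' @return A list with the new `state`, `completed` (logical) and `event`
#'   (reaction id or `"noop"`).
#' @export
attempt <- function(state, scheme, mediator_sampler = NULL) {
  L <- length(state)
  if (L < 1) stop("state must be non-empty")
  if (is.null(mediator_sampler))
    mediator_sampler <- function(state, target) {
      j <- sample.int(L - 1L, 1L)
      if (j >= target) j + 1L else j
    }
  ev <- choose_event(scheme)
  if (ev == "noop")
    return(list(state = state, completed = FALSE, event = "noop"))
  cat <- reaction_catalogue()
  row <- cat[cat$id == ev, ]
  target <- sample.int(L, 1L)
  ok <- if (row$collaborative) {
    med <- mediator_sampler(state, target)
    reaction_applicability(ev, state[target], state[med])
  } else {
    reaction_applicability(ev, state[target])
  }
  if (ok) state[target] <- row$product
  list(state = state, completed = ok, event = ev)
}

# Internal bridge to the compiled generation loop. geometry/rules NULL for
# the non-spatial engine. stop_class is a classification code (0 U, 1
# intermediate, 2 M) or -1 for no early stopping.
run_core <- function(init, scheme, config, geometry = NULL, rules = NULL,
                     stop_class = -1L, thresholds = class_thresholds()) {
  spatial <- !is.null(geometry)
  res <- cpp_simulate(
    state_to_int(init), unname(scheme$rates),
    as.integer(config$generations), config$N_t,
    config$attempt_mode == "poisson", isTRUE(config$record_full),
    isTRUE(config$track_time_average), spatial,
    if (spatial) geometry$coords else numeric(0),
    if (spatial) as.integer(geometry$island) else integer(0),
    if (spatial) geometry$alpha else 0,
    spatial && isTRUE(rules$restrict_demethylation),
    as.integer(stop_class), thresholds$lower, thresholds$upper
  )
  rec <- as.data.frame(res$records)
  names(rec) <- c("generation", "n_u", "n_h", "n_m", "attempts",
                  paste0("comp_", REACTION_IDS),
                  "tavg_u", "tavg_h", "tavg_m")
  list(records = rec, final_state = int_to_state(res$final_state),
       stopped = res$stopped,
       full_states = if (isTRUE(config$record_full)) res$full_states)
}

#' Run a single generation
#'
#' Applies replication first (replication begins each generation), then the
#' generation's reaction attempts, and returns the end-of-generation state
#' together with its record.
#'
#' @param state Island state at the end of the previous generation.
#' @param scheme A `reaction_scheme`.
#' @param config A [sim_config()] (its `generations` field is ignored).
#' @return List with `state` (end-of-generation island state) and `record`
#'   (one-row data frame: counts, attempts, per-reaction completions,
#'   time-averaged densities).
#' @export
run_generation <- function(state, scheme, config = sim_config()) {
  cfg <- config
  cfg$generations <- 1L
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- run_core(state, scheme, cfg)
  list(state = res$final_state, record = res$records)
}

#' Simulate a trajectory over many generations
#'
#' Iterates [run_generation()] for the configured horizon, recording
#' end-of-generation counts, per-reaction completion counts and
#' (optionally) full site states. With `stop_on_flip = TRUE` the run stops
#' at the end of the first generation classified in the opposite state to
#' the initial classification (M-init runs stop on reaching U and vice
#' versa).
#'
#' @param init Initial island state.
#' @param scheme A `reaction_scheme`.
#' @param config A [sim_config()].
#' @param stop_on_flip Stop early when the island flips to the opposite
#'   collective state.
#' @param thresholds Classification thresholds, see [class_thresholds()].
#' @return An object of class `cpg_trajectory`: list with `records` (one
#'   row per simulated generation), `init`, `scheme`, `config`,
#'   `full_states` (or `NULL`) and `termination` (`"horizon"` or
#'   `"flipped"`).
#' @examples
#' traj <- run_trajectory(island_state(80, "m"), preset_scheme("standard"),
#'                        sim_config(generations = 30, seed = 1))
#' head(traj$records[, 1:5])
#' @export
run_trajectory <- function(init, scheme, config = sim_config(),
                           stop_on_flip = FALSE,
                           thresholds = class_thresholds()) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  if (!is.null(config$seed)) set.seed(config$seed)
  stop_class <- -1L
  if (stop_on_flip) {
    init_class <- classify(init, thresholds)
    if (init_class == "intermediate")
      stop("stop_on_flip requires an init classified as U or M")
    stop_class <- if (init_class == "M") 0L else 2L
  }
  res <- run_core(init, scheme, config, stop_class = stop_class,
                  thresholds = thresholds)
  structure(list(records = res$records, init = init, scheme = scheme,
                 config = config, full_states = res$full_states,
                 final_state = res$final_state,
                 termination = if (res$stopped) "flipped" else "horizon"),
            class = "cpg_trajectory")
}

#' @export
print.cpg_trajectory <- function(x, ...) {
  n <- nrow(x$records)
  cat("CpG island trajectory: L =", length(x$init), ", generations =", n,
      paste0("(", x$termination, ")\n"))
  if (n > 0) {
    last <- x$records[n, ]
    cat(sprintf("  final counts u/h/m: %d/%d/%d  (methylation level %.3f)\n",
                last$n_u, last$n_h, last$n_m,
                (2 * last$n_m + last$n_h) / (2 * length(x$init))))
  }
  invisible(x)
}

#' Simulate a dividing cell population
#'
#' At each division both daughters of replication are retained: the
#' hemimethylated parental pattern is resolved independently for each
#' daughter, and each daughter then undergoes a full generation of
#' reaction attempts. After `divisions` rounds the 2^divisions leaf islands
#' are returned; under the standard model the leaf methylation levels
#' spread towards an intermediate unimodal distribution, whereas bistable
#' collaborative schemes produce a mosaic of polarized M and U leaves.
#'
#' @param founder Founder island state.
#' @param scheme A `reaction_scheme`.
#' @param config A [sim_config()].
#' @param divisions Number of division rounds (>= 0).
#' @param max_divisions Safety cap (memory grows as `2^divisions`).
#' @return List with `leaves` (list of island states) and `levels`
#'   (numeric vector of leaf methylation levels).
#' @export
population_run <- function(founder, scheme, config = sim_config(),
                           divisions = 5, max_divisions = 14) {
  if (divisions < 0) stop("divisions must be non-negative")
  if (divisions > max_divisions)
    stop("divisions exceeds the configured cap (", max_divisions, ")")
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$generations <- 1L
  cfg$seed <- NULL
  cells <- list(founder)
  for (d in seq_len(divisions)) {
    nxt <- vector("list", 2L * length(cells))
    for (i in seq_along(cells)) {
      # each run_core call replicates the shared parent independently
      nxt[[2L * i - 1L]] <- run_core(cells[[i]], scheme, cfg)$final_state
      nxt[[2L * i]] <- run_core(cells[[i]], scheme, cfg)$final_state
    }
    cells <- nxt
  }
  list(leaves = cells,
       levels = vapply(cells, methylation_level, numeric(1)))
}
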