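# State classification, lifetime estimation, density/completion statistics
# and the mean-field companion of the standard model.

#' Classification thresholds
#'
#' The island's collective state is classified from its methylation level
#' `f = (2 n_m + n_h) / (2 L)` (fraction of methylated strand-sites):
#' `f < lower` is the hypomethylated U state, `f > upper` the
#' hypermethylated M state, anything between is intermediate. The defaults
#' (0.4/0.6) bracket the mixed state `u ~ m ~ 1/2` to which the standard
#' model converges, separating the two basins symmetrically.
#'
#' @param lower,upper Band limits, `0 <= lower < upper <= 1`.
#' @return List with `lower` and `upper`.
#' @export
class_thresholds <- function(lower = 0.4, upper = 0.6) {
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("need 0 <= lower < upper <= 1")
  list(lower = lower, upper = upper)
}

#' Methylation level of an island state
#'
#' @param state Island state vector (or a `cpg_trajectory`, in which case
#'   per-generation levels are computed from its records).
#' @return Fraction of methylated strand-sites, `(2 n_m + n_h) / (2 L)`.
#' @examples
#' methylation_level(island_state(80, "m")) # 1
#' @export
methylation_level <- function(state) {
  if (inherits(state, "cpg_trajectory")) return(trajectory_levels(state))
  n <- state_counts(state)
  unname((2 * n["m"] + n["h"]) / (2 * length(state)))
}

trajectory_levels <- function(traj) {
  L <- length(traj$init)
  with(traj$records, (2 * n_m + n_h) / (2 * L))
}

#' Classify an island state as U, intermediate or M
#'
#' @param x Island state vector, a methylation level in `[0, 1]`, or a
#'   `cpg_trajectory` (classified per generation).
#' @param thresholds A [class_thresholds()] object.
#' @return Character vector over `{"U", "intermediate", "M"}`.
#' @examples
#' classify(0.815)  # "M"
#' classify(0.5)    # "intermediate"
#' @export
classify <- function(x, thresholds = class_thresholds()) {
  f <- if (is.numeric(x)) x else methylation_level(x)
  ifelse(f < thresholds$lower, "U",
         ifelse(f > thresholds$upper, "M", "intermediate"))
}

#' First flip of a trajectory
#'
#' The first generation whose end-of-generation classification is the
#' state opposite to `init_class`; transitions between U and M occur
#' rapidly, so this is the natural first-passage observable.
#'
#' @param trajectory A `cpg_trajectory`.
#' @param init_class `"M"` or `"U"` (the classification of the initial
#'   state).
#' @param thresholds A [class_thresholds()] object.
#' @return List with `generation` (integer or `NA` if censored) and
#'   `censored`.
#' @export
first_flip <- function(trajectory, init_class = c("M", "U"),
                       thresholds = class_thresholds()) {
  init_class <- match.arg(init_class)
  if (nrow(trajectory$records) == 0) stop("trajectory is empty")
  cls <- classify(trajectory_levels(trajectory), thresholds)
  opposite <- if (init_class == "M") "U" else "M"
  hit <- which(cls == opposite)
  if (length(hit))
    list(generation = trajectory$records$generation[hit[1]],
         censored = FALSE)
  else
    list(generation = NA_integer_, censored = TRUE)
}

#' Censoring-aware lifetime estimate
#'
#' Estimates the expected state lifetime from replicate first-flip
#' generations, some of which may be censored at the assay horizon, via
#' the Kaplan-Meier restricted mean (restricted at the largest observed
#' time). When every replicate is censored the estimate is only a lower
#' bound (the horizon).
#'
#' @param times Numeric vector of first-flip generations (censored
#'   replicates at the horizon).
#' @param censored Logical vector, `TRUE` where the replicate never
#'   flipped.
#' @return List with `estimate`, `n`, `n_censored` and `lower_bound_only`.
#' @examples
#' estimate_lifetime(c(40, 80, 1000), c(FALSE, FALSE, TRUE))
#' @export
estimate_lifetime <- function(times, censored = rep(FALSE, length(times))) {
  if (length(times) == 0) stop("need at least one lifetime sample")
  if (length(censored) != length(times))
    stop("times and censored must have equal length")
  if (all(censored)) {
    return(list(estimate = min(times), n = length(times),
                n_censored = length(times), lower_bound_only = TRUE))
  }
  if (length(times) == 1L) {
    return(list(estimate = times, n = 1L, n_censored = 0L,
                lower_bound_only = FALSE))
  }
  fit <- survival::survfit(survival::Surv(times, !censored) ~ 1)
  tab <- summary(fit, rmean = max(times))$table
  list(estimate = unname(tab["rmean"]), n = length(times),
       n_censored = sum(censored), lower_bound_only = FALSE)
}

#' Steady-state densities of a trajectory
#'
#' Mean u/h/m fractions after a burn-in, either from end-of-generation
#' snapshot counts (`type = "snapshot"`) or from within-generation
#' time-averaged densities (`type = "time_average"`). Snapshots measure
#' the restored, pre-replication state; time averages correspond to
#' sampling cells at random cell-cycle positions, the relevant comparison
#' for hairpin-bisulfite hemimethylation data.
#'
#' @param trajectory A `cpg_trajectory`.
#' @param burn_in Generations discarded from the start.
#' @param type `"snapshot"` or `"time_average"`.
#' @return Named numeric `c(u=, h=, m=)`, summing to 1.
#' @export
steady_densities <- function(trajectory, burn_in = 0,
                             type = c("snapshot", "time_average")) {
  type <- match.arg(type)
  rec <- trajectory$records
  if (nrow(rec) <= burn_in)
    stop("trajectory must be longer than burn_in")
  rec <- rec[rec$generation > burn_in, , drop = FALSE]
  L <- length(trajectory$init)
  if (type == "snapshot") {
    c(u = mean(rec$n_u) / L, h = mean(rec$n_h) / L, m = mean(rec$n_m) / L)
  } else {
    out <- c(u = mean(rec$tavg_u), h = mean(rec$tavg_h),
             m = mean(rec$tavg_m))
    out / sum(out)
  }
}

#' Completed reactions per CpG per generation
#'
#' @param trajectory A `cpg_trajectory`.
#' @param burn_in Generations discarded from the start.
#' @return List with `per_reaction` (named numeric over the 12 reaction
#'   ids) and `total` completions per CpG per generation.
#' @export
completion_rates <- function(trajectory, burn_in = 0) {
  rec <- trajectory$records
  rec <- rec[rec$generation > burn_in, , drop = FALSE]
  if (nrow(rec) == 0) stop("no generations after burn_in")
  L <- length(trajectory$init)
  comp <- colSums(rec[, paste0("comp_", REACTION_IDS), drop = FALSE])
  per <- stats::setNames(as.numeric(comp) / (L * nrow(rec)), REACTION_IDS)
  list(per_reaction = per, total = sum(per))
}

#' Per-position time-averaged densities
#'
#' For a trajectory recorded with full site states, the per-position mean
#' occupancy of each state over post-burn-in generations (the space-time
#' summary used for island/shore/sea profiles).
#'
#' @param trajectory A `cpg_trajectory` with `full_states`.
#' @param burn_in Generations discarded from the start.
#' @return Data frame with `position` (1-based site index), `coord` (DNA
#'   coordinate when the trajectory has a geometry), `island` flag, and
#'   `u`, `h`, `m` per-position means (each row sums to 1).
#' @export
positional_averages <- function(trajectory, burn_in = 0) {
  if (is.null(trajectory$full_states))
    stop("trajectory was run without record_full; no site states available")
  states <- trajectory$full_states
  gens <- trajectory$records$generation
  keep <- gens > burn_in
  if (!any(keep)) stop("no generations after burn_in")
  states <- states[keep]
  mat <- do.call(rbind, strsplit(states, ""))
  L <- ncol(mat)
  out <- data.frame(
    position = seq_len(L),
    u = colMeans(mat == "u"),
    h = colMeans(mat == "h"),
    m = colMeans(mat == "m")
  )
  if (!is.null(trajectory$geometry)) {
    out$coord <- trajectory$geometry$coords
    out$island <- trajectory$geometry$island
  }
  out
}

#' Population bimodality summary
#'
#' Classification histogram of leaf methylation levels from a
#' [population_run()]: a bistable scheme keeps nearly all leaves polarized
#' (U or M, mosaicism), whereas the standard model accumulates
#' intermediate leaves.
#'
#' @param levels Numeric vector of leaf methylation levels (or the result
#'   of [population_run()]).
#' @param thresholds A [class_thresholds()] object.
#' @return Named numeric `c(U=, intermediate=, M=)` fractions summing
#'   to 1.
#' @export
bimodality_summary <- function(levels, thresholds = class_thresholds()) {
  if (is.list(levels) && !is.null(levels$levels)) levels <- levels$levels
  if (length(levels) == 0) stop("need at least one leaf")
  cls <- classify(levels, thresholds)
  c(U = mean(cls == "U"),
    intermediate = mean(cls == "intermediate"),
    M = mean(cls == "M"))
}

#' Generations of strict U-state purity from an all-u start
#'
#' The number of consecutive generations, counted from an all-u
#' initialization, during which the island keeps `m + h < 0.01` of total
#' CpGs at every moment (not only at end-of-generation snapshots). For an
#' 80-site island that bound means zero non-u sites, so a generation
#' preserves purity if and only if it starts pure, ends pure, and
#' completes no u-methylating reaction (`u+`, `u+m`, `u+h`) meanwhile.
#' With the de novo floor `u+ = 1e-4` purity is typically lost within a
#' couple of generations.
#'
#' @param trajectory A `cpg_trajectory` started from an all-u state.
#' @param tol Purity bound on the `(n_h + n_m) / L` fraction
#'   (default 0.01).
#' @return Integer: the number of leading pure generations (possibly 0).
#' @export
u_state_purity_span <- function(trajectory, tol = 0.01) {
  rec <- trajectory$records
  if (any(trajectory$init != "u"))
    stop("purity span is defined for an all-u initial state")
  L <- length(trajectory$init)
  end_pure <- (rec$n_h + rec$n_m) < tol * L
  no_methylation <- (rec[["comp_u+"]] + rec[["comp_u+m"]] +
                       rec[["comp_u+h"]]) == 0
  pure <- end_pure & no_methylation
  if (all(pure)) return(nrow(rec))
  which(!pure)[1] - 1L
}

#' Mean-field upper bound on the standard-model state lifetime
#'
#' For the site-independent (standard) model the expected lifetime of a
#' methylation state cannot exceed `1 / (N_t * u_plus)` generations: with
#' `N_t = 100` attempts per CpG per generation and the de novo rate at its
#' floor `u+ = 1e-4`, at most 100 generations.
#'
#' @param N_t Reaction attempts per CpG per generation.
#' @param u_plus De novo methylation rate.
#' @return The bound, in generations.
#' @examples
#' lifetime_bound(100, 1e-4) # 100
#' @export
lifetime_bound <- function(N_t, u_plus) {
  if (N_t <= 0 || u_plus <= 0) stop("N_t and u_plus must be positive")
  1 / (N_t * u_plus)
}

#' Mean-field trajectory of the standard model
#'
#' Deterministic companion of the stochastic engine for site-independent
#' schemes. Each generation applies the replication map
#' `(u, h, m) -> (u + h/2, h/2 + m, 0)` and then iterates the expected
#' per-attempt update `N_t` times (per-site exposure): mass moves u->h at
#' `u+ * u`, h->m at `h+ * h`, h->u at `h- * h` and m->h at `m- * m`.
#' Trajectories from any initial composition converge to a unique mixed
#' fixed point whenever `u+ > 0`, which is why the standard model cannot
#' hold distinct M and U states.
#'
#' @param scheme A `reaction_scheme` with all collaborative rates zero.
#' @param init Numeric `c(u, h, m)` fractions summing to 1.
#' @param generations Number of generations.
#' @param N_t Attempts per CpG per generation.
#' @return Matrix with `generations + 1` rows (row 1 = `init`) and columns
#'   `u`, `h`, `m`.
#' @examples
#' s <- preset_scheme("standard")
#' tail(meanfield_trajectory(s, c(0, 0, 1), 50), 1)
#' @export
meanfield_trajectory <- function(scheme, init, generations, N_t = 100) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  if (any(scheme$rates[COLLAB_IDS] > 0))
    stop("mean-field analysis is implemented for the standard model only")
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop("init must be (u, h, m) fractions summing to 1")
  r <- scheme$rates
  out <- matrix(NA_real_, nrow = generations + 1, ncol = 3,
                dimnames = list(NULL, c("u", "h", "m")))
  x <- as.numeric(init)
  out[1, ] <- x
  for (g in seq_len(generations)) {
    x <- c(x[1] + x[2] / 2, x[2] / 2 + x[3], 0) # replication
    for (k in seq_len(N_t)) {
      d_uh <- r[["u+"]] * x[1]
      d_hm <- r[["h+"]] * x[2]
      d_hu <- r[["h-"]] * x[2]
      d_mh <- r[["m-"]] * x[3]
      x <- c(x[1] - d_uh + d_hu,
             x[2] + d_uh + d_mh - d_hm - d_hu,
             x[3] + d_hm - d_mh)
    }
    out[g + 1, ] <- x
  }
  out
}
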