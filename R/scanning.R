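# Parameter-space scanning: random sampling of reaction schemes,
# bistability assays, pass-fraction scans, motif ablations and iterative
# refinement towards long-horizon stability.

#' Scan configuration
#'
#' @param n_samples Number of schemes to sample.
#' @param motif Motif preset name (or `motif_preset` object) constraining
#'   the sampled schemes.
#' @param horizon Assay horizon G in generations; a scheme passes if no
#'   replicate from either initialization flips before G.
#' @param replicates Replicate trajectories per initialization (default 3;
#'   guards against single lucky runs).
#' @param L,N_t Island size and attempts per CpG per generation.
#' @param rate_min Lower bound for sampled rates (default 1e-4; also the
#'   noise floor kept on `u+` and `h+`).
#' @param u_plus_max Upper bound used when sampling `u+` (drawn first; the
#'   remaining rates are bounded by `1 - u+`). Capped at 0.5 so the bound
#'   `1 - u+` never falls below `u+` itself.
#' @param thresholds Classification thresholds for flip detection.
#' @param seed Optional integer seed making the whole scan reproducible.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(n_samples = 100, motif = "full_feedback",
                        horizon = 1000, replicates = 3, L = 80, N_t = 100,
                        rate_min = 1e-4, u_plus_max = 0.5,
                        thresholds = class_thresholds(), seed = NULL) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  if (horizon < 1) stop("horizon must be at least 1")
  if (rate_min <= 0 || rate_min > u_plus_max)
    stop("rate bounds must satisfy 0 < rate_min <= u_plus_max")
  structure(list(n_samples = n_samples, motif = resolve_motif(motif),
                 horizon = horizon, replicates = replicates, L = L,
                 N_t = N_t, rate_min = rate_min, u_plus_max = u_plus_max,
                 thresholds = thresholds, seed = seed),
            class = "scan_config")
}

#' Sample a random reaction scheme
#'
#' Draws `u+` first, log-uniformly on `[rate_min, u_plus_max]`, then every
#' other unconstrained rate log-uniformly on `[rate_min, 1 - u+]`
#' (the sampling bounds used in the scans). Zero-constrained rates are 0.
#' Schemes whose rates sum above 1 are rejected and resampled so that the
#' rates remain interpretable as per-attempt selection probabilities.
#'
#' @param config A [scan_config()].
#' @return A validated `reaction_scheme`.
#' @export
sample_scheme <- function(config) {
  motif <- config$motif
  free <- setdiff(REACTION_IDS, motif$zero_constraints)
  logmin <- log10(config$rate_min)
  repeat {
    u_plus <- 10^stats::runif(1, logmin, log10(config$u_plus_max))
    rmax <- 1 - u_plus
    rates <- stats::setNames(numeric(length(free)), free)
    rates["u+"] <- u_plus
    others <- setdiff(free, "u+")
    rates[others] <- 10^stats::runif(length(others), logmin, log10(rmax))
    if (sum(rates) <= 1) break
  }
  make_scheme(rates, motif = motif)
}

#' Assay a scheme for bistability
#'
#' Runs `replicates` trajectories from the all-m and all-u initializations
#' with a flip stop rule; the assay aborts at the first observed flip
#' (which already decides failure). A scheme passes if no replicate from
#' either initialization flips within the horizon.
#'
#' @param scheme A `reaction_scheme`.
#' @param config A [scan_config()].
#' @return List of class `bistability_outcome`: `pass`, `flip_m` /
#'   `flip_u` (first-flip generations, `NA` when censored at the horizon),
#'   and `densities_m` / `densities_u` (steady snapshot densities of the
#'   first surviving replicate per init, `NULL` if that init flipped).
#' @export
bistability_assay <- function(scheme, config) {
  sim <- sim_config(L = config$L, N_t = config$N_t,
                    generations = config$horizon)
  flips <- list(m = rep(NA_real_, config$replicates),
                u = rep(NA_real_, config$replicates))
  densities <- list(m = NULL, u = NULL)
  burn <- max(1L, min(100L, config$horizon %/% 5L))
  for (init_fill in c("m", "u")) {
    init <- island_state(config$L, init_fill)
    for (r in seq_len(config$replicates)) {
      traj <- run_trajectory(init, scheme, sim, stop_on_flip = TRUE,
                             thresholds = config$thresholds)
      if (traj$termination == "flipped") {
        flips[[init_fill]][r] <-
          traj$records$generation[nrow(traj$records)]
        return(structure(list(pass = FALSE, flip_m = flips$m,
                              flip_u = flips$u,
                              densities_m = densities$m,
                              densities_u = densities$u),
                         class = "bistability_outcome"))
      }
      if (r == 1L && nrow(traj$records) > burn)
        densities[[init_fill]] <- steady_densities(traj, burn_in = burn)
    }
  }
  structure(list(pass = TRUE, flip_m = flips$m, flip_u = flips$u,
                 densities_m = densities$m, densities_u = densities$u),
            class = "bistability_outcome")
}

#' First generation at which paired M- and U-init runs lose distinction
#'
#' Runs one trajectory from all-m and one from all-u in lockstep and
#' returns the first generation at which the pair no longer maintains
#' distinct M and U classifications, i.e. the first generation where the
#' M-init run does not classify M or the U-init run does not classify U
#' (whichever state fails first, that state is no longer being
#' maintained). Standard-model schemes lose the distinction within at
#' most ~100 generations, usually ~10.
#'
#' @param scheme A `reaction_scheme`.
#' @param L,N_t Island size and attempts per CpG per generation.
#' @param max_gen Horizon; `NA` is returned if the pair stays distinct.
#' @param thresholds A [class_thresholds()] object.
#' @param chunk Generations simulated between merge checks (checks are
#'   still per generation; chunking only batches the compiled calls).
#' @return List with `generation` (or `NA`) and `censored`.
#' @export
merge_generation <- function(scheme, L = 80, N_t = 100, max_gen = 200,
                             thresholds = class_thresholds(), chunk = 20) {
  cfg <- sim_config(L = L, N_t = N_t, generations = chunk)
  state_m <- island_state(L, "m")
  state_u <- island_state(L, "u")
  done <- 0
  while (done < max_gen) {
    cfg$generations <- min(chunk, max_gen - done)
    res_m <- run_core(state_m, scheme, cfg, thresholds = thresholds)
    res_u <- run_core(state_u, scheme, cfg, thresholds = thresholds)
    lev <- function(res) (2 * res$records$n_m + res$records$n_h) / (2 * L)
    cls_m <- classify(lev(res_m), thresholds)
    cls_u <- classify(lev(res_u), thresholds)
    lost <- which(cls_m != "M" | cls_u != "U")
    if (length(lost))
      return(list(generation = done + lost[1], censored = FALSE))
    done <- done + cfg$generations
    state_m <- res_m$final_state
    state_u <- res_u$final_state
  }
  list(generation = NA_real_, censored = TRUE)
}

#' Scan random schemes for bistability
#'
#' Samples schemes via [sample_scheme()], assays each with
#' [bistability_assay()], and aggregates the pass fraction, per-reaction
#' rates and steady densities of passing schemes.
#'
#' @param config A [scan_config()].
#' @return Object of class `cpg_scan`: list with `config`, `schemes` (one
#'   row per sampled scheme: the 12 rates, `pass`, earliest flip
#'   generation per init) and `pass_fraction`.
#' @export
scan <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  rates_mat <- matrix(NA_real_, nrow = config$n_samples, ncol = 12,
                      dimnames = list(NULL, REACTION_IDS))
  pass <- logical(config$n_samples)
  flip_m <- flip_u <- rep(NA_real_, config$n_samples)
  dens <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    scheme <- sample_scheme(config)
    out <- bistability_assay(scheme, config)
    rates_mat[i, ] <- scheme$rates
    pass[i] <- out$pass
    if (any(!is.na(out$flip_m))) flip_m[i] <- min(out$flip_m, na.rm = TRUE)
    if (any(!is.na(out$flip_u))) flip_u[i] <- min(out$flip_u, na.rm = TRUE)
    dens[[i]] <- list(m = out$densities_m, u = out$densities_u)
  }
  schemes <- data.frame(rates_mat, check.names = FALSE)
  schemes$pass <- pass
  schemes$first_flip_m <- flip_m
  schemes$first_flip_u <- flip_u
  structure(list(config = config, schemes = schemes, densities = dens,
                 pass_fraction = mean(pass)),
            class = "cpg_scan")
}

#' @export
print.cpg_scan <- function(x, ...) {
  cat("Bistability scan:", nrow(x$schemes), "schemes, motif",
      x$config$motif$name, ", horizon", x$config$horizon, "\n")
  cat(sprintf("  pass fraction: %.4f (%d passing)\n", x$pass_fraction,
              sum(x$schemes$pass)))
  invisible(x)
}

#' Ablation scan
#'
#' As [scan()], with one additional reaction pinned to zero, used to ask
#' which reactions are essential for bistability (the three collaborative
#' methylation reactions are; every other collaborative reaction can be
#' removed).
#'
#' @param config A [scan_config()].
#' @param zero_id Reaction id to remove.
#' @return A `cpg_scan`.
#' @export
ablation_scan <- function(config, zero_id) {
  if (!zero_id %in% REACTION_IDS)
    stop("unknown reaction id: ", zero_id)
  if (zero_id %in% c("u+", "h+"))
    stop("non-collaborative methylation floors cannot be ablated")
  base <- config$motif
  config$motif <- resolve_motif(list(
    name = paste0(base$name, "_minus_", zero_id),
    zero_constraints = union(base$zero_constraints, zero_id)
  ))
  scan(config)
}

km_stability <- function(flips, horizon) {
  # censoring-aware mean-lifetime lower bound from pooled first-flip times
  times <- ifelse(is.na(flips), horizon, flips)
  est <- estimate_lifetime(times, is.na(flips))
  est$estimate
}

#' Iteratively refine a scheme towards longer-horizon stability
#'
#' Hill-climbing analogue of the refinement procedure that reaches
#' long-horizon stability: each step multiplies every free rate by
#' `exp(eps)` with small random `eps`, keeps zero constraints and the
#' rate-sum bound, assays the candidate, and accepts it if its
#' survival-based stability estimate does not decrease. The assay horizon
#' doubles towards `target_horizon` whenever the current scheme survives
#' the present horizon unflipped.
#'
#' @param start A `reaction_scheme` passing the initial criterion.
#' @param target_horizon Stability horizon to certify (generations).
#' @param base_horizon Initial assay horizon.
#' @param perturb_sd Standard deviation of `eps` (0 returns `start`
#'   unchanged).
#' @param budget Maximum number of candidate assays.
#' @param replicates Replicates per init in each assay.
#' @param L,N_t Island size and attempts per CpG per generation.
#' @param rate_min Rates are clamped to stay at or above this floor.
#' @param thresholds Classification thresholds.
#' @param seed Optional integer seed.
#' @return List with `scheme` (best so far), `stability` (its estimate at
#'   the final horizon), `horizon` (final assay horizon reached) and
#'   `accepted` (number of accepted moves).
#' @export
refine <- function(start, target_horizon = 1e4, base_horizon = 500,
                   perturb_sd = 0.1, budget = 40, replicates = 2,
                   L = 80, N_t = 100, rate_min = 1e-4,
                   thresholds = class_thresholds(), seed = NULL) {
  stopifnot(inherits(start, "reaction_scheme"))
  if (!is.null(seed)) set.seed(seed)
  motif <- resolve_motif(list(name = start$motif,
                              zero_constraints =
                                names(start$rates)[start$rates == 0]))
  assay <- function(scheme, horizon) {
    cfg <- scan_config(n_samples = 1, motif = motif, horizon = horizon,
                       replicates = replicates, L = L, N_t = N_t,
                       thresholds = thresholds)
    out <- bistability_assay(scheme, cfg)
    flips <- c(out$flip_m, out$flip_u)
    list(pass = out$pass, stability = km_stability(flips, horizon))
  }
  horizon <- min(base_horizon, target_horizon)
  cur <- start
  cur_assay <- assay(cur, horizon)
  if (!cur_assay$pass)
    stop("start scheme does not pass the initial criterion at horizon ",
         horizon)
  accepted <- 0L
  for (step in seq_len(budget)) {
    if (cur_assay$pass && horizon < target_horizon) {
      horizon <- min(2 * horizon, target_horizon)
      cur_assay <- assay(cur, horizon)
      next
    }
    free <- names(cur$rates)[cur$rates > 0]
    cand_rates <- cur$rates
    cand_rates[free] <- cand_rates[free] *
      exp(stats::rnorm(length(free), 0, perturb_sd))
    cand_rates[free] <- pmax(cand_rates[free], rate_min)
    cand_rates[free] <- pmin(cand_rates[free], 1 - cand_rates[["u+"]])
    if (sum(cand_rates) > 1) next
    cand <- make_scheme(cand_rates[cand_rates > 0], motif = motif)
    cand_assay <- assay(cand, horizon)
    if (cand_assay$stability >= cur_assay$stability) {
      cur <- cand
      cur_assay <- cand_assay
      accepted <- accepted + 1L
    }
  }
  list(scheme = cur, stability = cur_assay$stability, horizon = horizon,
       accepted = accepted)
}
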