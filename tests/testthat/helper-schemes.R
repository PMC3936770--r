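# Shared fixtures and the brute-force one-attempt transition oracle.

# a scheme touching all 12 reactions, used for kernel and conservation
# checks
all_reactions_scheme <- function() {
  make_scheme(c(
    "u+" = 0.05, "h+" = 0.06, "h-" = 0.04, "m-" = 0.05,
    "u+m" = 0.05, "u+h" = 0.04, "h+m" = 0.06, "h+h" = 0.05,
    "m-u" = 0.04, "m-h" = 0.05, "h-u" = 0.06, "h-h" = 0.04
  ))
}

two_site_states <- function() {
  g <- expand.grid(s1 = c("u", "h", "m"), s2 = c("u", "h", "m"),
                   stringsAsFactors = FALSE)
  g[order(g$s1, g$s2), ]
}

# Brute-force enumeration of the exact one-attempt transition matrix for a
# two-site island under the non-spatial mediator rule (the mediator is the
# other site). Built from the reaction table alone, independently of the
# compiled attempt loop.
enumerate_two_site_kernel <- function(scheme) {
  catal <- reaction_catalogue()
  grid <- two_site_states()
  states <- paste0(grid$s1, grid$s2)
  M <- matrix(0, 9, 9, dimnames = list(states, states))
  for (i in seq_len(9)) {
    s <- c(grid$s1[i], grid$s2[i])
    stay <- 1
    for (k in seq_len(12)) {
      r <- scheme$rates[[catal$id[k]]]
      if (r == 0) next
      for (t in 1:2) {
        ok <- s[t] == catal$target[k] &&
          (!catal$collaborative[k] || s[3 - t] == catal$mediator[k])
        if (ok) {
          ns <- s
          ns[t] <- catal$product[k]
          j <- match(paste0(ns[1], ns[2]), states)
          M[i, j] <- M[i, j] + r / 2
          stay <- stay - r / 2
        }
      }
    }
    M[i, i] <- M[i, i] + stay
  }
  M
}

# empirical one-attempt end-state frequencies from the compiled engine
attempt_trial_freqs <- function(init, scheme, n) {
  out <- cpgcollab:::cpp_attempt_trials(
    cpgcollab:::state_to_int(init), unname(scheme$rates), n,
    FALSE, numeric(0), integer(0), 0, FALSE)
  key <- paste0(cpgcollab:::int_to_state(out[, 1]),
                cpgcollab:::int_to_state(out[, 2]))
  states <- paste0(two_site_states()$s1, two_site_states()$s2)
  tab <- table(factor(key, levels = states))
  as.numeric(tab) / n
}

# minimal hand-built trajectory for analysis-layer tests
fake_trajectory <- function(n_u, n_h, n_m, L = 80, init_fill = "m") {
  G <- length(n_u)
  rec <- data.frame(generation = seq_len(G), n_u = n_u, n_h = n_h,
                    n_m = n_m, attempts = rep(100 * L, G))
  for (id in cpgcollab:::REACTION_IDS) rec[[paste0("comp_", id)]] <- 0
  rec$tavg_u <- n_u / L
  rec$tavg_h <- n_h / L
  rec$tavg_m <- n_m / L
  structure(list(records = rec, init = island_state(L, init_fill),
                 scheme = preset_scheme("standard"),
                 config = sim_config(L = L, generations = G),
                 full_states = NULL, termination = "horizon"),
            class = "cpg_trajectory")
}
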