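# Classification, lifetimes, densities and the mean-field companion.

test_that("methylation level counts methylated strand-sites", {
  expect_equal(methylation_level(island_state(80, "m")), 1)
  expect_equal(methylation_level(island_state(80, "u")), 0)
  expect_equal(methylation_level(c(rep("h", 40), rep("u", 40))), 0.25)
  # invariant under site permutation
  st <- sample(c(rep("m", 10), rep("h", 20), rep("u", 50)))
  expect_equal(methylation_level(st),
               methylation_level(sort(st)))
})

test_that("classification brackets the mixed state", {
  expect_equal(classify(0.815), "M")   # u=0.15 h=0.07 m=0.78
  expect_equal(classify(0.5), "intermediate")
  expect_equal(classify(1 / 160), "U") # m + h below 1% of strand-sites
  expect_equal(classify(c(0.1, 0.5, 0.9)), c("U", "intermediate", "M"))
  th <- class_thresholds(0.2, 0.8)
  expect_equal(classify(0.5, th), "intermediate")
  expect_error(class_thresholds(0.7, 0.3))
})

test_that("first flip finds the first opposite-state generation", {
  lv <- c(rep(70, 6), 20, 15, 70, 70)  # n_m; enters U at generation 7
  traj <- fake_trajectory(n_u = 80 - lv, n_h = rep(0, 10), n_m = lv)
  expect_equal(first_flip(traj, "M")$generation, 7)
  expect_false(first_flip(traj, "M")$censored)
  stay <- fake_trajectory(n_u = rep(2, 10), n_h = rep(1, 10),
                          n_m = rep(77, 10))
  expect_true(first_flip(stay, "M")$censored)
  expect_error(first_flip(stay, "Q"))
})

test_that("lifetime estimation matches a geometric oracle", {
  set.seed(30)
  times <- stats::rgeom(1000, 0.01) + 1
  est <- estimate_lifetime(times)
  expect_lt(abs(est$estimate - 100) / 100, 0.1)
  expect_false(est$lower_bound_only)
  # censoring-aware: censoring half the data should not halve the mean
  cens <- pmin(times, 150)
  est2 <- estimate_lifetime(cens, censored = times > 150)
  expect_lt(abs(est2$estimate - mean(pmin(times, 150))) , 1e-6)
  # pure censoring yields a lower bound, single samples pass through
  est3 <- estimate_lifetime(rep(1000, 5), rep(TRUE, 5))
  expect_true(est3$lower_bound_only)
  expect_equal(est3$estimate, 1000)
  expect_equal(estimate_lifetime(42)$estimate, 42)
  expect_error(estimate_lifetime(numeric(0)))
})

test_that("steady densities average the records and sum to one", {
  traj <- fake_trajectory(n_u = rep(0, 20), n_h = rep(0, 20),
                          n_m = rep(80, 20))
  expect_equal(steady_densities(traj), c(u = 0, h = 0, m = 1))
  mixed <- fake_trajectory(n_u = rep(40, 20), n_h = rep(10, 20),
                           n_m = rep(30, 20))
  expect_equal(sum(steady_densities(mixed, burn_in = 5)), 1)
  expect_equal(sum(steady_densities(mixed, type = "time_average")), 1)
  expect_error(steady_densities(mixed, burn_in = 20), "burn_in")
})

test_that("completion rates normalize by island size and horizon", {
  s <- make_scheme(c("u+" = 0))
  traj <- run_trajectory(island_state(40, "m"), s,
                         sim_config(L = 40, generations = 10, seed = 31))
  cr <- completion_rates(traj)
  expect_equal(cr$total, 0)
  s2 <- all_reactions_scheme()
  traj2 <- run_trajectory(island_state(40, "m"), s2,
                          sim_config(L = 40, generations = 20, seed = 32))
  cr2 <- completion_rates(traj2)
  expect_lte(cr2$total, 100) # cannot complete more than attempted
  expect_equal(cr2$total, sum(cr2$per_reaction))
})

test_that("maintaining M costs far more completions than maintaining U", {
  fx <- fixtures("fig1e_collab")
  tm <- run_trajectory(fx$init_m, fx$scheme,
                       sim_config(generations = 300, seed = 33))
  tu <- run_trajectory(fx$init_u, fx$scheme,
                       sim_config(generations = 300, seed = 34))
  rate_m <- completion_rates(tm, burn_in = 50)$total
  rate_u <- completion_rates(tu, burn_in = 50)$total
  expect_lt(rate_u / rate_m, 0.1)
  expect_gt(rate_m, 0.5)  # ~ a few reactions per CpG per generation
  expect_lt(rate_m, 10)
})

test_that("positional averages are per-position densities summing to 1", {
  traj <- fake_trajectory(n_u = rep(0, 5), n_h = rep(0, 5), n_m = rep(80, 5))
  traj$full_states <- rep(strrep("m", 80), 5)
  pa <- positional_averages(traj)
  expect_equal(nrow(pa), 80)
  expect_true(all(pa$m == 1))
  expect_true(all(abs(pa$u + pa$h + pa$m - 1) < 1e-12))
  traj$full_states <- NULL
  expect_error(positional_averages(traj), "record_full")
})

test_that("bimodality summary classifies leaves", {
  expect_equal(bimodality_summary(rep(1, 8)),
               c(U = 0, intermediate = 0, M = 1))
  expect_equal(bimodality_summary(c(0.05, 0.5, 0.95)),
               c(U = 1 / 3, intermediate = 1 / 3, M = 1 / 3))
  expect_error(bimodality_summary(numeric(0)))
})

test_that("u-state purity span counts strictly pure generations", {
  traj <- fake_trajectory(n_u = rep(80, 6), n_h = rep(0, 6),
                          n_m = rep(0, 6), init_fill = "u")
  expect_equal(u_state_purity_span(traj), 6)
  traj$records[["comp_u+"]][3] <- 1   # transient h within generation 3
  expect_equal(u_state_purity_span(traj), 2)
  traj2 <- fake_trajectory(n_u = c(80, 79, 80), n_h = c(0, 1, 0),
                           n_m = rep(0, 3), init_fill = "u")
  expect_equal(u_state_purity_span(traj2), 1)
  expect_error(u_state_purity_span(fake_trajectory(80, 0, 0)), "all-u")
})

test_that("the analytic lifetime bound is 1/(N_t u+)", {
  expect_equal(lifetime_bound(100, 1e-4), 100)
  expect_equal(lifetime_bound(100, 1e-2), 1)
  expect_equal(lifetime_bound(200, 1e-4), 50)
  expect_error(lifetime_bound(0, 1e-4))
  expect_error(lifetime_bound(100, 0))
})

test_that("state distinction never outlives twice the mean-field bound", {
  # longest-lived standard family: h+ near 1, minimal other noise
  set.seed(35)
  for (u_plus in c(1e-4, 1e-3, 1e-2)) {
    s <- make_scheme(c("u+" = u_plus, "h+" = 0.98, "h-" = 1e-4,
                       "m-" = 1e-4), motif = "standard")
    bound <- lifetime_bound(100, u_plus)
    spans <- replicate(5, {
      g <- merge_generation(s, max_gen = ceiling(4 * bound) + 20)$generation
      ifelse(is.na(g), 4 * bound + 20, g)
    })
    expect_lte(stats::median(spans), 2 * bound + 1)
  }
})

test_that("mean-field replication alone follows the closed form", {
  s <- make_scheme(c("u+" = 0), motif = "standard")
  mf <- meanfield_trajectory(s, c(0, 0, 1), 12)
  for (k in 1:12)
    expect_equal(unname(mf[k + 1, "u"]), 1 - 2^(1 - k), tolerance = 1e-12)
  expect_true(all(abs(rowSums(mf) - 1) < 1e-12))
})

test_that("mean-field trajectories converge to a unique mixed point", {
  s <- preset_scheme("standard")
  a <- meanfield_trajectory(s, c(1, 0, 0), 500)
  b <- meanfield_trajectory(s, c(0, 0, 1), 500)
  expect_lt(max(abs(a[501, ] - b[501, ])), 1e-6)
  expect_error(meanfield_trajectory(preset_scheme("full_feedback"),
                                    c(0, 0, 1), 10), "standard")
  expect_error(meanfield_trajectory(s, c(0.5, 0.5, 0.5), 10))
})

test_that("mean-field fixed point matches the stochastic steady state", {
  s <- preset_scheme("standard")
  fp <- meanfield_trajectory(s, c(0, 0, 1), 300)[301, ]
  traj <- run_trajectory(island_state(80, "m"), s,
                         sim_config(generations = 1500, seed = 36))
  sd_hat <- steady_densities(traj, burn_in = 200)
  expect_lt(max(abs(fp - sd_hat)), 0.02)
})
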