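# Stochastic engine: replication, attempt kernel, trajectories,
# populations.

test_that("replication maps m->h, keeps u, and splits h half-half", {
  set.seed(1)
  expect_equal(replicate_island(island_state(50, "m")),
               island_state(50, "h"))
  expect_equal(replicate_island(island_state(50, "u")),
               island_state(50, "u"))
  # replication never creates m and never destroys u
  for (i in 1:20) {
    st <- sample(c("u", "h", "m"), 40, replace = TRUE)
    daughter <- replicate_island(st)
    expect_equal(sum(daughter == "m"), 0L)
    expect_true(all(daughter[st == "u"] == "u"))
    expect_length(daughter, 40)
  }
  # h resolution is a fair coin: binomial check at L = 10^4
  daughter <- replicate_island(island_state(1e4, "h"))
  n_u <- sum(daughter == "u")
  expect_lt(abs(n_u - 5000), 4 * sqrt(1e4 * 0.25))
})

test_that("choose_event selects reactions with their rates", {
  zero <- make_scheme(c("u+" = 0))
  expect_true(all(choose_event(zero, 50) == "noop"))
  set.seed(2)
  s <- make_scheme(c("h+" = 0.5))
  draws <- choose_event(s, 1e5)
  p_hat <- mean(draws == "h+")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("single attempts complete if and only if the reaction applies", {
  set.seed(3)
  s_u <- make_scheme(c("u+" = 1))
  out <- attempt(island_state(5, "u"), s_u)
  expect_true(out$completed)
  expect_equal(sum(out$state == "h"), 1L)
  # collaborative event with no matching mediator anywhere never completes
  s_um <- make_scheme(c("u+m" = 1))
  out <- attempt(island_state(5, "u"), s_um)
  expect_false(out$completed)
  expect_equal(out$state, island_state(5, "u"))
  # two sites: mediator is forced to be the other site
  for (i in 1:20) {
    out <- attempt(c("u", "m"), s_um)
    if (out$completed) expect_equal(out$state, c("h", "m"))
    else expect_equal(out$state, c("u", "m"))
  }
})

test_that("one-attempt kernel matches the brute-force enumerated matrix", {
  s <- all_reactions_scheme()
  kernel <- enumerate_two_site_kernel(s)
  grid <- two_site_states()
  set.seed(4)
  n <- 3e4
  for (i in seq_len(9)) {
    init <- c(grid$s1[i], grid$s2[i])
    freq <- attempt_trial_freqs(init, s, n)
    p <- kernel[i, ]
    for (j in seq_len(9)) {
      if (p[j] == 0) {
        expect_equal(freq[j], 0)
      } else {
        expect_lt(abs(freq[j] - p[j]),
                  4 * sqrt(p[j] * (1 - p[j]) / n) + 1e-12)
      }
    }
  }
})

test_that("the R attempt path agrees with the enumerated kernel", {
  s <- all_reactions_scheme()
  kernel <- enumerate_two_site_kernel(s)
  set.seed(5)
  n <- 4000
  init <- c("h", "m")
  ends <- replicate(n, paste0(attempt(init, s)$state, collapse = ""))
  states <- paste0(two_site_states()$s1, two_site_states()$s2)
  freq <- as.numeric(table(factor(ends, levels = states))) / n
  i <- match("hm", states)
  for (j in seq_len(9)) {
    p <- kernel[i, j]
    expect_lt(abs(freq[j] - p), 4 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("counts are conserved through every generation", {
  s <- all_reactions_scheme()
  traj <- run_trajectory(sample(c("u", "h", "m"), 30, replace = TRUE), s,
                         sim_config(L = 30, generations = 50, seed = 6))
  with(traj$records, expect_true(all(n_u + n_h + n_m == 30)))
  with(traj$records, expect_true(all(
    rowSums(traj$records[, paste0("comp_", cpgcollab:::REACTION_IDS)]) <=
      attempts)))
})

test_that("a zero-rate scheme only replicates", {
  s <- make_scheme(c("u+" = 0))
  out <- run_generation(island_state(40, "u"), s, sim_config(L = 40))
  expect_equal(out$state, island_state(40, "u"))
  expect_equal(sum(out$record[paste0("comp_", cpgcollab:::REACTION_IDS)]),
               0)
  # from all-m: replication turns everything h, and h decays to u over
  # generations with no reactions to restore it
  traj <- run_trajectory(island_state(40, "m"), s,
                         sim_config(L = 40, generations = 30, seed = 7))
  expect_equal(traj$records$n_m[1], 0)
  expect_equal(traj$final_state, island_state(40, "u"))
})

test_that("maintenance restores methylation lost at replication", {
  s <- preset_scheme("standard")
  # strong-maintenance variant: m density is rebuilt by generation end
  strong <- make_scheme(c("u+" = 1e-4, "h+" = 0.9, "h-" = 1e-3,
                          "m-" = 1e-3), motif = "standard")
  out <- run_generation(island_state(80, "m"), strong,
                        sim_config(seed = 8))
  expect_gt(sum(out$state == "m") / 80, 0.9)
  # ... whereas immediately after replication alone n_m is zero
  expect_equal(sum(replicate_island(island_state(80, "m")) == "m"), 0L)
})

test_that("trajectories are reproducible given a seed", {
  s <- preset_scheme("full_feedback")
  cfg <- sim_config(generations = 40, record_full = TRUE, seed = 9)
  t1 <- run_trajectory(island_state(80, "m"), s, cfg)
  t2 <- run_trajectory(island_state(80, "m"), s, cfg)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$full_states, t2$full_states)
  expect_identical(t1$final_state, t2$final_state)
})

test_that("poisson attempt mode draws a variable attempt budget", {
  s <- preset_scheme("standard")
  cfg <- sim_config(generations = 40, attempt_mode = "poisson", seed = 10)
  traj <- run_trajectory(island_state(80, "u"), s, cfg)
  a <- traj$records$attempts
  expect_gt(length(unique(a)), 1L)
  expect_lt(abs(mean(a) - 8000), 4 * sqrt(8000 / 40))
})

test_that("population runs return all 2^divisions leaves", {
  s <- preset_scheme("standard")
  set.seed(11)
  pop <- population_run(island_state(20, "m"), s, sim_config(L = 20),
                        divisions = 5)
  expect_length(pop$leaves, 32L)
  expect_length(pop$levels, 32L)
  expect_true(all(pop$levels >= 0 & pop$levels <= 1))
  expect_error(population_run(island_state(20, "m"), s,
                              sim_config(L = 20), divisions = 20), "cap")
  expect_length(population_run(island_state(20, "m"), s,
                               sim_config(L = 20), divisions = 0)$leaves,
                1L)
})

test_that("standard-model populations spread towards intermediate levels", {
  fx <- fixtures("fig1b_standard")
  set.seed(12)
  v <- sapply(1:8, function(d)
    stats::var(population_run(fx$init_m, fx$scheme, sim_config(),
                              divisions = d)$levels))
  ct <- stats::cor.test(1:8, v, method = "spearman", alternative = "greater",
                        exact = FALSE)
  expect_lt(ct$p.value, 0.05)
  pop <- population_run(fx$init_m, fx$scheme, sim_config(), divisions = 10)
  frac <- bimodality_summary(pop)
  expect_gt(frac["intermediate"], max(frac["U"], frac["M"]))
})

test_that("bistable populations stay polarized", {
  fx <- fixtures("fig1e_collab")
  set.seed(13)
  pop <- population_run(fx$init_m, fx$scheme, sim_config(), divisions = 7)
  frac <- bimodality_summary(pop)
  expect_lt(frac[["intermediate"]], 0.05)
})
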