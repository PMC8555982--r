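test_that("window rates count spikes in half-open event-aligned windows", {
  events <- data.frame(trial_index = 1:3, offer_on = c(10, 20, 30))
  events$offer_off <- events$offer_on + 1
  events$target_on <- events$offer_on + 2
  events$go <- events$offer_on + 2.8
  events$juice <- events$offer_on + 3.6
  spikes <- data.frame(
    trial_index = c(rep(1, 5), 2, 2, 3),
    time = c(10.0, 10.1, 10.2, 10.3, 10.49,  # trial 1 post-offer
             20.5, 19.7,                      # trial 2: boundary + pre-offer
             33.6))                           # trial 3: post-juice start
  wr <- window_rates(spikes, events)
  po <- wr[wr$window == "post-offer", ]
  expect_equal(po$rate[po$trial_index == 1], 10)  # 5 spikes / 0.5 s
  # spike exactly at offer_on + 0.5 falls in late-delay, not post-offer
  expect_equal(po$count[po$trial_index == 2], 0L)
  ld <- wr[wr$window == "late-delay", ]
  expect_equal(ld$count[ld$trial_index == 2], 1L)
  expect_equal(wr$count[wr$window == "pre-offer" & wr$trial_index == 2], 1L)
  expect_equal(wr$count[wr$window == "post-juice" & wr$trial_index == 3], 1L)
  # no spikes anywhere else
  expect_equal(sum(wr$count), 8L)
  # missing event: trial dropped with warning
  events$go[2] <- NA
  expect_warning(wr2 <- window_rates(spikes, events), "missing event")
  expect_false(2 %in% wr2$trial_index)
})

test_that("main-effects ANOVA matches the closed-form balanced oracle", {
  set.seed(31)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
  d <- d[rep(1:8, 2), ]
  y <- rnorm(16, mean = 2 + (d$A == "a2") * 1.5 + (d$B == "b2") * 0.7)
  # balanced orthogonal design: classical sums of squares
  g <- mean(y)
  ss <- sapply(d, function(f) sum(tapply(y, f, function(v)
    length(v) * (mean(v) - g)^2)))
  ss_res <- sum((y - g)^2) - sum(ss)
  Fs <- ss / (ss_res / 12)
  p_oracle <- stats::pf(Fs, 1, 12, lower.tail = FALSE)
  p_pkg <- costchoice:::main_effects_anova(matrix(y), as.list(d))
  expect_equal(unname(drop(p_pkg)), unname(p_oracle), tolerance = 1e-12)
})

test_that("task-relatedness screen flags signal and is scale invariant", {
  cfg <- session_config(n_trials = 300, seed = 55)
  tr <- generate_session(cfg)
  pan <- compute_variables(tr, cfg$rho, cfg$xi)
  tuned <- generate_neuron(neuron_spec("chosen_value", slope = 3,
                                       baseline = 6, neuron_id = "sig"),
                           tr, pan, seed = 1)
  rel <- screen_task_related(tuned, tr)
  expect_true(all(rel$task_related))
  expect_true(all(rel$p_trial_type < 1e-5))
  # rescaling rates by a positive constant leaves p-values unchanged
  tuned2 <- tuned; tuned2$rate <- tuned2$rate * 3.7
  rel2 <- screen_task_related(tuned2, tr)
  expect_equal(rel$p_trial_type, rel2$p_trial_type, tolerance = 1e-9)
  # location-only neuron is picked up by the chosen-location factors
  loc <- generate_neuron(neuron_spec("none", location_offset = 10,
                                     baseline = 5, neuron_id = "loc"),
                         tr, pan, seed = 2)
  rel_loc <- screen_task_related(loc, tr)
  early <- rel_loc[rel_loc$window == "post-offer", ]
  expect_lt(early$p_chosen_offer_loc, 0.001)
})

test_that("constant factors yield p = 1 with a warning", {
  y <- matrix(rnorm(20))
  fac <- list(f1 = rep("x", 20), f2 = rep(c("u", "v"), 10))
  expect_warning(p <- costchoice:::main_effects_anova(y, fac), "constant")
  expect_equal(unname(p["f1", 1]), 1)
  expect_lt(p["f2", 1], 1)
})

test_that("relevance counts are internally consistent with the screen", {
  pop <- generate_population(config = session_config(n_trials = 250,
                                                     seed = 91))
  rel <- screen_task_related(pop$rates, pop$trials)
  rc <- relevance_counts(rel)
  alpha <- attr(rel, "alpha")
  # recompute one window column by hand
  w <- "late-delay"
  expect_equal(rc$by_window$p_trial_type[rc$by_window$window == w],
               sum(rel$p_trial_type[rel$window == w] < alpha))
  # "at least 1" row is the per-neuron union over windows
  u <- tapply(rel$p_chosen_target_loc < alpha, rel$neuron_id, any)
  expect_equal(as.integer(
    rc$by_window$p_chosen_target_loc[rc$by_window$window == "at least 1"]),
    sum(u))
  expect_equal(rc$n_task_related,
               length(unique(rel$neuron_id[rel$task_related])))
  expect_lte(rc$n_task_related, rc$n_neurons)
})
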