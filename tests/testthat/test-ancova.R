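test_that("parallel-lines fit matches the normal-equations oracle", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(12:40, 1)
    x <- rnorm(n)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    y <- 1 + 0.6 * x + 0.8 * g + rnorm(n)
    f <- fit_parallel(y, x, g)
    o <- ols_oracle(y, cbind(x = x, g = g))
    expect_equal(f$r2_model, o$r2, tolerance = 1e-10)
    expect_equal(f$p_factor, unname(o$p["x"]), tolerance = 1e-10)
    expect_equal(f$p_group, unname(o$p["g"]), tolerance = 1e-10)
    h <- fit_horizontal(y, g)
    oh <- ols_oracle(y, cbind(g = g))
    expect_equal(h$r2_model, oh$r2, tolerance = 1e-10)
    expect_equal(h$p_group, unname(oh$p["g"]), tolerance = 1e-10)
    # nestedness: group-only model never beats the two-regressor model
    expect_lte(h$r2_model, f$r2_model + 1e-12)
  }
})

test_that("noiseless linear responses give R2 = 1 and a null group effect", {
  x <- rep(1:6, each = 4)
  g <- rep(c(0, 1), 12)
  y <- 2 + 0.5 * x
  f <- suppressWarnings(fit_parallel(y, x, g))  # perfect-fit summary note
  expect_true(f$explains)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_lt(f$p_factor, 1e-12)
  expect_equal(f$slope_sign, 1)
  # pure group step: horizontal model explains with R2 = 1
  h <- suppressWarnings(fit_horizontal(ifelse(g == 1, 2, 1), g))
  expect_true(h$explains)
  expect_equal(h$r2, 1, tolerance = 1e-9)
})

test_that("degenerate inputs do not explain", {
  expect_false(fit_parallel(rnorm(10), rep(2, 10), rbinom(10, 1, .5))$explains)
  expect_false(fit_horizontal(rnorm(10), rep(1, 10))$explains)
  f <- fit_parallel(c(1, 2), c(1, 2), c(0, 1))  # too few points
  expect_false(f$explains)
  expect_equal(f$r2, 0)
})

test_that("group-balanced noise explains at about the nominal rate", {
  set.seed(23)
  hits <- replicate(400, {
    y <- rnorm(30)
    g <- rep(0:1, 15)
    fit_horizontal(y, g)$explains
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("response classification enforces the sole-explanation rule", {
  base <- data.frame(
    variable_id = 1:21, variable = cc_variables()$variable,
    window = "pre-go", model = c(rep("parallel", 19), "horizontal",
                                 "horizontal"),
    r2 = 0, r2_model = 0, p_factor = NA_real_, p_group = NA_real_,
    explains = FALSE, slope_sign = NA_real_, stringsAsFactors = FALSE)
  # only the location-only variable explains: it is best
  f1 <- base; f1$explains[21] <- TRUE; f1$r2[21] <- 0.4
  c1 <- classify_response(f1)
  expect_equal(c1$best_variable, "chosen_target_loc_only")
  # chosen value also explains: location-only cannot win
  f2 <- f1; f2$explains[17] <- TRUE; f2$r2[17] <- 0.45
  c2 <- classify_response(f2)
  expect_equal(c2$best_variable, "chosen_value")
  expect_equal(c2$n_explained, 2)
  # straight argmax among non-location explainers
  f3 <- base; f3$explains[c(6, 17)] <- TRUE
  f3$r2[c(6, 17)] <- c(0.7, 0.6)
  expect_equal(classify_response(f3)$best_variable, "chosen_cost")
  # nothing explains
  expect_true(is.na(classify_response(base)$best_variable_id))
  # exact ties break in panel order
  f4 <- base; f4$explains[c(4, 9)] <- TRUE; f4$r2[c(4, 9)] <- 0.5
  expect_equal(classify_response(f4)$best_variable_id, 4L)
})

test_that("count matrices respect per-response bookkeeping", {
  cfg <- session_config(n_trials = 250, seed = 61)
  rec <- data.frame(tuned_variable = c("chosen_value", "none"),
                    n = c(3, 2), slope = c(2, 0), baseline = c(4, 5),
                    location_offset = c(0, 8))
  pop <- generate_population(rec, cfg)
  rel <- screen_task_related(pop$rates, pop$trials)
  cls <- ancova_classify(pop$rates, pop$trials, pop$panel, relevance = rel)
  cm <- count_matrices(cls)
  # each response contributes at most once to the best-fit matrix
  expect_equal(sum(cm$best),
               sum(!is.na(cls$classification$best_variable_id)))
  # and at least as often to the explained matrix
  expect_true(all(cm$best <= cm$explained))
  expect_equal(sum(cm$explained), sum(cls$fits$explains))
  # empty population gives zero matrices
  empty <- list(fits = cls$fits[0, ], classification =
                  cls$classification[0, ])
  cm0 <- count_matrices(empty)
  expect_true(all(cm0$explained == 0) && all(cm0$best == 0))
})

test_that("nestedness holds for every explaining parallel fit", {
  cfg <- session_config(n_trials = 300, seed = 71)
  tr <- generate_session(cfg)
  pan <- compute_variables(tr, cfg$rho, cfg$xi)
  for (tv in c("chosen_value", "chosen_cost")) {
    nr <- generate_neuron(neuron_spec(tv, slope = 3, baseline = 6,
                                      location_offset = 3,
                                      neuron_id = tv), tr, pan, seed = 7)
    for (w in c("post-offer", "pre-go")) {
      rate <- nr$rate[nr$window == w][
        match(tr$trial_index, nr$trial_index[nr$window == w])]
      fits <- costchoice:::ancova_response(rate, tr, pan, w)
      hz <- fits$r2_model[fits$variable_id ==
                            (if (w == "post-offer") 20 else 21)]
      par_expl <- fits$r2_model[fits$explains & fits$model == "parallel"]
      expect_true(all(hz <= par_expl + 1e-12))
    }
  }
})
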