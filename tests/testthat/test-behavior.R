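test_that("choice probability follows the logistic in the value difference", {
  # X = 0: indifference
  tr <- trials_fixture(trial_row(qA = 1, qB = 2, costA = "low",
                                 offerA_side = "L", targetA_side = "L"))
  # a0 qB - a1 qA with a0=1, a1=2: X = 2 - 2 = 0 up to indicator terms;
  # zero out the indicator coefficients so only quantities matter
  p <- choice_probability(c(1, 2, 0, 0, 0, 0, 0), tr)
  expect_equal(p, 0.5)
  # cost term: B at low cost raises P(B) relative to costs swapped
  trBlow <- trials_fixture(trial_row(costA = "high"))
  trAlow <- trials_fixture(trial_row(costA = "low"))
  cf <- c(1, 2, 0.5, 0, 0, 0, 0)
  expect_gt(choice_probability(cf, trBlow), choice_probability(cf, trAlow))
  expect_true(all(choice_probability(cf, trBlow) >= 0 &
                  choice_probability(cf, trBlow) <= 1))
})

test_that("maximum-likelihood fit recovers generating parameters", {
  cfg <- session_config(n_trials = 5000, rho = 2, xi = 0.25, eta = 0,
                        phi = 0, delta = 0, epsilon = 0, a0 = 2, seed = 9)
  tr <- generate_session(cfg)
  f <- fit_session(tr)
  expect_true(f$converged)
  expect_lt(abs(f$rho - 2) / 2, 0.05)
  expect_lt(abs(f$xi - 0.25), 0.05)
  # grid-search oracle over (a0, a1, a2) confirms glm sits at the optimum
  X <- cbind(tr$qB, -tr$qA, tr$d_B_plus - tr$d_A_plus)
  y <- as.integer(tr$chosen_juice == "B")
  ll <- function(a) {
    p <- stats::plogis(drop(X %*% a))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  grid <- expand.grid(a0 = seq(1.4, 2.6, 0.2), a1 = seq(3, 5, 0.25),
                      a2 = seq(0, 1, 0.125))
  ll_grid <- max(apply(grid, 1, ll))
  # the simplified (a0, a1, a2) refit is the ML for this reduced model
  sp <- split_choice_pattern(tr)
  expect_gte(ll(sp$coef), ll_grid - 1e-6)
})

test_that("likelihood at the fit dominates the generating coefficients", {
  for (seed in c(2, 4)) {
    cfg <- session_config(n_trials = 300, seed = seed)
    tr <- generate_session(cfg)
    f <- fit_session(tr)
    y <- as.integer(tr$chosen_juice == "B")
    ll <- function(a) {
      p <- stats::plogis(drop(costchoice:::choice_design(tr) %*% a))
      sum(y * log(p) + (1 - y) * log(1 - p))
    }
    expect_gte(f$logLik, ll(unname(cfg$coef)) - 1e-8)
  }
})

test_that("normalized parameters are invariant to coefficient rescaling", {
  tr <- trials_fixture(trial_row())
  a <- c(2, 4, 0.5, 0.3, 0, -0.1, 0.05)
  for (k in c(0.5, 3)) {
    expect_equal((k * a[2]) / (k * a[1]), a[2] / a[1])
    # the linear predictor scales but the ratio definitions do not
    expect_equal(choice_probability(a, tr) > 0.5,
                 choice_probability(k * a, tr) > 0.5)
  }
})

test_that("degenerate sessions are rejected or flagged", {
  # single juice chosen throughout
  one_juice <- do.call(trials_fixture, lapply(1:20, function(i)
    trial_row(qA = 3, qB = 1, chosen_juice = "A",
              costA = c("low", "high")[1 + i %% 2])))
  expect_error(fit_session(one_juice), "both juices")
  # single offer type
  rows <- lapply(1:10, function(i)
    trial_row(chosen_juice = c("A", "B")[1 + i %% 2]))
  expect_error(fit_session(do.call(trials_fixture, rows)),
               "offer types")
  # deterministic choices: separation flagged, estimates bounded
  cfg <- session_config(n_trials = 200, a0 = 60, eta = 0, phi = 0,
                        delta = 0, epsilon = 0, seed = 12)
  tr <- generate_session(cfg)
  expect_warning(f <- fit_session(tr), "separation|capped|steepness")
  expect_false(f$converged)
  expect_true(all(abs(f$coef) <= 50))
})

test_that("no-signal sessions fit near-zero effect coefficients", {
  cfg <- session_config(n_trials = 2000, a0 = 1e-6, rho = 1, xi = 0,
                        eta = 0, phi = 0, delta = 0, epsilon = 0, seed = 8)
  tr <- generate_session(cfg)   # P(B) = 0.5 everywhere
  f <- suppressWarnings(fit_session(tr))
  expect_true(all(abs(f$coef[3:7]) < 0.2))
})

test_that("split choice pattern shifts the indifference point with cost", {
  cfg <- session_config(n_trials = 3000, rho = 2, xi = 0.3, eta = 0,
                        phi = 0, delta = 0, epsilon = 0, a0 = 4, seed = 21)
  tr <- generate_session(cfg)
  sp <- split_choice_pattern(tr)
  # A high cost: indifference displaced to a lower qB:qA ratio
  expect_lt(sp$indifference["A_high"], sp$indifference["A_low"])
  # closed-form X = 0 solution at qA = 1: rho +/- xi
  expect_lt(abs(sp$indifference["A_low"] - (sp$rho + sp$xi)), 1e-10)
  expect_lt(abs(sp$indifference["A_high"] - (sp$rho - sp$xi)), 1e-10)
  expect_lt(abs(sp$rho - 2), 0.15)
  expect_lt(abs(sp$xi - 0.3), 0.1)
  # raw points tabulated per offer type and cost condition
  expect_true(all(sp$points$n >= 1))
  expect_true(all(sp$points$pct_B >= 0 & sp$points$pct_B <= 100))
  # no cost effect: the two condition curves coincide
  cfg0 <- session_config(n_trials = 3000, xi = 0, eta = 0, phi = 0,
                         delta = 0, epsilon = 0, a0 = 4, seed = 22)
  sp0 <- split_choice_pattern(generate_session(cfg0))
  expect_lt(abs(sp0$indifference["A_low"] - sp0$indifference["A_high"]),
            0.1)
})

test_that("per-session fitting returns one row per session", {
  tr1 <- generate_session(session_config(n_trials = 250, seed = 31,
                                         session_id = "S1"))
  tr2 <- generate_session(session_config(n_trials = 250, seed = 32,
                                         session_id = "S2"))
  both <- as_cc_trials(rbind(as.data.frame(tr1)[, 1:9],
                             as.data.frame(tr2)[, 1:9]))
  fits <- fit_sessions(both)
  expect_equal(nrow(fits), 2)
  expect_setequal(fits$session_id, c("S1", "S2"))
  f1 <- fit_session(tr1)
  expect_equal(fits$xi[fits$session_id == "S1"], f1$xi)
})
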