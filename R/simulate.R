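#' Configure a synthetic behavioral session
#'
#' Defaults describe a typical session of the saccade-cost choice task: 250
#' trials, offer types spanning quantity ratios around indifference, and
#' generating parameters set to the session medians observed in this task
#' family (steepness `a0 = 2`, relative value `rho = 2`, action cost
#' `xi = 0.27`, juice hysteresis `eta = 0.16`, cost hysteresis
#' `phi = -0.008`, offer-side bias `delta = -0.03`, target-side bias
#' `epsilon = 0.017`). Cost assignment, offer sides and target sides are
#' counterbalanced across trials in shuffled blocks of the eight spatial/cost
#' configurations, so each configuration count is within 1 of its expected
#' value.
#'
#' @param n_trials number of completed trials.
#' @param offer_types data.frame with columns `qA`, `qB` (drops of juice).
#' @param a0,rho,xi,eta,phi,delta,epsilon generating parameters; the Eq.
#'   coefficients are `a1 = a0*rho`, `a2 = a0*xi`, ..., `a6 = a0*epsilon`.
#' @param hemisphere recorded hemisphere for covariate coding.
#' @param session_id session label.
#' @param seed integer seed; identical seeds give identical sessions.
#' @return list of class `"cc_session_config"`.
#' @export
session_config <- function(n_trials = 250,
                           offer_types = default_offer_types(),
                           a0 = 2, rho = 2, xi = 0.27, eta = 0.16,
                           phi = -0.008, delta = -0.03, epsilon = 0.017,
                           hemisphere = "left",
                           session_id = "S1", seed = 1L) {
  stopifnot(n_trials >= 0, a0 > 0)
  offer_types <- as.data.frame(offer_types)
  if (n_trials > 0 && nrow(offer_types) == 0) {
    stop("offer-type list must not be empty")
  }
  stopifnot(all(c("qA", "qB") %in% names(offer_types)))
  structure(list(
    n_trials = as.integer(n_trials), offer_types = offer_types,
    coef = c(a0 = a0, a1 = a0 * rho, a2 = a0 * xi, a3 = a0 * eta,
             a4 = a0 * phi, a5 = a0 * delta, a6 = a0 * epsilon),
    rho = rho, xi = xi, hemisphere = hemisphere,
    session_id = session_id, seed = as.integer(seed)
  ), class = "cc_session_config")
}

#' @rdname session_config
#' @export
default_offer_types <- function() {
  data.frame(qA = c(1, 1, 1, 1, 1, 1, 2, 3),
             qB = c(1, 2, 3, 4, 6, 8, 3, 2))
}

# shuffled-block sequence: each of the `k` items appears floor/ceil(n/k)
# times, order randomized within consecutive blocks
block_sequence <- function(k, n) {
  if (n == 0) return(integer())
  idx <- unlist(lapply(seq_len(ceiling(n / k)), function(i) sample.int(k)))
  idx[seq_len(n)]
}

#' Generate one behavioral session from the logistic choice model
#'
#' Offer types and the eight (cost assignment x offer side x target side)
#' configurations are assigned in counterbalanced shuffled blocks; choices
#' are then drawn trial by trial from [choice_probability()], with the
#' hysteresis indicators computed from the realized choice sequence (first
#' trial: zero).
#'
#' @param config a [session_config()].
#' @return a `cc_trials` table of `n_trials` completed trials.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "cc_session_config"))
  set.seed(config$seed)
  n <- config$n_trials
  ot <- config$offer_types[block_sequence(nrow(config$offer_types), n), ,
                           drop = FALSE]
  cfg <- expand.grid(costA = c("low", "high"), offerA_side = c("L", "R"),
                     targetA_side = c("L", "R"), stringsAsFactors = FALSE)
  cfg <- cfg[block_sequence(8L, n), , drop = FALSE]
  df <- data.frame(
    session_id = rep(config$session_id, n),
    trial_index = seq_len(n),
    qA = ot$qA, qB = ot$qB,
    costA = cfg$costA,
    costB = ifelse(cfg$costA == "low", "high", "low"),
    offerA_side = cfg$offerA_side,
    targetA_side = cfg$targetA_side,
    stringsAsFactors = FALSE
  )
  a <- unname(config$coef)
  u <- stats::runif(n)
  chosen <- character(n)
  prev_juice <- NA_character_
  prev_cost <- NA_character_
  for (i in seq_len(n)) {
    d_hyst <- if (is.na(prev_juice)) 0 else
      (prev_juice == "B") - (prev_juice == "A")
    d_chyst <- if (is.na(prev_cost)) 0 else
      (df$costB[i] == prev_cost) - (df$costA[i] == prev_cost)
    d_offer <- (df$offerA_side[i] == "R") - (df$offerA_side[i] == "L")
    d_target <- (df$targetA_side[i] == "R") - (df$targetA_side[i] == "L")
    X <- a[1] * df$qB[i] - a[2] * df$qA[i] +
      a[3] * ((df$costB[i] == "low") - (df$costA[i] == "low")) +
      a[4] * d_hyst + a[5] * d_chyst +
      a[6] * d_offer + a[7] * d_target
    chosen[i] <- if (u[i] < stats::plogis(X)) "B" else "A"
    prev_juice <- chosen[i]
    prev_cost <- if (chosen[i] == "A") df$costA[i] else df$costB[i]
  }
  df$chosen_juice <- chosen
  as_cc_trials(df)
}

#' Specify a synthetic neuron
#'
#' A neuron's trial rate is linear in (at most) one decision variable plus
#' an additive offset tied to the epoch covariate (chosen offer location in
#' early windows, chosen target location in late windows), mirroring the
#' additive structure of the parallel-lines ANCOVA:
#' `rate = max(0, baseline + slope * variable + location_offset * covariate)`.
#' Spike counts per 0.5-s window are Poisson with mean `rate * 0.5`.
#'
#' @param tuned_variable name of a column of the variable panel passed to
#'   [generate_neuron()] (usually one of [cc_variables()], but any numeric
#'   column works, e.g. a chosen-value variant added by the caller), or
#'   `"none"` for untuned / location-only cells.
#' @param slope spikes/s per unit of the tuned variable (0 when untuned).
#' @param baseline baseline firing rate, spikes/s.
#' @param location_offset spikes/s added when the epoch covariate equals 1
#'   (contralateral choice).
#' @param neuron_id label.
#' @return list of class `"cc_neuron_spec"`.
#' @export
neuron_spec <- function(tuned_variable = "none", slope = 0, baseline = 5,
                        location_offset = 0, neuron_id = "n1") {
  if (identical(tuned_variable, "none") && slope != 0) {
    stop("untuned neurons must have slope = 0")
  }
  structure(list(tuned_variable = tuned_variable, slope = slope,
                 baseline = baseline, location_offset = location_offset,
                 neuron_id = neuron_id), class = "cc_neuron_spec")
}

#' Generate Poisson-windowed responses for one neuron
#'
#' @param spec a [neuron_spec()].
#' @param trials a `cc_trials` table.
#' @param panel the matching [compute_variables()] panel.
#' @param windows window ids to simulate (default all nine).
#' @param duration window duration in seconds (must be positive).
#' @param seed integer seed.
#' @return long data.frame: `neuron_id, session_id, trial_index, window,
#'   count, rate` with `rate = count / duration`.
#' @export
generate_neuron <- function(spec, trials, panel, windows = cc_windows(),
                            duration = WINDOW_DURATION, seed = 1L) {
  stopifnot(inherits(spec, "cc_neuron_spec"))
  if (duration <= 0) stop("window duration must be positive")
  windows <- match.arg(windows, cc_windows(), several.ok = TRUE)
  set.seed(seed)
  n <- nrow(trials)
  if (identical(spec$tuned_variable, "none")) {
    x <- numeric(n)
  } else {
    if (is.null(panel[[spec$tuned_variable]])) {
      stop("tuned_variable '", spec$tuned_variable,
           "' is not a column of the panel")
    }
    x <- panel[[spec$tuned_variable]]
  }
  x[is.na(x)] <- 0
  out <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    cov <- if (cc_epoch(windows[w]) == "early") panel$chosen_offer_contra
           else panel$chosen_target_contra
    rate <- pmax(0, spec$baseline + spec$slope * x +
                    spec$location_offset * cov)
    cnt <- stats::rpois(n, rate * duration)
    out[[w]] <- data.frame(
      neuron_id = spec$neuron_id, session_id = trials$session_id,
      trial_index = trials$trial_index, window = windows[w],
      count = cnt, rate = cnt / duration, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a labeled synthetic population
#'
#' Builds one behavioral session, its variable panel, and a set of neurons
#' given a recipe. The default recipe emulates the mixture of signals this
#' task elicits: chosen-value, chosen-cost and chosen-juice tuned cells,
#' location-only cells (rate follows the epoch covariate), and untuned
#' cells.
#'
#' @param recipe data.frame with columns `tuned_variable`, `n`, `slope`,
#'   `baseline`, `location_offset`.
#' @param config a [session_config()].
#' @return list with `trials`, `panel`, `rates` (long data.frame across
#'   neurons), `truth` (per-neuron ground-truth labels), `fit` (the
#'   generating `rho`/`xi` used for the panel).
#' @export
generate_population <- function(recipe = default_recipe(),
                                config = session_config()) {
  recipe <- as.data.frame(recipe)
  stopifnot(all(c("tuned_variable", "n", "slope", "baseline",
                  "location_offset") %in% names(recipe)))
  trials <- generate_session(config)
  panel <- compute_variables(trials, config$rho, config$xi,
                             config$hemisphere)
  rows <- rep(seq_len(nrow(recipe)), recipe$n)
  rates <- vector("list", length(rows))
  truth <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- recipe[rows[i], ]
    id <- sprintf("n%03d", i)
    sp <- neuron_spec(r$tuned_variable, r$slope, r$baseline,
                      r$location_offset, neuron_id = id)
    rates[[i]] <- generate_neuron(sp, trials, panel,
                                  seed = config$seed + 1000L + i)
    truth[[i]] <- data.frame(neuron_id = id,
                             tuned_variable = r$tuned_variable,
                             slope = r$slope, baseline = r$baseline,
                             location_offset = r$location_offset,
                             stringsAsFactors = FALSE)
  }
  list(trials = trials, panel = panel,
       rates = do.call(rbind, rates), truth = do.call(rbind, truth),
       fit = list(rho = config$rho, xi = config$xi,
                  hemisphere = config$hemisphere))
}

#' @rdname generate_population
#' @export
default_recipe <- function() {
  data.frame(
    tuned_variable = c("chosen_value", "chosen_cost", "chosen_juice",
                       "none", "none"),
    n = c(12, 8, 6, 10, 12),
    slope = c(2, 8, 8, 0, 0),
    baseline = c(4, 4, 4, 4, 5),
    location_offset = c(0, 0, 0, 8, 0),
    stringsAsFactors = FALSE
  )
}
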