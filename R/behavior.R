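#' Choice probability under the logistic choice model
#'
#' The per-trial probability of choosing juice B is
#' `1 / (1 + exp(-X))` with
#' `X = a0*qB - a1*qA + a2*(dB+ - dA+) + a3*(dprevB - dprevA) +
#'  a4*(dcostprevB - dcostprevA) + a5*(dofferB,left - dofferA,left) +
#'  a6*(dtargetB,left - dtargetA,left)`,
#' where `dJ+` marks juice J offered at low cost, `dprevJ` marks juice J
#' chosen and received on the previous trial, `dcostprevJ` marks the cost of
#' J matching the previously chosen cost, and the last two terms are
#' offer-side and target-side indicators. Normalizing `a1..a6` by the
#' steepness `a0` expresses every effect in units of juice B: relative value
#' `rho = a1/a0`, action cost `xi = a2/a0`, juice hysteresis `eta = a3/a0`,
#' cost hysteresis `phi = a4/a0`, offer-side bias `delta = a5/a0`,
#' target-side bias `epsilon = a6/a0`.
#'
#' @param coeffs numeric vector `c(a0, a1, a2, a3, a4, a5, a6)`.
#' @param trials a `cc_trials` table with indicator columns.
#' @return numeric vector of P(choose B), one per trial, in [0, 1].
#' @export
choice_probability <- function(coeffs, trials) {
  stopifnot(length(coeffs) == 7)
  X <- choice_design(trials) %*% coeffs
  stats::plogis(drop(X))
}

# design matrix whose columns multiply a0..a6 in the linear predictor
choice_design <- function(trials) {
  cbind(
    qB       = trials$qB,
    neg_qA   = -trials$qA,
    d_cost   = trials$d_B_plus - trials$d_A_plus,
    d_hyst   = trials$d_prev_B - trials$d_prev_A,
    d_chyst  = trials$d_costprev_B - trials$d_costprev_A,
    d_offer  = trials$offerB_left - trials$offerA_left,
    d_target = trials$targetB_left - trials$targetA_left
  )
}

# cap used when a session is (near) separable
COEF_CAP <- 50

#' Fit the logistic choice model to one session
#'
#' Maximum-likelihood logistic regression of choice B on the model of
#' [choice_probability()] (no intercept). Sessions in which the animal is
#' deterministic (complete or quasi-complete separation) yield diverging
#' coefficients; these are capped at +/-50 and flagged as non-converged.
#'
#' @param trials a `cc_trials` table from a single session, with at least
#'   two distinct offer types and both juices chosen at least once.
#' @return an object of class `"cc_behavior_fit"`: list with `coef`
#'   (`a0..a6`), the normalized parameters `rho, xi, eta, phi, delta,
#'   epsilon`, `logLik`, `converged`, `n_trials`, `session_id`.
#' @export
fit_session <- function(trials) {
  if (length(unique(trials$session_id)) > 1) {
    stop("fit_session() expects trials from a single session")
  }
  ot <- unique(paste(trials$qA, trials$qB, trials$costA))
  if (length(ot) < 2) stop("need at least 2 distinct offer types")
  if (length(unique(trials$chosen_juice)) < 2) {
    stop("both juices must be chosen at least once in a session")
  }
  X <- choice_design(trials)
  y <- as.integer(trials$chosen_juice == "B")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100))
  )
  a <- unname(fit$coefficients)
  a[is.na(a)] <- 0
  converged <- fit$converged && all(abs(a) < COEF_CAP)
  if (!converged) {
    a <- pmin(pmax(a, -COEF_CAP), COEF_CAP)
    warning("session ", trials$session_id[1],
            ": separation or non-convergence; coefficients capped at +/-",
            COEF_CAP)
  }
  if (a[1] <= 0) {
    warning("session ", trials$session_id[1],
            ": non-positive steepness a0; normalized parameters unreliable")
    converged <- FALSE
  }
  p <- stats::plogis(drop(X %*% a))
  eps <- .Machine$double.eps
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  structure(list(
    coef = stats::setNames(a, paste0("a", 0:6)),
    rho = a[2] / a[1], xi = a[3] / a[1], eta = a[4] / a[1],
    phi = a[5] / a[1], delta = a[6] / a[1], epsilon = a[7] / a[1],
    logLik = ll, converged = converged, n_trials = nrow(trials),
    session_id = trials$session_id[1]
  ), class = "cc_behavior_fit")
}

#' @export
print.cc_behavior_fit <- function(x, ...) {
  cat("Logistic choice fit, session", x$session_id,
      sprintf("(%d trials, %s)\n", x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  rho = %.3f  xi = %.3f  eta = %.3f  phi = %.3f  delta = %.3f  epsilon = %.3f\n",
              x$rho, x$xi, x$eta, x$phi, x$delta, x$epsilon))
  cat(sprintf("  logLik = %.2f\n", x$logLik))
  invisible(x)
}

#' Fit the choice model to every session in a trial table
#'
#' @param trials a `cc_trials` table, possibly spanning many sessions.
#' @return data.frame, one row per session: `session_id`, `a0..a6`, `rho`,
#'   `xi`, `eta`, `phi`, `delta`, `epsilon`, `logLik`, `n_trials`,
#'   `converged`.
#' @export
fit_sessions <- function(trials) {
  out <- lapply(split(trials, trials$session_id), function(tr) {
    cls <- class(trials)
    class(tr) <- cls
    f <- fit_session(tr)
    data.frame(session_id = f$session_id, t(f$coef),
               rho = f$rho, xi = f$xi, eta = f$eta, phi = f$phi,
               delta = f$delta, epsilon = f$epsilon,
               logLik = f$logLik, n_trials = f$n_trials,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Choice pattern split by the action cost of juice A
#'
#' Separates trials by whether juice A carried the high or the low action
#' cost, tabulates percent B choices per offer type within each group, and
#' refits a simplified choice model (hysteresis and spatial terms removed,
#' i.e. only `a0, a1, a2`). From the simplified fit, the indifference
#' quantity ratio qB:qA at the reference quantity qA = 1 is `rho + xi` when
#' A is low cost and `rho - xi` when A is high cost: a positive action cost
#' shifts the A-high-cost sigmoid to a lower indifference point.
#'
#' @param trials one session's `cc_trials` table.
#' @return list with `points` (data.frame: `cost_A`, `qA`, `qB`, `ratio`,
#'   `n`, `pct_B`, `fitted_pct_B`), `coef` (simplified `a0, a1, a2`),
#'   `rho`, `xi` and `indifference` (named vector, `A_low` / `A_high`;
#'   a condition with fewer than 2 offer types gets `NA` and keeps its raw
#'   points).
#' @export
split_choice_pattern <- function(trials) {
  X <- choice_design(trials)[, 1:3, drop = FALSE]
  y <- as.integer(trials$chosen_juice == "B")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100))
  )
  a <- unname(fit$coefficients)
  a[is.na(a)] <- 0
  a <- pmin(pmax(a, -COEF_CAP), COEF_CAP)
  rho <- a[2] / a[1]; xi <- a[3] / a[1]
  key <- paste(trials$costA, trials$qA, trials$qB)
  keep <- !duplicated(key)
  pts <- data.frame(cost_A = trials$costA[keep], qA = trials$qA[keep],
                    qB = trials$qB[keep], stringsAsFactors = FALSE)
  pts$ratio <- pts$qB / pmax(pts$qA, .Machine$double.eps)
  pts$n <- as.integer(table(key)[key[keep]])
  pts$pct_B <- 100 * tapply(y, key, mean)[key[keep]]
  xfit <- a[1] * pts$qB - a[2] * pts$qA +
    a[3] * ifelse(pts$cost_A == "low", -1, 1)
  pts$fitted_pct_B <- 100 * stats::plogis(xfit)
  pts <- pts[order(pts$cost_A, pts$ratio), , drop = FALSE]
  rownames(pts) <- NULL
  n_ot <- table(pts$cost_A)
  ind <- c(A_low = if (isTRUE(n_ot["low"] >= 2)) rho + xi else NA_real_,
           A_high = if (isTRUE(n_ot["high"] >= 2)) rho - xi else NA_real_)
  list(points = pts, coef = stats::setNames(a, c("a0", "a1", "a2")),
       rho = rho, xi = xi, indifference = ind)
}
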