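# hand-constructable single trial row; defaults give a valid trial
trial_row <- function(qA = 1, qB = 2, costA = "low",
                      offerA_side = "L", targetA_side = "L",
                      chosen_juice = "B", session_id = "S1",
                      trial_index = 1) {
  data.frame(session_id = session_id, trial_index = trial_index,
             qA = qA, qB = qB, costA = costA,
             costB = ifelse(costA == "low", "high", "low"),
             offerA_side = offerA_side, targetA_side = targetA_side,
             chosen_juice = chosen_juice, stringsAsFactors = FALSE)
}

trials_fixture <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$trial_index <- i
  as_cc_trials(do.call(rbind, rows))
}

# closed-form OLS oracle via normal equations: returns total R2 and the
# two-sided t-test p-value for each regressor (columns of X, intercept
# added here)
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  XtX <- crossprod(X1)
  beta <- solve(XtX, crossprod(X1, y))
  res <- y - X1 %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- length(y) - ncol(X1)
  sigma2 <- rss / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- drop(beta) / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(r2 = 1 - rss / tss, beta = drop(beta), p = p[-1], df = df)
}

# exact two-sided signed-rank p-value by enumeration of all sign
# assignments (no ties/zeros assumed), mirroring the exact test's
# two-sided doubling rule
signed_rank_oracle <- function(x) {
  stopifnot(all(x != 0), !any(duplicated(abs(x))))
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
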