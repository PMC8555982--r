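#' Cost-affected and cost-independent chosen-value variants
#'
#' The cost-affected variant is the panel's chosen value (the chosen
#' offer's value including the action-cost term `xi`); the cost-independent
#' variant recomputes it with `xi` forced to 0, i.e. `rho * qA` when A was
#' chosen and `qB` when B was chosen. The two variants coincide when
#' `xi = 0`.
#'
#' @param trials a `cc_trials` table.
#' @param rho,xi session behavioral parameters.
#' @return data.frame with columns `cost_affected`, `cost_independent`.
#' @export
chosen_value_variants <- function(trials, rho, xi) {
  vA <- rho * trials$qA + xi * trials$d_A_plus
  vB <- trials$qB + xi * trials$d_B_plus
  choseB <- trials$chosen_juice == "B"
  data.frame(
    cost_affected = ifelse(choseB, vB, vA),
    cost_independent = ifelse(choseB, trials$qB, rho * trials$qA)
  )
}

#' Per-response \eqn{\Delta R^2} between chosen-value variants
#'
#' For each response (neuron x window, pre-offer excluded), both variants
#' are fit with the parallel-lines ANCOVA. A response qualifies as
#' chosen-value coding only when each variant explains it (factor
#' p < 0.05); it then contributes
#' \eqn{\Delta R^2 = R^2_{cost-affected} - R^2_{cost-independent}}.
#' Responses where only one variant explains are excluded and counted.
#'
#' @param rates long rate table.
#' @param trials the session's `cc_trials` table.
#' @param panel the matching variable panel.
#' @param rho,xi session behavioral parameters.
#' @param relevance optional `cc_relevance` table; restricts to
#'   task-related responses.
#' @param level `"means"` or `"trials"` data points (see
#'   [ancova_classify()]).
#' @return data.frame of qualifying responses: `neuron_id, window, epoch,
#'   r2_cost_affected, r2_cost_independent, delta_r2`; attribute
#'   `"one_sided"` counts responses where exactly one variant explained.
#' @export
delta_r2 <- function(rates, trials, panel, rho, xi, relevance = NULL,
                     level = "means") {
  variants <- chosen_value_variants(trials, rho, xi)
  wins <- setdiff(cc_windows(), "pre-offer")
  keys <- unique(rates[rates$window %in% wins, c("neuron_id", "window")])
  if (!is.null(relevance)) {
    tr <- relevance[relevance$task_related,
                    c("neuron_id", "window"), drop = FALSE]
    keys <- merge(keys, tr, by = c("neuron_id", "window"))
  }
  # shared cell structures and variant cell means, one per covariate
  pts <- lapply(c(chosen_offer_contra = "chosen_offer_contra",
                  chosen_target_contra = "chosen_target_contra"),
                function(cv) {
    p <- ancova_points(trials, panel, cv)
    p$xa <- as.numeric(tapply(variants$cost_affected[p$use], p$cell, mean))
    p$xi <- as.numeric(tapply(variants$cost_independent[p$use], p$cell, mean))
    p
  })
  out <- vector("list", nrow(keys))
  one_sided <- 0L
  for (k in seq_len(nrow(keys))) {
    w <- keys$window[k]
    sel <- rates$neuron_id == keys$neuron_id[k] & rates$window == w
    rate <- rates$rate[sel][match(trials$trial_index,
                                  rates$trial_index[sel])]
    covariate <- ancova_covariate(w)
    if (level == "means") {
      p <- pts[[covariate]]
      y <- cell_means(rate, p)
      gg <- p$g; xa <- p$xa; xi_ <- p$xi
    } else {
      y <- rate; gg <- panel[[covariate]]
      xa <- variants$cost_affected; xi_ <- variants$cost_independent
    }
    fa <- fit_parallel(y, xa, gg)
    fi <- fit_parallel(y, xi_, gg)
    if (fa$explains && fi$explains) {
      out[[k]] <- data.frame(
        neuron_id = keys$neuron_id[k], window = w,
        epoch = cc_epoch(w),
        r2_cost_affected = fa$r2_model,
        r2_cost_independent = fi$r2_model,
        delta_r2 = fa$r2_model - fi$r2_model,
        stringsAsFactors = FALSE)
    } else if (xor(isTRUE(fa$explains), isTRUE(fi$explains))) {
      one_sided <- one_sided + 1L
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(neuron_id = character(), window = character(),
                      epoch = character(), r2_cost_affected = numeric(),
                      r2_cost_independent = numeric(),
                      delta_r2 = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "one_sided") <- one_sided
  out
}

#' Epoch summary of the \eqn{\Delta R^2} distribution
#'
#' Aggregates chosen-value coding responses into the early epoch
#' (post-offer to pre-target) and the late epoch (post-target to
#' post-juice), reports mean and median \eqn{\Delta R^2} per epoch with a
#' two-sided Wilcoxon signed-rank test against 0, and compares the two
#' epochs with a Wilcoxon rank-sum test.
#'
#' @param deltas data.frame from [delta_r2()].
#' @return list with `by_epoch` (data.frame: `epoch, n, mean, median, p`)
#'   and `p_epoch_diff` (rank-sum p, NA if an epoch is empty).
#' @export
epoch_summary <- function(deltas) {
  eps <- c("early", "late")
  rows <- lapply(eps, function(e) {
    d <- deltas$delta_r2[deltas$epoch == e]
    p <- if (length(d) == 0 || all(d == 0)) NA_real_ else
      cc_signed_rank(d)
    data.frame(epoch = e, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               median = if (length(d)) stats::median(d) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  by_epoch <- do.call(rbind, rows)
  d1 <- deltas$delta_r2[deltas$epoch == "early"]
  d2 <- deltas$delta_r2[deltas$epoch == "late"]
  p_diff <- if (length(d1) && length(d2)) {
    suppressWarnings(stats::wilcox.test(d1, d2, exact = FALSE)$p.value)
  } else NA_real_
  if (any(by_epoch$n == 0)) {
    warning("empty epoch: statistics undefined for ",
            paste(by_epoch$epoch[by_epoch$n == 0], collapse = ", "))
  }
  list(by_epoch = by_epoch, p_epoch_diff = p_diff)
}

# two-sided Wilcoxon signed-rank test against 0: exact for n <= 25 (no
# ties/zeros), normal approximation otherwise
cc_signed_rank <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  if (!length(x) || all(x == mu)) return(NA_real_)
  use_exact <- length(x) <= 25 && !any(x == mu) &&
    !any(duplicated(abs(x - mu)))
  suppressWarnings(
    stats::wilcox.test(x, mu = mu, exact = use_exact,
                       correct = !use_exact)$p.value
  )
}
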