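#' Event-aligned window firing rates from spike times
#'
#' Counts spikes in each of the nine half-open 0.5-s windows (see
#' [cc_windows()]) and divides by the window duration. Trials whose
#' alignment event is missing are excluded with a warning.
#'
#' @param spikes data.frame with columns `trial_index`, `time` (s, same
#'   clock as the event times; one row per spike).
#' @param events data.frame with one row per trial: `trial_index`,
#'   `offer_on`, `offer_off`, `target_on`, `go`, `juice` (times in s).
#' @param neuron_id label attached to the output.
#' @return long data.frame: `neuron_id, trial_index, window, count, rate`.
#' @export
window_rates <- function(spikes, events, neuron_id = "n1") {
  al <- window_alignment()
  need <- c("trial_index", unique(al$event))
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(events[, unique(al$event)])
  if (any(bad)) {
    warning(sum(bad), " trial(s) excluded: missing event time")
    events <- events[!bad, , drop = FALSE]
  }
  out <- vector("list", nrow(al))
  for (k in seq_len(nrow(al))) {
    start <- events[[al$event[k]]] + al$offset[k]
    cnt <- vapply(seq_len(nrow(events)), function(i) {
      s <- spikes$time[spikes$trial_index == events$trial_index[i]]
      sum(s >= start[i] & s < start[i] + WINDOW_DURATION)
    }, integer(1))
    out[[k]] <- data.frame(
      neuron_id = neuron_id, trial_index = events$trial_index,
      window = al$window[k], count = cnt,
      rate = cnt / WINDOW_DURATION, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Type-II main-effect p-values for a k-factor ANOVA without interactions,
# computed as RSS differences between the full main-effects model and the
# model with one factor deleted. Y may be a matrix (one column per
# response); returns a p-value matrix factors x responses. Constant factors
# get p = 1 with a warning.
main_effects_anova <- function(Y, factors) {
  Y <- as.matrix(Y)
  keep <- vapply(factors, function(f) nlevels(droplevels(factor(f))) > 1,
                 logical(1))
  if (any(!keep)) {
    warning("constant factor(s) ", paste(names(factors)[!keep],
                                         collapse = ", "),
            ": p set to 1")
  }
  fac <- lapply(factors, function(f) droplevels(factor(f)))
  p <- matrix(1, nrow = length(factors), ncol = ncol(Y),
              dimnames = list(names(factors), colnames(Y)))
  used <- which(keep)
  if (!length(used)) return(p)
  mm <- function(idx) {
    if (!length(idx)) return(matrix(1, nrow(Y), 1))
    stats::model.matrix(~ ., data = as.data.frame(fac[idx]))
  }
  rss_rank <- function(X) {
    f <- stats::lm.fit(X, Y)
    list(rss = colSums(as.matrix(f$residuals)^2), rank = f$rank)
  }
  full <- rss_rank(mm(used))
  df_res <- nrow(Y) - full$rank
  if (df_res <= 0) {
    warning("no residual degrees of freedom; p set to 1")
    return(p)
  }
  for (j in used) {
    red <- rss_rank(mm(setdiff(used, j)))
    df1 <- full$rank - red$rank
    if (df1 <= 0) next
    Fstat <- ((red$rss - full$rss) / df1) / (full$rss / df_res)
    p[j, ] <- stats::pf(Fstat, df1, df_res, lower.tail = FALSE)
  }
  p
}

#' Screen responses for task-relatedness
#'
#' Each response (one neuron in one time window) is submitted to two 3-way
#' main-effects ANOVAs on trial firing rates: factors (trial type, offer A
#' location, target A location) and (trial type, chosen offer location,
#' chosen target location). A response is task related if any factor in
#' either ANOVA reaches `p < alpha`; only task-related responses enter the
#' tuning analyses. The trial-type p-value reported is the minimum over the
#' two ANOVAs. Trial-type levels with fewer than 2 trials are dropped.
#'
#' @param rates long data.frame (`neuron_id, trial_index, window, rate`),
#'   e.g. from [generate_neuron()] or [window_rates()].
#' @param trials the session's `cc_trials` table.
#' @param alpha significance threshold (default 0.001).
#' @return data.frame of class `"cc_relevance"`, one row per
#'   (neuron, window): p-values `p_trial_type, p_offerA_loc, p_targetA_loc,
#'   p_chosen_offer_loc, p_chosen_target_loc` and logical `task_related`.
#' @export
screen_task_related <- function(rates, trials, alpha = 0.001) {
  tt <- trial_type_label(trials)
  small <- names(which(table(tt) < 2))
  use <- !(tt %in% small)
  tr <- trials[use, , drop = FALSE]
  tt <- tt[use]
  out <- list()
  for (w in intersect(cc_windows(), unique(rates$window))) {
    rw <- rates[rates$window == w, , drop = FALSE]
    Y <- matrix_from_long(rw, tr$trial_index)
    ok <- stats::complete.cases(Y)
    Y <- Y[ok, , drop = FALSE]
    f1 <- list(trial_type = tt[ok], offerA_loc = tr$offerA_side[ok],
               targetA_loc = tr$targetA_side[ok])
    f2 <- list(trial_type = tt[ok], chosen_offer_loc = tr$chosen_side[ok],
               chosen_target_loc = tr$chosen_target_side[ok])
    p1 <- main_effects_anova(Y, f1)
    p2 <- main_effects_anova(Y, f2)
    res <- data.frame(
      neuron_id = colnames(Y), window = w,
      p_trial_type = pmin(p1["trial_type", ], p2["trial_type", ]),
      p_offerA_loc = p1["offerA_loc", ],
      p_targetA_loc = p1["targetA_loc", ],
      p_chosen_offer_loc = p2["chosen_offer_loc", ],
      p_chosen_target_loc = p2["chosen_target_loc", ],
      stringsAsFactors = FALSE
    )
    out[[w]] <- res
  }
  out <- do.call(rbind, out)
  pcols <- grep("^p_", names(out))
  out$task_related <- apply(out[, pcols, drop = FALSE] < alpha, 1, any)
  rownames(out) <- NULL
  class(out) <- c("cc_relevance", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

# long (neuron_id, trial_index, rate) -> trials x neurons matrix aligned to
# the given trial_index order; trials absent from `rates` are dropped from
# the matrix only if absent for all neurons
matrix_from_long <- function(rates, trial_index) {
  ids <- sort(unique(rates$neuron_id))
  Y <- matrix(NA_real_, length(trial_index), length(ids),
              dimnames = list(NULL, ids))
  row <- match(rates$trial_index, trial_index)
  ok <- !is.na(row)
  Y[cbind(row[ok], match(rates$neuron_id, ids)[ok])] <- rates$rate[ok]
  Y
}

#' Tally task-relatedness counts per window and factor
#'
#' Internal bookkeeping mirror of the screening step: for each window, the
#' number of neurons whose response passes `p < alpha` for each factor, an
#' "at least 1" row counting neurons significant for a factor in any
#' window, and the total number of neurons with at least one task-related
#' response.
#'
#' @param relevance a `cc_relevance` table.
#' @return list with `by_window` (data.frame, rows = windows plus
#'   `"at least 1"`), `n_task_related`, `n_neurons`.
#' @export
relevance_counts <- function(relevance) {
  alpha <- attr(relevance, "alpha")
  if (is.null(alpha)) alpha <- 0.001
  pcols <- grep("^p_", names(relevance), value = TRUE)
  sig <- as.data.frame(relevance[, pcols] < alpha)
  by_w <- stats::aggregate(sig, by = list(window = relevance$window), FUN = sum)
  by_w <- by_w[match(intersect(cc_windows(), by_w$window), by_w$window), ]
  any_w <- stats::aggregate(sig, by = list(neuron_id = relevance$neuron_id),
                     FUN = any)
  atleast <- c(window = "at least 1",
               lapply(any_w[, pcols, drop = FALSE], sum))
  by_w <- rbind(by_w, as.data.frame(atleast, stringsAsFactors = FALSE))
  rownames(by_w) <- NULL
  tr_by_neuron <- tapply(relevance$task_related, relevance$neuron_id, any)
  list(by_window = by_w,
       n_task_related = sum(tr_by_neuron),
       n_neurons = length(tr_by_neuron))
}
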