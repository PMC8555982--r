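#' Incidence table for variable selection
#'
#' Condenses the ANCOVA classification into the structure the selection
#' procedures operate on: per task-related response, the set of variables
#' that explain it, its best-fit variable, and its time window. Responses
#' are pooled across all nine windows.
#'
#' @param classified output of [ancova_classify()], or the
#'   `classification` data.frame alone (e.g. read back from CSV).
#' @return object of class `"cc_incidence"`: list with `explains` (logical
#'   responses x 21 matrix), `best` (integer vector, NA when nothing
#'   explains), `window`, `response_id`.
#' @export
incidence_table <- function(classified) {
  cl <- if (is.data.frame(classified)) classified else
    classified$classification
  stopifnot(all(c("explained_set", "best_variable_id", "window",
                  "neuron_id") %in% names(cl)))
  n <- nrow(cl)
  M <- matrix(FALSE, n, 21)
  for (i in seq_len(n)) {
    es <- cl$explained_set[i]
    if (!is.na(es) && nzchar(es)) {
      M[i, as.integer(strsplit(es, ",")[[1]])] <- TRUE
    }
  }
  colnames(M) <- cc_variables()$variable
  structure(list(explains = M, best = cl$best_variable_id,
                 window = cl$window,
                 response_id = paste(cl$neuron_id, cl$window, sep = ":")),
            class = "cc_incidence")
}

#' Explanatory power of a variable subset
#'
#' The number of responses collectively explained by the subset, i.e.
#' responses whose explained set intersects it.
#'
#' @param subset integer vector of variable indices (1..21).
#' @param table a `cc_incidence` table.
#' @return integer count.
#' @export
explanatory_power <- function(subset, table) {
  stopifnot(inherits(table, "cc_incidence"))
  if (!length(subset)) return(0L)
  stopifnot(all(subset %in% 1:21))
  sum(rowSums(table$explains[, subset, drop = FALSE]) > 0)
}

#' Stepwise variable selection
#'
#' At each step the variable providing the highest number of best fits
#' within any single time window (maximum over windows; `criterion = "sum"`
#' uses the total across windows) is selected; all responses it explains
#' are removed, and the procedure repeats on the residual data. Selection
#' stops when the marginal explanatory power of the would-be next variable
#' falls below `threshold` (a fraction of the number of responses in the
#' table). Ties on best-fit counts are broken by higher marginal
#' explanatory power, then by panel index.
#'
#' @param table a `cc_incidence` table.
#' @param threshold stopping fraction (default 0.02).
#' @param criterion `"max"` over windows (default) or `"sum"`.
#' @return object of class `"cc_selection"`: list with `method`,
#'   `selected` (ordered variable indices), `variables` (names), `trace`
#'   (data.frame per step: `variable_id, marginal, cumulative`),
#'   `stop_reason`, `n_responses`, `threshold_count`.
#' @export
stepwise_select <- function(table, threshold = 0.02,
                            criterion = c("max", "sum")) {
  stopifnot(inherits(table, "cc_incidence"))
  criterion <- match.arg(criterion)
  n_resp <- nrow(table$explains)
  if (n_resp == 0) stop("empty incidence table")
  thr <- threshold * n_resp
  remaining <- rep(TRUE, n_resp)
  selected <- integer()
  trace <- list()
  stop_reason <- "no remaining responses"
  repeat {
    if (!any(remaining)) break
    best <- table$best[remaining]
    win <- table$window[remaining]
    ok <- !is.na(best)
    if (!any(ok)) { stop_reason <- "no best fits remain"; break }
    counts <- table(factor(best[ok], 1:21), win[ok])
    score <- if (criterion == "max") apply(counts, 1, max)
             else rowSums(counts)
    score[selected] <- -1
    cand <- which(score == max(score) & score > 0)
    if (!length(cand)) { stop_reason <- "no candidate variable"; break }
    if (length(cand) > 1) {
      marg <- vapply(cand, function(v)
        sum(table$explains[remaining, v]), numeric(1))
      cand <- cand[order(-marg, cand)]
    }
    v <- unname(cand[1])
    marginal <- sum(table$explains[remaining, v])
    if (marginal < thr) {
      stop_reason <- sprintf("marginal explanatory power %d < %.1f (%.0f%% of %d responses)",
                             marginal, thr, 100 * threshold, n_resp)
      break
    }
    selected <- c(selected, v)
    trace[[length(trace) + 1]] <- data.frame(
      variable_id = v, marginal = marginal,
      cumulative = explanatory_power(selected, table))
    remaining <- remaining & !table$explains[, v]
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(variable_id = integer(), marginal = integer(),
               cumulative = integer())
  structure(list(method = "stepwise", selected = selected,
                 variables = cc_variables()$variable[selected],
                 trace = trace, stop_reason = stop_reason,
                 n_responses = n_resp, threshold_count = thr),
            class = "cc_selection")
}

#' Best-subset variable selection
#'
#' For each subset size n up to `max_size`, exhaustively finds the subset
#' of variables with the highest explanatory power (guaranteed optimal).
#' The returned size is the smallest n at which adding an (n+1)-th variable
#' gains less than `threshold` (fraction of responses). Candidate variables
#' are restricted to those explaining at least one response; equal-power
#' ties go to the lexicographically smallest index set.
#'
#' @param table a `cc_incidence` table.
#' @param max_size largest subset size to enumerate (<= 8).
#' @param threshold stopping fraction (default 0.02).
#' @param size optional fixed subset size: return the optimal subset of
#'   exactly this size, as when best-subset is used to verify the
#'   optimality of a stepwise result at its size. When `NULL` (default)
#'   the size is chosen by the marginal-gain rule; note that because
#'   explained sets overlap, cumulative coverage can saturate at a smaller
#'   size than stepwise selects.
#' @return a `cc_selection` object (`selected` is sorted by panel index;
#'   `trace` holds the best power per size).
#' @export
best_subset_select <- function(table, max_size = 8, threshold = 0.02,
                               size = NULL) {
  stopifnot(inherits(table, "cc_incidence"))
  if (max_size > 8) {
    stop("max_size > 8: exhaustive enumeration over 21 variables is not ",
         "tractable; use stepwise_select() or lower max_size")
  }
  n_resp <- nrow(table$explains)
  if (n_resp == 0) stop("empty incidence table")
  if (!is.null(size)) {
    stopifnot(size >= 1, size <= max_size)
  }
  thr <- threshold * n_resp
  # collapse responses to unique explained sets (bitmask + multiplicity)
  masks <- as.integer(table$explains %*% (2^(0:20)))
  tab <- table(masks)
  umask <- as.integer(names(tab))
  mult <- as.integer(tab)
  cand <- which(colSums(table$explains) > 0)
  power_of <- function(sub) {
    sm <- sum(2^(sub - 1))
    sum(mult[bitwAnd(umask, sm) > 0])
  }
  # equal-power ties: prefer the subset whose members best-fit the most
  # responses, then the lexicographically smallest index set
  bf <- tabulate(table$best[!is.na(table$best)], nbins = 21)
  best_sub <- list()
  best_pow <- numeric()
  for (n in seq_len(min(max_size, length(cand)))) {
    combs <- utils::combn(cand, n)
    pows <- apply(combs, 2, power_of)
    top <- which(pows == max(pows))
    if (length(top) > 1) {
      mass <- apply(combs[, top, drop = FALSE], 2, function(s) sum(bf[s]))
      top <- top[which.max(mass)]
    }
    i <- top[1]
    best_sub[[n]] <- combs[, i]
    best_pow[n] <- pows[i]
  }
  n_sizes <- length(best_pow)
  if (!is.null(size)) {
    if (size > n_sizes) stop("size exceeds the number of explaining variables")
    chosen <- size
    stop_reason <- sprintf("fixed size %d", size)
  } else {
    chosen <- n_sizes
    for (n in seq_len(n_sizes - 1)) {
      if (best_pow[n + 1] - best_pow[n] < thr) { chosen <- n; break }
    }
    stop_reason <- if (chosen < n_sizes) {
      sprintf("marginal gain at size %d < %.1f (%.0f%% of %d responses)",
              chosen + 1, thr, 100 * threshold, n_resp)
    } else "max_size reached"
  }
  selected <- sort(best_sub[[chosen]])
  structure(list(method = "best_subset", selected = selected,
                 variables = cc_variables()$variable[selected],
                 trace = data.frame(size = seq_len(n_sizes),
                                    power = best_pow),
                 stop_reason = stop_reason, n_responses = n_resp,
                 threshold_count = thr),
            class = "cc_selection")
}

#' @export
print.cc_selection <- function(x, ...) {
  cat(sprintf("%s selection over %d responses (stop threshold %.1f)\n",
              x$method, x$n_responses, x$threshold_count))
  cat("  selected:", if (length(x$selected))
    paste(x$variables, collapse = ", ") else "(none)", "\n")
  cat("  stop:", x$stop_reason, "\n")
  invisible(x)
}
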