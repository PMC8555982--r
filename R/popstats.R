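#' Session-level tests of the behavioral parameters
#'
#' Medians of the normalized behavioral parameters across sessions with
#' two-sided Wilcoxon signed-rank tests against 0 for the effect
#' parameters (`xi`, `eta`, `phi`, `delta`, `epsilon`). The relative value
#' `rho` is summarized by its median only (it is a ratio of quantities, not
#' an effect with a natural null at 0).
#'
#' @param fits per-session fit table from [fit_sessions()].
#' @param min_sessions minimum number of sessions required (default 6).
#' @return data.frame: `parameter, n, median, p`.
#' @export
session_param_tests <- function(fits, min_sessions = 6) {
  pars <- c("rho", "xi", "eta", "phi", "delta", "epsilon")
  stopifnot(all(pars %in% names(fits)))
  if (nrow(fits) < min_sessions) {
    stop("need at least ", min_sessions, " sessions")
  }
  rows <- lapply(pars, function(p) {
    x <- fits[[p]]
    pv <- if (p == "rho") NA_real_ else cc_signed_rank(x)
    if (p != "rho" && is.na(pv)) {
      warning("parameter ", p, ": test undefined (degenerate values)")
    }
    data.frame(parameter = p, n = sum(!is.na(x)),
               median = stats::median(x, na.rm = TRUE), p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square comparison of encoding percentages across two areas
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' area x (encodes / does not encode), one test per row of `counts`. When
#' any expected cell is below 1 a warning is raised and the Fisher exact
#' p-value is reported alongside.
#'
#' @param counts data.frame with columns `n_enc_1`, `n_tot_1`, `n_enc_2`,
#'   `n_tot_2` (and any id columns, carried through).
#' @return `counts` with appended `pct_1`, `pct_2`, `chisq`, `p`,
#'   `p_fisher` (NA unless expected counts were degenerate).
#' @export
area_comparison <- function(counts) {
  need <- c("n_enc_1", "n_tot_1", "n_enc_2", "n_tot_2")
  stopifnot(all(need %in% names(counts)))
  stopifnot(all(counts$n_tot_1 > 0), all(counts$n_tot_2 > 0),
            all(counts$n_enc_1 <= counts$n_tot_1),
            all(counts$n_enc_2 <= counts$n_tot_2))
  n <- nrow(counts)
  chisq <- p <- p_fisher <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- matrix(c(counts$n_enc_1[i], counts$n_tot_1[i] - counts$n_enc_1[i],
                  counts$n_enc_2[i], counts$n_tot_2[i] - counts$n_enc_2[i]),
                2, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      warning("row ", i, ": degenerate margin; chi-square set to 0, p = 1")
      chisq[i] <- 0; p[i] <- 1
      next
    }
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    chisq[i] <- unname(ct$statistic)
    p[i] <- ct$p.value
    if (any(ct$expected < 1)) {
      warning("row ", i, ": expected cell count < 1; reporting Fisher ",
              "exact p alongside")
      p_fisher[i] <- stats::fisher.test(m)$p.value
    }
  }
  counts$pct_1 <- 100 * counts$n_enc_1 / counts$n_tot_1
  counts$pct_2 <- 100 * counts$n_enc_2 / counts$n_tot_2
  counts$chisq <- chisq
  counts$p <- p
  counts$p_fisher <- p_fisher
  counts
}

#' Assemble the summary report of a full pipeline run
#'
#' Collects the stage outputs into the standard summary tables:
#' task-relatedness counts per window and factor, explained and best-fit
#' count matrices, per-window encoding percentages for the selected
#' variables, the epoch Delta-R2 summary, and the behavioral parameter
#' tests. Missing stages yield explicit gaps rather than errors.
#'
#' @param behavior_fits per-session fit table ([fit_sessions()]) or NULL.
#' @param relevance `cc_relevance` table or NULL.
#' @param classified [ancova_classify()] output or NULL.
#' @param selection `cc_selection` object or NULL.
#' @param integration [epoch_summary()] output or NULL.
#' @param n_neurons total number of recorded neurons (for percentages);
#'   inferred from `relevance` when NULL.
#' @return list of class `"cc_report"` with elements `behavior`,
#'   `task_relatedness`, `explained`, `best_fit`, `encoding_pct`,
#'   `selection`, `integration`, `gaps`.
#' @export
build_report <- function(behavior_fits = NULL, relevance = NULL,
                         classified = NULL, selection = NULL,
                         integration = NULL, n_neurons = NULL) {
  gaps <- character()
  rep_ <- list()
  if (!is.null(behavior_fits) && nrow(behavior_fits) >= 6) {
    rep_$behavior <- session_param_tests(behavior_fits)
  } else if (!is.null(behavior_fits)) {
    rep_$behavior <- behavior_fits
    gaps <- c(gaps, "behavior: < 6 sessions, medians reported without tests")
  } else gaps <- c(gaps, "behavior: missing")
  if (!is.null(relevance)) {
    rc <- relevance_counts(relevance)
    rep_$task_relatedness <- rc$by_window
    if (is.null(n_neurons)) n_neurons <- rc$n_neurons
    rep_$n_task_related <- rc$n_task_related
  } else gaps <- c(gaps, "task_relatedness: missing")
  if (!is.null(classified)) {
    cm <- count_matrices(classified)
    rep_$explained <- cm$explained
    rep_$best_fit <- cm$best
    if (!is.null(n_neurons) && n_neurons > 0) {
      sel_vars <- if (!is.null(selection)) selection$selected else
        which(colSums(cm$best) > 0)
      pct <- 100 * cm$best[, sel_vars, drop = FALSE] / n_neurons
      rep_$encoding_pct <- pct
    }
  } else gaps <- c(gaps, "ancova: missing")
  if (!is.null(selection)) {
    rep_$selection <- data.frame(step = seq_along(selection$selected),
                                 variable = selection$variables,
                                 stringsAsFactors = FALSE)
  } else gaps <- c(gaps, "selection: missing")
  if (!is.null(integration)) {
    rep_$integration <- integration$by_epoch
    rep_$p_epoch_diff <- integration$p_epoch_diff
  } else gaps <- c(gaps, "integration: missing")
  rep_$gaps <- gaps
  class(rep_) <- "cc_report"
  rep_
}

#' @export
print.cc_report <- function(x, ...) {
  cat("== choice-under-action-cost pipeline report ==\n")
  if (!is.null(x$behavior)) {
    cat("\nBehavioral parameters (per-session medians):\n")
    print(x$behavior)
  }
  if (!is.null(x$task_relatedness)) {
    cat("\nTask-related responses per window and factor (p < 0.001):\n")
    print(x$task_relatedness)
    cat("neurons with >= 1 task-related response:", x$n_task_related, "\n")
  }
  if (!is.null(x$best_fit)) {
    nz <- colSums(x$best_fit) > 0
    cat("\nBest-fit counts (windows x variables with any best fit):\n")
    print(x$best_fit[, nz, drop = FALSE])
  }
  if (!is.null(x$selection)) {
    cat("\nSelected variables (stepwise order):\n")
    print(x$selection)
  }
  if (!is.null(x$integration)) {
    cat("\nChosen-value Delta-R2 by epoch:\n")
    print(x$integration)
    cat("epoch difference (rank-sum) p =", format(x$p_epoch_diff), "\n")
  }
  if (length(x$gaps)) cat("\nGaps:", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

#' Write report tables to CSV
#'
#' @param report a `cc_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(obj, name) {
    if (is.null(obj)) return()
    path <- file.path(dir, paste0(name, ".csv"))
    if (is.matrix(obj)) {
      utils::write.csv(as.data.frame(obj), path, row.names = TRUE)
    } else {
      utils::write.csv(obj, path, row.names = FALSE)
    }
    files <<- c(files, path)
  }
  wr(report$behavior, "behavior_parameters")
  wr(report$task_relatedness, "task_relatedness")
  wr(report$explained, "explained_counts")
  wr(report$best_fit, "best_fit_counts")
  wr(report$encoding_pct, "encoding_percentages")
  wr(report$selection, "selected_variables")
  wr(report$integration, "integration_epochs")
  invisible(files)
}
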