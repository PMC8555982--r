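#' ANCOVA covariate for a time window
#'
#' Early windows (pre-offer through pre-target) use the chosen offer
#' location; late windows (post-target through post-juice) use the chosen
#' target location. Both are coded 1 = contralateral to the recorded
#' hemisphere.
#'
#' @param window window id(s).
#' @return covariate column name(s) in the variable panel.
#' @export
ancova_covariate <- function(window) {
  ifelse(cc_epoch(window) == "early", "chosen_offer_contra",
         "chosen_target_contra")
}

# ANCOVA data-point structure: per (trial type x covariate level) cell with
# at least `min_trials` trials, the mean of each panel variable (NA-aware:
# a cell keeps a variable only if >= min_trials non-NA trials, so undefined
# value ratios drop out pairwise). Shared by every neuron in a session, so
# computed once per covariate.
ancova_points <- function(trials, panel, covariate, min_trials = 2) {
  g <- panel[[covariate]]
  cell <- paste(trial_type_label(trials), g, sep = "|")
  cnt <- table(cell)
  keep_cells <- names(cnt)[cnt >= min_trials]
  use <- cell %in% keep_cells
  cell <- factor(cell[use], levels = keep_cells)
  vars <- cc_variables()$variable
  xm <- sapply(vars, function(v) {
    x <- panel[[v]][use]
    m <- tapply(x, cell, function(z) {
      z <- z[!is.na(z)]
      if (length(z) >= min_trials) mean(z) else NA_real_
    })
    as.numeric(m)
  })
  list(use = use, cell = cell,
       g = as.numeric(tapply(g[use], cell, mean)),
       x = xm, cells = keep_cells)
}

# cell-mean rates for one response on a precomputed point structure
cell_means <- function(rate, points) {
  as.numeric(tapply(rate[points$use], points$cell, mean))
}

# one-shot OLS summary used by both ANCOVA models; X is a named matrix of
# regressors (aliased regressors are absent from the coefficient table and
# report NA)
ols_summary <- function(y, X) {
  df <- data.frame(y = y, as.data.frame(X))
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  rn <- rownames(co)
  get <- function(name) {
    i <- match(name, rn)
    if (is.na(i)) c(est = NA_real_, p = NA_real_)
    else c(est = co[i, 1], p = co[i, 4])
  }
  list(r2 = sm$r.squared, get = get, df_res = fit$df.residual)
}

#' Parallel-lines ANCOVA fit of one response against one variable
#'
#' Linear model `rate ~ variable + group` (no interaction) on the response
#' data points; the group is the binary chosen-location covariate. The
#' variable "explains" the response when its slope is significant at
#' `p < 0.05`; the reported R2 is the total R2 of the two-regressor model,
#' bookkept as 0 when the variable does not explain.
#'
#' @param y numeric response (mean rate per data point).
#' @param x numeric variable value per data point.
#' @param g binary group (0/1 covariate level) per data point.
#' @param alpha significance level for "explains" (default 0.05).
#' @return one-row data.frame: `model, r2, r2_model, p_factor, p_group,
#'   explains, slope_sign`.
#' @export
fit_parallel <- function(y, x, g, alpha = 0.05) {
  ok <- !(is.na(y) | is.na(x) | is.na(g))
  y <- y[ok]; x <- x[ok]; g <- g[ok]
  if (length(y) < 4 || stats::sd(x) == 0) {
    return(data.frame(model = "parallel", r2 = 0, r2_model = NA_real_,
                      p_factor = NA_real_, p_group = NA_real_,
                      explains = FALSE, slope_sign = NA_real_,
                      stringsAsFactors = FALSE))
  }
  s <- ols_summary(y, cbind(x = x, g = g))
  fx <- s$get("x"); fg <- s$get("g")
  explains <- isTRUE(fx["p"] < alpha)
  data.frame(model = "parallel",
             r2 = if (explains) s$r2 else 0,
             r2_model = s$r2,
             p_factor = unname(fx["p"]), p_group = unname(fg["p"]),
             explains = explains,
             slope_sign = unname(sign(fx["est"])),
             stringsAsFactors = FALSE)
}

#' Horizontal-lines ANCOVA fit (group only)
#'
#' Linear model `rate ~ group`, used for the location-only variables: the
#' response is explained when the group effect is significant. Because the
#' group is one of the two regressors of every parallel-lines model on the
#' same data points, the horizontal R2 can never exceed an explaining
#' parallel R2, so a location-only variable can provide the best fit only
#' when it provides the sole explanation.
#'
#' @inheritParams fit_parallel
#' @return one-row data.frame as in [fit_parallel()] (`p_factor` is `NA`).
#' @export
fit_horizontal <- function(y, g, alpha = 0.05) {
  ok <- !(is.na(y) | is.na(g))
  y <- y[ok]; g <- g[ok]
  if (length(y) < 3 || length(unique(g)) < 2) {
    return(data.frame(model = "horizontal", r2 = 0, r2_model = NA_real_,
                      p_factor = NA_real_, p_group = NA_real_,
                      explains = FALSE, slope_sign = NA_real_,
                      stringsAsFactors = FALSE))
  }
  s <- ols_summary(y, cbind(g = g))
  fg <- s$get("g")
  explains <- isTRUE(fg["p"] < alpha)
  data.frame(model = "horizontal",
             r2 = if (explains) s$r2 else 0,
             r2_model = s$r2,
             p_factor = NA_real_, p_group = unname(fg["p"]),
             explains = explains, slope_sign = unname(sign(fg["est"])),
             stringsAsFactors = FALSE)
}

# All 21 variable fits for one response (one neuron, one window).
# Location-only variables are assessed with the horizontal model in their
# matching epoch only (variable 20 early, variable 21 late); the other one
# is recorded as not explaining.
ancova_response <- function(rate, trials, panel, window,
                            level = c("means", "trials"), alpha = 0.05,
                            points = NULL) {
  level <- match.arg(level)
  covariate <- ancova_covariate(window)
  vt <- cc_variables()
  if (level == "means") {
    if (is.null(points)) {
      points <- ancova_points(trials, panel, covariate)
    }
    y <- cell_means(rate, points)
    g <- points$g
    xs <- function(i) points$x[, vt$variable[i]]
  } else {
    y <- rate; g <- panel[[covariate]]
    xs <- function(i) panel[[vt$variable[i]]]
  }
  loc_var <- if (cc_epoch(window) == "early") 20L else 21L
  rows <- vector("list", 21L)
  for (i in 1:21) {
    rows[[i]] <- if (i %in% LOC_ONLY_VARS) {
      if (i == loc_var) fit_horizontal(y, g, alpha)
      else data.frame(model = "horizontal", r2 = 0, r2_model = NA_real_,
                      p_factor = NA_real_, p_group = NA_real_,
                      explains = FALSE, slope_sign = NA_real_,
                      stringsAsFactors = FALSE)
    } else {
      fit_parallel(y, xs(i), g, alpha)
    }
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(variable_id = vt$index, variable = vt$variable,
                   window = window, stringsAsFactors = FALSE), out)
}

#' Classify one response from its 21 variable fits
#'
#' The explained set contains every variable whose ANCOVA factor (or, for
#' location-only variables, group) is significant. The best variable is the
#' explainer with the highest bookkept R2, with two rules: a location-only
#' variable can be best only when it is the sole explainer, and exact R2
#' ties are broken in panel-index order.
#'
#' @param fits data.frame from `ancova_response()` (21 rows).
#' @return one-row data.frame: `window, best_variable_id, best_variable,
#'   best_r2, n_explained, explained_set` (comma-separated indices).
#' @export
classify_response <- function(fits) {
  stopifnot(nrow(fits) == 21)
  expl <- which(fits$explains)
  best_id <- NA_integer_; best_r2 <- NA_real_
  if (length(expl)) {
    cand <- expl
    non_loc <- setdiff(cand, LOC_ONLY_VARS)
    if (length(non_loc)) cand <- non_loc
    cand <- cand[order(-fits$r2[cand], fits$variable_id[cand])]
    best_id <- fits$variable_id[cand[1]]
    best_r2 <- fits$r2[cand[1]]
  }
  data.frame(
    window = fits$window[1],
    best_variable_id = best_id,
    best_variable = if (is.na(best_id)) NA_character_ else
      cc_variables()$variable[best_id],
    best_r2 = best_r2,
    n_explained = length(expl),
    explained_set = paste(expl, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Fit and classify every task-related response of a population
#'
#' Runs the parallel/horizontal ANCOVAs for all 21 panel variables on each
#' task-related (neuron, window) response and classifies it. By default the
#' data points are per-(trial type x covariate level) mean rates with at
#' least 2 trials per cell; `level = "trials"` fits on individual trials.
#'
#' @param rates long rate table (`neuron_id, trial_index, window, rate`).
#' @param trials the session's `cc_trials` table.
#' @param panel the matching [compute_variables()] panel.
#' @param relevance optional `cc_relevance` table from
#'   [screen_task_related()]; when supplied only task-related responses are
#'   analyzed, otherwise all responses are.
#' @param level `"means"` (default) or `"trials"`.
#' @param alpha ANCOVA significance level (default 0.05).
#' @return list with `fits` (long data.frame over responses x variables)
#'   and `classification` (one row per response, see
#'   [classify_response()]).
#' @export
ancova_classify <- function(rates, trials, panel, relevance = NULL,
                            level = "means", alpha = 0.05) {
  keys <- unique(rates[, c("neuron_id", "window")])
  if (!is.null(relevance)) {
    tr <- relevance[relevance$task_related,
                    c("neuron_id", "window"), drop = FALSE]
    keys <- merge(keys, tr, by = c("neuron_id", "window"))
  }
  keys <- keys[order(keys$neuron_id, match(keys$window, cc_windows())), ,
               drop = FALSE]
  pts <- list(
    chosen_offer_contra = ancova_points(trials, panel, "chosen_offer_contra"),
    chosen_target_contra = ancova_points(trials, panel, "chosen_target_contra")
  )
  fits <- vector("list", nrow(keys))
  cls <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sel <- rates$neuron_id == keys$neuron_id[k] &
      rates$window == keys$window[k]
    rate <- rates$rate[sel][match(trials$trial_index,
                                  rates$trial_index[sel])]
    f <- ancova_response(rate, trials, panel, keys$window[k],
                         level = level, alpha = alpha,
                         points = if (level == "means")
                           pts[[ancova_covariate(keys$window[k])]])
    f$neuron_id <- keys$neuron_id[k]
    fits[[k]] <- f
    ck <- classify_response(f)
    ck$neuron_id <- keys$neuron_id[k]
    cls[[k]] <- ck
  }
  fits <- do.call(rbind, fits)
  cls <- do.call(rbind, cls)
  rownames(fits) <- rownames(cls) <- NULL
  list(fits = fits, classification = cls)
}

#' Explained-response and best-fit count matrices
#'
#' Per (window, variable): the number of responses explained by the
#' variable (a response can contribute to several variables) and the number
#' for which it provided the best fit (each response contributes at most
#' once). The group split gives, per variable and window, how many
#' explained responses also had a significant group effect.
#'
#' @param classified output of [ancova_classify()].
#' @return list of matrices `explained`, `best` (windows x 21) and
#'   data.frame `group_split` with `n_explained`, `n_factor_and_group`,
#'   `n_factor_only` per (window, variable).
#' @export
count_matrices <- function(classified) {
  fits <- classified$fits
  vt <- cc_variables()
  wins <- cc_windows()
  zero <- matrix(0L, length(wins), 21,
                 dimnames = list(wins, vt$variable))
  explained <- best <- zero
  if (nrow(fits)) {
    e <- fits[fits$explains, , drop = FALSE]
    if (nrow(e)) {
      t1 <- table(factor(e$window, wins), factor(e$variable_id, 1:21))
      explained <- explained + unclass(t1)
    }
    cl <- classified$classification
    cb <- cl[!is.na(cl$best_variable_id), , drop = FALSE]
    if (nrow(cb)) {
      t2 <- table(factor(cb$window, wins),
                  factor(cb$best_variable_id, 1:21))
      best <- best + unclass(t2)
    }
    gs <- fits[fits$explains, , drop = FALSE]
    both <- !is.na(gs$p_group) & gs$p_group < 0.05 &
      gs$model == "parallel"
    split_df <- stats::aggregate(
      cbind(n_explained = rep(1L, nrow(gs)),
            n_factor_and_group = as.integer(both)),
      by = list(window = gs$window, variable = gs$variable),
      FUN = sum)
    split_df$n_factor_only <- split_df$n_explained -
      split_df$n_factor_and_group
  } else {
    split_df <- data.frame(window = character(), variable = character(),
                           n_explained = integer(),
                           n_factor_and_group = integer(),
                           n_factor_only = integer())
  }
  dimnames(explained) <- dimnames(best) <- dimnames(zero)
  list(explained = explained, best = best, group_split = split_df)
}
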