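#' Build and validate a trial table
#'
#' A trial table holds one completed choice trial per row. Each trial offers
#' two juices (A and B) in quantities `qA`, `qB`; exactly one offer carries
#' the low action cost (short saccade) and the other the high cost (long
#' saccade). Offers appear on opposite sides of fixation and the two saccade
#' targets occupy opposite hemifields. `chosen_juice` records the outcome.
#'
#' `as_cc_trials()` checks the structural invariants, binarizes the target
#' angle into a hemifield when only `target_angle_deg` is supplied (angles in
#' (90, 270) map to the left hemifield), and appends the 0/1 indicator
#' columns used by the logistic choice model (low-cost indicators, previous
#' trial juice and cost indicators, offer/target side indicators). Indicators
#' referring to the previous trial are 0 on the first trial of a session.
#'
#' @param df data.frame with columns `session_id`, `trial_index`, `qA`, `qB`,
#'   `costA`, `costB` (each `"low"` or `"high"`), `offerA_side`,
#'   `targetA_side` (`"L"`/`"R"`; `targetA_side` may be omitted if
#'   `target_angle_deg` is present), `chosen_juice` (`"A"`/`"B"`).
#' @return the validated data.frame with class `"cc_trials"` and indicator
#'   columns appended.
#' @export
as_cc_trials <- function(df) {
  need <- c("session_id", "trial_index", "qA", "qB", "costA", "costB",
            "offerA_side", "chosen_juice")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"targetA_side" %in% names(df)) {
    if (!"target_angle_deg" %in% names(df)) {
      stop("need either targetA_side or target_angle_deg")
    }
    ang <- df$target_angle_deg %% 360
    df$targetA_side <- ifelse(ang > 90 & ang < 270, "L", "R")
  }
  stopifnot(all(df$qA >= 0), all(df$qB >= 0))
  if (!all(df$costA %in% c("low", "high")) ||
      !all(df$costB %in% c("low", "high"))) {
    stop("costA/costB must be 'low' or 'high'")
  }
  if (any(df$costA == df$costB)) {
    stop("exactly one offer must be low cost and the other high cost")
  }
  if (!all(df$offerA_side %in% c("L", "R")) ||
      !all(df$targetA_side %in% c("L", "R"))) {
    stop("offerA_side/targetA_side must be 'L' or 'R'")
  }
  if (!all(df$chosen_juice %in% c("A", "B"))) {
    stop("chosen_juice must be 'A' or 'B'")
  }
  ord <- order(df$session_id, df$trial_index)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("session_id", "trial_index")])
  if (any(dup)) stop("duplicated (session_id, trial_index)")
  df <- add_indicators(df)
  rownames(df) <- NULL
  class(df) <- c("cc_trials", "data.frame")
  df
}

# Append the 0/1 indicators of Eq.-style choice model and convenience
# columns (opposite-side fields, chosen sides). Assumes rows sorted by
# session and trial index.
add_indicators <- function(df) {
  df$offerB_side  <- ifelse(df$offerA_side == "L", "R", "L")
  df$targetB_side <- ifelse(df$targetA_side == "L", "R", "L")
  df$d_A_plus <- as.integer(df$costA == "low")
  df$d_B_plus <- as.integer(df$costB == "low")
  df$offerA_left  <- as.integer(df$offerA_side == "L")
  df$offerB_left  <- 1L - df$offerA_left
  df$targetA_left <- as.integer(df$targetA_side == "L")
  df$targetB_left <- 1L - df$targetA_left
  df$chosen_side <- ifelse(df$chosen_juice == "A", df$offerA_side,
                           df$offerB_side)
  df$chosen_target_side <- ifelse(df$chosen_juice == "A", df$targetA_side,
                                  df$targetB_side)
  df$chosen_cost_level <- ifelse(df$chosen_juice == "A", df$costA, df$costB)

  # previous-trial indicators, per session; first trial gets all zeros
  n <- nrow(df)
  prev_juice <- rep(NA_character_, n)
  prev_cost  <- rep(NA_character_, n)
  if (n > 1) {
    same <- df$session_id[-1] == df$session_id[-n]
    prev_juice[-1][same] <- df$chosen_juice[-n][same]
    prev_cost[-1][same]  <- df$chosen_cost_level[-n][same]
  }
  df$d_prev_A <- as.integer(!is.na(prev_juice) & prev_juice == "A")
  df$d_prev_B <- as.integer(!is.na(prev_juice) & prev_juice == "B")
  df$d_costprev_A <- as.integer(!is.na(prev_cost) & df$costA == prev_cost)
  df$d_costprev_B <- as.integer(!is.na(prev_cost) & df$costB == prev_cost)
  df
}

#' Enumerate trial types within a session
#'
#' A trial type is a pair of offers plus the choice made, e.g.
#' `[1A+:3B-, A]`: 1 drop of juice A at low cost against 3 drops of juice B
#' at high cost, juice A chosen. Every completed trial belongs to exactly
#' one trial type; the counts returned sum to the number of trials.
#'
#' @param trials a `cc_trials` table from a single session.
#' @return data.frame with columns `trial_type` (label like `"1A+:3B-,A"`),
#'   `qA`, `qB`, `costA`, `chosen_juice`, `n`.
#' @export
enumerate_trial_types <- function(trials) {
  if (nrow(trials) == 0) {
    return(data.frame(trial_type = character(), qA = numeric(),
                      qB = numeric(), costA = character(),
                      chosen_juice = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  if (length(unique(trials$session_id)) > 1) {
    stop("trial types are defined within a session; got multiple session_id")
  }
  lab <- trial_type_label(trials)
  tab <- table(lab)
  key <- !duplicated(lab)
  out <- data.frame(
    trial_type = lab[key],
    qA = trials$qA[key], qB = trials$qB[key],
    costA = trials$costA[key], chosen_juice = trials$chosen_juice[key],
    stringsAsFactors = FALSE
  )
  out$n <- as.integer(tab[out$trial_type])
  out <- out[order(out$qB / pmax(out$qA, 0.5), out$costA, out$chosen_juice), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# compact [qA A cost : qB B cost, choice] label; also the trial-type factor
# used by the ANOVA screen and the ANCOVA cell means
trial_type_label <- function(trials) {
  pm <- function(cost) ifelse(cost == "low", "+", "-")
  paste0(trials$qA, "A", pm(trials$costA), ":",
         trials$qB, "B", pm(trials$costB), ",", trials$chosen_juice)
}

#' Read a trial table from CSV
#'
#' Expected columns: `session_id, trial_index, qA, qB, costA, costB,
#' offerA_side, targetA_side, chosen_juice` and optionally
#' `target_angle_deg, chosen_side`.
#'
#' @param path CSV file path.
#' @return a validated `cc_trials` table.
#' @export
read_trials_csv <- function(path) {
  as_cc_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}
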