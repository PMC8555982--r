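#' The candidate decision-variable panel
#'
#' Twenty-one candidate variables that neurons might encode, defined in
#' juice-, cost-, spatial- (visual) and action-based reference frames.
#' Offer values are expressed in units of juice B: offer value A is
#' `rho * qA + xi * d(A low cost)` and offer value B is
#' `qB + xi * d(B low cost)`, where `rho` is the session's relative value of
#' the two juices and `xi` the value-equivalent action cost, both taken from
#' the behavioral logistic fit.
#'
#' @return data.frame with columns `index`, `variable` (column name used in
#'   the computed panel), `collapsed` (collapsed-variable group label, `NA`
#'   for singletons) and `frame`.
#' @export
cc_variables <- function() {
  data.frame(
    index = 1:21,
    variable = c("offer_value_A", "offer_value_B", "chosen_juice",
                 "offer_value_minus", "offer_value_plus", "chosen_cost",
                 "offer_value_L", "offer_value_R",
                 "offer_value_target_L", "offer_value_target_R",
                 "cost_of_A", "offer_A_location", "target_A_location",
                 "offer_plus_location", "target_plus_location",
                 "spatial_congruence", "chosen_value", "value_ratio",
                 "cost_benefit_conflict",
                 "chosen_offer_loc_only", "chosen_target_loc_only"),
    collapsed = c("offer value (juice)", "offer value (juice)", NA,
                  "offer value (cost)", "offer value (cost)", NA,
                  "offer value (location)", "offer value (location)",
                  "offer value (target)", "offer value (target)",
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    frame = c("juice", "juice", "juice", "cost", "cost", "cost",
              "visual", "visual", "action", "action",
              NA, NA, NA, NA, NA, NA, NA, NA, NA, "visual", "action"),
    stringsAsFactors = FALSE
  )
}

# indices of the location-only variables, handled by the horizontal model
LOC_ONLY_VARS <- c(20L, 21L)

#' Compute the decision-variable panel for every trial
#'
#' Populates one value per variable per trial, plus the two binary ANCOVA
#' covariates `chosen_offer_contra` and `chosen_target_contra` (1 when the
#' chosen offer / chosen target lies in the hemifield contralateral to the
#' recorded hemisphere).
#'
#' Definitions, per trial: offer value A/B as in [cc_variables()]; chosen
#' juice = 1 if B chosen; offer value -/+ = value of the high-/low-cost
#' offer; chosen cost = 1 if the low-cost offer was chosen; offer value L/R
#' = value of the juice offered left/right; offer value target L/R = value
#' of the juice whose saccade target is in the left/right hemifield; cost of
#' A = 1 if offer A is low cost; location indicators are 1 for left;
#' spatial congruence = 1 if each juice's offer and target share a
#' hemifield; chosen value = value of the chosen offer; value ratio =
#' other value / chosen value (NA when the chosen value is 0, and such
#' trials are excluded pairwise from regressions on value ratio);
#' cost/benefit conflict = 1 if the high-cost offer carries the strictly
#' higher offer value; chosen offer/target loc only = 1 if the chosen
#' offer/target is on the left.
#'
#' @param trials a `cc_trials` table (one session).
#' @param rho relative value of juice A in units of juice B (`a1/a0`).
#' @param xi value-equivalent action cost in units of juice B (`a2/a0`).
#' @param hemisphere recorded hemisphere, `"left"` or `"right"`; determines
#'   the contralateral coding of the covariates.
#' @return data.frame of 21 variable columns plus `chosen_offer_contra` and
#'   `chosen_target_contra`, with class `"cc_variable_panel"`.
#' @export
compute_variables <- function(trials, rho, xi, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.finite(rho), is.finite(xi))
  vA <- rho * trials$qA + xi * trials$d_A_plus
  vB <- trials$qB + xi * trials$d_B_plus
  choseB <- as.integer(trials$chosen_juice == "B")
  a_low <- trials$costA == "low"
  v <- data.frame(
    offer_value_A = vA,
    offer_value_B = vB,
    chosen_juice = choseB,
    offer_value_minus = ifelse(a_low, vB, vA),
    offer_value_plus  = ifelse(a_low, vA, vB),
    chosen_cost = as.integer(trials$chosen_cost_level == "low"),
    offer_value_L = ifelse(trials$offerA_side == "L", vA, vB),
    offer_value_R = ifelse(trials$offerA_side == "R", vA, vB),
    offer_value_target_L = ifelse(trials$targetA_side == "L", vA, vB),
    offer_value_target_R = ifelse(trials$targetA_side == "R", vA, vB),
    cost_of_A = trials$d_A_plus,
    offer_A_location = trials$offerA_left,
    target_A_location = trials$targetA_left,
    offer_plus_location = ifelse(a_low, trials$offerA_left, trials$offerB_left),
    target_plus_location = ifelse(a_low, trials$targetA_left, trials$targetB_left),
    spatial_congruence = as.integer(trials$offerA_side == trials$targetA_side),
    chosen_value = ifelse(choseB == 1, vB, vA),
    stringsAsFactors = FALSE
  )
  other_value <- ifelse(choseB == 1, vA, vB)
  v$value_ratio <- ifelse(v$chosen_value > 0, other_value / v$chosen_value, NA_real_)
  high_value <- ifelse(a_low, vB, vA)  # value of the high-cost offer
  low_value  <- ifelse(a_low, vA, vB)
  v$cost_benefit_conflict <- as.integer(high_value > low_value)
  v$chosen_offer_loc_only  <- as.integer(trials$chosen_side == "L")
  v$chosen_target_loc_only <- as.integer(trials$chosen_target_side == "L")
  contra <- if (hemisphere == "left") "R" else "L"
  v$chosen_offer_contra  <- as.integer(trials$chosen_side == contra)
  v$chosen_target_contra <- as.integer(trials$chosen_target_side == contra)
  class(v) <- c("cc_variable_panel", "data.frame")
  v
}
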