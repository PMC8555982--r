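#' Time windows and epochs
#'
#' Neuronal activity is analyzed in nine 0.5-s time windows aligned with
#' behavioral events: pre-offer (0.5 s before offer onset), post-offer
#' (0.5 s after offer onset), late-delay (0.5-1.0 s after offer onset),
#' mem-delay (0-0.5 s after offer offset), pre-target (0.5 s before target
#' onset), post-target (0.5 s after target onset), pre-go (0.5 s before the
#' go signal), pre-juice (0.5 s before juice delivery), and post-juice
#' (0.5 s after juice delivery). Windows are half-open [start, start + 0.5)
#' so boundary spikes are never double counted.
#'
#' Windows before target presentation form the "early" epoch, in which the
#' ANCOVA covariate is the chosen offer location; windows from target onset
#' on form the "late" epoch, using the chosen target location. The pre-offer
#' window follows the early convention.
#'
#' @return `cc_windows()` returns the nine window ids in trial order;
#'   `cc_epoch()` returns `"early"` or `"late"` for each requested window.
#' @examples
#' cc_windows()
#' cc_epoch("pre-go")
#' @export
cc_windows <- function() {
  c("pre-offer", "post-offer", "late-delay", "mem-delay", "pre-target",
    "post-target", "pre-go", "pre-juice", "post-juice")
}

#' @rdname cc_windows
#' @param window character vector of window ids.
#' @export
cc_epoch <- function(window) {
  window <- match.arg(window, cc_windows(), several.ok = TRUE)
  ifelse(window %in% cc_windows()[1:5], "early", "late")
}

# duration common to all nine windows, seconds
WINDOW_DURATION <- 0.5

# window id -> (alignment event, offset of window start relative to event)
window_alignment <- function() {
  data.frame(
    window = cc_windows(),
    event  = c("offer_on", "offer_on", "offer_on", "offer_off", "target_on",
               "target_on", "go", "juice", "juice"),
    offset = c(-0.5, 0, 0.5, 0, -0.5, 0, -0.5, -0.5, 0),
    stringsAsFactors = FALSE
  )
}
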