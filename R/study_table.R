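#' Published per-student results of the reference KYT observer study
#'
#' The printed per-observer results for the six radiological-technologist
#' students who read the 53-scene hazard-prediction set twice, before and
#' after patient-safety training: figure of merit (3 decimals), point-based
#' sensitivity and scene-based specificity (percentages, 1 decimal, over 42
#' hazard points and 27 no-hazard scenes respectively). These printed values
#' are the only per-observer numbers the study released; they are the inputs
#' for reproducing its summary rows and paired t tests.
#'
#' @return data.frame with columns `observer_id`, `fom_before`, `fom_after`,
#'   `sensitivity_before`, `sensitivity_after`, `specificity_before`,
#'   `specificity_after`.
#' @examples
#' tab <- kyt_rt_students()
#' round_half_up(mean(tab$fom_before), 3) # 0.732
#' fom_t_test(tab$fom_before[1:5], tab$fom_after[1:5], kind = "paired")
#' @export
kyt_rt_students <- function() {
  data.frame(
    observer_id = paste0("S", 1:6),
    fom_before = c(0.713, 0.729, 0.743, 0.707, 0.746, 0.751),
    fom_after = c(0.799, 0.788, 0.764, 0.751, 0.756, 0.683),
    sensitivity_before = c(45.2, 57.1, 57.1, 47.6, 57.1, 66.7),
    sensitivity_after = c(54.8, 66.7, 78.6, 59.5, 61.9, 61.9),
    specificity_before = c(100.0, 81.5, 85.2, 85.2, 81.5, 88.9),
    specificity_after = c(100.0, 88.9, 66.7, 88.9, 88.9, 51.9),
    stringsAsFactors = FALSE
  )
}
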