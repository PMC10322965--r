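# Reported accuracy of the seven algorithms in the reference in-hospital
# validation study, shipped as worked-example input.  The underlying 210
# vignettes are unpublished, so these printed values serve as fixed inputs
# for metric-identity checks (e.g. recomputing the Youden index from the
# reported sensitivity/specificity pairs), not as something this package
# recomputes from raw data.

#' Reported diagnostic-accuracy table
#'
#' Sensitivity, specificity, predictive values, Youden index and
#' triage-error percentages reported for the seven triage algorithms, per
#' detection category (1 = SK I .. 3 = SK III), in the reference
#' in-hospital validation study.  Over-triage is structurally impossible
#' for SK I and under-triage for SK III; those cells are \code{NA}.
#'
#' @return data.frame with columns \code{algorithm}, \code{category},
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   \code{youden}, \code{overtriage_pct}, \code{undertriage_pct}.
#' @export
#' @examples
#' acc <- reported_accuracy()
#' ber1 <- acc[acc$algorithm == "BER" & acc$category == 1, ]
#' youden(ber1$sensitivity, ber1$specificity)
reported_accuracy <- function() {
  utils::read.csv(system.file("extdata", "reported_accuracy.csv",
                              package = "mcitriage", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
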