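## Closed-form calculators for the qPCR resection assay and reporter
## normalization.

#' Percentage of single-stranded DNA from a qPCR delta-CT
#'
#' Quantifies DNA-end resection at a double-strand break site from
#' quantitative PCR across a restriction site: with \code{deltaCT} the
#' difference in average cycles between the enzyme-digested sample and its
#' undigested counterpart,
#' \deqn{\%ssDNA = 1 / (2^{\Delta CT - 1} + 0.5) \times 100.}
#' The function is strictly decreasing in \code{deltaCT}, equals exactly
#' 100 at 0 (fully single-stranded), and tends to 0 as \code{deltaCT} grows.
#' Negative inputs (possible from replicate noise) are accepted with a
#' warning since they yield values above 100.
#'
#' @param deltaCT Numeric vector of cycle differences (digested minus
#'   undigested).
#' @return Percentage(s) of ssDNA.
#' @examples
#' ssdnaPercentage(0)  # 100
#' ssdnaPercentage(3)  # 22.22...
#' @export
ssdnaPercentage <- function(deltaCT) {
  if (any(!is.finite(deltaCT)))
    stop("'deltaCT' must be finite")
  if (any(deltaCT < 0))
    warning("negative deltaCT yields > 100% ssDNA; check replicate order")
  1 / (2^(deltaCT - 1) + 0.5) * 100
}

#' Normalize measurements to a control mean
#'
#' Divides each value by the control mean so the control set maps to mean
#' 1; used to express reporter efficiencies relative to control samples.
#'
#' @param values Numeric vector of measurements (may be empty).
#' @param controlMean Positive control mean.
#' @return \code{values / controlMean}.
#' @examples
#' normalizeToControl(c(2, 4), 2)  # 1, 2
#' @export
normalizeToControl <- function(values, controlMean) {
  if (!is.finite(controlMean) || controlMean <= 0)
    stop("'controlMean' must be a positive finite value")
  values / controlMean
}
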