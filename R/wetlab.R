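#' Relative electrolyte leakage
#'
#' `100 * conductivity_sample / conductivity_boiled`: the conductivity of
#' an aqueous leaf extract before or after freezing, relative to the same
#' sample after boiling (complete membrane disruption), in percent. A
#' membrane-integrity marker of cold-stress load.
#'
#' @param conductivity_sample Conductivity of the tested sample (uS/cm),
#'   before or after freezing depending on the assay variant.
#' @param conductivity_boiled Conductivity of the same sample after
#'   boiling (uS/cm), must be positive.
#' @return Leakage in percent.
#' @export
electrolyte_leakage_percent <- function(conductivity_sample,
                                        conductivity_boiled) {
  if (any(conductivity_boiled <= 0))
    stop("conductivity after boiling must be positive")
  if (any(conductivity_sample < 0))
    stop("conductivity must be nonnegative")
  100 * conductivity_sample / conductivity_boiled
}

#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification: `dCt = Ct_target - mean(reference
#' Cts)` per record, `ddCt = dCt_sample - dCt_calibrator`, fold change
#' `2^-ddCt`. Multiple reference genes (e.g. RPL2, EF-1-alpha, UBI) are
#' combined by the arithmetic mean of their Cts, i.e. the geometric mean
#' on the linear scale. Amplification efficiency is fixed at 2 per cycle.
#'
#' @param sample_ct Target-gene Ct in the sample of interest.
#' @param sample_ref_cts Named numeric vector of reference-gene Cts for
#'   the sample.
#' @param calibrator_ct Target-gene Ct in the calibrator (e.g. control)
#'   sample.
#' @param calibrator_ref_cts Named numeric vector of reference-gene Cts
#'   for the calibrator; must name the same reference genes.
#' @return Fold change of the target in the sample relative to the
#'   calibrator.
#' @export
relative_expression_ddct <- function(sample_ct, sample_ref_cts,
                                     calibrator_ct, calibrator_ref_cts) {
  cts <- c(sample_ct, sample_ref_cts, calibrator_ct, calibrator_ref_cts)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be finite and positive")
  if (!is.null(names(sample_ref_cts)) || !is.null(names(calibrator_ref_cts))) {
    if (!setequal(names(sample_ref_cts), names(calibrator_ref_cts)))
      stop("sample and calibrator must use the same reference genes")
    calibrator_ref_cts <- calibrator_ref_cts[names(sample_ref_cts)]
  } else if (length(sample_ref_cts) != length(calibrator_ref_cts)) {
    stop("sample and calibrator must use the same reference genes")
  }
  d_sample <- sample_ct - mean(sample_ref_cts)
  d_calib <- calibrator_ct - mean(calibrator_ref_cts)
  2^(-(d_sample - d_calib))
}
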