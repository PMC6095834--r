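#' A replicated qPCR measurement
#'
#' Ct values (threshold cycles) for one target gene and one reference gene
#' in one sample.
#'
#' @param sample Sample label.
#' @param target Target gene.
#' @param ct_target Numeric Ct replicates for the target, finite and > 0.
#' @param reference Reference (housekeeping) gene, default `"GAPDH"`.
#' @param ct_reference Numeric Ct replicates for the reference.
#' @return List of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample, target, ct_target,
                             reference = "GAPDH", ct_reference) {
  chk <- function(x, what) {
    if (length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
      stop(what, " Ct values must be finite, positive, with >= 1 replicate")
  }
  chk(ct_target, "target"); chk(ct_reference, "reference")
  structure(list(sample = sample, target = target,
                 ct_target = as.numeric(ct_target),
                 reference = reference,
                 ct_reference = as.numeric(ct_reference)),
            class = "qpcr_measurement")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of the target transcript in the treated sample relative to
#' the control, each normalized to the reference gene:
#' `dCt = mean(Ct_target) - mean(Ct_ref)` per sample,
#' `ddCt = dCt_treated - dCt_control`, fold change `= efficiency^(-ddCt)`.
#' Replicate Cts are averaged on the cycle scale.
#'
#' @param treated,control [qpcr_measurement()] objects with matching target
#'   and reference genes.
#' @param efficiency Amplification efficiency per cycle (default exactly 2).
#' @return Fold change (dimensionless, > 0).
#' @export
relative_expression <- function(treated, control, efficiency = 2) {
  stopifnot(inherits(treated, "qpcr_measurement"),
            inherits(control, "qpcr_measurement"))
  if (!identical(treated$target, control$target) ||
      !identical(treated$reference, control$reference))
    stop("treated and control must share target and reference genes")
  dct_t <- mean(treated$ct_target) - mean(treated$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  efficiency ^ (-(dct_t - dct_c))
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Adjusts the input Ct for the fraction of chromatin used as input
#' (`Ct_input_adj = Ct_input - log2(1 / input_fraction)`) and returns
#' `100 * 2^(Ct_input_adj - Ct_IP)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the chromatin input.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. a 1% input).
#' @return Enrichment as a percentage.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1)
    stop("input_fraction must be in (0, 1]")
  ct_input_adj <- ct_input - log2(1 / input_fraction)
  100 * 2 ^ (ct_input_adj - ct_ip)
}
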