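#' The published 12-gene breast-cancer methylation risk signature
#'
#' The reference multivariable-Cox signature this methodology was developed
#' around: 12 genes whose promoter methylation pattern scores combine into
#' a breast-cancer methylation risk score, 7 protective (negative
#' coefficient) and 5 risk (positive coefficient). Shipped as a plain-text
#' table with the reported coefficient, hazard ratio and Wald p-value per
#' gene; the hazard ratios satisfy `hr = exp(coef)` at the printed
#' precision, which [signature_consistency()] verifies.
#'
#' @return A data.frame: `gene_id`, `coef`, `hr_printed`, `p_value`.
#' @export
brca_signature <- function() {
  path <- system.file("extdata", "brca_mrs_signature.tsv", package = "methrisk")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Internal-consistency check of a reported Cox gene signature
#'
#' Recomputes each gene's hazard ratio as `exp(coef)` and compares it to
#' the reported value at 3 significant figures, and counts the
#' protective/risk partition from the coefficient signs.
#'
#' @param sig A signature data.frame as from [brca_signature()].
#' @return A list: `table` (with recomputed `hr` and relative deviation
#'   `hr_rel_err`), `max_rel_err`, `n_protective`, `n_risk`.
#' @export
signature_consistency <- function(sig = brca_signature()) {
  hr <- exp(sig$coef)
  rel <- abs(hr - sig$hr_printed) / sig$hr_printed
  list(
    table = data.frame(sig, hr = hr, hr_rel_err = rel),
    max_rel_err = max(rel),
    n_protective = sum(sig$coef < 0),
    n_risk = sum(sig$coef > 0)
  )
}
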