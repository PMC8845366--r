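#' Packaged synthetic epithelial/fibroblast/immune DNAm reference
#'
#' A \linkS4class{ReferenceMatrix} over 150 marker CpGs and the three broad
#' cell types (Epi, Fib, IC), built by running
#' \code{\link{buildReferenceMatrix}} on synthetic purified profiles from
#' \code{\link{simulatePureProfiles}} (fixed generator seed). It is a
#' synthetic stand-in for the proprietary epithelial/fibroblast/immune
#' reference used with real 450k/EPIC data, shipped so that the
#' deconvolution layer can be exercised without external artifacts; it is
#' not applicable to real methylomes.
#'
#' @return a \linkS4class{ReferenceMatrix}.
#' @examples
#' ref <- syntheticReference()
#' cellTypes(ref)
#' @export
syntheticReference <- function() {
  readReferenceMatrix(system.file("extdata",
                                  "synthetic_epi_fib_ic_reference.csv",
                                  package = "femnet", mustWork = TRUE))
}
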