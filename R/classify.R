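#' Is the compound organometallic?
#'
#' A compound is classified as organometallic when it contains at least one
#' zero-order bond and at least one atom from the configured metal list
#' (default Hf, Co, Zr, W, Ni, Pt, Os, Ti, Rh, Fe). The classification
#' decides which identifier regime applies to a compound; the internal
#' identity key is computed for all molecules regardless.
#'
#' @param m a `zmol`.
#' @return logical.
#' @examples
#' is_organometallic(make_metallocene("Fe"))  # TRUE
#' is_organometallic(molecule("C"))           # FALSE
#' @export
is_organometallic <- function(m) {
  has_zero_bond(m) && any(m$atoms$element %in% zob_option("metals"))
}
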