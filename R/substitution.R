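#' Substitution matrix with X scoring zero
#'
#' Returns a BLOSUM substitution matrix restricted to the 20 canonical
#' residues plus `X`. Unknown residues (`X`) score 0 against every residue,
#' so sequences containing `X` are retained without biasing local alignment
#' scores up or down.
#'
#' @param name Matrix name, `"BLOSUM50"` or `"BLOSUM62"`.
#' @return A 21 x 21 numeric matrix with dimnames over the residue alphabet.
#' @export
#' @examples
#' m <- ssp_matrix("BLOSUM50")
#' m["W", "W"]   # 15
ssp_matrix <- function(name = c("BLOSUM50", "BLOSUM62")) {
  name <- match.arg(name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  full <- get(name, envir = env)
  m <- full[AA20, AA20]
  out <- matrix(0, 21, 21, dimnames = list(AAX, AAX))
  out[AA20, AA20] <- m
  # X row/column already 0
  storage.mode(out) <- "double"
  out
}
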