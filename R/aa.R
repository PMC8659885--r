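# Amino-acid bookkeeping shared across the package.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA3 <- setNames(names(AA1), AA1)

ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

#' Convert a one-letter sequence to three-letter residue codes
#'
#' @param sequence character scalar, one-letter amino-acid codes
#' @return character vector of three-letter codes
#' @keywords internal
seq_to_resid <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters1 %in% names(AA1))
  if (length(bad))
    stop("unknown residue code '", letters1[bad[1]], "' at position ", bad[1])
  unname(AA1[letters1])
}

atom_element <- function(name) {
  # first character of a PDB heavy-atom name is its element for C/N/O/S
  substr(name, 1L, 1L)
}
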