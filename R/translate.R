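# Standard-genetic-code translation of in-frame nucleotide strings.
# Returns NA for strings whose length is not a multiple of 3; stop codons
# translate to "*". Vectorised over its input.
translate_nt <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  out <- rep(NA_character_, length(nt))
  n <- nchar(nt)
  ok <- !is.na(nt) & n > 0L & n %% 3L == 0L
  if (!any(ok)) return(out)
  out[ok] <- vapply(nt[ok], function(s) {
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aa <- code[codons]
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

# codon lists per amino acid, stops excluded (used by the simulator)
sense_codons_by_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  split(names(code), code)
}
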