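## Standard genetic code tables, built once at load from seqinr's
## translation machinery. Codons are upper-case DNA triplets.

.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$aa)) {
    codons <- toupper(seqinr::words(3, alphabet = c("a", "c", "g", "t")))
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(tolower(cd), "")[[1L]]), character(1))
    names(aa) <- codons
    .codon_env$aa <- aa
  }
  .codon_env$aa
}

#' The 61 sense codons of the standard genetic code
#' @return character vector of upper-case triplets.
#' @export
sense_codons <- function() {
  aa <- codon_table()
  names(aa)[aa != "*"]
}

translate_codon <- function(codon) {
  unname(codon_table()[codon])
}

is_stop_codon <- function(codon) {
  codon_table()[codon] == "*"
}

## single-nucleotide neighbors of a codon, with the changed position
codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  out <- character(0); pos <- integer(0)
  for (p in 1:3) {
    for (nt in setdiff(nts, chars[p])) {
      alt <- chars; alt[p] <- nt
      out <- c(out, paste0(alt, collapse = ""))
      pos <- c(pos, p)
    }
  }
  data.frame(codon = out, position = pos, stringsAsFactors = FALSE)
}
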