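## Canonical amino-acid order (matches the packaged JTT table / PAML).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-", "X")

#' Construct an alignment from a character matrix
#'
#' The core alignment container: a character matrix with one row per
#' sequence (rownames are the sequence identifiers) and one column per
#' aligned site. In amino-acid mode entries are the 20 one-letter residue
#' codes plus `-` (gap) and `X` (fully ambiguous); in codon mode entries
#' are upper-case sense-codon triplets plus `---`.
#'
#' @param mat character matrix, rows named by sequence identifier.
#' @param alphabet `"amino_acid"` or `"codon"`.
#' @return An object of class `conv_alignment`.
#' @export
as_alignment <- function(mat, alphabet = c("amino_acid", "codon")) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(mat) || !is.character(mat))
    stop("`mat` must be a character matrix")
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequence identifiers must be present and unique")
  mat[] <- toupper(mat)
  mat[mat == "."] <- "-"
  if (alphabet == "amino_acid") {
    legal <- c(AA_ALPHABET, GAP_CHARS)
    bad <- which(!(mat %in% legal))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(mat))
      stop(sprintf("illegal symbol '%s' in sequence '%s' at site %d",
                   mat[bad[1L]], ids[i[1L]], i[2L]))
    }
  } else {
    mat[mat == "-"] <- "---"
    legal <- c(sense_codons(), "---")
    bad <- which(!(mat %in% legal) & !grepl("N|X|-", mat))
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(mat))
      stop(sprintf("illegal codon '%s' in sequence '%s' at codon site %d",
                   mat[bad[1L]], ids[i[1L]], i[2L]))
    }
    mat[!(mat %in% legal)] <- "---"  # partially gapped/ambiguous codons
  }
  structure(mat, class = "conv_alignment", alphabet = alphabet)
}

#' @export
print.conv_alignment <- function(x, ...) {
  cat(sprintf("<conv_alignment> %d sequences x %d %s columns\n",
              nrow(x), ncol(x),
              if (attr(x, "alphabet") == "codon") "codon" else "amino-acid"))
  invisible(x)
}

n_columns <- function(aln) ncol(aln)
alignment_ids <- function(aln) rownames(aln)

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file, validates that all rows have equal length
#' and that every symbol belongs to the declared alphabet. `.` is
#' normalized to `-`; symbols are upper-cased. A terminal `*` (stop) is
#' stripped in amino-acid mode when `strip_terminal_stop` is `TRUE`,
#' otherwise any `*` is an error.
#'
#' @param path FASTA file.
#' @param alphabet `"amino_acid"` (default) or `"codon"`; codon mode reads
#'   nucleotides and groups them into triplets.
#' @param strip_terminal_stop drop a trailing `*` column-wise per sequence
#'   (replaced by gap) in amino-acid mode.
#' @return A [as_alignment()] object.
#' @export
read_alignment <- function(path, alphabet = c("amino_acid", "codon"),
                           strip_terminal_stop = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  seqtype <- if (alphabet == "amino_acid") "AA" else "DNA"
  recs <- seqinr::read.fasta(path, seqtype = seqtype, set.attributes = FALSE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop("no sequences in ", path)
  ids <- names(recs)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    short <- ids[which.min(lens)]
    stop(sprintf("alignment is ragged: sequence '%s' has length %d, expected %d",
                 short, min(lens), max(lens)))
  }
  mat <- do.call(rbind, lapply(recs, toupper))
  rownames(mat) <- ids
  if (alphabet == "amino_acid") {
    if (strip_terminal_stop) {
      for (i in seq_len(nrow(mat))) {
        nz <- which(mat[i, ] != "-")
        if (length(nz) && mat[i, nz[length(nz)]] == "*")
          mat[i, nz[length(nz)]] <- "-"
      }
    }
    if (any(mat == "*"))
      stop("internal stop codon symbol '*' in alignment")
    as_alignment(mat, "amino_acid")
  } else {
    if (ncol(mat) %% 3L != 0L)
      stop("codon alignment length not divisible by 3")
    nc <- ncol(mat) %/% 3L
    cod <- matrix("", nrow(mat), nc, dimnames = list(ids, NULL))
    for (k in seq_len(nc))
      cod[, k] <- paste0(mat[, 3 * k - 2], mat[, 3 * k - 1], mat[, 3 * k])
    as_alignment(cod, "codon")
  }
}

#' Write an alignment to FASTA
#'
#' @param aln a `conv_alignment`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "conv_alignment"))
  seqs <- apply(unclass(aln), 1L, paste0, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Map an alignment column to an ungapped reference position
#'
#' Residue coordinates in reports are expressed in the ungapped coordinate
#' system of a designated reference sequence (the human orthologue, in the
#' motivating analyses). The mapped position of column `j` is the number of
#' non-gap reference symbols in columns `1..j`; columns where the reference
#' itself has a gap map to `NA`.
#'
#' @param aln a `conv_alignment`.
#' @param ref_id reference sequence identifier.
#' @param column 1-based column index (vectorized).
#' @return integer vector of 1-based ungapped positions, `NA` at reference
#'   gaps.
#' @export
map_column_to_reference <- function(aln, ref_id, column) {
  stopifnot(inherits(aln, "conv_alignment"))
  if (!ref_id %in% rownames(aln))
    stop("unknown reference id: ", ref_id)
  if (any(column < 1L | column > ncol(aln)))
    stop("column index out of range 1..", ncol(aln))
  ref <- unclass(aln)[ref_id, ]
  gap <- if (attr(aln, "alphabet") == "codon") "---" else "-"
  nongap <- ref != gap
  pos <- cumsum(nongap)
  out <- pos[column]
  out[!nongap[column]] <- NA_integer_
  as.integer(out)
}
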