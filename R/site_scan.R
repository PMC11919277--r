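## Column-wise scan for lineage-specific and shared-specific amino-acid
## substitutions by strict identity: a column is group-specific when every
## foreground member carries the same residue and every background
## residue differs from it. Background gaps and 'X' are ignored (absence
## of evidence); a foreground gap/'X' disqualifies the column.

site_label <- function(aln, ref_id, column, foreground_residue) {
  if (is.null(ref_id)) return(NA_character_)
  pos <- map_column_to_reference(aln, ref_id, column)
  refres <- unclass(aln)[ref_id, column]
  ifelse(is.na(pos), NA_character_,
         paste0(refres, pos, foreground_residue))
}

#' Find group-specific substitution columns
#'
#' @param aln amino-acid alignment.
#' @param foreground character vector of foreground sequence ids
#'   (nonempty strict subset of the alignment).
#' @param ref_id optional reference id for position labels in the
#'   "T699P" style (reference residue, reference position, foreground
#'   residue).
#' @return data frame: column, reference_position, foreground_residue,
#'   background_residues (collapsed), background_masked (count of
#'   background gaps/X), label.
#' @export
find_group_specific_sites <- function(aln, foreground, ref_id = NULL) {
  ids <- rownames(aln)
  unknown <- setdiff(foreground, ids)
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  if (!length(foreground)) stop("foreground is empty")
  if (length(setdiff(ids, foreground)) == 0L)
    stop("foreground must be a strict subset of the alignment")
  M <- unclass(aln)
  fg <- M[foreground, , drop = FALSE]
  bg <- M[setdiff(ids, foreground), , drop = FALSE]
  out <- lapply(seq_len(ncol(M)), function(j) {
    f <- fg[, j]
    if (any(f %in% GAP_CHARS) || length(unique(f)) != 1L) return(NULL)
    x <- f[1L]
    b <- bg[, j]
    masked <- sum(b %in% GAP_CHARS)
    b <- b[!(b %in% GAP_CHARS)]
    if (length(b) == 0L || any(b == x)) return(NULL)
    data.frame(column = j,
               reference_position = if (is.null(ref_id)) NA_integer_
                 else map_column_to_reference(aln, ref_id, j),
               foreground_residue = x,
               background_residues = paste(sort(unique(b)), collapse = ""),
               background_masked = masked,
               label = site_label(aln, ref_id, j, x),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(column = integer(), reference_position = integer(),
                      foreground_residue = character(),
                      background_residues = character(),
                      background_masked = integer(), label = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find shared-specific substitution columns across groups
#'
#' A column qualifies for a subset G of the groups (|G| >= 2) when every
#' member of every group in G carries the same residue x and every
#' species outside the union of G with a non-gap residue differs from x.
#' The maximal qualifying subset is reported per column.
#'
#' @param aln amino-acid alignment.
#' @param groups named list of disjoint id sets.
#' @param ref_id optional reference id for labels.
#' @return data frame: column, reference_position, groups (comma-joined),
#'   shared_residue, label.
#' @export
find_shared_specific_sites <- function(aln, groups, ref_id = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  unknown <- setdiff(all_ids, rownames(aln))
  if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
  M <- unclass(aln)
  out <- list()
  for (j in seq_len(ncol(M))) {
    ## residue uniformly carried by each group (NA when mixed or gapped)
    gres <- vapply(groups, function(g) {
      r <- M[g, j]
      if (any(r %in% GAP_CHARS) || length(unique(r)) != 1L) NA_character_
      else r[1L]
    }, character(1))
    for (x in unique(gres[!is.na(gres)])) {
      G <- names(groups)[!is.na(gres) & gres == x]
      if (length(G) < 2L) next
      outside <- setdiff(rownames(M), unlist(groups[G], use.names = FALSE))
      b <- M[outside, j]
      b <- b[!(b %in% GAP_CHARS)]
      if (length(b) && all(b != x)) {
        out[[length(out) + 1L]] <- data.frame(
          column = j,
          reference_position = if (is.null(ref_id)) NA_integer_
            else map_column_to_reference(aln, ref_id, j),
          groups = paste(G, collapse = ","),
          shared_residue = x,
          label = site_label(aln, ref_id, j, x),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(column = integer(), reference_position = integer(),
                      groups = character(), shared_residue = character(),
                      label = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$column), , drop = FALSE]
}

#' Combined site-scan report
#'
#' Group-specific sites for every group, shared-specific sites across
#' group subsets, and a tally of columns excluded because a foreground
#' member is gapped or ambiguous.
#'
#' @param aln amino-acid alignment.
#' @param groups named list of id sets.
#' @param ref_id optional reference id.
#' @return list: `group_specific` (named list of data frames), `shared`
#'   (data frame), `counts` (per-group site counts), `excluded` (per-group
#'   count of foreground-gapped columns).
#' @export
scan_report <- function(aln, groups, ref_id = NULL) {
  M <- unclass(aln)
  gs <- lapply(groups, function(g)
    find_group_specific_sites(aln, g, ref_id = ref_id))
  excluded <- vapply(groups, function(g)
    sum(apply(M[g, , drop = FALSE], 2L,
              function(col) any(col %in% GAP_CHARS))), integer(1))
  shared <- if (length(groups) >= 2L)
    find_shared_specific_sites(aln, groups, ref_id = ref_id)
  else NULL
  list(group_specific = gs,
       shared = shared,
       counts = vapply(gs, nrow, integer(1)),
       excluded = excluded)
}
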