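## Phylogenies are ape "phylo" objects, validated on read. Internal nodes
## without labels get stable generated labels "nd<number>"; branch group
## tags live in tree$branch_tags, a character vector indexed by the child
## node of each branch (NA at the root, "background" where untagged).

#' Validate a phylogeny
#'
#' Checks for a single root, unique tip labels, and finite nonnegative
#' branch lengths; assigns stable internal node labels where missing.
#'
#' @param tree an `ape::phylo` object.
#' @param require_lengths error when branch lengths are absent (default).
#' @return the validated tree.
#' @export
validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (require_lengths) stop("tree has no branch lengths")
  } else {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch length")
    if (any(tree$edge.length < 0))
      stop("negative branch length: ", min(tree$edge.length))
  }
  ## exactly one root: nodes never appearing as a child
  nn <- ape::Ntip(tree) + tree$Nnode
  children <- tree$edge[, 2L]
  roots <- setdiff(seq_len(nn), children)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyDuplicated(c(tree$tip.label, tree$node.label))) {
    tree$node.label <- paste0("nd", seq_len(tree$Nnode) + ape::Ntip(tree))
  }
  tree
}

#' Read a rooted Newick tree
#'
#' Single-quoted labels and `[]` comments are handled by the Newick parser;
#' branch lengths are required by default and must be nonnegative.
#'
#' @param path Newick file (or use `text=` to parse a string).
#' @param text optional Newick string instead of a file.
#' @param require_lengths error when branch lengths are absent.
#' @return a validated `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL, require_lengths = TRUE) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else {
            if (!file.exists(path)) stop("file not found: ", path)
            ape::read.tree(path)
          }
  if (is.null(tree)) stop("failed to parse Newick input")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree")
  validate_tree(tree, require_lengths = require_lengths)
}

#' Write a tree to Newick
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

node_parents <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, nn)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

root_node <- function(tree) {
  which(is.na(node_parents(tree)))
}

node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

node_number <- function(tree, label) {
  idx <- match(label, node_labels(tree))
  if (anyNA(idx)) stop("unknown node label: ",
                       paste(label[is.na(idx)], collapse = ", "))
  idx
}

## all nodes in the clade rooted at `node` (including `node`)
clade_nodes <- function(tree, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- tree$edge[tree$edge[, 1L] %in% frontier, 2L]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

is_ancestor <- function(tree, a, b) {
  ## is node a an ancestor of node b?
  par <- node_parents(tree)
  while (!is.na(b)) {
    b <- par[b]
    if (!is.na(b) && b == a) return(TRUE)
  }
  FALSE
}

branch_length_of <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  if (is.na(i)) stop("node has no parent branch (root?)")
  tree$edge.length[i]
}

#' Tag foreground branches by group
#'
#' Marks branches with group labels (e.g. `"cetacea"`, `"walrus"`,
#' `"manatee"`) for use as foreground lineages in the convergence scan.
#' Each element of `spec` is a character vector of tip labels: a single
#' tip names that terminal branch; several tips name their last common
#' ancestor. In `"stem"` mode (default) only the branch subtending the
#' named clade is tagged; `"clade"` mode tags every branch inside it.
#' All untagged branches are labeled `"background"`.
#'
#' @param tree a validated `phylo`.
#' @param spec named list of character vectors of tip labels.
#' @param mode `"stem"` or `"clade"`.
#' @return the tree with a `branch_tags` element (character, indexed by
#'   child node; `NA` at the root).
#' @export
tag_branches <- function(tree, spec, mode = c("stem", "clade")) {
  mode <- match.arg(mode)
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("`spec` must be a named list of groups")
  nn <- ape::Ntip(tree) + tree$Nnode
  tags <- rep("background", nn)
  tags[root_node(tree)] <- NA_character_
  for (g in names(spec)) {
    tips <- spec[[g]]
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing))
      stop("unknown tip name(s) in group '", g, "': ",
           paste(missing, collapse = ", "))
    node <- if (length(tips) == 1L) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    if (node == root_node(tree))
      stop("group '", g, "' resolves to the root, which has no branch")
    targets <- if (mode == "stem") node else clade_nodes(tree, node)
    targets <- setdiff(targets, root_node(tree))
    tags[targets] <- g
  }
  tree$branch_tags <- tags
  tree
}

#' Branch tags as a readable table
#' @param tree a tagged tree.
#' @return data frame with branch (child-node label), group.
#' @export
branch_tag_table <- function(tree) {
  if (is.null(tree$branch_tags)) stop("tree has no branch tags; run tag_branches()")
  keep <- !is.na(tree$branch_tags)
  data.frame(branch = node_labels(tree)[keep],
             group = tree$branch_tags[keep],
             stringsAsFactors = FALSE)
}
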