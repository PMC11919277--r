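## Felsenstein pruning and marginal ancestral reconstruction.
##
## Conditional likelihoods are held as 20 x n_sites matrices per node and
## propagated by dense matrix products, with per-site rescaling to avoid
## underflow on deep trees. Tip conditionals are indicators; gaps and 'X'
## are missing data (all-ones conditionals).

tip_conditionals <- function(aln, tree) {
  S <- ncol(aln)
  orphan <- setdiff(rownames(aln), tree$tip.label)
  if (length(orphan))
    stop("alignment sequence(s) missing from tree: ",
         paste(orphan, collapse = ", "))
  lapply(seq_len(ape::Ntip(tree)), function(i) {
    lab <- tree$tip.label[i]
    if (!lab %in% rownames(aln))
      return(matrix(1, 20L, S))            # tip without data: missing
    M <- matrix(0, 20L, S)
    res <- unclass(aln)[lab, ]
    idx <- match(res, AA_ALPHABET)
    miss <- is.na(idx)
    M[cbind(idx[!miss], which(!miss))] <- 1
    M[, miss] <- 1
    M
  })
}

## Up-pass: conditional likelihood of the data below each node given its
## state. Returns per-node matrices, per-node P matrices, and per-site log
## scaling accumulated at internal nodes.
prune_up <- function(aln, tree, model) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  S <- ncol(aln)
  po <- ape::reorder.phylo(tree, "postorder")
  D <- vector("list", nn)
  D[seq_len(ntip)] <- tip_conditionals(aln, tree)
  P <- vector("list", nn)          # P over the branch above each node
  for (e in seq_len(nrow(po$edge)))
    P[[po$edge[e, 2L]]] <- transition_matrix(model, po$edge.length[e])
  logscale <- numeric(S)
  parents <- unique(po$edge[, 1L]) # postorder parent visitation order
  for (u in parents) {
    kids <- po$edge[po$edge[, 1L] == u, 2L]
    M <- P[[kids[1L]]] %*% D[[kids[1L]]]
    for (v in kids[-1L]) M <- M * (P[[v]] %*% D[[v]])
    sc <- apply(M, 2L, max)
    sc[sc <= 0] <- 1
    M <- sweep(M, 2L, sc, "/")
    logscale <- logscale + log(sc)
    D[[u]] <- M
  }
  list(D = D, P = P, logscale = logscale, root = root_node(tree))
}

#' Tree log-likelihood by the pruning algorithm
#'
#' @param aln amino-acid `conv_alignment`; every tree tip must be present.
#' @param tree validated `phylo` with branch lengths.
#' @param model a `subst_model`.
#' @return list with `total` and per-site vector `site_log_likelihoods`.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  up <- prune_up(aln, tree, model)
  site_l <- colSums(up$D[[up$root]] * model$frequencies)
  if (any(site_l <= 0))
    stop("non-finite likelihood at site ", which(site_l <= 0)[1L])
  site_ll <- log(site_l) + up$logscale
  list(total = sum(site_ll), site_log_likelihoods = site_ll)
}

#' Refit branch lengths by maximum likelihood
#'
#' Coordinate ascent over branches: each branch length in turn is solved
#' by bounded scalar maximization of the tree likelihood on `[0, t_max]`,
#' sweeping until the log-likelihood gain falls below `tol` or `max_sweeps`
#' is reached. The log-likelihood is non-decreasing across sweeps.
#'
#' @param aln,tree,model as [tree_log_likelihood()].
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param t_max upper bound per branch (default 20).
#' @param max_sweeps sweep cap (default 50).
#' @return list with the refitted `tree`, `log_likelihood`, and the
#'   per-sweep `trace`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    t_max = 20, max_sweeps = 50) {
  ll <- tree_log_likelihood(aln, tree, model)$total
  trace <- ll
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_along(tree$edge.length)) {
      f <- function(t) {
        tree$edge.length[e] <- t
        tree_log_likelihood(aln, tree, model)$total
      }
      opt <- stats::optimize(f, c(0, t_max), maximum = TRUE, tol = 1e-8)
      if (opt$objective >= ll) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol) break
  }
  list(tree = tree, log_likelihood = ll, trace = trace)
}

#' Marginal ancestral state reconstruction
#'
#' For every internal node and site, the posterior distribution over the
#' 20 amino acids given all tip data, computed by the standard up-pass /
#' down-pass; the MAP state is recorded per node and site with an
#' alphabetical (lowest canonical index) tie-break. Tip rows of
#' `map_states` carry the observed residues.
#'
#' @param aln,tree,model as [tree_log_likelihood()].
#' @return an `ancestral_recon`: `node_posteriors` (list over internal
#'   nodes of 20 x n_sites matrices), `map_states` (character matrix,
#'   all nodes x sites), `site_log_likelihoods`, `total_log_likelihood`.
#' @export
marginal_ancestral_states <- function(aln, tree, model) {
  up <- prune_up(aln, tree, model)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  S <- ncol(aln)
  site_l <- colSums(up$D[[up$root]] * model$frequencies)
  if (any(site_l <= 0))
    stop("non-finite likelihood at site ", which(site_l <= 0)[1L])
  site_ll <- log(site_l) + up$logscale

  ## down-pass: F[[v]] = likelihood of data outside the clade of v, as a
  ## function of the state at v (F at the root is the prior pi)
  Fo <- vector("list", nn)
  Fo[[up$root]] <- matrix(model$frequencies, 20L, S)
  pre <- ape::reorder.phylo(tree, "postorder")
  edges <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE] # preorder
  PD <- vector("list", nn)
  for (v in seq_len(nn)) if (!is.null(up$P[[v]]))
    PD[[v]] <- up$P[[v]] %*% up$D[[v]]
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == u, 2L], v)
    M <- Fo[[u]]
    for (w in sibs) M <- M * PD[[w]]
    Fv <- crossprod(up$P[[v]], M)          # t(P_v) %*% M
    cs <- colSums(Fv); cs[cs <= 0] <- 1
    Fo[[v]] <- sweep(Fv, 2L, cs, "/")      # proportionality suffices
  }

  internal <- (ntip + 1L):nn
  posts <- vector("list", nn)
  ties <- 0L
  map_states <- matrix(NA_character_, nn, S,
                       dimnames = list(node_labels(tree), NULL))
  for (v in internal) {
    Pm <- up$D[[v]] * Fo[[v]]
    Pm <- sweep(Pm, 2L, colSums(Pm), "/")
    rownames(Pm) <- AA_ALPHABET
    posts[[v]] <- Pm
    mx <- apply(Pm, 2L, max)
    ties <- ties + sum(colSums(Pm >= mx[col(Pm)] - 1e-12) > 1L)
    map_states[v, ] <- AA_ALPHABET[apply(Pm, 2L, which.max)]
  }
  if (ties > 0L)
    warning(ties, " node-site posterior tie(s) broken alphabetically")
  tipdat <- matrix("-", ntip, S)
  have <- tree$tip.label %in% rownames(aln)
  tipdat[have, ] <- unclass(aln)[tree$tip.label[have], , drop = FALSE]
  map_states[seq_len(ntip), ] <- tipdat
  structure(list(node_posteriors = posts,
                 map_states = map_states,
                 site_log_likelihoods = site_ll,
                 total_log_likelihood = sum(site_ll),
                 tree_labels = node_labels(tree)),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat(sprintf("<ancestral_recon> %d nodes x %d sites, logL = %.4f\n",
              nrow(x$map_states), ncol(x$map_states),
              x$total_log_likelihood))
  invisible(x)
}

#' List per-branch substitution events from a reconstruction
#'
#' A substitution event is a branch/site where the MAP state at the parent
#' node differs from the state at the child end (MAP for internal nodes,
#' observed residue for tips). Branch/site combinations whose tip state is
#' a gap or `X` produce no event.
#'
#' @param recon an [marginal_ancestral_states()] result.
#' @param tree the tree the reconstruction was computed on.
#' @param aln the alignment.
#' @param ref_id optional reference sequence id for coordinate mapping.
#' @return data frame: branch (child-node label), site, parent_state,
#'   child_state, reference_position.
#' @export
list_substitutions <- function(recon, tree, aln, ref_id = NULL) {
  if (!identical(recon$tree_labels, node_labels(tree)))
    stop("reconstruction does not match this tree")
  par <- node_parents(tree)
  nn <- length(par)
  out <- list()
  refpos <- if (!is.null(ref_id))
    map_column_to_reference(aln, ref_id, seq_len(ncol(aln))) else
    rep(NA_integer_, ncol(aln))
  for (v in seq_len(nn)) {
    u <- par[v]
    if (is.na(u)) next
    ps <- recon$map_states[u, ]
    cs <- recon$map_states[v, ]
    hit <- which(ps != cs & !(cs %in% GAP_CHARS))
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        branch = node_labels(tree)[v], site = hit,
        parent_state = ps[hit], child_state = cs[hit],
        reference_position = refpos[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(branch = character(), site = integer(),
                      parent_state = character(), child_state = character(),
                      reference_position = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, res$branch), , drop = FALSE]
}
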