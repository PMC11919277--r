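# Shared fixtures and independent oracles used across the suite.

AA <- convclock:::AA_ALPHABET

# quick alignment builder: named character vector of residue strings
aln_from_strings <- function(...) {
  seqs <- c(...)
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1L]]))
  rownames(mat) <- names(seqs)
  as_alignment(mat, "amino_acid")
}

# random rooted binary tree with uniform branch lengths
random_tree <- function(ntips, min_len = 0.02, max_len = 1) {
  tr <- ape::rtree(ntips, rooted = TRUE,
                   br = function(n) runif(n, min_len, max_len))
  validate_tree(tr)
}

# Brute-force likelihood and marginal posteriors by enumeration over all
# internal-state assignments. Independent of the pruning implementation:
# only transition_matrix() is shared machinery.
brute_force_recon <- function(aln, tree, model) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  S <- ncol(aln)
  par <- convclock:::node_parents(tree)
  root <- which(is.na(par))
  internal <- (ntip + 1L):nn
  P <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    P[[tree$edge[e, 2L]]] <- transition_matrix(model, tree$edge.length[e])
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  colnames(grid) <- as.character(internal)
  assign_state <- function(v) grid[, as.character(v)]
  # factors independent of the site: internal-child edges
  w <- model$frequencies[assign_state(root)]
  for (v in setdiff(internal, root))
    w <- w * P[[v]][cbind(assign_state(par[v]), assign_state(v))]
  M <- unclass(aln)[tree$tip.label, , drop = FALSE]
  site_lik <- numeric(S)
  posts <- lapply(seq_len(nn), function(v) matrix(NA_real_, 20L, S))
  for (s in seq_len(S)) {
    ws <- w
    for (tp in seq_len(ntip)) {
      res <- M[tp, s]
      idx <- match(res, AA)
      ws <- ws * if (is.na(idx)) 1 else
        P[[tp]][cbind(assign_state(par[tp]), idx)]
    }
    site_lik[s] <- sum(ws)
    for (v in internal) {
      tab <- vapply(1:20, function(a) sum(ws[assign_state(v) == a]),
                    numeric(1))
      posts[[v]][, s] <- tab / sum(tab)
    }
  }
  list(site_log_lik = log(site_lik), posteriors = posts)
}

# closed-form quantities for the 20-state equal-rates model
er_p_same <- function(t) 1 / 20 + (19 / 20) * exp(-20 * t / 19)
er_p_diff <- function(t) (1 / 20) * (1 - exp(-20 * t / 19))  # per target state

# a small mammal-like tagged tree reused by convergence tests: three
# marine foreground lineages on a 12-tip background
marine_tree <- function() {
  txt <- paste0(
    "(((dolphin:0.08,orca:0.07):0.12,(cow:0.15,pig:0.16):0.05):0.06,",
    "((walrus:0.18,(seal:0.1,bear:0.11):0.04):0.05,",
    "((manatee:0.2,elephant:0.17):0.06,",
    "(human:0.09,(mouse:0.2,rat:0.19):0.08):0.07):0.03):0.04);")
  tr <- read_tree(text = txt)
  tag_branches(tr, list(cetacea = c("dolphin", "orca"),
                        walrus = "walrus",
                        manatee = "manatee"))
}

# tree for planted-convergence detection: the two foreground tips sit next
# to densely sampled, near-identical sister taxa, so the states of their
# parent nodes are identifiable from data (emulating the dense cetacean
# sampling of real convergence scans); the long path between the two
# foreground parents supplies sites where the ancestral states differ
detection_tree <- function() {
  txt <- paste0(
    "(((walrus:0.1,(seal:0.002,bear:0.002):0.002):0.3,",
    "(cow:0.1,pig:0.1):0.1):0.1,",
    "((manatee:0.1,(elephant:0.002,hyrax:0.002):0.002):0.3,",
    "(human:0.1,mouse:0.1):0.1):0.1);")
  tr <- read_tree(text = txt)
  tag_branches(tr, list(walrus = "walrus", manatee = "manatee"))
}
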