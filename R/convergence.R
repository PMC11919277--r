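## Zhang-Kumar convergence counting between independent foreground
## lineage pairs, with a model-based expected count and a one-sided
## Poisson test. At a site, for a branch pair with parent states p1, p2
## and child-end states c1, c2: convergent means c1 == c2, both changed,
## and p1 != p2; parallel means the same with p1 == p2.

#' Enumerate independent foreground branch pairs
#'
#' All unordered pairs of tagged branches whose groups differ, excluding
#' pairs where one branch is an ancestor of the other (such pairs are not
#' independent).
#'
#' @param tree a [tag_branches()]-tagged tree.
#' @return data frame: branch_a, branch_b (child-node labels), group_a,
#'   group_b, node_a, node_b.
#' @export
enumerate_branch_pairs <- function(tree) {
  if (is.null(tree$branch_tags)) stop("tree has no branch tags")
  tagged <- which(!is.na(tree$branch_tags) &
                  tree$branch_tags != "background")
  groups <- tree$branch_tags[tagged]
  if (length(unique(groups)) < 2L)
    stop("need at least 2 distinct foreground groups")
  labs <- node_labels(tree)
  out <- list()
  if (length(tagged) >= 2L) {
    for (i in seq_len(length(tagged) - 1L)) for (j in (i + 1L):length(tagged)) {
      a <- tagged[i]; b <- tagged[j]
      if (groups[i] == groups[j]) next
      if (is_ancestor(tree, a, b) || is_ancestor(tree, b, a)) next
      out[[length(out) + 1L]] <- data.frame(
        branch_a = labs[a], branch_b = labs[b],
        group_a = groups[i], group_b = groups[j],
        node_a = a, node_b = b, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(branch_a = character(), branch_b = character(),
                      group_a = character(), group_b = character(),
                      node_a = integer(), node_b = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## sites usable for a branch pair: child-end states present (not gap/X)
pair_site_states <- function(recon, tree, pair_row) {
  par <- node_parents(tree)
  a <- pair_row$node_a; b <- pair_row$node_b
  list(p1 = recon$map_states[par[a], ], c1 = recon$map_states[a, ],
       p2 = recon$map_states[par[b], ], c2 = recon$map_states[b, ])
}

#' Count observed convergent and parallel substitutions
#'
#' @param recon an [marginal_ancestral_states()] reconstruction.
#' @param tree the (tagged) tree.
#' @param pairs output of [enumerate_branch_pairs()].
#' @param aln optional alignment for reference-coordinate labels.
#' @param ref_id optional reference sequence id.
#' @return list: `convergent`, `parallel` (integer totals over sites and
#'   pairs), and `sites`, a data frame of the contributing events.
#' @export
observed_convergence <- function(recon, tree, pairs, aln = NULL,
                                 ref_id = NULL) {
  sites <- list()
  conv <- 0L; para <- 0L
  refpos <- if (!is.null(aln) && !is.null(ref_id))
    map_column_to_reference(aln, ref_id, seq_len(ncol(recon$map_states)))
  else rep(NA_integer_, ncol(recon$map_states))
  for (r in seq_len(nrow(pairs))) {
    st <- pair_site_states(recon, tree, pairs[r, ])
    usable <- !(st$c1 %in% GAP_CHARS) & !(st$c2 %in% GAP_CHARS)
    both_changed <- usable & st$c1 == st$c2 &
      st$p1 != st$c1 & st$p2 != st$c2
    is_conv <- both_changed & st$p1 != st$p2
    is_para <- both_changed & st$p1 == st$p2
    conv <- conv + sum(is_conv)
    para <- para + sum(is_para)
    hit <- which(is_conv | is_para)
    if (length(hit))
      sites[[length(sites) + 1L]] <- data.frame(
        site = hit, reference_position = refpos[hit],
        branch_a = pairs$branch_a[r], branch_b = pairs$branch_b[r],
        parent_a = st$p1[hit], parent_b = st$p2[hit],
        derived = st$c1[hit],
        type = ifelse(is_conv[hit], "convergent", "parallel"),
        stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) {
    s <- do.call(rbind, sites); rownames(s) <- NULL
    s[order(s$site), , drop = FALSE]
  } else data.frame(site = integer(), reference_position = integer(),
                    branch_a = character(), branch_b = character(),
                    parent_a = character(), parent_b = character(),
                    derived = character(), type = character(),
                    stringsAsFactors = FALSE)
  list(convergent = conv, parallel = para, sites = sites)
}

#' Model-expected convergent and parallel substitution counts
#'
#' For each branch pair and site, conditioning on the parent states, the
#' probability that both branches end in the same residue j with both
#' having changed: sum over j not in \{p1, p2\} of P(t1)[p1, j] P(t2)[p2, j]
#' when p1 != p2 (convergence), and sum over j != p of
#' P(t1)[p, j] P(t2)[p, j] when p1 == p2 == p (parallelism). Totals are
#' summed over sites and pairs; sites skipped by the observed count
#' (missing child-end data) are skipped here too.
#'
#' @param model a `subst_model`.
#' @param tree the tree whose branch lengths parameterize P(t).
#' @param recon the reconstruction supplying parent states.
#' @param pairs branch pairs.
#' @param condition `"map"` conditions on MAP parent states; `"posterior"`
#'   marginalizes over the product of the parent-state posteriors.
#' @return list: `expected_convergent`, `expected_parallel`.
#' @export
expected_convergence <- function(model, tree, recon, pairs,
                                 condition = c("map", "posterior")) {
  condition <- match.arg(condition)
  if (!nrow(pairs)) stop("no branch pairs")
  par <- node_parents(tree)
  S <- ncol(recon$map_states)
  Ec <- 0; Ep <- 0
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$node_a[r]; b <- pairs$node_b[r]
    P1 <- transition_matrix(model, branch_length_of(tree, a))
    P2 <- transition_matrix(model, branch_length_of(tree, b))
    st <- pair_site_states(recon, tree, pairs[r, ])
    usable <- which(!(st$c1 %in% GAP_CHARS) & !(st$c2 %in% GAP_CHARS))
    if (!length(usable)) next
    if (condition == "map") {
      i1 <- match(st$p1[usable], AA_ALPHABET)
      i2 <- match(st$p2[usable], AA_ALPHABET)
      A <- P1[i1, , drop = FALSE] * P2[i2, , drop = FALSE]
      tot <- rowSums(A)
      a11 <- A[cbind(seq_along(i1), i1)]
      a22 <- A[cbind(seq_along(i2), i2)]
      same <- i1 == i2
      Ec <- Ec + sum((tot - a11 - a22)[!same])
      Ep <- Ep + sum((tot - a11)[same])
    } else {
      Q1 <- recon$node_posteriors[[par[a]]][, usable, drop = FALSE]
      Q2 <- recon$node_posteriors[[par[b]]][, usable, drop = FALSE]
      for (p1 in 1:20) for (p2 in 1:20) {
        w <- Q1[p1, ] * Q2[p2, ]
        if (all(w == 0)) next
        prod_vec <- P1[p1, ] * P2[p2, ]
        if (p1 != p2) {
          pr <- sum(prod_vec) - prod_vec[p1] - prod_vec[p2]
          Ec <- Ec + pr * sum(w)
        } else {
          pr <- sum(prod_vec) - prod_vec[p1]
          Ep <- Ep + pr * sum(w)
        }
      }
    }
  }
  list(expected_convergent = Ec, expected_parallel = Ep)
}

#' One-sided Poisson test for excess convergence
#'
#' Upper-tail probability that a Poisson(E) count reaches the observed
#' value: p = Pr(X >= C).
#'
#' @param observed nonnegative integer count C.
#' @param expected nonnegative expected count E.
#' @return p-value in \[0, 1\].
#' @export
poisson_test <- function(observed, expected) {
  if (observed < 0 || expected < 0) stop("negative input")
  if (expected == 0) {
    if (observed == 0) return(1)
    warning("observed > 0 with expected = 0")
    return(0)
  }
  if (observed == 0) return(1)
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment mapping p-values to q-values, clipped to 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full convergence analysis for one gene
#'
#' Runs the whole per-gene pipeline: gene-specific frequencies (JTT-f_genes
#' by default), optional branch-length refit, marginal ancestral
#' reconstruction, Zhang-Kumar observed counts over all independent
#' foreground pairs, model-expected counts, and the one-sided Poisson test.
#'
#' @param aln amino-acid alignment.
#' @param tree tagged tree (see [tag_branches()]).
#' @param model optional `subst_model`; default JTT with frequencies
#'   estimated from `aln`.
#' @param gene gene name for the report.
#' @param ref_id optional reference id for site labels.
#' @param refit_lengths refit branch lengths under the amino-acid model
#'   before reconstructing (default TRUE); FALSE uses the input lengths.
#' @param condition conditioning mode for the expectation.
#' @return a `convergence_report` list.
#' @export
convergence_report <- function(aln, tree, model = NULL, gene = "gene",
                               ref_id = NULL, refit_lengths = TRUE,
                               condition = "map") {
  if (is.null(model)) model <- jtt_model(estimate_frequencies(aln))
  if (refit_lengths)
    tree <- optimize_branch_lengths(aln, tree, model)$tree
  recon <- marginal_ancestral_states(aln, tree, model)
  pairs <- enumerate_branch_pairs(tree)
  obs <- observed_convergence(recon, tree, pairs, aln = aln, ref_id = ref_id)
  ex <- expected_convergence(model, tree, recon, pairs,
                             condition = condition)
  p <- poisson_test(obs$convergent, ex$expected_convergent)
  structure(list(gene = gene, pairs = pairs,
                 observed_convergent = obs$convergent,
                 observed_parallel = obs$parallel,
                 observed_total = obs$convergent + obs$parallel,
                 convergent_sites = obs$sites,
                 expected_convergent = ex$expected_convergent,
                 expected_parallel = ex$expected_parallel,
                 poisson_p = p, fdr_q = NA_real_,
                 model = model$name, refit_lengths = refit_lengths),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s: C = %d (parallel %d), E = %.4f, Poisson p = %.4g\n",
              x$gene, x$observed_convergent, x$observed_parallel,
              x$expected_convergent, x$poisson_p))
  invisible(x)
}

#' FDR-adjust a set of per-gene convergence reports
#' @param reports list of `convergence_report`s.
#' @return the list with `fdr_q` filled in across genes.
#' @export
adjust_convergence_reports <- function(reports) {
  q <- fdr_adjust(vapply(reports, `[[`, numeric(1), "poisson_p"))
  for (i in seq_along(reports)) reports[[i]]$fdr_q <- q[i]
  reports
}
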