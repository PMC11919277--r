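## Seed-deterministic synthetic-data generators. Every generator takes a
## `seed`, restores the caller's RNG state on exit, and logs its
## parameters into the returned truth object, so fixtures for one stage
## cannot silently shift another's.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate an amino-acid alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies; each
#' child state is drawn from the row of P(t_branch) indexed by its
#' parent's state. The truth records every node's sequence and all
#' implied substitution events.
#'
#' @param tree `phylo` with branch lengths.
#' @param model a `subst_model`.
#' @param n_sites number of sites.
#' @param seed integer seed (optional but recommended).
#' @return list: `alignment` (tips only) and `truth` with
#'   `ancestral_states` (all-node character matrix), `events` data frame,
#'   `params`, `seed`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  with_seed(seed, {
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nn, n_sites)
    root <- root_node(tree)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    po <- ape::reorder.phylo(tree, "postorder")
    edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE] # preorder
    elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      P <- transition_matrix(model, elen[e])
      ps <- states[u, ]
      cs <- integer(n_sites)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[v, ] <- cs
    }
    chars <- matrix(AA_ALPHABET[states], nn, n_sites,
                    dimnames = list(node_labels(tree), NULL))
    aln <- as_alignment(chars[seq_len(ntip), , drop = FALSE], "amino_acid")
    par <- node_parents(tree)
    ev <- list()
    for (v in seq_len(nn)) {
      u <- par[v]
      if (is.na(u)) next
      hit <- which(states[u, ] != states[v, ])
      if (length(hit))
        ev[[length(ev) + 1L]] <- data.frame(
          branch = node_labels(tree)[v], site = hit,
          parent_state = chars[u, hit], child_state = chars[v, hit],
          stringsAsFactors = FALSE)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(branch = character(), site = integer(),
                 parent_state = character(), child_state = character(),
                 stringsAsFactors = FALSE)
    list(alignment = aln,
         truth = list(ancestral_states = chars, events = events,
                      planted_convergent_sites = integer(),
                      params = list(n_sites = n_sites, model = model$name),
                      seed = seed))
  })
}

#' Plant convergent substitutions into a simulated alignment
#'
#' At `k` randomly chosen sites the clades below the designated branches
#' are overwritten with a common residue x chosen so that (i) x differs
#' from each branch's parent state, (ii) the parent states differ between
#' branches (true convergence, not parallelism), and, under the
#' `"exclusive"` policy, (iii) x does not occur anywhere else in the
#' column. This is an exactly verifiable edit for detector tests, not a
#' draw from a coherent evolutionary model.
#'
#' @param sim a [simulate_alignment()] result.
#' @param tree the tree used for the simulation.
#' @param branches character vector of >= 2 node labels (one branch per
#'   foreground group; non-nested).
#' @param k number of sites to plant.
#' @param policy `"exclusive"` (x absent from the background; default) or
#'   `"parent_distinct"` (only conditions i-ii).
#' @param seed integer seed.
#' @param max_retries site-resampling budget when a site admits no legal
#'   residue.
#' @return the modified `sim` with truth updated
#'   (`planted_convergent_sites`, overwritten ancestral states).
#' @export
plant_convergent_sites <- function(sim, tree, branches, k,
                                   policy = c("exclusive", "parent_distinct"),
                                   seed = NULL, max_retries = 100L) {
  policy <- match.arg(policy)
  stopifnot(length(branches) >= 2L)
  nodes <- node_number(tree, branches)
  for (i in seq_along(nodes)) for (j in seq_along(nodes))
    if (i != j && is_ancestor(tree, nodes[i], nodes[j]))
      stop("branches must be non-nested")
  if (k == 0L) return(sim)
  chars <- sim$truth$ancestral_states
  n_sites <- ncol(chars)
  if (k > n_sites) stop("k exceeds the number of sites")
  par <- node_parents(tree)
  ntip <- ape::Ntip(tree)
  clades <- lapply(nodes, function(v) clade_nodes(tree, v))
  fg_tips <- unlist(lapply(clades, function(cl) cl[cl <= ntip]))
  with_seed(seed, {
    planted <- integer(0)
    tries <- 0L
    while (length(planted) < k) {
      if (tries >= max_retries)
        stop("could not find ", k, " plantable sites in ", max_retries,
             " retries (policy '", policy, "')")
      s <- sample(setdiff(seq_len(n_sites), planted), 1L)
      parents <- chars[par[nodes], s]
      if (length(unique(parents)) != length(parents)) {
        tries <- tries + 1L; next
      }
      banned <- parents
      if (policy == "exclusive")
        banned <- c(banned, chars[setdiff(seq_len(ntip), fg_tips), s])
      candidates <- setdiff(AA_ALPHABET, banned)
      if (!length(candidates)) { tries <- tries + 1L; next }
      x <- sample(candidates, 1L)
      for (cl in clades) chars[cl, s] <- x
      planted <- c(planted, s)
      tries <- 0L                     # retry budget is per planted site
    }
    planted <- sort(planted)
    sim$truth$ancestral_states <- chars
    sim$truth$planted_convergent_sites <- planted
    sim$truth$params$planted_k <- k
    sim$truth$params$planted_policy <- policy
    sim$alignment <- as_alignment(chars[seq_len(ntip), , drop = FALSE],
                                  "amino_acid")
    sim
  })
}

#' Simulate a trait table with known lambda, slope, and noise
#'
#' The response is intercept + beta * predictor + e with e drawn from a
#' multivariate normal with covariance sigma2 * C(lambda) (Brownian
#' motion on the tree, off-diagonals scaled by lambda). The predictor is
#' standard normal unless supplied.
#'
#' @param tree `phylo`.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param beta slope.
#' @param sigma2 residual variance scale (>= 0).
#' @param intercept intercept (default 0).
#' @param predictor optional numeric vector named by species.
#' @param seed integer seed.
#' @return list: `traits` data frame (species, predictor, response) and
#'   `params`.
#' @export
simulate_trait <- function(tree, lambda, beta, sigma2, intercept = 0,
                           predictor = NULL, seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 >= 0)
  with_seed(seed, {
    sp <- tree$tip.label
    n <- length(sp)
    if (is.null(predictor)) predictor <- stats::rnorm(n)
    C <- bm_covariance(tree, lambda)[sp, sp]
    e <- if (sigma2 == 0) numeric(n)
    else drop(crossprod(chol(sigma2 * C + diag(1e-12, n)), stats::rnorm(n)))
    traits <- data.frame(species = sp, predictor = predictor,
                         response = intercept + beta * predictor + e,
                         stringsAsFactors = FALSE)
    list(traits = traits,
         params = list(lambda = lambda, beta = beta, sigma2 = sigma2,
                       intercept = intercept, seed = seed))
  })
}

#' Simulate a codon sequence pair with known omega
#'
#' The ancestor is uniform over the 61 sense codons; the descendant
#' evolves by a continuous-time process in which each single-nucleotide
#' change has rate 1/9 if synonymous and omega/9 if nonsynonymous
#' (changes to stop codons have rate 0), run for duration `t`. At
#' omega = 1 this gives roughly `t` substitutions per codon.
#'
#' @param n_codons number of codons.
#' @param t evolution time (expected neutral substitutions per codon).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param seed integer seed.
#' @return list: `ancestor`, `descendant` (codon vectors), `params`.
#' @export
simulate_codon_pair <- function(n_codons, t, omega, seed = NULL) {
  stopifnot(n_codons >= 1, t >= 0, omega >= 0)
  with_seed(seed, {
    sc <- sense_codons()
    anc <- sample(sc, n_codons, replace = TRUE)
    des <- anc
    for (i in seq_len(n_codons)) {
      time <- 0
      cur <- anc[i]
      repeat {
        nb <- codon_neighbors(cur)
        keep <- !is_stop_codon(nb$codon)
        nbc <- nb$codon[keep]
        syn <- translate_codon(nbc) == translate_codon(cur)
        rates <- ifelse(syn, 1, omega) / 9
        total <- sum(rates)
        if (total == 0) break
        time <- time + stats::rexp(1L, total)
        if (time > t) break
        cur <- sample(nbc, 1L, prob = rates / total)
      }
      des[i] <- cur
    }
    list(ancestor = anc, descendant = des,
         params = list(n_codons = n_codons, t = t, omega = omega,
                       seed = seed))
  })
}

#' Simulate a binned activity trace with known sleep bouts
#'
#' Alternating wake and sleep runs are generated bin-by-bin with
#' phase-dependent geometric run lengths; wake bins carry gamma-
#' distributed positive activity, sleep bins are exactly zero. Run
#' parameters are chosen at run onset from the phase of the onset bin.
#' The truth lists every sleep bout (start bin, length).
#'
#' @param n_days number of 24-h days (default 1).
#' @param lights_on,lights_off schedule (defaults 09:00 / 23:00).
#' @param start_clock_time first-bin clock time (default lights-on).
#' @param day,night per-phase parameter lists:
#'   `mean_sleep_bout_min` (geometric mean sleep run length, minutes),
#'   `mean_wake_bout_min`, and `wake_activity_shape`/`wake_activity_rate`
#'   for the gamma activity draw. A `mean_sleep_bout_min` of 0 disables
#'   sleep in that phase.
#' @param bin_seconds bin width (default 60).
#' @param larva_id,group trace labels.
#' @param seed integer seed.
#' @return list: `trace` (an `activity_trace`) and `truth` with
#'   `sleep_bouts` (start_bin, length_bins) and `params`.
#' @export
simulate_activity_trace <- function(n_days = 1,
                                    lights_on = "09:00",
                                    lights_off = "23:00",
                                    start_clock_time = lights_on,
                                    day = list(mean_sleep_bout_min = 2,
                                               mean_wake_bout_min = 20,
                                               wake_activity_shape = 2,
                                               wake_activity_rate = 0.2),
                                    night = list(mean_sleep_bout_min = 8,
                                                 mean_wake_bout_min = 6,
                                                 wake_activity_shape = 2,
                                                 wake_activity_rate = 0.4),
                                    bin_seconds = 60L,
                                    larva_id = "larva1", group = "control",
                                    seed = NULL) {
  nb <- as.integer(n_days * 24 * 3600 / bin_seconds)
  with_seed(seed, {
    dummy <- activity_trace(numeric(nb) + 1, larva_id, group,
                            start_clock_time, bin_seconds)
    phases <- bin_phases(dummy, lights_on, lights_off)
    act <- numeric(nb)
    bouts <- list()
    i <- 1L
    awake <- TRUE
    while (i <= nb) {
      p <- if (phases[i] == "day") day else night
      if (awake || p$mean_sleep_bout_min <= 0) {
        len <- 1L + stats::rgeom(1L, 1 / max(1, p$mean_wake_bout_min))
        len <- min(len, nb - i + 1L)
        act[i:(i + len - 1L)] <-
          stats::rgamma(len, shape = p$wake_activity_shape,
                        rate = p$wake_activity_rate) + 1e-6
        awake <- FALSE
      } else {
        len <- 1L + stats::rgeom(1L, 1 / max(1, p$mean_sleep_bout_min))
        len <- min(len, nb - i + 1L)
        act[i:(i + len - 1L)] <- 0
        bouts[[length(bouts) + 1L]] <- c(start_bin = i, length_bins = len)
        awake <- TRUE
      }
      i <- i + len
    }
    sleep_bouts <- if (length(bouts))
      as.data.frame(do.call(rbind, bouts)) else
      data.frame(start_bin = integer(), length_bins = integer())
    trace <- activity_trace(act, larva_id, group, start_clock_time,
                            bin_seconds)
    list(trace = trace,
         truth = list(sleep_bouts = sleep_bouts,
                      params = list(n_days = n_days, day = day,
                                    night = night, seed = seed)))
  })
}
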