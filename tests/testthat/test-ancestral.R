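test_that("single-tip and no-data likelihoods reduce to the prior", {
  m <- equal_rates_model()
  tr <- read_tree(text = "(A:0.3,B:0.4);")
  aln <- aln_from_strings(A = "R", B = "-")
  ll <- tree_log_likelihood(aln, tr, m)
  expect_equal(ll$total, log(1 / 20), tolerance = 1e-12)
  # all-gap site: posterior equals pi at every internal node
  aln2 <- aln_from_strings(A = "-", B = "-")
  expect_warning(rec <- marginal_ancestral_states(aln2, tr, m),
                 "tie")   # all states tie without data
  expect_equal(unname(rec$node_posteriors[[3]][, 1]), rep(1 / 20, 20),
               tolerance = 1e-12)
})

test_that("pruning matches brute-force enumeration on small trees", {
  set.seed(7)
  m <- jtt_model()
  for (rep in 1:5) {
    tr <- random_tree(sample(3:5, 1))
    sim <- simulate_alignment(tr, m, 4, seed = 100 + rep)
    ours <- marginal_ancestral_states(sim$alignment, tr, m)
    oracle <- brute_force_recon(sim$alignment, tr, m)
    expect_equal(ours$site_log_likelihoods, oracle$site_log_lik,
                 tolerance = 1e-10)
    ntip <- ape::Ntip(tr)
    for (v in (ntip + 1):(ntip + tr$Nnode))
      expect_equal(unname(ours$node_posteriors[[v]]),
                   unname(oracle$posteriors[[v]]), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  m <- jtt_model()
  # same unrooted metric, rooted on two different branches
  t1 <- read_tree(text = "((A:1,B:1):0.5,C:1.5);")
  t2 <- read_tree(text = "(A:0.4,(B:1,C:2):0.6);")
  aln <- aln_from_strings(A = "MARND", B = "MKRNE", C = "LARHD")
  expect_equal(tree_log_likelihood(aln, t1, m)$total,
               tree_log_likelihood(aln, t2, m)$total, tolerance = 1e-9)
})

test_that("a concordant cherry reconstructs its shared residue", {
  m <- equal_rates_model()
  tr <- read_tree(text = "(A:0.1,B:0.1);")
  aln <- aln_from_strings(A = "R", B = "R")
  rec <- marginal_ancestral_states(aln, tr, m)
  expect_identical(unname(rec$map_states[3, 1]), "R")
  expect_gt(rec$node_posteriors[[3]]["R", 1], 0.9)
})

test_that("ancestral reconstruction agrees with an independent package", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- random_tree(8)
  m <- jtt_model()
  sim <- simulate_alignment(tr, m, 30, seed = 77)
  ours <- tree_log_likelihood(sim$alignment, tr, m)$total
  dat <- phangorn::phyDat(unclass(sim$alignment), type = "AA")
  fit <- phangorn::pml(tr, dat, model = "JTT",
                       bf = unname(m$frequencies))
  expect_equal(ours, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("posteriors are proper and the MAP maximizes them", {
  set.seed(9)
  tr <- random_tree(6)
  m <- jtt_model()
  sim <- simulate_alignment(tr, m, 20, seed = 5)
  rec <- marginal_ancestral_states(sim$alignment, tr, m)
  for (v in 7:11) {
    Pv <- rec$node_posteriors[[v]]
    expect_lt(max(abs(colSums(Pv) - 1)), 1e-9)
    expect_identical(unname(rec$map_states[v, ]),
                     AA[apply(Pv, 2, which.max)])
  }
  expect_equal(rec$total_log_likelihood, sum(rec$site_log_likelihoods))
})

test_that("substitution listing applies the missing-data and identity rules", {
  m <- equal_rates_model()
  tr <- read_tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  aln <- aln_from_strings(A = "PAX", B = "PA-", C = "SAP", D = "SAP")
  rec <- suppressWarnings(marginal_ancestral_states(aln, tr, m))
  ev <- list_substitutions(rec, tr, aln, ref_id = "C")
  # site 2 invariant: no events; gap/X tips produce no events
  expect_false(any(ev$site == 2))
  expect_false(any(ev$branch %in% c("A", "B") & ev$site == 3))
  # site 1: P vs S split must yield at least one event with correct states
  s1 <- ev[ev$site == 1, ]
  expect_gt(nrow(s1), 0)
  expect_true(all(s1$parent_state != s1$child_state))
  expect_true(all(ev$reference_position ==
                    map_column_to_reference(aln, "C", ev$site)))
})

test_that("branch-length refit recovers the pairwise ML distance", {
  m <- equal_rates_model()
  tr <- read_tree(text = "(A:0.05,B:0.05);")
  set.seed(13)
  sim <- simulate_alignment(read_tree(text = "(A:0.1,B:0.1);"), m, 500,
                            seed = 13)
  fit <- optimize_branch_lengths(sim$alignment, tr, m)
  d <- ml_pairwise_distance(unclass(sim$alignment)["A", ],
                            unclass(sim$alignment)["B", ], m)
  expect_equal(sum(fit$tree$edge.length), d$t_hat, tolerance = 1e-4)
  expect_true(all(diff(fit$trace) >= -1e-9))  # monotone ascent
})

test_that("identical tip sequences refit to zero-length branches", {
  m <- equal_rates_model()
  tr <- read_tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
  aln <- aln_from_strings(A = "MARNDCQ", B = "MARNDCQ", C = "MARNDCQ")
  fit <- optimize_branch_lengths(aln, tr, m)
  expect_lt(max(fit$tree$edge.length), 1e-4)
})

test_that("simulated ancestral states are recovered at short branch lengths", {
  m <- equal_rates_model()
  tr <- read_tree(text = paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.05);"))
  sim <- simulate_alignment(tr, m, 300, seed = 31)
  rec <- suppressWarnings(marginal_ancestral_states(sim$alignment, tr, m))
  internal <- 9:15
  truth <- sim$truth$ancestral_states[internal, ]
  est <- rec$map_states[internal, ]
  expect_gt(mean(truth == est), 0.95)
})

test_that("refitted branch lengths recover simulation truth within 15%", {
  m <- equal_rates_model()
  true_tree <- read_tree(text = "((A:0.3,B:0.02):0.1,(C:0.5,D:0.25):0.05);")
  sim <- simulate_alignment(true_tree, m, 2000, seed = 19)
  start <- true_tree; start$edge.length[] <- 0.1
  fit <- optimize_branch_lengths(sim$alignment, start, m)
  # terminal branches are identifiable individually; very short branches
  # are judged on the absolute scale of their sampling error (the ML
  # standard error at t = 0.02 with 2000 sites is ~0.003, on the order of
  # 15% of t itself)
  tip_edges <- match(1:4, true_tree$edge[, 2])
  err <- abs(fit$tree$edge.length[tip_edges] -
               true_tree$edge.length[tip_edges])
  rel_ok <- err < 0.15 * true_tree$edge.length[tip_edges]
  abs_ok <- err < 0.01
  expect_true(all(rel_ok | abs_ok))
})
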