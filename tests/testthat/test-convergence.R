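# fake reconstruction with chosen MAP states, for definition-level tests
fake_recon <- function(tree, map_states) {
  structure(list(map_states = map_states,
                 node_posteriors = NULL,
                 tree_labels = convclock:::node_labels(tree)),
            class = "ancestral_recon")
}

test_that("branch-pair enumeration excludes nested and same-group pairs", {
  tr <- marine_tree()
  pairs <- enumerate_branch_pairs(tr)
  expect_equal(nrow(pairs), 3L)  # cetacea-walrus, cetacea-manatee, walrus-manatee
  expect_setequal(paste(pmin(pairs$group_a, pairs$group_b),
                        pmax(pairs$group_a, pairs$group_b)),
                  c("cetacea walrus", "cetacea manatee", "manatee walrus"))

  # a branch and its own descendant in different groups: excluded
  tr2 <- read_tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  tr2 <- tag_branches(tr2, list(g1 = c("A", "B"), g2 = "A"))
  expect_equal(nrow(enumerate_branch_pairs(tr2)), 0L)

  # 2 x 3 non-nested branches -> 6 pairs
  tr3 <- read_tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  tr3 <- tag_branches(tr3, list(g1 = c("A"), g2 = "C"))
  tr3$branch_tags[match(c("B", "D", "E"),
                        convclock:::node_labels(tr3))] <- c("g1", "g2", "g2")
  expect_equal(nrow(enumerate_branch_pairs(tr3)), 6L)

  expect_error(enumerate_branch_pairs(
    tag_branches(read_tree(text = "(A:1,B:1);"), list(g = "A"))),
    "2 distinct")
})

test_that("observed counts follow the Zhang-Kumar definitions", {
  tr <- read_tree(text = "((A:0.2,B:0.1):0.1,(C:0.2,D:0.1):0.1);")
  tr <- tag_branches(tr, list(g1 = "A", g2 = "C"))
  pairs <- enumerate_branch_pairs(tr)
  nn <- 7L
  mk <- function(pA, cA, pC, cC) {
    ms <- matrix("G", nn, 1)
    labs <- convclock:::node_labels(tr)
    ms[convclock:::node_number(tr, "A"), 1] <- cA
    ms[convclock:::node_number(tr, "C"), 1] <- cC
    ms[6L, 1] <- pA   # parent of A cherry
    ms[7L, 1] <- pC   # parent of C cherry
    rownames(ms) <- labs
    ms
  }
  # convergent: different parents, same derived state, both changed
  obs <- observed_convergence(fake_recon(tr, mk("S", "P", "T", "P")), tr, pairs)
  expect_equal(obs$convergent, 1L)
  expect_equal(obs$parallel, 0L)
  expect_identical(obs$sites$type, "convergent")
  # parallel: same parents
  obs <- observed_convergence(fake_recon(tr, mk("S", "P", "S", "P")), tr, pairs)
  expect_equal(obs$convergent, 0L)
  expect_equal(obs$parallel, 1L)
  # different derived states: neither
  obs <- observed_convergence(fake_recon(tr, mk("S", "P", "T", "Q")), tr, pairs)
  expect_equal(obs$convergent + obs$parallel, 0L)
  # only one branch changed: neither
  obs <- observed_convergence(fake_recon(tr, mk("S", "P", "P", "P")), tr, pairs)
  expect_equal(obs$convergent + obs$parallel, 0L)
  # gap at a child end: site skipped
  obs <- observed_convergence(fake_recon(tr, mk("S", "-", "T", "P")), tr, pairs)
  expect_equal(obs$convergent + obs$parallel, 0L)
})

test_that("expected convergence matches the equal-rates closed form", {
  m <- equal_rates_model()
  t1 <- 0.23; t2 <- 0.41
  tr <- read_tree(text = sprintf("((A:%g,B:0.1):0.1,(C:%g,D:0.1):0.1);", t1, t2))
  tr <- tag_branches(tr, list(g1 = "A", g2 = "C"))
  pairs <- enumerate_branch_pairs(tr)
  n_sites <- 37L
  ms <- matrix("A", 7L, n_sites,
               dimnames = list(convclock:::node_labels(tr), NULL))
  ms[6L, ] <- "S"; ms[7L, ] <- "T"
  ex <- expected_convergence(m, tr, fake_recon(tr, ms), pairs)
  g <- function(t) er_p_diff(t)
  expect_equal(ex$expected_convergent, 18 * g(t1) * g(t2) * n_sites,
               tolerance = 1e-12)
  # parallel parents: analogous closed form with 19 target states
  ms[7L, ] <- "S"
  ex <- expected_convergence(m, tr, fake_recon(tr, ms), pairs)
  expect_equal(ex$expected_parallel, 19 * g(t1) * g(t2) * n_sites,
               tolerance = 1e-12)
})

test_that("expected convergence vanishes on zero-length branches", {
  m <- equal_rates_model()
  tr <- read_tree(text = "((A:0,B:0.1):0.1,(C:0.4,D:0.1):0.1);")
  tr <- tag_branches(tr, list(g1 = "A", g2 = "C"))
  ms <- matrix("A", 7L, 10L,
               dimnames = list(convclock:::node_labels(tr), NULL))
  ms[6L, ] <- "S"; ms[7L, ] <- "T"
  ex <- expected_convergence(m, tr, fake_recon(tr, ms),
                             enumerate_branch_pairs(tr))
  expect_equal(ex$expected_convergent, 0)
})

test_that("expected counts scale linearly with the number of sites", {
  m <- jtt_model()
  tr <- read_tree(text = "((A:0.3,B:0.1):0.1,(C:0.2,D:0.1):0.1);")
  tr <- tag_branches(tr, list(g1 = "A", g2 = "C"))
  pairs <- enumerate_branch_pairs(tr)
  mk <- function(S) {
    ms <- matrix("A", 7L, S,
                 dimnames = list(convclock:::node_labels(tr), NULL))
    ms[6L, ] <- "S"; ms[7L, ] <- "T"
    fake_recon(tr, ms)
  }
  e1 <- expected_convergence(m, tr, mk(50L), pairs)$expected_convergent
  e2 <- expected_convergence(m, tr, mk(150L), pairs)$expected_convergent
  expect_equal(e2, 3 * e1, tolerance = 1e-12)
})

test_that("the Poisson test handles boundaries and is monotone in C", {
  expect_equal(poisson_test(0, 2), 1)
  expect_equal(poisson_test(0, 0), 1)
  expect_warning(p <- poisson_test(3, 0), "expected = 0")
  expect_equal(p, 0)
  expect_error(poisson_test(-1, 2), "negative")
  ps <- vapply(0:10, poisson_test, numeric(1), expected = 2)
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches hand-computed q-values", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the per-gene report ties the pipeline together", {
  m <- jtt_model()
  tr <- marine_tree()
  sim <- simulate_alignment(tr, m, 150, seed = 404)
  rep1 <- convergence_report(sim$alignment, tr, model = m, gene = "NPAS2",
                             refit_lengths = FALSE)
  expect_s3_class(rep1, "convergence_report")
  expect_gte(rep1$observed_convergent, 0)
  expect_gt(rep1$expected_convergent, 0)
  expect_true(rep1$poisson_p >= 0 && rep1$poisson_p <= 1)
  reps <- adjust_convergence_reports(list(rep1, rep1, rep1))
  qs <- vapply(reps, `[[`, numeric(1), "fdr_q")
  expect_true(all(qs >= 0 & qs <= 1))
})
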