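test_that("NG86 on the hand-worked 10-codon toy", {
  a <- paste0(strrep("AAA", 9), "TTT")
  b <- paste0(strrep("AAA", 9), "TTC")
  est <- ng86_pair(a, b)
  expect_equal(est$S, 10 / 3, tolerance = 1e-12)
  expect_equal(est$sd, 1)
  expect_equal(est$nd, 0)
  expect_equal(est$pS, 0.3, tolerance = 1e-12)
  expect_equal(est$dS, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(est$dN, 0)
  expect_equal(est$omega, 0)
})

test_that("NG86 is symmetric and flags undefined omega", {
  est <- ng86_pair("AAATTT", "AAATTT")
  expect_equal(est$sd + est$nd, 0)
  expect_false(est$omega_defined)
  expect_true(is.na(est$omega))
  a <- "AAATTTCGACCA"; b <- "AAGTATCGGCCT"
  e1 <- ng86_pair(a, b); e2 <- ng86_pair(b, a)
  expect_equal(e1$dN, e2$dN)
  expect_equal(e1$dS, e2$dS)
  expect_error(ng86_pair("AAATAA", "AAATAC"), "stop codon")
  expect_error(ng86_pair("AAAT", "AAAT"), "divisible by 3")
})

test_that("multi-position codon differences average over stop-free paths", {
  # TTA (L) -> ATG (M): positions 1 and 3 differ.
  # path via ATA (I): T->A nonsyn (L->I), A->G nonsyn (I->M)
  # path via TTG (L): T->G syn (L->L), T->A nonsyn (L->M)
  # average: sd = 0.5, nd = 1.5
  d <- convclock:::codon_path_differences("TTA", "ATG")
  expect_equal(unname(d["sd"]), 0.5)
  expect_equal(unname(d["nd"]), 1.5)
})

test_that("root-to-tip omega orders selective regimes correctly", {
  sims <- lapply(1:8, function(i) {
    low <- simulate_codon_pair(300, 0.4, 0.2, seed = 1000 + i)
    neu <- simulate_codon_pair(300, 0.4, 1.0, seed = 2000 + i)
    c(low = ng86_pair(low$ancestor, low$descendant)$omega,
      neu = ng86_pair(neu$ancestor, neu$descendant)$omega)
  })
  m <- do.call(rbind, sims)
  expect_lt(median(m[, "low"]), median(m[, "neu"]))
  expect_lt(median(m[, "low"]), 0.5)
})

test_that("root_to_tip_omega flags identical tips and validates lengths", {
  root <- c(rep("AAA", 9), "TTT")
  mat <- rbind(t1 = root, t2 = c(rep("AAA", 9), "TTC"))
  caln <- as_alignment(mat, "codon")
  tab <- root_to_tip_omega(caln, root)
  expect_false(tab$omega_defined[tab$species == "t1"])
  expect_true(is.na(tab$omega[tab$species == "t1"]))
  expect_equal(tab$omega[tab$species == "t2"], 0)
  expect_error(root_to_tip_omega(caln, c("AAA", "TTT")), "length")
})

test_that("lambda scaling of the Brownian covariance reads path lengths", {
  tr <- read_tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  C1 <- bm_covariance(tr, 1)
  expect_equal(C1["A", "B"], 0.5)
  expect_equal(C1["A", "A"], 1)
  Chalf <- bm_covariance(tr, 0.4)
  expect_equal(Chalf["A", "B"], 0.2)
  expect_equal(diag(Chalf), diag(C1))
  C0 <- bm_covariance(tr, 0)
  expect_true(all(C0[upper.tri(C0)] == 0))
  star <- read_tree(text = "(A:1,B:1,C:1,D:1);")
  expect_true(all(bm_covariance(star, 0.7)[upper.tri(diag(4))] == 0))
  expect_error(bm_covariance(tr, 1.2), "\\[0, 1\\]")
  expect_error(bm_covariance(tr, 1, species = c("A", "Z")), "missing")
})

test_that("PGLS on a star tree equals ordinary least squares", {
  set.seed(77)
  n <- 20
  star <- read_tree(text = paste0(
    "(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  x <- rnorm(n); y <- 1 + 0.8 * x + rnorm(n, sd = 0.3)
  traits <- data.frame(species = paste0("t", 1:n), predictor = x,
                       response = y)
  fit <- pgls_fit(traits, star, "response", "predictor")
  ols <- summary(lm(y ~ x))
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ x))), tolerance = 1e-8)
  expect_equal(fit$p_slope, ols$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-8)
  expect_equal(fit$r_squared, ols$r.squared, tolerance = 1e-8)
})

test_that("a noiseless linear trait is fit exactly", {
  set.seed(5)
  tr <- random_tree(12)
  sim <- simulate_trait(tr, lambda = 0.5, beta = 2, sigma2 = 0, seed = 9)
  fit <- pgls_fit(sim$traits, tr, "response", "predictor")
  expect_equal(unname(fit$beta["slope"]), 2, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("PGLS agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(14)
  tr <- ape::rcoal(30)
  tr <- validate_tree(tr)
  sim <- simulate_trait(tr, lambda = 0.8, beta = 0.5, sigma2 = 0.4,
                        seed = 15)
  fit <- pgls_fit(sim$traits, tr, "response", "predictor")
  dat <- sim$traits
  rownames(dat) <- dat$species
  g <- nlme::gls(response ~ predictor, data = dat,
                 correlation = ape::corPagel(0.8, tr, form = ~species),
                 method = "ML")
  expect_equal(unname(fit$beta["slope"]),
               unname(coef(g)["predictor"]), tolerance = 0.05)
  expect_equal(fit$lambda_hat,
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 0.1)
})

test_that("GLS residuals are C-orthogonal to the design at the optimum", {
  set.seed(23)
  tr <- ape::rcoal(25); tr <- validate_tree(tr)
  sim <- simulate_trait(tr, lambda = 1, beta = 0.5, sigma2 = 0.3, seed = 8)
  fit <- pgls_fit(sim$traits, tr, "response", "predictor")
  C <- bm_covariance(tr, fit$lambda_hat, species = sim$traits$species)
  X <- cbind(1, sim$traits$predictor)
  e <- sim$traits$response - X %*% fit$beta
  expect_lt(max(abs(t(X) %*% solve(C, e))), 1e-8)
  # profile optimum beats the usual fixed-lambda fits
  ll_at <- function(lam) {
    Cl <- bm_covariance(tr, lam, species = sim$traits$species)
    convclock:::pgls_gls(X, sim$traits$response, Cl)$loglik
  }
  for (lam in c(0, 0.5, 1))
    expect_gte(fit$log_likelihood + 1e-8, ll_at(lam))
})

test_that("degenerate designs are rejected", {
  tr <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  traits <- data.frame(species = c("A", "B", "C", "D"),
                       predictor = rep(1, 4), response = rnorm(4))
  expect_error(pgls_fit(traits, tr, "response", "predictor"), "singular")
  expect_error(pgls_fit(traits[1:3, ], tr, "response", "predictor"),
               "fewer than 4")
})
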