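## NG86 (Nei & Gojobori 1986) dN/dS counting and phylogenetic GLS
## regression with maximum-likelihood Pagel's lambda.

## per-codon synonymous site count: at each position, the fraction of
## non-stop single-nucleotide changes that are synonymous
codon_syn_sites <- function(codon) {
  nb <- codon_neighbors(codon)
  aa0 <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    alts <- nb$codon[nb$position == p]
    alts <- alts[!is_stop_codon(alts)]
    if (!length(alts)) next
    s <- s + mean(translate_codon(alts) == aa0)
  }
  s
}

## average syn/nonsyn differences between two codons over all orderings
## of the single-nucleotide steps, excluding pathways through stop codons
codon_path_differences <- function(a, b) {
  diffpos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  nd <- length(diffpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  count_path <- function(order) {
    cur <- strsplit(a, "")[[1L]]
    tgt <- strsplit(b, "")[[1L]]
    sd <- 0; nsd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- tgt[p]
      c1 <- paste0(cur, collapse = ""); c2 <- paste0(nxt, collapse = "")
      if (is_stop_codon(c2)) return(NULL)
      if (translate_codon(c1) == translate_codon(c2)) sd <- sd + 1
      else nsd <- nsd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nsd)
  }
  orders <- if (nd == 1L) list(diffpos)
            else if (nd == 2L) list(diffpos, rev(diffpos))
            else {
      perms <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        perms[[length(perms) + 1L]] <- diffpos[c(i, j, setdiff(1:3, c(i, j)))]
      perms
  }
  res <- Filter(Negate(is.null), lapply(orders, count_path))
  if (!length(res))  # every pathway passes through a stop; fall back to
    res <- Filter(Negate(is.null), lapply(orders, function(o) {
      cur <- strsplit(a, "")[[1L]]; tgt <- strsplit(b, "")[[1L]]
      sd <- 0; nsd <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- tgt[p]
        c1 <- paste0(cur, collapse = ""); c2 <- paste0(nxt, collapse = "")
        aa1 <- translate_codon(c1); aa2 <- translate_codon(c2)
        if (identical(aa1, aa2)) sd <- sd + 1 else nsd <- nsd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nsd)
    }))
  colMeans(do.call(rbind, res))
}

#' NG86 pairwise dN/dS
#'
#' Nei-Gojobori counting between two aligned codon sequences: synonymous
#' site fractions per codon position over non-stop single-nucleotide
#' changes, multi-position codon differences averaged over all stop-free
#' orderings of single steps, proportions corrected by the Jukes-Cantor
#' formula d = -(3/4) log(1 - (4/3) p). `omega` is `NA` (flagged) when
#' dS = 0 or a proportion reaches the correction's domain limit 3/4.
#'
#' @param a,b codon sequences: character vectors of triplets, or
#'   nucleotide strings with length divisible by 3. Codon pairs where
#'   either side contains a gap or ambiguity are dropped.
#' @return an `ng86` list: S, N, sd, nd, pS, pN, dS, dN, omega,
#'   omega_defined, n_codons_used.
#' @export
ng86_pair <- function(a, b) {
  a <- as_codon_vector(a); b <- as_codon_vector(b)
  if (length(a) != length(b)) stop("sequences differ in codon length")
  ok_a <- a %in% sense_codons(); ok_b <- b %in% sense_codons()
  gap_a <- grepl("-|N|X", a); gap_b <- grepl("-|N|X", b)
  if (any(!ok_a & !gap_a))
    stop("internal stop codon in first sequence at codon ",
         which(!ok_a & !gap_a)[1L])
  if (any(!ok_b & !gap_b))
    stop("internal stop codon in second sequence at codon ",
         which(!ok_b & !gap_b)[1L])
  keep <- ok_a & ok_b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no ungapped codon pairs")
  Sa <- sum(vapply(a, codon_syn_sites, numeric(1)))
  Sb <- sum(vapply(b, codon_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(a) - S
  diffs <- vapply(seq_along(a), function(i)
    codon_path_differences(a[i], b[i]), numeric(2))
  sd <- sum(diffs["sd", ]); nd <- sum(diffs["nd", ])
  pS <- sd / S; pN <- nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  dS <- jc(pS); dN <- jc(pN)
  defined <- !is.na(dS) && !is.na(dN) && dS > 0
  structure(list(S = S, N = N, sd = sd, nd = nd, pS = pS, pN = pN,
                 dS = dS, dN = dN,
                 omega = if (defined) dN / dS else NA_real_,
                 omega_defined = defined, n_codons_used = length(a)),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf("<ng86> dN = %.4f, dS = %.4f, omega = %s (%d codons)\n",
              x$dN, x$dS,
              if (x$omega_defined) sprintf("%.4f", x$omega) else "undefined",
              x$n_codons_used))
  invisible(x)
}

as_codon_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 3L) {
    if (nchar(x) %% 3L != 0L) stop("sequence length not divisible by 3")
    x <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  toupper(x)
}

#' Root-to-tip omega table
#'
#' NG86 omega between a root codon sequence and each tip sequence of a
#' codon alignment. Rows with undefined omega (dS = 0 or saturation) are
#' flagged; downstream fits drop them with a message.
#'
#' @param codon_aln codon-mode `conv_alignment`.
#' @param root_seq codon sequence of the root, aligned to the alignment.
#' @param tips optional subset of ids (default all).
#' @return data frame: species, omega, dN, dS, omega_defined.
#' @export
root_to_tip_omega <- function(codon_aln, root_seq, tips = NULL) {
  stopifnot(attr(codon_aln, "alphabet") == "codon")
  root_seq <- as_codon_vector(root_seq)
  if (length(root_seq) != ncol(codon_aln))
    stop("root sequence length does not match alignment")
  if (is.null(tips)) tips <- rownames(codon_aln)
  rows <- lapply(tips, function(id) {
    est <- ng86_pair(root_seq, unclass(codon_aln)[id, ])
    data.frame(species = id, omega = est$omega, dN = est$dN, dS = est$dS,
               omega_defined = est$omega_defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Brownian-motion covariance with Pagel's lambda
#'
#' C_ij is the shared root-to-MRCA path length for i != j and the
#' root-to-tip length on the diagonal; lambda multiplies the
#' off-diagonal entries only.
#'
#' @param tree `phylo` with branch lengths.
#' @param lambda value in \[0, 1\].
#' @param species optional ordering/subset of tip labels.
#' @return covariance matrix over species.
#' @export
bm_covariance <- function(tree, lambda = 1, species = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing))
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    C <- C[species, species, drop = FALSE]
  }
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

pgls_gls <- function(X, y, C) {
  R <- chol(C)
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  n <- length(y)
  logdet <- 2 * sum(log(diag(R)))
  sigma2_ml <- max(rss / n, 1e-300)   # keep the profile finite at RSS = 0
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  list(beta = drop(beta), rss = rss, logdet = logdet, loglik = ll,
       XtX_inv = solve(XtX), Xs = Xs, ys = ys)
}

#' PGLS regression with maximum-likelihood Pagel's lambda
#'
#' Generalized least squares of `response` on `predictor` with residual
#' covariance sigma^2 C(lambda); lambda is profiled by ML over \[0, 1\]
#' (101-point grid then bounded refinement around the grid optimum).
#' The slope p-value uses the t statistic with n - 2 degrees of freedom;
#' R^2 = 1 - (e' C^-1 e) / (y~' C^-1 y~) with y~ the GLS-demeaned
#' response.
#'
#' @param traits data frame with a `species` column and numeric columns.
#' @param tree `phylo` covering the species.
#' @param response,predictor column names in `traits`.
#' @return a `pgls_fit` list: lambda_hat, beta, se, sigma2, r_squared,
#'   t_slope, p_slope, log_likelihood, n, dropped.
#' @export
pgls_fit <- function(traits, tree, response, predictor) {
  stopifnot(all(c("species", response, predictor) %in% names(traits)))
  keep <- stats::complete.cases(traits[, c(response, predictor)]) &
    traits$species %in% tree$tip.label
  dropped <- sum(!keep)
  if (dropped) message(dropped, " row(s) dropped (missing data or absent from tree)")
  dat <- traits[keep, , drop = FALSE]
  n <- nrow(dat)
  if (n < 4L) stop("fewer than 4 complete cases")
  y <- dat[[response]]
  x <- dat[[predictor]]
  X <- cbind(intercept = 1, slope = x)
  if (qr(X)$rank < 2L) stop("singular design (constant predictor)")
  C1 <- bm_covariance(tree, 1, species = dat$species)
  prof <- function(lam) {
    C <- C1 * lam; diag(C) <- diag(C1)
    pgls_gls(X, y, C)$loglik
  }
  grid <- seq(0, 1, length.out = 101L)
  lls <- vapply(grid, prof, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(101L, i + 1L)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda_hat <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  C <- C1 * lambda_hat; diag(C) <- diag(C1)
  fit <- pgls_gls(X, y, C)
  sigma2 <- fit$rss / (n - 2)
  se <- sqrt(diag(fit$XtX_inv) * sigma2)
  t_slope <- fit$beta[2L] / se[2L]
  p_slope <- 2 * stats::pt(abs(t_slope), df = n - 2, lower.tail = FALSE)
  ## GLS-demeaned response: residuals from the intercept-only GLS fit
  null_fit <- pgls_gls(matrix(1, n, 1), y, C)
  r_squared <- 1 - fit$rss / null_fit$rss
  structure(list(lambda_hat = lambda_hat,
                 beta = stats::setNames(fit$beta, c("intercept", "slope")),
                 se = stats::setNames(se, c("intercept", "slope")),
                 sigma2 = sigma2, r_squared = r_squared,
                 t_slope = t_slope, p_slope = p_slope,
                 log_likelihood = pgls_gls(X, y, C)$loglik,
                 n = n, dropped = dropped,
                 response = response, predictor = predictor),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> %s ~ %s (n = %d)\n", x$response, x$predictor, x$n))
  cat(sprintf("  lambda = %.3f, slope = %.4f (se %.4f), p = %.4g, R^2 = %.3f\n",
              x$lambda_hat, x$beta["slope"], x$se["slope"], x$p_slope,
              x$r_squared))
  invisible(x)
}
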