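## Empirical amino-acid substitution models: symmetric exchangeabilities
## s_ij combined with stationary frequencies pi to give a reversible rate
## matrix Q with q_ij = s_ij * pi_j, scaled to one expected substitution
## per site per unit branch length. Transition probabilities come from the
## eigendecomposition of the symmetrized rate matrix.

#' Estimate equilibrium amino-acid frequencies from an alignment
#'
#' The "f_genes" frequencies: counts pooled over the whole gene alignment
#' (gaps and `X` excluded) with an additive pseudocount so that no state
#' has probability zero. pi_a = (count_a + pseudocount) / (total + 20 *
#' pseudocount).
#'
#' @param aln amino-acid `conv_alignment`.
#' @param pseudocount nonnegative real added per amino acid (default 0.5;
#'   gene alignments are a few hundred columns and rarely observe all 20
#'   residues).
#' @return named numeric vector of length 20 in canonical order.
#' @export
estimate_frequencies <- function(aln, pseudocount = 0.5) {
  stopifnot(inherits(aln, "conv_alignment"),
            attr(aln, "alphabet") == "amino_acid",
            pseudocount >= 0)
  counts <- table(factor(unclass(aln), levels = AA_ALPHABET))
  total <- sum(counts)
  if (total == 0) stop("alignment has no unambiguous residues")
  freqs <- (as.numeric(counts) + pseudocount) / (total + 20 * pseudocount)
  names(freqs) <- AA_ALPHABET
  freqs
}

#' Read the packaged JTT exchangeability table
#' @return symmetric 20x20 matrix and the published stationary frequencies.
#' @keywords internal
read_jtt_table <- function() {
  path <- system.file("extdata", "jtt_exchangeabilities.txt",
                      package = "convclock", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  nums <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in 2:20) S[i, seq_len(i - 1L)] <- nums[[i - 1L]]
  S <- S + t(S)
  freqs <- nums[[20L]]
  names(freqs) <- AA_ALPHABET
  list(exchangeabilities = S, frequencies = freqs)
}

#' Build a reversible amino-acid substitution model
#'
#' @param exchangeabilities symmetric nonnegative 20x20 matrix (diagonal
#'   ignored).
#' @param frequencies positive probability vector of length 20.
#' @param name model name for reports.
#' @return a `subst_model` with the normalized rate matrix `Q` and a
#'   cached spectral decomposition for fast `P(t)`.
#' @export
build_model <- function(exchangeabilities, frequencies, name = "custom") {
  S <- as.matrix(exchangeabilities)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
    stop("exchangeability matrix must be symmetric")
  if (any(S < 0)) stop("exchangeabilities must be nonnegative")
  pi <- as.numeric(frequencies)
  if (length(pi) != 20L || any(pi <= 0))
    stop("frequencies must be 20 positive values")
  if (abs(sum(pi)) < 1e-12) stop("frequencies sum to zero")
  pi <- pi / sum(pi)
  diag(S) <- 0
  Q <- S * rep(pi, each = 20L)      # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # mean substitution rate
  if (mu <= 0) stop("degenerate model: zero mean rate")
  Q <- Q / mu
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  ## symmetrize: B = D^(1/2) Q D^(-1/2) is symmetric for reversible Q
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name,
                 exchangeabilities = S,
                 frequencies = stats::setNames(pi, AA_ALPHABET),
                 Q = Q,
                 eigenvalues = eig$values,
                 ## P(t) = L diag(exp(lambda t)) R with L = D^(-1/2) U,
                 ## R = U' D^(1/2)
                 left = (1 / sq) * eig$vectors,
                 right = t(eig$vectors * sq)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s (20-state reversible, mean rate 1)\n", x$name))
  invisible(x)
}

#' The JTT model with packaged or gene-specific frequencies
#'
#' `frequencies = NULL` uses the published JTT frequencies; pass
#' [estimate_frequencies()] output for the JTT-f_genes variant.
#'
#' @param frequencies optional length-20 probability vector.
#' @return a `subst_model`.
#' @export
jtt_model <- function(frequencies = NULL) {
  tab <- read_jtt_table()
  default_freqs <- is.null(frequencies)
  if (default_freqs) frequencies <- tab$frequencies
  build_model(tab$exchangeabilities, frequencies,
              name = if (default_freqs) "JTT" else "JTT-f_genes")
}

#' The equal-rates (Jukes-Cantor-like) 20-state test model
#' @return a `subst_model` with all exchangeabilities equal and uniform
#'   frequencies; off-diagonal rates are all 1/19.
#' @export
equal_rates_model <- function() {
  S <- matrix(1, 20, 20); diag(S) <- 0
  build_model(S, rep(1 / 20, 20), name = "equal_rates")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `subst_model`.
#' @param t branch length in expected substitutions/site, finite and >= 0.
#' @return 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- model$left %*% (exp(model$eigenvalues * t) * model$right)
  ## tiny negatives from roundoff are clamped
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Maximum-likelihood pairwise distance under a substitution model
#'
#' Maximizes the likelihood of one aligned sequence pair over the branch
#' length separating them, sum over sites of log(pi_a * P_ab(t)). Sites
#' where either sequence has a gap or `X` are dropped first. Under the
#' equal-rates model this matches the closed form
#' t = -(19/20) log(1 - (20/19) p) with p the observed difference
#' fraction.
#'
#' @param a,b character vectors of residues (or single strings).
#' @param model a `subst_model`.
#' @param t_max optimization upper bound (default 20).
#' @return list with `t_hat`, `log_likelihood`, `p_hat`, `n_sites`.
#' @export
ml_pairwise_distance <- function(a, b, model, t_max = 20) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1L]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b)) stop("sequences differ in length")
  keep <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
  if (!any(keep)) stop("no overlapping ungapped sites")
  a <- a[keep]; b <- b[keep]
  ia <- match(a, AA_ALPHABET); ib <- match(b, AA_ALPHABET)
  if (anyNA(ia) || anyNA(ib)) stop("illegal residue symbol")
  p_hat <- mean(ia != ib)
  if (p_hat >= 19 / 20)
    stop(sprintf("sequences saturated (p = %.3f >= 0.95): distance not estimable", p_hat))
  if (p_hat == 0)
    return(list(t_hat = 0,
                log_likelihood = sum(log(model$frequencies[ia])),
                p_hat = 0, n_sites = length(a)))
  nll <- function(t) {
    P <- transition_matrix(model, t)
    -sum(log(model$frequencies[ia] * pmax(P[cbind(ia, ib)], 1e-300)))
  }
  opt <- stats::optimize(nll, c(0, t_max), tol = 1e-9)
  list(t_hat = opt$minimum, log_likelihood = -opt$objective,
       p_hat = p_hat, n_sites = length(a))
}
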