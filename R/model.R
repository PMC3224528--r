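#' Construct a WAG(+F)+I+Gamma substitution model
#'
#' Assembles the reversible amino-acid substitution model used throughout
#' the package: WAG exchangeabilities, stationary frequencies (the published
#' WAG frequencies by default, or empirical `+F` frequencies from the data),
#' a discrete-gamma distribution of relative rates with `n_cat` equal-weight
#' categories, and a proportion `p_inv` of invariant sites.
#'
#' @param pi stationary frequencies (length 20, ARNDCQEGHILKMFPSTWYV order);
#'   default the published WAG frequencies. Use [empirical_frequencies()]
#'   for `+F`.
#' @param alpha gamma shape (> 0).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param n_cat number of gamma categories (default 4).
#' @param S 20x20 symmetric exchangeability matrix; default WAG.
#' @return an object of class `subst_model`: list with the inputs plus the
#'   normalized generator `Q`, its symmetric eigendecomposition (`B`,
#'   `Binv`, `lam` with `P(t) = B exp(lam t) Binv`), the scaled gamma
#'   category rates (`rates`) and the per-category gamma weight `wg`.
#' @export
substitution_model <- function(pi = WAG_FREQS, alpha = 1, p_inv = 0,
                               n_cat = 4L, S = wag_exchangeability_matrix()) {
  stopifnot(alpha > 0, p_inv >= 0, p_inv < 1, n_cat >= 1)
  Q <- build_rate_matrix(S, pi)
  # symmetric eigendecomposition in the pi^(1/2) inner product
  d <- sqrt(pi)
  A <- (Q * d) / rep(d, each = 20L) # D^1/2 Q D^-1/2
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  B <- e$vectors / d
  Binv <- t(e$vectors) * rep(d, each = 20L)
  g <- discretize_gamma(alpha, n_cat)
  structure(list(S = S, pi = pi, alpha = alpha, p_inv = p_inv,
                 n_cat = as.integer(n_cat), Q = Q,
                 B = B, Binv = Binv, lam = e$values,
                 rates = g$rates / (1 - p_inv),
                 wg = (1 - p_inv) / n_cat),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: alpha=%.4g p_inv=%.4g n_cat=%d (+%s frequencies)\n",
              x$alpha, x$p_inv, x$n_cat,
              if (isTRUE(all.equal(x$pi, WAG_FREQS))) "WAG" else "F"))
  invisible(x)
}

update_model <- function(model, alpha = model$alpha, p_inv = model$p_inv) {
  substitution_model(pi = model$pi, alpha = alpha, p_inv = p_inv,
                     n_cat = model$n_cat, S = model$S)
}

#' Build a normalized reversible rate matrix
#'
#' `Q[i,j] = S[i,j] * pi[j]` off the diagonal; the diagonal makes rows sum
#' to zero and the whole generator is rescaled so the expected substitution
#' rate at stationarity, `-sum(pi * diag(Q))`, equals 1 (branch lengths are
#' then in expected substitutions per site).
#'
#' @param S symmetric non-negative exchangeability matrix.
#' @param pi frequency vector (positive, sums to 1 within 1e-8).
#' @return 20x20 generator matrix.
#' @export
build_rate_matrix <- function(S, pi) {
  if (!isSymmetric(unname(S), tol = 1e-10)) stop("S must be symmetric")
  if (any(S[upper.tri(S)] < 0)) stop("S must have non-negative off-diagonals")
  if (length(pi) != nrow(S) || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be positive and sum to 1")
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

#' Transition probability matrix P(t) = expm(Q t)
#'
#' Computed from the model's symmetric eigendecomposition; entries are
#' clipped to `[0, 1]` after numerical exponentiation.
#'
#' @param model a [substitution_model()].
#' @param t elapsed time (branch length times relative rate), `>= 0`.
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("t must be >= 0")
  cpp_pmat(model$B, model$Binv, model$lam, t)
}

#' Discrete-gamma rate categories
#'
#' Equal-weight categories; each category rate is the conditional mean of
#' the Gamma(alpha, alpha) distribution within its inter-quantile slice
#' (mean-rate discretization), so the rates average exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param n_cat number of categories (>= 1).
#' @return list with `rates` (increasing, mean 1) and `weights`.
#' @export
discretize_gamma <- function(alpha, n_cat = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  n_cat <- as.integer(n_cat)
  stopifnot(n_cat >= 1L)
  if (n_cat == 1L) return(list(rates = 1, weights = 1))
  # E[X | q_{k-1} < X <= q_k] for X ~ Gamma(alpha, alpha):
  # = (F_{alpha+1}(q_k) - F_{alpha+1}(q_{k-1})) * n_cat  (rate param alpha)
  qs <- qgamma(seq_len(n_cat - 1L) / n_cat, shape = alpha, rate = alpha)
  Fa1 <- pgamma(c(0, qs, Inf), shape = alpha + 1, rate = alpha)
  rates <- diff(Fa1) * n_cat
  rates <- rates / mean(rates) # exact unit mean despite roundoff
  list(rates = rates, weights = rep(1 / n_cat, n_cat))
}

#' Rate classes of the +I+Gamma mixture
#'
#' With invariant proportion `p_inv`, the mixture has one class of rate 0
#' and weight `p_inv`, and `n_cat` gamma classes whose rates are scaled by
#' `1/(1 - p_inv)` so the overall mean rate stays 1.
#'
#' @param model a [substitution_model()].
#' @return list with `rates` and `weights` (including the invariant class
#'   first when `p_inv > 0`).
#' @export
rate_classes <- function(model) {
  g <- discretize_gamma(model$alpha, model$n_cat)
  if (model$p_inv == 0)
    return(list(rates = g$rates, weights = g$weights))
  list(rates = c(0, g$rates / (1 - model$p_inv)),
       weights = c(model$p_inv, g$weights * (1 - model$p_inv)))
}

#' Empirical amino-acid frequencies (+F)
#'
#' Observed residue proportions over all non-gap, non-ambiguous cells with
#' an add-one pseudocount per state (guarantees strictly positive
#' frequencies, as the eigendecomposition requires).
#'
#' @param aln an [aa_alignment].
#' @return frequency vector of length 20 (ARNDCQEGHILKMFPSTWYV order).
#' @export
empirical_frequencies <- function(aln) {
  m <- unclass(aln)
  cells <- m[m != "-" & m != "X"]
  if (length(cells) == 0L)
    stop("alignment has no unambiguous residues")
  counts <- table(factor(cells, levels = AA_STATES))
  p <- (as.numeric(counts) + 1) / (length(cells) + 20)
  stats::setNames(p, AA_STATES)
}
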