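# Shared fixtures and independent oracles for the test suite. Everything
# here is deliberately naive (direct enumeration / recounting) and does not
# reuse the package's computational paths.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

rand_alignment <- function(nt, ns, seed, gap_frac = 0, amb_frac = 0,
                           taxa = sprintf("t%02d", seq_len(nt))) {
  set.seed(seed)
  m <- matrix(sample(AA20, nt * ns, replace = TRUE), nt, ns)
  if (gap_frac > 0)
    m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  if (amb_frac > 0)
    m[sample(length(m), round(amb_frac * length(m)))] <- "X"
  rownames(m) <- taxa
  aa_alignment(m)
}

rand_unrooted_tree <- function(n, seed, bl = c(0.05, 0.5)) {
  set.seed(seed)
  ape::unroot(ape::rtree(n, br = function(k) runif(k, bl[1], bl[2])))
}

# Brute-force quartet site log-likelihoods for an unrooted quartet written
# exactly as "((A:ta,B:tb):tab,C:tc,D:td);": explicit double sum over all
# 20^2 internal-state assignments (x at the C/D trifurcation, y at the A/B
# node), per rate class of the +I+Gamma mixture.
quartet_tree <- function(ta, tb, tab, tc, td,
                         labels = c("A", "B", "C", "D")) {
  ape::read.tree(text = sprintf("((%s:%.17g,%s:%.17g):%.17g,%s:%.17g,%s:%.17g);",
                                labels[1], ta, labels[2], tb, tab,
                                labels[3], tc, labels[4], td))
}

quartet_bruteforce <- function(lens, aln, model,
                               labels = c("A", "B", "C", "D")) {
  lens <- pmax(lens, 1e-8) # (ta, tb, tab, tc, td)
  codes <- match(unclass(aln)[labels, ], AA20)
  dim(codes) <- c(4L, ncol(aln))
  g <- discretize_gamma(model$alpha, model$n_cat)
  rates <- c(if (model$p_inv > 0) 0, g$rates / (1 - model$p_inv))
  wts <- c(if (model$p_inv > 0) model$p_inv,
           rep((1 - model$p_inv) / model$n_cat, model$n_cat))
  tipv <- function(code) if (is.na(code)) rep(1, 20) else
    as.numeric(seq_len(20) == code)
  out <- numeric(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    tot <- 0
    for (ci in seq_along(rates)) {
      r <- rates[ci]
      PA <- transition_matrix(model, lens[1] * r)
      PB <- transition_matrix(model, lens[2] * r)
      PAB <- transition_matrix(model, lens[3] * r)
      PC <- transition_matrix(model, lens[4] * r)
      PD <- transition_matrix(model, lens[5] * r)
      vA <- tipv(codes[1, j]); vB <- tipv(codes[2, j])
      vC <- tipv(codes[3, j]); vD <- tipv(codes[4, j])
      # every (x, y) internal assignment enumerated via outer()
      fx <- model$pi * as.vector(PC %*% vC) * as.vector(PD %*% vD)
      fy <- as.vector(PA %*% vA) * as.vector(PB %*% vB)
      lik <- sum(outer(fx, fy) * PAB)
      tot <- tot + wts[ci] * lik
    }
    out[j] <- log(tot)
  }
  out
}

# independent split enumeration: tip-label sets below each edge via a plain
# queue walk over the edge matrix, canonicalized like a bipartition should be
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  below <- function(v) {
    out <- c(); stack <- v
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      if (x <= n) out <- c(out, tree$tip.label[x])
      else stack <- c(stack, edge[edge[, 1] == x, 2])
    }
    out
  }
  keys <- character(0)
  for (e in seq_len(nrow(edge))) {
    a <- sort(below(edge[e, 2]))
    b <- sort(setdiff(tree$tip.label, a))
    if (length(a) <= 1 || length(b) <= 1) next
    key <- if (length(a) < length(b) ||
               (length(a) == length(b) && a[1] < b[1]))
      paste(a, collapse = "|") else paste(b, collapse = "|")
    keys <- c(keys, key)
  }
  sort(unique(keys))
}
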