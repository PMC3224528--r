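# --- alignment encoding and pattern compression -----------------------------

# integer codes 1..20 in AA_STATES order; 0 for missing (gap or X)
encode_alignment <- function(aln, taxa_order) {
  m <- unclass(aln)[taxa_order, , drop = FALSE]
  codes <- match(m, AA_STATES)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = length(taxa_order))
}

# collapse identical columns; returns codes (ntip x npat), weights, and the
# per-site pattern index
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(codes = codes[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(u))),
       index = idx)
}

# invariant-class contribution per pattern: p_inv * pi[a] for columns whose
# non-missing states all equal a (gaps do not break constancy); p_inv for
# all-missing columns; 0 otherwise
invariant_contrib <- function(codes, model) {
  if (model$p_inv == 0) return(numeric(ncol(codes)))
  apply(codes, 2L, function(col) {
    obs <- unique(col[col > 0L])
    if (length(obs) == 0L) model$p_inv
    else if (length(obs) == 1L) model$p_inv * model$pi[obs]
    else 0
  })
}

# shared setup for likelihood computations on a (tree, alignment) pair
lik_data <- function(tree, aln, model, bl_floor = 1e-8) {
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("tree leaves and alignment taxa differ: only in tree {",
         paste(setdiff(tree$tip.label, rownames(aln)), collapse = ","),
         "}, only in alignment {",
         paste(setdiff(rownames(aln), tree$tip.label), collapse = ","), "}")
  tree <- ape::reorder.phylo(floor_lengths(as_unrooted(tree), bl_floor),
                             "postorder")
  pat <- compress_patterns(encode_alignment(aln, tree$tip.label))
  list(tree = tree, codes = pat$codes, weights = pat$weights,
       index = pat$index, invc = invariant_contrib(pat$codes, model))
}

pattern_loglik <- function(ld, model, elen = ld$tree$edge.length) {
  catll <- cpp_cat_loglik(ld$tree$edge, elen, length(ld$tree$tip.label),
                          ld$tree$Nnode, ld$codes, model$B, model$Binv,
                          model$lam, model$rates, model$pi)
  cpp_mix_loglik(catll, ld$invc, model$wg)
}

#' Site-wise log-likelihoods by the pruning algorithm
#'
#' Computes the natural-log likelihood of every alignment column on a tree
#' under a [substitution_model()]. Each column's likelihood is the
#' `+I+Gamma` mixture: the equal-weight discrete-gamma categories plus a
#' rate-zero invariant class that contributes `p_inv * pi[a]` only when the
#' column is constant ignoring gaps. Gaps and `X` are treated as missing
#' data. Underflow is controlled by per-node rescaling with accumulated
#' log-scalers.
#'
#' @param tree an [ape::phylo] whose leaf set equals the alignment's taxa.
#' @param aln an [aa_alignment].
#' @param model a [substitution_model()].
#' @param bl_floor lower bound applied to branch lengths (default 1e-8).
#' @return numeric vector of per-site log-likelihoods (length `ncol(aln)`).
#' @export
site_log_likelihoods <- function(tree, aln, model, bl_floor = 1e-8) {
  ld <- lik_data(tree, aln, model, bl_floor)
  ll <- pattern_loglik(ld, model)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll[ld$index]))[1L]
    stop("non-finite site log-likelihood at column ", bad)
  }
  ll[ld$index]
}

#' Total log-likelihood of a (tree, alignment, model) triple
#' @inheritParams site_log_likelihoods
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(tree, aln, model, bl_floor = 1e-8) {
  ld <- lik_data(tree, aln, model, bl_floor)
  sum(pattern_loglik(ld, model) * ld$weights)
}

# per-edge directional context in single-edge mode; returns K-slice cubes
edge_context <- function(ld, model, eidx, elen = ld$tree$edge.length) {
  tr <- ld$tree
  cpp_edge_contexts(tr$edge, elen, length(tr$tip.label), tr$Nnode, ld$codes,
                    model$B, model$Binv, model$lam, model$rates, model$pi,
                    only_edge = eidx)
}

edge_profile_loglik <- function(ctx, ld, model, t) {
  catll <- cpp_edge_loglik(ctx$V, ctx$vscal, ctx$D, ctx$dscal,
                           model$B, model$Binv, model$lam, model$rates, t)
  sum(cpp_mix_loglik(catll, ld$invc, model$wg) * ld$weights)
}

#' Optimize branch lengths by round-robin univariate search
#'
#' Each edge in turn is re-optimized by bounded scalar search on
#' `[bl_floor, max_bl]` while all other lengths are held fixed (using
#' directional partial likelihoods so each profile evaluation is cheap);
#' rounds repeat until the total log-likelihood improves by less than `tol`
#' or `max_rounds` is reached. The incumbent length is kept whenever the
#' proposed one does not improve the likelihood, so the total
#' log-likelihood never decreases.
#'
#' @inheritParams site_log_likelihoods
#' @param tol convergence tolerance on the total log-likelihood (default 1e-4).
#' @param max_rounds maximum optimization sweeps (default 20).
#' @param max_bl upper bound for a single branch (default 10).
#' @return list with `tree` (optimized lengths), `loglik`, and `rounds`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-4,
                                    max_rounds = 20L, bl_floor = 1e-8,
                                    max_bl = 10) {
  ld <- lik_data(tree, aln, model, bl_floor)
  tr <- ld$tree
  total <- sum(pattern_loglik(ld, model) * ld$weights)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    for (e in seq_len(nrow(tr$edge))) {
      ctx <- edge_context(ld, model, e, tr$edge.length)
      f <- function(t) edge_profile_loglik(ctx, ld, model, t)
      cur <- f(tr$edge.length[e])
      opt <- stats::optimize(f, c(bl_floor, max_bl), maximum = TRUE,
                             tol = 1e-6)
      if (opt$objective > cur) tr$edge.length[e] <- opt$maximum
    }
    ld$tree <- tr
    new_total <- sum(pattern_loglik(ld, model) * ld$weights)
    if (new_total - total < tol) {
      total <- max(total, new_total)
      break
    }
    total <- new_total
    if (rounds >= max_rounds) {
      warning("branch-length optimization did not converge in ",
              max_rounds, " rounds; returning best so far")
      break
    }
  }
  list(tree = tr, loglik = total, rounds = rounds)
}

#' Estimate gamma shape and invariant proportion by maximum likelihood
#'
#' Bounded univariate optimization of `alpha` (log scale, in
#' `[0.02, 100]`) and `p_inv` (in `[0, 0.99]`), alternated, optionally
#' interleaved with branch-length sweeps, until the joint improvement falls
#' below `tol`. Parameters not listed in `free` are held fixed; incumbent
#' values are kept on flat directions.
#'
#' @inheritParams optimize_branch_lengths
#' @param free character subset of `c("alpha", "p_inv")` to estimate.
#' @param optimize_branches also re-optimize branch lengths each iteration.
#' @return list with `model` (fitted), `tree`, `loglik`, and `iterations`.
#' @export
optimize_model <- function(tree, aln, model, free = c("alpha", "p_inv"),
                           optimize_branches = FALSE, tol = 1e-4,
                           max_rounds = 10L, bl_floor = 1e-8) {
  stopifnot(all(free %in% c("alpha", "p_inv")))
  tree <- ape::reorder.phylo(floor_lengths(as_unrooted(tree), bl_floor),
                             "postorder")
  total <- total_loglik(tree, aln, model, bl_floor)
  if (length(free) == 0L && !optimize_branches)
    return(list(model = model, tree = tree, loglik = total, iterations = 0L))
  it <- 0L
  repeat {
    it <- it + 1L
    if (optimize_branches) {
      ob <- optimize_branch_lengths(tree, aln, model, tol = tol,
                                    max_rounds = 3L, bl_floor = bl_floor)
      tree <- ob$tree
    }
    ld <- lik_data(tree, aln, model, bl_floor)
    if ("alpha" %in% free) {
      f <- function(la) {
        m2 <- update_model(model, alpha = exp(la))
        sum(cpp_mix_loglik(
          cpp_cat_loglik(ld$tree$edge, ld$tree$edge.length,
                         length(ld$tree$tip.label), ld$tree$Nnode, ld$codes,
                         m2$B, m2$Binv, m2$lam, m2$rates, m2$pi),
          invariant_contrib(ld$codes, m2), m2$wg) * ld$weights)
      }
      cur <- f(log(model$alpha))
      opt <- stats::optimize(f, log(c(0.02, 100)), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur)
        model <- update_model(model, alpha = exp(opt$maximum))
    }
    if ("p_inv" %in% free) {
      f <- function(p) {
        m2 <- update_model(model, p_inv = p)
        sum(cpp_mix_loglik(
          cpp_cat_loglik(ld$tree$edge, ld$tree$edge.length,
                         length(ld$tree$tip.label), ld$tree$Nnode, ld$codes,
                         m2$B, m2$Binv, m2$lam, m2$rates, m2$pi),
          invariant_contrib(ld$codes, m2), m2$wg) * ld$weights)
      }
      cur <- f(model$p_inv)
      opt <- stats::optimize(f, c(0, 0.99), maximum = TRUE, tol = 1e-5)
      if (opt$objective > cur)
        model <- update_model(model, p_inv = opt$maximum)
    }
    new_total <- total_loglik(tree, aln, model, bl_floor)
    done <- new_total - total < tol || it >= max_rounds
    total <- max(total, new_total)
    if (done) break
  }
  list(model = model, tree = tree, loglik = total, iterations = it)
}
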