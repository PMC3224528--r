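#' Pairwise maximum-likelihood distances
#'
#' For each taxon pair, the ML branch length of the two-taxon tree under the
#' (fixed) substitution model, found by bounded scalar search over the
#' shared non-missing columns. Pairs with no shared sites receive `cap`.
#'
#' @param aln an [aa_alignment] with at least 2 taxa.
#' @param model a [substitution_model()].
#' @param cap distance assigned when no columns are shared (default 5).
#' @param bl_floor minimum distance (default 1e-8).
#' @return symmetric distance matrix with zero diagonal.
#' @export
ml_distances <- function(aln, model, cap = 5, bl_floor = 1e-8) {
  taxa <- rownames(aln)
  nt <- length(taxa)
  if (nt < 2L) stop("need at least 2 taxa")
  codes <- encode_alignment(aln, taxa)
  D <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  K <- model$n_cat
  Pk <- function(t) lapply(seq_len(K), function(k)
    cpp_pmat(model$B, model$Binv, model$lam, t * model$rates[k]))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- codes[i, ] > 0L & codes[j, ] > 0L
    if (!any(ok)) { D[i, j] <- D[j, i] <- cap; next }
    cells <- (codes[i, ok] - 1L) * 20L + codes[j, ok]
    counts <- tabulate(cells, 400L)
    use <- counts > 0L
    f <- function(t) {
      M <- Reduce(`+`, Pk(t)) * model$wg * model$pi # sum_k wg pi_x P_xy
      if (model$p_inv > 0)
        diag(M) <- diag(M) + model$p_inv * model$pi
      sum(counts[use] * log(as.vector(t(M))[use]))
    }
    opt <- stats::optimize(f, c(bl_floor, cap), maximum = TRUE, tol = 1e-6)
    d <- if (f(bl_floor) >= opt$objective) bl_floor else opt$maximum
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Wraps [ape::nj()] with input validation; negative branch-length
#' estimates are floored at zero and the result is returned unrooted.
#'
#' @param dist symmetric distance matrix (zero diagonal, finite entries).
#' @return an [ape::phylo].
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 taxa for neighbor joining")
  if (any(!is.finite(dist))) stop("distances must be finite")
  if (max(abs(dist - t(dist))) > 1e-8 || any(abs(diag(dist)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  tr <- ape::nj(dist)
  tr$edge.length <- pmax(tr$edge.length, 0)
  validate_tree(as_unrooted(tr), require_binary = TRUE)
}

# the two NNI rearrangements around internal edge `eidx` (child must be an
# internal node); subtree swap leaves branch lengths attached to their edges
nni_neighbors_at <- function(tree, eidx) {
  edge <- tree$edge
  u <- edge[eidx, 1L]; v <- edge[eidx, 2L]
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(list())
  ab <- edge[edge[, 1L] == v, 2L]
  cc <- setdiff(edge[edge[, 1L] == u, 2L], v)[1L]
  lapply(ab[1:2], function(a) {
    t2 <- tree
    t2$edge[t2$edge[, 1L] == v & t2$edge[, 2L] == a, 1L] <- u
    t2$edge[t2$edge[, 1L] == u & t2$edge[, 2L] == cc, 1L] <- v
    ape::reorder.phylo(t2, "cladewise")
  })
}

all_nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > ntip)
  out <- list()
  for (e in internal) out <- c(out, nni_neighbors_at(tree, e))
  out
}

#' Hill-climbing tree search over nearest-neighbor interchanges
#'
#' From a binary start tree, all NNI rearrangements are scored at their
#' inherited branch lengths; the best strictly improving move is accepted
#' (ties broken by enumeration order: smallest edge, then neighbor, index),
#' branch lengths are re-optimized after each acceptance, and the search
#' stops when no move improves the log-likelihood by more than `tol`.
#'
#' @inheritParams optimize_branch_lengths
#' @param tree binary start tree (e.g. from [nj_tree()]).
#' @return list with `tree`, `loglik`, and `moves` (number of accepted NNIs).
#' @export
nni_search <- function(tree, aln, model, tol = 1e-4, bl_floor = 1e-8) {
  tree <- validate_tree(as_unrooted(tree), require_binary = TRUE)
  fit <- optimize_branch_lengths(tree, aln, model, tol = tol,
                                 bl_floor = bl_floor)
  tree <- fit$tree; lnl <- fit$loglik
  moves <- 0L
  repeat {
    nbrs <- all_nni_neighbors(tree)
    if (length(nbrs) == 0L) break
    scores <- vapply(nbrs, function(t2) total_loglik(t2, aln, model,
                                                     bl_floor), numeric(1))
    best <- which.max(scores)
    if (scores[best] <= lnl + tol) break
    fit <- optimize_branch_lengths(nbrs[[best]], aln, model, tol = tol,
                                   bl_floor = bl_floor)
    tree <- fit$tree; lnl <- fit$loglik
    moves <- moves + 1L
  }
  list(tree = tree, loglik = lnl, moves = moves)
}

#' Fit an ML tree (NJ start + NNI hill climbing)
#'
#' @inheritParams nni_search
#' @return list with `tree`, `loglik`, and `moves`.
#' @export
fit_ml_tree <- function(aln, model, tol = 1e-4, bl_floor = 1e-8) {
  nni_search(nj_tree(ml_distances(aln, model)), aln, model, tol = tol,
             bl_floor = bl_floor)
}

# descendant tip-label sets per internal node, and the canonical split key
# of each (reusing the convention of split_set())
node_split_keys <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  M <- ntip + tree$Nnode
  below <- vector("list", M)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  all_t <- tree$tip.label
  keys <- rep(NA_character_, M)
  for (v in (ntip + 1L):M) {
    a <- sort(below[[v]]); b <- sort(setdiff(all_t, a))
    if (length(a) <= 1L || length(b) <= 1L) next
    keys[v] <- paste(
      if (length(a) < length(b) || (length(a) == length(b) && a[1L] < b[1L]))
        a else b, collapse = "|")
  }
  keys
}

#' Nonparametric bootstrap support for an ML tree
#'
#' Resamples alignment columns with replacement; each replicate is analyzed
#' by `nj_tree(ml_distances())` followed by NNI hill climbing, and each
#' internal edge of the point-estimate tree receives the percentage of
#' replicate trees containing its bipartition. Replicate `r` uses the
#' derived seed `seed + r`, so replicates are order-independent.
#'
#' @inheritParams nni_search
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed master RNG seed.
#' @param tree optional point-estimate tree; fitted with [fit_ml_tree()]
#'   when omitted.
#' @param reestimate re-estimate `alpha` and `p_inv` on each replicate
#'   alignment (slower); when `FALSE` (default) the supplied model is used
#'   for every replicate.
#' @param search run the NNI search per replicate (default TRUE); `FALSE`
#'   scores replicates by NJ alone.
#' @return list with `tree` (node labels carry integer support percentages),
#'   `support` (named vector keyed by split), and `replicates`.
#' @export
bootstrap_support <- function(aln, model, replicates = 100L, seed = 1L,
                              tree = NULL, reestimate = FALSE,
                              search = TRUE, tol = 1e-4) {
  stopifnot(replicates >= 1L)
  if (is.null(tree)) tree <- fit_ml_tree(aln, model, tol = tol)$tree
  keys <- node_split_keys(tree)
  tally <- stats::setNames(numeric(sum(!is.na(keys))), keys[!is.na(keys)])
  for (r in seq_len(replicates)) {
    set.seed((seed + r) %% .Machine$integer.max)
    cols <- sample.int(ncol(aln), replace = TRUE)
    arep <- aa_alignment(unclass(aln)[, cols, drop = FALSE])
    mrep <- model
    if (reestimate)
      mrep <- optimize_model(nj_tree(ml_distances(arep, model)), arep,
                             model, max_rounds = 2L)$model
    trep <- nj_tree(ml_distances(arep, mrep))
    if (search) trep <- nni_search(trep, arep, mrep, tol = tol)$tree
    reps <- split_set(trep)
    hit <- names(tally) %in% reps
    tally[hit] <- tally[hit] + 1
  }
  support <- round(100 * tally / replicates)
  tree2 <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree2$tip.label)
  keys2 <- node_split_keys(tree2)
  lab <- ifelse(is.na(keys2), "", as.character(support[keys2]))
  tree2$node.label <- lab[(ntip + 1L):(ntip + tree2$Nnode)]
  list(tree = tree2, support = support, replicates = replicates)
}
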