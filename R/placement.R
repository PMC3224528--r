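#' Prune a monophyletic query clade from a tree
#'
#' Detaches the subtree spanned by `clade_taxa`, returning the backbone
#' (with the degree-2 attachment node suppressed and its two incident
#' branch lengths summed) and the clade subtree with its internal structure
#' and branch lengths intact.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param clade_taxa character vector of clade tip labels, monophyletic in
#'   `tree`, with `1 <= length(clade_taxa) <= n - 3`.
#' @return list with `backbone` ([ape::phylo]), `clade` (an [ape::phylo]
#'   for clades of 2+ taxa, or the single tip label), and `attach_edge`
#'   (index of the original attachment edge in the backbone's canonical
#'   cladewise edge order).
#' @export
prune_clade <- function(tree, clade_taxa) {
  tree <- validate_tree(as_unrooted(tree), require_binary = TRUE)
  n <- length(tree$tip.label)
  miss <- setdiff(clade_taxa, tree$tip.label)
  if (length(miss)) stop("clade taxa not in tree: ", paste(miss, collapse = ", "))
  k <- length(clade_taxa)
  if (k < 1L || k > n - 3L)
    stop("clade size must be between 1 and n-3 (= ", n - 3L, "), got ", k)
  if (!is_monophyletic_unrooted(tree, clade_taxa)) {
    stop("clade taxa are not monophyletic: no edge of the tree separates {",
         paste(sort(clade_taxa), collapse = ","), "} from the rest")
  }
  backbone <- ape::drop.tip(tree, clade_taxa)
  backbone <- validate_tree(as_unrooted(backbone), require_binary = TRUE)
  clade <- if (k == 1L) clade_taxa else {
    ro <- ape::root(tree, outgroup = setdiff(tree$tip.label, clade_taxa)[1L],
                    resolve.root = TRUE)
    ape::extract.clade(ro, ape::getMRCA(ro, clade_taxa))
  }
  ps <- enumerate_placements(backbone, clade)
  rf <- vapply(ps$trees, function(t2) robinson_foulds(t2, tree), integer(1))
  attach_edge <- which(rf == 0L)
  if (length(attach_edge) != 1L)
    stop("internal error: original attachment edge not uniquely recovered")
  list(backbone = backbone, clade = clade, attach_edge = attach_edge)
}

# a taxon set is monophyletic in an unrooted tree iff some edge splits it
# off exactly (or it is the complement of such a side)
is_monophyletic_unrooted <- function(tree, taxa) {
  n <- length(tree$tip.label)
  k <- length(taxa)
  if (k == 1L) return(TRUE)
  key <- paste(sort(taxa), collapse = "|")
  ckey <- paste(sort(setdiff(tree$tip.label, taxa)), collapse = "|")
  sides <- edge_child_sides(tree)
  any(vapply(sides, function(s) {
    sk <- paste(sort(s), collapse = "|")
    sk == key || sk == ckey
  }, logical(1)))
}

# tip-label set on the child side of every edge, in cladewise edge order
# (the package's canonical backbone-edge ordering)
edge_child_sides <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(tree$edge[, 2L], function(v) sort(below[[v]]))
}

edge_labels_of <- function(tree) {
  vapply(edge_child_sides(tree), paste, character(1), collapse = ",")
}

# attach `clade` (phylo or single tip label) onto backbone edge `eidx`
# (cladewise order): the edge is bisected (halving its length) and the clade
# joins the new node by a branch of length `graft_length`
graft_at_edge <- function(backbone, clade, eidx, graft_length = 0.1) {
  backbone <- ape::reorder.phylo(as_unrooted(backbone), "cladewise")
  v <- backbone$edge[eidx, 2L]
  len <- backbone$edge.length[eidx]
  t2 <- backbone
  if (is.character(clade)) {
    out <- phytools::bind.tip(t2, clade, edge.length = graft_length,
                              where = v, position = len / 2)
  } else {
    cl <- clade
    cl$root.edge <- graft_length
    out <- ape::bind.tree(t2, cl, where = v, position = len / 2)
  }
  validate_tree(as_unrooted(out), require_binary = TRUE)
}

#' Enumerate all re-graft placements of a clade on a backbone
#'
#' Generates one candidate topology per backbone edge: the edge is bisected
#' and the clade subtree (kept intact) is attached to the midpoint by a new
#' branch of length `graft_length`. With `m` backbone leaves this yields
#' `2m - 3` pairwise distinct topologies, ordered by the backbone's
#' canonical (cladewise) edge order.
#'
#' @param backbone an unrooted binary [ape::phylo].
#' @param clade an [ape::phylo] subtree, or a single tip label.
#' @param graft_length initial length of the new attachment branch.
#' @return an object of class `placement_set`: list with `backbone`,
#'   `clade`, `trees`, `edge_labels` (comma-joined child-side taxa of each
#'   backbone edge) and `graft_length`.
#' @export
enumerate_placements <- function(backbone, clade, graft_length = 0.1) {
  backbone <- validate_tree(as_unrooted(backbone), require_binary = TRUE)
  backbone <- ape::reorder.phylo(backbone, "cladewise")
  E <- nrow(backbone$edge)
  trees <- lapply(seq_len(E), function(e)
    graft_at_edge(backbone, clade, e, graft_length))
  structure(list(backbone = backbone, clade = clade, trees = trees,
                 edge_labels = edge_labels_of(backbone),
                 graft_length = graft_length),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("placement_set:", length(x$trees), "candidate topologies on",
      length(x$backbone$tip.label), "backbone leaves\n")
  invisible(x)
}

#' Prune a clade and enumerate all of its re-graft placements
#'
#' Convenience wrapper: [prune_clade()] then [enumerate_placements()]; the
#' returned set records which candidate reproduces the input topology.
#'
#' @inheritParams prune_clade
#' @inheritParams enumerate_placements
#' @return a `placement_set` with an extra element `original_index`.
#' @export
place_clade <- function(tree, clade_taxa, graft_length = 0.1) {
  pr <- prune_clade(tree, clade_taxa)
  ps <- enumerate_placements(pr$backbone, pr$clade, graft_length)
  ps$original_index <- pr$attach_edge
  ps
}

#' Evaluate every placement: likelihoods and ranking
#'
#' Computes, for each candidate topology in a [enumerate_placements()] set,
#' the total log-likelihood, the per-site log-likelihood vector, the
#' log-likelihood difference to the best placement, and the rank. With
#' `optimize = "graft_only"` the backbone branch lengths are kept fixed
#' (each bisected edge keeps its halves) and only the attachment branch is
#' optimized, using directional partial likelihoods so the whole scan costs
#' two tree traversals plus one cheap profile optimization per edge. With
#' `optimize = "all_branches"` every branch of every candidate is
#' re-optimized (slower; the conservative choice for final analyses).
#'
#' @param pset a `placement_set`.
#' @param aln an [aa_alignment] containing backbone and clade taxa.
#' @param model a [substitution_model()].
#' @param optimize `"graft_only"` or `"all_branches"`.
#' @param bl_floor,max_bl branch-length bounds.
#' @param tol optimization tolerance.
#' @return an object of class `placement_result`: list with `table` (one
#'   row per topology: `topology`, `edge_label`, `loglik`, `delta`,
#'   `graft_length`, `rank`), `site_loglik` (topologies x sites matrix in
#'   placement order), and the inputs.
#' @export
evaluate_placements <- function(pset, aln, model,
                                optimize = c("graft_only", "all_branches"),
                                bl_floor = 1e-8, max_bl = 10, tol = 1e-4) {
  optimize <- match.arg(optimize)
  stopifnot(inherits(pset, "placement_set"))
  E <- length(pset$trees)
  ns <- ncol(aln)
  M <- matrix(NA_real_, E, ns)
  lnl <- numeric(E)
  glen <- numeric(E)
  if (optimize == "graft_only") {
    res <- graft_scan(pset, aln, model, bl_floor, max_bl, tol)
    M <- res$site_loglik; lnl <- res$loglik; glen <- res$graft_length
  } else {
    for (e in seq_len(E)) {
      fit <- tryCatch(
        optimize_branch_lengths(pset$trees[[e]], aln, model, tol = tol,
                                bl_floor = bl_floor, max_bl = max_bl),
        error = function(err)
          stop("placement topology ", e, ": ", conditionMessage(err)))
      M[e, ] <- site_log_likelihoods(fit$tree, aln, model, bl_floor)
      lnl[e] <- fit$loglik
      glen[e] <- NA_real_
    }
  }
  rk <- rank(-lnl, ties.method = "first")
  tab <- data.frame(topology = seq_len(E),
                    edge_label = pset$edge_labels,
                    loglik = lnl,
                    delta = max(lnl) - lnl,
                    graft_length = glen,
                    rank = rk)
  structure(list(table = tab, site_loglik = M, pset = pset,
                 optimize = optimize, model = model),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("placement_result (", x$optimize, "): best placement on edge {",
      x$table$edge_label[which.min(x$table$rank)], "}\n", sep = "")
  print(utils::head(x$table[order(x$table$rank), ], 5L))
  invisible(x)
}

# fast graft-only scan via directional partials on the backbone
graft_scan <- function(pset, aln, model, bl_floor, max_bl, tol) {
  bb <- ape::reorder.phylo(floor_lengths(pset$backbone, bl_floor), "postorder")
  clade_taxa <- if (is.character(pset$clade)) pset$clade else
    pset$clade$tip.label
  need <- c(bb$tip.label, clade_taxa)
  miss <- setdiff(need, rownames(aln))
  if (length(miss)) stop("alignment lacks taxa: ", paste(miss, collapse = ", "))
  pat <- compress_patterns(encode_alignment(aln, need))
  npat <- ncol(pat$codes)
  K <- model$n_cat
  invc <- invariant_contrib(pat$codes, model)
  nb <- length(bb$tip.label)
  bcodes <- pat$codes[seq_len(nb), , drop = FALSE]
  ctx <- cpp_edge_contexts(bb$edge, bb$edge.length, nb, bb$Nnode, bcodes,
                           model$B, model$Binv, model$lam, model$rates,
                           model$pi, only_edge = 0L)
  # clade root partial per category
  ccodes <- pat$codes[nb + seq_along(clade_taxa), , drop = FALSE]
  if (is.character(pset$clade)) {
    Ccube <- array(0, c(20L, npat, K))
    ind <- matrix(0, 20L, npat)
    for (j in seq_len(npat)) {
      cd <- ccodes[1L, j]
      if (cd == 0L) ind[, j] <- 1 else ind[cd, j] <- 1
    }
    for (k in seq_len(K)) Ccube[, , k] <- ind
    cscal <- matrix(0, npat, K)
  } else {
    cl <- ape::reorder.phylo(floor_lengths(ape::multi2di(pset$clade),
                                           bl_floor), "postorder")
    ccodes2 <- pat$codes[nb + match(cl$tip.label, clade_taxa), , drop = FALSE]
    rp <- cpp_root_partial(cl$edge, cl$edge.length, length(cl$tip.label),
                           cl$Nnode, ccodes2, model$B, model$Binv,
                           model$lam, model$rates)
    Ccube <- rp$part; cscal <- rp$scal
  }
  # cladewise -> postorder edge correspondence (contexts are postorder)
  cw <- ape::reorder.phylo(bb, "cladewise")
  eo <- match(paste(cw$edge[, 1L], cw$edge[, 2L]),
              paste(bb$edge[, 1L], bb$edge[, 2L]))
  E <- nrow(bb$edge)
  out_lnl <- numeric(E); out_t <- numeric(E)
  out_site <- matrix(NA_real_, E, length(pat$index))
  for (i in seq_len(E)) {
    e <- eo[i]
    h <- bb$edge.length[e] / 2
    G <- array(0, c(20L, npat, K))
    gscal <- matrix(0, npat, K)
    for (k in seq_len(K)) {
      sl <- e + E * (k - 1L)
      Ph <- cpp_pmat(model$B, model$Binv, model$lam, h * model$rates[k])
      G[, , k] <- crossprod(Ph, ctx$V[, , sl]) * (Ph %*% ctx$D[, , sl])
      gscal[, k] <- ctx$vscal[, sl] + ctx$dscal[, sl]
    }
    r <- cpp_graft_opt(G, gscal, Ccube, cscal, model$B, model$Binv,
                       model$lam, model$rates, invc, model$wg, pat$weights,
                       bl_floor, max_bl, 0.005, 1L)
    out_lnl[i] <- r$loglik
    out_t[i] <- r$t
    out_site[i, ] <- r$site[pat$index]
  }
  list(loglik = out_lnl, graft_length = out_t, site_loglik = out_site)
}
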