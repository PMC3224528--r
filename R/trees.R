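#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the package's unrooted
#' convention: the returned tree is stored unrooted (trifurcating root) and
#' validated for unique leaf labels and finite, non-negative branch lengths.
#' Support values present as internal node labels are preserved.
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("Newick parse error (unbalanced parentheses?)")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(as_unrooted(tr))
}

#' Write a Newick tree
#'
#' Binary trees are emitted with a trifurcating root (unrooted convention);
#' support values, when present, are written as internal node labels.
#'
#' @param tree an [ape::phylo].
#' @param file optional path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- as_unrooted(tree)
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

as_unrooted <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) >= 3L)
    tree <- ape::unroot(tree)
  ape::reorder.phylo(tree, "cladewise")
}

validate_tree <- function(tree, require_binary = FALSE) {
  lab <- tree$tip.label
  if (anyDuplicated(lab))
    stop("duplicate leaf labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  el <- tree$edge.length
  if (!is.null(el) && (any(!is.finite(el)) || any(el < 0)))
    stop("branch lengths must be finite and >= 0")
  n <- length(lab)
  if (require_binary && n >= 3L) {
    if (nrow(tree$edge) != 2L * n - 3L || tree$Nnode != n - 2L)
      stop("tree is not an unrooted binary tree: expected ", 2L * n - 3L,
           " edges and ", n - 2L, " internal nodes, got ", nrow(tree$edge),
           " and ", tree$Nnode)
  }
  tree
}

# floor branch lengths before likelihood work (singular P matrices otherwise)
floor_lengths <- function(tree, floor = 1e-8) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  tree$edge.length <- pmax(tree$edge.length, floor)
  tree
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions between two
#' unrooted trees on the same leaf set; 0 iff the unrooted topologies agree.
#'
#' @param t1,t2 [ape::phylo] objects with identical leaf sets.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  d <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d) || length(d2))
    stop("leaf sets differ: only in first {",
         paste(d, collapse = ","), "}, only in second {",
         paste(d2, collapse = ","), "}")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

# Canonical non-trivial splits of an unrooted tree as a character set:
# each split is the sorted smaller-side label set (ties broken by the side
# containing the alphabetically first label), rendered "a|b|c".
split_set <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  out <- character(0)
  for (p in bp) {
    if (length(p) <= 1L || length(p) >= n - 1L) next
    a <- sort(labs[p]); b <- sort(labs[-p])
    key <- if (length(a) < length(b) || (length(a) == length(b) && a[1L] < b[1L]))
      a else b
    out <- c(out, paste(key, collapse = "|"))
  }
  unique(out)
}
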