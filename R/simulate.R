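#' Simulate a protein alignment on a tree
#'
#' Generates sequences under the model used for inference: each site is
#' invariant with probability `p_inv` (rate 0), otherwise it draws one of
#' the equal-weight discrete-gamma rate categories (scaled so the overall
#' mean rate is 1); the root state is drawn from the stationary
#' frequencies and propagated along each branch with the transition matrix
#' `P(length * rate)`. Deterministic given the seed.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [substitution_model()].
#' @param n_sites number of columns.
#' @param seed RNG seed.
#' @return an [aa_alignment] (rows in tree tip order).
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  stopifnot(n_sites >= 1L)
  set.seed(seed)
  tree <- ape::reorder.phylo(floor_lengths(as_unrooted(tree)), "postorder")
  ntip <- length(tree$tip.label)
  M <- ntip + tree$Nnode
  root <- ntip + 1L
  K <- model$n_cat
  inv <- stats::runif(n_sites) < model$p_inv
  cat <- sample.int(K, n_sites, replace = TRUE)
  states <- matrix(0L, M, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  # preorder propagation (reverse postorder)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    st <- states[par, ]
    out <- st # invariant sites copy the parent
    for (k in seq_len(K)) {
      P <- cpp_pmat(model$B, model$Binv, model$lam,
                    tree$edge.length[e] * model$rates[k])
      for (s in unique(st[!inv & cat == k])) {
        idx <- which(!inv & cat == k & st == s)
        out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                               prob = P[s, ])
      }
    }
    states[ch, ] <- out
  }
  m <- matrix(AA_STATES[states[seq_len(ntip), , drop = FALSE]], ntip,
              n_sites)
  rownames(m) <- tree$tip.label
  aa_alignment(m)
}

#' Overwrite an interval with gaps in selected taxa
#'
#' Plants a deletion-like block: columns `start .. start+length-1` are set
#' to `"-"` in exactly the listed taxa. `length = 0` is the identity;
#' planting the same block twice is idempotent.
#'
#' @param aln an [aa_alignment].
#' @param taxa taxa to gap.
#' @param start first column (1-based).
#' @param length number of columns.
#' @return the modified [aa_alignment].
#' @export
plant_indel <- function(aln, taxa, start, length) {
  if (length == 0L) return(aln)
  m <- unclass(aln)
  miss <- setdiff(taxa, rownames(m))
  if (length(miss)) stop("taxa not in alignment: ", paste(miss, collapse = ", "))
  if (start < 1L || start + length - 1L > ncol(m))
    stop("indel interval [", start, ", ", start + length - 1L,
         "] out of range 1..", ncol(m))
  m[taxa, start:(start + length - 1L)] <- "-"
  aa_alignment(m)
}

#' Simulation configuration for the HGT fixture
#'
#' Describes a study-shaped dataset: a backbone of named taxon groups, a
#' query clade truly attached inside a "donor" group (the transfer
#' signal), WAG+I+Gamma4 site rates, and planted group-specific deletion
#' blocks. Defaults copy the shape of a typical single-protein HGT matrix:
#' 56 taxa (14-taxon outgroup block), 327 columns, `alpha = 0.8`,
#' `p_inv = 0.1`.
#'
#' @param n_sites alignment length.
#' @param alpha gamma shape.
#' @param p_inv invariant proportion.
#' @param seed master seed (mandatory).
#' @param group_sizes named integer vector of backbone group sizes.
#' @param query_size number of query-clade taxa.
#' @param query_into group the query clade truly attaches inside.
#' @param indels data.frame of plants (`group`, `start`, `length`), where
#'   `group` may be `"query+<donor>"` for blocks shared with the donor.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 327L, alpha = 0.8, p_inv = 0.1, seed = 1L,
                       group_sizes = c(outgroup = 14L, donor = 10L,
                                       sister = 8L, green = 12L, red = 9L),
                       query_size = 3L, query_into = "donor",
                       indels = data.frame(
                         group = c("query+donor", "green"),
                         start = c(41L, 201L),
                         length = c(5L, 3L))) {
  stopifnot(n_sites >= 1L, query_size >= 1L, !is.null(seed))
  if (!query_into %in% names(group_sizes))
    stop("query_into must name a backbone group")
  if (nrow(indels) && any(indels$start < 1L |
                          indels$start + indels$length - 1L > n_sites))
    stop("indel plants must lie within [1, n_sites]")
  structure(list(n_sites = as.integer(n_sites), alpha = alpha,
                 p_inv = p_inv, seed = as.integer(seed),
                 group_sizes = group_sizes,
                 query_size = as.integer(query_size),
                 query_into = query_into, indels = indels),
            class = "sim_config")
}

# random rooted subtree with the given tip labels and modest branch lengths
random_subtree <- function(labels, bl_range = c(0.02, 0.25)) {
  n <- length(labels)
  if (n == 1L) return(labels)
  tr <- ape::rtree(n, rooted = TRUE, tip.label = labels, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), bl_range[1L], bl_range[2L])
  tr
}

# join two subtrees (phylo or single label) under a new root, each on a
# stem of the given length
join_pair <- function(a, b, stem_a = 0.15, stem_b = 0.15) {
  nwk <- function(x, stem) {
    if (is.character(x)) return(paste0(x, ":", stem))
    s <- ape::write.tree(x)
    paste0(substr(s, 1L, nchar(s) - 1L), ":", stem)
  }
  ape::read.tree(text = paste0("(", nwk(a, stem_a), ",", nwk(b, stem_b),
                               ");"))
}

#' Simulate a full HGT-placement dataset
#'
#' Builds the true tree (named backbone groups joined by well-separated
#' internal branches; the query clade grafted onto an internal edge of the
#' donor group), simulates the alignment under WAG+I+Gamma4, plants the
#' configured group-specific deletion blocks, and returns a truth record
#' for downstream assertions.
#'
#' @param cfg a [sim_config()].
#' @return list with `alignment`, `tree` (the true tree), `model`,
#'   `groups` (named list of taxa incl. `query`), and `truth` (list:
#'   `clade_taxa`, `true_edge_label` — the backbone attachment edge as a
#'   comma-joined child-side taxon set, `attach_edge` index, `indels`
#'   data.frame, `seed`).
#' @export
simulate_hgt_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gs <- cfg$group_sizes
  groups <- lapply(names(gs), function(g)
    sprintf("%s%02d", g, seq_len(gs[[g]])))
  names(groups) <- names(gs)
  query <- sprintf("query%02d", seq_len(cfg$query_size))

  sub <- lapply(groups, random_subtree)
  # ingroup: ((donor, sister), green) vs (red) -- deep splits well separated
  ing <- join_pair(join_pair(sub$donor, sub$sister, 0.3, 0.3),
                   sub$green, 0.25, 0.3)
  ing <- join_pair(ing, sub$red, 0.2, 0.35)
  full <- join_pair(ing, sub$outgroup, 0.3, 0.5)
  full <- as_unrooted(full)

  # graft the query clade onto an internal edge inside the donor group
  qsub <- if (cfg$query_size == 1L) query else {
    qt <- random_subtree(query)
    qt$edge.length <- qt$edge.length * 0.6
    qt
  }
  donor_tips <- groups[[cfg$query_into]]
  sides <- edge_child_sides(full)
  cand <- which(vapply(sides, function(s)
    length(s) >= 2L && all(s %in% donor_tips), logical(1)))
  if (!length(cand))
    cand <- which(vapply(sides, function(s)
      length(s) == 1L && all(s %in% donor_tips), logical(1)))
  eidx <- cand[1L + (cfg$seed %% length(cand))]
  true_tree <- graft_at_edge(full, qsub, eidx, graft_length = 0.12)

  model <- substitution_model(alpha = cfg$alpha, p_inv = cfg$p_inv)
  aln <- simulate_alignment(true_tree, model, cfg$n_sites,
                            seed = cfg$seed + 1L)

  planted <- cfg$indels
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      gnames <- strsplit(planted$group[i], "+", fixed = TRUE)[[1L]]
      taxa <- unlist(lapply(gnames, function(g)
        if (g == "query") query else groups[[g]]))
      aln <- plant_indel(aln, taxa, planted$start[i], planted$length[i])
    }
  }
  true_edge_label <- paste(sides[[eidx]], collapse = ",")
  list(alignment = aln, tree = true_tree, model = model,
       groups = c(groups, list(query = query)),
       truth = list(clade_taxa = query,
                    true_edge_label = true_edge_label,
                    attach_edge = eidx,
                    indels = planted,
                    seed = cfg$seed))
}

#' Write/read a truth record
#'
#' Serializes the truth record of [simulate_hgt_dataset()] as YAML so that
#' simulated datasets can round-trip through files.
#'
#' @param truth truth record list.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  truth$indels <- as.list(truth$indels)
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- yaml::read_yaml(path)
  tr$indels <- as.data.frame(tr$indels, stringsAsFactors = FALSE)
  tr$clade_taxa <- as.character(tr$clade_taxa)
  tr
}
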