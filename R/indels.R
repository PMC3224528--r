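#' Per-taxon maximal gap runs
#'
#' Every maximal run of consecutive gap (`"-"`) columns in each row,
#' reported as 1-based closed intervals.
#'
#' @param aln an [aa_alignment].
#' @return data.frame with columns `taxon`, `start`, `end`, `length`.
#' @export
find_gap_blocks <- function(aln) {
  m <- unclass(aln)
  out <- lapply(rownames(m), function(tx) {
    r <- rle(m[tx, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values)
    if (!length(i)) return(NULL)
    data.frame(taxon = tx, start = starts[i], end = ends[i],
               length = r$lengths[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(taxon = character(), start = integer(),
                      end = integer(), length = integer())
  rownames(out) <- NULL
  out
}

#' Taxon-group-specific gap blocks
#'
#' Clusters per-taxon gap runs whose interval boundaries agree within
#' `boundary_slack` columns at both ends, and reports every cluster (of
#' core length at least `min_len`) for which at least one named taxon group
#' is fully "present" (every member carries the gap) and at least one is
#' fully "absent" (no member does). Such shared indel blocks are the
#' alignment-level synapomorphies used to corroborate clade affiliations
#' independently of the tree. Each signal is labelled "deletion-like" when
#' the gapped taxa are a minority of the alignment and "insertion-like"
#' otherwise, and carries reference-protein coordinates when `ref_taxon`
#' is given (see [map_to_reference()]).
#'
#' @param aln an [aa_alignment].
#' @param groups named list of disjoint taxon character vectors.
#' @param min_len minimum block length in columns (default 2).
#' @param boundary_slack maximum boundary disagreement in columns
#'   (default 1).
#' @param ref_taxon optional reference taxon for coordinate reporting.
#' @return data.frame with one row per signal: `start`, `end` (core
#'   interval shared by all clustered runs, 1-based closed), `ref_start`,
#'   `ref_end`, `taxa`, `present_groups`, `absent_groups`, `purity`
#'   (comma-separated per-group conforming fractions), `kind`.
#' @export
group_specific_blocks <- function(aln, groups, min_len = 2L,
                                  boundary_slack = 1L, ref_taxon = NULL) {
  stopifnot(min_len >= 1L)
  all_g <- unlist(groups)
  if (anyDuplicated(all_g))
    stop("groups overlap: ", paste(unique(all_g[duplicated(all_g)]),
                                   collapse = ", "))
  miss <- setdiff(all_g, rownames(aln))
  if (length(miss)) stop("group taxa not in alignment: ",
                         paste(miss, collapse = ", "))
  runs <- find_gap_blocks(aln)
  runs <- runs[order(runs$start, runs$end, runs$taxon), , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_signals())
  # single-linkage clustering on boundary agreement
  cl <- integer(nrow(runs))
  refs <- list() # per cluster: first member's (start, end)
  for (i in seq_len(nrow(runs))) {
    hit <- 0L
    for (ci in seq_along(refs)) {
      if (abs(runs$start[i] - refs[[ci]][1L]) <= boundary_slack &&
          abs(runs$end[i] - refs[[ci]][2L]) <= boundary_slack) {
        hit <- ci; break
      }
    }
    if (hit == 0L) {
      refs[[length(refs) + 1L]] <- c(runs$start[i], runs$end[i])
      hit <- length(refs)
    }
    cl[i] <- hit
  }
  refmap <- if (is.null(ref_taxon)) NULL else map_to_reference(aln, ref_taxon)
  sig <- list()
  for (ci in seq_along(refs)) {
    mem <- runs[cl == ci, , drop = FALSE]
    core_start <- max(mem$start); core_end <- min(mem$end)
    if (core_end - core_start + 1L < min_len) next
    taxa <- unique(mem$taxon)
    pur <- vapply(groups, function(g) mean(g %in% taxa), numeric(1))
    present <- names(groups)[pur == 1]
    absent <- names(groups)[pur == 0]
    if (length(present) == 0L || length(absent) == 0L) next
    rs <- re <- NA_integer_
    if (!is.null(refmap)) {
      inref <- refmap[core_start:core_end]
      # a gap block sits between reference residues; report the nearest
      # flanking residue positions
      prev <- refmap[seq_len(core_start - 1L)]
      rs <- if (all(is.na(inref))) {
        if (any(!is.na(prev))) max(prev, na.rm = TRUE) else 0L
      } else min(inref, na.rm = TRUE)
      re <- if (all(is.na(inref))) rs + 1L else max(inref, na.rm = TRUE)
    }
    sig[[length(sig) + 1L]] <- data.frame(
      start = core_start, end = core_end,
      ref_start = rs, ref_end = re,
      taxa = paste(sort(taxa), collapse = ","),
      present_groups = paste(present, collapse = ","),
      absent_groups = paste(absent, collapse = ","),
      purity = paste(sprintf("%s=%.2f", names(groups), pur), collapse = ","),
      kind = if (length(taxa) <= nrow(aln) / 2) "deletion-like"
             else "insertion-like")
  }
  if (!length(sig)) return(empty_signals())
  out <- do.call(rbind, sig)
  rownames(out) <- NULL
  out
}

empty_signals <- function() {
  data.frame(start = integer(), end = integer(), ref_start = integer(),
             ref_end = integer(), taxa = character(),
             present_groups = character(), absent_groups = character(),
             purity = character(), kind = character())
}
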