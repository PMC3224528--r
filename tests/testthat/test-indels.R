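test_that("per-taxon maximal gap runs match a direct scan", {
  aln <- aa_alignment(rbind(a = c("M", "K", "-", "-", "A", "V"),
                            b = c("M", "K", "A", "A", "A", "V")))
  runs <- find_gap_blocks(aln)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start, 3L)
  expect_equal(runs$end, 4L)

  expect_equal(nrow(find_gap_blocks(aa_alignment(rbind(x = rep("A", 5))))), 0L)

  aln2 <- rand_alignment(8, 60, seed = 14, gap_frac = 0.3)
  runs2 <- find_gap_blocks(aln2)
  # oracle: naive per-cell scan
  for (tx in rownames(aln2)) {
    gaps <- which(unclass(aln2)[tx, ] == "-")
    mine <- runs2[runs2$taxon == tx, ]
    covered <- unlist(lapply(seq_len(nrow(mine)), function(i)
      mine$start[i]:mine$end[i]))
    expect_equal(sort(covered), gaps)
    if (nrow(mine) > 1L) # maximality: runs are separated
      expect_true(all(mine$start[-1L] > mine$end[-nrow(mine)] + 1L))
  }
})

test_that("group-specific blocks: shared deletion between two groups", {
  set.seed(15)
  m <- matrix(sample(AA20, 8 * 30, replace = TRUE), 8, 30)
  rownames(m) <- c("E1", "E2", "S1", "S2", "G1", "G2", "G3", "G4")
  m[c("E1", "E2", "S1", "S2"), 11:14] <- "-"
  aln <- aa_alignment(m)
  groups <- list(euglenophytes = c("E1", "E2"),
                 stramenopiles = c("S1", "S2"),
                 greens = c("G1", "G2", "G3", "G4"))
  sig <- group_specific_blocks(aln, groups, min_len = 2, boundary_slack = 0)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$start, 11L)
  expect_equal(sig$end, 14L)
  expect_equal(sig$present_groups, "euglenophytes,stramenopiles")
  expect_equal(sig$absent_groups, "greens")
  expect_equal(sig$kind, "deletion-like")

  # min_len larger than every run -> empty
  expect_equal(nrow(group_specific_blocks(aln, groups, min_len = 10)), 0L)

  # taxon-order invariance
  sig2 <- group_specific_blocks(aa_alignment(m[sample(8), ]), groups,
                                min_len = 2, boundary_slack = 0)
  expect_equal(sig2, sig)

  expect_error(group_specific_blocks(aln, list(a = "E1", b = "E1")),
               "overlap")
})

test_that("reference coordinates and insertion-like labelling", {
  m <- matrix("A", 5, 20)
  rownames(m) <- c("ref", "x1", "x2", "y1", "y2")
  m[c("ref", "x1", "x2", "y1"), 6:9] <- "-" # majority gapped: insertion-like
  aln <- aa_alignment(m)
  sig <- group_specific_blocks(aln, list(X = c("x1", "x2"),
                                         Y = c("y2")),
                               min_len = 2, boundary_slack = 0,
                               ref_taxon = "ref")
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$kind, "insertion-like")
  # reference is gapped across the block: flanking residue positions 5..6
  expect_equal(sig$ref_start, 5L)
  expect_equal(sig$ref_end, 6L)
})

test_that("planted blocks are recovered exactly (plant -> scan round trip)", {
  m <- substitution_model(alpha = 1)
  tr <- rand_unrooted_tree(8, seed = 16)
  aln <- simulate_alignment(tr, m, 120, seed = 17)
  taxa <- tr$tip.label
  g <- list(g1 = taxa[1:3], g2 = taxa[4:6], g3 = taxa[7:8])
  aln <- plant_indel(aln, g$g1, 31, 6)
  aln <- plant_indel(aln, g$g3, 80, 4)
  sig <- group_specific_blocks(aln, g, min_len = 2, boundary_slack = 0)
  sig <- sig[order(sig$start), ]
  expect_equal(sig$start, c(31L, 80L))
  expect_equal(sig$end, c(36L, 83L))
  expect_equal(sig$present_groups, c("g1", "g3"))
})
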