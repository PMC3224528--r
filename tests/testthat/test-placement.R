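test_that("prune_clade: shapes, bookkeeping, and errors", {
  q <- quartet_tree(1, 1, 1, 1, 1)
  pr <- prune_clade(q, "A")
  expect_equal(length(pr$backbone$tip.label), 3L)
  expect_equal(nrow(pr$backbone$edge), 3L)

  tr <- rand_unrooted_tree(10, seed = 3)
  sides <- regraft:::edge_child_sides(tr)
  clade2 <- sides[[which(vapply(sides, length, 1L) == 2L)[1L]]]
  pr2 <- prune_clade(tr, clade2)
  expect_equal(length(pr2$backbone$tip.label), 8L)
  expect_equal(nrow(pr2$backbone$edge), 13L) # 2m-3

  # suppressed-node bookkeeping: backbone path lengths unchanged
  D0 <- ape::cophenetic.phylo(tr)
  Db <- ape::cophenetic.phylo(pr2$backbone)
  keep <- rownames(Db)
  expect_equal(Db, D0[keep, keep], tolerance = 1e-10)

  # non-monophyletic set is refused
  nonmono <- c(clade2[1], setdiff(tr$tip.label, clade2)[1])
  sides_all <- vapply(sides, function(s) paste(sort(s), collapse = "|"), "")
  if (!paste(sort(nonmono), collapse = "|") %in% sides_all)
    expect_error(prune_clade(tr, nonmono), "not monophyletic")
  expect_error(prune_clade(tr, tr$tip.label[1:8]), "clade size")
})

test_that("enumeration yields 2m-3 pairwise distinct topologies incl. original", {
  q <- quartet_tree(1, 1, 1, 1, 1)
  ps1 <- place_clade(q, "A")
  expect_equal(length(ps1$trees), 3L) # the three quartet topologies
  rf <- vapply(ps1$trees, function(t2) robinson_foulds(t2, q), integer(1))
  expect_equal(sum(rf == 0L), 1L)
  expect_equal(which(rf == 0L), ps1$original_index)

  tr <- rand_unrooted_tree(10, seed = 17)
  sides <- regraft:::edge_child_sides(tr)
  clade3 <- sides[[which(vapply(sides, length, 1L) == 3L)[1L]]]
  ps <- place_clade(tr, clade3)
  expect_equal(length(ps$trees), 2L * 7L - 3L) # m = 7 backbone leaves
  keys <- vapply(ps$trees, function(t2)
    paste(oracle_splits(t2), collapse = ";"), "")
  expect_equal(anyDuplicated(keys), 0L)
  # every candidate keeps the clade monophyletic and restricts to the backbone
  for (t2 in ps$trees) {
    expect_identical(
      robinson_foulds(ape::drop.tip(t2, clade3), ps$backbone), 0L)
  }
})

test_that("graft-only evaluation equals full-tree pruning at matched lengths", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  tr <- rand_unrooted_tree(9, seed = 5, bl = c(0.05, 0.4))
  aln <- simulate_alignment(tr, m, 150, seed = 6)
  sides <- regraft:::edge_child_sides(tr)
  ct <- sides[[which(vapply(sides, length, 1L) == 2L)[1L]]]
  ps <- place_clade(tr, ct)
  ev <- evaluate_placements(ps, aln, m, optimize = "graft_only")
  expect_equal(dim(ev$site_loglik), c(length(ps$trees), ncol(aln)))
  expect_equal(min(ev$table$delta), 0)
  for (i in c(1L, length(ps$trees))) {
    t2 <- ps$trees[[i]]
    s2 <- regraft:::edge_child_sides(t2)
    ge <- which(vapply(s2, function(s) setequal(s, ct), logical(1)))
    t2$edge.length[ge] <- ev$table$graft_length[i]
    expect_equal(ev$site_loglik[i, ], site_log_likelihoods(t2, aln, m),
                 tolerance = 1e-10)
  }
})

test_that("all-branches optimization only improves on graft-only", {
  m <- substitution_model(alpha = 1)
  tr <- rand_unrooted_tree(6, seed = 8, bl = c(0.1, 0.4))
  aln <- simulate_alignment(tr, m, 120, seed = 9)
  ps <- place_clade(tr, tr$tip.label[1])
  evg <- evaluate_placements(ps, aln, m, optimize = "graft_only")
  eva <- evaluate_placements(ps, aln, m, optimize = "all_branches")
  expect_true(all(eva$table$loglik >= evg$table$loglik - 1e-6))
  expect_equal(min(eva$table$delta), 0)
})

test_that("the true attachment edge is recovered on simulated transfers", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  tr <- rand_unrooted_tree(12, seed = 23, bl = c(0.08, 0.45))
  aln <- simulate_alignment(tr, m, 2000, seed = 24)
  sides <- regraft:::edge_child_sides(tr)
  ct <- sides[[which(vapply(sides, length, 1L) == 2L)[1L]]]
  ps <- place_clade(tr, ct)
  ev <- evaluate_placements(ps, aln, m, optimize = "graft_only")
  expect_equal(which(ev$table$rank == 1L), ps$original_index)
})
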