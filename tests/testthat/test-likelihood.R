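test_that("pruning equals brute-force state summation on random quartets", {
  set.seed(10)
  worst <- 0
  for (case in 1:30) {
    lens <- runif(5, 0.01, 1.5)
    tr <- quartet_tree(lens[1], lens[2], lens[3], lens[4], lens[5])
    m <- substitution_model(alpha = runif(1, 0.3, 2),
                            p_inv = sample(c(0, runif(1, 0, 0.4)), 1))
    aln <- rand_alignment(4, 8, seed = case, gap_frac = 0.15,
                          amb_frac = 0.05, taxa = c("A", "B", "C", "D"))
    ll <- site_log_likelihoods(tr, aln, m)
    oracle <- quartet_bruteforce(lens, aln, m)
    worst <- max(worst, max(abs(ll - oracle) / abs(oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("two-taxon limit cases behave as the model dictates", {
  m <- substitution_model(alpha = 1, p_inv = 0)
  t2 <- ape::read.tree(text = "(A:0,B:0);")
  same <- aa_alignment(rbind(A = "W", B = "W"))
  # identical residues at t -> 0: lnL -> log(pi_a)
  expect_equal(site_log_likelihoods(t2, same, m), unname(log(m$pi["W"])),
               tolerance = 1e-5)
  diff <- aa_alignment(rbind(A = "W", B = "C"))
  expect_lt(site_log_likelihoods(t2, diff, m), log(1e-6))
})

test_that("total log-likelihood is invariant to the rooting representation", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  tr <- rand_unrooted_tree(12, seed = 6)
  aln <- simulate_alignment(tr, m, 100, seed = 7)
  base <- sum(site_log_likelihoods(tr, aln, m))
  ntip <- length(tr$tip.label)
  for (nd in (ntip + 2):(ntip + tr$Nnode)) {
    alt <- ape::unroot(ape::root(tr, node = nd, resolve.root = TRUE))
    expect_equal(sum(site_log_likelihoods(alt, aln, m)), base,
                 tolerance = 1e-8)
  }
})

test_that("gaps and X are missing data: all-gap taxa do not change lnL", {
  m <- substitution_model(alpha = 1)
  tr <- quartet_tree(0.2, 0.3, 0.15, 0.25, 0.1)
  aln <- rand_alignment(4, 30, seed = 8, taxa = c("A", "B", "C", "D"))
  m4 <- unclass(aln)
  m4["D", ] <- "-"
  llfull <- site_log_likelihoods(tr, aa_alignment(m4), m)
  # the 3-taxon tree obtained by dropping D must give the same likelihoods
  tr3 <- ape::drop.tip(tr, "D")
  ll3 <- site_log_likelihoods(tr3, aa_alignment(m4[c("A", "B", "C"), ]), m)
  expect_equal(llfull, ll3, tolerance = 1e-10)
})

test_that("branch-length optimization recovers truth and never decreases lnL", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  t2 <- ape::read.tree(text = "(A:0.1,B:0.1);")
  truth <- 0.3
  sim <- simulate_alignment(ape::read.tree(text = "(A:0.15,B:0.15);"),
                            m, 10000, seed = 21)
  before <- total_loglik(t2, sim, m)
  fit <- optimize_branch_lengths(t2, sim, m)
  expect_gte(fit$loglik, before)
  expect_equal(sum(fit$tree$edge.length), truth, tolerance = 0.03)

  # optimizing twice is a no-op
  fit2 <- optimize_branch_lengths(fit$tree, sim, m)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-3)
  expect_equal(fit2$rounds, 1L)
})

test_that("model optimization honours `free` and the ML property", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  tr <- rand_unrooted_tree(10, seed = 9)
  aln <- simulate_alignment(tr, m, 400, seed = 10)

  fixed <- optimize_model(tr, aln, m, free = character(0))
  expect_identical(fixed$model$alpha, m$alpha)
  expect_identical(fixed$model$p_inv, m$p_inv)

  fit <- optimize_model(tr, aln, m, free = c("alpha", "p_inv"))
  expect_gte(fit$loglik, total_loglik(tr, aln, m) - 1e-8)
})

test_that("taxon mismatches are rejected", {
  m <- substitution_model()
  tr <- quartet_tree(1, 1, 1, 1, 1)
  aln <- rand_alignment(4, 10, seed = 1, taxa = c("A", "B", "C", "E"))
  expect_error(site_log_likelihoods(tr, aln, m), "differ")
})
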