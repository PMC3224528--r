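test_that("RELL bootstrap proportions: dominance, ties, determinism", {
  M <- rbind(c(-1, -1, -1), c(-2, -2, -2), c(-3, -3, -3))
  bp <- rell_bootstrap(M, scales = c(0.5, 1, 1.4), B = 200, seed = 1)
  expect_equal(unname(bp[1, ]), rep(1, 3))
  expect_equal(unname(bp[2, ]), rep(0, 3))

  # argmax ties resolved by lowest row index
  M2 <- rbind(c(-1, -2), c(-1, -2))
  bp2 <- rell_bootstrap(M2, scales = 1, B = 200, seed = 1)
  expect_equal(unname(bp2[, 1]), c(1, 0))

  set.seed(99)
  M3 <- matrix(rnorm(5 * 40, -2), 5, 40)
  b1 <- rell_bootstrap(M3, B = 500, seed = 7)
  b2 <- rell_bootstrap(M3, B = 500, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(abs(colSums(b1) - 1) < 1e-12)) # BP sums to 1 per scale

  expect_error(rell_bootstrap(M[1, , drop = FALSE]), "at least 2")
  expect_error(rell_bootstrap(M, scales = c(-1, 1)), "positive")
})

test_that("exhaustive RELL equals direct enumeration of all resamples", {
  set.seed(3)
  M <- matrix(rnorm(18, -3), 3, 6)
  bp <- rell_bootstrap(M, scales = 1, B = 100, seed = 1, exhaustive = TRUE)
  # oracle: all 6^6 ordered resamples enumerated one by one
  idx <- as.matrix(expand.grid(rep(list(1:6), 6)))
  wins <- integer(3)
  for (r in seq_len(nrow(idx))) {
    s <- rowSums(M[, idx[r, ]])
    wins[which.max(s)] <- wins[which.max(s)] + 1L
  }
  expect_equal(unname(bp[, 1]), wins / 6^6, tolerance = 1e-12)
})

test_that("AU p-values round-trip a known (d, c) curve", {
  scales <- seq(0.5, 1.4, by = 0.1)
  d <- 1.0; cc <- 0.2
  bp <- matrix(1 - pnorm(d * sqrt(scales) + cc / sqrt(scales)), 1)
  res <- au_pvalues(bp, scales, B = 10000)
  expect_equal(res$au, 1 - pnorm(d - cc), tolerance = 1e-3)
  expect_equal(res$d, d, tolerance = 1e-3)
  expect_equal(res$c, cc, tolerance = 1e-3)

  # symmetric case d = c gives exactly 1/2
  bp2 <- matrix(1 - pnorm(0.7 * sqrt(scales) + 0.7 / sqrt(scales)), 1)
  expect_equal(au_pvalues(bp2, scales, B = 10000)$au, 0.5, tolerance = 1e-6)

  # fully degenerate curves hit the boundary
  bp3 <- rbind(rep(0, 10), rep(1, 10))
  res3 <- au_pvalues(bp3, scales, B = 1000)
  expect_equal(res3$au, c(0, 1))
  expect_true(all(res3$untestable))
})

test_that("KH test: null, extreme, and normal-theory behaviour", {
  set.seed(11)
  base <- rnorm(400, -2)
  noise <- rnorm(400, 0, 0.3)
  # rows differ site-wise but the total difference is exactly zero
  M <- rbind(base, base - (noise - mean(noise)))
  expect_equal(kh_test(M, 1, 2, B = 5000, seed = 2), 0.5, tolerance = 0.05)

  M2 <- rbind(rnorm(300, -2), rnorm(300, -4)) # huge delta
  expect_lt(kh_test(M2, 1, 2, B = 2000, seed = 3), 0.001)
  expect_error(kh_test(M2, 1, 1), "differ")

  # gaussian site differences: agree with z = delta / (s sqrt(n))
  for (s in 1:3) {
    set.seed(s)
    n <- 500
    dif <- rnorm(n, 0.02, 0.8)
    M3 <- rbind(dif, 0)
    p <- kh_test(M3, 1, 2, B = 20000, seed = s + 10)
    z <- sum(dif) / (sd(dif) * sqrt(n))
    expect_lt(abs(p - (1 - pnorm(z))), 0.02)
  }
})

test_that("SH test: best topology maximal, null case, conservativeness", {
  set.seed(21)
  M <- matrix(rnorm(4 * 200, -2), 4, 200)
  p <- sh_test(M, B = 5000, seed = 5)
  best <- which.max(rowSums(M))
  expect_equal(max(p), p[best])
  expect_gte(p[best], 0.99)

  Mnull <- matrix(rep(rnorm(100, -2), each = 3), 3)
  expect_true(all(sh_test(Mnull, B = 1000, seed = 6) == 1))

  # SH >= KH for non-best topologies (same replicate set via same seed)
  for (s in 1:5) {
    set.seed(s + 30)
    M4 <- matrix(rnorm(3 * 150, -2, 0.5), 3, 150)
    psh <- sh_test(M4, B = 10000, seed = 77)
    best4 <- which.max(rowSums(M4))
    for (k in seq_len(3)[-best4])
      expect_gte(psh[k], kh_test(M4, best4, k, B = 10000, seed = 77) - 1e-12)
  }
})

test_that("raising a topology's likelihoods never lowers its AU p", {
  for (s in 1:6) {
    set.seed(s + 50)
    M <- matrix(rnorm(4 * 120, -2, 0.6), 4, 120)
    k <- sample(4, 1)
    bp1 <- rell_bootstrap(M, B = 2000, seed = 13)
    M2 <- M; M2[k, ] <- M2[k, ] + 0.05
    bp2 <- rell_bootstrap(M2, B = 2000, seed = 13)
    au1 <- au_pvalues(bp1)$au[k]
    au2 <- au_pvalues(bp2)$au[k]
    expect_gte(au2, au1 - 1e-9)
  }
})

test_that("report assembly and site-matrix serialization round-trip", {
  set.seed(61)
  M <- matrix(rnorm(5 * 80, -2), 5, 80)
  rep1 <- topology_tests(M, B = 1000, seed = 9)
  expect_s3_class(rep1, "topology_test_report")
  expect_true(all(rep1$au >= 0 & rep1$au <= 1))
  expect_true(all(rep1$kh >= 0 & rep1$kh <= 1))
  expect_true(all(rep1$sh >= 0 & rep1$sh <= 1))
  expect_equal(rep1$delta[which.max(rep1$loglik)], 0)
  expect_identical(rep1$rejected_05, rep1$au < 0.05)
  rep2 <- topology_tests(M, B = 1000, seed = 9)
  expect_identical(rep1, rep2) # seeded determinism

  p <- withr::local_tempfile()
  write_site_loglik(M, p, "mt")
  expect_equal(read_site_loglik(p), M, tolerance = 1e-9)
})
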