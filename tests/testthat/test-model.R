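test_that("generator construction satisfies the reversible-CTMC algebra", {
  m <- substitution_model(alpha = 0.8, p_inv = 0.1)
  Q <- m$Q
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_lt(abs(-sum(m$pi * diag(Q)) - 1), 1e-12)
  DB <- m$pi * Q # detailed balance: pi_i Q_ij symmetric
  expect_lt(max(abs(DB - t(DB))), 1e-12)

  expect_error(build_rate_matrix(matrix(runif(400), 20), WAG_FREQS),
               "symmetric")
  expect_error(build_rate_matrix(wag_exchangeability_matrix(), rep(1, 20)),
               "sum to 1")
})

test_that("transition matrices behave like a stochastic semigroup", {
  m <- substitution_model(alpha = 1)
  expect_lt(max(abs(transition_matrix(m, 0) - diag(20))), 1e-12)
  set.seed(4)
  for (i in 1:5) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    P1 <- transition_matrix(m, t1)
    expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
    expect_lt(max(abs(m$pi %*% P1 - m$pi)), 1e-10) # stationarity
    expect_lt(max(abs(P1 %*% transition_matrix(m, t2) -
                      transition_matrix(m, t1 + t2))), 1e-10)
  }
  expect_error(transition_matrix(m, -0.1), ">= 0")
})

test_that("equal-exchangeability model matches the F81-style closed form", {
  S1 <- matrix(1, 20, 20); diag(S1) <- 0
  m <- substitution_model(S = S1, alpha = 1, n_cat = 1)
  beta <- 1 / (1 - sum(m$pi^2))
  for (t in c(0.05, 0.4, 1.7)) {
    Pex <- outer(rep(1, 20), m$pi) +
      (diag(20) - outer(rep(1, 20), m$pi)) * exp(-beta * t)
    expect_lt(max(abs(transition_matrix(m, t) - Pex)), 1e-12)
  }
})

test_that("discrete gamma uses conditional category means", {
  expect_equal(discretize_gamma(0.7, 1)$rates, 1)
  expect_lt(max(abs(discretize_gamma(1e6, 4)$rates - 1)), 1e-2)
  expect_error(discretize_gamma(-1, 4), "> 0")

  g <- discretize_gamma(0.5, 4)
  expect_true(all(diff(g$rates) > 0))
  expect_equal(mean(g$rates), 1, tolerance = 1e-12)
  # quadrature oracle: conditional means by numerical integration
  qs <- qgamma(c(0, 0.25, 0.5, 0.75, 1), shape = 0.5, rate = 0.5)
  for (k in 1:4) {
    mk <- integrate(function(x) x * dgamma(x, 0.5, rate = 0.5),
                    qs[k], qs[k + 1], rel.tol = 1e-10)$value * 4
    expect_equal(g$rates[k], mk, tolerance = 1e-6)
  }
})

test_that("rate classes with invariant sites keep unit mean rate", {
  m <- substitution_model(alpha = 0.6, p_inv = 0.25)
  rc <- rate_classes(m)
  expect_equal(sum(rc$weights), 1, tolerance = 1e-12)
  expect_equal(rc$rates[1], 0)
  expect_equal(rc$weights[1], 0.25)
  expect_equal(sum(rc$weights * rc$rates), 1, tolerance = 1e-12)
})

test_that("empirical +F frequencies use add-one pseudocounts", {
  m <- matrix("A", 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  pi <- empirical_frequencies(aa_alignment(m))
  expect_equal(unname(pi["A"]), (30 + 1) / (30 + 20))
  expect_equal(sum(pi), 1)
  expect_true(all(pi > 0))

  aln <- rand_alignment(20, 400, seed = 3)
  pi2 <- empirical_frequencies(aln)
  expect_true(all(abs(pi2 - 1 / 20) < 0.01)) # uniform source, 8000 cells
  perm <- aa_alignment(unclass(aln)[sample(20), ])
  expect_equal(empirical_frequencies(perm), pi2)

  gaps <- matrix("-", 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(empirical_frequencies(aa_alignment(gaps)), "no unambiguous")
})

test_that("bundled WAG constants agree with an independent copy", {
  w <- phangorn:::.WAG
  S <- wag_exchangeability_matrix()
  expect_equal(unname(S[lower.tri(S)]), w$Q, tolerance = 1e-8)
  expect_equal(unname(WAG_FREQS), unname(w$bf), tolerance = 1e-8)
})
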