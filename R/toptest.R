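#' Multiscale RELL bootstrap proportions
#'
#' Resampling of estimated log-likelihoods: at each scale `r`, draws
#' `round(r * n_sites)` columns with replacement `B` times, sums each
#' topology's site log-likelihoods over the resample, and records the
#' fraction of replicates in which each topology attains the maximum
#' (argmax ties broken by the lowest row index). Resampling is implemented
#' by multinomial column counts, so each replicate sum is a single
#' matrix-vector product. With `exhaustive = TRUE` the bootstrap
#' proportions are computed exactly by enumerating all column-count
#' compositions with their multinomial weights (tiny matrices only).
#'
#' @param M topologies x sites matrix of site log-likelihoods (>= 2 rows).
#' @param scales positive resampling scale factors (default `0.5..1.4`,
#'   the conventional ten-scale grid).
#' @param B replicates per scale (default 10000).
#' @param seed RNG seed.
#' @param exhaustive compute exact proportions by enumeration.
#' @return matrix of bootstrap proportions (topologies x scales), with the
#'   scales as column names and `attr(,"B")` recording the replicate count.
#' @export
rell_bootstrap <- function(M, scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                           seed = 1L, exhaustive = FALSE) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 topologies")
  if (any(scales <= 0)) stop("scales must be positive")
  if (!exhaustive && B < 100L) stop("B must be >= 100")
  n <- ncol(M)
  K <- nrow(M)
  set.seed(seed)
  bp <- matrix(0, K, length(scales),
               dimnames = list(NULL, format(scales)))
  for (s in seq_along(scales)) {
    m <- max(1L, as.integer(round(scales[s] * n)))
    if (exhaustive) {
      comps <- compositions_of(m, n)
      w <- apply(comps, 1L, function(k)
        exp(lgamma(m + 1) - sum(lgamma(k + 1)) - m * log(n)))
      S <- M %*% t(comps)
      win <- apply(S, 2L, which.max)
      bp[, s] <- vapply(seq_len(K), function(k) sum(w[win == k]), numeric(1))
    } else {
      counts <- stats::rmultinom(B, m, rep(1 / n, n))
      S <- M %*% counts
      win <- max.col(t(S), ties.method = "first")
      bp[, s] <- tabulate(win, K) / B
    }
  }
  attr(bp, "B") <- if (exhaustive) Inf else B
  attr(bp, "scales") <- scales
  bp
}

# all length-n non-negative integer vectors summing to m (compositions)
compositions_of <- function(m, n) {
  if (choose(m + n - 1, n - 1) > 2e5)
    stop("exhaustive enumeration infeasible: ",
         choose(m + n - 1, n - 1), " compositions")
  if (n == 1L) return(matrix(m, 1L, 1L))
  out <- do.call(rbind, lapply(0:m, function(k)
    cbind(k, compositions_of(m - k, n - 1L))))
  unname(as.matrix(out))
}

#' Approximately unbiased (AU) p-values from multiscale bootstrap curves
#'
#' For each topology the bootstrap proportions `BP(r)` across scales are
#' transformed to `z_r = qnorm(1 - BP(r))` (proportions clamped to
#' `[1/(2B), 1 - 1/(2B)]` as a continuity correction) and fitted by
#' weighted least squares to `z_r = d * sqrt(r) + c / sqrt(r)`, with
#' weights `B * dnorm(z_r)^2 / (BP (1 - BP))`. The AU p-value is
#' `1 - pnorm(d - c)`, where `d` estimates the signed distance to the
#' region boundary and `c` its curvature. Curves degenerate at 0 (or 1) on
#' nearly all scales get the boundary p-value 0 (or 1) and are flagged.
#'
#' @param bp matrix from [rell_bootstrap()] (topologies x scales).
#' @param scales the scale factors (defaults to `attr(bp, "scales")`).
#' @param B replicates per scale (defaults to `attr(bp, "B")`).
#' @return data.frame with columns `au`, `d`, `c`, `untestable`.
#' @export
au_pvalues <- function(bp, scales = attr(bp, "scales"), B = attr(bp, "B")) {
  if (is.null(scales)) stop("scales must be supplied")
  if (is.null(B) || !is.finite(B)) B <- 10000L
  K <- nrow(bp)
  out <- data.frame(au = numeric(K), d = NA_real_, c = NA_real_,
                    untestable = FALSE)
  lo <- 1 / (2 * B)
  x1 <- sqrt(scales); x2 <- 1 / sqrt(scales)
  for (k in seq_len(K)) {
    raw <- bp[k, ]
    nondeg <- sum(raw > 0 & raw < 1)
    if (nondeg < 2L) {
      out$au[k] <- if (mean(raw) >= 0.5) 1 else 0
      out$untestable[k] <- TRUE
      next
    }
    p <- pmin(pmax(raw, lo), 1 - lo)
    z <- stats::qnorm(1 - p)
    w <- B * stats::dnorm(z)^2 / (p * (1 - p))
    X <- cbind(x1, x2)
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    out$d[k] <- beta[1L]; out$c[k] <- beta[2L]
    out$au[k] <- 1 - stats::pnorm(beta[1L] - beta[2L])
  }
  out
}

#' Kishino-Hasegawa test between two topologies
#'
#' Centered RELL bootstrap of the per-site log-likelihood difference
#' between topologies `i` and `j`: the one-sided p-value is the fraction of
#' centered replicate sums at least as large as the observed total
#' difference `sum(M[i,] - M[j,])`.
#'
#' @inheritParams rell_bootstrap
#' @param i,j row indices of the two topologies (`i != j`).
#' @return one-sided p-value.
#' @export
kh_test <- function(M, i, j, B = 10000L, seed = 1L) {
  M <- as.matrix(M)
  if (i == j) stop("i and j must differ")
  d <- M[i, ] - M[j, ]
  delta <- sum(d)
  set.seed(seed)
  n <- length(d)
  counts <- stats::rmultinom(B, n, rep(1 / n, n))
  reps <- as.vector((d - mean(d)) %*% counts)
  mean(reps >= delta)
}

#' Shimodaira-Hasegawa test
#'
#' Centered RELL bootstrap: each topology's replicate sums are centered at
#' their own mean, and the per-topology p-value is the fraction of
#' replicates in which the maximum centered deviation over all topologies
#' exceeds the observed log-likelihood deficit of that topology.
#'
#' @inheritParams rell_bootstrap
#' @return vector of per-topology p-values.
#' @export
sh_test <- function(M, B = 10000L, seed = 1L) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 topologies")
  lnl <- rowSums(M)
  delta <- max(lnl) - lnl
  set.seed(seed)
  n <- ncol(M)
  counts <- stats::rmultinom(B, n, rep(1 / n, n))
  S <- M %*% counts
  Sc <- S - rowMeans(S)
  mx <- apply(Sc, 2L, max)
  Dk <- matrix(mx, nrow(M), B, byrow = TRUE) - Sc
  rowMeans(Dk >= delta)
}

#' Full topology-test report (BP, KH, SH, AU)
#'
#' Runs the multiscale RELL bootstrap and assembles, for each topology, the
#' total log-likelihood, the deficit to the best topology, the scale-1
#' bootstrap proportion, KH and SH p-values, the AU p-value with its fitted
#' signed distance `d` and curvature `c`, and a flag marking topologies
#' rejected at the 5% level (a reporting convention, mirrored from the
#' thick/thin branch style of published placement figures). The KH test for
#' each topology is taken against the best topology (the best is tested
#' against the runner-up).
#'
#' @inheritParams rell_bootstrap
#' @param edge_labels optional per-topology labels.
#' @return data.frame of class `topology_test_report`, one row per
#'   topology, with the per-scale BP matrix in `attr(,"bp")`.
#' @export
topology_tests <- function(M, scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                           seed = 1L, edge_labels = NULL) {
  M <- as.matrix(M)
  K <- nrow(M)
  n <- ncol(M)
  lnl <- rowSums(M)
  best <- which.max(lnl)
  second <- order(-lnl)[2L]
  bp <- rell_bootstrap(M, scales, B, seed = seed)
  au <- au_pvalues(bp, scales, B)
  # KH and SH share one scale-1 replicate set (as the classic RELL tools do)
  set.seed(seed + 1L)
  counts <- stats::rmultinom(B, n, rep(1 / n, n))
  S <- M %*% counts
  Sc <- S - rowMeans(S)
  mx <- apply(Sc, 2L, max)
  sh <- rowMeans((matrix(mx, K, B, byrow = TRUE) - Sc) >= (max(lnl) - lnl))
  # per-topology KH: deficit of k against the best (runner-up for the best)
  kh <- vapply(seq_len(K), function(k) {
    j <- if (k == best) second else best
    mean((Sc[j, ] - Sc[k, ]) >= (lnl[j] - lnl[k]))
  }, numeric(1))
  s1 <- which.min(abs(scales - 1))
  rep <- data.frame(topology = seq_len(K),
                    edge_label = if (is.null(edge_labels))
                      as.character(seq_len(K)) else edge_labels,
                    loglik = lnl,
                    delta = max(lnl) - lnl,
                    bp = bp[, s1],
                    kh = kh, sh = sh, au = au$au,
                    au_d = au$d, au_c = au$c,
                    rejected_05 = au$au < 0.05)
  attr(rep, "bp") <- bp
  attr(rep, "scales") <- scales
  class(rep) <- c("topology_test_report", "data.frame")
  rep
}

#' Write/read a site log-likelihood matrix
#'
#' `"mt"` is the plain-text topologies-by-sites layout consumed by the
#' classic RELL tools: a header line `K n` followed by one whitespace-
#' separated row of `n` site log-likelihoods per topology. `"tsv"` adds a
#' header of site columns.
#'
#' @param M topologies x sites matrix.
#' @param path file path.
#' @param format `"mt"` or `"tsv"`.
#' @export
write_site_loglik <- function(M, path, format = c("mt", "tsv")) {
  format <- match.arg(format)
  if (format == "mt") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(M), ncol(M)), con)
    apply(M, 1L, function(r)
      writeLines(paste(formatC(r, format = "g", digits = 10),
                       collapse = " "), con))
  } else {
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_site_loglik
#' @export
read_site_loglik <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  vals <- lapply(lines[-1L][nzchar(trimws(lines[-1L]))], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  M <- do.call(rbind, vals)
  if (nrow(M) != hdr[1L] || ncol(M) != hdr[2L])
    stop("matrix dimensions do not match header")
  M
}
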