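#' Weighted delete-one-block jackknife
#'
#' Combines per-block estimates into a whole-data estimate and a standard
#' error using the weighted delete-one-block jackknife, with block weights
#' typically equal to block SNP counts. With equal weights the formula
#' reduces exactly to the textbook unweighted delete-one jackknife.
#'
#' @param block_estimates numeric vector of per-block estimates (block means
#'   of the per-SNP terms).
#' @param block_weights positive block weights (SNP counts).
#' @return A list with `mean` (weighted whole-data estimate) and `se`.
#' @export
block_jackknife <- function(block_estimates, block_weights) {
  g <- length(block_estimates)
  if (g < 2L) stop("need at least 2 blocks for a jackknife variance")
  if (length(block_weights) != g || any(block_weights <= 0))
    stop("block_weights must be positive and match block_estimates")
  n <- sum(block_weights)
  est <- sum(block_weights * block_estimates) / n
  loo <- (n * est - block_weights * block_estimates) / (n - block_weights)
  h <- n / block_weights
  est_j <- g * est - sum((1 - block_weights / n) * loo)
  tau <- h * est - (h - 1) * loo
  se <- sqrt(sum((tau - est_j)^2 / (h - 1)) / g)
  list(mean = est, se = se)
}

# Jackknife mean vector + covariance for a D-dimensional statistic.
# block_mat: g x D matrix of per-block mean vectors; weights: block SNP counts.
jackknife_cov <- function(block_mat, block_weights) {
  g <- nrow(block_mat)
  if (g < 2L) stop("need at least 2 blocks for a jackknife covariance")
  n <- sum(block_weights)
  est <- colSums(block_mat * block_weights) / n
  # delete-one-block mean vectors
  tot <- est * n
  loo <- (matrix(tot, g, length(est), byrow = TRUE) -
            block_mat * block_weights) / (n - block_weights)
  h <- n / block_weights
  est_j <- g * est - colSums((1 - block_weights / n) * loo)
  tau <- outer(h, est) - (h - 1) * loo    # g x D
  dev <- sweep(tau, 2L, est_j)
  cov <- crossprod(dev / sqrt(h - 1)) / g
  list(mean = est, cov = cov, loo = loo)
}

# Resolve per-SNP term vector into an fstat via the block jackknife,
# restricted to SNPs where `defined` is TRUE.
fstat_from_terms <- function(kind, pops, term, defined, blocks) {
  use <- which(defined & !is.na(term))
  if (!length(use)) stop("no SNPs with defined frequencies in all of: ",
                         paste(pops, collapse = ", "))
  b <- blocks$block_of[use]
  sums <- rowsum(term[use], b)
  cnt <- tabulate(factor(b, levels = sort(unique(b))))
  bw <- as.numeric(cnt)
  jk <- block_jackknife(as.vector(sums) / bw, bw)
  structure(list(kind = kind, populations = pops, estimate = jk$mean,
                 se = jk$se, z = if (jk$se > 0) jk$mean / jk$se else NA_real_,
                 n_blocks = length(bw), n_snps = length(use)),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  se %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              x$kind, paste(x$populations, collapse = ", "),
              x$estimate, x$se,
              if (is.na(x$z)) 0 else x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

# shared helpers -------------------------------------------------------------

freq_row <- function(F, pop) {
  i <- match(pop, F$populations)
  if (is.na(i)) stop("population not in frequency table: ", pop)
  i
}

# h/c correction term: p(1-p)/(c-1), i.e. an unbiased estimate of the
# sampling contribution to (p_hat)^2 terms; 0 where c < 2.
hc_term <- function(p, c) {
  out <- p * (1 - p) / (c - 1)
  out[c < 2] <- NA_real_
  out
}

#' Estimate f2 between two populations
#'
#' Per-SNP term `(pA - pB)^2`, with (by default) the sample-size bias
#' correction `- hA/cA - hB/cB` where `h = p(1-p) c/(c-1)` and `c` is the
#' observed allele count. Aggregated over SNPs by the weighted block
#' jackknife.
#'
#' @param F a [freq_table()].
#' @param A,B population labels, distinct.
#' @param blocks a [block_partition()] over `F$snps`.
#' @param corrected apply the sample-size bias correction (default `TRUE`).
#' @return An object of class `fstat`.
#' @export
estimate_f2 <- function(F, A, B, blocks, corrected = TRUE) {
  if (A == B) stop("A and B must differ")
  ia <- freq_row(F, A); ib <- freq_row(F, B)
  pa <- F$freq[ia, ]; pb <- F$freq[ib, ]
  defined <- F$total[ia, ] > 0 & F$total[ib, ] > 0
  term <- (pa - pb)^2
  if (corrected) {
    term <- term - hc_term(pa, F$total[ia, ]) - hc_term(pb, F$total[ib, ])
  }
  fstat_from_terms("f2", c(A, B), term, defined, blocks)
}

#' Estimate f3(X; A, B)
#'
#' Per-SNP term `(pX - pA)(pX - pB)`, with (by default) the bias correction
#' `- hX/cX` for the target population X. Significantly negative outgroup-f3
#' values indicate that X is admixed; with X an outgroup the statistic
#' measures shared drift between A and B.
#'
#' @inheritParams estimate_f2
#' @param X target (or outgroup) population label.
#' @return An object of class `fstat`.
#' @export
estimate_f3 <- function(F, X, A, B, blocks, corrected = TRUE) {
  if (anyDuplicated(c(X, A, B))) stop("X, A, B must be distinct")
  ix <- freq_row(F, X); ia <- freq_row(F, A); ib <- freq_row(F, B)
  px <- F$freq[ix, ]; pa <- F$freq[ia, ]; pb <- F$freq[ib, ]
  defined <- F$total[ix, ] > 0 & F$total[ia, ] > 0 & F$total[ib, ] > 0
  term <- (px - pa) * (px - pb)
  if (corrected) term <- term - hc_term(px, F$total[ix, ])
  fstat_from_terms("f3", c(X, A, B), term, defined, blocks)
}

#' Estimate f4(A, B; C, D)
#'
#' Per-SNP term `(pA - pB)(pC - pD)`; no bias correction is needed because
#' the four sampling errors are independent across the two differences.
#'
#' @inheritParams estimate_f2
#' @param A,B,C,D population labels; `A != B` and `C != D`.
#' @return An object of class `fstat`.
#' @export
estimate_f4 <- function(F, A, B, C, D, blocks) {
  if (A == B || C == D) stop("need A != B and C != D")
  ia <- freq_row(F, A); ib <- freq_row(F, B)
  ic <- freq_row(F, C); id <- freq_row(F, D)
  defined <- F$total[ia, ] > 0 & F$total[ib, ] > 0 &
    F$total[ic, ] > 0 & F$total[id, ] > 0
  term <- (F$freq[ia, ] - F$freq[ib, ]) * (F$freq[ic, ] - F$freq[id, ])
  fstat_from_terms("f4", c(A, B, C, D), term, defined, blocks)
}

#' Outgroup-f3 shared-drift biplot with trend-line deviations
#'
#' For every test population computes `x = f3(outgroup; refA, test)` and
#' `y = f3(outgroup; refB, test)`, fits an ordinary least-squares line over
#' the populations in `trend_set`, and reports each population's vertical
#' deviation from the fitted line. A population with elevated shared drift
#' with `refB`'s clade (relative to the trend populations) shows a positive
#' deviation exceeding its propagated standard error.
#'
#' @param F a [freq_table()].
#' @param outgroup outgroup population label.
#' @param refA,refB the two reference populations spanning the biplot axes.
#' @param tests test population labels.
#' @param trend_set subset of `tests` (at least 3) used to fit the trend
#'   line; defaults to all of `tests`.
#' @param blocks a [block_partition()].
#' @return A data frame of class `drift_biplot` with columns
#'   `test_population`, `x`, `x_se`, `y`, `y_se`, `fitted_y`, `deviation`,
#'   `deviation_se`. The fitted intercept/slope are in attributes
#'   `intercept`/`slope`. `deviation_se = sqrt(se_y^2 + slope^2 se_x^2)`
#'   (x-y covariance ignored).
#' @export
drift_biplot <- function(F, outgroup, refA, refB, tests,
                         trend_set = tests, blocks) {
  if (!all(trend_set %in% tests)) stop("trend_set must be a subset of tests")
  if (length(trend_set) < 3L) stop("trend_set needs at least 3 populations")
  fx <- lapply(tests, function(t) estimate_f3(F, outgroup, refA, t, blocks))
  fy <- lapply(tests, function(t) estimate_f3(F, outgroup, refB, t, blocks))
  x <- vapply(fx, `[[`, numeric(1), "estimate")
  y <- vapply(fy, `[[`, numeric(1), "estimate")
  x_se <- vapply(fx, `[[`, numeric(1), "se")
  y_se <- vapply(fy, `[[`, numeric(1), "se")
  it <- match(trend_set, tests)
  if (stats::var(x[it]) <= 0)
    stop("degenerate trend: zero variance of x over trend_set")
  fit <- stats::lm.fit(cbind(1, x[it]), y[it])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  fitted_y <- a + b * x
  out <- data.frame(test_population = tests, x = x, x_se = x_se,
                    y = y, y_se = y_se, fitted_y = fitted_y,
                    deviation = y - fitted_y,
                    deviation_se = sqrt(y_se^2 + b^2 * x_se^2),
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- unname(a)
  attr(out, "slope") <- unname(b)
  class(out) <- c("drift_biplot", "data.frame")
  out
}

#' Plot a shared-drift biplot
#'
#' Draws the outgroup-f3 biplot produced by [drift_biplot()] with its trend
#' line; populations whose deviation exceeds `label_z` standard errors are
#' labelled. Requires ggplot2.
#'
#' @param x a `drift_biplot` data frame.
#' @param label_z label populations with `|deviation| > label_z *
#'   deviation_se` (default 3).
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.drift_biplot <- function(x, label_z = 3, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  lab <- x[abs(x$deviation) > label_z * x$deviation_se, , drop = FALSE]
  ggplot2::ggplot(x, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(intercept = attr(x, "intercept"),
                         slope = attr(x, "slope"), linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$test_population),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "f3(outgroup; refA, test)",
                  y = "f3(outgroup; refB, test)")
}
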