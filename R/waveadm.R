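#' Build the left/right f4 statistic system
#'
#' Assembles the matrix `X[i, j] = f4(l0, l_i; r0, r_j)` over the non-base
#' left populations `l_i` and non-base right populations `r_j`, on the
#' complete-case SNP set across all populations involved, together with the
#' weighted block-jackknife covariance of `vec(X)`. This matrix is the
#' substrate of both the rank (number-of-ancestry-streams) test and the
#' admixture-proportion fit.
#'
#' @param F a [freq_table()].
#' @param left left populations; the first is the base `l0` (for an
#'   admixture fit: the target, then the sources).
#' @param right right (outgroup/reference) populations; the first is the
#'   base `r0`. Requires `|right| >= |left| + 1` and no overlap with
#'   `left`.
#' @param blocks a [block_partition()].
#' @return An object of class `f4_system`: `X`, `cov`, `left`, `right`,
#'   `n_blocks`, `n_snps`, plus per-block sums for delete-one re-fits.
#' @export
build_f4_system <- function(F, left, right, blocks) {
  if (length(intersect(left, right)))
    stop("left and right populations overlap: ",
         paste(intersect(left, right), collapse = ", "))
  if (length(left) < 2L) stop("need at least 2 left populations")
  if (length(right) < length(left) + 1L)
    stop("need |right| >= |left| + 1")
  pops <- c(left, right)
  idx <- match(pops, F$populations)
  if (anyNA(idx))
    stop("population(s) not in frequency table: ",
         paste(pops[is.na(idx)], collapse = ", "))
  defined <- colSums(F$total[idx, , drop = FALSE] > 0) == length(pops)
  use <- which(defined)
  if (length(use) < 2L) stop("no SNPs with defined frequencies everywhere")
  p <- F$freq[idx, use, drop = FALSE]
  rownames(p) <- pops
  nl <- length(left) - 1L; nr <- length(right) - 1L
  dl <- outer(rep(1, nl), p[left[1], ]) -
    p[left[-1], , drop = FALSE]                          # nl x S
  dr <- outer(rep(1, nr), p[right[1], ]) -
    p[right[-1], , drop = FALSE]                         # nr x S
  # terms for vec(X): column-major over (i, j), i fastest
  terms <- matrix(0, nrow = length(use), ncol = nl * nr)
  cn <- character(nl * nr)
  for (j in seq_len(nr)) for (i in seq_len(nl)) {
    k <- (j - 1L) * nl + i
    terms[, k] <- dl[i, ] * dr[j, ]
    cn[k] <- paste0("f4(", left[1], ",", left[i + 1L], ";",
                    right[1], ",", right[j + 1L], ")")
  }
  colnames(terms) <- cn
  b <- blocks$block_of[use]
  ub <- sort(unique(b))
  if (length(ub) < 2L) stop("need at least 2 jackknife blocks")
  sums <- rowsum(terms, b)
  cnt <- as.numeric(tabulate(factor(b, levels = ub)))
  jk <- jackknife_cov(sums / cnt, cnt)
  X <- matrix(jk$mean, nrow = nl, ncol = nr,
              dimnames = list(left[-1], right[-1]))
  structure(list(X = X, cov = jk$cov, left = left, right = right,
                 n_blocks = length(ub), n_snps = length(use),
                 block_sums = sums, block_weights = cnt),
            class = "f4_system")
}

#' @export
print.f4_system <- function(x, ...) {
  cat("f4_system:", nrow(x$X), "x", ncol(x$X),
      "statistics; left base", x$left[1], ", right base", x$right[1], "\n")
  cat(" ", x$n_snps, "SNPs in", x$n_blocks, "blocks\n")
  invisible(x)
}

# Regularized inverse covariance for a system.
system_qinv <- function(S, diag_scale = 1e-4) {
  Q <- S$cov + diag(diag_scale * mean(diag(S$cov)), nrow(S$cov))
  tryCatch(solve(Q), error = function(e)
    stop("singular regularized covariance; increase diag_scale",
         call. = FALSE))
}

# Rank-constrained generalized least squares: find E = A B (nl x r times
# r x nr) minimizing (x - vec(E))' Qi (x - vec(E)) by alternating exact GLS
# solves in A and B. Returns the minimized quadratic form and factors.
rank_gls <- function(X, Qi, r, tol = 1e-6, max_iter = 200) {
  nl <- nrow(X); nr <- ncol(X)
  x <- as.vector(X)
  if (r == 0L)
    return(list(quad = drop(crossprod(x, Qi %*% x)), A = NULL, B = NULL,
                iterations = 0L, trace = numeric(0)))
  sv <- svd(X)
  A <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(r)]), r)
  B <- diag(sqrt(sv$d[seq_len(r)]), r) %*%
    t(sv$v[, seq_len(r), drop = FALSE])
  quad_of <- function(A, B) {
    d <- x - as.vector(A %*% B)
    drop(crossprod(d, Qi %*% d))
  }
  Inl <- diag(nl); Inr <- diag(nr)
  last <- quad_of(A, B)
  trace <- last
  for (it in seq_len(max_iter)) {
    # vec(AB) = (B' kron I_nl) vec(A): GLS update of A
    Ma <- kronecker(t(B), Inl)
    Ha <- crossprod(Ma, Qi %*% Ma)
    A <- matrix(solve(Ha + diag(1e-12 * max(abs(Ha)), nrow(Ha)),
                      crossprod(Ma, Qi %*% x)), nrow = nl)
    # vec(AB) = (I_nr kron A) vec(B): GLS update of B
    Mb <- kronecker(Inr, A)
    Hb <- crossprod(Mb, Qi %*% Mb)
    B <- matrix(solve(Hb + diag(1e-12 * max(abs(Hb)), nrow(Hb)),
                      crossprod(Mb, Qi %*% x)), nrow = r)
    quad <- quad_of(A, B)
    trace <- c(trace, quad)
    if (last - quad < tol && it >= 2L)
      return(list(quad = quad, A = A, B = B, iterations = it,
                  trace = trace))
    last <- quad
  }
  err <- simpleError("rank-constrained GLS did not converge")
  err$trace <- trace
  stop(err)
}

#' Rank test for the number of ancestry streams
#'
#' Tests whether the expectation of the left/right f4 matrix has rank at
#' most `r`, i.e. whether `r + 1` streams of ancestry (relative to the right
#' set) suffice for the left populations. Cladality of a pair is the rank-0
#' test of the 1 x (|right|-1) system. The statistic is twice the Gaussian
#' log-likelihood gap between the unconstrained and rank-constrained means,
#' referred to a chi-squared distribution with
#' `(|left|-1-r)(|right|-1-r)` degrees of freedom.
#'
#' @param S an [build_f4_system()] result.
#' @param r rank to test, `0 <= r < min(|left|-1, |right|-1)`.
#' @param diag_scale covariance regularization (default 1e-4).
#' @return An object of class `rank_test`: `rank_tested`, `chi2`, `dof`,
#'   `p_value`.
#' @export
rank_test <- function(S, r, diag_scale = 1e-4) {
  nl <- nrow(S$X); nr <- ncol(S$X)
  if (r < 0 || r >= min(nl, nr))
    stop("rank must satisfy 0 <= r < min(|left|-1, |right|-1)")
  Qi <- system_qinv(S, diag_scale)
  fit <- rank_gls(S$X, Qi, r)
  dof <- (nl - r) * (nr - r)
  structure(list(rank_tested = r, chi2 = fit$quad, dof = dof,
                 p_value = stats::pchisq(fit$quad, dof, lower.tail = FALSE)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("rank_test: rank <= %d, chi2 = %.3f, dof = %d, p = %.4g\n",
              x$rank_tested, x$chi2, x$dof, x$p_value))
  invisible(x)
}

# Admixture weights from a rank-(k-1) factorization: the left null vector c
# of A (c' A = 0) normalized to sum 1; with left = (target, sources) the
# model's source weights.
weights_from_factor <- function(A) {
  if (is.null(A)) return(1)
  k <- nrow(A)
  sv <- svd(A, nu = k)
  c0 <- sv$u[, k]
  if (abs(sum(c0)) < 1e-12)
    stop("degenerate null vector: weights do not sum to a nonzero total")
  c0 / sum(c0)
}

#' Fit admixture proportions for a target population
#'
#' Models the first left population (the target) as a mixture of the
#' remaining left populations (1-3 sources) relative to the right set. The
#' weights are the left null vector of the rank-(k-1) factorization of the
#' f4 matrix, normalized to sum to 1; negative weights are reported, not
#' clamped (the plausibility classifier is the filter). Standard errors come
#' from delete-one-block jackknife re-fits, and the model p-value is the
#' rank-(k-1) test.
#'
#' @param S an [build_f4_system()] result with `left = c(target, sources)`.
#' @param diag_scale covariance regularization (default 1e-4).
#' @return An object of class `qpadm_fit`: `target`, `sources`, `weights`,
#'   `weight_se`, `p_value`, `chi2`, `dof`, `plausible` (`NA` until
#'   [classify_model()]), `failure_reasons`, `n_blocks`, `n_snps`.
#' @export
fit_qpadm <- function(S, diag_scale = 1e-4) {
  k <- nrow(S$X)
  if (k < 1L || k > 3L) stop("supported source counts: 1-3")
  target <- S$left[1]
  sources <- S$left[-1]
  Qi <- system_qinv(S, diag_scale)
  r <- k - 1L
  if (k == 1L) {
    w <- 1
    w_se <- 0
  } else {
    fit <- rank_gls(S$X, Qi, r)
    w <- weights_from_factor(fit$A)
    # delete-one-block re-fits
    g <- length(S$block_weights)
    n <- sum(S$block_weights)
    tot <- colSums(S$block_sums)
    loo_w <- matrix(0, nrow = g, ncol = k)
    for (j in seq_len(g)) {
      xj <- (tot - S$block_sums[j, ]) / (n - S$block_weights[j])
      Xj <- matrix(xj, nrow = k)
      fj <- rank_gls(Xj, Qi, r)
      wj <- weights_from_factor(fj$A)
      if (sum((wj - w)^2) > sum((-wj - w)^2)) wj <- -wj  # sign alignment
      loo_w[j, ] <- wj
    }
    h <- n / S$block_weights
    est_j <- g * w - colSums((1 - S$block_weights / n) * loo_w)
    tau <- outer(h, w) - (h - 1) * loo_w
    dev <- sweep(tau, 2L, est_j)
    w_se <- sqrt(colSums(dev^2 / (h - 1)) / g)
  }
  rt <- rank_test(S, r, diag_scale)
  structure(list(target = target, sources = sources,
                 weights = stats::setNames(as.numeric(w), sources),
                 weight_se = stats::setNames(as.numeric(w_se), sources),
                 p_value = rt$p_value, chi2 = rt$chi2, dof = rt$dof,
                 plausible = NA, failure_reasons = character(0),
                 n_blocks = S$n_blocks, n_snps = S$n_snps),
            class = "qpadm_fit")
}

#' Construct an admixture model object directly
#'
#' Mostly useful for classifying externally produced (or constructed) fits
#' with [classify_model()].
#'
#' @param target target population label.
#' @param sources source labels.
#' @param weights,weight_se numeric vectors aligned with `sources`.
#' @param p_value model p-value.
#' @return A `qpadm_fit` object.
#' @export
qpadm_model <- function(target, sources, weights, weight_se, p_value) {
  stopifnot(length(weights) == length(sources),
            length(weight_se) == length(sources))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1")
  structure(list(target = target, sources = sources,
                 weights = stats::setNames(as.numeric(weights), sources),
                 weight_se = stats::setNames(as.numeric(weight_se), sources),
                 p_value = p_value, chi2 = NA_real_, dof = NA_integer_,
                 plausible = NA, failure_reasons = character(0),
                 n_blocks = NA_integer_, n_snps = NA_integer_),
            class = "qpadm_fit")
}

#' Classify an admixture model as plausible or not
#'
#' A model is plausible when (a) it is not rejected at the chosen p-value
#' cutoff and (b) every inferred admixture proportion +/- 2 standard errors
#' lies between 0 and 1. Violations are recorded in `failure_reasons` as
#' `p_below_cutoff` and/or `weight_ci_outside_unit`.
#'
#' @param M a `qpadm_fit`.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return `M` with `plausible` and `failure_reasons` filled in.
#' @export
classify_model <- function(M, p_cutoff = 0.05) {
  stopifnot(inherits(M, "qpadm_fit"))
  reasons <- character(0)
  if (M$p_value < p_cutoff) reasons <- c(reasons, "p_below_cutoff")
  lo <- M$weights - 2 * M$weight_se
  hi <- M$weights + 2 * M$weight_se
  if (any(lo < 0) || any(hi > 1))
    reasons <- c(reasons, "weight_ci_outside_unit")
  M$failure_reasons <- reasons
  M$plausible <- length(reasons) == 0L
  M
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat("qpadm_fit:", x$target, "=",
      paste(sprintf("%.3f x %s", x$weights, x$sources), collapse = " + "),
      "\n")
  cat(sprintf("  p = %.4g; weight SEs: %s\n", x$p_value,
              paste(sprintf("%.3f", x$weight_se), collapse = ", ")))
  if (!is.na(x$plausible))
    cat("  plausible:", x$plausible,
        if (length(x$failure_reasons))
          paste0("(", paste(x$failure_reasons, collapse = ", "), ")")
        else "", "\n")
  invisible(x)
}

#' Sweep admixture models across surrogate sets
#'
#' For every East/Southeast Asian (ESEA) surrogate emits the single-source
#' cladality model `target = ESEA`, the 2-way model `target = ESEA + NEGA`,
#' and one 3-way model `target = ESEA + NEGA + SAS` per South Asian
#' surrogate, each classified by the plausibility criteria. The summary
#' averages the weights of each ancestry across all plausible models.
#'
#' @param F a [freq_table()].
#' @param target target population label.
#' @param esea ESEA surrogate labels.
#' @param nega single deeply-diverged hunter-gatherer surrogate label.
#' @param sas South Asian surrogate labels.
#' @param right right (outgroup) population labels.
#' @param blocks a [block_partition()].
#' @param p_cutoff plausibility p-value cutoff (default 0.05).
#' @return An object of class `model_sweep`: `table` (one row per model:
#'   target, model, esea, sas, weights/SEs per ancestry, p, plausible,
#'   reasons) and `summary` (mean weight per ancestry over plausible
#'   models).
#' @export
sweep_models <- function(F, target, esea, nega, sas, right, blocks,
                         p_cutoff = 0.05) {
  labels <- c(target, esea, nega, sas)
  if (length(intersect(labels, right)))
    stop("left-side labels overlap the right set")
  rows <- list()
  add_row <- function(model, e, s, M) {
    w <- function(pop) if (!is.null(pop) && pop %in% names(M$weights))
      M$weights[[pop]] else NA_real_
    se <- function(pop) if (!is.null(pop) && pop %in% names(M$weight_se))
      M$weight_se[[pop]] else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, model = model, esea = e,
      sas = if (is.null(s)) NA_character_ else s,
      w_esea = w(e), se_esea = se(e),
      w_nega = w(nega), se_nega = se(nega),
      w_sas = w(s), se_sas = se(s),
      p_value = M$p_value, plausible = M$plausible,
      reasons = paste(M$failure_reasons, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (e in esea) {
    S1 <- build_f4_system(F, c(target, e), right, blocks)
    add_row("ESEA", e, NULL, classify_model(fit_qpadm(S1), p_cutoff))
    S2 <- build_f4_system(F, c(target, e, nega), right, blocks)
    add_row("ESEA+NEGA", e, NULL, classify_model(fit_qpadm(S2), p_cutoff))
    for (s in sas) {
      S3 <- build_f4_system(F, c(target, e, nega, s), right, blocks)
      add_row("ESEA+NEGA+SAS", e, s,
              classify_model(fit_qpadm(S3), p_cutoff))
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$plausible
  summary <- c(esea = mean(tab$w_esea[ok], na.rm = TRUE),
               nega = mean(tab$w_nega[ok], na.rm = TRUE),
               sas = mean(tab$w_sas[ok], na.rm = TRUE))
  structure(list(table = tab, summary = summary), class = "model_sweep")
}

#' @export
print.model_sweep <- function(x, ...) {
  cat("model_sweep:", nrow(x$table), "models,",
      sum(x$table$plausible), "plausible\n")
  cat("  mean weights over plausible models:",
      paste(sprintf("%s %.3f", names(x$summary), x$summary),
            collapse = ", "), "\n")
  invisible(x)
}
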