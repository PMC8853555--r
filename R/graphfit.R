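# Basis of f-statistics used for graph fitting: f2(base, X) for every other
# leaf X, plus f3(base; X, Y) for every unordered pair X < Y. Every f2/f3/f4
# over the leaf set is an exact linear combination of this basis (bias
# corrections included), so one jackknife covariance of the basis vector
# yields the standard error of any derived statistic.

basis_spec <- function(pops, base) {
  others <- setdiff(pops, base)
  f2s <- data.frame(kind = "f2", p1 = base, p2 = others, p3 = NA,
                    stringsAsFactors = FALSE)
  f3s <- if (length(others) >= 2) {
    prs <- utils::combn(others, 2)
    data.frame(kind = "f3", p1 = base, p2 = prs[1, ], p3 = prs[2, ],
               stringsAsFactors = FALSE)
  }
  spec <- rbind(f2s, f3s)
  spec$name <- ifelse(spec$kind == "f2",
                      paste0("f2(", spec$p1, ",", spec$p2, ")"),
                      paste0("f3(", spec$p1, ";", spec$p2, ",", spec$p3, ")"))
  spec
}

#' Observed f-statistic basis with jackknife covariance
#'
#' Computes the fitting basis (f2 of a base population with every other
#' population, and f3 of the base with every pair) on the complete-case SNP
#' set over all listed populations, together with the weighted
#' block-jackknife covariance of the stacked vector.
#'
#' @param F a [freq_table()].
#' @param pops populations spanning the basis (the graph's leaves).
#' @param blocks a [block_partition()].
#' @param base base population; default first of `pops`.
#' @param corrected apply sample-size bias corrections (default `TRUE`).
#' @return An object of class `fstat_basis`: `est`, `cov`, `spec`, `base`,
#'   `pops`, `n_snps`, `n_blocks`.
#' @export
observed_basis <- function(F, pops, blocks, base = pops[1],
                           corrected = TRUE) {
  stopifnot(base %in% pops)
  idx <- match(pops, F$populations)
  if (anyNA(idx))
    stop("population(s) not in frequency table: ",
         paste(pops[is.na(idx)], collapse = ", "))
  defined <- colSums(F$total[idx, , drop = FALSE] > 0) == length(pops)
  use <- which(defined)
  if (length(use) < 2L)
    stop("fewer than 2 SNPs with defined frequencies in all populations")
  p <- F$freq[idx, use, drop = FALSE]
  cc <- F$total[idx, use, drop = FALSE]
  rownames(p) <- rownames(cc) <- pops
  h <- p * (1 - p) / pmax(cc - 1, 1)
  spec <- basis_spec(pops, base)
  terms <- matrix(0, nrow = length(use), ncol = nrow(spec),
                  dimnames = list(NULL, spec$name))
  pb <- p[base, ]; hb <- h[base, ]
  for (s in seq_len(nrow(spec))) {
    if (spec$kind[s] == "f2") {
      px <- p[spec$p2[s], ]
      t0 <- (pb - px)^2
      if (corrected) t0 <- t0 - hb - h[spec$p2[s], ]
    } else {
      t0 <- (pb - p[spec$p2[s], ]) * (pb - p[spec$p3[s], ])
      if (corrected) t0 <- t0 - hb
    }
    terms[, s] <- t0
  }
  b <- blocks$block_of[use]
  ub <- sort(unique(b))
  sums <- rowsum(terms, b)
  cnt <- as.numeric(tabulate(factor(b, levels = ub)))
  if (length(ub) < 2L) stop("need at least 2 jackknife blocks")
  jk <- jackknife_cov(sums / cnt, cnt)
  structure(list(est = jk$mean, cov = jk$cov, spec = spec, base = base,
                 pops = pops, n_snps = length(use), n_blocks = length(ub),
                 block_est = sums / cnt, block_weights = cnt),
            class = "fstat_basis")
}

#' Noise-free basis from a graph's expected statistics
#'
#' Packages the expected basis of a parameterized graph as an `fstat_basis`
#' with identity covariance — useful for self-consistency fitting (fit the
#' generating topology to its own expectations and recover the parameters).
#'
#' @param g a fully parameterized [admix_graph()].
#' @param base base population; default first leaf.
#' @param scale covariance scale (default `1e-6`, giving a well-conditioned
#'   identity covariance on the f2 magnitude scale).
#' @return An `fstat_basis`.
#' @export
basis_from_graph <- function(g, base = unname(g$leaf_map[1]),
                             scale = 1e-6) {
  E <- expected_stats(g)
  pops <- E$populations
  spec <- basis_spec(pops, base)
  est <- vapply(seq_len(nrow(spec)), function(s) {
    if (spec$kind[s] == "f2") exp_f2(E, spec$p1[s], spec$p2[s])
    else exp_f3(E, spec$p1[s], spec$p2[s], spec$p3[s])
  }, numeric(1))
  names(est) <- spec$name
  structure(list(est = est, cov = diag(scale, length(est)), spec = spec,
                 base = base, pops = pops, n_snps = NA_integer_,
                 n_blocks = NA_integer_),
            class = "fstat_basis")
}

# Design matrix: coefficient of each basis statistic on each drift edge,
# given the graph's path-probability matrix (depends on admixture weights).
# spec_cols precomputes the leaf-column indices of each statistic.
spec_columns <- function(spec, leaf_names) {
  i1 <- match(spec$p1, leaf_names)
  i2 <- match(spec$p2, leaf_names)
  i3 <- ifelse(spec$kind == "f2", i2, match(spec$p3, leaf_names))
  list(i1 = i1, i2 = i2, i3 = i3)
}

basis_design <- function(A, spec, cols = spec_columns(spec, colnames(A))) {
  D1 <- A[, cols$i1, drop = FALSE] - A[, cols$i2, drop = FALSE]
  D2 <- A[, cols$i1, drop = FALSE] - A[, cols$i3, drop = FALSE]
  M <- t(D1 * D2)
  dimnames(M) <- list(spec$name, rownames(A))
  M
}

# Fast non-negative least squares on the normal equations (active-set,
# Bro & de Jong style). Minimizes ||U(y - M x)||^2 s.t. x >= 0 given
# H = M'U'UM and f = M'U'Uy. pracma::lsqnonneg is the reference
# implementation; this one avoids re-forming dense QR factors in the
# graph-search inner loop.
fnnls <- function(H, f) {
  n <- length(f)
  # small ridge keeps passive-set solves defined when edges are confounded
  H <- H + diag(1e-10 * max(mean(abs(diag(H))), 1e-300), n)
  tol_w <- 1e-9 * max(abs(f), 1e-300)   # gradient scale
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- f                      # negative gradient of the objective at x = 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 5L * n) break
    cand <- which(!passive & w > tol_w)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      Pp <- which(passive)
      s[Pp] <- solve(H[Pp, Pp, drop = FALSE], f[Pp])
      if (all(s[Pp] > 0)) { x <- s; break }
      neg <- Pp[s[Pp] <= 0]
      alpha <- suppressWarnings(min(x[neg] / (x[neg] - s[neg]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (s - x)
      passive[Pp][x[Pp] <= 1e-14] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- f - drop(H %*% x)
  }
  pmax(x, 0)
}

#' Graph-fitting configuration
#'
#' @param block_span jackknife block width in Morgans (default 0.05).
#' @param cov_diag covariance regularization: `cov_diag * mean(diag(cov))`
#'   is added to the diagonal before inversion (default 1e-4).
#' @param n_restarts number of deterministic lattice starting points for
#'   admixture-weight optimization (default 100).
#' @param tol convergence tolerance for weight optimization (default 1e-4).
#' @param zero_tol drift lengths at or below this are treated as zero for
#'   the trifurcation rule (default 1e-7).
#' @param max_waves maximum number of ancestry streams when mapping a
#'   target (default 3; larger values are outside the supported model
#'   space).
#' @param refit_skeleton_weights when mapping a target onto a fitted
#'   skeleton, re-optimize the skeleton's own (non-fixed) admixture weights
#'   for every candidate model (default `FALSE`: only newly introduced
#'   weights are optimized; branch lengths are always refit).
#' @param base base population for the fitting basis (default: first leaf).
#' @return A named list of class `graph_config`.
#' @export
graph_config <- function(block_span = 0.05, cov_diag = 1e-4,
                         n_restarts = 100, tol = 1e-4, zero_tol = 1e-7,
                         max_waves = 3, refit_skeleton_weights = FALSE,
                         base = NULL) {
  structure(list(block_span = block_span, cov_diag = cov_diag,
                 n_restarts = n_restarts, tol = tol, zero_tol = zero_tol,
                 max_waves = max_waves,
                 refit_skeleton_weights = refit_skeleton_weights,
                 base = base),
            class = "graph_config")
}

# Deterministic restart lattice on [0,1]^p (excludes the degenerate corners).
restart_lattice <- function(p, n) {
  if (p == 0L) return(matrix(numeric(0), nrow = 1, ncol = 0))
  per <- max(2L, ceiling(n^(1 / p)))
  pts <- seq(0.5 / per, 1 - 0.5 / per, length.out = per)
  as.matrix(expand.grid(rep(list(pts), p)))
}

# Core fitter: given a basis (observed or expected) and a topology, optimize
# free admixture weights (deterministic multistart + local refinement) with
# an inner exact GLS/NNLS solve for all branch lengths.
fit_graph_core <- function(topology, basis, config, free_weights = NULL) {
  spec <- basis$spec
  Qreg <- basis$cov
  if (config$cov_diag > 0)
    Qreg <- Qreg + diag(config$cov_diag * mean(diag(Qreg)), nrow(Qreg))
  Qi <- tryCatch(solve(Qreg), error = function(e)
    stop("singular regularized covariance; increase cov_diag", call. = FALSE))
  y <- basis$est
  Qiy <- Qi %*% y
  yQiy <- drop(crossprod(y, Qiy))
  g <- topology
  if (is.null(free_weights)) free_weights <- which(!g$admix$fixed)
  if (nrow(g$admix) && anyNA(g$admix$weight[g$admix$fixed]))
    stop("fixed admixture weight is unset")
  cols <- NULL
  score_at <- function(wvec) {
    gg <- g
    if (length(free_weights)) gg$admix$weight[free_weights] <- wvec
    A <- path_matrix(gg)
    if (is.null(cols)) cols <<- spec_columns(spec, colnames(A))
    M <- basis_design(A, spec, cols)
    H <- crossprod(M, Qi %*% M)
    f <- drop(crossprod(M, Qiy))
    len <- fnnls(H, f)
    # score = -1/2 d' Qi d with d = y - M len
    quad <- yQiy - 2 * sum(f * len) + drop(crossprod(len, H %*% len))
    list(score = -0.5 * max(quad, 0), lengths = len, M = M)
  }
  p <- length(free_weights)
  if (p == 0L) {
    best_w <- numeric(0)
    best <- score_at(best_w)
  } else if (p == 1L) {
    opt <- stats::optimize(function(w) -score_at(w)$score,
                           interval = c(0, 1), tol = config$tol / 10)
    best_w <- opt$minimum
    # check the end points too: optimize() can miss boundary optima
    for (w in c(0, 1)) if (-score_at(w)$score < -score_at(best_w)$score)
      best_w <- w
    best <- score_at(best_w)
  } else {
    starts <- restart_lattice(p, config$n_restarts)
    best <- NULL; best_w <- NULL
    for (i in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[i, ], function(w) -score_at(w)$score,
                          method = "L-BFGS-B", lower = 0, upper = 1,
                          control = list(factr = 1e4))
      if (is.null(best) || -opt$value > best$score) {
        best_w <- opt$par
        best <- score_at(best_w)
      }
    }
  }
  if (length(free_weights)) g$admix$weight[free_weights] <- best_w
  g$edges$length <- as.vector(best$lengths)
  # non-identifiable lengths: edges traversed by no sampled lineage
  Afit <- path_matrix(g)
  dead <- rowSums(abs(Afit)) == 0
  if (any(dead))
    warning("non-identifiable length(s) reported as 0 on edge(s): ",
            paste(g$edges$label[dead], collapse = ", "))
  list(graph = g, score = best$score, Qreg = Qreg, Qi = Qi,
       expected = drop(best$M %*% best$lengths))
}

# Coefficient vector of f2(X, Y) in the fitting basis.
f2_coef <- function(spec, base, X, Y) {
  v <- numeric(nrow(spec))
  if (X == Y) return(v)
  if (X == base || Y == base) {
    other <- if (X == base) Y else X
    v[spec$kind == "f2" & spec$p2 == other] <- 1
    return(v)
  }
  v[spec$kind == "f2" & spec$p2 == X] <- 1
  v[spec$kind == "f2" & spec$p2 == Y] <- 1
  hit <- spec$kind == "f3" &
    ((spec$p2 == X & spec$p3 == Y) | (spec$p2 == Y & spec$p3 == X))
  v[hit] <- -2
  v
}

# All residual statistics (f2 pairs, f3 triples, f4 quadruples over the leaf
# set) as rows of a coefficient matrix on the basis, plus display names.
residual_functionals <- function(spec, base, pops) {
  rows <- list(); names <- character(0); kinds <- character(0)
  f2c <- function(X, Y) f2_coef(spec, base, X, Y)
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i < j) {
      rows[[length(rows) + 1L]] <- f2c(pops[i], pops[j])
      names <- c(names, paste0("f2(", pops[i], ",", pops[j], ")"))
      kinds <- c(kinds, "f2")
    }
  }
  for (x in pops) {
    others <- setdiff(pops, x)
    prs <- utils::combn(others, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      rows[[length(rows) + 1L]] <-
        (f2c(x, a) + f2c(x, b) - f2c(a, b)) / 2
      names <- c(names, paste0("f3(", x, ";", a, ",", b, ")"))
      kinds <- c(kinds, "f3")
    }
  }
  if (length(pops) >= 4) {
    quads <- utils::combn(pops, 4)
    for (k in seq_len(ncol(quads))) {
      q <- quads[, k]
      arr <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
      for (ar in arr) {
        A <- q[ar[1]]; B <- q[ar[2]]; C <- q[ar[3]]; D <- q[ar[4]]
        rows[[length(rows) + 1L]] <-
          (f2c(A, D) + f2c(B, C) - f2c(A, C) - f2c(B, D)) / 2
        names <- c(names, paste0("f4(", A, ",", B, ";", C, ",", D, ")"))
        kinds <- c(kinds, "f4")
      }
    }
  }
  L <- do.call(rbind, rows)
  rownames(L) <- names
  list(L = L, kind = kinds)
}

#' Fit an admixture graph to observed f-statistics
#'
#' Fits all drift-edge lengths (non-negative generalized least squares) and
#' all free admixture weights of a topology to the observed f2/f3 basis of a
#' frequency table, scoring with `-1/2 d' Q^-1 d` where `d` is the misfit of
#' the basis vector and `Q` its regularized block-jackknife covariance. The
#' residual table spans every f2, f3 and f4 statistic over the leaves; the
#' worst residual is the largest |Z| among them.
#'
#' @param topology an [admix_graph()]; lengths need not be set. Admixture
#'   weights marked `fixed` keep their stated value.
#' @param F a [freq_table()] containing every leaf population.
#' @param blocks a [block_partition()].
#' @param config a [graph_config()].
#' @return An object of class `graph_fit`: `graph` (with fitted parameters),
#'   `score` (log-likelihood, <= 0), `worst_residual`, `residuals` (data
#'   frame: statistic, kind, observed, expected, se, z), `n_snps`,
#'   `n_blocks`, `n_admix`, `base`.
#' @export
fit_graph <- function(topology, F, blocks, config = graph_config()) {
  pops <- unname(topology$leaf_map)
  base <- if (is.null(config$base)) pops[1] else config$base
  basis <- observed_basis(F, pops, blocks, base = base)
  fit_graph_basis(topology, basis, config)
}

#' Fit an admixture graph to a prepared statistic basis
#'
#' Same as [fit_graph()] but takes an [observed_basis()] (or
#' [basis_from_graph()]) directly, so one basis can serve many candidate
#' topologies.
#'
#' @param topology an [admix_graph()].
#' @param basis an `fstat_basis`.
#' @param config a [graph_config()].
#' @return A `graph_fit` (see [fit_graph()]).
#' @export
fit_graph_basis <- function(topology, basis, config = graph_config()) {
  pops <- unname(topology$leaf_map)
  if (!setequal(pops, basis$pops))
    stop("topology leaves and basis populations differ")
  core <- fit_graph_core(topology, basis, config)
  rf <- residual_functionals(basis$spec, basis$base, pops)
  E <- expected_stats(core$graph)
  expected_basis <- vapply(seq_len(nrow(basis$spec)), function(s) {
    if (basis$spec$kind[s] == "f2") exp_f2(E, basis$spec$p1[s],
                                           basis$spec$p2[s])
    else exp_f3(E, basis$spec$p1[s], basis$spec$p2[s], basis$spec$p3[s])
  }, numeric(1))
  obs <- drop(rf$L %*% basis$est)
  expv <- drop(rf$L %*% expected_basis)
  se <- sqrt(pmax(rowSums((rf$L %*% basis$cov) * rf$L), 0))
  z <- ifelse(se > 0, (obs - expv) / se, 0)
  residuals <- data.frame(statistic = rownames(rf$L), kind = rf$kind,
                          observed = obs, expected = expv, se = se, z = z,
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(graph = core$graph, score = core$score,
                 worst_residual = max(abs(z)), residuals = residuals,
                 n_snps = basis$n_snps, n_blocks = basis$n_blocks,
                 n_admix = n_admix(core$graph), base = basis$base),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf(
    "graph_fit: score %.3f, worst residual %.2f SE, %d admixture event(s)\n",
    x$score, x$worst_residual, x$n_admix))
  worst <- x$residuals[which.max(abs(x$residuals$z)), ]
  cat("  worst statistic:", worst$statistic,
      sprintf("(obs %.5f, exp %.5f, Z %.2f)\n",
              worst$observed, worst$expected, worst$z))
  invisible(x)
}

# Internal ("backbone") drift edges whose fitted length is (numerically)
# zero signal an unresolved trifurcation. Leaf edges (including the target's
# attachment leg) are never counted, and neither are the root's child
# edges: only the sum of the two basal edges is identifiable from
# f-statistics, so one of them fitting to zero is a parameterization
# artifact, not a topological degeneracy.
backbone_zero <- function(g, zero_tol = 1e-7) {
  backbone <- !(g$edges$child %in% g$leaves) & g$edges$parent != g$root
  any(backbone & g$edges$length <= zero_tol)
}

has_trifurcation <- function(fit, zero_tol = 1e-7) {
  backbone_zero(fit$graph, zero_tol)
}

#' Compare two graph fits with the model-selection cut-offs
#'
#' Fits with different admixture counts: the more complex model is preferred
#' only if it gains more than 10 log-likelihood units or reduces the worst
#' residual by more than 0.5 standard errors; otherwise the simpler model is
#' preferred. Fits with equal admixture counts within 3 log-units of one
#' another are tied (both retained); otherwise the higher likelihood wins.
#' A fit containing a trifurcation (a zero-length internal drift edge) is
#' discarded before comparison.
#'
#' @param A,B `graph_fit` objects on the same data and SNP set.
#' @param zero_tol zero-length tolerance for the trifurcation rule.
#' @return A list of class `comparison_verdict`: `preferred` (`"A"`, `"B"`
#'   or `"tie"`), `rule_applied` (one of `delta_ll_10`, `worst_resid_0.5`,
#'   `delta_ll_3`, `trifurcation_filter`), `margin`.
#' @export
compare_fits <- function(A, B, zero_tol = 1e-7) {
  if (!is.na(A$n_snps) && !is.na(B$n_snps) && A$n_snps != B$n_snps)
    stop("fits computed on different SNP sets (",
         A$n_snps, " vs ", B$n_snps, ")")
  tri_a <- has_trifurcation(A, zero_tol)
  tri_b <- has_trifurcation(B, zero_tol)
  verdict <- function(preferred, rule, margin)
    structure(list(preferred = preferred, rule_applied = rule,
                   margin = margin), class = "comparison_verdict")
  if (tri_a || tri_b) {
    if (tri_a && tri_b) return(verdict("tie", "trifurcation_filter", 0))
    return(verdict(if (tri_a) "B" else "A", "trifurcation_filter", NA_real_))
  }
  if (A$n_admix == B$n_admix) {
    d <- A$score - B$score
    if (abs(d) <= 3) return(verdict("tie", "delta_ll_3", abs(d)))
    return(verdict(if (d > 0) "A" else "B", "delta_ll_3", abs(d)))
  }
  simple <- if (A$n_admix < B$n_admix) "A" else "B"
  complexm <- setdiff(c("A", "B"), simple)
  fs <- if (simple == "A") A else B
  fc <- if (simple == "A") B else A
  ll_gain <- fc$score - fs$score
  wr_gain <- fs$worst_residual - fc$worst_residual
  if (ll_gain > 10) return(verdict(complexm, "delta_ll_10", ll_gain))
  if (wr_gain > 0.5) return(verdict(complexm, "worst_resid_0.5", wr_gain))
  verdict(simple, "delta_ll_10", ll_gain)
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat("comparison_verdict: prefer", x$preferred, "by rule", x$rule_applied,
      if (!is.na(x$margin)) sprintf("(margin %.3g)", x$margin) else "", "\n")
  invisible(x)
}
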