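test_that("f2 matches hand oracles with and without bias correction", {
  # identical frequencies, exact counts, correction off: estimate and se 0
  p <- rbind(A = c(.1, .5, .9), B = c(.1, .5, .9))
  F <- make_freqs(p)
  b <- make_blocks(3, 3)
  f <- estimate_f2(F, "A", "B", b, corrected = FALSE)
  expect_equal(f$estimate, 0)
  expect_equal(f$se, 0)
  # 3-SNP uncorrected oracle: mean of squared differences
  F2 <- make_freqs(rbind(A = c(.1, .5, .9), B = c(.2, .4, .8)))
  f2 <- estimate_f2(F2, "A", "B", b, corrected = FALSE)
  expect_equal(f2$estimate, mean(c(.01, .01, .01)), tolerance = 1e-12)
  # corrected single-SNP value: direct evaluation of the per-SNP formula
  F3 <- freq_table(c("A", "B"), make_snps(2),
                   count1 = rbind(c(10, 10), c(10, 10)),
                   total = rbind(c(20, 20), c(20, 20)))
  f3 <- estimate_f2(F3, "A", "B", make_blocks(2, 2))
  term <- 0 - (0.25 * 20 / 19) / 20 - (0.25 * 20 / 19) / 20
  expect_equal(f3$estimate, term, tolerance = 1e-12)
  expect_equal(f3$estimate, -0.02631578947, tolerance = 1e-9)
  expect_error(estimate_f2(F, "A", "A", b), "differ")
})

test_that("f3 matches hand oracles and reduces to f2 when A = B", {
  b <- make_blocks(3, 3)
  p <- rbind(X = c(.3, .3, .7), A = c(.1, .5, .9), B = c(.2, .4, .8))
  F <- make_freqs(p)
  f <- estimate_f3(F, "X", "A", "B", b, corrected = FALSE)
  expect_equal(f$estimate, mean(c(.2 * .1, -.2 * -.1, -.2 * -.1)),
               tolerance = 1e-12)
  # f3(X; A, A') = f2(X, A) when A' duplicates A (correction off)
  p2 <- rbind(X = c(.3, .6), A = c(.1, .5), A2 = c(.1, .5))
  F2 <- make_freqs(p2)
  b2 <- make_blocks(2, 2)
  expect_equal(estimate_f3(F2, "X", "A", "A2", b2, corrected = FALSE)$estimate,
               estimate_f2(F2, "X", "A", b2, corrected = FALSE)$estimate,
               tolerance = 1e-12)
})

test_that("f4 obeys the hand oracle, antisymmetry and the zero case", {
  b <- make_blocks(3, 3)
  p <- rbind(A = c(.1, .5, .9), B = c(.2, .4, .8),
             C = c(.3, .3, .7), D = c(.4, .2, .6), D2 = c(.4, .2, .6))
  F <- make_freqs(p)
  f <- estimate_f4(F, "A", "B", "C", "D", b)
  expect_equal(f$estimate, mean(c(-.1 * -.1, .1 * .1, .1 * .1)),
               tolerance = 1e-12)
  expect_equal(f$estimate, 0.01, tolerance = 1e-12)
  # swapping C and D negates the estimate, se unchanged
  fswap <- estimate_f4(F, "A", "B", "D", "C", b)
  expect_equal(fswap$estimate, -f$estimate, tolerance = 1e-15)
  expect_equal(fswap$se, f$se, tolerance = 1e-15)
  # C = D (duplicated frequencies): exactly 0 with zero se
  fz <- estimate_f4(F, "A", "B", "D", "D2", b)
  expect_equal(fz$estimate, 0)
  expect_equal(fz$se, 0)
  expect_error(estimate_f4(F, "A", "A", "C", "D", b), "!=")
})

test_that("linear identities hold exactly, corrections included", {
  set.seed(33)
  n <- 400
  p <- matrix(runif(4 * n, .05, .95), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  tot <- matrix(sample(c(8L, 12L, 20L), 4 * n, replace = TRUE), nrow = 4)
  F <- freq_table(rownames(p), make_snps(n), round(p * tot), tot)
  b <- make_blocks(n, 10)
  f2 <- function(x, y) estimate_f2(F, x, y, b)$estimate
  f3 <- function(x, y, z) estimate_f3(F, x, y, z, b)$estimate
  f4 <- function(w, x, y, z) estimate_f4(F, w, x, y, z, b)$estimate
  tol <- 1e-12
  expect_equal(f3("A", "B", "C"), (f2("A", "B") + f2("A", "C") - f2("B", "C")) / 2,
               tolerance = tol)
  expect_equal(f4("A", "B", "C", "D"),
               (f2("A", "D") + f2("B", "C") - f2("A", "C") - f2("B", "D")) / 2,
               tolerance = tol)
  expect_equal(f4("A", "B", "C", "D"), f4("C", "D", "A", "B"), tolerance = tol)
  expect_equal(f4("A", "B", "C", "D"), -f4("B", "A", "C", "D"), tolerance = tol)
})

test_that("block jackknife reproduces delete-one recomputation", {
  # equal weights: reduces to the unweighted delete-one jackknife
  est <- c(1.2, 0.8, 1.1, 0.9, 1.0)
  jk <- block_jackknife(est, rep(10, 5))
  loo <- vapply(1:5, function(j) mean(est[-j]), numeric(1))
  se_ref <- sqrt((5 - 1) / 5 * sum((loo - mean(loo))^2))
  expect_equal(jk$mean, mean(est))
  expect_equal(jk$se, se_ref, tolerance = 1e-12)
  # all blocks equal: zero variance
  expect_equal(block_jackknife(rep(2.5, 4), c(3, 5, 2, 9))$se, 0)
  # unequal weights: literal delete-one recomputation over pooled values
  set.seed(4)
  w <- c(5, 9, 3, 14, 7)
  vals <- lapply(w, function(m) rnorm(m))
  bmeans <- vapply(vals, mean, numeric(1))
  jk2 <- block_jackknife(bmeans, w)
  all_mean <- mean(unlist(vals))
  expect_equal(jk2$mean, all_mean, tolerance = 1e-12)
  n <- sum(w); g <- 5
  loo <- vapply(1:5, function(j) mean(unlist(vals[-j])), numeric(1))
  theta_j <- g * all_mean - sum((1 - w / n) * loo)
  h <- n / w
  tau <- h * all_mean - (h - 1) * loo
  expect_equal(jk2$se, sqrt(sum((tau - theta_j)^2 / (h - 1)) / g),
               tolerance = 1e-12)
  expect_error(block_jackknife(1, 1), "2 blocks")
})

test_that("jackknife SE tracks the sampling SD of estimated f2", {
  # moderate drift, interior root law: clamping negligible
  g <- parse_graph(c("edge a R A 0.03", "edge b R B 0.05"))
  spec <- sim_spec(g, n_snps = 5e3, samples_per_pop = 10,
                   root_freq_law = c(0.2, 0.8), n_chromosomes = 2,
                   map_length = 0.5)
  ests <- ses <- numeric(60)
  set.seed(17)
  for (r in 1:60) {
    s <- sample.int(1e6, 1)
    sim <- simulate_graph_freqs(spec, seed = s)
    G <- sample_genotypes(sim, seed = s + 1)
    F <- pop_freqs(G)
    b <- assign_blocks(G$snps)
    f <- estimate_f2(F, "A", "B", b)
    ests[r] <- f$estimate; ses[r] <- f$se
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.25)
  # and the estimates centre on the closed-form raw-scale truth
  tr <- truth_stats(spec)
  zdev <- (mean(ests) - exp_f2(tr$expectation, "A", "B")) /
    (sd(ests) / sqrt(60))
  expect_lt(abs(zdev), 4)
})

test_that("drift biplot reports collinear points as zero deviations", {
  # construct frequencies whose f3 statistics are exactly collinear:
  # identical x and y coordinates for duplicated populations
  set.seed(51)
  n <- 300
  out <- runif(n, .3, .7)
  mk <- function(shift) pmin(pmax(out + rnorm(n, 0, sqrt(shift * out * (1 - out))), 0), 1)
  p <- rbind(Out = out, RefA = mk(.04), RefB = mk(.04),
             T1 = mk(.02), T2 = mk(.03), T3 = mk(.05))
  p <- rbind(p, T1dup = p["T1", ])
  F <- make_freqs(p)
  b <- make_blocks(n, 5)
  bp <- drift_biplot(F, "Out", "RefA", "RefB",
                     tests = c("T1", "T2", "T3", "T1dup"),
                     trend_set = c("T1", "T2", "T3"), blocks = b)
  # a duplicated trend member deviates exactly as its twin
  expect_equal(bp$deviation[bp$test_population == "T1dup"],
               bp$deviation[bp$test_population == "T1"], tolerance = 1e-10)
  # trend-set residuals from a 3-point OLS fit sum to ~0
  expect_lt(abs(sum(bp$deviation[1:3])), 1e-12)
  expect_error(drift_biplot(F, "Out", "RefA", "RefB",
                            tests = c("T1", "T2"), blocks = b),
               "at least 3")
})

test_that("extra shared drift with refB's clade shows as positive deviation", {
  F <- cached("biplot_sim", {
    sim_preset_data(mix = c(esea = 0.7, nega = 0, sas = 0.3),
                    n_snps = 2e4, seed = 23)
  })
  # the South Asian-like leaf carries half its ancestry from the
  # Iranian-related branch: far above the East Eurasian trend vs IranN
  bp <- drift_biplot(F$F, "African", "ESEA1", "IranN",
                     tests = c("ESEA2", "ESEA3", "Onge", "Papuan", "SAS"),
                     trend_set = c("ESEA2", "ESEA3", "Onge", "Papuan"),
                     blocks = F$blocks)
  tgt <- bp[bp$test_population == "SAS", ]
  expect_gt(tgt$deviation, 0)
  expect_gt(tgt$deviation / tgt$deviation_se, 3)
  # trend-set deviations centre on zero and are dwarfed by the outlier
  trend <- bp[bp$test_population != "SAS", ]
  expect_lt(abs(mean(trend$deviation / trend$deviation_se)), 1.5)
  expect_gt(tgt$deviation, 5 * max(abs(trend$deviation)))
})

test_that("estimated statistics land within 3 SE of the closed form", {
  # 5-leaf tree with interior root law; checks the generator/estimator
  # agreement end to end across many statistics
  g <- tree5()
  spec <- sim_spec(g, n_snps = 4e4, samples_per_pop = 15,
                   root_freq_law = c(0.2, 0.8), n_chromosomes = 4,
                   map_length = 1)
  sim <- simulate_graph_freqs(spec, seed = 29)
  G <- sample_genotypes(sim, seed = 30)
  F <- pop_freqs(G)
  b <- assign_blocks(G$snps)
  tr <- truth_stats(spec)
  zs <- c()
  for (pair in list(c("A", "B"), c("A", "E"), c("C", "D"), c("B", "D"))) {
    f <- estimate_f2(F, pair[1], pair[2], b)
    zs <- c(zs, (f$estimate - exp_f2(tr$expectation, pair[1], pair[2])) / f$se)
  }
  f3 <- estimate_f3(F, "E", "A", "C", b)
  zs <- c(zs, (f3$estimate - exp_f3(tr$expectation, "E", "A", "C")) / f3$se)
  f4 <- estimate_f4(F, "A", "B", "C", "D", b)
  zs <- c(zs, (f4$estimate - exp_f4(tr$expectation, "A", "B", "C", "D")) / f4$se)
  expect_true(all(abs(zs) < 3.5))
})
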