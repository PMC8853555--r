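test_that("EIGENSTRAT fixtures decode per the documented digit code", {
  d <- withr::local_tempdir()
  writeLines(c("02", "19", "20"), file.path(d, "fix.geno"))
  writeLines(c("rs1\t1\t0.0\t100\tA\tG",
               "rs2\t1\t0.1\t200\tC\tT",
               "rs3\t1\t0.2\t300\tG\tA"), file.path(d, "fix.snp"))
  writeLines(c("s1\tU\tPopA", "s2\tU\tPopB"), file.path(d, "fix.ind"))
  G <- read_genotypes(file.path(d, "fix"), "eigenstrat")
  expect_equal(unname(G$calls),
               matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3))
  expect_equal(G$samples$population, c("PopA", "PopB"))
  expect_equal(G$snps$genetic_pos, c(0, 0.1, 0.2))
  # dimension mismatch names the offending file
  writeLines(c("02", "19"), file.path(d, "fix.geno"))
  expect_error(read_genotypes(file.path(d, "fix"), "eigenstrat"), "geno")
  # unknown genotype symbol is located
  writeLines(c("02", "17", "20"), file.path(d, "fix.geno"))
  expect_error(read_genotypes(file.path(d, "fix"), "eigenstrat"),
               "SNP 2.*sample 2")
})

test_that("a hand-packed PLINK .bed matches the EIGENSTRAT decode", {
  d <- withr::local_tempdir()
  # same 3 SNP x 2 sample matrix as the EIGENSTRAT fixture:
  # calls (copies of allele1): snp1 (0,2), snp2 (1,NA), snp3 (2,0)
  # two-bit codes, sample1 in bits 0-1: 0->11, 2->00, 1->10, NA->01
  bytes <- as.raw(c(0x6c, 0x1b, 0x01,
                    0x03,          # 11 00 -> (0, 2)
                    0x06,          # 10 01 -> (1, NA)
                    0x0c))         # 00 11 -> (2, 0)
  writeBin(bytes, file.path(d, "fix.bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG",
               "1\trs2\t10\t200\tC\tT",
               "1\trs3\t20\t300\tG\tA"), file.path(d, "fix.bim"))
  writeLines(c("PopA\ts1\t0\t0\t0\t-9",
               "PopB\ts2\t0\t0\t0\t-9"), file.path(d, "fix.fam"))
  G <- read_genotypes(file.path(d, "fix"), "plink")
  expect_equal(unname(G$calls),
               matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3))
  expect_equal(G$samples$population, c("PopA", "PopB"))
  # .bim centiMorgans converted to Morgans
  expect_equal(G$snps$genetic_pos, c(0, 0.1, 0.2))
})

test_that("write/read round-trips are the identity in both formats", {
  set.seed(71)
  calls <- matrix(sample(c(0:2, NA), 50 * 10, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 50)
  G <- make_geno(calls, populations = rep(c("X", "Y"), each = 5),
                 n_chrom = 2)
  d <- withr::local_tempdir()
  for (fmt in c("eigenstrat", "plink")) {
    write_genotypes(G, file.path(d, fmt), fmt)
    G2 <- read_genotypes(file.path(d, fmt), fmt)
    expect_equal(unname(G2$calls), unname(G$calls), info = fmt)
    expect_equal(G2$samples, G$samples, info = fmt)
    expect_equal(G2$snps$snp_id, G$snps$snp_id, info = fmt)
    expect_equal(G2$snps$genetic_pos, G$snps$genetic_pos,
                 tolerance = 1e-12, info = fmt)
    expect_equal(G2$snps$allele1, G$snps$allele1, info = fmt)
  }
  # degenerate writes refused
  empty <- G; empty$calls <- G$calls[, 0, drop = FALSE]
  empty$samples <- G$samples[0, ]
  expect_error(write_genotypes(empty, file.path(d, "z"), "eigenstrat"),
               "no samples")
  # 1x1 matrix writes the bare digit
  g1 <- make_geno(matrix(2L, 1, 1))
  write_genotypes(g1, file.path(d, "one"), "eigenstrat")
  expect_identical(readLines(file.path(d, "one.geno")), "2")
})

test_that("filter_sites retains sites at or below the missingness bound", {
  # 20 samples, 1 missing call = 5% exactly: retained at threshold 0.05
  calls <- matrix(1L, nrow = 3, ncol = 20)
  calls[2, 1] <- NA            # 5% missing
  calls[3, 1:2] <- NA          # 10% missing
  G <- make_geno(calls)
  kept <- filter_sites(G, 0.05)
  expect_equal(kept$snps$snp_id, c("rs1", "rs2"))
  expect_equal(ncol(kept$calls), 20)   # samples unchanged
  expect_error(filter_sites(G, 1.5), "max_missing")
})

test_that("filter_sites matches a brute-force recount and is idempotent", {
  set.seed(5)
  calls <- matrix(sample(c(0:2, NA), 500 * 50, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 500)
  G <- make_geno(calls)
  out <- filter_sites(G, 0.05)
  keep_brute <- vapply(seq_len(nrow(calls)), function(i)
    sum(is.na(calls[i, ])) / 50 <= 0.05, logical(1))
  expect_equal(out$snps$snp_id, G$snps$snp_id[keep_brute])
  expect_equal(filter_sites(out, 0.05)$calls, out$calls)
})

test_that("ld_prune removes later members of correlated pairs", {
  set.seed(8)
  base <- matrix(sample(0:2, 40 * 30, replace = TRUE), nrow = 40)
  base[2, ] <- base[1, ]            # perfect duplicate pair
  G <- make_geno(base)
  out <- ld_prune(G, window = 10, step = 5, r2_max = 0.5)
  expect_true("rs1" %in% out$snps$snp_id)
  expect_false("rs2" %in% out$snps$snp_id)
  # mutually independent SNPs all survive
  set.seed(9)
  indep <- matrix(rbinom(30 * 60, 2, 0.5), nrow = 30)
  G2 <- make_geno(indep)
  expect_gte(nrow(ld_prune(G2, 10, 5, 0.95)$calls), 29)
  expect_error(ld_prune(G, window = 3, step = 5), "window")
})

test_that("ld_prune equals a window-replay oracle and is idempotent", {
  set.seed(13)
  n <- 200
  calls <- matrix(sample(0:2, n * 40, replace = TRUE), nrow = n)
  for (i in seq(5, 195, by = 13)) {   # plant correlated neighbours
    calls[i + 1, ] <- calls[i, ]
    flip <- sample(40, 4)
    calls[i + 1, flip] <- sample(0:2, 4, replace = TRUE)
  }
  G <- make_geno(calls)
  out <- ld_prune(G, window = 50, step = 5, r2_max = 0.5)
  # independent replay of the documented greedy rule
  keep <- rep(TRUE, n)
  for (s in seq(1, n, by = 5)) {
    w <- s:min(s + 49, n)
    for (a in w) for (b in w) {
      if (a < b && keep[a] && keep[b]) {
        r2 <- suppressWarnings(cor(calls[a, ], calls[b, ],
                                   use = "pairwise.complete.obs"))^2
        if (isTRUE(r2 > 0.5)) keep[b] <- FALSE
      }
    }
  }
  expect_equal(out$snps$snp_id, G$snps$snp_id[keep])
  again <- ld_prune(out, window = 50, step = 5, r2_max = 0.5)
  expect_equal(again$snps$snp_id, out$snps$snp_id)
})

test_that("pop_freqs counts allele copies over non-missing calls", {
  G <- make_geno(matrix(c(2L, 1L, NA, 0L), nrow = 2),
                 populations = c("A", "A"))
  F <- pop_freqs(G)
  # SNP 1: calls (2, NA) -> count 2 of 2; SNP 2: (1, 0) -> 1 of 4
  expect_equal(unname(F$count1[1, ]), c(2, 1))
  expect_equal(unname(F$total[1, ]), c(2, 4))
  expect_equal(unname(F$freq[1, ]), c(1, 0.25))
  expect_error(pop_freqs(G, "Nope"), "known")
})

test_that("pop_freqs equals a per-sample tally on random data", {
  set.seed(21)
  calls <- matrix(sample(c(0:2, NA), 500 * 30, replace = TRUE), nrow = 500)
  G <- make_geno(calls, populations = rep(c("A", "B", "C"), each = 10))
  F <- pop_freqs(G, c("B", "A"))
  bcols <- 11:20
  cnt <- rowSums(calls[, bcols], na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(calls[, bcols]))
  expect_equal(unname(F$count1["B", ]), cnt)
  expect_equal(unname(F$total["B", ]), tot)
  expect_true(all(F$total <= 2 * 10))
  expect_true(all(is.nan(F$freq[F$total == 0])))
})

test_that("assign_blocks follows the start-anchored rule", {
  snps <- make_snps(4, gpos = c(0, 0.03, 0.06, 0.09))
  b <- assign_blocks(snps, 0.05)
  expect_equal(b$block_of, c(1L, 1L, 2L, 2L))
  # all SNPs at one position: a single block
  b1 <- assign_blocks(make_snps(10, gpos = rep(0.42, 10)), 0.05)
  expect_equal(b1$n_blocks, 1L)
  expect_equal(b1$block_sizes, 10L)
  # blocks never cross a chromosome boundary
  snps2 <- make_snps(40, n_chrom = 2, map_length = 0.02)
  b2 <- assign_blocks(snps2, 0.05)
  expect_gte(b2$n_blocks, 2L)
  expect_true(all(tapply(snps2$chromosome, b2$block_of,
                         function(x) length(unique(x))) == 1))
  # contiguity: concatenating blocks reconstructs the SNP order
  expect_true(all(diff(b2$block_of) %in% c(0L, 1L)))
  expect_equal(sum(b2$block_sizes), 40L)
  expect_error(assign_blocks(snps, -0.1), "non-negative")
})

test_that("merge_genotypes intersects SNPs and flips swapped alleles", {
  A <- make_geno(matrix(c(0L, 1L, 2L), 3, 2), populations = c("X", "X"))
  Bc <- matrix(c(2L, 0L, 1L, 1L), 2, 2)
  snpsB <- make_snps(2)
  snpsB$snp_id <- c("rs2", "rs3")
  snpsB$allele1 <- c("G", "T")   # rs2 swapped relative to A, rs3 mismatched
  snpsB$allele2 <- c("A", "C")
  B <- genotype_matrix(Bc, snpsB,
                       data.frame(sample_id = c("t1", "t2"),
                                  population = "Y"))
  M <- merge_genotypes(A, B)
  expect_equal(M$snps$snp_id, "rs2")        # rs3 dropped: allele mismatch
  expect_equal(unname(M$calls), matrix(c(1L, 1L, 0L, 1L), nrow = 1))
  expect_equal(M$samples$population, c("X", "X", "Y", "Y"))
})
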