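#' Filter SNPs by per-site missingness
#'
#' Retains exactly the SNPs whose missing-call fraction across all samples is
#' less than or equal to `max_missing` (boundary inclusive, mirroring
#' removal-above-threshold semantics). The sample set is unchanged.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction per SNP, in
#'   \[0, 1\]. Default 0.05.
#' @return A filtered [genotype_matrix()].
#' @export
filter_sites <- function(G, max_missing = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1)
    stop("max_missing must lie in [0, 1]")
  keep <- rowMeans(is.na(G$calls)) <= max_missing
  genotype_matrix(G$calls[keep, , drop = FALSE],
                  G$snps[keep, , drop = FALSE], G$samples)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` SNPs, for every pair of retained SNPs with
#' squared genotype correlation above `r2_max` the later-indexed SNP is
#' removed; the window then advances by `step` SNPs. Windows never span a
#' chromosome boundary and the result is deterministic for a fixed input
#' order. Correlations use pairwise-complete genotype calls.
#'
#' @param G a [genotype_matrix()] with SNPs sorted by chromosome then
#'   physical position.
#' @param window window size in SNPs (default 50).
#' @param step window step in SNPs (default 5).
#' @param r2_max squared-correlation threshold above which the later SNP of
#'   a pair is removed (default 0.5).
#' @return A pruned [genotype_matrix()].
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (window < step) stop("window must be >= step")
  keep <- rep(TRUE, nrow(G$calls))
  for (chr in unique(G$snps$chromosome)) {
    idx <- which(G$snps$chromosome == chr)
    n <- length(idx)
    starts <- if (n <= window) 1L else seq.int(1L, n, by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1L, n)]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      r2 <- suppressWarnings(
        stats::cor(G$calls[w, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))^2
      for (a in seq_len(length(w) - 1L)) {
        if (!keep[w[a]]) next
        for (b in seq.int(a + 1L, length(w))) {
          if (keep[w[b]] && isTRUE(r2[a, b] > r2_max)) keep[w[b]] <- FALSE
        }
      }
    }
  }
  genotype_matrix(G$calls[keep, , drop = FALSE],
                  G$snps[keep, , drop = FALSE], G$samples)
}

#' Per-population allele counts and frequencies
#'
#' Counts copies of allele1 among non-missing calls in each requested
#' population. Sites where a population has no non-missing calls get
#' `total = 0` and an undefined (`NaN`) frequency.
#'
#' @param G a [genotype_matrix()].
#' @param populations population labels to tabulate; defaults to all
#'   populations present.
#' @return A [freq_table()].
#' @export
pop_freqs <- function(G, populations = unique(G$samples$population)) {
  stopifnot(inherits(G, "genotype_matrix"))
  known <- unique(G$samples$population)
  unknown <- setdiff(populations, known)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(known, collapse = ", "))
  n_snp <- nrow(G$calls)
  count1 <- total <- matrix(0, nrow = length(populations), ncol = n_snp)
  for (i in seq_along(populations)) {
    cols <- which(G$samples$population == populations[i])
    sub <- G$calls[, cols, drop = FALSE]
    count1[i, ] <- rowSums(sub, na.rm = TRUE)
    total[i, ] <- 2 * rowSums(!is.na(sub))
  }
  freq_table(populations, G$snps, count1, total)
}

#' Merge two genotype datasets on shared SNPs
#'
#' Intersects SNPs by id, harmonizes alleles by allele-pair match allowing an
#' allele1/allele2 swap (in which case calls of the second dataset are
#' flipped, `2 - call`), and drops SNPs whose allele pairs do not match
#' either way.
#'
#' @param A,B two [genotype_matrix()] objects with disjoint sample ids.
#' @return A merged [genotype_matrix()] over the harmonized SNP
#'   intersection, with `A`'s SNP metadata and the samples of both inputs.
#' @export
merge_genotypes <- function(A, B) {
  stopifnot(inherits(A, "genotype_matrix"), inherits(B, "genotype_matrix"))
  if (length(intersect(A$samples$sample_id, B$samples$sample_id)))
    stop("sample ids overlap between datasets")
  common <- intersect(A$snps$snp_id, B$snps$snp_id)
  ia <- match(common, A$snps$snp_id)
  ib <- match(common, B$snps$snp_id)
  same <- A$snps$allele1[ia] == B$snps$allele1[ib] &
    A$snps$allele2[ia] == B$snps$allele2[ib]
  swapped <- A$snps$allele1[ia] == B$snps$allele2[ib] &
    A$snps$allele2[ia] == B$snps$allele1[ib]
  keep <- same | swapped
  ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]
  cb <- B$calls[ib, , drop = FALSE]
  if (any(swapped)) cb[swapped, ] <- 2L - cb[swapped, , drop = FALSE]
  genotype_matrix(cbind(A$calls[ia, , drop = FALSE], cb),
                  A$snps[ia, , drop = FALSE],
                  rbind(A$samples, B$samples))
}
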