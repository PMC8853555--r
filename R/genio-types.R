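#' Construct a genotype matrix
#'
#' The basic container for diploid biallelic SNP data. Calls count copies of
#' `allele1` at each site, so each non-missing call is 0, 1 or 2; missing
#' calls are `NA`. Calls are stored SNP-major (rows = SNPs, columns =
#' samples), matching the on-disk layout of both supported formats.
#'
#' @param calls integer matrix, SNPs x samples, values in \{0, 1, 2, NA\}.
#' @param snps data frame with columns `snp_id`, `chromosome`, `genetic_pos`
#'   (Morgans), `physical_pos` (base pairs), `allele1`, `allele2`.
#' @param samples data frame with columns `sample_id`, `population`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req_snp <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
               "allele1", "allele2")
  if (!all(req_snp %in% names(snps)))
    stop("snps must have columns: ", paste(req_snp, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id, population")
  if (nrow(calls) != nrow(snps))
    stop("calls has ", nrow(calls), " rows but snps describes ",
         nrow(snps), " SNPs")
  if (ncol(calls) != nrow(samples))
    stop("calls has ", ncol(calls), " columns but samples describes ",
         nrow(samples), " samples")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing calls must be 0, 1 or 2")
  if (any(snps$allele1 == snps$allele2))
    stop("allele1 must differ from allele2 at every SNP")
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "SNPs x", ncol(x$calls),
      "samples;", length(unique(x$samples$population)), "populations\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-population allele counts and frequencies
#'
#' @param populations character vector of population labels (row order of the
#'   count matrices).
#' @param snps SNP metadata data frame (as in [genotype_matrix()]).
#' @param count1 populations x SNPs matrix of observed copies of allele1.
#' @param total populations x SNPs matrix of observed allele counts
#'   (2 x non-missing samples).
#' @return An object of class `freq_table` with a `freq` matrix that is `NaN`
#'   where `total` is 0 (frequency undefined there).
#' @export
freq_table <- function(populations, snps, count1, total) {
  count1 <- as.matrix(count1); total <- as.matrix(total)
  if (!identical(dim(count1), dim(total)))
    stop("count1 and total must have identical dimensions")
  if (length(populations) != nrow(count1))
    stop("populations length must match matrix rows")
  if (any(count1 < 0) || any(count1 > total))
    stop("need 0 <= count1 <= total")
  freq <- count1 / total  # NaN where total == 0: frequency undefined
  rownames(count1) <- rownames(total) <- rownames(freq) <- populations
  structure(list(populations = populations, snps = snps,
                 count1 = count1, total = total, freq = freq),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", length(x$populations), "populations x",
      ncol(x$freq), "SNPs\n")
  cat("  populations:", paste(utils::head(x$populations, 8), collapse = ", "),
      if (length(x$populations) > 8) "..." else "", "\n")
  invisible(x)
}

#' Assign SNPs to contiguous jackknife blocks
#'
#' Blocks are start-anchored: a block opens at its first SNP's genetic
#' position and accepts subsequent SNPs within `block_span` Morgans of that
#' anchor; the next SNP beyond the span opens a new block. Blocks never cross
#' a chromosome boundary. If genetic positions carry no information (all
#' missing or constant), the function falls back to 5 Mb physical-position
#' spans and says so.
#'
#' @param snps SNP metadata data frame, sorted by chromosome then physical
#'   position.
#' @param block_span block width in Morgans (default 0.05).
#' @return An object of class `block_partition`: `block_of` (SNP index ->
#'   block index), `block_sizes`, `block_span` (Morgans actually spanned per
#'   block), `n_blocks`.
#' @export
assign_blocks <- function(snps, block_span = 0.05) {
  if (block_span < 0) stop("block_span must be non-negative")
  n <- nrow(snps)
  if (n == 0L) stop("no SNPs to block")
  gp <- snps$genetic_pos
  fallback <- all(is.na(gp)) ||
    isTRUE(max(gp, na.rm = TRUE) == min(gp, na.rm = TRUE)) && n > 1L
  if (fallback && n > 1L) {
    message("genetic positions absent or constant; ",
            "falling back to 5 Mb physical blocks")
    gp <- snps$physical_pos
    span <- 5e6
  } else {
    span <- block_span
  }
  block_of <- integer(n)
  blk <- 0L
  chrs <- snps$chromosome
  i <- 1L
  while (i <= n) {
    blk <- blk + 1L
    anchor <- gp[i]
    chr <- chrs[i]
    j <- i
    while (j <= n && chrs[j] == chr && gp[j] - anchor <= span) {
      block_of[j] <- blk
      j <- j + 1L
    }
    i <- j
  }
  sizes <- tabulate(block_of, nbins = blk)
  spans <- vapply(seq_len(blk), function(b) {
    idx <- which(block_of == b)
    max(gp[idx]) - min(gp[idx])
  }, numeric(1))
  structure(list(block_of = block_of, block_sizes = sizes,
                 block_span = spans, n_blocks = blk),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block_partition:", x$n_blocks, "blocks,",
      sum(x$block_sizes), "SNPs (block sizes",
      min(x$block_sizes), "-", max(x$block_sizes), ")\n")
  invisible(x)
}
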