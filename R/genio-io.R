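#' Read genotypes from EIGENSTRAT or PLINK binary files
#'
#' EIGENSTRAT prefix expands to `.geno` (one text line per SNP, one digit per
#' sample; 0/1/2 copies of allele1, 9 = missing), `.snp` (id, chromosome,
#' genetic position in Morgans, physical position, allele1, allele2) and
#' `.ind` (id, sex, population). PLINK prefix expands to `.bed`/`.bim`/`.fam`
#' per the published binary specification; the `.bim` genetic-distance column
#' is read as centiMorgans and converted to Morgans, and the `.fam` family-id
#' column is taken as the population label.
#'
#' @param prefix path prefix of the three component files.
#' @param format `"eigenstrat"` or `"plink"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(prefix, format = c("eigenstrat", "plink")) {
  format <- match.arg(format)
  if (format == "eigenstrat") read_eigenstrat(prefix) else read_plink(prefix)
}

#' Write genotypes to EIGENSTRAT or PLINK binary files
#'
#' Inverse of [read_genotypes()]: the written files round-trip exactly
#' (calls, SNP metadata, sample metadata).
#'
#' @param G a [genotype_matrix()].
#' @inheritParams read_genotypes
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(G, prefix, format = c("eigenstrat", "plink")) {
  format <- match.arg(format)
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$calls) == 0L) stop("refusing to write a matrix with no samples")
  if (nrow(G$calls) == 0L) stop("refusing to write a matrix with no SNPs")
  if (format == "eigenstrat") write_eigenstrat(G, prefix)
  else write_plink(G, prefix)
  invisible(prefix)
}

read_eigenstrat <- function(prefix) {
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (f in files) if (!file.exists(f)) stop("missing file: ", f)
  snp <- utils::read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
    col.names = c("snp_id", "chromosome", "genetic_pos", "physical_pos",
                  "allele1", "allele2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character"))
  ind <- utils::read.table(files[3], header = FALSE, stringsAsFactors = FALSE,
    col.names = c("sample_id", "sex", "population"),
    colClasses = "character")
  lines <- readLines(files[1])
  if (length(lines) != nrow(snp))
    stop(files[1], " has ", length(lines), " lines but ", files[2],
         " describes ", nrow(snp), " SNPs")
  wid <- nchar(lines)
  if (any(wid != nrow(ind)))
    stop(files[1], " line ", which(wid != nrow(ind))[1], " has ",
         wid[which(wid != nrow(ind))[1]], " genotypes but ", files[3],
         " describes ", nrow(ind), " samples")
  # digits decoded via raw bytes; one line per SNP
  m <- vapply(lines, function(l) as.integer(charToRaw(l)) - 48L,
              integer(nrow(ind)), USE.NAMES = FALSE)
  m <- if (is.matrix(m)) t(m) else matrix(m, nrow = nrow(snp))
  bad <- which(!(m %in% c(0L, 1L, 2L, 9L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop("unknown genotype symbol at SNP ", rc[1], ", sample ", rc[2])
  }
  m[m == 9L] <- NA_integer_
  genotype_matrix(m, snp, ind[c("sample_id", "population")])
}

write_eigenstrat <- function(G, prefix) {
  m <- G$calls
  m[is.na(m)] <- 9L
  ch <- matrix(as.character(m), nrow = nrow(m))
  lines <- do.call(paste0, asplit(ch, 2))
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- G$snps
  utils::write.table(
    data.frame(snp$snp_id, snp$chromosome,
               sprintf("%.12g", snp$genetic_pos),
               snp$physical_pos, snp$allele1, snp$allele2),
    paste0(prefix, ".snp"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(G$samples$sample_id, "U", G$samples$population),
    paste0(prefix, ".ind"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
}

# PLINK .bed two-bit codes (SNP-major): 00 = hom allele1 -> 2 copies,
# 01 = missing, 10 = het -> 1, 11 = hom allele2 -> 0.
.bed_decode <- c(2L, NA_integer_, 1L, 0L)

read_plink <- function(prefix) {
  files <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (f in files) if (!file.exists(f)) stop("missing file: ", f)
  bim <- utils::read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chromosome", "snp_id", "cm", "physical_pos",
                  "allele1", "allele2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character"))
  fam <- utils::read.table(files[3], header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character")
  n_snp <- nrow(bim); n_ind <- nrow(fam)
  raw <- readBin(files[1], "raw", n = file.info(files[1])$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop(files[1], ": not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop(files[1], ": only SNP-major .bed files are supported")
  bps <- ceiling(n_ind / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * n_snp)
    stop(files[1], " has ", length(body), " data bytes but ", files[2],
         "/", files[3], " imply ", bps * n_snp)
  bytes <- as.integer(body)
  dim(bytes) <- c(bps, n_snp)
  calls <- matrix(NA_integer_, nrow = n_snp, ncol = n_ind)
  for (k in 0:3) {
    cols <- seq.int(k + 1L, by = 4L, length.out = ceiling((n_ind - k) / 4))
    cols <- cols[cols <= n_ind]
    if (!length(cols)) next
    byte_row <- ((cols - 1L) %/% 4L) + 1L
    crumbs <- bitwAnd(bitwShiftR(bytes[byte_row, , drop = FALSE], 2L * k), 3L)
    calls[, cols] <- t(matrix(.bed_decode[crumbs + 1L], nrow = length(cols)))
  }
  snp <- data.frame(snp_id = bim$snp_id, chromosome = bim$chromosome,
                    genetic_pos = bim$cm / 100, physical_pos = bim$physical_pos,
                    allele1 = bim$allele1, allele2 = bim$allele2,
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam[[2]], population = fam[[1]],
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, snp, samples)
}

write_plink <- function(G, prefix) {
  m <- G$calls
  n_snp <- nrow(m); n_ind <- ncol(m)
  # call -> crumb: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  enc <- integer(length(m))
  v <- as.vector(m)
  enc[is.na(v)] <- 1L
  enc[!is.na(v) & v == 2L] <- 0L
  enc[!is.na(v) & v == 1L] <- 2L
  enc[!is.na(v) & v == 0L] <- 3L
  bps <- ceiling(n_ind / 4)
  pad <- bps * 4L - n_ind
  crumbs <- matrix(0L, nrow = n_ind + pad, ncol = n_snp)
  crumbs[seq_len(n_ind), ] <- matrix(enc, nrow = n_snp, ncol = n_ind,
                                     byrow = FALSE) |> t()
  i4 <- seq.int(1L, n_ind + pad, by = 4L)
  bytes <- crumbs[i4, , drop = FALSE] +
    4L * crumbs[i4 + 1L, , drop = FALSE] +
    16L * crumbs[i4 + 2L, , drop = FALSE] +
    64L * crumbs[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(G$snps$chromosome, G$snps$snp_id,
               sprintf("%.12g", G$snps$genetic_pos * 100),
               G$snps$physical_pos, G$snps$allele1, G$snps$allele2),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(G$samples$population, G$samples$sample_id, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
}
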