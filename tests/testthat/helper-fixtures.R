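# Shared fixture builders: everything is generated in code at test time.

# SNP metadata for n SNPs spread over n_chrom chromosomes.
make_snps <- function(n, n_chrom = 1, map_length = 1,
                      gpos = NULL) {
  per <- diff(round(seq(0, n, length.out = n_chrom + 1)))
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  if (is.null(gpos))
    gpos <- unlist(lapply(per, function(m) seq(0, map_length,
                                               length.out = max(m, 1))[seq_len(m)]))
  data.frame(snp_id = paste0("rs", seq_len(n)), chromosome = chrom,
             genetic_pos = gpos,
             physical_pos = as.integer(seq_len(n)) * 1000L,
             allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
}

# Genotype matrix from an explicit call matrix (SNPs x samples).
make_geno <- function(calls, populations = NULL, n_chrom = 1) {
  calls <- as.matrix(calls)
  if (is.null(populations)) populations <- rep("P1", ncol(calls))
  genotype_matrix(calls, make_snps(nrow(calls), n_chrom),
                  data.frame(sample_id = paste0("s", seq_len(ncol(calls))),
                             population = populations,
                             stringsAsFactors = FALSE))
}

# Frequency table from an explicit frequency matrix (pops x SNPs) with a
# fixed allele-count per population ("exactly known" frequencies when the
# correction is off, finite-sample when counts are small).
make_freqs <- function(p, total = 1000L) {
  p <- as.matrix(p)
  pops <- rownames(p)
  if (is.null(pops)) pops <- paste0("P", seq_len(nrow(p)))
  tot <- matrix(total, nrow(p), ncol(p))
  freq_table(pops, make_snps(ncol(p)), round(p * tot), tot)
}

# Equal-size contiguous block partition over n SNPs (internal structure).
make_blocks <- function(n, n_blocks) {
  block_of <- sort(rep_len(seq_len(n_blocks), n))
  structure(list(block_of = block_of,
                 block_sizes = tabulate(block_of, n_blocks),
                 block_span = rep(0.05, n_blocks), n_blocks = n_blocks),
            class = "block_partition")
}

# A small 5-leaf tree (no admixture) with set lengths, for graph tests.
tree5 <- function() {
  admix_graph(data.frame(
    label = c("e_out", "e_ab", "e_a", "e_b", "e_cd", "e_c", "e_d", "e_e"),
    parent = c("R", "X", "AB", "AB", "X", "CD", "CD", "R"),
    child = c("X", "AB", "A", "B", "CD", "C", "D", "E"),
    length = c(0.02, 0.015, 0.01, 0.012, 0.018, 0.009, 0.011, 0.05),
    stringsAsFactors = FALSE))
}

# The standard right set used with the bundled preset: differentially
# related to the ESEA, hunter-gatherer and South Asian source branches.
preset_right <- function()
  c("African", "WEur", "IranN", "Papuan", "ESEA1", "Deep1")

# Simulated genotype dataset from a preset-graph target mix; returns
# freq table + blocks. Kept small by default.
sim_preset_data <- function(mix = NULL, n_snps = 1e4, seed = 1,
                            samples = 10, n_chromosomes = 22,
                            map_length = 1.5, ...) {
  g <- preset_graph(target_mix = mix)
  spec <- sim_spec(g, n_snps = n_snps, samples_per_pop = samples,
                   n_chromosomes = n_chromosomes, map_length = map_length,
                   ...)
  sim <- simulate_graph_freqs(spec, seed = seed)
  G <- sample_genotypes(sim, seed = seed + 1)
  list(F = pop_freqs(G), blocks = assign_blocks(G$snps), spec = spec,
       G = G)
}

# Session-level cache for expensive shared simulations.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A skeleton whose candidate-edge count is exactly 33 (the root's child
# edges are excluded by default): a caterpillar tree with 35 drift edges.
skeleton33 <- function() {
  n_int <- 17
  # each internal node hangs one leaf and one deeper internal node
  e <- list()
  e[[1]] <- data.frame(parent = "R", child = "I1")
  e[[2]] <- data.frame(parent = "R", child = "L0")
  for (i in seq_len(n_int)) {
    e[[length(e) + 1L]] <- data.frame(parent = paste0("I", i),
                                      child = paste0("L", i))
    if (i < n_int)
      e[[length(e) + 1L]] <- data.frame(parent = paste0("I", i),
                                        child = paste0("I", i + 1))
  }
  ed <- do.call(rbind, e)
  ed$length <- 0.01
  admix_graph(ed)
}

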