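#' Simulation specification for a known admixture graph
#'
#' Bundles a fully parameterized graph with the sampling conditions the
#' simulator emulates: a Human Origins-like SNP set (tens of thousands to
#' hundreds of thousands of biallelic autosomal sites with genetic-map
#' positions), 5-30 diploid samples per population, and a few percent of
#' missing calls. Defaults mirror that input class: 1e5 SNPs, 10 diploids
#' per population, 2% missingness, 22 chromosomes of 1.5 Morgans.
#'
#' @param graph an [admix_graph()] with true lengths and weights set; drift
#'   lengths must be at most 0.25 (a warning is issued above 0.1, the edge
#'   of the normal-increment drift approximation's comfortable range).
#' @param n_snps number of SNPs.
#' @param samples_per_pop diploid samples per population: a single number
#'   or a named vector by population label.
#' @param missing_rate independent per-call missingness probability.
#' @param root_freq_law lower and upper bound of the uniform law for the
#'   ancestral allele frequency (default `c(0.05, 0.95)`).
#' @param n_chromosomes,map_length chromosomes and genetic map length per
#'   chromosome (Morgans) for the synthetic SNP map.
#' @param seed default seed used when none is passed to the simulator.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(graph, n_snps = 1e5, samples_per_pop = 10,
                     missing_rate = 0.02, root_freq_law = c(0.05, 0.95),
                     n_chromosomes = 22, map_length = 1.5, seed = 1L) {
  stopifnot(inherits(graph, "admix_graph"))
  if (anyNA(graph$edges$length) ||
      (nrow(graph$admix) && anyNA(graph$admix$weight)))
    stop("simulation graph must be fully parameterized")
  if (any(graph$edges$length > 0.25))
    stop("drift lengths above 0.25 are outside the model's validity domain")
  if (any(graph$edges$length > 0.1))
    warning("drift length(s) above 0.1: the normal-increment drift ",
            "approximation degrades; interpret absolute statistics with care")
  pops <- unname(graph$leaf_map)
  if (length(samples_per_pop) == 1L && is.null(names(samples_per_pop)))
    samples_per_pop <- stats::setNames(rep(samples_per_pop, length(pops)),
                                       pops)
  if (!all(pops %in% names(samples_per_pop)))
    stop("samples_per_pop must cover every leaf population")
  if (any(samples_per_pop < 1)) stop("samples_per_pop must be >= 1")
  structure(list(graph = graph, n_snps = as.integer(n_snps),
                 samples_per_pop = samples_per_pop[pops],
                 missing_rate = missing_rate,
                 root_freq_law = root_freq_law,
                 n_chromosomes = as.integer(n_chromosomes),
                 map_length = map_length, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate per-population allele frequencies along an admixture graph
#'
#' The ancestral frequency of each SNP is drawn uniformly from the root
#' law. A drift edge of length `l` perturbs frequencies as
#' `p -> clamp(p + N(0, l p (1 - p)), 0, 1)` — the normal approximation to
#' Wright-Fisher drift on the f2 scale — and an admixture node mixes its
#' parents' frequencies as `w pA + (1 - w) pB`. Monomorphic post-clamp
#' sites are retained by default (estimators must tolerate them).
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed (default `spec$seed`); identical seeds give
#'   bit-identical output.
#' @param drop_monomorphic drop sites monomorphic in every population
#'   (default `FALSE`).
#' @return A list of class `sim_freqs`: `freq` (leaf populations x SNPs
#'   matrix), `spec`, `kept` (SNP indices retained).
#' @export
simulate_graph_freqs <- function(spec, seed = spec$seed,
                                 drop_monomorphic = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$graph
  n <- spec$n_snps
  set.seed(seed)
  pmat <- matrix(NA_real_, nrow = length(g$nodes), ncol = n,
                 dimnames = list(g$nodes, NULL))
  pmat[g$root, ] <- stats::runif(n, spec$root_freq_law[1],
                                 spec$root_freq_law[2])
  drift_parent <- stats::setNames(g$edges$parent, g$edges$child)
  drift_len <- stats::setNames(g$edges$length, g$edges$child)
  ai <- match(g$topo, g$admix$child)
  for (k in seq_along(g$topo)) {
    nd <- g$topo[k]
    if (nd == g$root) next
    if (!is.na(ai[k])) {
      a <- g$admix[ai[k], ]
      pmat[nd, ] <- a$weight * pmat[a$parentA, ] +
        (1 - a$weight) * pmat[a$parentB, ]
    } else {
      p0 <- pmat[drift_parent[nd], ]
      l <- drift_len[nd]
      pmat[nd, ] <- if (l > 0)
        pmin(pmax(p0 + stats::rnorm(n, 0, sqrt(l * p0 * (1 - p0))), 0), 1)
      else p0
    }
  }
  freq <- pmat[g$leaves, , drop = FALSE]
  rownames(freq) <- unname(g$leaf_map[g$leaves])
  kept <- seq_len(n)
  if (drop_monomorphic) {
    poly <- colSums(freq > 0) > 0 & colSums(freq < 1) > 0
    freq <- freq[, poly, drop = FALSE]
    kept <- which(poly)
  }
  structure(list(freq = freq, spec = spec, kept = kept),
            class = "sim_freqs")
}

#' Sample diploid genotypes from simulated population frequencies
#'
#' Each diploid call is binomial(2, p) for its population's frequency at
#' the SNP; missingness is applied independently per call. SNP genetic
#' positions are spaced uniformly across `n_chromosomes` chromosomes of
#' `map_length` Morgans each.
#'
#' @param sim a `sim_freqs` from [simulate_graph_freqs()].
#' @param seed integer seed (default: `spec$seed + 1` so that frequencies
#'   and genotypes decouple).
#' @return A [genotype_matrix()] with sample ids `<pop>_<i>`.
#' @export
sample_genotypes <- function(sim, seed = sim$spec$seed + 1L) {
  stopifnot(inherits(sim, "sim_freqs"))
  spec <- sim$spec
  set.seed(seed)
  pops <- rownames(sim$freq)
  n_snp <- ncol(sim$freq)
  nper <- spec$samples_per_pop[pops]
  calls <- matrix(NA_integer_, nrow = n_snp, ncol = sum(nper))
  ids <- character(sum(nper)); popcol <- character(sum(nper))
  off <- 0L
  for (pop in pops) {
    m <- nper[[pop]]
    p <- sim$freq[pop, ]
    block <- matrix(stats::rbinom(n_snp * m, 2L, rep(p, m)), nrow = n_snp)
    if (spec$missing_rate > 0)
      block[matrix(stats::runif(n_snp * m) < spec$missing_rate,
                   nrow = n_snp)] <- NA_integer_
    calls[, off + seq_len(m)] <- block
    ids[off + seq_len(m)] <- paste0(pop, "_", seq_len(m))
    popcol[off + seq_len(m)] <- pop
    off <- off + m
  }
  per_chr <- diff(round(seq(0, n_snp, length.out = spec$n_chromosomes + 1)))
  chrom <- rep(seq_len(spec$n_chromosomes), per_chr)
  gpos <- unlist(lapply(per_chr, function(m)
    if (m > 0) seq(0, spec$map_length, length.out = m) else numeric(0)))
  snps <- data.frame(snp_id = paste0("snp", seq_len(n_snp)),
                     chromosome = as.character(chrom), genetic_pos = gpos,
                     physical_pos = as.integer(round(gpos * 1e8)) + 1L,
                     allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, snps,
                  data.frame(sample_id = ids, population = popcol,
                             stringsAsFactors = FALSE))
}

#' Closed-form expected f-statistics of a simulation graph
#'
#' Packages two oracles. `$drift` delegates to [expected_stats()] on the
#' true graph: f-statistics in drift units, where `f2` is additive in
#' branch lengths. `$expectation` is the expectation on the scale of the
#' data the simulator actually emits (raw allele-frequency statistics):
#' each drift edge contributes `l * E[p(1-p)]` of its parent node, so the
#' raw scale is the drift-unit scale shrunk by the root law's mean
#' heterozygosity with exact drift-decay corrections, computed by a
#' second-moment recursion over the graph. Estimated f-statistics are
#' compared against `$expectation`; fitted branch lengths against
#' `$effective_lengths` (the raw-scale length of each edge). Boundary
#' clamping in the simulator is not modelled here, so the oracle is exact
#' only while clamping is rare (short edges or an interior root law).
#'
#' @param spec a [sim_spec()].
#' @return A list of class `sim_truth`: `expectation` (raw scale,
#'   `graph_expectation`), `drift` (drift-unit scale), `effective_lengths`
#'   (named by edge label), `spec`. Query expected values with [exp_f2()],
#'   [exp_f3()], [exp_f4()] on either expectation.
#' @export
truth_stats <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$graph
  lo <- spec$root_freq_law[1]; hi <- spec$root_freq_law[2]
  mu <- (lo + hi) / 2
  mu2 <- (lo^2 + lo * hi + hi^2) / 3
  nodes <- g$topo
  M <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  M[g$root, g$root] <- mu2
  drift_parent <- stats::setNames(g$edges$parent, g$edges$child)
  drift_len <- stats::setNames(g$edges$length, g$edges$child)
  ai <- match(nodes, g$admix$child)
  done <- g$root
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    if (nd == g$root) next
    if (!is.na(ai[k])) {
      a <- g$admix[ai[k], ]; w <- a$weight
      M[nd, done] <- M[done, nd] <-
        w * M[a$parentA, done] + (1 - w) * M[a$parentB, done]
      M[nd, nd] <- w^2 * M[a$parentA, a$parentA] +
        2 * w * (1 - w) * M[a$parentA, a$parentB] +
        (1 - w)^2 * M[a$parentB, a$parentB]
    } else {
      pa <- drift_parent[nd]
      M[nd, done] <- M[done, nd] <- M[pa, done]
      M[nd, nd] <- M[pa, pa] + drift_len[nd] * (mu - M[pa, pa])
    }
    done <- c(done, nd)
  }
  eff <- g$edges$length * (mu - diag(M)[g$edges$parent])
  names(eff) <- g$edges$label
  Ml <- M[g$leaves, g$leaves, drop = FALSE]
  dimnames(Ml) <- list(unname(g$leaf_map[g$leaves]),
                       unname(g$leaf_map[g$leaves]))
  raw <- structure(list(C = Ml, populations = rownames(Ml), graph = g),
                   class = "graph_expectation")
  structure(list(expectation = raw, drift = expected_stats(g),
                 effective_lengths = eff, spec = spec),
            class = "sim_truth")
}

#' Bundled study-shaped simulation graph
#'
#' An 11-leaf skeleton-like admixture graph: two deep archaic-like
#' outgroups, an African-like leaf, a West Eurasian leaf and an
#' Iranian-like leaf on the western branch, a South Asian-like leaf that is
#' an even mixture of the Iranian-related branch and a deep East Eurasian
#' branch, a deeply diverged hunter-gatherer leaf (Onge-like), a Papuan-like
#' deep leaf, and an East/Southeast Asian clade of three leaves. Optionally
#' a target population is attached as a sister of ESEA2 carrying a chosen
#' mixture of ESEA, hunter-gatherer (NEGA-like) and South Asian-related
#' ancestry — the study's model space for Mainland Southeast Asian targets.
#'
#' @param target_mix `NULL` for the bare 11-leaf skeleton, or a numeric
#'   vector `c(esea = , nega = , sas = )` summing to 1: the target's
#'   ancestry proportions drawn from the ESEA2 branch, the hunter-gatherer
#'   branch and the South Asian branch.
#' @param target name of the attached target population.
#' @return An [admix_graph()] with true parameters set.
#' @export
preset_graph <- function(target_mix = NULL, target = "Target") {
  e <- function(label, parent, child, length)
    data.frame(label = label, parent = parent, child = child,
               length = length, stringsAsFactors = FALSE)
  edges <- rbind(
    e("arc",     "R",     "ARC",    0.05),
    e("den",     "ARC",   "Deep1",  0.09),
    e("nea",     "ARC",   "Deep2",  0.09),
    e("mh",      "R",     "MH",     0.03),
    e("afr",     "MH",    "African", 0.05),
    e("ooa",     "MH",    "OOA",    0.04),
    e("we",      "OOA",   "WE",     0.02),
    e("weur",    "WE",    "WEur",   0.05),
    e("ir",      "WE",    "IR",     0.015),
    e("iran",    "IR",    "IranN",  0.04),
    e("ee",      "OOA",   "EE",     0.02),
    e("papuan",  "EE",    "Papuan", 0.08),
    e("eas",     "EE",    "EAS",    0.015),
    e("hg",      "EAS",   "H1",     0.03),
    e("onge",    "H1",    "Onge",   0.03),
    e("eseanc",  "EAS",   "ESEAanc", 0.015),
    e("esea1",   "ESEAanc", "ESEA1", 0.03),
    e("ec",      "ESEAanc", "EC",   0.01),
    e("esea2",   "EC",    "ESEA2",  0.025),
    e("esea3",   "EC",    "ESEA3",  0.025),
    e("sas",     "SASmix", "SAS",   0.04))
  admix <- data.frame(child = "SASmix", parentA = "IR", parentB = "H1",
                      weight = 0.5, fixed = FALSE, stringsAsFactors = FALSE)
  if (!is.null(target_mix)) {
    stopifnot(all(c("esea", "nega", "sas") %in% names(target_mix)))
    if (abs(sum(target_mix) - 1) > 1e-8)
      stop("target_mix must sum to 1")
    esea <- target_mix[["esea"]]; nega <- target_mix[["nega"]]
    sas <- target_mix[["sas"]]
    # split the ESEA2 edge: the target's ESEA ancestry comes from T1
    edges <- edges[edges$label != "esea2", ]
    edges <- rbind(edges,
                   e("esea2_u", "EC", "T1", 0.012),
                   e("esea2_l", "T1", "ESEA2", 0.013))
    anc <- "T1"
    if (nega > 0) {
      edges <- edges[edges$label != "onge", ]
      edges <- rbind(edges,
                     e("onge_u", "H1", "N1", 0.015),
                     e("onge_l", "N1", "Onge", 0.015))
      admix <- rbind(admix, data.frame(
        child = "TmixN", parentA = anc, parentB = "N1",
        weight = esea / (esea + nega), fixed = FALSE,
        stringsAsFactors = FALSE))
      anc <- "TmixN"
    }
    if (sas > 0) {
      edges <- edges[edges$label != "sas", ]
      edges <- rbind(edges,
                     e("sas_u", "SASmix", "S1", 0.02),
                     e("sas_l", "S1", "SAS", 0.02))
      admix <- rbind(admix, data.frame(
        child = "TmixS", parentA = anc, parentB = "S1",
        weight = 1 - sas, fixed = FALSE, stringsAsFactors = FALSE))
      anc <- "TmixS"
    }
    edges <- rbind(edges, e("att_target", anc, target, 0.01))
  }
  admix_graph(edges, admix)
}
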