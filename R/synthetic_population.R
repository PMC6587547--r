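#' Specification of a structured synthetic population
#'
#' Describes a Balding-Nichols structured population with founder-haplotype
#' mosaic LD. Ancestral allele frequencies are drawn from `maf_spec`;
#' each subpopulation's frequencies are Beta-dispersed around them with
#' differentiation `fst`; individuals are mosaics of a finite founder
#' haplotype pool, with copy switches occurring at rate
#' `switch_rate_per_bp`, so the LD decay length is roughly
#' `1 / switch_rate_per_bp`.
#'
#' @param n_individuals number of individuals
#' @param n_markers total marker count (split evenly across chromosomes)
#' @param n_chromosomes number of chromosomes
#' @param chrom_length_bp chromosome length in bp
#' @param n_subpops number of subpopulations (individuals assigned evenly)
#' @param fst Balding-Nichols differentiation in `[0, 1)`
#' @param n_haplotypes_per_subpop founder haplotype pool size per subpopulation
#' @param switch_rate_per_bp founder copy-switch probability per bp (> 0);
#'   controls LD decay
#' @param maf_spec `"u-shaped"` (Beta(0.2, 0.2) ancestral frequencies
#'   truncated to `[0.01, 0.99]`, imitating GBS spectra) or
#'   `"common-filtered"` (MAF ~ Uniform(0.1, 0.5), imitating array /
#'   pre-filtered spectra)
#' @param missing_rate fraction of calls masked at random, in `[0, 1)`
#' @param inbred if `TRUE` (default, matching inbred crop panels) each
#'   individual carries two copies of a single mosaic haplotype, so
#'   heterozygosity arises only from missing-data imputation downstream;
#'   if `FALSE`, two independent mosaics are drawn
#' @param seed RNG seed making the population reproducible
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_individuals = 500, n_markers = 5000,
                            n_chromosomes = 5, chrom_length_bp = 1e8,
                            n_subpops = 3, fst = 0.25,
                            n_haplotypes_per_subpop = 20,
                            switch_rate_per_bp = 1e-6,
                            maf_spec = c("u-shaped", "common-filtered"),
                            missing_rate = 0, inbred = TRUE, seed = 1L) {
  maf_spec <- match.arg(maf_spec)
  spec <- list(n_individuals = as.integer(n_individuals),
               n_markers = as.integer(n_markers),
               n_chromosomes = as.integer(n_chromosomes),
               chrom_length_bp = chrom_length_bp,
               n_subpops = as.integer(n_subpops), fst = fst,
               n_haplotypes_per_subpop = as.integer(n_haplotypes_per_subpop),
               switch_rate_per_bp = switch_rate_per_bp,
               maf_spec = maf_spec, missing_rate = missing_rate,
               inbred = isTRUE(inbred), seed = as.integer(seed))
  validate_population_spec(spec)
  structure(spec, class = "population_spec")
}

validate_population_spec <- function(spec) {
  if (!(spec$fst >= 0 && spec$fst < 1)) stop("fst must lie in [0, 1)")
  if (spec$n_haplotypes_per_subpop < 2) stop("need >= 2 founder haplotypes per subpopulation")
  if (spec$switch_rate_per_bp <= 0) stop("switch_rate_per_bp must be > 0")
  if (!(spec$missing_rate >= 0 && spec$missing_rate < 1)) stop("missing_rate must lie in [0, 1)")
  if (spec$n_individuals < 2 || spec$n_markers < 1 || spec$n_chromosomes < 1)
    stop("population dimensions too small")
  invisible(spec)
}

draw_ancestral_freqs <- function(M, maf_spec) {
  if (maf_spec == "u-shaped") {
    p <- stats::rbeta(M, 0.2, 0.2)
    pmin(pmax(p, 0.01), 0.99)
  } else {
    maf <- stats::runif(M, 0.1, 0.5)
    side <- stats::runif(M) < 0.5
    ifelse(side, maf, 1 - maf)
  }
}

#' Generate a structured genotype matrix with known truth
#'
#' Balding-Nichols model: ancestral frequency `p` drawn from the
#' configured `maf_spec`; subpopulation frequency `~ Beta(p (1 - F) / F,
#' (1 - p)(1 - F) / F)` (degenerate at `p` when `F = 0`); per
#' subpopulation a pool of founder haplotypes drawn site-wise from that
#' frequency; each individual's haplotype copies from the founder pool
#' with a per-bp switch probability, giving geometric tract lengths and
#' hence tunable LD decay; dosage = haplotype sum; missing calls masked
#' uniformly at random. Fully reproducible from `spec$seed`.
#'
#' @param spec a [population_spec()]
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (list: `subpop` labels per individual, `ancestral_freq`,
#'   `subpop_freq` M x n_subpops matrix)
#' @export
generate_population <- function(spec) {
  validate_population_spec(spec)
  set.seed(spec$seed)
  M <- spec$n_markers; N <- spec$n_individuals
  S <- spec$n_subpops; Hn <- spec$n_haplotypes_per_subpop
  # marker map: markers split evenly over chromosomes, sorted positions
  per_chr <- diff(round(seq(0, M, length.out = spec$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(spec$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(m)
    sort(sample.int(spec$chrom_length_bp, m, replace = FALSE))))
  markers <- data.frame(id = sprintf("m%05d", seq_len(M)), chrom = chrom,
                        pos = pos, counted = "A", other = "B",
                        stringsAsFactors = FALSE)
  p_anc <- draw_ancestral_freqs(M, spec$maf_spec)
  F <- spec$fst
  p_sub <- matrix(0, M, S)
  for (s in seq_len(S)) {
    p_sub[, s] <- if (F == 0) p_anc else
      stats::rbeta(M, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  # founder haplotype pools: list over subpops of M x Hn 0/1 matrices
  founders <- lapply(seq_len(S), function(s)
    matrix(stats::rbinom(M * Hn, 1L, p_sub[, s]), M, Hn))
  subpop <- rep(seq_len(S), length.out = N)
  chr_index <- split(seq_len(M), factor(chrom, levels = unique(chrom)))
  dos <- matrix(0, M, N)
  n_hap <- if (spec$inbred) 1L else 2L
  for (j in seq_len(N)) {
    pool <- founders[[subpop[j]]]
    hap_sum <- numeric(M)
    for (h in seq_len(n_hap)) {
      hap <- numeric(M)
      for (ci in chr_index) {
        hap[ci] <- mosaic_haplotype(pool, ci, pos[ci], spec$switch_rate_per_bp, Hn)
      }
      hap_sum <- hap_sum + hap
    }
    dos[, j] <- if (spec$inbred) 2 * hap_sum else hap_sum
  }
  samples <- sprintf("ind%04d", seq_len(N))
  G <- genotype_matrix(dos, markers, samples)
  if (spec$missing_rate > 0)
    G <- inject_missingness(G, spec$missing_rate,
                            seed = spec$seed + 104729L)
  list(genotypes = G,
       truth = list(subpop = subpop, ancestral_freq = p_anc,
                    subpop_freq = p_sub))
}

# one mosaic haplotype over a single chromosome: copy from a random founder,
# switching to a (uniformly re-drawn) founder with prob 1 - exp(-rate * gap)
mosaic_haplotype <- function(pool, idx, pos_chr, rate, Hn) {
  m <- length(idx)
  gaps <- diff(pos_chr)
  switch_prob <- 1 - exp(-rate * gaps)
  switches <- c(TRUE, stats::runif(m - 1) < switch_prob)
  seg <- cumsum(switches)
  donor_per_seg <- sample.int(Hn, seg[m], replace = TRUE)
  donor <- donor_per_seg[seg]
  pool[cbind(idx, donor)]
}

#' Mask genotype calls at random
#'
#' @param G a `genotype_matrix`
#' @param rate expected fraction of entries masked, in `[0, 1)`
#' @param seed RNG seed (deterministic mask)
#' @return a `genotype_matrix` with missing calls injected
#' @export
inject_missingness <- function(G, rate, seed = 1L) {
  if (rate >= 1) stop("rate must be < 1")
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(G)
  X <- G$dosages
  set.seed(seed)
  mask <- stats::runif(length(X)) < rate
  X[mask] <- NA_real_
  genotype_matrix(X, G$markers, G$samples, validate = FALSE)
}
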