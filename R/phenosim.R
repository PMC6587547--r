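#' Sample a trait architecture (causal markers and their effects)
#'
#' Causal marker indices are drawn uniformly without replacement.
#' Effect sizes are drawn `~ N(0, 1)` (`effect_dist = "normal"`, the
#' default used throughout the benchmark) or follow a geometric series
#' `a_i = r^i` with random signs (`"geometric"`), the alternative some
#' multi-locus GWAS evaluations have used.
#'
#' @param G a complete [genotype_matrix()]
#' @param n_qtn number of causal markers (QTNs), `1 <= n_qtn <= M`
#' @param h2 target narrow-sense heritability in `(0, 1]`
#' @param effect_dist `"normal"` or `"geometric"`
#' @param geometric_ratio ratio `r` of the geometric series (default 0.92)
#' @param min_maf optional MAF floor on candidate causal markers (default
#'   0, i.e. no floor)
#' @param seed RNG seed
#' @return an object of class `trait_architecture` with fields
#'   `causal_indices`, `effects`, `h2`, `effect_dist`, `seed`
#' @export
sample_architecture <- function(G, n_qtn, h2 = 0.5,
                                effect_dist = c("normal", "geometric"),
                                geometric_ratio = 0.92, min_maf = 0,
                                seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  M <- n_markers(G)
  candidates <- seq_len(M)
  if (min_maf > 0) {
    s <- summarize_markers(G)
    candidates <- which(s$maf >= min_maf)
  }
  if (n_qtn > length(candidates))
    stop("n_qtn (", n_qtn, ") exceeds the number of eligible markers (",
         length(candidates), ")")
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must lie in (0, 1]")
  set.seed(seed)
  idx <- sort(candidates[sample.int(length(candidates), n_qtn)])
  effects <- if (effect_dist == "normal") {
    stats::rnorm(n_qtn)
  } else {
    geometric_ratio^seq_len(n_qtn) * sample(c(-1, 1), n_qtn, replace = TRUE)
  }
  structure(list(causal_indices = idx, effects = effects, h2 = h2,
                 effect_dist = effect_dist, seed = as.integer(seed)),
            class = "trait_architecture")
}

#' Simulate an additive phenotype: Y_j = sum_i a_i S_ij + e_j
#'
#' Genetic values `g_j = sum_i a_i S_ij` are computed from the dosage
#' matrix; residuals are drawn `~ N(0, sd)` with
#' `sd = sqrt(Var(g) (1 / h2 - 1))`, where `Var(g)` is the realized
#' sample variance (denominator `n - 1`) of the genetic values, so the
#' expected realized heritability `Var(g) / Var(Y)` equals the target
#' `h2`. At `h2 = 1` residuals are exactly zero. The residual stream is
#' seeded from `arch$seed` plus a fixed offset (so architecture and
#' noise are independently re-drawable); pass `residual_seed` to draw
#' independent noise replicates on a fixed architecture.
#'
#' @param G a complete [genotype_matrix()]
#' @param arch a [sample_architecture()] result
#' @param residual_seed optional seed overriding the derived residual seed
#' @return an object of class `phenotype_vector`: list with `values`,
#'   `genetic_values`, `residuals` (all length N, named by sample id)
#' @export
simulate_trait <- function(G, arch, residual_seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  X <- G$dosages
  if (anyNA(X)) stop("genotype matrix must be complete (impute first)")
  g <- as.vector(crossprod(X[arch$causal_indices, , drop = FALSE], arch$effects))
  var_g <- stats::var(g)
  h2 <- arch$h2
  if (h2 < 1 && var_g == 0)
    stop("degenerate genetic variance: Var(g) = 0 with h2 < 1")
  e <- if (h2 == 1) {
    numeric(length(g))
  } else {
    sd_e <- sqrt(var_g * (1 / h2 - 1))
    set.seed(if (is.null(residual_seed)) arch$seed + 7919L else residual_seed)
    stats::rnorm(length(g), 0, sd_e)
  }
  y <- g + e
  names(y) <- names(g) <- names(e) <- G$samples
  structure(list(values = y, genetic_values = g, residuals = e),
            class = "phenotype_vector")
}

#' Realized heritability of a simulated phenotype
#'
#' `Var(g) / Var(Y)` with sample variances, the quantity the simulator
#' calibrates toward the target `h2`.
#'
#' @param pheno a `phenotype_vector`
#' @return a single numeric value (near `arch$h2` up to sampling noise)
#' @export
realized_h2 <- function(pheno) {
  stats::var(pheno$genetic_values) / stats::var(pheno$values)
}

#' Write a phenotype table (sample id, value), tab-delimited
#' @param pheno a `phenotype_vector`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(data.frame(id = names(pheno$values),
                                value = pheno$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotype()]
#' @param path input path
#' @param G optional `genotype_matrix`; if given, values are reordered to
#'   match `G$samples` and checked for completeness
#' @return named numeric vector of trait values
#' @export
read_phenotype <- function(path, G = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  y <- stats::setNames(tab$value, tab$id)
  if (!is.null(G)) {
    if (!all(G$samples %in% names(y)))
      stop("phenotype table missing individuals present in genotypes")
    y <- y[G$samples]
  }
  y
}
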