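# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small structured population used across engine tests
pop_small <- function() fixture("pop_small", function()
  generate_population(population_spec(n_individuals = 200, n_markers = 1000,
                                      seed = 42)))

# hand-built tiny genotype matrix
toy_genotypes <- function(dos, chrom = NULL, pos = NULL) {
  M <- nrow(dos); N <- ncol(dos)
  genotype_matrix(dos,
                  data.frame(id = paste0("m", seq_len(M)),
                             chrom = chrom %||% rep("chr1", M),
                             pos = pos %||% seq_len(M) * 1000,
                             counted = "A", other = "B"),
                  paste0("s", seq_len(N)), validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir-Cockerham theta (haploid ANOVA form), ratio-of-sums over markers:
# independent oracle for the generator's Fst (inbred individuals carry one
# effective haplotype each, so subpop allele frequency = mean dosage / 2
# with n_s = number of individuals independent copies)
wc_fst <- function(G, subpop) {
  p_hat <- sapply(split(seq_along(subpop), subpop), function(idx)
    rowMeans(G$dosages[, idx, drop = FALSE]) / 2)
  n_s <- as.numeric(table(subpop))
  r <- length(n_s)
  n_tot <- sum(n_s)
  n_c <- (n_tot - sum(n_s^2) / n_tot) / (r - 1)
  p_bar <- as.vector(p_hat %*% n_s) / n_tot
  msb <- rowSums(sweep((p_hat - p_bar)^2, 2, n_s, `*`)) / (r - 1)
  msw <- rowSums(sweep(p_hat * (1 - p_hat), 2, n_s, `*`)) / (n_tot - r)
  sum(msb - msw) / sum(msb + (n_c - 1) * msw)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

silhouette_pc12 <- function(scores, labels) {
  d <- as.matrix(dist(scores))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# OLS per-marker scan with covariates: closed-form oracle for scan_mlm
# with identity kinship
ols_scan_oracle <- function(G, y, W) {
  X <- t(G$dosages)
  n <- length(y)
  sapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(y ~ W + X[, j] - 1)
    cf <- summary(fit)$coefficients
    cf[nrow(cf), 4]
  })
}
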