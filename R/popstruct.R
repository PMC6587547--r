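#' Principal components of the individuals
#'
#' PCA of individuals on marker-standardized dosages (markers centered,
#' and by default scaled to unit variance). The first three score
#' columns are the population-structure covariates fed to the mixed
#' model and to the FarmCPU scan.
#'
#' @param G a complete [genotype_matrix()]
#' @param n_components number of components to keep (default 10)
#' @param scale. scale markers to unit variance? Default `TRUE`
#' @return list of class `pc_matrix`: `scores` (N x n_components),
#'   `variance_explained` (fraction per kept component),
#'   `all_variance` (full eigen-spectrum fractions)
#' @export
compute_pca <- function(G, n_components = 10, scale. = TRUE) {
  X <- t(G$dosages)                       # individuals x markers
  if (anyNA(X)) stop("genotype matrix must be complete")
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(N, M)")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  Xs <- scale(X[, keep, drop = FALSE], center = TRUE,
              scale = if (scale.) sds[keep] else FALSE)
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- G$samples
  structure(list(scores = scores,
                 variance_explained = ve[seq_len(n_components)],
                 all_variance = ve),
            class = "pc_matrix")
}

#' Genomic relationship (kinship) matrix
#'
#' Two standard estimators on centered dosages `Xc` (individuals x
#' markers, each marker minus its mean `2 p_k`):
#' \describe{
#'   \item{`centered`}{`K = Xc Xc' / M` — the centered relatedness
#'     matrix used by single-marker mixed-model software.}
#'   \item{`vanraden`}{`K = Xc Xc' / (2 sum_k p_k (1 - p_k))` — the
#'     VanRaden genomic relationship matrix.}
#' }
#' The two differ only by the global scalar
#' `M / (2 sum p (1 - p))`, so their entries correlate perfectly; this
#' proportionality is exercised by the test suite.
#'
#' @param G a complete [genotype_matrix()]
#' @param estimator `"centered"` or `"vanraden"`
#' @return list of class `kinship_matrix`: `values` (N x N symmetric
#'   PSD), `estimator`
#' @export
compute_kinship <- function(G, estimator = c("centered", "vanraden")) {
  estimator <- match.arg(estimator)
  X <- t(G$dosages)
  if (anyNA(X)) stop("genotype matrix must be complete")
  p <- colMeans(X) / 2
  het <- sum(2 * p * (1 - p))
  if (het == 0) stop("all markers monomorphic: kinship undefined")
  Xc <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Xc) / switch(estimator,
                               centered = ncol(X),
                               vanraden = het)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$samples, G$samples)
  structure(list(values = K, estimator = estimator),
            class = "kinship_matrix")
}

#' Pairwise LD (r^2) between nearby markers
#'
#' Squared Pearson correlation of dosage vectors for every pair of
#' markers on the same chromosome separated by less than `max_dist_bp`
#' (default 10 Mb). Pairs containing a zero-variance marker are skipped
#' (and counted in the `n_skipped` attribute).
#'
#' @param G a complete [genotype_matrix()]
#' @param max_dist_bp maximum pair separation in bp (default `1e7`)
#' @param max_pairs optional cap: if the table would exceed this many
#'   pairs, a deterministic evenly-spaced subsample of marker pairs is
#'   returned (keeps memory bounded on dense maps)
#' @return data.frame of class `ld_table`: `marker_i`, `marker_j`,
#'   `chrom`, `distance_bp`, `r2`
#' @export
pairwise_ld <- function(G, max_dist_bp = 1e7, max_pairs = Inf) {
  X <- G$dosages
  if (anyNA(X)) stop("genotype matrix must be complete")
  out <- vector("list", 0L)
  sds <- apply(X, 1, stats::sd)
  for (chr in unique(G$markers$chrom)) {
    idx <- which(G$markers$chrom == chr)
    idx <- idx[order(G$markers$pos[idx])]
    m <- length(idx)
    if (m < 2) next
    pos <- G$markers$pos[idx]
    ok <- sds[idx] > 0
    # enumerate in-window pairs via a two-pointer sweep
    ii <- vector("list", m - 1L); jj <- vector("list", m - 1L)
    hi <- 1L
    for (a in seq_len(m - 1L)) {
      if (hi < a + 1L) hi <- a + 1L
      while (hi < m && pos[hi + 1L] - pos[a] < max_dist_bp) hi <- hi + 1L
      if (hi > a && pos[hi] - pos[a] < max_dist_bp) {
        js <- (a + 1L):hi
        ii[[a]] <- rep.int(a, length(js)); jj[[a]] <- js
      }
    }
    pi_ <- unlist(ii); pj_ <- unlist(jj)
    if (is.null(pi_)) { pi_ <- integer(0); pj_ <- integer(0) }
    keep <- ok[pi_] & ok[pj_]
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
    n_skip <- sum(!keep)
    if (!length(pi_)) next
    Xc <- X[idx, , drop = FALSE] - rowMeans(X[idx, , drop = FALSE])
    norms <- sqrt(rowSums(Xc^2))
    # chunk the pair dot-products to bound memory on dense maps
    r <- numeric(length(pi_))
    chunk <- 20000L
    for (s in seq(1L, length(pi_), by = chunk)) {
      sel <- s:min(s + chunk - 1L, length(pi_))
      r[sel] <- rowSums(Xc[pi_[sel], , drop = FALSE] *
                          Xc[pj_[sel], , drop = FALSE]) /
        (norms[pi_[sel]] * norms[pj_[sel]])
    }
    out[[length(out) + 1L]] <- data.frame(
      marker_i = G$markers$id[idx[pi_]],
      marker_j = G$markers$id[idx[pj_]],
      chrom = chr,
      distance_bp = pos[pj_] - pos[pi_],
      r2 = pmin(r^2, 1),
      stringsAsFactors = FALSE)
    attr(out[[length(out)]], "n_skipped") <- n_skip
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(marker_i = character(), marker_j = character(),
                      chrom = character(), distance_bp = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  if (nrow(tab) > max_pairs) {
    keep <- unique(round(seq(1L, nrow(tab), length.out = max_pairs)))
    tab <- tab[keep, , drop = FALSE]
  }
  class(tab) <- c("ld_table", "data.frame")
  tab
}

#' Log-binned LD decay curve
#'
#' Bins pair distances at log10 edges `0.1, 0.2, ..., 7.0` and reports
#' the mean r^2 per bin. The decay scale is the center of the first bin
#' at which the (3-bin running-mean smoothed) curve drops below
#' `threshold_frac` of its maximum; if it never does, the last
#' non-empty bin center is reported. The half-max criterion is this
#' package's convention, since published decay distances rarely state
#' theirs.
#'
#' @param ld an [pairwise_ld()] table
#' @param threshold_frac decay threshold as a fraction of the maximum
#'   smoothed mean r^2 (default 0.5)
#' @return list of class `ld_decay`: `bins` data.frame (`center_bp`,
#'   `mean_r2`, `n`, `empty`), `decay_scale_bp`
#' @export
ld_decay_curve <- function(ld, threshold_frac = 0.5) {
  if (nrow(ld) == 0) stop("empty LD table")
  edges <- seq(0.1, 7.0, by = 0.1)
  centers <- 10^((edges[-length(edges)] + edges[-1]) / 2)
  bin <- cut(log10(ld$distance_bp), breaks = edges, include.lowest = TRUE)
  mean_r2 <- tapply(ld$r2, bin, mean)
  n <- tapply(ld$r2, bin, length)
  bins <- data.frame(center_bp = centers,
                     mean_r2 = as.numeric(mean_r2),
                     n = ifelse(is.na(n), 0L, as.integer(n)))
  bins$empty <- bins$n == 0L
  filled <- bins[!bins$empty, , drop = FALSE]
  sm <- if (nrow(filled) >= 3)
    stats::filter(filled$mean_r2, rep(1 / 3, 3), sides = 2)
  else filled$mean_r2
  sm[is.na(sm)] <- filled$mean_r2[is.na(sm)]
  below <- which(sm < threshold_frac * max(sm))
  decay <- if (length(below)) filled$center_bp[below[1]] else
    filled$center_bp[nrow(filled)]
  structure(list(bins = bins, decay_scale_bp = decay), class = "ld_decay")
}

#' Write a kinship matrix as square text with a sample-id header
#' @param K a `kinship_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_kinship <- function(K, path) {
  utils::write.table(K$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
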