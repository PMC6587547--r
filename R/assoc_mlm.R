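# Q+K mixed linear model engine.
#
# Model: y = W b + u + e,  u ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I),
# with W = intercept + leading principal components. A single
# eigendecomposition of K rotates the model to independent errors with
# per-observation variance sigma_e^2 (lambda d_i + 1), lambda =
# sigma_g^2 / sigma_e^2; the REML likelihood is then a 1-D profile in
# lambda, optimized on log10(lambda) in [-5, 5].

mlm_eigen <- function(K) {
  eg <- eigen(K$values, symmetric = TRUE)
  tol <- 1e-8 * sum(diag(K$values)) / nrow(K$values)
  if (min(eg$values) < -tol)
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         format(min(eg$values)), ")")
  eg$values <- pmax(eg$values, 0)
  eg
}

# profiled REML log-likelihood at a given lambda, in the rotated basis
reml_loglik <- function(log10_lambda, d, yr, Wr, logdet_WtW) {
  lambda <- 10^log10_lambda
  v <- lambda * d + 1
  n <- length(yr); q <- ncol(Wr)
  Wv <- Wr / v
  WtVW <- crossprod(Wr, Wv)
  b <- solve(WtVW, crossprod(Wv, yr))
  resid <- yr - Wr %*% b
  rss <- sum(resid^2 / v)
  sigma_e2 <- rss / (n - q)
  -0.5 * ((n - q) * (log(2 * pi * sigma_e2) + 1) + sum(log(v)) +
            determinant(WtVW, logarithm = TRUE)$modulus - logdet_WtW)
}

#' Fit the null Q+K mixed model by profiled REML
#'
#' Estimates the variance ratio `lambda = sigma_g^2 / sigma_e^2` by
#' 1-D REML after rotating phenotype and covariates by the
#' eigenvectors of `K`, then recovers both variance components.
#'
#' @param y numeric phenotype vector or a `phenotype_vector`
#' @param Q a `pc_matrix` (its first `n_pcs` columns are used) or a
#'   numeric covariate matrix without intercept; `NULL` for
#'   intercept-only
#' @param K a `kinship_matrix`
#' @param n_pcs number of leading PCs used as fixed covariates (default 3)
#' @return list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `lambda`, `loglik`, `boundary` (TRUE if the optimizer settled at a
#'   search-interval end), plus the rotation reused by [scan_mlm()]
#' @export
fit_null_mlm <- function(y, Q, K, n_pcs = 3) {
  y <- as_phenotype_values(y)
  W <- build_covariates(Q, length(y), n_pcs)
  stopifnot(nrow(K$values) == length(y))
  eg <- mlm_eigen(K)
  yr <- drop(crossprod(eg$vectors, y))
  Wr <- crossprod(eg$vectors, W)
  logdet_WtW <- determinant(crossprod(W), logarithm = TRUE)$modulus
  opt <- stats::optimize(reml_loglik, interval = c(-5, 5), maximum = TRUE,
                         d = eg$values, yr = yr, Wr = Wr,
                         logdet_WtW = logdet_WtW, tol = 1e-6)
  lambda <- 10^opt$maximum
  v <- lambda * eg$values + 1
  Wv <- Wr / v
  b <- solve(crossprod(Wr, Wv), crossprod(Wv, yr))
  rss <- sum((yr - Wr %*% b)^2 / v)
  sigma_e2 <- rss / (length(y) - ncol(W))
  boundary <- opt$maximum < -5 + 1e-3 || opt$maximum > 5 - 1e-3
  structure(list(sigma_g2 = lambda * sigma_e2, sigma_e2 = sigma_e2,
                 lambda = lambda, loglik = opt$objective,
                 boundary = boundary,
                 eigen = eg, yr = yr, Wr = Wr, W = W),
            class = "variance_components")
}

as_phenotype_values <- function(y) {
  if (inherits(y, "phenotype_vector")) y <- y$values
  as.numeric(y)
}

build_covariates <- function(Q, n, n_pcs) {
  if (is.null(Q)) return(matrix(1, n, 1))
  S <- if (inherits(Q, "pc_matrix"))
    Q$scores[, seq_len(min(n_pcs, ncol(Q$scores))), drop = FALSE]
  else as.matrix(Q)
  stopifnot(nrow(S) == n)
  cbind(1, S)
}

#' Single-marker mixed-model association scan
#'
#' Per-marker Wald test of the marker coefficient in the generalized
#' least-squares regression implied by the fitted Q+K model. In
#' `approx` mode (the default; the EMMAX-style approximation) the null
#' variance components are reused for every marker; `exact` mode
#' re-optimizes `lambda` per marker.
#'
#' @param G a complete [genotype_matrix()]
#' @param y phenotype vector or `phenotype_vector`
#' @param Q a `pc_matrix` or covariate matrix (see [fit_null_mlm()])
#' @param K a `kinship_matrix`
#' @param mode `"approx"` or `"exact"`
#' @param n_pcs number of leading PCs as covariates (default 3)
#' @return an `assoc_result`: data.frame (`marker`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `flag`) with attributes `engine = "mlm"` and the
#'   fitted `variance_components`. Monomorphic markers get `p = 1` and
#'   `flag = "monomorphic"`.
#' @export
scan_mlm <- function(G, y, Q, K, mode = c("approx", "exact"), n_pcs = 3) {
  mode <- match.arg(mode)
  y <- as_phenotype_values(y)
  X <- t(G$dosages)                       # individuals x markers
  if (anyNA(X)) stop("genotype matrix must be complete")
  vc <- fit_null_mlm(y, Q, K, n_pcs = n_pcs)
  n <- length(y); q <- ncol(vc$W)
  Xr <- crossprod(vc$eigen$vectors, X)
  mono <- apply(X, 2, function(col) stats::var(col) == 0)
  if (mode == "approx") {
    v <- vc$lambda * vc$eigen$values + 1
    vs <- sqrt(v)
    yw <- vc$yr / vs
    Ww <- vc$Wr / vs
    Xw <- Xr / vs
    qrW <- qr(Ww)
    ry <- stats::setNames(qr.resid(qrW, yw), NULL)
    RX <- qr.resid(qrW, Xw)
    xx <- colSums(RX^2)
    xy <- as.vector(crossprod(RX, ry))
    beta <- xy / xx
    df <- n - q - 1
    rss <- sum(ry^2) - beta^2 * xx
    rss <- pmax(rss, 0)
    se <- sqrt(rss / df / xx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    M <- ncol(X)
    beta <- se <- p <- numeric(M)
    logdet <- NA
    for (j in seq_len(M)) {
      if (mono[j]) { beta[j] <- 0; se[j] <- NA; p[j] <- 1; next }
      Wj <- cbind(vc$Wr, Xr[, j])
      ld <- determinant(crossprod(cbind(vc$W, X[, j])), logarithm = TRUE)$modulus
      opt <- stats::optimize(reml_loglik, interval = c(-5, 5), maximum = TRUE,
                             d = vc$eigen$values, yr = vc$yr, Wr = Wj,
                             logdet_WtW = ld, tol = 1e-6)
      v <- 10^opt$maximum * vc$eigen$values + 1
      Wv <- Wj / v
      A <- crossprod(Wj, Wv)
      bj <- solve(A, crossprod(Wv, vc$yr))
      rssj <- sum((vc$yr - Wj %*% bj)^2 / v)
      s2 <- rssj / (n - ncol(Wj))
      cov_b <- solve(A) * s2
      k <- ncol(Wj)
      beta[j] <- bj[k]
      se[j] <- sqrt(cov_b[k, k])
      tj <- beta[j] / se[j]
      p[j] <- 2 * stats::pt(-abs(tj), n - k)
    }
  }
  beta[mono] <- 0; se[mono] <- NA; p[mono] <- 1
  res <- data.frame(marker = G$markers$id, chrom = G$markers$chrom,
                    pos = G$markers$pos, beta = beta, se = se, p = p,
                    flag = ifelse(mono, "monomorphic", ""),
                    stringsAsFactors = FALSE)
  new_assoc_result(res, engine = "mlm",
                   extra = list(variance_components =
                                  vc[c("sigma_g2", "sigma_e2", "lambda",
                                       "loglik", "boundary")]))
}

new_assoc_result <- function(df, engine, extra = list()) {
  attr(df, "engine") <- engine
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("assoc_result", "data.frame")
  df
}

#' Markers passing a Bonferroni-corrected significance cutoff
#'
#' @param result an `assoc_result` from a frequentist engine (`p` column)
#' @param alpha family-wise error target (default 0.05); the per-marker
#'   threshold is `alpha / M`
#' @return character vector of significant marker ids (possibly empty)
#' @export
bonferroni_calls <- function(result, alpha = 0.05) {
  if (!"p" %in% names(result))
    stop("bonferroni_calls needs a frequentist result with p-values")
  result$marker[result$p < alpha / nrow(result)]
}
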