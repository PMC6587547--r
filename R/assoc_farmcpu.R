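# Multi-locus iterative scan alternating a fixed-effect GLM (with
# pseudo-QTN covariates) and a random-effect model that scores candidate
# pseudo-QTN sets by the REML likelihood of a kinship built from the
# candidates only (SUPER-style), over a grid of bin sizes and set sizes.

#' Covariate-adjusted ordinary least-squares scan
#'
#' Per-marker two-sided t-test of the marker coefficient in OLS with
#' intercept + leading PCs + the dosages of the current pseudo-QTNs as
#' covariates. A marker that is itself a pseudo-QTN is reported with
#' its covariate's own t-test p-value from the joint fit rather than a
#' redundant (collinear) marker test; all other markers keep their own
#' conditional test, so the ranking is not flooded with copies of a
#' pseudo-QTN's p-value. Collinear covariate columns are dropped with
#' a warning.
#'
#' @param G a complete [genotype_matrix()]
#' @param y phenotype vector or `phenotype_vector`
#' @param Q a `pc_matrix` or covariate matrix (see [fit_null_mlm()])
#' @param pseudo_qtns integer vector of marker indices used as fixed
#'   covariates (default none)
#' @param n_pcs number of leading PCs as covariates (default 3)
#' @return an `assoc_result` with engine `"glm"` (columns as [scan_mlm()])
#' @export
glm_scan <- function(G, y, Q, pseudo_qtns = integer(0), n_pcs = 3) {
  y <- as_phenotype_values(y)
  X <- t(G$dosages)
  if (anyNA(X)) stop("genotype matrix must be complete")
  n <- length(y)
  C <- build_covariates(Q, n, n_pcs)
  pseudo_qtns <- as.integer(pseudo_qtns)
  if (length(pseudo_qtns)) {
    P <- X[, pseudo_qtns, drop = FALSE]
    full <- cbind(C, P)
    qrf <- qr(full)
    if (qrf$rank < ncol(full)) {
      drop_cols <- qrf$pivot[(qrf$rank + 1):ncol(full)]
      drop_pseudo <- drop_cols[drop_cols > ncol(C)] - ncol(C)
      if (length(drop_pseudo)) {
        warning("dropping ", length(drop_pseudo),
                " collinear pseudo-QTN covariate(s)")
        pseudo_qtns <- pseudo_qtns[-drop_pseudo]
        P <- X[, pseudo_qtns, drop = FALSE]
      }
      keep_base <- setdiff(seq_len(ncol(C)),
                           drop_cols[drop_cols <= ncol(C)])
      C <- C[, keep_base, drop = FALSE]
      full <- cbind(C, P)
    }
  } else full <- C
  qrW <- qr(full)
  q <- ncol(full)
  ry <- qr.resid(qrW, y)
  RX <- qr.resid(qrW, X)
  xx <- colSums(RX^2)
  mono <- xx < 1e-10 * n
  xx[mono] <- NA
  beta <- as.vector(crossprod(RX, ry)) / xx
  df <- n - q - 1
  rss <- pmax(sum(ry^2) - beta^2 * xx, 0)
  se <- sqrt(rss / df / xx)
  p <- 2 * stats::pt(-abs(beta / se), df)
  beta[mono] <- 0; se[mono] <- NA; p[mono] <- 1
  flag <- ifelse(mono, "monomorphic", "")
  # pseudo-QTN substitution: their own t-test from the joint fit
  if (length(pseudo_qtns)) {
    fit <- stats::lm.fit(full, y)
    rdf <- fit$df.residual
    s2 <- sum(fit$residuals^2) / rdf
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R)
    d_piv <- diag(XtXinv)
    cov_diag <- d_piv[match(seq_len(ncol(full)),
                            fit$qr$pivot)][(ncol(C) + 1):ncol(full)] * s2
    tp <- fit$coefficients[(ncol(C) + 1):ncol(full)] / sqrt(cov_diag)
    p_pseudo <- 2 * stats::pt(-abs(tp), rdf)
    for (k in seq_along(pseudo_qtns)) {
      jq <- pseudo_qtns[k]
      p[jq] <- p_pseudo[k]
      beta[jq] <- fit$coefficients[ncol(C) + k]
      se[jq] <- sqrt(cov_diag[k])
      flag[jq] <- "pseudo_qtn"
    }
  }
  res <- data.frame(marker = G$markers$id, chrom = G$markers$chrom,
                    pos = G$markers$pos, beta = beta, se = se, p = p,
                    flag = flag, stringsAsFactors = FALSE)
  new_assoc_result(res, engine = "glm",
                   extra = list(pseudo_qtns = pseudo_qtns))
}

# REML log-likelihood of y ~ intercept with random effect covariance K
# (NULL K = plain i.i.d. null), on the same scale as reml_loglik()
score_candidate_set <- function(y, K) {
  n <- length(y)
  if (is.null(K)) {
    sigma2 <- stats::var(y)          # denominator n - 1 = n - q
    return(-0.5 * ((n - 1) * (log(2 * pi * sigma2) + 1)))
  }
  vc <- fit_null_mlm(y, NULL, K)
  vc$loglik
}

#' Select pseudo-QTNs by binned candidates and random-effect scoring
#'
#' For each bin size `b` the best-p marker per `b`-bp genomic bin is a
#' candidate; for each count `t` the top-`t` candidates (by p-value)
#' form a set, scored by the REML likelihood of an intercept-only model
#' whose random effect has the VanRaden kinship built from the
#' candidate markers alone. The empty set (plain i.i.d. null) competes
#' too. The winning set is pruned of mutually collinear members
#' (pairwise r^2 > `prune_r2`, keeping the better p-value).
#'
#' @param result an `assoc_result` from [glm_scan()] (or any engine with
#'   p-values)
#' @param G a complete [genotype_matrix()]
#' @param y phenotype vector
#' @param bin_sizes bin-width grid in bp (default `c(5e5, 5e6, 5e7)`)
#' @param counts set-size grid (default `seq(10, 100, 10)`); every entry
#'   is capped at `max_set`
#' @param prune_r2 LD pruning threshold among selected pseudo-QTNs
#' @param max_set hard cap on the pseudo-QTN count; default
#'   `round(sqrt(n) / sqrt(log10(n)))`, which keeps the fixed-effect
#'   model from overfitting small samples (a selected covariate set that
#'   grows with the grid rather than with n deflates every conditional
#'   test's residual variance)
#' @return list of class `pseudo_qtn_set`: `indices` (marker indices,
#'   possibly empty), `bin_bp` (winning bin size), `loglik`,
#'   `null_loglik`
#' @export
select_pseudo_qtns <- function(result, G, y,
                               bin_sizes = c(5e5, 5e6, 5e7),
                               counts = seq(10, 100, by = 10),
                               prune_r2 = 0.7, max_set = NULL) {
  y <- as_phenotype_values(y)
  if (is.null(max_set))
    max_set <- max(2L, round(sqrt(length(y)) / sqrt(log10(length(y)))))
  counts <- sort(unique(pmin(counts, max_set)))
  p <- result$p
  null_ll <- score_candidate_set(y, NULL)
  best <- list(indices = integer(0), bin_bp = bin_sizes[1], loglik = null_ll)
  for (b in bin_sizes) {
    bin_id <- paste(G$markers$chrom, floor(G$markers$pos / b))
    ord <- order(p)
    first <- ord[!duplicated(bin_id[ord])]   # best-p marker per bin
    for (t in counts) {
      idx <- first[seq_len(min(t, length(first)))]
      poly <- idx[apply(G$dosages[idx, , drop = FALSE], 1, stats::var) > 0]
      if (!length(poly)) next
      Kc <- tryCatch(compute_kinship(subset_genotypes(G, markers = poly),
                                     "vanraden"), error = function(e) NULL)
      if (is.null(Kc)) next
      ll <- score_candidate_set(y, Kc)
      if (ll > best$loglik)
        best <- list(indices = sort(poly), bin_bp = b, loglik = ll)
    }
  }
  if (length(best$indices) > 1)
    best$indices <- prune_by_ld(best$indices, G, p, prune_r2)
  structure(list(indices = best$indices, bin_bp = best$bin_bp,
                 loglik = best$loglik, null_loglik = null_ll),
            class = "pseudo_qtn_set")
}

prune_by_ld <- function(idx, G, p, r2_max) {
  idx <- idx[order(p[idx])]                 # best first; greedy keep
  kept <- idx[1]
  for (j in idx[-1]) {
    r2 <- (stats::cor(G$dosages[j, ], t(G$dosages[kept, , drop = FALSE])))^2
    if (all(r2 <= r2_max, na.rm = TRUE)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Run the full FarmCPU-style iteration
#'
#' Alternates [glm_scan()] and [select_pseudo_qtns()] until the
#' pseudo-QTN set repeats (set equality with any earlier iteration) or
#' `max_iter` is reached. Iteration stops immediately after the first
#' scan if no marker reaches the entry threshold `p_entry` (default
#' `0.01 / M`, the reference implementation's safeguard against pseudo-
#' QTN selection on null traits). The final scan's p-values are
#' returned, with the per-iteration history attached.
#'
#' @param G a complete [genotype_matrix()]
#' @param y phenotype vector or `phenotype_vector`
#' @param Q a `pc_matrix` or covariate matrix
#' @param max_iter maximum iterations (default 10)
#' @param bin_sizes,counts,prune_r2 passed to [select_pseudo_qtns()]
#' @param p_entry entry threshold for starting the iteration; `NULL`
#'   for the default `0.01 / M`, `0` to disable the safeguard
#' @param n_pcs number of leading PCs as covariates (default 3)
#' @return an `assoc_result` with engine `"farmcpu"`, attributes
#'   `iterations` (data.frame: iteration, n_pseudo, loglik, pseudo ids)
#'   and `converged`
#' @export
run_farmcpu <- function(G, y, Q, max_iter = 10,
                        bin_sizes = c(5e5, 5e6, 5e7),
                        counts = seq(10, 100, by = 10), prune_r2 = 0.7,
                        p_entry = NULL, n_pcs = 3) {
  y <- as_phenotype_values(y)
  M <- n_markers(G)
  if (is.null(p_entry)) p_entry <- 0.01 / M
  history <- list()
  pset <- integer(0)
  scan <- glm_scan(G, y, Q, pseudo_qtns = pset, n_pcs = n_pcs)
  converged <- FALSE
  if (min(scan$p, na.rm = TRUE) > p_entry) {
    converged <- TRUE                      # nothing passes entry: GLM result
    history[[1]] <- list(iteration = 1L, pseudo = integer(0), loglik = NA)
  } else {
    prev_sets <- list(integer(0))
    for (it in seq_len(max_iter)) {
      sel <- select_pseudo_qtns(scan, G, y, bin_sizes, counts, prune_r2)
      pset <- sel$indices
      history[[it]] <- list(iteration = it, pseudo = pset, loglik = sel$loglik)
      scan <- glm_scan(G, y, Q, pseudo_qtns = pset, n_pcs = n_pcs)
      if (any(vapply(prev_sets, identical, TRUE, y = pset))) {
        converged <- TRUE
        break
      }
      prev_sets[[length(prev_sets) + 1L]] <- pset
    }
  }
  if (!converged)
    warning("FarmCPU iteration did not converge in ", max_iter, " iterations")
  iters <- data.frame(
    iteration = vapply(history, `[[`, 0L, "iteration"),
    n_pseudo = vapply(history, function(h) length(h$pseudo), 0L),
    loglik = vapply(history, function(h) as.numeric(h$loglik)[1], 0))
  iters$pseudo_ids <- vapply(history, function(h)
    paste(G$markers$id[h$pseudo], collapse = ","), "")
  res <- scan
  attr(res, "engine") <- "farmcpu"
  attr(res, "iterations") <- iters
  attr(res, "converged") <- converged
  res
}
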