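# LD-aware scoring of association results against simulated truth:
# engine-specific ranking, true positives defined by causal membership
# or r^2 > 0.6 linkage, merging of multiple positives linked to one
# causal variant, and the power / FDR / Type-I formulas
#   power = TP / n_causal,  FDR = FP / positives,  TypeI = FP / (M - n_causal).

#' Rank markers under an engine's ordering rule
#'
#' Frequentist engines sort ascending by p-value; the Bayesian engine
#' sorts descending by model frequency, breaking ties by descending
#' per-marker genetic variance and finally by marker index (stable).
#' Non-finite scores are placed last.
#'
#' @param result an `assoc_result` (p-value engines) or a
#'   `posterior_summary` (Bayesian engine)
#' @return list of class `ranked_calls`: `order` (marker indices, best
#'   first), `markers` (ids in ranked order), `engine`
#' @export
rank_markers <- function(result) {
  if (inherits(result, "posterior_summary")) {
    mf <- result$model_frequency
    mv <- result$marker_variance
    bad <- !is.finite(mf)
    mf[bad] <- -Inf
    ord <- order(-mf, -mv, seq_along(mf))
    ids <- result$markers
    engine <- "bayescpi"
  } else {
    p <- result$p
    bad <- !is.finite(p)
    p[bad] <- Inf
    ord <- order(p, seq_along(p))
    ids <- result$marker
    engine <- attr(result, "engine") %||% "unknown"
  }
  structure(list(order = ord, markers = ids[ord], engine = engine,
                 n_nonfinite = sum(bad)),
            class = "ranked_calls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match the top-K calls against the causal truth, LD-aware
#'
#' A positive is a true positive if it is itself causal or has
#' `r^2 > r2_threshold` (strict) with a causal marker on the same
#' chromosome within `window_bp`. All positives linked to the same
#' causal variant collapse to a single true positive, and the
#' effective positive count shrinks accordingly. A positive linked to
#' several causal variants is credited to the one with the highest r^2.
#'
#' @param calls a [rank_markers()] result, or an integer vector of
#'   marker indices already ordered best-first
#' @param arch a `trait_architecture` (the simulated truth)
#' @param G the complete [genotype_matrix()] both refer to
#' @param K number of top calls accepted as positives
#' @param r2_threshold LD threshold (strict `>`, default 0.6)
#' @param window_bp maximum linkage distance in bp (default `1e7`)
#' @return list: `TP`, `effective_positives`, `FP`, `detected_causals`
#'   (indices of causal markers credited), `assignment` (per-positive
#'   causal index or `NA`)
#' @export
match_positives <- function(calls, arch, G, K, r2_threshold = 0.6,
                            window_bp = 1e7) {
  pos_idx <- if (inherits(calls, "ranked_calls")) calls$order else as.integer(calls)
  K <- min(K, length(pos_idx))
  pos_idx <- pos_idx[seq_len(K)]
  if (K == 0)
    return(list(TP = 0L, effective_positives = 0L, FP = 0L,
                detected_causals = integer(0), assignment = integer(0)))
  assignment <- link_to_causals(pos_idx, arch$causal_indices, G,
                                r2_threshold, window_bp)
  detected <- unique(assignment[!is.na(assignment)])
  TP <- length(detected)
  FP <- sum(is.na(assignment))
  effective <- TP + FP
  list(TP = TP, effective_positives = effective, FP = FP,
       detected_causals = detected, assignment = assignment)
}

# per-positive: index of the linked causal marker (highest r^2 wins), or NA
link_to_causals <- function(pos_idx, causal, G, r2_threshold, window_bp) {
  X <- G$dosages
  chrom <- G$markers$chrom
  pos <- G$markers$pos
  vapply(pos_idx, function(j) {
    if (j %in% causal) return(j)
    cand <- causal[chrom[causal] == chrom[j] &
                     abs(pos[causal] - pos[j]) < window_bp]
    if (!length(cand)) return(NA_integer_)
    xj <- X[j, ]
    if (stats::var(xj) == 0) return(NA_integer_)
    r2 <- vapply(cand, function(ci) {
      xc <- X[ci, ]
      if (stats::var(xc) == 0) return(0)
      stats::cor(xj, xc)^2
    }, 0)
    if (max(r2) > r2_threshold) cand[which.max(r2)] else NA_integer_
  }, NA_integer_)
}

#' Power, FDR and Type-I error from matched counts
#'
#' `power = TP / n_causal`; `fdr = FP / effective_positives` (reported
#' as 0 with `fdr_defined = FALSE` when there are no positives);
#' `type1 = FP / (M - n_causal)`.
#'
#' @param TP true positives (merged)
#' @param effective_positives positives after merging LD-linked duplicates
#' @param FP false positives
#' @param n_causal number of simulated causal variants (> 0)
#' @param M total marker count
#' @return one-row data.frame: `TP`, `effective_positives`, `FP`,
#'   `power`, `fdr`, `type1`, `fdr_defined`
#' @export
compute_metrics <- function(TP, effective_positives, FP, n_causal, M) {
  if (n_causal <= 0) stop("n_causal must be positive")
  stopifnot(TP + FP == effective_positives, TP <= n_causal)
  data.frame(TP = TP, effective_positives = effective_positives, FP = FP,
             power = TP / n_causal,
             fdr = if (effective_positives > 0) FP / effective_positives else 0,
             type1 = FP / (M - n_causal),
             fdr_defined = effective_positives > 0)
}

#' Metrics along the increasing-rank curve
#'
#' Evaluates [compute_metrics()] at every accepted-positive count `K`
#' in `K_grid` (default `1..2 n_causal`), reusing a single LD-matching
#' pass over the largest K.
#'
#' @param result an `assoc_result` or `posterior_summary`
#' @param arch the `trait_architecture` truth
#' @param G the complete [genotype_matrix()]
#' @param K_grid accepted-positive counts (default `1:(2 * n_causal)`)
#' @param r2_threshold,window_bp see [match_positives()]
#' @return data.frame of class `evaluation_report`: one row per K with
#'   the [compute_metrics()] columns plus `K` and `engine`
#' @export
metrics_curve <- function(result, arch, G, K_grid = NULL,
                          r2_threshold = 0.6, window_bp = 1e7) {
  calls <- if (inherits(result, "ranked_calls")) result else rank_markers(result)
  n_causal <- length(arch$causal_indices)
  M <- n_markers(G)
  if (is.null(K_grid)) K_grid <- seq_len(min(2 * n_causal, M))
  K_grid <- sort(unique(pmin(K_grid, M)))
  Kmax <- max(K_grid)
  assignment <- link_to_causals(calls$order[seq_len(Kmax)],
                                arch$causal_indices, G,
                                r2_threshold, window_bp)
  rows <- lapply(K_grid, function(K) {
    a <- assignment[seq_len(K)]
    detected <- unique(a[!is.na(a)])
    TP <- length(detected)
    FP <- sum(is.na(a))
    cbind(K = K, compute_metrics(TP, TP + FP, FP, n_causal, M))
  })
  rep_ <- do.call(rbind, rows)
  rep_$engine <- calls$engine
  class(rep_) <- c("evaluation_report", "data.frame")
  rep_
}

#' Classify causal variants by which engines detected them
#'
#' Causal variants fall into four mutually exclusive categories given
#' two engines' accepted positives at a common K: detected by both, by
#' the first only, by the second only, or by neither. MAF and absolute
#' effect size are compared between category pairs by two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests.
#'
#' @param result_a,result_b the two engines' results
#' @param arch the `trait_architecture` truth
#' @param G the complete [genotype_matrix()]
#' @param K accepted-positive count applied to both engines
#' @param r2_threshold,window_bp see [match_positives()]
#' @param labels length-2 character: names of the two engines
#' @return list: `categories` (data.frame: causal index, marker id,
#'   maf, abs_effect, category), `tests` (data.frame of pairwise
#'   Mann-Whitney p-values for maf and abs_effect; skipped pairs
#'   flagged)
#' @export
detection_categories <- function(result_a, result_b, arch, G, K,
                                 r2_threshold = 0.6, window_bp = 1e7,
                                 labels = c("farmcpu", "bayescpi")) {
  ma <- match_positives(rank_markers(result_a), arch, G, K, r2_threshold,
                        window_bp)
  mb <- match_positives(rank_markers(result_b), arch, G, K, r2_threshold,
                        window_bp)
  causal <- arch$causal_indices
  in_a <- causal %in% ma$detected_causals
  in_b <- causal %in% mb$detected_causals
  category <- ifelse(in_a & in_b, "both",
                     ifelse(in_a, paste0(labels[1], "_only"),
                            ifelse(in_b, paste0(labels[2], "_only"),
                                   "neither")))
  maf <- summarize_markers(subset_genotypes(G, markers = causal))$maf
  cats <- data.frame(causal_index = causal,
                     marker = G$markers$id[causal],
                     maf = maf, abs_effect = abs(arch$effects),
                     category = category, stringsAsFactors = FALSE)
  pairs <- utils::combn(unique(category), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    ga <- cats[cats$category == pr[1], ]
    gb <- cats[cats$category == pr[2], ]
    if (nrow(ga) == 0 || nrow(gb) == 0)
      return(data.frame(group1 = pr[1], group2 = pr[2], p_maf = NA,
                        p_abs_effect = NA, skipped = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2],
               p_maf = stats::wilcox.test(ga$maf, gb$maf, exact = FALSE)$p.value,
               p_abs_effect = stats::wilcox.test(ga$abs_effect, gb$abs_effect,
                                                 exact = FALSE)$p.value,
               skipped = FALSE)
  }))
  list(categories = cats, tests = tests)
}
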