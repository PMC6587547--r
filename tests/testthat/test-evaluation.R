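make_arch <- function(idx, effects = rep(1, length(idx)), h2 = 0.9) {
  structure(list(causal_indices = as.integer(idx), effects = effects,
                 h2 = h2, effect_dist = "normal", seed = 1L),
            class = "trait_architecture")
}

test_that("frequentist ranking sorts ascending by p with stable ties", {
  res <- data.frame(marker = c("m1", "m2", "m3"), p = c(0.5, 1e-4, 0.01))
  attr(res, "engine") <- "mlm"
  class(res) <- c("assoc_result", "data.frame")
  rk <- rank_markers(res)
  expect_equal(rk$order, c(2L, 3L, 1L))
  # all equal -> marker-index order
  res$p <- rep(0.3, 3)
  expect_equal(rank_markers(res)$order, 1:3)
  # non-finite placed last
  res$p <- c(NaN, 0.1, 0.2)
  rk2 <- rank_markers(res)
  expect_equal(rk2$order, c(2L, 3L, 1L))
  expect_equal(rk2$n_nonfinite, 1L)
})

test_that("Bayesian ranking breaks frequency ties by marker variance", {
  fake <- structure(list(model_frequency = c(0.9, 0.9, 0.2),
                         marker_variance = c(0.1, 0.4, 0.0),
                         markers = c("m1", "m2", "m3")),
                    class = "posterior_summary")
  rk <- rank_markers(fake)
  expect_equal(rk$order, c(2L, 1L, 3L))
  expect_equal(rk$engine, "bayescpi")
})

test_that("membership-only matching counts TP/FP per the toy example", {
  # positives {m1, m7, m9}, causal {m1, m4}, no LD links
  G <- toy_genotypes(matrix(rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0), 10),
                            nrow = 10, byrow = FALSE),
                     pos = seq(1e6, 1e7, 1e6))
  set.seed(5)
  G$dosages <- matrix(rbinom(100, 2, 0.5), 10)   # independent markers
  arch <- make_arch(c(1, 4))
  m <- match_positives(c(1L, 7L, 9L), arch, G, K = 3, r2_threshold = 0.99)
  expect_equal(m$TP, 1L)
  expect_equal(m$FP, 2L)
  expect_equal(m$effective_positives, 3L)
})

test_that("positives linked to one causal variant merge into a single TP", {
  # p1 and p2 both proxy c1 (r2 > 0.6); p3 unlinked
  set.seed(8)
  c1 <- rbinom(60, 1, 0.5) * 2
  flip <- function(x, k) { i <- sample(60, k); x[i] <- 2 - x[i]; x }
  dos <- rbind(c1, flip(c1, 4), flip(c1, 5), rbinom(60, 1, 0.5) * 2)
  G <- toy_genotypes(dos, pos = c(1e3, 2e3, 3e3, 4e3))
  arch <- make_arch(1)
  r12 <- cor(dos[1, ], dos[2, ])^2
  r13 <- cor(dos[1, ], dos[3, ])^2
  expect_true(r12 > 0.6 && r13 > 0.6)
  m <- match_positives(c(2L, 3L, 4L), arch, G, K = 3)
  expect_equal(m$TP, 1L)
  expect_equal(m$effective_positives, 2L)
  expect_equal(m$FP, 1L)
})

test_that("r2 exactly at the threshold is NOT a true positive (strict >)", {
  # two markers engineered to r2 == 0.64, then threshold set to exactly 0.64
  x <- c(rep(0, 5), rep(2, 5))
  yv <- c(rep(0, 4), 2, 0, rep(2, 4))
  r2 <- cor(x, yv)^2
  G <- toy_genotypes(rbind(x, yv), pos = c(1000, 2000))
  arch <- make_arch(1)
  m_at <- match_positives(2L, arch, G, K = 1, r2_threshold = r2)
  expect_equal(m_at$TP, 0L)
  expect_equal(m_at$FP, 1L)
  m_below <- match_positives(2L, arch, G, K = 1, r2_threshold = r2 - 1e-9)
  expect_equal(m_below$TP, 1L)
})

test_that("LD matching respects the same-chromosome 10 Mb window", {
  x <- rbinom(80, 1, 0.5) * 2
  G <- toy_genotypes(rbind(x, x, x),
                     chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1e6, 1e6 + 2e7, 1e6))
  arch <- make_arch(1)
  # marker 2: same chromosome but 20 Mb away; marker 3: other chromosome
  m <- match_positives(c(2L, 3L), arch, G, K = 2)
  expect_equal(m$TP, 0L)
  expect_equal(m$FP, 2L)
})

test_that("metric formulas follow power = TP/n_causal, FDR = FP/pos, TypeI = FP/noncausal", {
  row <- compute_metrics(TP = 1, effective_positives = 3, FP = 2,
                         n_causal = 2, M = 10)
  expect_equal(row$power, 0.5)
  expect_equal(row$fdr, 2 / 3)
  expect_equal(row$type1, 0.25)
  perfect <- compute_metrics(TP = 2, effective_positives = 2, FP = 0,
                             n_causal = 2, M = 10)
  expect_equal(c(perfect$power, perfect$fdr, perfect$type1), c(1, 0, 0))
  empty <- compute_metrics(TP = 0, effective_positives = 0, FP = 0,
                           n_causal = 2, M = 10)
  expect_equal(c(empty$power, empty$fdr, empty$type1), c(0, 0, 0))
  expect_false(empty$fdr_defined)
  expect_error(compute_metrics(0, 0, 0, 0, 10), "n_causal")
})

test_that("metrics curve is monotone in K and perfect ranking reaches power 1", {
  set.seed(30)
  dos <- matrix(rbinom(50 * 120, 2, 0.4), 50)
  G <- toy_genotypes(dos, pos = sort(sample.int(1e9, 50)))
  causal <- c(4L, 17L, 30L, 42L)
  arch <- make_arch(causal)
  # oracle ranking: causal first
  fake <- data.frame(marker = G$markers$id,
                     p = replace(rep(0.5, 50), causal, 1e-8))
  attr(fake, "engine") <- "mlm"
  class(fake) <- c("assoc_result", "data.frame")
  curve <- metrics_curve(fake, arch, G)
  expect_true(all(diff(curve$TP) >= 0))
  expect_true(all(diff(curve$power) >= 0))
  expect_true(all(diff(curve$type1) >= 0))
  expect_true(all(curve$effective_positives <= curve$K))
  expect_true(all(curve$TP + curve$FP == curve$effective_positives))
  at4 <- curve[curve$K == 4, ]
  expect_equal(at4$power, 1)
  expect_equal(at4$fdr, 0)
  # single-K grid equals compute_metrics at the best call
  one <- metrics_curve(fake, arch, G, K_grid = 1)
  expect_equal(one$TP, 1L)
  expect_equal(one$power, 0.25)
})

test_that("random rankings on LD-free markers give hypergeometric power at K = n_causal", {
  set.seed(31)
  M <- 2000; N <- 80; n_causal <- 40
  dos <- matrix(rbinom(M * N, 2, 0.5), M)
  G <- toy_genotypes(dos, pos = seq_len(M) * 3e7)   # all pairs > 10 Mb apart
  arch <- make_arch(seq_len(n_causal))
  powers <- sapply(1:30, function(s) {
    set.seed(s)
    ord <- sample.int(M)
    m <- match_positives(ord, arch, G, K = n_causal)
    m$TP / n_causal
  })
  expected <- n_causal / M
  se <- sqrt(expected * (1 - expected) / (n_causal * 30))
  expect_lt(abs(mean(powers) - expected), 3 * se)
})

test_that("detection categories partition causal variants and tests behave", {
  set.seed(33)
  dos <- matrix(rbinom(40 * 100, 2, 0.4), 40)
  G <- toy_genotypes(dos, pos = sort(sample.int(1e9, 40)))
  causal <- c(1L, 5L, 9L, 13L)
  arch <- make_arch(causal, effects = c(2, 1.5, 1, 0.5))
  mk_res <- function(top) {
    d <- data.frame(marker = G$markers$id,
                    p = replace(rep(0.5, 40), top, 1e-9))
    attr(d, "engine") <- "mlm"
    class(d) <- c("assoc_result", "data.frame")
    d
  }
  res_a <- mk_res(c(1L, 5L))     # detects c1, c2
  res_b <- mk_res(c(5L, 9L))     # detects c2, c3
  dc <- detection_categories(res_a, res_b, arch, G, K = 2,
                             labels = c("A", "B"))
  got <- setNames(dc$categories$category, dc$categories$causal_index)
  expect_equal(unname(got[as.character(c(1, 5, 9, 13))]),
               c("A_only", "both", "B_only", "neither"))
  expect_true(all(table(dc$categories$category) == 1))
  # identical groups -> Mann-Whitney p near 1; separated groups -> tiny p
  set.seed(34)
  g1 <- rnorm(50); g2 <- rnorm(50, 2)
  expect_gt(stats::wilcox.test(g1, g1, exact = FALSE)$p.value, 0.99)
  expect_lt(stats::wilcox.test(g1, g2, exact = FALSE)$p.value, 1e-4)
})

test_that("power varies little across r2 thresholds 0.6-0.9 under moderate LD", {
  G <- filter_markers(pop_small()$genotypes, min_maf = 0.05)
  Q <- compute_pca(G); K <- compute_kinship(G, "centered")
  powers <- sapply(1:3, function(s) {
    arch <- sample_architecture(G, 16, h2 = 0.9, seed = 900 + s)
    y <- simulate_trait(G, arch)$values
    res <- scan_mlm(G, y, Q, K)
    sapply(c(0.6, 0.7, 0.8, 0.9), function(thr) {
      m <- match_positives(rank_markers(res), arch, G, K = 16,
                           r2_threshold = thr)
      m$TP / 16
    })
  })
  mean_by_threshold <- rowMeans(powers)
  expect_lt(max(mean_by_threshold) - min(mean_by_threshold), 0.1)
})
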