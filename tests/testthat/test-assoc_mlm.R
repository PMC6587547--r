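# fixtures reused across blocks: structured population (MAF-filtered, as
# any real scan would be), covariates, kinship
mlm_fix <- function() fixture("mlm_fix", function() {
  G <- filter_markers(pop_small()$genotypes, min_maf = 0.05)
  list(G = G, Q = compute_pca(G), K = compute_kinship(G, "centered"))
})

# restricted likelihood from first principles: no rotation, no profiling
reml_direct_oracle <- function(sg2, se2, y, W, Kv) {
  V <- sg2 * Kv + se2 * diag(length(y))
  Vi <- solve(V)
  WVW <- t(W) %*% Vi %*% W
  b <- solve(WVW, t(W) %*% Vi %*% y)
  r <- y - W %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(WVW)$modulus +
                       t(r) %*% Vi %*% r))
}

test_that("REML with identity kinship collapses to OLS", {
  f <- mlm_fix()
  G <- f$G
  N <- n_individuals(G)
  Kid <- structure(list(values = diag(N), estimator = "centered"),
                   class = "kinship_matrix")
  arch <- sample_architecture(G, 10, h2 = 0.6, seed = 2)
  y <- simulate_trait(G, arch)$values
  vc <- fit_null_mlm(y, f$Q, Kid)
  W <- cbind(1, f$Q$scores[, 1:3])
  ols_var <- sum(stats::lm.fit(W, y)$residuals^2) / (N - 4)
  # with K = I the rotated weights are constant: total variance = OLS error var
  expect_equal(vc$sigma_g2 + vc$sigma_e2, ols_var, tolerance = 1e-6)
})

test_that("REML recovers variance components simulated under the model", {
  f <- mlm_fix()
  K <- f$K
  eg <- eigen(K$values, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  lam_hats <- sapply(1:10, function(s) {
    set.seed(s)
    u <- as.vector(L %*% rnorm(nrow(L))) * sqrt(2)   # sigma_g2 = 2
    y <- u + rnorm(nrow(L))                          # sigma_e2 = 1
    fit_null_mlm(y, NULL, K)$lambda
  })
  expect_lt(abs(mean(lam_hats) - 2), 0.3 * 2)
})

test_that("profiled REML agrees with a from-scratch 2-D grid oracle", {
  f <- mlm_fix()
  W <- cbind(1, f$Q$scores[, 1:3])
  set.seed(101)
  y <- rnorm(n_individuals(f$G))
  vc <- fit_null_mlm(y, f$Q, f$K)
  grid <- expand.grid(sg2 = seq(0.01, 1.5, length.out = 40),
                      se2 = seq(0.3, 1.5, length.out = 40))
  ll <- mapply(reml_direct_oracle, grid$sg2, grid$se2,
               MoreArgs = list(y = y, W = W, Kv = f$K$values))
  best <- grid[which.max(ll), ]
  expect_lt(abs(vc$sigma_g2 - best$sg2), 0.04)   # grid resolution
  expect_lt(abs(vc$sigma_e2 - best$se2), 0.04)
  # and the returned optimum beats the lambda search-range ends on the
  # oracle's own scale
  at_opt <- reml_direct_oracle(vc$sigma_g2, vc$sigma_e2, y, W, f$K$values)
  at_low <- reml_direct_oracle(1e-5 * vc$sigma_e2, vc$sigma_e2, y, W, f$K$values)
  at_high <- reml_direct_oracle(1e5 * vc$sigma_e2, vc$sigma_e2, y, W, f$K$values)
  expect_gte(at_opt, at_low - 1e-6)
  expect_gte(at_opt, at_high - 1e-6)
})

test_that("null-trait genetic variance sits stochastically below a true signal's", {
  f <- mlm_fix()
  eg <- eigen(f$K$values, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  ratio <- sapply(1:8, function(s) {
    set.seed(100 + s)
    y_null <- rnorm(n_individuals(f$G))
    y_gen <- as.vector(L %*% rnorm(n_individuals(f$G))) * sqrt(2) +
      rnorm(n_individuals(f$G))
    c(null = fit_null_mlm(y_null, f$Q, f$K)$lambda,
      gen = fit_null_mlm(y_gen, f$Q, f$K)$lambda)
  })
  expect_lt(mean(ratio["null", ]), mean(ratio["gen", ]) / 2)
})

test_that("scan with identity kinship matches the OLS closed form", {
  f <- mlm_fix()
  G <- subset_genotypes(f$G, markers = 1:40)
  N <- n_individuals(G)
  Kid <- structure(list(values = diag(N), estimator = "centered"),
                   class = "kinship_matrix")
  arch <- sample_architecture(G, 3, h2 = 0.7, seed = 9)
  y <- simulate_trait(G, arch)$values
  res <- scan_mlm(G, y, f$Q, Kid)
  W <- cbind(1, f$Q$scores[, 1:3])
  p_oracle <- ols_scan_oracle(G, y, W)
  poly <- apply(G$dosages, 1, var) > 0
  expect_equal(res$p[poly], p_oracle[poly], tolerance = 1e-8)
})

test_that("null traits give uniform p-values (KS)", {
  f <- mlm_fix()
  crit <- 1.63 / sqrt(n_markers(f$G))    # 1% critical value, large-sample KS
  ok <- sapply(1:10, function(s) {
    set.seed(200 + s)
    y <- rnorm(n_individuals(f$G))
    res <- scan_mlm(f$G, y, f$Q, f$K)
    ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
    ks$statistic < crit
  })
  expect_gte(mean(ok), 0.9)
})

test_that("a dominant causal marker attains the minimum p-value", {
  f <- mlm_fix()
  s <- summarize_markers(f$G)
  j <- which(s$maf > 0.3)[5]
  arch <- structure(list(causal_indices = j, effects = 1, h2 = 0.9,
                         effect_dist = "normal", seed = 33L),
                    class = "trait_architecture")
  y <- simulate_trait(f$G, arch)$values
  res <- scan_mlm(f$G, y, f$Q, f$K)
  # the top marker is the causal one or a near-perfect LD proxy of it
  top <- which.min(res$p)
  r2 <- cor(f$G$dosages[top, ], f$G$dosages[j, ])^2
  expect_gt(r2, 0.9)
})

test_that("approx and exact modes agree closely on the top signals", {
  f <- mlm_fix()
  G <- f$G
  arch <- sample_architecture(G, 8, h2 = 0.8, seed = 12)
  y <- simulate_trait(G, arch)$values
  ra <- scan_mlm(G, y, f$Q, f$K, mode = "approx")
  re <- scan_mlm(G, y, f$Q, f$K, mode = "exact")
  top <- order(ra$p)[1:10]
  rel <- abs(log10(ra$p[top]) - log10(re$p[top])) / abs(log10(re$p[top]))
  expect_lt(max(rel), 0.15)
})

test_that("scan is invariant to phenotype shifts and marker relabeling", {
  f <- mlm_fix()
  arch <- sample_architecture(f$G, 6, h2 = 0.7, seed = 21)
  y <- simulate_trait(f$G, arch)$values
  r1 <- scan_mlm(f$G, y, f$Q, f$K)
  r2 <- scan_mlm(f$G, y + 100, f$Q, f$K)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  perm <- sample(seq_len(n_markers(f$G)))
  Gp <- subset_genotypes(f$G, markers = perm)
  rp <- scan_mlm(Gp, y, f$Q, f$K)
  expect_equal(rp$p, r1$p[perm], tolerance = 1e-9)
})

test_that("monomorphic markers are flagged with p = 1", {
  f <- mlm_fix()
  G <- subset_genotypes(f$G, markers = 1:20)
  G$dosages[3, ] <- 2
  arch <- sample_architecture(G, 2, h2 = 0.8, seed = 3)
  y <- simulate_trait(G, arch)$values
  res <- scan_mlm(G, y, f$Q, f$K)
  expect_equal(res$p[3], 1)
  expect_equal(res$flag[3], "monomorphic")
})

test_that("Bonferroni calls apply the alpha/M threshold", {
  p <- c(1e-6, 1e-3, rep(0.5, 998))
  res <- data.frame(marker = paste0("m", 1:1000), p = p)
  expect_equal(bonferroni_calls(res, 0.05), "m1")   # threshold 5e-5
  res2 <- data.frame(marker = paste0("m", 1:100), p = rep(1, 100))
  expect_length(bonferroni_calls(res2, 0.05), 0)
  res3 <- data.frame(marker = c("a", "b"), p = c(4.9e-4, 5.1e-4))
  res3 <- rbind(res3, data.frame(marker = paste0("x", 1:98), p = 1))
  expect_equal(bonferroni_calls(res3, 0.05), "a")   # threshold 5e-4, strict <
})
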