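# Orchestration of the factorial benchmark: architectures (QTN counts) x
# heritabilities x replicates x engines, with collision-free per-cell
# seeds, the population-size subsampling experiment, and aggregation /
# plotting of the tidy results table.

#' Configuration of a benchmark sweep
#'
#' The default design is the full factorial benchmark: QTN counts
#' `2^1 .. 2^10`, heritabilities `0.1 .. 1.0` in steps of 0.1, and 10
#' replicates per cell — exactly 1000 phenotype datasets per
#' population.
#'
#' @param n_qtn_grid causal-variant counts (default `2^(1:10)`)
#' @param h2_grid heritabilities (default `seq(0.1, 1, 0.1)`)
#' @param replicates replicates per cell (default 10)
#' @param engines subset of `c("mlm", "farmcpu", "bayescpi")`
#' @param base_seed base RNG seed; per-cell seeds are derived by a
#'   deterministic integer mix (see [cell_seed()])
#' @param K_grid accepted-positive counts per cell; `NULL` for the
#'   default `1..2 n_qtn` thinned log-spaced above 100
#' @param bayes_config `bayes_chain_config` template for the Bayesian
#'   engine (its seed is overridden per cell)
#' @return list of class `sweep_config`
#' @export
sweep_config <- function(n_qtn_grid = 2^(1:10),
                         h2_grid = seq(0.1, 1, by = 0.1),
                         replicates = 10,
                         engines = c("mlm", "farmcpu", "bayescpi"),
                         base_seed = 1L, K_grid = NULL,
                         bayes_config = bayes_chain_config(
                           chain_length = 2000, burnin = 200)) {
  engines <- match.arg(engines, several.ok = TRUE)
  stopifnot(length(n_qtn_grid) > 0, length(h2_grid) > 0, replicates >= 1)
  structure(list(n_qtn_grid = n_qtn_grid, h2_grid = h2_grid,
                 replicates = as.integer(replicates), engines = engines,
                 base_seed = as.integer(base_seed), K_grid = K_grid,
                 bayes_config = bayes_config),
            class = "sweep_config")
}

#' Enumerate the cells of a sweep design
#' @param config a [sweep_config()]
#' @return data.frame with one row per phenotype dataset: `n_qtn`,
#'   `h2`, `replicate`, `seed`
#' @export
enumerate_design <- function(config) {
  cells <- expand.grid(replicate = seq_len(config$replicates),
                       h2 = config$h2_grid, n_qtn = config$n_qtn_grid)
  cells <- cells[, c("n_qtn", "h2", "replicate")]
  cells$seed <- mapply(cell_seed, cells$n_qtn, round(cells$h2 * 1000),
                       cells$replicate,
                       MoreArgs = list(base_seed = config$base_seed))
  rownames(cells) <- NULL
  cells
}

#' Deterministic collision-free per-cell seed
#'
#' A multiplicative integer mix (Knuth-style) of the base seed and the
#' cell coordinates, folded into the 31-bit range R accepts, so grids
#' can be extended without perturbing existing cells.
#'
#' @param n_qtn,h2_key,replicate integer cell coordinates (`h2_key`
#'   should be an integerized heritability, e.g. `h2 * 1000`)
#' @param base_seed base seed
#' @return a single integer seed
#' @export
cell_seed <- function(n_qtn, h2_key, replicate, base_seed = 1L) {
  mix <- function(h, k) ((h * 2654435761 + k * 40503 + 97) %% 2147483647)
  h <- mix(base_seed %% 2147483647, 0)
  h <- mix(h, n_qtn)
  h <- mix(h, h2_key)
  h <- mix(h, replicate)
  as.integer(h %% 2147483562 + 1)
}

default_K_grid <- function(n_qtn) {
  up <- 2 * n_qtn
  if (up <= 100) return(seq_len(up))
  unique(c(1:100, round(10^(seq(2, log10(up), by = 0.05)))))
}

run_engine <- function(engine, G, y, Q, K, bayes_config, seed) {
  switch(engine,
         mlm = scan_mlm(G, y, Q, K),
         farmcpu = run_farmcpu(G, y, Q),
         bayescpi = {
           cfg <- bayes_config
           cfg$seed <- seed
           run_bayescpi(G, y, cfg)
         },
         stop("unknown engine: ", engine))
}

#' Run the factorial benchmark sweep
#'
#' For every (n_qtn, h2, replicate) cell: sample an architecture,
#' simulate the trait, run each engine, and evaluate the
#' increasing-rank metrics curve. PCA covariates and kinship are
#' computed once. Per-cell artifacts can be written to `out_dir`
#' (one TSV per cell and engine); cells whose artifact already exists
#' are skipped and reloaded, making long sweeps resumable.
#'
#' @param config a [sweep_config()]
#' @param G a complete [genotype_matrix()] (the benchmark population)
#' @param out_dir optional directory for resumable per-cell artifacts
#' @param r2_threshold LD threshold for true-positive matching
#' @param verbose log per-cell progress to stderr? Default `TRUE`
#' @return tidy data.frame: `engine`, `n_qtn`, `h2`, `replicate`, `K`,
#'   `TP`, `effective_positives`, `FP`, `power`, `fdr`, `type1`,
#'   `fdr_defined`, `failed`
#' @export
run_sweep <- function(config, G, out_dir = NULL, r2_threshold = 0.6,
                      verbose = TRUE) {
  design <- enumerate_design(config)
  Q <- compute_pca(G)
  K <- compute_kinship(G, "centered")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- vector("list", nrow(design) * length(config$engines))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    cell <- design[i, ]
    arch <- sample_architecture(G, cell$n_qtn, h2 = cell$h2,
                                seed = cell$seed)
    pheno <- simulate_trait(G, arch)
    K_grid <- config$K_grid %||% default_K_grid(cell$n_qtn)
    for (engine in config$engines) {
      k <- k + 1L
      tag <- sprintf("cell_q%d_h%03d_r%d_%s", cell$n_qtn,
                     round(cell$h2 * 100), cell$replicate, engine)
      artifact <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".tsv"))
      if (!is.null(out_dir) && file.exists(artifact)) {
        if (verbose) message("[sweep] ", tag, " (cached)")
        out[[k]] <- utils::read.table(artifact, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
        next
      }
      if (verbose) message("[sweep] ", tag)
      row <- tryCatch({
        res <- run_engine(engine, G, pheno, Q, K, config$bayes_config,
                          seed = cell$seed + 1L)
        curve <- metrics_curve(res, arch, G, K_grid = K_grid,
                               r2_threshold = r2_threshold)
        curve$engine <- engine
        curve$n_qtn <- cell$n_qtn
        curve$h2 <- cell$h2
        curve$replicate <- cell$replicate
        curve$failed <- FALSE
        as.data.frame(curve)
      }, error = function(e) {
        warning("engine ", engine, " failed in cell ", tag, ": ",
                conditionMessage(e))
        data.frame(K = NA, TP = NA, effective_positives = NA, FP = NA,
                   power = NA, fdr = NA, type1 = NA, fdr_defined = NA,
                   engine = engine, n_qtn = cell$n_qtn, h2 = cell$h2,
                   replicate = cell$replicate, failed = TRUE)
      })
      if (!is.null(out_dir))
        utils::write.table(row, artifact, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power versus population size by subsampling
#'
#' Individuals are sampled without replacement at each target size; the
#' trait is re-simulated on the subsample (same architecture seeds per
#' replicate across sizes) and the single-marker mixed model's
#' Bonferroni power is reported.
#'
#' @param G a complete [genotype_matrix()]
#' @param sizes subsample sizes (each `<= N`)
#' @param n_qtn causal-variant count (benchmark design uses 32/128/256)
#' @param h2 heritability (benchmark design uses 0.7)
#' @param replicates replicates per size (default 10)
#' @param base_seed base seed
#' @param alpha Bonferroni family-wise level (default 0.05)
#' @param r2_threshold LD threshold for true-positive matching
#' @return data.frame: `size`, `replicate`, `n_calls`, `TP`, `power`
#' @export
subsample_experiment <- function(G, sizes, n_qtn, h2 = 0.7,
                                 replicates = 10, base_seed = 1L,
                                 alpha = 0.05, r2_threshold = 0.6) {
  N <- n_individuals(G)
  if (any(sizes > N)) stop("subsample size exceeds population size")
  rows <- list()
  for (size in sizes) {
    for (r in seq_len(replicates)) {
      seed <- cell_seed(n_qtn, round(h2 * 1000) + size, r, base_seed)
      set.seed(seed)
      sub <- sort(sample.int(N, size))
      Gs <- subset_genotypes(G, samples = sub)
      arch <- sample_architecture(Gs, n_qtn, h2 = h2,
                                  seed = cell_seed(n_qtn, round(h2 * 1000),
                                                   r, base_seed))
      pheno <- simulate_trait(Gs, arch)
      Q <- compute_pca(Gs)
      K <- compute_kinship(Gs, "centered")
      res <- scan_mlm(Gs, pheno, Q, K)
      calls <- bonferroni_calls(res, alpha)
      idx <- match(calls, Gs$markers$id)
      m <- match_positives(idx[order(res$p[idx])], arch, Gs,
                           K = length(idx), r2_threshold = r2_threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, replicate = r, n_calls = length(calls),
                   TP = m$TP, power = m$TP / n_qtn)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a sweep table and render the benchmark figures
#'
#' Means and standard errors over replicates per (engine, n_qtn, h2, K)
#' cell, plus ggplot objects: power and FDR versus accepted-positive
#' count per engine, and power versus architecture/heritability.
#'
#' @param results the tidy table from [run_sweep()]
#' @param out_dir optional directory to write the aggregate TSV and
#'   PDFs into
#' @return list: `aggregate` (data.frame with `mean_power`, `se_power`,
#'   `mean_fdr`, `se_fdr`, `mean_type1`, `n_reps`), `plots` (named list
#'   of ggplot objects)
#' @export
summarize_report <- function(results, out_dir = NULL) {
  ok <- results[!results$failed & !is.na(results$K), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful cells to summarize")
  key <- interaction(ok$engine, ok$n_qtn, ok$h2, ok$K, drop = TRUE)
  agg_one <- function(v) {
    m <- tapply(v, key, mean)
    s <- tapply(v, key, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
    list(mean = as.numeric(m), se = as.numeric(s))
  }
  first <- !duplicated(key)
  pw <- agg_one(ok$power); fd <- agg_one(ok$fdr); t1 <- agg_one(ok$type1)
  base <- ok[first, c("engine", "n_qtn", "h2", "K")][order(key[first]), ]
  aggregate <- data.frame(base,
                          mean_power = pw$mean, se_power = pw$se,
                          mean_fdr = fd$mean, se_fdr = fd$se,
                          mean_type1 = t1$mean, se_type1 = t1$se,
                          n_reps = as.integer(table(key)))
  rownames(aggregate) <- NULL
  matched <- aggregate[aggregate$K == aggregate$n_qtn, , drop = FALSE]
  plots <- list(
    power_vs_K = ggplot2::ggplot(
      aggregate, ggplot2::aes(x = K, y = mean_power, colour = engine)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(h2 ~ n_qtn, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "accepted positives (K)", y = "mean power"),
    fdr_vs_K = ggplot2::ggplot(
      aggregate, ggplot2::aes(x = K, y = mean_fdr, colour = engine)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(h2 ~ n_qtn, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "accepted positives (K)", y = "mean FDR"),
    power_vs_architecture = ggplot2::ggplot(
      matched, ggplot2::aes(x = n_qtn, y = mean_power, colour = engine)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~h2, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "number of causal variants",
                    y = "mean power at K = n_qtn"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(aggregate, file.path(out_dir, "aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(plots))
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, paste0(nm, ".pdf")), plots[[nm]],
        width = 9, height = 7))
  }
  list(aggregate = aggregate, plots = plots)
}
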