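#' Construct a GenotypeMatrix
#'
#' The central container of the package: an M (markers) x N (individuals)
#' dosage matrix counting copies of the designated "counted" allele
#' (0/1/2, `NA` for missing calls), together with a marker map
#' (id, chromosome, 1-based position in bp, counted allele, other allele)
#' and sample ids.
#'
#' @param dosages numeric matrix, markers in rows, individuals in columns;
#'   non-missing entries must be 0, 1 or 2 (fractional dosages in `[0, 2]`
#'   are permitted only after mean-imputation, see [impute_missing()]).
#' @param markers data.frame with columns `id`, `chrom`, `pos`,
#'   `counted`, `other`.
#' @param samples character vector of individual ids (length `ncol(dosages)`).
#' @param validate check invariants (strict 0/1/2 coding)? Default `TRUE`;
#'   set `FALSE` for matrices carrying fractional imputed dosages.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `markers`, `samples`.
#' @export
genotype_matrix <- function(dosages, markers, samples, validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(nrow(dosages) == nrow(markers), ncol(dosages) == length(samples))
  need <- c("id", "chrom", "pos", "counted", "other")
  if (!all(need %in% names(markers)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.numeric(markers$pos)
  if (validate) {
    vals <- dosages[!is.na(dosages)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      stop("non-missing dosages must be 0, 1 or 2")
  }
  dimnames(dosages) <- list(markers$id, samples)
  structure(list(dosages = dosages, markers = markers,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals (%d chromosome%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$markers$chrom)),
              if (length(unique(x$markers$chrom)) == 1) "" else "s"))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of markers / individuals
#' @param G a `genotype_matrix`
#' @return integer count
#' @export
n_markers <- function(G) nrow(G$dosages)

#' @rdname n_markers
#' @export
n_individuals <- function(G) ncol(G$dosages)

#' Subset a genotype matrix by marker and/or individual
#' @param G a `genotype_matrix`
#' @param markers marker index vector (row subset), default all
#' @param samples sample index vector (column subset), default all
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(G, markers = NULL, samples = NULL) {
  mi <- if (is.null(markers)) seq_len(n_markers(G)) else markers
  si <- if (is.null(samples)) seq_len(n_individuals(G)) else samples
  genotype_matrix(G$dosages[mi, si, drop = FALSE],
                  G$markers[mi, , drop = FALSE],
                  G$samples[si], validate = FALSE)
}

#' Read genotypes from VCF, HapMap text, or the dosage-matrix dialect
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`vcf`}{VCF v4.x, `GT` field only (parsed with \pkg{vcfR}).
#'     The counted allele is ALT, so `0/0, 0/1, 1/1` map to dosages
#'     `0, 1, 2`. Phased and unphased calls are treated identically.}
#'   \item{`hapmap`}{tab-delimited HapMap text: 11 metadata columns
#'     (`rs#, alleles, chrom, pos, strand, assembly#, center, protLSID,
#'     assayLSID, panelLSID, QCcode`) followed by one IUPAC genotype call
#'     per sample; the counted allele is the first allele of the
#'     `alleles` field, heterozygous IUPAC codes map to dosage 1 and `N`
#'     to missing.}
#'   \item{`dosage`}{the package's plain-text dosage dialect: a header
#'     row `id chrom pos counted other <sample ids...>`, then one row per
#'     marker with dosages in `{0, 1, 2, NA}`.}
#' }
#' Multi-allelic sites are rejected with an error naming the marker
#' (`multiallelic = "error"`) or dropped (`"drop"`); splitting into
#' per-allele pseudo-markers is not offered.
#'
#' @param path file path
#' @param format one of `"vcf"`, `"hapmap"`, `"dosage"`
#' @param multiallelic policy for non-biallelic sites: `"error"` or `"drop"`
#' @return a [genotype_matrix()]
#' @export
load_genotypes <- function(path, format = c("dosage", "vcf", "hapmap"),
                           multiallelic = c("error", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         dosage = read_dosage_matrix(path),
         vcf    = read_vcf_genotypes(path, multiallelic),
         hapmap = read_hapmap_genotypes(path, multiallelic))
}

read_dosage_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 6L)
    stop("dosage-matrix parse error: header must be ",
         "'id chrom pos counted other <samples...>' (line 1)")
  samples <- header[-(1:5)]
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "character", "character",
                                          rep("numeric", length(samples))),
                           check.names = FALSE, na.strings = "NA")
  if (ncol(dat) != length(header))
    stop("dosage-matrix parse error: ragged rows")
  markers <- data.frame(id = dat[[1]], chrom = dat[[2]], pos = dat[[3]],
                        counted = dat[[4]], other = dat[[5]],
                        stringsAsFactors = FALSE)
  dos <- as.matrix(dat[, -(1:5), drop = FALSE])
  bad <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(dos)) + 1
    stop(sprintf("dosage-matrix parse error: invalid dosage at marker '%s' (line %d)",
                 markers$id[row], row + 1L))
  }
  genotype_matrix(dos, markers, samples)
}

read_vcf_genotypes <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | fix$ALT %in% c(".", "")
  if (any(multi)) {
    ids <- ifelse(is.na(fix$ID[multi]) | fix$ID[multi] == ".",
                  paste0(fix$CHROM[multi], ":", fix$POS[multi]), fix$ID[multi])
    if (multiallelic == "error")
      stop("non-biallelic site(s) without split policy: ",
           paste(utils::head(ids, 5), collapse = ", "))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # dosage of the ALT allele; "|" and "/" separators treated identically
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  dos[clean %in% c("0")] <- 0    # haploid calls
  dos[clean %in% c("1")] <- 2
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  markers <- data.frame(id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                        counted = fix$ALT, other = fix$REF,
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, markers, colnames(gt))
}

# IUPAC ambiguity codes for heterozygous diploid calls
.iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_hapmap_genotypes <- function(path, multiallelic) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(dat) < 12L)
    stop("hapmap parse error: expected 11 metadata columns + >=1 sample")
  samples <- names(dat)[-(1:11)]
  alleles <- strsplit(dat[[2]], "/", fixed = TRUE)
  multi <- lengths(alleles) != 2L
  if (any(multi)) {
    if (multiallelic == "error")
      stop("non-biallelic site(s) without split policy: ",
           paste(utils::head(dat[[1]][multi], 5), collapse = ", "))
    dat <- dat[!multi, , drop = FALSE]
    alleles <- alleles[!multi]
  }
  counted <- vapply(alleles, `[`, "", 1L)
  other <- vapply(alleles, `[`, "", 2L)
  calls <- as.matrix(dat[, -(1:11), drop = FALSE])
  M <- nrow(calls)
  dos <- matrix(NA_real_, M, ncol(calls))
  cm <- matrix(counted, M, ncol(calls))
  om <- matrix(other, M, ncol(calls))
  dos[calls == cm] <- 2
  dos[calls == om] <- 0
  het <- matrix(FALSE, M, ncol(calls))
  for (code in names(.iupac_het)) {
    pair <- strsplit(.iupac_het[[code]], "")[[1]]
    ok <- (cm == pair[1] & om == pair[2]) | (cm == pair[2] & om == pair[1])
    het <- het | (calls == code & ok)
  }
  dos[het] <- 1
  markers <- data.frame(id = dat[[1]], chrom = dat[[3]], pos = as.numeric(dat[[4]]),
                        counted = counted, other = other, stringsAsFactors = FALSE)
  genotype_matrix(dos, markers, samples)
}

#' Write a genotype matrix in the dosage-matrix text dialect
#'
#' Round-trips bit-identically through [load_genotypes()] with
#' `format = "dosage"`. Missing calls are written as `NA`.
#'
#' @param G a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_genotypes <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", "chrom", "pos", "counted", "other", G$samples),
                   collapse = "\t"), con)
  body <- cbind(G$markers$id, G$markers$chrom,
                format(G$markers$pos, scientific = FALSE, trim = TRUE),
                G$markers$counted, G$markers$other,
                matrix(as.character(G$dosages), nrow(G$dosages)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Per-marker summary statistics
#'
#' Minor allele frequency, missing-call rate and heterozygosity rate per
#' marker. MAF is `min(f, 1 - f)` where `f` is the counted-allele
#' frequency over non-missing calls only; het rate is the fraction of
#' non-missing calls equal to 1.
#'
#' @param G a `genotype_matrix`
#' @return data.frame with columns `id`, `maf`, `missing_rate`, `het_rate`
#' @export
summarize_markers <- function(G) {
  X <- G$dosages
  n_obs <- rowSums(!is.na(X))
  if (any(n_obs == 0))
    stop("marker(s) with all calls missing: ",
         paste(utils::head(G$markers$id[n_obs == 0], 5), collapse = ", "))
  f <- rowSums(X, na.rm = TRUE) / (2 * n_obs)
  data.frame(id = G$markers$id,
             maf = pmin(f, 1 - f),
             missing_rate = 1 - n_obs / ncol(X),
             het_rate = rowSums(X == 1, na.rm = TRUE) / n_obs,
             stringsAsFactors = FALSE)
}

#' Filter markers on missingness, heterozygosity and MAF
#'
#' Retains markers with `missing_rate <= max_missing`,
#' `het_rate <= max_het` and `maf >= min_maf` (all thresholds are
#' boundary-inclusive for retention: the removal rules are strict
#' "greater than" / "lower than"). Marker order is preserved.
#'
#' @param G a `genotype_matrix`
#' @param max_missing maximum tolerated missing-call fraction (default 1 = off)
#' @param max_het maximum tolerated heterozygosity fraction (default 1 = off)
#' @param min_maf minimum minor allele frequency (default 0 = off)
#' @return the filtered `genotype_matrix`
#' @export
filter_markers <- function(G, max_missing = 1, max_het = 1, min_maf = 0) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1,
            min_maf >= 0, min_maf <= 1)
  s <- summarize_markers(G)
  keep <- s$missing_rate <= max_missing & s$het_rate <= max_het & s$maf >= min_maf
  if (!any(keep)) stop("all markers removed by filters")
  subset_genotypes(G, markers = which(keep))
}

#' Impute missing dosages marker-by-marker
#'
#' Simple single-marker imputation replacing the (out-of-scope)
#' haplotype-aware step of a full pipeline. `marker-mean` fills each
#' missing call with the marker's mean dosage (fractional values in
#' `[0, 2]`); `marker-mode` with its most frequent dosage (ties broken
#' toward the smaller dosage).
#'
#' @param G a `genotype_matrix`
#' @param method `"marker-mean"` or `"marker-mode"`
#' @return a complete `genotype_matrix` (no missing values)
#' @export
impute_missing <- function(G, method = c("marker-mean", "marker-mode")) {
  method <- match.arg(method)
  X <- G$dosages
  miss <- is.na(X)
  if (!any(miss)) return(G)
  n_obs <- rowSums(!miss)
  if (any(n_obs == 0))
    stop("marker(s) with all calls missing: ",
         paste(utils::head(G$markers$id[n_obs == 0], 5), collapse = ", "))
  fill <- if (method == "marker-mean") {
    rowSums(X, na.rm = TRUE) / n_obs
  } else {
    apply(X, 1, function(r) {
      tab <- table(r)
      as.numeric(names(tab)[which.max(tab)])
    })
  }
  idx <- which(miss, arr.ind = TRUE)
  X[miss] <- fill[idx[, 1]]
  genotype_matrix(X, G$markers, G$samples, validate = FALSE)
}

#' Recode every marker to count its minor allele
#'
#' Swaps counted/other labels (dosage `x -> 2 - x`) for markers whose
#' counted-allele frequency exceeds 0.5, so that afterwards every
#' marker's counted-allele frequency equals its MAF.
#'
#' @param G a `genotype_matrix`
#' @return a `genotype_matrix` with every MAF <= 0.5
#' @export
recode_to_minor <- function(G) {
  X <- G$dosages
  n_obs <- rowSums(!is.na(X))
  f <- rowSums(X, na.rm = TRUE) / (2 * n_obs)
  flip <- which(f > 0.5)
  if (length(flip)) {
    X[flip, ] <- 2 - X[flip, , drop = FALSE]
    mk <- G$markers
    tmp <- mk$counted[flip]
    mk$counted[flip] <- mk$other[flip]
    mk$other[flip] <- tmp
    return(genotype_matrix(X, mk, G$samples, validate = FALSE))
  }
  G
}
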