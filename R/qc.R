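#' Phenotype quality control
#'
#' Single-pass trimming of records more than `sd_bound` standard
#' deviations from their contemporary-group mean (mean and sd taken from
#' the incoming data), followed by removal of CGs left with fewer than
#' `min_cg` records. Trimming precedes the CG-size rule.
#'
#' @param pheno data frame with columns `animal`, `cg`, `value`.
#' @param sd_bound trim bound in within-CG sd units (default 3.5).
#' @param min_cg minimum records per CG (default 5).
#' @return list(pheno = filtered table, report = `qc_report`).
#' @export
filter_phenotypes <- function(pheno, sd_bound = 3.5, min_cg = 5) {
  stopifnot(all(c("cg", "value") %in% names(pheno)))
  if (nrow(pheno) == 0L) stop("empty phenotype table")
  n0 <- nrow(pheno)
  mu <- tapply(pheno$value, pheno$cg, mean)
  sdv <- tapply(pheno$value, pheno$cg, stats::sd)
  sdv[is.na(sdv)] <- 0
  dev <- abs(pheno$value - mu[pheno$cg])
  out_sd <- dev > sd_bound * sdv[pheno$cg] & sdv[pheno$cg] > 0
  kept <- pheno[!out_sd, , drop = FALSE]
  sizes <- table(kept$cg)
  small <- names(sizes)[sizes < min_cg]
  out_cg <- kept$cg %in% small
  final <- kept[!out_cg, , drop = FALSE]
  if (nrow(final) == 0L) stop("phenotype QC removed every record")
  report <- qc_report(
    stages = data.frame(
      stage = c("sd_trim", "small_cg"),
      n_in = c(n0, nrow(kept)),
      n_out = c(nrow(kept), nrow(final)),
      stringsAsFactors = FALSE),
    removed = list(
      sd_trim = if ("animal" %in% names(pheno))
        pheno$animal[out_sd] else which(out_sd),
      small_cg = if ("animal" %in% names(kept))
        kept$animal[out_cg] else which(out_cg)))
  list(pheno = final, report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test (probability method, no mid-p): the p-value is the
#' total probability of heterozygote counts no more likely than the
#' observed one, under the conditional distribution given allele counts.
#'
#' @param nAA,nAB,nBB genotype counts (vectors allowed).
#' @return p-values.
#' @export
hwe_exact_test <- function(nAA, nAB, nBB) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0L) return(NA_real_)
    n1 <- 2L * aa + ab          # allele counts
    n2 <- 2L * bb + ab
    rare <- min(n1, n2)
    het_vals <- seq.int(rare %% 2L, rare, by = 2L)
    # P(het = h | n, allele counts): h*log2 + multinomial over genotypes,
    # conditioned on the allele-count hypergeometric denominator
    logp <- vapply(het_vals, function(h) {
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      h * log(2) + lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) -
        lgamma(hom_c + 1) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
        lgamma(2 * n + 1)
    }, numeric(1))
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    obs <- which(het_vals == ab)
    min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
  }, nAA, nAB, nBB)
}

#' Genotype quality control
#'
#' Order (fixed so counts are reproducible): non-autosomal SNPs out, then
#' samples below the call-rate threshold, then SNPs failing call rate,
#' minor allele frequency, or the exact Hardy-Weinberg test.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min MAF threshold (remove MAF < maf_min).
#' @param hwe_p remove SNPs with exact-test p <= hwe_p.
#' @param callrate_min call-rate threshold for both samples and SNPs.
#' @param autosomes chromosome labels considered autosomal.
#' @return list(geno = filtered matrix (frequencies recomputed), report =
#'   `qc_report`).
#' @export
filter_genotypes <- function(geno, maf_min = 0.03, hwe_p = 1e-5,
                             callrate_min = 0.95, autosomes = 1:29) {
  calls <- geno$calls
  if (length(calls) == 0L) stop("empty genotype matrix")
  snp_auto <- geno$map$chrom %in% autosomes
  removed_nonauto <- geno$map$snp[!snp_auto]
  g <- subset_geno(geno, j = which(snp_auto), recompute_p = TRUE)
  cr_sample <- rowMeans(!is.na(g$calls))
  bad_sample <- rownames(g$calls)[cr_sample < callrate_min]
  g <- subset_geno(g, i = which(cr_sample >= callrate_min),
                   recompute_p = TRUE)
  cr_snp <- colMeans(!is.na(g$calls))
  p <- g$p
  maf <- pmin(p, 1 - p)
  nAA <- colSums(g$calls == 0L, na.rm = TRUE)
  nAB <- colSums(g$calls == 1L, na.rm = TRUE)
  nBB <- colSums(g$calls == 2L, na.rm = TRUE)
  hp <- hwe_exact_test(nAA, nAB, nBB)
  fail_cr <- cr_snp < callrate_min
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  fail_hwe <- !fail_cr & !fail_maf & !is.na(hp) & hp <= hwe_p
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("genotype QC removed every SNP")
  out <- subset_geno(g, j = which(keep), recompute_p = TRUE)
  report <- qc_report(
    stages = data.frame(
      stage = c("non_autosomal", "sample_callrate", "snp_callrate",
                "snp_maf", "snp_hwe"),
      n_in = c(ncol(geno$calls), nrow(geno$calls), sum(snp_auto),
               sum(snp_auto) - sum(fail_cr),
               sum(snp_auto) - sum(fail_cr) - sum(fail_maf)),
      n_out = c(sum(snp_auto), nrow(g$calls),
                sum(snp_auto) - sum(fail_cr),
                sum(snp_auto) - sum(fail_cr) - sum(fail_maf),
                sum(keep)),
      stringsAsFactors = FALSE),
    removed = list(non_autosomal = removed_nonauto,
                   sample_callrate = bad_sample,
                   snp_callrate = g$map$snp[fail_cr],
                   snp_maf = g$map$snp[fail_maf],
                   snp_hwe = g$map$snp[fail_hwe]))
  list(geno = out, report = report)
}

#' QC report container
#'
#' @param stages data frame stage, n_in, n_out; @param removed named list
#'   of removed ids per reason (the reasons partition the removed set).
#' @export
qc_report <- function(stages, removed) {
  stopifnot(all(stages$n_out <= stages$n_in))
  structure(list(stages = stages, removed = removed), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Serialize a QC report as TSV
#' @param report a `qc_report`; @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
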