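#' Back-solve SNP intercept/slope effects from breeding-value coefficients
#'
#' Animals below the accuracy threshold on either reaction-norm
#' coefficient are dropped; for each coefficient q the marker effects are
#' alpha_q = (1 / (2 sum p q)) Mc' Gb^-1 a_q over the retained genotyped
#' animals, where Mc is the dosage matrix centered with the genotype
#' matrix's own allele frequencies and Gb the (optionally blended) genomic
#' relationship on those animals. With an unblended G and a_q in the row
#' space of Mc this is an exact projection: Mc alpha_q reconstructs a_q.
#'
#' @param rn an `rn_solution` from [fit_ssgrn()].
#' @param geno genotype matrix of the genotyped animals (QC-passed set the
#'   G used in the fit was built from).
#' @param accuracy_min drop animals below this accuracy on intercept or
#'   slope (default 0.40).
#' @param blend_weight G blending used before inversion (1 = unblended);
#'   @param A22 pedigree relationships of the genotyped animals, required
#'   when `blend_weight` < 1.
#' @return matrix n_snp x 2 (intercept, slope effects) with attributes
#'   `retained` (animal ids used) and `p` (allele frequencies).
#' @export
backsolve_snp_coefficients <- function(rn, geno, accuracy_min = 0.40,
                                       blend_weight = 1, A22 = NULL) {
  gids <- rownames(geno$calls)
  stopifnot(all(gids %in% rownames(rn$alpha)))
  if (accuracy_min > 0) {
    if (is.null(rn$accuracy))
      stop("accuracy filtering requested but the fit carries no accuracies")
    acc <- rn$accuracy[gids, , drop = FALSE]
    keep <- rowSums(acc >= accuracy_min) == ncol(acc)
  } else {
    keep <- rep(TRUE, length(gids))
  }
  if (!any(keep))
    stop("no genotyped animal reaches accuracy ", accuracy_min,
         " on both coefficients")
  ret <- gids[keep]
  Mc <- dosage_matrix(geno, center = TRUE)[ret, , drop = FALSE]
  poly <- geno$p > 0 & geno$p < 1
  k <- 2 * sum(geno$p[poly] * (1 - geno$p[poly]))
  Gr <- tcrossprod(Mc) / k
  if (blend_weight < 1) {
    if (is.null(A22)) stop("A22 required for blended back-solving")
    Gr <- blend_weight * Gr +
      (1 - blend_weight) * unclass(A22)[ret, ret, drop = FALSE]
  }
  a <- rn$alpha[ret, , drop = FALSE]
  # observed-frequency centering leaves the ones vector in G's null space,
  # so an unblended G is rank-deficient by construction: solve on its range
  sol <- tryCatch(solve(Gr, a), error = function(e) {
    ed <- eigen(Gr, symmetric = TRUE)
    pos <- ed$values > 1e-10 * max(ed$values)
    ed$vectors[, pos] %*% (crossprod(ed$vectors[, pos], a) / ed$values[pos])
  })
  alpha <- crossprod(Mc, sol) / k
  colnames(alpha) <- c("intercept", "slope")[seq_len(ncol(alpha))]
  rownames(alpha) <- geno$map$snp
  attr(alpha, "retained") <- ret
  attr(alpha, "p") <- geno$p
  alpha
}

#' Project SNP coefficient effects to an environment level
#'
#' u_k(ec) = alpha_k . phi(ec), the dot product of the per-SNP
#' (intercept, slope) vector with the Legendre basis at the level.
#'
#' @param alpha n_snp x q coefficient matrix (or a single q-vector).
#' @param ec environment level (scalar).
#' @return numeric vector of effects at `ec`.
#' @export
project_effect <- function(alpha, ec) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, 1)
  phi <- legendre_basis(ec, order = ncol(alpha) - 1L)
  drop(alpha %*% t(phi))
}

#' Percentage of genetic variance explained by a SNP at a level
#'
#' 100 * 2 p q u^2 / sigma2_a(ec), the effect entering squared (the
#' variance contributed by a marker at Hardy-Weinberg proportions over the
#' level's genetic variance).
#'
#' @param u_hat SNP effect(s) at the level; @param p allele frequencies;
#'   @param sigma2_a_ec genetic variance at the level.
#' @return percentages.
#' @export
variance_explained <- function(u_hat, p, sigma2_a_ec) {
  stopifnot(sigma2_a_ec > 0)
  100 * 2 * p * (1 - p) * u_hat^2 / sigma2_a_ec
}

#' Genome-wide test of SNP effects at one environment level
#'
#' Effects are standardized genome-wide within the level. When allele
#' frequencies are supplied (the default path in [snp_effect_table()]),
#' each effect is first put on its per-SNP variance scale, u / sqrt(2pq) —
#' back-solved effects have standard deviation proportional to
#' sqrt(2 p q), so this removes the heterozygosity scale mixture and
#' yields a calibrated null (lambda near 1); the standardized statistic is
#' then z = (x - mean x) / sd(x) genome-wide, with two-sided normal
#' p-values, Benjamini-Hochberg q-values, and the significance flag
#' -log10(p) > `sig_threshold_neglog10p`. The threshold-form FDR estimate
#' n_m * p_sig / n_msig at p_sig = 0.01 is attached as attribute
#' `fdr_threshold_form`. A literal variant z = u / sqrt(realized
#' var-explained share) is available for inspection via `literal = TRUE`
#' (its |z| is constant by construction, so it yields no p-value
#' distribution; see the methods vignette).
#'
#' @param effects per-SNP effects at one level.
#' @param p optional allele frequencies for the 2pq variance scaling;
#'   monomorphic SNPs get z = 0, p-value 1.
#' @param sig_threshold_neglog10p significance threshold on -log10(p).
#' @param p_sig threshold used in the threshold-form FDR estimate.
#' @param literal return the literal (non-discriminating) standardization.
#' @return data frame z, p, q (BH), neglog10p, significant.
#' @export
snp_test <- function(effects, p = NULL, sig_threshold_neglog10p = 6.0,
                     p_sig = 0.01, literal = FALSE) {
  stopifnot(length(effects) >= 2L, all(is.finite(effects)))
  if (literal) {
    fr <- effects^2 / sum(effects^2)
    z <- effects / sqrt(fr)
  } else {
    x <- effects
    keep <- rep(TRUE, length(x))
    if (!is.null(p)) {
      het <- 2 * p * (1 - p)
      keep <- het > 0
      x <- ifelse(keep, x / sqrt(pmax(het, .Machine$double.eps)), 0)
    }
    s <- stats::sd(x[keep])
    if (is.na(s) || s == 0)
      stop("zero variance among SNP effects; z undefined")
    z <- (x - mean(x[keep])) / s
    z[!keep] <- 0
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(z = z, p = p, q = q,
                    neglog10p = -log10(pmax(p, .Machine$double.xmin)),
                    significant = -log10(pmax(p, .Machine$double.xmin)) >
                      sig_threshold_neglog10p)
  n_msig <- sum(p < p_sig)
  attr(out, "fdr_threshold_form") <-
    if (n_msig > 0) length(p) * p_sig / n_msig else NA_real_
  out
}

#' Genomic inflation factor
#'
#' lambda = median(z^2) / 0.456, the chi-square(1)-median convention
#' (0.4549 rounded to the conventional printed constant). The literal
#' median(p)/constant ratio is also returned for inspection; for any
#' well-calibrated test it sits near 0.5/0.456 and cannot discriminate
#' inflation, so the chi-square form drives interpretation.
#'
#' @param z per-SNP z-scores at one level; @param constant null median.
#' @return list(lambda, lambda_literal_p).
#' @export
inflation_factor <- function(z, constant = 0.456) {
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(lambda = stats::median(z^2) / constant,
       lambda_literal_p = stats::median(p) / constant)
}

#' Venn partition of significant SNP sets across levels
#'
#' For three named sets, the 7-cell partition: specific to each level,
#' each pairwise-only overlap, and the all-three cell.
#'
#' @param sig_sets named list of SNP id vectors (length 3).
#' @return named list of the 7 cells (names like "Low_only",
#'   "Low_and_Medium", "all").
#' @export
stratify_shared_specific <- function(sig_sets) {
  stopifnot(length(sig_sets) == 3L, !is.null(names(sig_sets)))
  nm <- names(sig_sets)
  s1 <- sig_sets[[1]]; s2 <- sig_sets[[2]]; s3 <- sig_sets[[3]]
  all3 <- intersect(intersect(s1, s2), s3)
  out <- list(
    setdiff(s1, union(s2, s3)),
    setdiff(s2, union(s1, s3)),
    setdiff(s3, union(s1, s2)),
    setdiff(intersect(s1, s2), s3),
    setdiff(intersect(s1, s3), s2),
    setdiff(intersect(s2, s3), s1),
    all3)
  names(out) <- c(paste0(nm, "_only"),
                  paste0(nm[1], "_and_", nm[2]),
                  paste0(nm[1], "_and_", nm[3]),
                  paste0(nm[2], "_and_", nm[3]), "all")
  out
}

#' Full per-SNP, per-level effect table
#'
#' Back-solves coefficients, projects them to each configured level,
#' computes variance explained, z, p, BH q and the significance flag, and
#' the inflation factor per level.
#'
#' @param rn an `rn_solution`; @param geno genotype matrix (genotyped,
#'   QC-passed animals).
#' @param ec_levels named or unnamed numeric levels (default -3, 0, 3).
#' @param accuracy_min,blend_weight,A22 passed to
#'   [backsolve_snp_coefficients()].
#' @param sig_threshold_neglog10p significance rule on -log10(p).
#' @return data frame of class `snp_effect_table` (snp, chrom, pos, p_freq,
#'   alpha_intercept, alpha_slope, then per level: effect, pct_var, z, p,
#'   q, significant), with attribute `inflation` (per-level list) and
#'   `retained`.
#' @export
snp_effect_table <- function(rn, geno, ec_levels = c(Low = -3, Medium = 0,
                                                     High = 3),
                             accuracy_min = 0.40, blend_weight = 1,
                             A22 = NULL, sig_threshold_neglog10p = 6.0) {
  if (is.null(names(ec_levels)))
    names(ec_levels) <- paste0("EC", seq_along(ec_levels))
  alpha <- backsolve_snp_coefficients(rn, geno, accuracy_min, blend_weight,
                                      A22)
  out <- data.frame(snp = geno$map$snp, chrom = geno$map$chrom,
                    pos = geno$map$pos, p_freq = geno$p,
                    alpha_intercept = alpha[, 1], alpha_slope = alpha[, 2],
                    stringsAsFactors = FALSE)
  infl <- list()
  for (lv in names(ec_levels)) {
    ec <- ec_levels[[lv]]
    u <- project_effect(alpha, ec)
    va <- genetic_variance_at(rn$K, ec)
    tst <- snp_test(u, p = geno$p,
                    sig_threshold_neglog10p = sig_threshold_neglog10p)
    out[[paste0("effect_", lv)]] <- u
    out[[paste0("pct_var_", lv)]] <- variance_explained(u, geno$p, va)
    out[[paste0("z_", lv)]] <- tst$z
    out[[paste0("p_", lv)]] <- tst$p
    out[[paste0("q_", lv)]] <- tst$q
    out[[paste0("significant_", lv)]] <- tst$significant
    infl[[lv]] <- inflation_factor(tst$z)
  }
  rownames(out) <- NULL
  attr(out, "inflation") <- infl
  attr(out, "retained") <- attr(alpha, "retained")
  attr(out, "ec_levels") <- ec_levels
  class(out) <- c("snp_effect_table", "data.frame")
  out
}

#' Significant SNP ids per level from an effect table
#' @param tab a `snp_effect_table`.
#' @export
significant_sets <- function(tab) {
  lv <- names(attr(tab, "ec_levels"))
  stats::setNames(lapply(lv, function(l)
    tab$snp[tab[[paste0("significant_", l)]]]), lv)
}

#' Write a SNP effect table as TSV
#' @param tab a `snp_effect_table`; @param path output path.
#' @export
write_snp_effect_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
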