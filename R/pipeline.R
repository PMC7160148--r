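#' Run configuration
#'
#' Holds the analysis constants: environment levels at which SNP effects
#' are reported (default Low/Medium/High = -3/0/+3 sd), Legendre order,
#' the -log10(p) significance threshold (6.0, the 5% FDR operating point),
#' the BH level, the gene-window flank (200 kb), the minimum BLUP accuracy
#' for the back-solving set (0.40), and the G blending weight.
#'
#' @param ec_levels named numeric vector in \[-3, 3\].
#' @param legendre_order polynomial order (1 = intercept + slope).
#' @param sig_threshold_neglog10p significance threshold on -log10(p).
#' @param fdr_level BH level in (0, 1).
#' @param window_bp gene-window flank in bp (> 0).
#' @param accuracy_min back-solving accuracy filter.
#' @param blend_weight G blending weight in (0, 1].
#' @param rng_seed integer seed fixed at pipeline start.
#' @return list of class `run_config`.
#' @export
run_config <- function(ec_levels = c(Low = -3, Medium = 0, High = 3),
                       legendre_order = 1, sig_threshold_neglog10p = 6.0,
                       fdr_level = 0.05, window_bp = 200000L,
                       accuracy_min = 0.40, blend_weight = 0.95,
                       rng_seed = 1L) {
  stopifnot(all(ec_levels >= -3), all(ec_levels <= 3),
            fdr_level > 0, fdr_level < 1, window_bp > 0,
            blend_weight > 0, blend_weight <= 1)
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full reaction-norm GWAS pipeline from files on disk
#'
#' Reads the inputs, applies phenotype and genotype QC, builds the
#' single-step relationship matrices, estimates the environmental
#' gradient from descriptor-trait CG effects, fits the reaction-norm
#' model, back-solves and tests SNP effects at the configured levels, and
#' (when annotation files are given) maps significant SNPs to gene
#' windows and runs gene-set enrichment. All outputs are TSVs under
#' `out_dir`; record counts per stage go to stderr and qc_log.tsv. The
#' run is deterministic given `config$rng_seed`.
#'
#' @param paths named list: `pedigree`, `genotypes` (.raw), `genotype_map`
#'   (TSV snp, chrom, pos), `descriptor_phenotypes`, `target_phenotypes`,
#'   optional `genes` (BED/GFF3) and `gene_sets` (GMT).
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(paths, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$rng_seed)
  log_counts <- list()
  note <- function(...) message("[ssgrn] ", ...)

  ped <- stage("io", read_pedigree(paths$pedigree))
  gmap <- stage("io", utils::read.table(paths$genotype_map, header = TRUE,
                                        stringsAsFactors = FALSE))
  geno <- stage("io", read_genotypes(paths$genotypes, "raw_additive",
                                     map = gmap, pedigree = ped))
  desc <- stage("io", utils::read.csv(paths$descriptor_phenotypes,
                                      stringsAsFactors = FALSE))
  targ <- stage("io", utils::read.csv(paths$target_phenotypes,
                                      stringsAsFactors = FALSE))
  note("inputs: ", nrow(ped), " animals, ", ncol(geno$calls), " SNPs, ",
       nrow(desc), " descriptor records, ", nrow(targ), " target records")

  qc_d <- stage("qc", filter_phenotypes(desc))
  qc_t <- stage("qc", filter_phenotypes(targ))
  qc_g <- stage("qc", filter_genotypes(geno))
  note("qc: descriptor ", nrow(qc_d$pheno), "/", nrow(desc),
       ", target ", nrow(qc_t$pheno), "/", nrow(targ),
       ", SNPs ", ncol(qc_g$geno$calls), "/", ncol(geno$calls),
       ", samples ", nrow(qc_g$geno$calls), "/", nrow(geno$calls))
  qc_stages <- rbind(
    cbind(table = "descriptor", qc_d$report$stages),
    cbind(table = "target", qc_t$report$stages),
    cbind(table = "genotypes", qc_g$report$stages))
  utils::write.table(qc_stages, file.path(out_dir, "qc_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rel <- stage("relationships", {
    A <- build_A(ped)
    gids <- rownames(qc_g$geno$calls)
    gids <- gids[gids %in% ped$animal]
    g2 <- subset_geno(qc_g$geno, i = gids, recompute_p = TRUE)
    A22 <- relmat(unclass(A)[gids, gids, drop = FALSE], gids, "A22")
    G <- build_G(g2)
    Ainv <- invert_relmat(A)
    Hinv <- build_H_inverse(Ainv, A22, G, config$blend_weight)
    H <- build_H(A, A22, G, config$blend_weight)
    list(A = A, A22 = A22, G = G, Hinv = Hinv, H = H, geno = g2)
  })

  ecd <- stage("ec_descriptor", {
    ph <- qc_d$pheno[qc_d$pheno$animal %in% ped$animal, , drop = FALSE]
    blues <- estimate_cg_blues(ph, rel$Hinv, H = rel$H)
    standardize_ec(blues)
  })
  write_ec_descriptor(ecd, file.path(out_dir, "ec_descriptor.tsv"))
  note("ec: ", nrow(ecd), " CG levels, range ",
       round(min(ecd$ec), 2), "..", round(max(ecd$ec), 2))

  rn <- stage("reaction_norm", {
    ph <- qc_t$pheno[qc_t$pheno$animal %in% ped$animal &
                       qc_t$pheno$cg %in% ecd$cg, , drop = FALSE]
    fit_ssgrn(ph, ecd, rel$Hinv, H = rel$H,
              order = config$legendre_order)
  })
  write_varcomp_report(rn, file.path(out_dir, "variance_components.tsv"))
  note("reaction norm: K intercept ", round(rn$K[1, 1], 1),
       ", slope ", round(rn$K[2, 2], 1), ", cov ", round(rn$K[1, 2], 1))

  tab <- stage("snp_gwas", snp_effect_table(
    rn, rel$geno, ec_levels = config$ec_levels,
    accuracy_min = config$accuracy_min,
    blend_weight = config$blend_weight, A22 = rel$A22,
    sig_threshold_neglog10p = config$sig_threshold_neglog10p))
  write_snp_effect_table(tab, file.path(out_dir, "snp_effects.tsv"))
  sig <- significant_sets(tab)
  note("gwas: significant SNPs per level: ",
       paste(names(sig), vapply(sig, length, 1L), sep = "=",
             collapse = ", "))

  ann_out <- NULL
  if (!is.null(paths$genes)) {
    ann_out <- stage("annotation", {
      genes <- read_gene_annotation(paths$genes)
      sig_all <- unique(unlist(sig))
      sig_df <- tab[tab$snp %in% sig_all, c("snp", "chrom", "pos")]
      win <- map_windows(sig_df, genes, config$window_bp)
      enr <- NULL
      if (!is.null(paths$gene_sets) && nrow(win)) {
        sets <- read_gmt(paths$gene_sets)
        enr <- hypergeom_enrichment(
          intersect(unique(win$gene), genes$gene), sets,
          background = genes$gene, fdr_level = config$fdr_level)
      }
      list(windows = win, enrichment = enr)
    })
    utils::write.table(ann_out$windows,
                       file.path(out_dir, "gene_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ann_out$enrichment))
      utils::write.table(ann_out$enrichment,
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(qc = list(descriptor = qc_d, target = qc_t,
                           genotypes = qc_g),
                 relationships = rel, ecd = ecd, rn = rn, snp_table = tab,
                 significant = sig, annotation = ann_out))
}
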