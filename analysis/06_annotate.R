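#!/usr/bin/env Rscript
# Stage 4: offline annotation of the significant markers. Maps each
# significant SNP to the genes intersecting its +/-200 kb window, runs
# hypergeometric gene-set enrichment against the synthetic GMT
# collection (background = the annotation's gene universe), and writes a
# regional LD (r2) table around the top marker.

library(ssgrn)

std <- file.path("results", "study")
out <- file.path("results", "annotation")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- readRDS(file.path("scratch", "snp_table.rds"))
rel <- readRDS(file.path("scratch", "relationships.rds"))
genes <- read_gene_annotation(file.path(std, "genes_synthetic.bed"))
sets <- read_gmt(file.path(std, "gene_sets_synthetic.gmt"))

sig <- unique(unlist(significant_sets(tab)))
sig_df <- tab[tab$snp %in% sig, c("snp", "chrom", "pos")]
win <- map_windows(sig_df, genes, window_bp = 200000)
write.table(win, file.path(out, "gene_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d significant SNPs -> %d gene hits (%d unique genes)",
                nrow(sig_df), nrow(win), length(unique(win$gene))))

if (nrow(win)) {
  enr <- hypergeom_enrichment(unique(win$gene), sets,
                              background = genes$gene)
  write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%d/%d gene sets enriched at 5%% FDR (best p = %.2g)",
                  sum(enr$enriched), nrow(enr), min(enr$p)))
  # regional association/LD table around the strongest marker
  top <- sig_df$snp[which.max(-log10(
    do.call(pmin, tab[tab$snp %in% sig, grep("^p_", names(tab))])))]
  ld <- pairwise_r2(rel$geno, top, window_bp = 2e6)
  write.table(ld, file.path(out, "region_r2.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("regional r2 table around %s: %d SNPs", top, nrow(ld)))
}
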