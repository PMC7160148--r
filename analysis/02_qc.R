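#!/usr/bin/env Rscript
# Phenotype and genotype quality control: 3.5-sd trimming within
# contemporary group, minimum CG size 5, then per-sample and per-SNP call
# rate 0.95, MAF 0.03 and exact Hardy-Weinberg (p <= 1e-5) filters on the
# autosomal SNPs. Writes the filtered tables and a per-stage count log.

library(ssgrn)

dir <- file.path("results", "study")
out <- file.path("results", "qc")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ped <- read_pedigree(file.path(dir, "pedigree.csv"))
gmap <- read.table(file.path(dir, "genotypes_map.tsv"), header = TRUE)
geno <- read_genotypes(file.path(dir, "genotypes.raw"), "raw_additive",
                       map = gmap, pedigree = ped)
desc <- read.csv(file.path(dir, "descriptor_phenotypes.csv"))
targ <- read.csv(file.path(dir, "target_phenotypes.csv"))

qc_d <- filter_phenotypes(desc)
qc_t <- filter_phenotypes(targ)
qc_g <- filter_genotypes(geno)

message(sprintf("descriptor records: %d -> %d", nrow(desc),
                nrow(qc_d$pheno)))
message(sprintf("target records: %d -> %d", nrow(targ), nrow(qc_t$pheno)))
message(sprintf("SNPs: %d -> %d; samples: %d -> %d", ncol(geno$calls),
                ncol(qc_g$geno$calls), nrow(geno$calls),
                nrow(qc_g$geno$calls)))

write.csv(qc_d$pheno, file.path(out, "descriptor_qc.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(qc_t$pheno, file.path(out, "target_qc.csv"), row.names = FALSE,
          quote = FALSE)
write_genotypes(qc_g$geno, file.path(out, "genotypes_qc.raw"))
write.table(qc_g$geno$map, file.path(out, "genotypes_qc_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_qc_report(qc_d$report, file.path(out, "qc_descriptor.tsv"))
write_qc_report(qc_t$report, file.path(out, "qc_target.tsv"))
write_qc_report(qc_g$report, file.path(out, "qc_genotypes.tsv"))
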