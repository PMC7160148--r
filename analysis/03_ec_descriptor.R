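#!/usr/bin/env Rscript
# Stage 1: the environmental gradient. Builds A, G and the blended
# single-step H inverse, fits the descriptor-trait animal model
# (CG + age + animal), extracts the contemporary-group BLUEs, and
# standardizes them into the EC descriptor (mean 0, sd 1, winsorized at
# +/-3) with the five fixed residual classes. Compares the estimate with
# the simulation truth.

library(ssgrn)

qc <- file.path("results", "qc")
std <- file.path("results", "study")
out <- file.path("results", "ec")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ped <- read_pedigree(file.path(std, "pedigree.csv"))
gmap <- read.table(file.path(qc, "genotypes_qc_map.tsv"), header = TRUE)
geno <- read_genotypes(file.path(qc, "genotypes_qc.raw"), "raw_additive",
                       map = gmap)
desc <- read.csv(file.path(qc, "descriptor_qc.csv"))

A <- build_A(ped)
gids <- intersect(rownames(geno$calls), ped$animal)
geno <- subset_geno(geno, i = gids, recompute_p = TRUE)
A22 <- A[gids, gids]
attr(A22, "kind") <- "A22"
G <- build_G(geno)
Ainv <- invert_relmat(A)
Hinv <- build_H_inverse(Ainv, A22, G, blend_weight = 0.95)
H <- build_H(A, A22, G, blend_weight = 0.95)

blues <- estimate_cg_blues(desc, Hinv, H = H)
vc <- attr(blues, "varcomps")
message(sprintf("descriptor REML: sigma2_a %.1f, sigma2_e %.1f (h2 %.2f)",
                vc$sigma2_a, vc$sigma2_e,
                vc$sigma2_a / (vc$sigma2_a + vc$sigma2_e)))
ecd <- standardize_ec(blues)
write_ec_descriptor(ecd, file.path(out, "ec_descriptor.tsv"))

truth <- read.delim(file.path(std, "truth_cg.tsv"))
m <- match(ecd$cg, truth$cg)
message(sprintf("EC range %.2f..%.2f over %d CGs; cor(EC, truth) = %.3f",
                min(ecd$ec), max(ecd$ec), nrow(ecd),
                cor(ecd$ec, truth$ec_true[m])))
message(sprintf("records per residual class: %s",
                paste(tabulate(ecd$residual_class, 5), collapse = " ")))

saveRDS(list(Hinv = Hinv, H = H, A22 = A22, geno = geno),
        file.path("scratch", "relationships.rds"))
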