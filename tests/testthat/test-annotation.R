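toy_geno <- function(seed = 91, n = 40, m = 30) {
  set.seed(seed)
  calls <- sapply(runif(m, .2, .5), function(p) rbinom(n, 2, p))
  rownames(calls) <- sprintf("A%02d", seq_len(n))
  genotype_matrix(calls, chrom = rep(1, m), pos = seq_len(m) * 1000,
                  snp_ids = sprintf("s%02d", seq_len(m)))
}

test_that("pairwise r2 is a correlation with the documented invariances", {
  g <- toy_geno()
  r <- pairwise_r2(g, "s05", window_bp = 1e6)
  expect_equal(r$r2[r$snp == "s05"], 1)
  # duplicated SNP column and allele flips
  g2 <- g
  g2$calls[, "s06"] <- g$calls[, "s05"]
  g2$calls[, "s07"] <- 2L - g$calls[, "s05"]
  r2 <- pairwise_r2(g2, "s05", window_bp = 1e6)
  expect_equal(r2$r2[r2$snp == "s06"], 1)
  expect_equal(r2$r2[r2$snp == "s07"], 1)
  # symmetry
  ra <- pairwise_r2(g, "s03", 1e6); rb <- pairwise_r2(g, "s09", 1e6)
  expect_equal(ra$r2[ra$snp == "s09"], rb$r2[rb$snp == "s03"])
  # monomorphic comparator is skipped with a note
  g3 <- g; g3$calls[, "s08"] <- 1L
  r3 <- pairwise_r2(g3, "s05", 1e6)
  expect_true(is.na(r3$r2[r3$snp == "s08"]))
  expect_true("s08" %in% attr(r3, "skipped_monomorphic"))
  # independent SNPs: mean r2 near 1/(n-1)
  gbig <- toy_geno(seed = 93, n = 60, m = 200)
  rr <- pairwise_r2(gbig, gbig$map$snp[1], window_bp = 1e9)
  expect_equal(mean(rr$r2[-1], na.rm = TRUE), 1 / 59, tolerance = 0.5 / 59 * 3)
})

test_that("window mapping honors the closed +/-200 kb boundary", {
  snps <- data.frame(snp = "top", chrom = 5, pos = 1000000)
  genes <- data.frame(chrom = 5,
                      start = c(700000, 500000, 1199000, 1200001, 500000),
                      end = c(820000, 800000, 1250000, 1300000, 799999),
                      gene = c("in1", "edge", "in2", "out_right", "out_left"))
  hit <- map_windows(snps, genes, window_bp = 200000)
  expect_setequal(hit$gene, c("in1", "edge", "in2"))
  # gene ending exactly at pos - 200000 is included (closed interval)
  expect_true("edge" %in% hit$gene)
  # 200,001 bp away on either side is excluded
  expect_false(any(c("out_right", "out_left") %in% hit$gene))
  expect_warning(map_windows(data.frame(snp = "x", chrom = 9, pos = 1),
                             genes, 1000), "skipped")
})

test_that("window mapping agrees with a brute-force interval scan", {
  set.seed(95)
  for (rep in 1:5) {
    snps <- data.frame(snp = paste0("s", 1:3),
                       chrom = sample(1:2, 3, TRUE),
                       pos = sample.int(5e6, 3))
    st <- sample.int(5e6, 5)
    genes <- data.frame(chrom = sample(1:2, 5, TRUE), start = st,
                        end = st + sample.int(2e5, 5),
                        gene = paste0("g", 1:5))
    got <- suppressWarnings(map_windows(snps, genes, window_bp = 200000))
    want <- do.call(rbind, lapply(1:3, function(i) {
      hits <- which(genes$chrom == snps$chrom[i] &
                      genes$end >= snps$pos[i] - 200000 &
                      genes$start <= snps$pos[i] + 200000)
      if (length(hits)) data.frame(snp = snps$snp[i], gene = genes$gene[hits])
    }))
    got_pairs <- paste(got$snp, got$gene)
    want_pairs <- if (is.null(want)) character() else paste(want$snp,
                                                            want$gene)
    expect_setequal(got_pairs, want_pairs)
  }
})

test_that("hypergeometric enrichment equals pmf summation and edge cases", {
  bg <- paste0("g", 1:20)
  sets <- list(whole = bg, five = paste0("g", 1:5))
  hits <- paste0("g", 1:5)
  res <- hypergeom_enrichment(hits, sets, background = bg)
  expect_equal(res$p[res$set == "whole"], 1)
  expect_equal(res$p[res$set == "five"], 1 / choose(20, 5), tolerance = 1e-12)
  # brute-force pmf summation over configurations with N <= 30
  set.seed(97)
  for (i in 1:20) {
    N <- sample(5:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    brute <- sum(sapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j))) / choose(N, n)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE), brute,
                 tolerance = 1e-12)
  }
  # monotone in overlap at fixed margins
  ps <- sapply(0:5, function(k) phyper(k - 1, 5, 15, 5, lower.tail = FALSE))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_enrichment("zz", sets, background = bg), "outside")
  expect_error(hypergeom_enrichment(character(), sets,
                                    background = character()), "empty")
})

test_that("annotation files round-trip through BED and GMT", {
  g <- toy_geno()
  ann <- simulate_annotation(g, n_genes = 12, n_sets = 4, seed = 5)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_bed(ann$genes, bed)
  back <- read_gene_annotation(bed)
  expect_equal(back$start, ann$genes$start)  # 1-based restored from BED
  expect_equal(back$end, ann$genes$end)
  expect_setequal(back$gene, ann$genes$gene)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann$gene_sets, gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets[names(ann$gene_sets)], ann$gene_sets)
})
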