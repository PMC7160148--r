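#' Read a gene annotation (BED or GFF3) into 1-based intervals
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive convention on read; GFF3 is taken as-is. Only `gene` features
#' are kept from GFF3 (falling back to all features if none are typed
#' "gene"). Parsing goes through rtracklayer.
#'
#' @param path `.bed`, `.gff`/`.gff3` file.
#' @return data frame chrom, start, end, gene (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ty <- as.character(gr$type)
    if (any(ty == "gene")) gr <- gr[ty == "gene"]
    ids <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$ID)) gr$ID
      else paste0("feature", seq_along(gr))
  } else {
    ids <- if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene = as.character(ids), stringsAsFactors = FALSE)
}

#' Write gene intervals as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param genes data frame chrom, start, end, gene; @param path output.
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' @param path `.gmt` file (set name, description, then member ids per
#'   line).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise linkage disequilibrium (r2) around a focal SNP
#'
#' Composite (genotype-correlation) r2: the squared Pearson correlation of
#' dosage vectors over animals with both calls observed, for every SNP
#' within `window_bp` of the focal SNP on the same chromosome.
#' Monomorphic comparators yield NA (skipped with a note attribute).
#'
#' @param geno a [genotype_matrix()].
#' @param focal focal SNP id.
#' @param window_bp window half-width in bp (default 2e6, a regional
#'   plot's scale).
#' @return data frame snp, chrom, pos, r2 (focal vs itself = 1).
#' @export
pairwise_r2 <- function(geno, focal, window_bp = 2e6) {
  i <- match(focal, geno$map$snp)
  if (is.na(i)) stop("focal SNP not found: ", focal)
  ch <- geno$map$chrom[i]; ps <- geno$map$pos[i]
  sel <- which(geno$map$chrom == ch & abs(geno$map$pos - ps) <= window_bp)
  x <- geno$calls[, i]
  r2 <- vapply(sel, function(j) {
    y <- geno$calls[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
  out <- data.frame(snp = geno$map$snp[sel], chrom = ch,
                    pos = geno$map$pos[sel], r2 = r2,
                    stringsAsFactors = FALSE)
  attr(out, "skipped_monomorphic") <- out$snp[is.na(out$r2)]
  out
}

#' Map significant SNPs to gene/QTL windows
#'
#' Returns every annotation interval intersecting the closed window
#' \[pos - window_bp, pos + window_bp\] around each SNP (the +/- flank
#' reading of a "200 kb region"). Overlap is computed with IRanges.
#' SNPs on chromosomes absent from the annotation are skipped with a
#' warning.
#'
#' @param sig_snps data frame snp, chrom, pos.
#' @param genes data frame chrom, start, end, gene (1-based inclusive).
#' @param window_bp flank size (default 200000).
#' @return data frame snp, chrom, pos, gene, gene_start, gene_end,
#'   distance (0 when the SNP lies inside the gene).
#' @export
map_windows <- function(sig_snps, genes, window_bp = 200000) {
  if (nrow(sig_snps) == 0L)
    return(data.frame(snp = character(), chrom = character(),
                      pos = integer(), gene = character(),
                      gene_start = integer(), gene_end = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(sig_snps$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("no annotation on chromosome(s) ",
            paste(unknown, collapse = ", "), "; SNP(s) skipped")
    sig_snps <- sig_snps[!sig_snps$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(sig_snps) == 0L) return(map_windows(sig_snps, genes, window_bp))
  qry <- GenomicRanges::GRanges(
    sig_snps$chrom,
    IRanges::IRanges(pmax(1L, sig_snps$pos - window_bp),
                     sig_snps$pos + window_bp))
  sbj <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(qry, sbj)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, pmax(genes$start[si] - sig_snps$pos[qi],
                        sig_snps$pos[qi] - genes$end[si]))
  data.frame(snp = sig_snps$snp[qi], chrom = sig_snps$chrom[qi],
             pos = sig_snps$pos[qi], gene = genes$gene[si],
             gene_start = genes$start[si], gene_end = genes$end[si],
             distance = dist, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per set: with a background universe of
#' size N, a set of size K, n hit genes and overlap k, p = P(X >= k);
#' Benjamini-Hochberg across sets; enriched when q <= `fdr_level`.
#'
#' @param hits character vector of hit gene ids (must lie in the
#'   background).
#' @param gene_sets named list of gene-id vectors; members outside the
#'   background are ignored.
#' @param background gene universe (default: union of all set members).
#' @param fdr_level BH threshold (default 0.05).
#' @return data frame set, set_size, overlap, p, q, enriched.
#' @export
hypergeom_enrichment <- function(hits, gene_sets,
                                 background = unique(unlist(gene_sets)),
                                 fdr_level = 0.05) {
  if (!length(background)) stop("empty background universe")
  hits <- unique(hits)
  if (!all(hits %in% background))
    stop("hit gene(s) outside the background universe: ",
         paste(utils::head(setdiff(hits, background)), collapse = ", "))
  N <- length(background); n <- length(hits)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= fdr_level
  out[order(out$p), , drop = FALSE]
}
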