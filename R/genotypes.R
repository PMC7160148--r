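#' Genotype matrix objects
#'
#' Container for biallelic SNP genotypes coded as allele dosages 0/1/2
#' (NA = missing) over an explicit animal and SNP ordering, with a genomic
#' map (chromosome, 1-based bp position) and per-SNP allele frequencies of
#' the counted allele computed from non-missing calls.
#'
#' @param calls integer matrix, animals in rows, SNPs in columns; entries in
#'   {0,1,2,NA}.
#' @param chrom integer/character vector of chromosomes per SNP.
#' @param pos integer vector of 1-based positions per SNP; must be
#'   non-decreasing within each chromosome.
#' @param animal_ids,snp_ids identifiers; default taken from dimnames.
#' @return An object of class `geno_matrix`: list with elements `calls`,
#'   `map` (data frame snp, chrom, pos), `p` (allele frequencies).
#' @export
genotype_matrix <- function(calls, chrom, pos,
                            animal_ids = rownames(calls),
                            snp_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(calls)))
  stopifnot(length(chrom) == ncol(calls), length(pos) == ncol(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be dosages in {0,1,2} or NA")
  for (ch in unique(chrom)) {
    pp <- pos[chrom == ch]
    if (is.unsorted(pp)) stop("positions not non-decreasing on chromosome ", ch)
  }
  dimnames(calls) <- list(animal_ids, snp_ids)
  obj <- list(
    calls = calls,
    map = data.frame(snp = snp_ids, chrom = chrom, pos = as.integer(pos),
                     stringsAsFactors = FALSE),
    p = colMeans(calls, na.rm = TRUE) / 2
  )
  class(obj) <- "geno_matrix"
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "animals x", ncol(x$calls), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param i animal ids or indices; @param j SNP ids or indices.
#' @param ... unused.
#' @param recompute_p recompute allele frequencies on the subset (default
#'   FALSE: frequencies of the parent matrix are retained, which is what the
#'   back-solving step needs).
#' @export
subset_geno <- function(x, i = NULL, j = NULL, ..., recompute_p = FALSE) {
  calls <- x$calls
  p <- x$p
  map <- x$map
  if (!is.null(i)) calls <- calls[i, , drop = FALSE]
  if (!is.null(j)) {
    calls <- calls[, j, drop = FALSE]
    keep <- match(colnames(calls), map$snp)
    map <- map[keep, , drop = FALSE]
    p <- p[keep]
  }
  obj <- list(calls = calls, map = map,
              p = if (recompute_p) colMeans(calls, na.rm = TRUE) / 2 else p)
  class(obj) <- "geno_matrix"
  obj
}

#' Centered (optionally mean-imputed) dosage matrix
#'
#' Missing calls are replaced by twice the allele frequency at matrix
#' construction time only; the stored calls keep their NAs. Centering
#' subtracts 2p per SNP.
#'
#' @param geno a `geno_matrix`.
#' @param center subtract 2p per column.
#' @param p allele frequencies to use (default: the matrix's own).
#' @return numeric matrix animals x SNPs.
#' @export
dosage_matrix <- function(geno, center = TRUE, p = geno$p) {
  M <- geno$calls
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- 2 * p[na[, 2L]]
  }
  if (center) M <- sweep(M, 2L, 2 * p, "-")
  M
}

#' Read genotypes in a PLINK-style dialect
#'
#' Supports two text dialects: `raw_additive` (PLINK `.raw`-style,
#' whitespace-separated, header `FID IID PAT MAT SEX PHENOTYPE snp1 ...`,
#' additive dosages 0/1/2 with `NA` for missing) and `ped_map`
#' (`.ped`/`.map` pair with two allele columns per SNP, `0` = missing).
#' Calls are recoded to minor-allele dosage; allele frequencies come from
#' non-missing calls. SNPs with more than two alleles are rejected.
#'
#' @param path file path. For `ped_map`, the `.ped` path (the `.map` is
#'   found by extension substitution) or the common prefix.
#' @param dialect `"raw_additive"` or `"ped_map"`.
#' @param map for `raw_additive`: optional data frame (snp, chrom, pos);
#'   when absent, all SNPs are placed on chromosome 1 at consecutive
#'   positions.
#' @param pedigree optional pedigree; ids absent from it are returned in an
#'   attribute `id_warnings` (with a warning).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("raw_additive", "ped_map"),
                           map = NULL, pedigree = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "raw_additive") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    snp_cols <- setdiff(names(df), meta)
    calls <- as.matrix(df[, snp_cols, drop = FALSE])
    storage.mode(calls) <- "integer"
    rownames(calls) <- as.character(df$IID)
    if (is.null(map)) {
      map <- data.frame(snp = snp_cols, chrom = 1L, pos = seq_along(snp_cols))
    }
    m <- map[match(snp_cols, map$snp), ]
    # flip to minor-allele dosage where the counted allele is the major one
    p <- colMeans(calls, na.rm = TRUE) / 2
    flip <- !is.na(p) & p > 0.5
    calls[, flip] <- 2L - calls[, flip]
    geno <- genotype_matrix(calls, m$chrom, m$pos, snp_ids = snp_cols)
  } else {
    ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
    map_path <- sub("\\.ped$", ".map", ped_path)
    mp <- utils::read.table(map_path, stringsAsFactors = FALSE)
    names(mp)[1:4] <- c("chrom", "snp", "cm", "pos")
    lines <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    ids <- lines[[2L]]
    al <- as.matrix(lines[, -(1:6), drop = FALSE])
    nsnp <- ncol(al) / 2L
    if (nsnp != nrow(mp)) stop(".ped/.map column count mismatch")
    a1 <- al[, 2L * seq_len(nsnp) - 1L, drop = FALSE]
    a2 <- al[, 2L * seq_len(nsnp), drop = FALSE]
    calls <- matrix(NA_integer_, length(ids), nsnp,
                    dimnames = list(ids, mp$snp))
    for (k in seq_len(nsnp)) {
      obs <- c(a1[, k], a2[, k])
      alleles <- sort(unique(obs[obs != "0"]))
      if (length(alleles) > 2L)
        stop("SNP ", mp$snp[k], " is not biallelic: ",
             paste(alleles, collapse = "/"))
      if (length(alleles) == 0L) next  # all missing
      counts <- tabulate(factor(obs[obs != "0"], levels = alleles),
                         nbins = length(alleles))
      minor <- alleles[which.min(counts)]  # ties -> first alphabetically
      ok <- a1[, k] != "0" & a2[, k] != "0"
      calls[ok, k] <- (a1[ok, k] == minor) + (a2[ok, k] == minor)
    }
    geno <- genotype_matrix(calls, mp$chrom, mp$pos, snp_ids = mp$snp)
  }
  if (!is.null(pedigree)) {
    missing_ids <- setdiff(rownames(geno$calls), pedigree$animal)
    if (length(missing_ids)) {
      warning(length(missing_ids), " genotyped id(s) absent from pedigree")
      attr(geno, "id_warnings") <- missing_ids
    }
  }
  geno
}

#' Write genotypes
#'
#' @param geno a `geno_matrix`.
#' @param path output path (`.raw`-style file, or `.ped` path/prefix for
#'   `ped_map`, whose `.map` companion is written alongside).
#' @param dialect output dialect, as in [read_genotypes()].
#' @export
write_genotypes <- function(geno, path, dialect = c("raw_additive", "ped_map")) {
  dialect <- match.arg(dialect)
  ids <- rownames(geno$calls)
  if (dialect == "raw_additive") {
    df <- data.frame(FID = ids, IID = ids, PAT = 0, MAT = 0, SEX = 0,
                     PHENOTYPE = -9, check.names = FALSE)
    df <- cbind(df, as.data.frame(geno$calls, check.names = FALSE))
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  } else {
    ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
    map_path <- sub("\\.ped$", ".map", ped_path)
    utils::write.table(
      data.frame(geno$map$chrom, geno$map$snp, 0, geno$map$pos),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    # minor allele "B", major "A"; dosage counts B
    n <- nrow(geno$calls); m <- ncol(geno$calls)
    a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
    one <- !is.na(geno$calls) & geno$calls >= 1L
    two <- !is.na(geno$calls) & geno$calls == 2L
    zero <- !is.na(geno$calls) & geno$calls == 0L
    a1[one] <- "B"; a1[zero] <- "A"
    a2[two] <- "B"; a2[one & !two] <- "A"; a2[zero] <- "A"
    inter <- matrix("", n, 2L * m)
    inter[, 2L * seq_len(m) - 1L] <- a1
    inter[, 2L * seq_len(m)] <- a2
    out <- cbind(ids, ids, "0", "0", "0", "-9", inter)
    utils::write.table(out, ped_path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
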