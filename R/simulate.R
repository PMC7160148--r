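#' Simulation configuration
#'
#' Population and marker settings for the synthetic study generator. The
#' defaults emulate a desk-scale version of a multi-herd beef-cattle
#' design: discrete generations, heavy sire reuse across contemporary
#' groups (CGs), part-genotyped animals, and a 29-autosome marker map.
#'
#' @param n_founders founder animals (generation 0, half of each sex).
#' @param n_generations total generations including founders.
#' @param offspring_per_mating offspring per dam per generation.
#' @param n_snps,n_qtl marker and causal-variant counts (QTLs are a subset
#'   of the genotyped SNPs, so marker effects are exactly recoverable).
#' @param maf_range founder allele-frequency range, in (0, 0.5].
#' @param n_cg total number of contemporary groups (split over the
#'   non-founder generations).
#' @param cg_mean_spread approximate range (max - min) of true CG effects
#'   on the descriptor trait, in trait units; effects are drawn normal with
#'   sd = spread/6 so standardized values span roughly -3..+3.
#' @param genotyped_fraction fraction of animals genotyped (latest
#'   generations first, mirroring selective genotyping of young animals and
#'   influential sires).
#' @param missing_rate genotype missing-call rate.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200, n_generations = 4,
                       offspring_per_mating = 2, n_snps = 2000, n_qtl = 100,
                       maf_range = c(0.05, 0.5), n_cg = 30,
                       cg_mean_spread = 180, genotyped_fraction = 0.6,
                       missing_rate = 0.01, seed = 1) {
  stopifnot(n_qtl <= n_snps, n_founders > 0, n_generations >= 1,
            offspring_per_mating > 0, n_cg > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            genotyped_fraction >= 0, genotyped_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' True simulation parameters for the reaction-norm trait
#'
#' @param K 2x2 genetic covariance of (intercept, slope) regression
#'   coefficients on the normalized Legendre basis; must be symmetric PSD.
#' @param residual_class_vars residual variances for the five environment
#'   classes (low to high EC).
#' @param qtl_var_frac fraction of K attributable to the QTLs (the rest is
#'   polygenic with pedigree covariance).
#' @param mu trait mean; @param cg_sd sd of CG effects on the target trait.
#' @return list of class `sim_truth_spec`.
#' @export
sim_truth_spec <- function(K = matrix(c(1600, -240, -240, 900), 2),
                           residual_class_vars = c(2800, 2400, 2000, 1800, 1600),
                           qtl_var_frac = 0.5, mu = 1050, cg_sd = 40) {
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("true K is not positive semidefinite")
  stopifnot(all(residual_class_vars >= 0), qtl_var_frac >= 0, qtl_var_frac <= 1)
  structure(list(K = K, residual_class_vars = residual_class_vars,
                 qtl_var_frac = qtl_var_frac, mu = mu, cg_sd = cg_sd),
            class = "sim_truth_spec")
}

# draw n samples from N(0, S) allowing singular S
rmvn0 <- function(n, S) {
  q <- nrow(S)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * q), n, q)
  Z %*% t(e$vectors %*% diag(sqrt(lam), q))
}

#' Simulate a multi-generation pedigree with contemporary groups
#'
#' Discrete generations; every non-founder has both parents in earlier
#' generations. Each generation's dams are mated once to sires drawn
#' cyclically from a reduced sire pool (each sire serving several matings),
#' and matings are spread over that generation's CGs, so common sires
#' connect CGs. A fix-up pass guarantees that every sire with two or more
#' matings appears in at least two distinct CGs whenever the generation has
#' two or more CGs.
#'
#' @param cfg a [sim_config()].
#' @return A `pedigree` with columns animal, sire, dam, generation, sex, cg
#'   (cg is NA for founders, which carry no records).
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  id_fmt <- function(g, i) sprintf("G%d_%04d", g, i)
  n0 <- cfg$n_founders
  ped <- data.frame(animal = id_fmt(0L, seq_len(n0)), sire = "0", dam = "0",
                    generation = 0L,
                    sex = rep_len(c("M", "F"), n0), cg = NA_character_,
                    stringsAsFactors = FALSE)
  n_gen_off <- max(1L, cfg$n_generations - 1L)
  n_cg_gen <- max(1L, round(cfg$n_cg / n_gen_off))
  for (g in seq_len(cfg$n_generations - 1L)) {
    prev <- ped[ped$generation == g - 1L, ]
    dams <- prev$animal[prev$sex == "F"]
    males <- prev$animal[prev$sex == "M"]
    if (!length(dams) || !length(males)) break
    n_mat <- length(dams)
    n_sires <- max(1L, min(length(males), floor(n_mat / 2)))
    pool <- sample(males, n_sires)
    sire_of <- rep_len(pool, n_mat)
    dams <- sample(dams)
    cg_of <- rep_len(paste0("Y", g, "_C", seq_len(n_cg_gen)), n_mat)
    # guarantee sire-CG connectedness
    if (n_cg_gen >= 2L) {
      for (s in unique(sire_of)) {
        m <- which(sire_of == s)
        if (length(m) >= 2L && length(unique(cg_of[m])) == 1L) {
          alt <- setdiff(unique(cg_of), cg_of[m[1L]])[1L]
          cg_of[m[length(m)]] <- alt
        }
      }
    }
    opm <- cfg$offspring_per_mating
    off <- data.frame(
      animal = id_fmt(g, seq_len(n_mat * opm)),
      sire = rep(sire_of, each = opm),
      dam = rep(dams, each = opm),
      generation = g,
      sex = rep_len(c("F", "M"), n_mat * opm),
      cg = rep(cg_of, each = opm),
      stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
  }
  as_pedigree(ped)
}

#' Closed-form size of a simulated pedigree
#'
#' Generation g (g >= 1) has floor(size(g-1)/2) dams, each producing
#' `offspring_per_mating` offspring.
#'
#' @param cfg a [sim_config()].
#' @export
expected_pedigree_size <- function(cfg) {
  sizes <- cfg$n_founders
  for (g in seq_len(cfg$n_generations - 1L)) {
    dams <- floor(sizes[g] / 2)
    sizes <- c(sizes, dams * cfg$offspring_per_mating)
  }
  sum(sizes)
}

#' Simulate genotypes by founder sampling and gene dropping
#'
#' Founder dosages are Binomial(2, p_k) with p_k uniform over
#' `maf_range`; descendants receive one allele per parent (Mendelian gene
#' dropping at unlinked loci). Positions are laid out on a 29-autosome map.
#' A `genotyped_ids` attribute marks the genotyped subset (latest
#' generations plus their sires, up to `genotyped_fraction`), and missing
#' calls are sprinkled at `missing_rate` among genotyped animals.
#'
#' @param ped a `pedigree` from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @param founder_p optional fixed founder frequencies (length n_snps).
#' @return A [genotype_matrix()] over all pedigree animals, with attributes
#'   `genotyped_ids` and `founder_p`.
#' @export
simulate_genotypes <- function(ped, cfg, founder_p = NULL) {
  set.seed(cfg$seed + 1L)
  n <- nrow(ped); m <- cfg$n_snps
  if (is.null(founder_p))
    founder_p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  chrom <- sort(rep_len(1:29, m))
  pos <- integer(m)
  for (ch in 1:29) {
    k <- sum(chrom == ch)
    # ~50 kb marker spacing: a desk-scale genome compressed so that
    # +/-200 kb windows and regional LD stay meaningful
    pos[chrom == ch] <- 1e5 + (seq_len(k) - 1L) * 5e4
  }
  pi <- ped_parent_index(ped)
  calls <- matrix(0L, n, m, dimnames = list(ped$animal, NULL))
  transmit <- function(d) {
    # one allele sampled from a parent with dosage vector d
    het <- d == 1L
    t <- as.integer(d == 2L)
    if (any(het)) t[het] <- stats::rbinom(sum(het), 1L, 0.5)
    t
  }
  for (i in seq_len(n)) {
    if (pi$sire[i] == 0L && pi$dam[i] == 0L) {
      calls[i, ] <- stats::rbinom(m, 2L, founder_p)
    } else {
      s <- if (pi$sire[i] > 0L) transmit(calls[pi$sire[i], ]) else
        stats::rbinom(m, 1L, founder_p)
      d <- if (pi$dam[i] > 0L) transmit(calls[pi$dam[i], ]) else
        stats::rbinom(m, 1L, founder_p)
      calls[i, ] <- s + d
    }
  }
  n_geno <- round(cfg$genotyped_fraction * n)
  genotyped <- utils::head(ped$animal[order(-ped$generation)], n_geno)
  if (cfg$missing_rate > 0 && length(genotyped)) {
    gi <- match(genotyped, ped$animal)
    nmiss <- stats::rbinom(1L, length(gi) * m, cfg$missing_rate)
    if (nmiss > 0) {
      miss <- cbind(sample(gi, nmiss, replace = TRUE),
                    sample.int(m, nmiss, replace = TRUE))
      calls[miss] <- NA_integer_
    }
  }
  geno <- genotype_matrix(calls, chrom, pos,
                          snp_ids = sprintf("snp%05d", seq_len(m)))
  attr(geno, "genotyped_ids") <- genotyped
  attr(geno, "founder_p") <- founder_p
  geno
}

# polygenic (q-coefficient) breeding values with pedigree covariance:
# founders ~ N(0, K), offspring = midparent + N(0, K/2) Mendelian sampling
# (inbreeding in the sampling variance is neglected; random mating at this
# scale keeps F below ~1%).
sim_polygenic <- function(ped, K) {
  q <- nrow(K)
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  U <- matrix(0, n, q, dimnames = list(ped$animal, NULL))
  founder <- pi$sire == 0L & pi$dam == 0L
  U[founder, ] <- rmvn0(sum(founder), K)
  ms <- rmvn0(n, K / 2)
  for (i in which(!founder)) {
    mid <- numeric(q)
    if (pi$sire[i] > 0L) mid <- mid + 0.5 * U[pi$sire[i], ]
    if (pi$dam[i] > 0L) mid <- mid + 0.5 * U[pi$dam[i], ]
    U[i, ] <- mid + ms[i, ]
  }
  U
}

#' Simulate the descriptor trait (stage-1 input)
#'
#' Body-weight-like animal model: y = mu + CG effect + age * slope +
#' additive value + residual, with additive values following the pedigree
#' and CG effects drawn normal with sd = `cg_mean_spread`/6 (so
#' standardized CG effects span roughly -3..+3). Records exist for every
#' animal with a CG (non-founders).
#'
#' @param geno unused except for reproducibility of the shared seed stream;
#'   may be NULL.
#' @param ped a simulated `pedigree` with a `cg` column.
#' @param cfg a [sim_config()].
#' @param mu,beta_age,sigma2_a,sigma2_e trait mean, age slope (units/day),
#'   additive and residual variances. Defaults give heritability 0.3.
#' @return data frame (animal, cg, value, age) with attribute `truth`:
#'   list(cg_effects, ec (standardized true CG effects, winsorized at
#'   +/-3), u (additive values), h2).
#' @export
simulate_descriptor_trait <- function(geno, ped, cfg, mu = 230,
                                      beta_age = 0.5, sigma2_a = 120,
                                      sigma2_e = 280) {
  set.seed(cfg$seed + 2L)
  rec <- ped[!is.na(ped$cg), ]
  cgs <- sort(unique(rec$cg))
  cg_eff <- stats::rnorm(length(cgs), 0, cfg$cg_mean_spread / 6)
  names(cg_eff) <- cgs
  u <- sim_polygenic(ped, matrix(sigma2_a, 1, 1))[, 1]
  age <- round(stats::runif(nrow(rec), 300, 420))
  y <- mu + cg_eff[rec$cg] + beta_age * (age - 360) + u[rec$animal] +
    stats::rnorm(nrow(rec), 0, sqrt(sigma2_e))
  ec <- if (length(cgs) > 1L && stats::sd(cg_eff) > 0)
    (cg_eff - mean(cg_eff)) / pop_sd(cg_eff) else rep(0, length(cgs))
  ec <- pmin(pmax(ec, -3), 3)
  names(ec) <- cgs
  out <- data.frame(animal = rec$animal, cg = rec$cg, value = unname(y),
                    age = age, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(cg_effects = cg_eff, ec = ec, u = u,
                             h2 = sigma2_a / (sigma2_a + sigma2_e))
  out
}

#' Simulate the reaction-norm target trait with QTLs and truth tables
#'
#' Each animal's genetic merit is a line over the environmental gradient:
#' coefficients (a_i, b_i) on the normalized Legendre basis are the sum of
#' a polygenic part (pedigree covariance, share 1 - `qtl_var_frac` of K)
#' and QTL contributions (centered dosages times bivariate-normal
#' intercept/slope effects scaled so the expected QTL share is
#' `qtl_var_frac` of K). Records are y = mu + CG effect + a phi0(EC) +
#' b phi1(EC) + e, with the residual variance of the EC's class.
#'
#' @param geno full-population [genotype_matrix()].
#' @param ped simulated `pedigree` with `cg`.
#' @param cfg a [sim_config()].
#' @param truth_spec a [sim_truth_spec()]; may carry `ec_by_cg` (named
#'   vector, typically the descriptor truth) — otherwise CG environment
#'   levels are drawn fresh.
#' @param qtl_mode `"intercept_slope"` (correlated, from K),
#'   `"slope_only"`, or `"intercept_only"`.
#' @param qtl_effect_dist `"normal"` (bivariate-normal draws) or
#'   `"fixed"`: equal per-QTL variance contributions with random signs,
#'   the standard design for detection-power experiments (a Gaussian draw
#'   leaves a third of QTLs with effects too small for any method to
#'   see). `"fixed"` applies to the single-component modes.
#' @return list(phenotypes = data.frame(animal, cg, value), truth =
#'   `sim_truth` list).
#' @export
simulate_reaction_norm_phenotypes <- function(geno, ped, cfg,
                                              truth_spec = sim_truth_spec(),
                                              qtl_mode = "intercept_slope",
                                              qtl_effect_dist = "normal") {
  set.seed(cfg$seed + 3L)
  K <- truth_spec$K
  rec <- ped[!is.na(ped$cg), ]
  cgs <- sort(unique(rec$cg))
  ec <- truth_spec$ec_by_cg
  if (is.null(ec)) {
    raw <- stats::rnorm(length(cgs))
    ec <- pmin(pmax((raw - mean(raw)) / pop_sd(raw), -3), 3)
    names(ec) <- cgs
  }
  ec <- ec[cgs]
  f <- truth_spec$qtl_var_frac
  # the QTLs take share f of the targeted component(s); the polygenic part
  # keeps the rest (congruence scaling keeps K_poly PSD)
  D <- switch(qtl_mode,
    intercept_slope = diag(sqrt(1 - f), 2),
    slope_only = diag(c(1, sqrt(1 - f))),
    intercept_only = diag(c(sqrt(1 - f), 1)),
    stop("unknown qtl_mode"))
  K_poly <- D %*% K %*% D
  U <- sim_polygenic(ped, K_poly)
  qtl_idx <- sort(sample.int(ncol(geno$calls), cfg$n_qtl))
  pq <- geno$p[qtl_idx]
  het <- 2 * pq * (1 - pq)
  Vb <- switch(qtl_mode,
    intercept_slope = f * K / sum(het),
    slope_only = f * matrix(c(0, 0, 0, K[2, 2]), 2) / sum(het),
    intercept_only = f * matrix(c(K[1, 1], 0, 0, 0), 2) / sum(het))
  if (qtl_effect_dist == "fixed" && qtl_mode != "intercept_slope") {
    comp <- if (qtl_mode == "slope_only") 2L else 1L
    mag <- sqrt(f * K[comp, comp] / (cfg$n_qtl * het))
    B <- matrix(0, cfg$n_qtl, 2)
    B[, comp] <- mag * sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
  } else {
    B <- rmvn0(cfg$n_qtl, Vb)
  }
  Mq <- dosage_matrix(subset_geno(geno, j = qtl_idx), center = TRUE)
  coef <- U + Mq %*% B
  K_qtl_real <- t(B) %*% (B * het)
  K_real <- K_poly + K_qtl_real
  cg_eff <- stats::rnorm(length(cgs), 0, truth_spec$cg_sd)
  names(cg_eff) <- cgs
  phi <- legendre_basis(ec, order = 1)
  cls <- assign_residual_class(ec)
  gval <- rowSums(coef[rec$animal, , drop = FALSE] * phi[match(rec$cg, cgs), ])
  sds <- sqrt(truth_spec$residual_class_vars[cls[match(rec$cg, cgs)]])
  y <- truth_spec$mu + cg_eff[rec$cg] + gval + stats::rnorm(nrow(rec), 0, sds)
  truth <- list(
    K_target = K, K_realized = K_real, K_poly = K_poly,
    residual_class_vars = truth_spec$residual_class_vars,
    qtl = data.frame(snp = geno$map$snp[qtl_idx], p = pq,
                     beta_intercept = B[, 1], beta_slope = B[, 2],
                     stringsAsFactors = FALSE),
    ec_by_cg = ec, cg_effects_target = cg_eff,
    coefficients = coef, mu = truth_spec$mu)
  class(truth) <- "sim_truth"
  list(phenotypes = data.frame(animal = rec$animal, cg = rec$cg,
                               value = unname(y), stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a gene annotation and gene-set collection
#'
#' Random gene intervals placed on the marker map's chromosomes (some near
#' SNPs so windows are non-trivially populated) plus GMT-style gene sets
#' drawn from the gene universe. Everything is synthetic, for pipeline
#' exercises and enrichment calibration only.
#'
#' @param geno a [genotype_matrix()] supplying the map.
#' @param n_genes,n_sets counts; @param set_size_range gene-set sizes.
#' @param seed RNG seed.
#' @return list(genes = data.frame(chrom, start, end, gene; 1-based
#'   inclusive), gene_sets = named list of gene-id vectors).
#' @export
simulate_annotation <- function(geno, n_genes = 150, n_sets = 25,
                                set_size_range = c(5, 25), seed = 1) {
  set.seed(seed)
  anchor <- sample.int(ncol(geno$calls), n_genes, replace = TRUE)
  offset <- round(stats::rnorm(n_genes, 0, 150000))
  start <- pmax(1L, geno$map$pos[anchor] + offset)
  len <- round(stats::runif(n_genes, 2000, 80000))
  genes <- data.frame(chrom = geno$map$chrom[anchor], start = start,
                      end = start + len,
                      gene = sprintf("GENE%04d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
    sort(sample(genes$gene, min(sz, n_genes)))
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  list(genes = genes, gene_sets = sets)
}

#' Simulate a full two-trait study and (optionally) write it to disk
#'
#' Orchestrates pedigree, genotypes, descriptor trait (whose true CG
#' effects define the environment levels used by the target trait),
#' reaction-norm target trait, and a synthetic annotation.
#'
#' @param cfg a [sim_config()]; @param truth_spec a [sim_truth_spec()].
#' @param qtl_mode passed to [simulate_reaction_norm_phenotypes()].
#' @param dir if non-NULL, write the pipeline's input files there (see
#'   [write_sim_bundle()]).
#' @return list(ped, geno, descriptor, target, truth, annotation).
#' @export
simulate_study <- function(cfg = sim_config(), truth_spec = sim_truth_spec(),
                           qtl_mode = "intercept_slope",
                           qtl_effect_dist = "normal", dir = NULL) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  desc <- simulate_descriptor_trait(geno, ped, cfg)
  ts <- truth_spec
  ts$ec_by_cg <- attr(desc, "truth")$ec
  rn <- simulate_reaction_norm_phenotypes(geno, ped, cfg, ts, qtl_mode,
                                          qtl_effect_dist)
  ann <- simulate_annotation(geno, seed = cfg$seed + 4L)
  bundle <- list(ped = ped, geno = geno, descriptor = desc,
                 target = rn$phenotypes, truth = rn$truth,
                 descriptor_truth = attr(desc, "truth"), annotation = ann)
  if (!is.null(dir)) write_sim_bundle(bundle, dir)
  bundle
}

#' Write a simulated study as the pipeline's input files
#'
#' Writes pedigree.csv, genotypes.raw + genotypes_map.tsv (genotyped
#' animals only), descriptor_phenotypes.csv, target_phenotypes.csv,
#' genes.bed (synthetic), gene_sets.gmt (synthetic), and truth tables
#' (truth_qtl.tsv, truth_cg.tsv, truth_K.tsv).
#'
#' @param bundle from [simulate_study()]; @param dir output directory.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_pedigree(bundle$ped, p("pedigree.csv"))
  gids <- attr(bundle$geno, "genotyped_ids")
  obs <- subset_geno(bundle$geno, i = gids)
  write_genotypes(obs, p("genotypes.raw"), dialect = "raw_additive")
  utils::write.table(obs$map, p("genotypes_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$descriptor, p("descriptor_phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$target, p("target_phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_gene_bed(bundle$annotation$genes, p("genes_synthetic.bed"))
  write_gmt(bundle$annotation$gene_sets, p("gene_sets_synthetic.gmt"))
  tr <- bundle$truth
  utils::write.table(tr$qtl, p("truth_qtl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(cg = names(tr$ec_by_cg), ec_true = unname(tr$ec_by_cg),
               cg_effect_target = unname(tr$cg_effects_target[names(tr$ec_by_cg)])),
    p("truth_cg.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(parameter = c("K11", "K12", "K22", paste0("resid_class", 1:5)),
               value = c(tr$K_realized[1, 1], tr$K_realized[1, 2],
                         tr$K_realized[2, 2], tr$residual_class_vars)),
    p("truth_K.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
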