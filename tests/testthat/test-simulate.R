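test_that("pedigree simulation matches the closed-form count and structure", {
  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    offspring_per_mating = 2, n_cg = 4, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), expected_pedigree_size(cfg))
  expect_true(all(ped$generation[ped$sire == "0" & ped$dam == "0"] == 0L))
  # one-generation config: all founders
  ped1 <- simulate_pedigree(sim_config(n_founders = 8, n_generations = 1))
  expect_true(all(ped1$sire == "0" & ped1$dam == "0"))
  # parents strictly earlier generations
  gen <- setNames(ped$generation, ped$animal)
  nf <- ped[ped$sire != "0", ]
  expect_true(all(gen[nf$sire] < nf$generation))
  expect_true(all(gen[nf$dam] < nf$generation))
})

test_that("sires connect contemporary groups", {
  cfg <- sim_config(n_founders = 60, n_generations = 3, n_cg = 6, seed = 4)
  ped <- simulate_pedigree(cfg)
  off <- ped[ped$sire != "0", ]
  cg_per_sire <- tapply(off$cg, off$sire, function(x) length(unique(x)))
  n_mat_per_sire <- tapply(off$dam, off$sire, function(x) length(unique(x)))
  expect_true(all(cg_per_sire[n_mat_per_sire >= 2] >= 2))
})

test_that("gene dropping respects Mendelian constraints for every trio", {
  cfg <- sim_config(n_founders = 40, n_generations = 3, n_snps = 50,
                    n_qtl = 10, missing_rate = 0, seed = 6)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  calls <- geno$calls
  for (i in which(ped$sire != "0")) {
    s <- calls[ped$sire[i], ]; d <- calls[ped$dam[i], ]; o <- calls[i, ]
    expect_true(all(o >= (s == 2) + (d == 2)))
    expect_true(all(o <= 2 - ((s == 0) + (d == 0))))
  }
})

test_that("fixed founder alleles propagate and frequencies match binomial", {
  cfg <- sim_config(n_founders = 500, n_generations = 2, n_snps = 60,
                    n_qtl = 10, missing_rate = 0, seed = 8)
  ped <- simulate_pedigree(cfg)
  pfix <- c(1, rep(0.3, 59))  # first SNP fixed
  geno <- simulate_genotypes(ped, cfg, founder_p = pfix)
  expect_true(all(geno$calls[, 1] == 2L))
  fo <- geno$calls[ped$generation == 0L, -1]
  phat <- colMeans(fo) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 500))
  expect_true(all(abs(phat - 0.3) < 3.5 * se))
  # offspring of 0 x 0 parents carry dosage 0 (already implied by trio test)
})

test_that("reaction-norm phenotypes are exact when noiseless", {
  cfg <- sim_config(n_founders = 30, n_generations = 3, n_snps = 40,
                    n_qtl = 10, n_cg = 4, missing_rate = 0, seed = 10)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ts <- sim_truth_spec(residual_class_vars = rep(0, 5))
  rn <- simulate_reaction_norm_phenotypes(geno, ped, cfg, ts)
  tr <- rn$truth
  phi <- legendre_basis(tr$ec_by_cg[rn$phenotypes$cg])
  gval <- rowSums(tr$coefficients[rn$phenotypes$animal, ] * phi)
  expect_equal(rn$phenotypes$value,
               unname(tr$mu + tr$cg_effects_target[rn$phenotypes$cg] + gval),
               tolerance = 1e-12)
})

test_that("zero slope variance means no GxE: genetic values constant in EC", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_snps = 40,
                    n_qtl = 10, n_cg = 4, seed = 12)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ts <- sim_truth_spec(K = matrix(c(1600, 0, 0, 0), 2))
  rn <- simulate_reaction_norm_phenotypes(geno, ped, cfg, ts)
  coefs <- rn$truth$coefficients
  expect_equal(max(abs(coefs[, 2])), 0)
  g_lo <- drop(coefs %*% t(legendre_basis(-3)))
  g_hi <- drop(coefs %*% t(legendre_basis(3)))
  expect_equal(g_lo, g_hi)
})

test_that("simulated coefficient covariance matches the realized truth", {
  cfg <- sim_config(n_founders = 1250, n_generations = 4, n_snps = 300,
                    n_qtl = 60, n_cg = 20, missing_rate = 0, seed = 14)
  ped <- simulate_pedigree(cfg)
  expect_gte(nrow(ped), 5000)
  geno <- simulate_genotypes(ped, cfg)
  rn <- simulate_reaction_norm_phenotypes(geno, ped, cfg)
  emp <- stats::cov(rn$truth$coefficients)
  K <- rn$truth$K_realized
  expect_lt(abs(emp[1, 1] - K[1, 1]) / K[1, 1], 0.10)
  expect_lt(abs(emp[2, 2] - K[2, 2]) / K[2, 2], 0.10)
  expect_lt(abs(emp[1, 2] - K[1, 2]) / sqrt(K[1, 1] * K[2, 2]), 0.10)
})

test_that("descriptor trait spreads standardized CG effects and controls h2", {
  cfg <- sim_config(n_founders = 1000, n_generations = 3, n_cg = 40,
                    cg_mean_spread = 180, seed = 16)
  ped <- simulate_pedigree(cfg)
  ph <- simulate_descriptor_trait(NULL, ped, cfg)
  tr <- attr(ph, "truth")
  expect_equal(mean(tr$ec), 0, tolerance = 1e-10)
  expect_true(min(tr$ec) < -1.5 && max(tr$ec) > 1.5)
  # realized heritability near the configured 0.3
  u <- tr$u[ph$animal]
  resid <- ph$value - u - tr$cg_effects[ph$cg] - 0.5 * (ph$age - 360) - 230
  h2 <- var(u) / (var(u) + var(resid))
  expect_lt(abs(h2 - tr$h2), 0.1 * tr$h2 + 0.03)
  # zero spread: all true CG effects equal
  cfg0 <- sim_config(n_founders = 40, n_generations = 2, n_cg = 4,
                     cg_mean_spread = 0, seed = 18)
  ped0 <- simulate_pedigree(cfg0)
  ph0 <- simulate_descriptor_trait(NULL, ped0, cfg0)
  expect_equal(var(attr(ph0, "truth")$cg_effects), 0)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 3, n_snps = 30,
                    n_qtl = 5, n_cg = 4, seed = 20)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$geno$calls, b2$geno$calls)
  expect_identical(b1$target$value, b2$target$value)
  expect_identical(b1$truth$K_realized, b2$truth$K_realized)
})
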