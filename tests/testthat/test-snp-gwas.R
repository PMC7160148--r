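test_that("projection to EC levels follows the Legendre basis", {
  expect_equal(project_effect(c(0, 1), 3), 1.22474, tolerance = 1e-5)
  # zero slope: identical effects at every level
  expect_equal(project_effect(c(2, 0), -3), project_effect(c(2, 0), 3))
  # zero intercept: odd in ec
  expect_equal(project_effect(c(0, 1.3), -2.2),
               -project_effect(c(0, 1.3), 2.2))
  alpha <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(unname(project_effect(alpha, 0)), c(sqrt(.5), 0),
               tolerance = 1e-12)
})

test_that("variance explained is the 2pq u^2 share in percent", {
  expect_equal(variance_explained(0, 0.3, 10), 0)
  expect_equal(variance_explained(sqrt(10), 0.5, 10), 50)
  # in linkage equilibrium the causal SNPs account for ~100% together
  set.seed(81)
  m <- 400; n <- 3000
  p <- runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  beta <- rnorm(m, 0, 0.1)
  gv <- drop(scale(M, center = 2 * p, scale = FALSE) %*% beta)
  tot <- sum(variance_explained(beta, p, var(gv)))
  expect_lt(abs(tot - 100), 7)
})

test_that("genome-wide z-tests, BH and the threshold-form FDR behave", {
  set.seed(83)
  u <- rnorm(500, 0, 3)
  tst <- snp_test(u, sig_threshold_neglog10p = 1.30103)  # p < 0.05 flag
  expect_equal(mean(tst$z), 0, tolerance = 1e-12)
  expect_equal(sd(tst$z), 1, tolerance = 1e-12)
  expect_equal(tst$p, 2 * pnorm(-abs(tst$z)), tolerance = 1e-12)
  i <- which.min(abs(tst$z - 1.96))
  expect_equal(tst$p[i], 0.05, tolerance = 0.1)
  expect_true(all(tst$significant == (tst$neglog10p > 1.30103)))
  # BH against a brute-force threshold scan
  ps <- c(0.001, 0.004, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 0.9)
  bh_brute <- sapply(seq_along(ps), function(i) {
    min(sapply(which(ps >= ps[i]), function(j)
      ps[j] * length(ps) / sum(ps <= ps[j])))
  })
  expect_equal(p.adjust(ps, "BH"), bh_brute)
  expect_true(all(diff(p.adjust(sort(ps), "BH")) >= 0))
  # degenerate effects are rejected
  expect_error(snp_test(rep(1, 10)), "zero variance")
  # threshold-form estimate n_m * p_sig / n_msig
  expect_equal(attr(snp_test(u), "fdr_threshold_form"),
               500 * 0.01 / sum(snp_test(u)$p < 0.01))
})

test_that("the literal z formulation has constant magnitude (why it is shelved)", {
  u <- rnorm(50)
  zl <- snp_test(u, literal = TRUE)$z
  expect_equal(sd(abs(zl)), 0, tolerance = 1e-9)
})

test_that("inflation factor matches its chi-square(1) convention", {
  expect_equal(inflation_factor(rep(sqrt(0.456), 200))$lambda, 1)
  set.seed(85)
  z <- rnorm(1e5)
  lam <- inflation_factor(z)
  expect_gt(lam$lambda, 0.97); expect_lt(lam$lambda, 1.03)
  lam2 <- inflation_factor(1.2 * z)
  expect_equal(lam2$lambda / lam$lambda, 1.44, tolerance = 1e-9)
  # the literal median-p form sits near 1.09 for any null set
  expect_equal(lam$lambda_literal_p, 0.5 / 0.456, tolerance = 0.05)
})

test_that("Venn stratification enumerates the 7 cells", {
  sets <- list(Low = c("A", "B", "C"), Medium = c("B", "C", "D"),
               High = "C")
  part <- stratify_shared_specific(sets)
  expect_equal(part$all, "C")
  expect_equal(part$Medium_and_High, character(0))
  expect_equal(part$Low_and_Medium, "B")
  expect_equal(part$Medium_only, "D")
  expect_equal(part$Low_only, "A")
  same <- stratify_shared_specific(list(L = "x", M = "x", H = "x"))
  expect_equal(same$all, "x")
  expect_true(all(lengths(same[1:6]) == 0))
  disj <- stratify_shared_specific(list(L = "a", M = "b", H = "c"))
  expect_true(all(lengths(disj[4:7]) == 0))
})

test_that("back-solving is an exact projection with unblended G", {
  b <- small_bundle()
  geno <- b$geno_obs
  Mc <- dosage_matrix(geno, center = TRUE)
  set.seed(87)
  w <- rnorm(ncol(Mc), 0, 0.1)
  a_target <- Mc %*% cbind(w, -w)  # breeding values in the row space
  rn <- list(alpha = a_target,
             accuracy = matrix(1, nrow(a_target), 2,
                               dimnames = list(rownames(a_target), NULL)))
  alpha <- backsolve_snp_coefficients(rn, geno, accuracy_min = 0.4,
                                      blend_weight = 1)
  recon <- Mc %*% alpha
  expect_lt(max(abs(recon - a_target)), 1e-6)
  # all-zero breeding values give all-zero marker effects
  rn0 <- rn; rn0$alpha <- a_target * 0
  expect_equal(max(abs(backsolve_snp_coefficients(rn0, geno))), 0)
  # accuracy filter: nobody passes -> error
  rn_bad <- rn; rn_bad$accuracy[] <- 0.1
  expect_error(backsolve_snp_coefficients(rn_bad, geno), "accuracy")
})

test_that("a single large QTL tops the genome-wide intercept effects", {
  cfg <- sim_config(n_founders = 150, n_generations = 3, n_snps = 400,
                    n_qtl = 1, n_cg = 10, genotyped_fraction = 0.8,
                    missing_rate = 0, seed = 89)
  ts <- sim_truth_spec(K = matrix(c(1600, 0, 0, 100), 2),
                       qtl_var_frac = 0.8,
                       residual_class_vars = rep(800, 5))
  b <- simulate_study(cfg, truth_spec = ts, qtl_mode = "intercept_only")
  rel <- study_relationships(b)
  rn <- suppressWarnings(fit_ssgrn(b$target, true_ecd(b), rel$Hinv,
                                   H = rel$H))
  alpha <- suppressWarnings(backsolve_snp_coefficients(
    rn, rel$geno_obs, accuracy_min = 0.4, blend_weight = 1))
  top <- rownames(alpha)[which.max(abs(alpha[, "intercept"]))]
  expect_equal(top, b$truth$qtl$snp[1])
})
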