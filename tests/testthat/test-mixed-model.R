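test_that("solve_mme equals the dense GLS oracle on random instances", {
  for (s in 1:10) {
    inst <- random_mme_instance(s)
    spec <- mme_spec(inst$y, inst$X, inst$animal, inst$Phi, inst$K,
                     rel_inv = inst$rel_inv, rel = inst$rel,
                     resid_class = inst$resid_class,
                     resid_vars = inst$resid_vars)
    sol <- solve_mme(spec)
    orc <- gls_oracle(inst$y, inst$X, inst$animal, inst$Phi, inst$K,
                      inst$rel, inst$resid_class, inst$resid_vars)
    expect_lt(max(abs(sol$beta - orc$beta)), 1e-8)
    expect_lt(max(abs(sol$u - orc$U)), 1e-8)
  }
})

test_that("with no random effect the solution is (weighted) least squares", {
  set.seed(51)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n)); colnames(X) <- c("i", "x1", "x2")
  y <- drop(X %*% c(2, 1, -1)) + rnorm(n)
  sol <- solve_mme(mme_spec(y, X, resid_vars = 1))
  expect_equal(unname(sol$beta), unname(coef(lm(y ~ 0 + X))),
               tolerance = 1e-10)
})

test_that("huge prior variance drives BLUPs to the fixed group means", {
  set.seed(53)
  ids <- paste0("A", 1:6)
  anim <- rep(ids, each = 8)
  mu <- rnorm(6, 0, 3)
  y <- 10 + mu[match(anim, ids)] + rnorm(48, 0, 0.5)
  I <- diag(6); dimnames(I) <- list(ids, ids)
  X <- matrix(1, 48, 1); colnames(X) <- "mu"
  spec <- mme_spec(y, X, anim, Phi = matrix(1, 48, 1),
                   K = matrix(1e8, 1, 1), rel_inv = I, resid_vars = 0.25)
  sol <- solve_mme(spec, compute_logL = FALSE)
  means <- tapply(y, anim, mean)[ids]
  expect_equal(unname(drop(sol$u) + sol$beta[["mu"]]), as.vector(means),
               tolerance = 1e-4)
})

test_that("fixed_design drops confounded columns and keeps contrasts stable", {
  df <- data.frame(cg = rep(c("a", "b", "c"), each = 4),
                   herd = rep(c("h1", "h1", "h2"), each = 4),
                   x = rnorm(12))
  X <- fixed_design(df, factors = c("cg", "herd"), covariates = "x")
  # herd h2 is confounded with cg c given full cg dummies -> dropped
  expect_true("herd:h2" %in% attr(X, "dropped"))
  expect_equal(qr(X)$rank, ncol(X))
  # estimable contrast (difference of cg effects) invariant to baseline
  set.seed(55)
  y <- rnorm(12)
  b1 <- qr.coef(qr(X), y)
  df2 <- df; df2$cg <- factor(df2$cg, levels = c("c", "b", "a"))
  X2 <- fixed_design(df2, factors = c("cg", "herd"), covariates = "x")
  b2 <- qr.coef(qr(X2), y)
  expect_equal(b1[["cg:a"]] - b1[["cg:b"]], b2[["cg:a"]] - b2[["cg:b"]],
               tolerance = 1e-10)
})

test_that("REML matches the balanced one-way closed form by both methods", {
  set.seed(57)
  ng <- 25; r <- 5
  ids <- paste0("S", 1:ng)
  anim <- rep(ids, each = r)
  y <- 10 + rnorm(ng, 0, 2)[match(anim, ids)] + rnorm(ng * r, 0, 1.5)
  I <- diag(ng); dimnames(I) <- list(ids, ids)
  spec <- mme_spec(y, matrix(1, ng * r, 1, dimnames = list(NULL, "mu")),
                   anim, Phi = matrix(1, ng * r, 1), K = matrix(1, 1, 1),
                   rel_inv = I, rel = I, resid_vars = 1)
  m <- tapply(y, anim, mean)
  MSW <- sum((y - m[anim])^2) / (ng * (r - 1))
  MSB <- r * sum((m - mean(y))^2) / (ng - 1)
  for (meth in c("AI", "EM")) {
    est <- reml_estimate(spec, meth, final_solve = FALSE, max_iter = 500,
                         tol = 1e-10)
    expect_equal(est$K[1, 1], (MSB - MSW) / r, tolerance = 1e-5)
    expect_equal(est$resid_vars[1], MSW, tolerance = 1e-5)
    expect_true(est$converged)
  }
})

test_that("EM-REML log-likelihood never decreases", {
  inst <- random_mme_instance(99, n_max = 25)
  spec <- mme_spec(inst$y, inst$X, inst$animal, inst$Phi, inst$K,
                   rel_inv = inst$rel_inv, rel = inst$rel,
                   resid_class = inst$resid_class,
                   resid_vars = inst$resid_vars)
  est <- suppressWarnings(reml_estimate(spec, "EM", final_solve = FALSE,
                                        max_iter = 40, tol = 0))
  expect_true(all(diff(est$history$logL) > -1e-6))
})

test_that("a truly zero variance component is driven to the boundary", {
  set.seed(59)
  ng <- 40; r <- 4
  ids <- paste0("S", 1:ng)
  anim <- rep(ids, each = r)
  y <- 5 + rnorm(ng * r)  # no group variance at all
  I <- diag(ng); dimnames(I) <- list(ids, ids)
  spec <- mme_spec(y, matrix(1, ng * r, 1, dimnames = list(NULL, "mu")),
                   anim, Phi = matrix(1, ng * r, 1), K = matrix(0.5, 1, 1),
                   rel_inv = I, rel = I, resid_vars = 1)
  est <- suppressWarnings(reml_estimate(spec, "AI", final_solve = FALSE))
  expect_lt(est$K[1, 1], 1e-3)
})

test_that("accuracy from PEV behaves at the endpoints and with information", {
  K <- diag(c(4, 2))
  sol <- list(pev = array(0, c(2, 2, 2), dimnames = list(NULL, NULL,
                                                         c("a", "b"))),
              spec = list(K = K))
  class(sol) <- "mme_solution"
  sol$pev[, , 1] <- 0           # perfect information
  sol$pev[, , 2] <- K           # no information
  acc <- accuracy_from_pev(sol, K)
  expect_equal(unname(acc["a", ]), c(1, 1))
  expect_equal(unname(acc["b", ]), c(0, 0))
  # an over-threshold PEV is clamped with a warning
  sol$pev[1, 1, 2] <- K[1, 1] * 1.1
  expect_warning(acc2 <- accuracy_from_pev(sol, K), "clamped")
  expect_equal(unname(acc2["b", 1]), 0)
  # a sire with many progeny (over several recorded dams) beats one with
  # no records and no progeny
  set.seed(61)
  kids <- paste0("k", 1:30)
  ped <- as_pedigree(data.frame(
    animal = c("s1", "s2", paste0("d", 1:10), kids),
    sire = c("0", "0", rep("0", 10), rep("s1", 30)),
    dam = c("0", "0", rep("0", 10), rep(paste0("d", 1:10), 3))))
  A <- build_A(ped)
  anim <- c(paste0("d", 1:10), kids)
  y <- rnorm(length(anim), 10)
  spec <- mme_spec(y, matrix(1, length(anim), 1,
                             dimnames = list(NULL, "mu")), anim,
                   Phi = matrix(1, length(anim), 1), K = matrix(2, 1, 1),
                   rel_inv = invert_relmat(A), resid_vars = 1)
  sol2 <- solve_mme(spec)
  acc3 <- accuracy_from_pev(sol2, matrix(2, 1, 1))
  expect_gt(acc3["s1", 1], 0.3)
  expect_gt(acc3["s1", 1], acc3["s2", 1])
})
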