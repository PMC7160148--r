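# Shared fixtures, all built in code.

# small study bundle with relationship matrices, cached per session
small_bundle <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3, n_founders = 120, n_generations = 4, n_snps = 600,
           n_qtl = 40, n_cg = 18, genotyped_fraction = 0.6,
           truth_spec = sim_truth_spec(), qtl_mode = "intercept_slope") {
    key <- paste(seed, n_founders, n_snps, n_qtl, n_cg, qtl_mode, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(n_founders = n_founders,
                      n_generations = n_generations, n_snps = n_snps,
                      n_qtl = n_qtl, n_cg = n_cg,
                      genotyped_fraction = genotyped_fraction, seed = seed)
    b <- simulate_study(cfg, truth_spec = truth_spec, qtl_mode = qtl_mode)
    b$cfg <- cfg
    b <- c(b, study_relationships(b))
    cache[[key]] <- b
    b
  }
})

# A, A22, G, Hinv, H and the genotyped submatrix for a bundle
study_relationships <- function(b, blend_weight = 0.95) {
  A <- build_A(b$ped)
  gids <- attr(b$geno, "genotyped_ids")
  g2 <- subset_geno(b$geno, i = gids, recompute_p = TRUE)
  A22 <- ssgrn:::relmat(unclass(A)[gids, gids, drop = FALSE], gids, "A22")
  G <- build_G(g2)
  Ainv <- invert_relmat(A)
  list(A = A, Ainv = Ainv, A22 = A22, G = G, geno_obs = g2,
       Hinv = build_H_inverse(Ainv, A22, G, blend_weight),
       H = build_H(A, A22, G, blend_weight))
}

# EC descriptor from the simulation truth (no stage-1 estimation error)
true_ecd <- function(b) {
  ec <- b$truth$ec_by_cg
  out <- data.frame(cg = names(ec), blue_raw = NA_real_,
                    ec_raw = unname(ec), ec = unname(ec),
                    residual_class = assign_residual_class(unname(ec)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ec_descriptor", "data.frame")
  out
}

# brute-force GLS solutions via dense V (independent oracle for solve_mme)
gls_oracle <- function(y, X, animal, Phi, K, rel, resid_class, resid_vars) {
  ids <- rownames(rel)
  ai <- match(animal, ids)
  n <- length(y); na <- length(ids); q <- ncol(Phi)
  Z <- matrix(0, n, na * q)
  for (i in seq_len(n)) Z[i, (ai[i] - 1L) * q + seq_len(q)] <- Phi[i, ]
  G0 <- kronecker(unclass(rel), K)
  V <- Z %*% G0 %*% t(Z) + diag(resid_vars[resid_class], n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  u <- G0 %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), U = matrix(u, na, q, byrow = TRUE))
}

# random small mixed-model instance for property tests
random_mme_instance <- function(seed, n_max = 30) {
  set.seed(seed)
  n <- sample(8:n_max, 1)
  na <- sample(4:8, 1)
  q <- sample(1:2, 1)
  ids <- paste0("A", seq_len(na))
  animal <- sample(ids, n, replace = TRUE)
  L <- matrix(rnorm(na * na), na)
  rel <- crossprod(L) / na + diag(na)
  dimnames(rel) <- list(ids, ids)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("intercept", "x")
  Phi <- matrix(rnorm(n * q), n, q)
  if (q >= 1) Phi[, 1] <- 1
  Kl <- matrix(rnorm(q * q), q)
  K <- crossprod(Kl) + diag(q)
  n_cls <- sample(1:3, 1)
  resid_class <- sample(seq_len(n_cls), n, replace = TRUE)
  resid_vars <- runif(n_cls, 0.5, 2)
  y <- rnorm(n, 5)
  list(y = y, X = X, animal = animal, Phi = Phi, K = K, rel = rel,
       rel_inv = ssgrn:::relmat(solve(rel), ids, "inv"),
       resid_class = resid_class, resid_vars = resid_vars)
}
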