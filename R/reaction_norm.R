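#' Normalized Legendre polynomial basis over the environmental gradient
#'
#' The sd-scale environment level (nominally in \[-3, 3\]) is mapped to the
#' Legendre domain by x = ec/3, and the basis uses the "standardized"
#' polynomials Phi_f(x) = sqrt((2f+1)/2) P_f(x), the random-regression
#' convention in animal breeding. Values beyond +/-3 are clamped with a
#' warning.
#'
#' @param ec numeric environment level(s).
#' @param order highest polynomial order f (0-based); order 1 gives an
#'   intercept-and-slope reaction norm.
#' @param domain half-range of the gradient (default 3 sd).
#' @return matrix length(ec) x (order+1) of basis values.
#' @export
legendre_basis <- function(ec, order = 1, domain = 3) {
  stopifnot(order >= 0)
  if (any(abs(ec) > domain)) {
    warning("EC value(s) beyond +/-", domain, " clamped to the domain")
    ec <- pmin(pmax(ec, -domain), domain)
  }
  x <- ec / domain
  P <- matrix(0, length(x), order + 1L)
  P[, 1L] <- 1
  if (order >= 1) P[, 2L] <- x
  if (order >= 2) for (f in 2:order)
    P[, f + 1L] <- ((2 * f - 1) * x * P[, f] - (f - 1) * P[, f - 1L]) / f
  for (f in 0:order) P[, f + 1L] <- sqrt((2 * f + 1) / 2) * P[, f + 1L]
  colnames(P) <- paste0("phi", 0:order)
  P
}

#' Fit the single-step genomic reaction-norm model
#'
#' y_ij = CG_j + sum_f omega_f Phi_f(EC_j) + sum_f alpha_fi Phi_f(EC_j) +
#' e_ij, with per-animal (intercept, slope) coefficients distributed
#' N(0, H %x% K), fixed regression omega alongside the CG effects (their
#' collinearity with the CG factor is resolved by the design's sequential
#' identifiability rule), and residual variances heterogeneous over the
#' five environment classes. Variance components by REML, then a final
#' solve with prediction-error variances.
#'
#' @param pheno data frame `animal`, `cg`, `value` for the target trait.
#' @param ecd an [standardize_ec()] descriptor covering every CG in
#'   `pheno`.
#' @param Hinv single-step relationship inverse over all animals;
#'   @param H optional dense H (computed by inversion when absent).
#' @param start_K,start_res starting values for K (2x2) and the residual
#'   class variances (length 5); defaults scale with var(y).
#' @param order Legendre order (1 = intercept + slope).
#' @param method,tol,max_iter passed to [reml_estimate()].
#' @param compute_pev invert the coefficient matrix for prediction-error
#'   variances and accuracies (needed before back-solving; skip for pure
#'   variance-component runs).
#' @return list of class `rn_solution`: `K`, `resid_vars`, `alpha` (animal
#'   x 2 coefficient BLUPs), `accuracy`, `pev`, `beta` (CG and regression
#'   BLUEs), `ec_by_cg`, `logL`, `reml` (fit details), `order`.
#' @export
fit_ssgrn <- function(pheno, ecd, Hinv, H = NULL, start_K = NULL,
                      start_res = NULL, order = 1, method = "AI",
                      tol = 1e-8, max_iter = 200, compute_pev = TRUE) {
  stopifnot(all(c("animal", "cg", "value") %in% names(pheno)))
  m <- match(pheno$cg, ecd$cg)
  if (anyNA(m))
    stop("no EC level for CG(s): ",
         paste(unique(pheno$cg[is.na(m)]), collapse = ", "))
  ec <- ecd$ec[m]
  cls <- ecd$residual_class[m]
  Phi <- legendre_basis(ec, order = order)
  q <- order + 1L
  vy <- stats::var(pheno$value)
  if (is.null(start_K)) start_K <- diag(vy / 4, q)
  if (is.null(start_res)) start_res <- rep(vy / 2, 5)
  X <- fixed_design(pheno, factors = "cg",
                    covariates = list(omega = Phi))
  if (length(unique(ec)) < q)
    stop("EC gradient spans fewer distinct levels (", length(unique(ec)),
         ") than regression coefficients (", q, "): slope unidentifiable")
  spec <- mme_spec(pheno$value, X, animal = pheno$animal, Phi = Phi,
                   K = start_K, rel_inv = Hinv, rel = H,
                   resid_class = cls, resid_vars = start_res)
  est <- reml_estimate(spec, method = method, tol = tol,
                       max_iter = max_iter, final_solve = FALSE)
  spec2 <- spec; spec2$K <- est$K; spec2$resid_vars <- est$resid_vars
  sol <- solve_mme(spec2, compute_pev = compute_pev)
  acc <- if (compute_pev) accuracy_from_pev(sol, est$K) else NULL
  ec_by_cg <- stats::setNames(ecd$ec, ecd$cg)
  out <- list(K = est$K, resid_vars = est$resid_vars, alpha = sol$u,
              accuracy = acc, pev = sol$pev, beta = sol$beta,
              ec_by_cg = ec_by_cg, residual_class_by_cg =
                stats::setNames(ecd$residual_class, ecd$cg),
              logL = est$logL, reml = est[c("iterations", "converged",
                                            "history", "method")],
              order = order, solution = sol)
  class(out) <- "rn_solution"
  out
}

#' @export
print.rn_solution <- function(x, ...) {
  cat("ssGRN reaction-norm fit:", nrow(x$alpha), "animals, order", x$order,
      "\nK (coefficient covariance):\n")
  print(round(x$K, 4))
  cat("residual class variances:", round(x$resid_vars, 2), "\n")
  cat("REML", x$reml$method, "logL", format(x$logL),
      if (x$reml$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Additive genetic variance at an environment level
#'
#' sigma2_a(ec) = phi(ec) K phi(ec)'.
#'
#' @param K coefficient covariance; @param ec environment level(s).
#' @export
genetic_variance_at <- function(K, ec) {
  phi <- legendre_basis(ec, order = nrow(K) - 1L)
  rowSums((phi %*% K) * phi)
}

#' Genetic correlation between two environment levels
#'
#' phi(ec1) K phi(ec2)' / sqrt(sigma2_a(ec1) sigma2_a(ec2)).
#'
#' @param K coefficient covariance; @param ec1,ec2 environment levels.
#' @export
genetic_correlation <- function(K, ec1, ec2) {
  v1 <- genetic_variance_at(K, ec1)
  v2 <- genetic_variance_at(K, ec2)
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("zero genetic variance at one of the levels; correlation undefined")
  p1 <- legendre_basis(ec1, order = nrow(K) - 1L)
  p2 <- legendre_basis(ec2, order = nrow(K) - 1L)
  drop(rowSums((p1 %*% K) * p2)) / sqrt(v1 * v2)
}

#' Heritability at an environment level
#'
#' h2(ec) = sigma2_a(ec) / (sigma2_a(ec) + sigma2_e(class(ec))) with the
#' residual class from the fixed boundary map.
#'
#' @param K coefficient covariance; @param residual_class_vars length-5
#'   class variances; @param ec environment level(s).
#' @export
heritability_at <- function(K, residual_class_vars, ec) {
  va <- genetic_variance_at(K, ec)
  ve <- residual_class_vars[assign_residual_class(ec)]
  va / (va + ve)
}

#' Variance-component report over an EC grid
#'
#' @param rn an `rn_solution`; @param ec_grid levels to evaluate.
#' @return data frame ec, sigma2_a, sigma2_e, h2, plus K and residual
#'   entries as attributes; written by [write_varcomp_report()].
#' @export
varcomp_report <- function(rn, ec_grid = seq(-3, 3, by = 1)) {
  data.frame(ec = ec_grid,
             sigma2_a = genetic_variance_at(rn$K, ec_grid),
             sigma2_e = rn$resid_vars[assign_residual_class(ec_grid)],
             h2 = heritability_at(rn$K, rn$resid_vars, ec_grid))
}

#' @rdname varcomp_report
#' @param path output TSV path.
#' @export
write_varcomp_report <- function(rn, path, ec_grid = seq(-3, 3, by = 1)) {
  hdr <- data.frame(
    parameter = c("K_intercept", "K_intercept_slope", "K_slope",
                  paste0("resid_class", seq_along(rn$resid_vars))),
    value = c(rn$K[1, 1], rn$K[1, 2], rn$K[2, 2], rn$resid_vars))
  utils::write.table(hdr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(utils::write.table(
    varcomp_report(rn, ec_grid), path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  invisible(path)
}
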