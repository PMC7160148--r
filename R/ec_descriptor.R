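#' Estimate contemporary-group BLUEs for the descriptor trait
#'
#' Fits the stage-1 animal model y = CG + age * b + animal + e with the
#' animal effect distributed N(0, H sigma2_a) (single-step relationship
#' inverse) and a homogeneous residual, and returns the best linear
#' unbiased estimates of the CG effects. Variance components are either
#' supplied or estimated by REML.
#'
#' @param pheno data frame with columns `animal`, `cg`, `value` and
#'   (optionally) `age`.
#' @param Hinv relationship inverse over all animals (pedigree or blended
#'   single-step); @param H optional dense counterpart, used by REML.
#' @param varcomps list(sigma2_a, sigma2_e) or NULL to REML-estimate.
#' @param reml_method passed to [reml_estimate()].
#' @return named numeric vector of CG BLUEs, with the full `mme_solution`
#'   in attribute `solution` (and REML estimates in `varcomps`).
#' @export
estimate_cg_blues <- function(pheno, Hinv, H = NULL, varcomps = NULL,
                              reml_method = "AI") {
  stopifnot(all(c("animal", "cg", "value") %in% names(pheno)))
  covs <- list()
  if ("age" %in% names(pheno)) covs$age <- pheno$age - mean(pheno$age)
  X <- fixed_design(pheno, factors = "cg", covariates = covs)
  if (is.null(varcomps)) {
    vy <- stats::var(pheno$value)
    spec <- mme_spec(pheno$value, X, animal = pheno$animal,
                     Phi = matrix(1, nrow(pheno), 1),
                     K = matrix(vy / 3, 1, 1), rel_inv = Hinv, rel = H,
                     resid_vars = vy / 2)
    est <- reml_estimate(spec, method = reml_method, final_solve = FALSE)
    varcomps <- list(sigma2_a = est$K[1, 1], sigma2_e = est$resid_vars[1])
  }
  spec <- mme_spec(pheno$value, X, animal = pheno$animal,
                   Phi = matrix(1, nrow(pheno), 1),
                   K = matrix(varcomps$sigma2_a, 1, 1),
                   rel_inv = Hinv, rel = H, resid_vars = varcomps$sigma2_e)
  sol <- solve_mme(spec, compute_pev = FALSE, compute_logL = FALSE)
  cg_cols <- grep("^cg:", names(sol$beta))
  blues <- sol$beta[cg_cols]
  names(blues) <- sub("^cg:", "", names(blues))
  attr(blues, "solution") <- sol
  attr(blues, "varcomps") <- varcomps
  blues
}

#' Standardize CG BLUEs into the environmental gradient
#'
#' EC = (BLUE - mean) / sd over the unique CGs (population-sd convention,
#' i.e. divide by n), winsorized at +/- `clip` standard deviations; the
#' unclipped value is retained. Each CG also receives its residual class
#' (fixed boundary map, see [assign_residual_class()]).
#'
#' @param blues named per-CG BLUEs.
#' @param clip winsorization bound in sd units (default 3).
#' @return data frame of class `ec_descriptor`: cg, blue_raw, ec_raw, ec,
#'   residual_class.
#' @export
standardize_ec <- function(blues, clip = 3.0) {
  if (length(unique(blues)) < 2L) stop("need at least two distinct CG BLUEs")
  s <- pop_sd(blues)
  if (s == 0) stop("zero standard deviation among CG BLUEs")
  ec_raw <- (blues - mean(blues)) / s
  ec <- pmin(pmax(ec_raw, -clip), clip)
  out <- data.frame(cg = names(blues), blue_raw = unname(blues),
                    ec_raw = unname(ec_raw), ec = unname(ec),
                    residual_class = assign_residual_class(unname(ec)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ec_descriptor", "data.frame")
  out
}

#' Residual class of an environment level (fixed boundary map)
#'
#' Class 1: EC < -1.5; class 2: -1.5 <= EC < -0.5; class 3: -0.5 <= EC < 0;
#' class 4: 0 <= EC < 1.5; class 5: EC >= 1.5 (the 1.5 boundary is assigned
#' upward). A total, monotone step function.
#'
#' @param ec numeric vector of environment levels.
#' @return integer vector in 1..5.
#' @export
assign_residual_class <- function(ec) {
  stopifnot(all(is.finite(ec)))
  findInterval(ec, c(-1.5, -0.5, 0, 1.5)) + 1L
}

#' K-means residual-class boundaries (generative alternative)
#'
#' One-dimensional k-means (many restarts under a fixed seed) on the EC
#' values; returns the k-1 sorted boundaries (midpoints between adjacent
#' cluster edges) that partition the gradient into k classes.
#'
#' @param ec numeric EC values; @param k number of classes; @param seed
#'   RNG seed; @param nstart restarts.
#' @return numeric vector of k-1 boundaries (empty for k = 1), with the
#'   cluster assignment in attribute `cluster`.
#' @export
kmeans_residual_classes <- function(ec, k = 5, seed = 1, nstart = 25) {
  if (length(unique(ec)) < k)
    stop("fewer distinct EC values (", length(unique(ec)),
         ") than classes (", k, ")")
  if (k == 1L) return(structure(numeric(0), cluster = rep(1L, length(ec))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(ec, centers = k, nstart = nstart)
  ord <- order(km$centers)
  relab <- match(km$cluster, ord)
  bounds <- vapply(seq_len(k - 1L), function(i) {
    (max(ec[relab == i]) + min(ec[relab == i + 1L])) / 2
  }, numeric(1))
  structure(bounds, cluster = relab)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write an EC descriptor table
#' @param ecd an `ec_descriptor`; @param path output TSV path.
#' @export
write_ec_descriptor <- function(ecd, path) {
  utils::write.table(as.data.frame(ecd), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
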