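#' Build a full-rank fixed-effect design matrix
#'
#' Full dummy coding for the first factor (no global intercept), drop-first
#' coding for subsequent factors, covariates appended as given. Columns
#' that are linearly dependent on earlier ones are dropped (sequential rank
#' check) and reported in the `dropped` attribute — this is how, e.g., a
#' fixed environmental regression that is deterministically linked to the
#' contemporary-group factor is made identifiable.
#'
#' @param data data frame of the records.
#' @param factors character vector of factor column names.
#' @param covariates character vector of numeric column names, or a named
#'   list of numeric matrices/vectors aligned with the records.
#' @return matrix with attribute `dropped` (names of removed columns).
#' @export
fixed_design <- function(data, factors = character(), covariates = list()) {
  n <- nrow(data)
  cols <- list(); nm <- character()
  for (k in seq_along(factors)) {
    f <- factor(data[[factors[k]]])
    lev <- levels(f)
    keep <- if (k == 1L) lev else lev[-1L]
    for (l in keep) {
      cols[[length(cols) + 1L]] <- as.numeric(f == l)
      nm <- c(nm, paste0(factors[k], ":", l))
    }
  }
  if (is.character(covariates))
    covariates <- stats::setNames(lapply(covariates, function(v) data[[v]]),
                                  covariates)
  for (cn in names(covariates)) {
    v <- covariates[[cn]]
    v <- as.matrix(v)
    for (j in seq_len(ncol(v))) {
      cols[[length(cols) + 1L]] <- v[, j]
      nm <- c(nm, if (ncol(v) == 1L) cn else paste0(cn, j - 1L))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  # sequential rank filter
  qr_acc <- NULL; keep <- logical(ncol(X))
  acc <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- cbind(acc, X[, j])
    if (qr(cand)$rank > (if (is.null(acc)) 0L else qr(acc)$rank)) {
      acc <- cand; keep[j] <- TRUE
    }
  }
  out <- X[, keep, drop = FALSE]
  attr(out, "dropped") <- nm[!keep]
  out
}

#' Mixed-model specification
#'
#' One fixed block X, one (optional) random regression block: each record
#' belongs to one animal and carries a q-vector of regression covariables
#' (`Phi`, e.g. the Legendre basis at the record's environment level).
#' Random coefficients u (animal-major, q per animal) have covariance
#' `rel` %x% K (relationship matrix times coefficient covariance K).
#' Residuals are independent with per-record class variances.
#'
#' @param y numeric response.
#' @param X full-rank fixed design ([fixed_design()]).
#' @param animal character id per record (must appear in the relationship
#'   matrix), or NULL for a fixed-effects-only model.
#' @param Phi n x q matrix of random-regression covariables (a column of
#'   ones for a plain animal model), or NULL.
#' @param K q x q coefficient covariance.
#' @param rel_inv inverse relationship matrix (A or H inverse) over the
#'   animal universe; @param rel the corresponding relationship matrix
#'   (needed by the dense REML path; computed by inversion when absent).
#' @param resid_class integer class (1-based) per record; default all 1.
#' @param resid_vars variance per residual class.
#' @return list of class `mme_spec`.
#' @export
mme_spec <- function(y, X, animal = NULL, Phi = NULL, K = NULL,
                     rel_inv = NULL, rel = NULL,
                     resid_class = NULL, resid_vars = 1) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X))
    stop("fixed design is rank deficient; use fixed_design() to drop ",
         "confounded columns")
  if (is.null(resid_class)) resid_class <- rep(1L, n)
  stopifnot(length(resid_class) == n,
            all(resid_class >= 1L), all(resid_class <= length(resid_vars)),
            all(resid_vars[sort(unique(resid_class))] > 0))
  if (!is.null(animal)) {
    stopifnot(!is.null(Phi), !is.null(K))
    Phi <- as.matrix(Phi)
    stopifnot(nrow(Phi) == n, ncol(Phi) == nrow(K))
    ids <- rownames(if (!is.null(rel_inv)) rel_inv else rel)
    if (is.null(ids)) stop("relationship matrix must carry animal ids")
    if (!all(animal %in% ids))
      stop("records refer to animals absent from the relationship matrix")
  }
  structure(list(y = y, X = X, animal = animal, Phi = Phi, K = K,
                 rel_inv = rel_inv, rel = rel,
                 resid_class = as.integer(resid_class),
                 resid_vars = resid_vars),
            class = "mme_spec")
}

spec_rel <- function(spec) {
  if (!is.null(spec$rel)) return(spec$rel)
  relmat(chol2inv(chol(unclass(spec$rel_inv))), rownames(spec$rel_inv), "rel")
}
spec_rel_inv <- function(spec) {
  if (!is.null(spec$rel_inv)) return(spec$rel_inv)
  relmat(chol2inv(chol(unclass(spec$rel))), rownames(spec$rel), "rel_inverse")
}

#' Solve Henderson's mixed-model equations
#'
#' Dense assembly and Cholesky solve of
#' \[X'R^-1X, X'R^-1Z; Z'R^-1X, Z'R^-1Z + rel_inv %x% K^-1\] s = rhs.
#' The random-effect cross-product blocks are assembled animal-wise (the
#' random design has one q-block per record), so no n x (q n_animal) dense
#' design is formed. Prediction-error-variance blocks come from the inverse
#' coefficient matrix.
#'
#' @param spec an [mme_spec()].
#' @param compute_pev invert the full coefficient matrix and return per-
#'   animal q x q PEV blocks (costs a full inverse; skip for variance-
#'   component iterations).
#' @param compute_logL also return the REML log-likelihood at the spec's
#'   variance parameters.
#' @param store_cinv keep the full inverse coefficient matrix (needed by
#'   EM-REML).
#' @return list of class `mme_solution`: `beta` (named BLUE), `u` (animal x
#'   q BLUP matrix over the full animal universe), `pev` (q x q x n_animal
#'   array or NULL), `logL`, `yPy`, plus bookkeeping.
#' @export
solve_mme <- function(spec, compute_pev = TRUE, compute_logL = TRUE,
                      store_cinv = FALSE) {
  y <- spec$y; X <- spec$X
  r <- 1 / spec$resid_vars[spec$resid_class]
  p <- ncol(X)
  XtRX <- crossprod(X, X * r)
  XtRy <- crossprod(X, y * r)
  if (is.null(spec$animal)) {
    bhat <- solve(XtRX, XtRy)
    e <- y - X %*% bhat
    out <- list(beta = stats::setNames(drop(bhat), colnames(X)), u = NULL,
                pev = NULL, logL = NA_real_, yPy = sum(e^2 * r),
                fitted = drop(X %*% bhat), spec = spec)
    class(out) <- "mme_solution"
    return(out)
  }
  Phi <- spec$Phi; q <- ncol(Phi)
  ids <- rownames(if (!is.null(spec$rel_inv)) spec$rel_inv else spec$rel)
  na <- length(ids)
  ai <- match(spec$animal, ids)
  nq <- na * q
  Kinv <- chol2inv(chol(spec$K))
  rel_inv <- unclass(spec_rel_inv(spec))
  C <- matrix(0, p + nq, p + nq)
  C[1:p, 1:p] <- XtRX
  # Z'R^-1Z (block diagonal over animals) and X'R^-1Z
  for (f in 1:q) for (g in 1:q) {
    v <- rowsum((Phi[, f] * Phi[, g] * r), ai)
    idx <- as.integer(rownames(v))
    C[cbind(p + (idx - 1L) * q + f, p + (idx - 1L) * q + g)] <-
      C[cbind(p + (idx - 1L) * q + f, p + (idx - 1L) * q + g)] + v[, 1L]
  }
  for (f in 1:q) {
    XZ <- rowsum(X * (Phi[, f] * r), ai)   # per-animal p-vectors
    idx <- as.integer(rownames(XZ))
    cols <- p + (idx - 1L) * q + f
    C[1:p, cols] <- t(XZ)
    C[cols, 1:p] <- XZ
  }
  C[(p + 1):(p + nq), (p + 1):(p + nq)] <-
    C[(p + 1):(p + nq), (p + 1):(p + nq)] + kronecker(rel_inv, Kinv)
  rhs <- numeric(p + nq)
  rhs[1:p] <- XtRy
  for (f in 1:q) {
    zy <- rowsum(Phi[, f] * r * y, ai)
    idx <- as.integer(rownames(zy))
    rhs[p + (idx - 1L) * q + f] <- zy[, 1L]
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("mixed-model equations not positive definite: ", conditionMessage(e)))
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  beta <- stats::setNames(sol[1:p], colnames(X))
  U <- matrix(sol[-(1:p)], na, q, byrow = TRUE, dimnames = list(ids, NULL))
  pev <- NULL; Cinv <- NULL
  if (compute_pev || store_cinv) {
    Cinv <- chol2inv(ch)
    pev <- array(0, c(q, q, na), dimnames = list(NULL, NULL, ids))
    for (f in 1:q) for (g in 1:q)
      pev[f, g, ] <- Cinv[cbind(p + (seq_len(na) - 1L) * q + f,
                                p + (seq_len(na) - 1L) * q + g)]
  }
  yPy <- sum(y^2 * r) - sum(sol * rhs)
  logL <- NA_real_
  if (compute_logL) {
    ldC <- 2 * sum(log(diag(ch)))
    ldR <- sum(log(spec$resid_vars[spec$resid_class]))
    ldrel <- -2 * sum(log(diag(chol(rel_inv))))
    ldK <- as.numeric(determinant(spec$K, logarithm = TRUE)$modulus)
    logL <- -0.5 * (ldR + q * ldrel + na * ldK + ldC + yPy)
  }
  fitted <- drop(X %*% beta) + rowSums(Phi * U[ai, , drop = FALSE])
  out <- list(beta = beta, u = U, pev = pev, logL = logL, yPy = yPy,
              fitted = fitted, Cinv = if (store_cinv) Cinv else NULL,
              record_animal_index = ai, spec = spec)
  class(out) <- "mme_solution"
  out
}

#' @export
print.mme_solution <- function(x, ...) {
  cat("mme_solution:", length(x$beta), "fixed effects",
      if (!is.null(x$u)) paste0(", ", nrow(x$u), " animals x ", ncol(x$u),
                                " random coefficients"), "\n")
  if (!is.na(x$logL)) cat("REML logL:", format(x$logL), "\n")
  invisible(x)
}

#' Per-coefficient BLUP accuracy from prediction error variance
#'
#' acc = sqrt(max(0, 1 - PEV_qq / K_qq)) per animal and coefficient. PEV
#' exceeding the prior variance by more than 1e-6 (relative) is clamped to
#' accuracy 0 with a warning.
#'
#' @param sol an `mme_solution` with PEV blocks.
#' @param K the coefficient covariance used in the fit.
#' @return matrix animals x q of accuracies in \[0, 1\].
#' @export
accuracy_from_pev <- function(sol, K = sol$spec$K) {
  if (is.null(sol$pev)) stop("solution carries no PEV blocks")
  q <- nrow(K)
  na <- dim(sol$pev)[3]
  acc <- matrix(NA_real_, na, q, dimnames = list(dimnames(sol$pev)[[3]], NULL))
  for (f in 1:q) {
    pevf <- sol$pev[f, f, ]
    over <- pevf > K[f, f] * (1 + 1e-6)
    if (any(over))
      warning(sum(over), " PEV value(s) exceed the prior variance; ",
              "accuracy clamped to 0")
    acc[, f] <- sqrt(pmax(0, 1 - pevf / K[f, f]))
  }
  acc
}

# --- REML ------------------------------------------------------------------

# index helper: symmetric K parameterized by lower-triangle entries
k_from_theta <- function(theta, q) {
  K <- matrix(0, q, q)
  K[lower.tri(K, diag = TRUE)] <- theta
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  K
}
theta_from_k <- function(K) K[lower.tri(K, diag = TRUE)]

floor_pd <- function(K, floor = 1e-8) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < floor) {
    K <- e$vectors %*% diag(pmax(e$values, floor), nrow(K)) %*% t(e$vectors)
    attr(K, "floored") <- TRUE
  }
  K
}

# dense-V machinery: V = rel[rec,rec] * (Phi K Phi') + R
dense_v_parts <- function(spec) {
  rel <- unclass(spec_rel(spec))
  ids <- rownames(rel)
  ai <- match(spec$animal, ids)
  list(Hrec = rel[ai, ai, drop = FALSE], Phi = spec$Phi,
       cls = spec$resid_class, y = spec$y, X = spec$X)
}

dense_v_logl <- function(parts, K, resid_vars) {
  V <- parts$Hrec * (parts$Phi %*% K %*% t(parts$Phi))
  diag(V) <- diag(V) + resid_vars[parts$cls]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% parts$X
  XtViX <- crossprod(parts$X, ViX)
  chx <- chol(XtViX)
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(ViX, parts$y)))
  Py <- Vi %*% parts$y - ViX %*% beta
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(parts$y * Py))
  list(logL = drop(logL), Vi = Vi, ViX = ViX, XtViX_chol = chx, Py = drop(Py))
}

#' REML estimation of the coefficient covariance and residual variances
#'
#' `method = "AI"` (default) runs average-information REML on the dense
#' phenotypic covariance V = H_rec * (Phi K Phi') + R, with step halving
#' whenever an update would reduce the restricted likelihood and
#' eigenvalue flooring (1e-8) to keep K positive definite. `method = "EM"`
#' runs expectation-maximization updates through the mixed-model equations
#' (guaranteed ascent, slower; intended for small problems and as a
#' cross-check). Convergence is declared when the largest relative
#' parameter change falls below `tol`.
#'
#' @param spec an [mme_spec()] with a random block.
#' @param method "AI" or "EM".
#' @param tol relative-change convergence criterion.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   last iterate flagged `converged = FALSE`.
#' @param final_solve also return [solve_mme()] at the estimates (with
#'   PEV).
#' @param verbose print the likelihood path.
#' @return list: `K`, `resid_vars`, `logL`, `iterations`, `converged`,
#'   `solution` (when `final_solve`), `history` (parameter path).
#' @export
reml_estimate <- function(spec, method = c("AI", "EM"), tol = 1e-8,
                          max_iter = 200, final_solve = TRUE,
                          verbose = FALSE) {
  method <- match.arg(method)
  q <- ncol(spec$Phi)
  cls_present <- sort(unique(spec$resid_class))
  K <- spec$K
  rv <- spec$resid_vars
  var_floor <- 1e-8 * stats::var(spec$y)
  est <- if (method == "AI")
    reml_ai(spec, K, rv, cls_present, tol, max_iter, var_floor, verbose)
  else
    reml_em(spec, K, rv, cls_present, tol, max_iter, var_floor, verbose)
  if (!est$converged)
    warning("REML (", method, ") did not converge in ", max_iter,
            " iterations; returning last iterate")
  out <- est
  if (final_solve) {
    spec2 <- spec; spec2$K <- est$K; spec2$resid_vars <- est$resid_vars
    out$solution <- solve_mme(spec2, compute_pev = TRUE)
  }
  out
}

reml_ai <- function(spec, K, rv, cls_present, tol, max_iter, var_floor,
                    verbose) {
  parts <- dense_v_parts(spec)
  q <- ncol(parts$Phi)
  nK <- q * (q + 1) / 2
  theta <- c(theta_from_k(K), rv[cls_present])
  fit <- dense_v_logl(parts, K, rv)
  history <- data.frame(iter = 0L, logL = fit$logL)
  converged <- FALSE
  # lower-triangle index pairs matching theta_from_k ordering
  lt <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  for (it in seq_len(max_iter)) {
    # projection matrix P, dense (needed for the trace terms)
    Pm <- fit$Vi - fit$ViX %*% chol2inv(fit$XtViX_chol) %*% t(fit$ViX)
    npar <- nK + length(cls_present)
    score <- numeric(npar)
    W <- matrix(0, length(parts$y), npar)
    for (k in seq_len(nK)) {
      f <- lt[k, 1]; g <- lt[k, 2]
      Q <- tcrossprod(parts$Phi[, f], parts$Phi[, g])
      if (f != g) Q <- Q + t(Q)
      dV <- parts$Hrec * Q
      score[k] <- -0.5 * (sum(Pm * dV) - sum(fit$Py * (dV %*% fit$Py)))
      W[, k] <- dV %*% fit$Py
    }
    for (j in seq_along(cls_present)) {
      sel <- parts$cls == cls_present[j]
      score[nK + j] <- -0.5 * (sum(diag(Pm)[sel]) - sum(fit$Py[sel]^2))
      W[sel, nK + j] <- fit$Py[sel]
    }
    AI <- 0.5 * crossprod(W, Pm %*% W)
    step <- tryCatch(solve(AI, score), error = function(e) score / diag(AI))
    lam <- 1
    repeat {
      theta_new <- theta + lam * step
      K_new <- floor_pd(k_from_theta(theta_new[seq_len(nK)], q))
      rv_new <- rv
      rv_new[cls_present] <- pmax(theta_new[nK + seq_along(cls_present)],
                                  var_floor)
      fit_new <- tryCatch(dense_v_logl(parts, K_new, rv_new),
                          error = function(e) NULL)
      if (!is.null(fit_new) && fit_new$logL >= fit$logL - 1e-10) break
      lam <- lam / 2
      if (lam < 1e-4) { fit_new <- fit; K_new <- k_from_theta(theta[seq_len(nK)], q)
        rv_new <- rv; break }
    }
    theta_new <- c(theta_from_k(K_new), rv_new[cls_present])
    rel_change <- max(abs(theta_new - theta) /
                        pmax(abs(theta), sqrt(var_floor)))
    theta <- theta_new; K <- K_new; rv <- rv_new; fit <- fit_new
    history <- rbind(history, data.frame(iter = it, logL = fit$logL))
    if (verbose) message(sprintf("AI iter %d logL %.6f", it, fit$logL))
    if (rel_change < tol) { converged <- TRUE; break }
  }
  list(K = k_from_theta(theta[seq_len(q * (q + 1) / 2)], q),
       resid_vars = rv, logL = fit$logL, iterations = nrow(history) - 1L,
       converged = converged, history = history, method = "AI")
}

reml_em <- function(spec, K, rv, cls_present, tol, max_iter, var_floor,
                    verbose) {
  q <- ncol(spec$Phi)
  ids <- rownames(if (!is.null(spec$rel_inv)) spec$rel_inv else spec$rel)
  na <- length(ids)
  rel_inv <- unclass(spec_rel_inv(spec))
  history <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    spec2 <- spec; spec2$K <- K; spec2$resid_vars <- rv
    sol <- solve_mme(spec2, compute_pev = TRUE, compute_logL = TRUE,
                     store_cinv = TRUE)
    history <- rbind(history, data.frame(iter = it, logL = sol$logL))
    if (verbose) message(sprintf("EM iter %d logL %.6f", it, sol$logL))
    p <- ncol(spec$X)
    Cinv <- sol$Cinv
    # K update: (U' Ainv U + sum_ij Ainv_ij Cuu_ij) / n_animals
    U <- sol$u
    T2 <- matrix(0, q, q)
    for (f in 1:q) for (g in 1:q) {
      Cuu_fg <- Cinv[p + (seq_len(na) - 1L) * q + f,
                     p + (seq_len(na) - 1L) * q + g, drop = FALSE]
      T2[f, g] <- sum(rel_inv * Cuu_fg)
    }
    K_new <- (crossprod(U, rel_inv %*% U) + T2) / na
    K_new <- floor_pd((K_new + t(K_new)) / 2)
    # residual updates per class
    e <- spec$y - sol$fitted
    rv_new <- rv
    Wrows <- cbind(spec$X, matrix(0, length(spec$y), na * q))
    ai <- sol$record_animal_index
    for (i in seq_along(spec$y))
      Wrows[i, p + (ai[i] - 1L) * q + seq_len(q)] <- spec$Phi[i, ]
    WC <- Wrows %*% Cinv
    wcw <- rowSums(WC * Wrows)
    for (j in cls_present) {
      sel <- spec$resid_class == j
      rv_new[j] <- max((sum(e[sel]^2) + sum(wcw[sel])) / sum(sel), var_floor)
    }
    rel_change <- max(abs(c(theta_from_k(K_new) - theta_from_k(K),
                            rv_new[cls_present] - rv[cls_present])) /
                        pmax(abs(c(theta_from_k(K), rv[cls_present])),
                             sqrt(var_floor)))
    K <- K_new; rv <- rv_new
    if (rel_change < tol) { converged <- TRUE; break }
  }
  spec2 <- spec; spec2$K <- K; spec2$resid_vars <- rv
  final <- solve_mme(spec2, compute_pev = FALSE, compute_logL = TRUE)
  list(K = K, resid_vars = rv, logL = final$logL,
       iterations = nrow(history), converged = converged,
       history = history, method = "EM")
}
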