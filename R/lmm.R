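#' Single-random-effect linear mixed model by REML
#'
#' Fits `y = X b + Z u + e` with `u ~ N(0, K sigma_a2)` and
#' `e ~ N(0, I sigma_e2)` for an arbitrary symmetric PSD relatedness matrix
#' `K` (a pedigree numerator relationship matrix or a genomic relationship
#' matrix). The variance ratio `lambda = sigma_a2 / sigma_e2` is profiled on
#' the eigendecomposition of `Z K Z'`, so each likelihood evaluation is
#' closed-form; the ratio is optimized by Brent search on the log scale.
#' Fixed effects are estimated by GLS at the optimum, random effects by
#' BLUP. The ML log-likelihood (ratio re-optimized under ML) is also
#' returned for AIC comparisons across fixed-effect structures.
#'
#' @param y numeric response vector
#' @param X fixed-effects design matrix (an intercept column should be
#'   included by the caller); rank-deficient columns are dropped
#' @param K relatedness matrix among the random-effect levels
#' @param Z incidence matrix mapping records to random-effect levels
#'   (default identity)
#' @param ratio_interval search interval for `log(lambda)`
#' @param tol convergence tolerance on `log(lambda)`
#' @return object of class `lmm_fit`: list with `beta` (table of estimates,
#'   SEs, t and p), `sigma_a2`, `sigma_e2`, `h2`, `blup`, `residuals`
#'   (`y - X beta - Z u`), `logL_reml`, `logL_ml`, `aic`, `boundary`, `n`,
#'   `p`, and `kept_columns`
#' @export
fit_lmm <- function(y, X, K, Z = NULL,
                    ratio_interval = c(-20, 20), tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("K must be symmetric")
  }
  if (is.null(Z)) {
    stopifnot(nrow(K) == n)
    ZKZ <- K
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n, ncol(Z) == nrow(K))
    ZKZ <- Z %*% K %*% t(Z)
  }
  # full-rank fixed-effects design
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  if (qrX$rank < ncol(X)) X <- X[, sort(keep), drop = FALSE]
  p <- ncol(X)
  if (n < p + 2) stop("too few records for the fixed-effects design")

  eg <- eigen(ZKZ, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d), 1)) stop("K (via ZKZ') is not PSD")
  d <- pmax(d, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  prof <- function(log_lambda, restricted) {
    lam <- exp(log_lambda)
    w <- 1 / (1 + lam * d)
    sw <- sqrt(w)
    Xw <- Xs * sw
    yw <- ys * sw
    XtX <- crossprod(Xw)
    beta <- solve(XtX, crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% beta)^2)
    ldV <- sum(log1p(lam * d))
    if (restricted) {
      s2 <- rss / (n - p)
      # log|V| + log|X'V^-1 X| = (n-p) log s2 + ldV + log|Xw'Xw|
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + ldV +
                      determinant(XtX, logarithm = TRUE)$modulus + (n - p))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + ldV + n)
    }
    list(ll = as.numeric(ll), beta = beta, s2 = s2, w = w, XtX = XtX)
  }

  opt_r <- stats::optimize(function(l) -prof(l, TRUE)$ll,
                           interval = ratio_interval, tol = tol)
  boundary <- exp(opt_r$minimum) < 1e-8   # variance ratio effectively zero
  log_lam <- if (boundary) -Inf else opt_r$minimum
  at <- prof(if (boundary) ratio_interval[1] - 30 else log_lam, TRUE)
  lam <- if (boundary) 0 else exp(log_lam)
  sigma_e2 <- at$s2
  sigma_a2 <- lam * sigma_e2

  opt_m <- stats::optimize(function(l) -prof(l, FALSE)$ll,
                           interval = ratio_interval, tol = tol)
  logL_ml <- max(-opt_m$objective, prof(ratio_interval[1] - 30, FALSE)$ll)

  beta <- drop(at$beta)
  se <- sqrt(diag(solve(at$XtX)) * sigma_e2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  beta_tab <- data.frame(term = colnames(X), estimate = beta, se = se,
                         t = tval, p = pval, row.names = NULL,
                         stringsAsFactors = FALSE)

  r_fix <- y - X %*% at$beta
  Vinv_r <- U %*% (crossprod(U, r_fix) * at$w / sigma_e2)
  blup <- if (is.null(Z)) {
    sigma_a2 * (K %*% Vinv_r)
  } else {
    sigma_a2 * (K %*% crossprod(Z, Vinv_r))
  }
  fitted_u <- if (is.null(Z)) blup else Z %*% blup
  resid <- drop(r_fix - fitted_u)

  fit <- structure(list(beta = beta_tab, sigma_a2 = sigma_a2,
                        sigma_e2 = sigma_e2,
                        h2 = sigma_a2 / (sigma_a2 + sigma_e2),
                        blup = drop(blup), residuals = resid,
                        logL_reml = at$ll, logL_ml = logL_ml,
                        boundary = boundary, n = n, p = p,
                        kept_columns = colnames(X)),
                   class = "lmm_fit")
  fit$aic <- model_aic(fit)
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: n=%d, p=%d, sigma_a2=%.4g, sigma_e2=%.4g, h2=%.3f%s\n",
              x$n, x$p, x$sigma_a2, x$sigma_e2, x$h2,
              if (x$boundary) " (boundary: sigma_a2 at 0)" else ""))
  cat(sprintf("  logL(REML)=%.4f, logL(ML)=%.4f, AIC=%.2f\n",
              x$logL_reml, x$logL_ml, x$aic))
  invisible(x)
}

#' Restricted (or marginal) log-likelihood at fixed variance components
#'
#' Evaluates the REML (Patterson-Thompson, without the constant |X'X| term)
#' or ML log-likelihood of the single-random-effect model at supplied
#' `sigma_a2`, `sigma_e2`, with the fixed effects profiled out by GLS.
#'
#' @inheritParams fit_lmm
#' @param sigma_a2,sigma_e2 variance components (sigma_e2 > 0)
#' @param restricted REML (default) or ML likelihood
#' @return log-likelihood value
#' @export
lmm_loglik <- function(y, X, K, sigma_a2, sigma_e2, Z = NULL,
                       restricted = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  ZKZ <- if (is.null(Z)) K else Z %*% K %*% t(Z)
  V <- sigma_a2 * ZKZ + diag(sigma_e2, n)
  cV <- chol(V)
  ldV <- 2 * sum(log(diag(cV)))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  quad <- sum(r * Vi_r)
  if (restricted) {
    as.numeric(-0.5 * ((n - p) * log(2 * pi) + ldV +
                         determinant(XtViX, logarithm = TRUE)$modulus + quad))
  } else {
    as.numeric(-0.5 * (n * log(2 * pi) + ldV + quad))
  }
}

#' Akaike information criterion of a mixed-model fit
#'
#' `AIC = -2 logL_ML + 2 (n_fixed + n_varcomp)`. The ML (not REML)
#' likelihood is used because models compared here differ in their
#' fixed-effect structures, for which REML likelihoods are not comparable.
#'
#' @param fit an [fit_lmm()] result
#' @return the AIC value
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  -2 * fit$logL_ml + 2 * (fit$p + 2)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the OLS regression of
#' covariate j on the remaining covariates (plus an intercept). Perfectly
#' collinear covariates are flagged as `Inf`.
#'
#' @param Xc numeric matrix of covariates (at least two columns, each
#'   non-constant)
#' @return named numeric vector of VIFs
#' @export
vif <- function(Xc) {
  Xc <- as.matrix(Xc)
  stopifnot(ncol(Xc) >= 2)
  if (any(apply(Xc, 2, stats::sd) == 0)) stop("constant covariate")
  if (is.null(colnames(Xc))) colnames(Xc) <- paste0("x", seq_len(ncol(Xc)))
  out <- vapply(seq_len(ncol(Xc)), function(j) {
    fit <- stats::lm.fit(cbind(1, Xc[, -j, drop = FALSE]), Xc[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((Xc[, j] - mean(Xc[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(Xc))
}

# factor columns of the trait association / adjustment models
.model_factors <- c("dam_parity", "birth_herd", "twin", "rec_class",
                    "contemporary_group")

#' Build a fixed-effects design matrix from a phenotype table
#'
#' Intercept plus treatment-coded dummies for the supplied factors; factor
#' levels observed fewer than twice are merged into the reference level with
#' a warning. Genetic-group fractions (columns of Q, first group dropped as
#' the reference) and numeric covariates can be appended.
#'
#' @param ph phenotype data.frame
#' @param factors factor column names to include
#' @param Q optional genetic-group incidence matrix (rows aligned with `ph`)
#' @param covariates optional numeric matrix/data.frame of covariates
#' @return numeric design matrix with an `(Intercept)` column
#' @export
build_design <- function(ph, factors = .model_factors, Q = NULL,
                         covariates = NULL) {
  factors <- intersect(factors, names(ph))
  df <- data.frame(row.names = seq_len(nrow(ph)))
  for (f in factors) {
    v <- factor(ph[[f]])
    small <- names(which(table(v) < 2))
    if (length(small) && nlevels(v) > 1) {
      warning("merging sparse level(s) of ", f, " into the reference: ",
              paste(small, collapse = ", "))
      ref <- setdiff(levels(v), small)[1]
      v <- factor(ifelse(as.character(v) %in% small, ref, as.character(v)))
    }
    if (nlevels(v) > 1) df[[f]] <- v
  }
  X <- if (ncol(df)) {
    stats::model.matrix(~., data = df)
  } else {
    matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(Q) && ncol(Q) > 1) {
    Qx <- Q[, -1, drop = FALSE]
    colnames(Qx) <- paste0("group_", colnames(Qx))
    X <- cbind(X, Qx)
  }
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates))
  }
  X
}

#' Association between heterozygosity measures and a trait
#'
#' Fits the trait-association mixed model: trait on dam parity, birth herd
#' type, twin status, recombination-loss class and contemporary group as
#' fixed effects, the requested heterosis/heterozygosity covariates, and a
#' random polygenic effect with covariance `A sigma_a2` whose expectation is
#' shifted by breed genetic groups (Q entering as fixed covariates). OH and
#' HL may not be requested together: they are near-duplicates of one
#' another and violate the multicollinearity assumption.
#'
#' @param ph phenotype data.frame with `animal_id`, `trait_value` and the
#'   factor columns (`dam_parity`, `birth_herd`, `twin`, `rec_class`,
#'   `contemporary_group`)
#' @param measures data.frame with `animal_id` and measure columns (e.g.
#'   `heterosis`, `oh`, `hl`, `rohet_count`)
#' @param covariates character vector of measure columns to include
#' @param pedmodel a [build_nrm_with_groups()] result covering all animals
#' @param sds optional named per-measure SDs; when given, SD-scaled
#'   coefficients (`estimate * sd`) are reported alongside the raw ones
#' @return list with `coefficients` (one row per requested covariate:
#'   estimate, se, t, p, and `estimate_per_sd` when `sds` given), `vif`
#'   (NULL for a single covariate) and `fit` (the full [fit_lmm()] object)
#' @export
het_association <- function(ph, measures, covariates, pedmodel, sds = NULL) {
  stopifnot(inherits(pedmodel, "ped_model"), length(covariates) >= 1,
            all(covariates %in% names(measures)))
  if (all(c("oh", "hl") %in% covariates)) {
    stop("OH and HL may not be included together: multicollinearity")
  }
  i <- match(ph$animal_id, measures$animal_id)
  if (anyNA(i)) stop("measures missing for some phenotyped animals")
  C <- as.matrix(measures[i, covariates, drop = FALSE])
  if (any(apply(C, 2, stats::sd) == 0)) stop("zero-variance covariate")
  k <- match(ph$animal_id, pedmodel$animal_ids)
  if (anyNA(k)) stop("phenotyped animal(s) absent from the pedigree model")
  A <- pedmodel$A[k, k, drop = FALSE]
  Q <- pedmodel$Q[k, , drop = FALSE]
  X <- build_design(ph, Q = Q, covariates = C)
  fit <- fit_lmm(ph$trait_value, X, A)
  coefs <- fit$beta[match(covariates, fit$beta$term), , drop = FALSE]
  if (!is.null(sds)) {
    coefs$estimate_per_sd <- coefs$estimate * sds[coefs$term]
  }
  v <- if (length(covariates) >= 2) vif(C) else NULL
  list(coefficients = coefs, vif = v, fit = fit)
}
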