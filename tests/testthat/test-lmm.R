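# small random mixed-model instance with K from markers
lmm_instance <- function(n = 30, p = 2, h2 = 0.4, m = 80) {
  D <- sapply(runif(m, 0.1, 0.9), function(pp) rbinom(n, 2, pp))
  dimnames(D) <- list(sprintf("an%02d", 1:n), NULL)
  map <- data.frame(snp_id = paste0("s", 1:m), chrom = "1",
                    pos_bp = 1:m * 1000, allele_a = "A", allele_b = "B")
  G <- build_grm_method1(geno_matrix(D, map))$G
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  L <- t(chol(G + diag(1e-6, n)))
  u <- sqrt(h2) * as.numeric(L %*% rnorm(n))
  y <- as.numeric(X %*% rnorm(p)) + u + rnorm(n, 0, sqrt(1 - h2))
  list(y = y, X = X, K = G)
}

test_that("with the ratio forced to zero GLS degenerates to OLS", {
  set.seed(51)
  inst <- lmm_instance()
  fit <- fit_lmm(inst$y, inst$X, inst$K, ratio_interval = c(-30, -29.9))
  ols <- lm.fit(inst$X, inst$y)
  expect_equal(unname(fit$beta$estimate), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_true(fit$boundary)
  expect_equal(fit$sigma_a2, 0, tolerance = 1e-10)
})

test_that("REML log-likelihood matches the dense direct formula", {
  set.seed(53)
  for (rep in 1:5) {
    inst <- lmm_instance(n = 20)
    fit <- fit_lmm(inst$y, inst$X, inst$K)
    ll <- oracle_reml_loglik(inst$y, inst$X, inst$K, fit$sigma_a2,
                             fit$sigma_e2)
    expect_equal(fit$logL_reml, ll, tolerance = 1e-8)
    # and at arbitrary (non-optimal) parameter values via lmm_loglik
    expect_equal(lmm_loglik(inst$y, inst$X, inst$K, 0.3, 0.9),
                 oracle_reml_loglik(inst$y, inst$X, inst$K, 0.3, 0.9),
                 tolerance = 1e-8)
  }
})

test_that("the REML optimum dominates random ratio points", {
  set.seed(57)
  inst <- lmm_instance(n = 40)
  fit <- fit_lmm(inst$y, inst$X, inst$K)
  for (lr in runif(20, -6, 6)) {
    lam <- exp(lr)
    # profile sigma_e2 at this ratio via the dense formula
    prof <- optimize(function(s2) {
      -oracle_reml_loglik(inst$y, inst$X, inst$K, lam * s2, s2)
    }, interval = c(1e-4, 10))
    expect_gte(fit$logL_reml + 1e-6, -prof$objective)
  }
})

test_that("fits are invariant to row permutation", {
  set.seed(59)
  inst <- lmm_instance(n = 25)
  fit <- fit_lmm(inst$y, inst$X, inst$K)
  perm <- sample(25)
  fit2 <- fit_lmm(inst$y[perm], inst$X[perm, ], inst$K[perm, perm])
  expect_equal(fit2$beta$estimate, fit$beta$estimate, tolerance = 1e-6)
  expect_equal(fit2$sigma_a2, fit$sigma_a2, tolerance = 1e-6)
  expect_equal(fit2$logL_reml, fit$logL_reml, tolerance = 1e-6)
  expect_equal(fit2$residuals[order(perm)], fit$residuals, tolerance = 1e-6)
})

test_that("residuals are GLS-orthogonal to the fixed-effects columns", {
  set.seed(61)
  inst <- lmm_instance(n = 35, p = 3)
  fit <- fit_lmm(inst$y, inst$X, inst$K)
  V <- fit$sigma_a2 * inst$K + diag(fit$sigma_e2, 35)
  # e = y - Xb - u; X' V^-1 (y - Xb) = 0 at the GLS solution, and
  # u = sa2 K V^-1 (y - Xb), so X' V^-1 e scaled by se2/V structure:
  r_fix <- inst$y - inst$X %*% fit$beta$estimate
  expect_lt(max(abs(t(inst$X) %*% solve(V, r_fix))), 1e-6)
})

test_that("variance inflation factors match the closed form", {
  set.seed(63)
  X <- matrix(rnorm(200), 100, 2)
  X <- qr.Q(qr(cbind(1, X)))[, 2:3] * 10  # orthogonal, centered
  v <- vif(X)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  # correlation 0.9 -> VIF = 1/(1-0.81)
  S <- chol(matrix(c(1, .9, .9, 1), 2))
  Y <- matrix(rnorm(4000), 2000) %*% S
  r <- cor(Y)[1, 2]
  expect_equal(unname(vif(Y)), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  dup <- cbind(a = rnorm(50), b = 0)
  dup[, "b"] <- dup[, "a"]
  expect_true(all(is.infinite(vif(dup))))
})

test_that("AIC: deterministic on refit, penalizes pure-noise covariates", {
  set.seed(67)
  inst <- lmm_instance(n = 60)
  f1 <- fit_lmm(inst$y, inst$X, inst$K)
  f2 <- fit_lmm(inst$y, inst$X, inst$K)
  expect_identical(model_aic(f1), model_aic(f2))
  worse <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    inst <- lmm_instance(n = 60)
    base <- fit_lmm(inst$y, inst$X, inst$K)
    noisy <- fit_lmm(inst$y, cbind(inst$X, noise = rnorm(60)), inst$K)
    worse <- worse + (model_aic(noisy) > model_aic(base))
  }
  expect_gte(worse / reps, 0.7)
})

test_that("heterozygosity-association model recovers a planted OH effect", {
  set.seed(71)
  hits <- 0
  reps <- 15
  for (r in seq_len(reps)) {
    sc <- sim_crossbred(seed = 7000 + r, n_per_breed = 8, n_purebred = 16,
                        n_f1 = 16, n_f2 = 16, n_backcross = 16,
                        n_threeway = 16)
    gg <- as_geno_matrix(sc$pop, animals = sc$cohort)
    oh <- observed_heterozygosity(gg)
    arch <- trait_architecture(h2_poly = 0.25, sigma_e = 1)
    sim <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort,
                               seed = 7100 + r)
    ph <- sim$pheno
    c_true <- 8
    ph$trait_value <- ph$trait_value + c_true * oh[ph$animal_id]
    founders <- sc$pop$pedigree$animal_id[is.na(sc$pop$pedigree$sire_id)]
    pm <- build_nrm_with_groups(sc$pop$pedigree,
                                sc$pop$comp[founders, , drop = FALSE])
    meas <- data.frame(animal_id = names(oh), oh = as.numeric(oh))
    res <- het_association(ph, meas, "oh", pm)
    est <- res$coefficients$estimate
    se <- res$coefficients$se
    hits <- hits + (abs(est - c_true) <= 2 * se)
  }
  expect_gte(hits / reps, 0.75)
})

test_that("association interface guards: order invariance, collinearity", {
  set.seed(73)
  sc <- sim_crossbred(seed = 99, n_per_breed = 6, n_purebred = 12, n_f1 = 12,
                      n_f2 = 12, n_backcross = 12, n_threeway = 12)
  gg <- as_geno_matrix(sc$pop, animals = sc$cohort)
  st <- locus_stats(gg)
  meas <- data.frame(animal_id = sc$cohort,
                     oh = as.numeric(observed_heterozygosity(gg)),
                     hl = as.numeric(homozygosity_by_locus(gg, st)),
                     heterosis = sc$coefficients$heterosis[
                       match(sc$cohort, sc$coefficients$animal_id)],
                     flat = 1)
  arch <- trait_architecture(h2_poly = 0.25, sigma_e = 1)
  ph <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort, seed = 5)$pheno
  founders <- sc$pop$pedigree$animal_id[is.na(sc$pop$pedigree$sire_id)]
  pm <- build_nrm_with_groups(sc$pop$pedigree,
                              sc$pop$comp[founders, , drop = FALSE])
  r1 <- het_association(ph, meas, c("heterosis", "oh"), pm)
  r2 <- het_association(ph, meas, c("oh", "heterosis"), pm)
  expect_equal(r1$coefficients[order(r1$coefficients$term), "estimate"],
               r2$coefficients[order(r2$coefficients$term), "estimate"],
               tolerance = 1e-6)
  expect_error(het_association(ph, meas, c("oh", "hl"), pm),
               "multicollinearity")
  expect_error(het_association(ph, meas, "flat", pm), "zero-variance")
  # SD-scaled coefficients are estimate * sd
  sds <- c(oh = sd(meas$oh), heterosis = sd(meas$heterosis))
  r3 <- het_association(ph, meas, c("heterosis", "oh"), pm, sds = sds)
  expect_equal(r3$coefficients$estimate_per_sd,
               r3$coefficients$estimate * sds[r3$coefficients$term],
               ignore_attr = TRUE)
})
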