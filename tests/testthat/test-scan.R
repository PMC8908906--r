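test_that("hand-worked locus: response equal to the dominance column", {
  D <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1,
              dimnames = list(paste0("a", 1:6), NULL))
  g <- geno_matrix(D, data.frame(snp_id = "s1", chrom = "1", pos_bp = 100,
                                 allele_a = "A", allele_b = "B"))
  e <- setNames(c(0, 0, 1, 1, 0, 0), paste0("a", 1:6))
  row <- scan_locus(e, g, "s1")
  expect_equal(row$b1, 0)
  expect_equal(row$b2, 1)
})

test_that("residuals linear in dosage give b2 = 0 and b1 = slope", {
  D <- matrix(rep(c(0L, 1L, 2L), each = 4), ncol = 1,
              dimnames = list(paste0("a", 1:12), NULL))
  g <- geno_matrix(D, data.frame(snp_id = "s1", chrom = "1", pos_bp = 1,
                                 allele_a = "A", allele_b = "B"))
  e <- setNames(3.5 * as.numeric(D), rownames(D))
  row <- scan_locus(e, g, "s1")
  expect_equal(row$b1, 3.5, tolerance = 1e-12)
  expect_equal(row$b2, 0, tolerance = 1e-12)
})

test_that("scan matches the lm() normal-equations oracle, incl. edge classes", {
  set.seed(81)
  n <- 60
  ids <- sprintf("an%02d", 1:n)
  e <- setNames(rnorm(n), ids)
  # polymorphic, missing-ridden, two-class and monomorphic loci
  cols <- cbind(rbinom(n, 2, 0.5),
                ifelse(runif(n) < 0.2, NA, rbinom(n, 2, 0.3)),
                sample(c(0L, 1L), n, replace = TRUE),
                sample(c(0L, 2L), n, replace = TRUE),
                rep(1L, n),
                rep(0L, n))
  map <- data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                    pos_bp = 1:6 * 100, allele_a = "A", allele_b = "B")
  g <- geno_matrix(matrix(as.integer(cols), n, 6, dimnames = list(ids, NULL)),
                   map)
  res <- run_scan(e, g, fdr_threshold = NULL)$table
  for (j in 1:6) {
    want <- oracle_scan_locus(e, g$dosage[, j])
    got <- res[j, c("b1", "se1", "p_add", "b2", "se2", "p_dom")]
    expect_equal(unname(unlist(got)), as.numeric(unname(want)),
                 tolerance = 1e-10, label = paste("locus", j))
  }
  # monomorphic loci are fully NA
  expect_true(all(is.na(res[5:6, c("b1", "b2")])))
})

test_that("allele relabeling flips b1's sign and preserves b2 and p-values", {
  set.seed(83)
  n <- 50
  ids <- sprintf("an%02d", 1:n)
  e <- setNames(rnorm(n), ids)
  d <- rbinom(n, 2, 0.4)
  mk <- function(dd) {
    geno_matrix(matrix(as.integer(dd), ncol = 1, dimnames = list(ids, NULL)),
                data.frame(snp_id = "s1", chrom = "1", pos_bp = 1,
                           allele_a = "A", allele_b = "B"))
  }
  r1 <- scan_locus(e, mk(d), "s1")
  r2 <- scan_locus(e, mk(2L - d), "s1")
  expect_equal(r2$b1, -r1$b1, tolerance = 1e-12)
  expect_equal(r2$b2, r1$b2, tolerance = 1e-12)
  expect_equal(r2$p_add, r1$p_add, tolerance = 1e-12)
  expect_equal(r2$p_dom, r1$p_dom, tolerance = 1e-12)
})

test_that("scan results do not depend on SNP processing order", {
  set.seed(85)
  g <- random_geno(40, 30, miss = 0.05)
  e <- setNames(rnorm(40), rownames(g$dosage))
  full <- run_scan(e, g, fdr_threshold = NULL)$table
  shuf <- sample(g$map$snp_id)
  part <- run_scan(e, g, fdr_threshold = NULL, snps = shuf)$table
  expect_equal(part[match(full$snp_id, part$snp_id), "b1"], full$b1)
})

test_that("genomic inflation factor: reference, scale equivariance", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1)
  set.seed(87)
  chi <- rchisq(1000, 1)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2 * genomic_lambda(p1), tolerance = 1e-10)
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  set.seed(89)
  for (rep in 1:10) {
    p <- c(runif(150), runif(50)^3)
    q <- qvalues(p, pi0 = 1)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_equal(qvalues(0.01, pi0 = 1), 0.01)
  q1 <- qvalues(0.01)
  expect_lte(q1, 0.01)
  ps <- sort(runif(300))
  expect_true(all(diff(qvalues(ps)) >= -1e-15))
  expect_error(qvalues(numeric(0)), "empty")
})

test_that("pi0 estimate calibrates between null and signal mixtures", {
  set.seed(91)
  p_null <- runif(5000)
  q_null <- qvalues(p_null)
  # under the null pi0 ~ 1, so q ~ BH
  expect_gt(min(q_null), 0.2)
  p_mix <- c(rbeta(2500, 0.2, 8), runif(2500))
  q_mix <- qvalues(p_mix)
  expect_lt(sum(q_mix <= 0.05) / 5000, 0.6)
  expect_gt(sum(q_mix <= 0.05), 100)
})

test_that("phenotype adjustment returns GLS residuals that match an oracle", {
  set.seed(93)
  sc <- sim_crossbred(seed = 17, n_per_breed = 6, n_purebred = 10, n_f1 = 10,
                      n_f2 = 10, n_backcross = 0, n_threeway = 0)
  gg <- as_geno_matrix(sc$pop, animals = sc$cohort)
  grm <- build_grm_method1(gg)
  arch <- trait_architecture(h2_poly = 0.3, sigma_e = 1)
  ph <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort, seed = 9)$pheno
  adj <- adjust_phenotypes(ph, grm)
  fit <- adj$fit
  n <- length(sc$cohort)
  X <- build_design(ph, factors = c("dam_parity", "birth_herd", "twin",
                                    "contemporary_group"))
  X <- X[, fit$kept_columns, drop = FALSE]
  V <- fit$sigma_a2 * grm$G + diag(fit$sigma_e2, n)
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, ph$trait_value))
  r_fix <- ph$trait_value - X %*% beta
  u <- fit$sigma_a2 * grm$G %*% solve(V, r_fix)
  expect_equal(unname(adj$residuals), as.numeric(r_fix - u), tolerance = 1e-8)
})

test_that("zero-noise, fixed-effects-only phenotypes adjust to zero residuals", {
  set.seed(95)
  sc <- sim_crossbred(seed = 23, n_per_breed = 6, n_purebred = 12, n_f1 = 12,
                      n_f2 = 12, n_backcross = 12, n_threeway = 12)
  gg <- as_geno_matrix(sc$pop, animals = sc$cohort)
  grm <- build_grm_method1(gg)
  arch <- trait_architecture(h2_poly = 0, sigma_e = 0, breed_mean_sd = 0)
  ph <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort, seed = 3)$pheno
  adj <- adjust_phenotypes(ph, grm)
  expect_lt(max(abs(adj$residuals)), 1e-6)
})
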