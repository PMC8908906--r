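small_bm <- function(seed = 1, ...) {
  breed_model(breeds = c("A", "B", "C", "D"), n_chrom = 2,
              snps_per_chrom = 150, seed = seed, ...)
}

test_that("founder simulation is a pure function of the seed", {
  bm <- small_bm()
  p1 <- simulate_founders(bm, 3, seed = 42)
  p2 <- simulate_founders(bm, 3, seed = 42)
  expect_identical(p1$hap1, p2$hap1)
  expect_identical(p1$hap2, p2$hap2)
  p3 <- simulate_founders(bm, 3, seed = 43)
  expect_false(identical(p1$hap1, p3$hap1))
})

test_that("n_per_breed = 1 gives exactly K founders, purebred compositions", {
  bm <- small_bm()
  pop <- simulate_founders(bm, 1, seed = 1)
  expect_equal(nrow(pop$pedigree), 4)
  expect_true(all(is.na(pop$pedigree$sire_id)))
  expect_equal(unname(rowSums(pop$comp)), rep(1, 4))
  expect_equal(unname(apply(pop$comp, 1, max)), rep(1, 4))
})

test_that("F1s of divergent breeds are more heterozygous than founders", {
  wins <- 0
  for (r in 1:10) {
    bm <- breed_model(breeds = c("A", "B"), n_chrom = 1, snps_per_chrom = 200,
                      fst = 0.25, seed = 300 + r)
    pop <- simulate_founders(bm, 6, seed = 400 + r)
    sires <- grep("^A_", rownames(pop$hap1), value = TRUE)
    dams <- grep("^B_", rownames(pop$hap1), value = TRUE)
    pop <- mate(pop, cbind(sires, dams), ids = paste0("f1_", 1:6),
                seed = 500 + r)
    g <- as_geno_matrix(pop)
    oh <- observed_heterozygosity(g)
    founders <- c(sires, dams)
    wins <- wins + (mean(oh[paste0("f1_", 1:6)]) > mean(oh[founders]))
  }
  expect_gte(wins, 9)
})

test_that("gamete dropping obeys Mendelian transmission at every locus", {
  set.seed(141)
  bm <- small_bm(seed = 5)
  pop <- simulate_founders(bm, 4, seed = 6)
  ids <- rownames(pop$hap1)
  pairs <- cbind(sample(ids, 40, replace = TRUE),
                 sample(ids, 40, replace = TRUE))
  pop <- mate(pop, pairs, ids = sprintf("o%02d", 1:40), seed = 7)
  m <- ncol(pop$hap1)
  checks <- 0
  for (i in 1:40) {
    off <- sprintf("o%02d", i)
    s <- pairs[i, 1]
    d <- pairs[i, 2]
    expect_true(all(pop$hap1[off, ] == pop$hap1[s, ] |
                      pop$hap1[off, ] == pop$hap2[s, ]))
    expect_true(all(pop$hap2[off, ] == pop$hap1[d, ] |
                      pop$hap2[off, ] == pop$hap2[d, ]))
    checks <- checks + 2 * m
  }
  expect_gte(checks, 10000)
})

test_that("homozygous parents transmit deterministically", {
  bm <- small_bm(seed = 8)
  pop <- simulate_founders(bm, 2, seed = 9)
  # force two parents homozygous reference everywhere
  pop$hap1[c("A_01", "B_01"), ] <- 0L
  pop$hap2[c("A_01", "B_01"), ] <- 0L
  pop <- mate(pop, cbind("A_01", "B_01"), ids = "off", seed = 10)
  expect_true(all(pop$hap1["off", ] + pop$hap2["off", ] == 0L))
  # opposite fixation -> heterozygous everywhere
  pop$hap1["A_02", ] <- 1L
  pop$hap2["A_02", ] <- 1L
  pop$hap1["B_02", ] <- 0L
  pop$hap2["B_02", ] <- 0L
  pop <- mate(pop, cbind("A_02", "B_02"), ids = "offh", seed = 11)
  g <- as_geno_matrix(pop, animals = "offh")
  expect_true(all(g$dosage == 1L))
})

test_that("unknown parents are refused; selfing is reported", {
  bm <- small_bm(seed = 12)
  pop <- simulate_founders(bm, 2, seed = 13)
  expect_error(mate(pop, cbind("ghost", "A_01")), "unknown parent")
  expect_message(mate(pop, cbind("A_01", "A_01"), ids = "selfed", seed = 14),
                 "self-mating")
})

test_that("deterministic phenotype components add up exactly", {
  sc <- sim_crossbred(seed = 19, n_per_breed = 6, n_purebred = 8, n_f1 = 8,
                      n_f2 = 8, n_backcross = 8, n_threeway = 8)
  # no noise, no QTL, no polygene: trait is exactly the fixed-effect sum
  arch0 <- trait_architecture(h2_poly = 0, sigma_e = 0, breed_mean_sd = 0)
  sim0 <- simulate_phenotypes(sc$pop, arch0, animals = sc$cohort, seed = 20)
  expect_equal(sim0$pheno$trait_value, sim0$truth$fixed)
  expect_true(all(sim0$truth$polygenic == 0))
  # single dominance QTL d = 1: heterozygote mean minus mid-homozygote = 1
  snp <- sc$pop$map$snp_id[30]
  archd <- trait_architecture(qtl_dom = setNames(1, snp), h2_poly = 0,
                              sigma_e = 0, breed_mean_sd = 0,
                              fixed_effect_levels = list(
                                dam_parity = setNames(rep(0, 5),
                                                      c("1", "2", "3", "4", "5+")),
                                birth_herd = c(beef = 0, dairy = 0),
                                twin = c("0" = 0, "1" = 0),
                                rec_class = setNames(rep(0, 7),
                                                     as.character(0:6))))
  simd <- simulate_phenotypes(sc$pop, archd, animals = sc$cohort, seed = 21)
  d <- (sc$pop$hap1 + sc$pop$hap2)[sc$cohort, snp]
  het <- d == 1
  hom <- !het
  skip_if(sum(het) == 0 || sum(hom) == 0)
  expect_equal(mean(simd$pheno$trait_value[het]) -
                 mean(simd$pheno$trait_value[hom]), 1, tolerance = 1e-12)
})

test_that("trait variance tracks its analytic target", {
  devs <- sapply(1:10, function(r) {
    sc <- sim_crossbred(seed = 600 + r, n_per_breed = 10, n_purebred = 30,
                        n_f1 = 30, n_f2 = 30, n_backcross = 30,
                        n_threeway = 30)
    snps <- sample(sc$pop$map$snp_id, 6)
    arch <- trait_architecture(
      qtl_add = setNames(rnorm(3, 0, 0.4), snps[1:3]),
      qtl_dom = setNames(rnorm(3, 0, 0.4), snps[4:6]),
      h2_poly = 0.3, breed_mean_sd = 0, sigma_e = 1)
    sim <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort,
                               seed = 700 + r)
    tr <- sim$truth
    target <- var(tr$fixed) + var(tr$qtl_add + tr$qtl_dom) +
      sim$sigma_poly^2 + 1
    var(sim$pheno$trait_value) / target
  })
  expect_lt(abs(mean(devs) - 1), 0.2)
})

test_that("phenotype simulation is reproducible under a fixed seed", {
  sc <- sim_crossbred(seed = 33, n_per_breed = 6, n_purebred = 8, n_f1 = 8,
                      n_f2 = 8, n_backcross = 8, n_threeway = 8)
  arch <- trait_architecture(h2_poly = 0.3, sigma_e = 1)
  s1 <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort, seed = 2)
  s2 <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort, seed = 2)
  expect_identical(s1$pheno, s2$pheno)
})
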