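#' Breed model: founder allele frequencies over a SNP map
#'
#' Builds the generative model for a multi-breed population: a SNP map with
#' per-chromosome genetic lengths and a K x m matrix of per-breed allele-b
#' frequencies. Breed divergence has two layers: genome-wide drift
#' (Balding-Nichols: breed frequencies Beta-distributed around a shared
#' ancestral frequency with divergence `fst`) plus a small number of
#' clustered "divergence islands" per chromosome in which breeds are pushed
#' near fixation for alternating alleles, mimicking the strongly
#' differentiated haplotype blocks (e.g. around selected loci) that give
#' crossbred animals contiguous heterozygous stretches.
#'
#' Each simulated chromosome is a compressed stand-in for a full autosome:
#' physical coordinates span a few Mb so the panel has the SNP density of a
#' high-density array (relevant for run detection), while the genetic
#' length stays at a full autosome's one Morgan, so chromosomes recombine
#' and assort like real ones.
#'
#' @param breeds character vector of breed labels (K >= 2)
#' @param n_chrom number of autosomes
#' @param snps_per_chrom SNPs per chromosome
#' @param chrom_length_bp physical length per chromosome (bp); the default
#'   4 Mb with 400 SNPs gives ~10 kb spacing
#' @param chrom_length_morgan genetic length per chromosome (Morgans)
#' @param fst Balding-Nichols divergence among breeds
#' @param n_islands islands per chromosome
#' @param island_snps SNPs per island
#' @param seed RNG seed
#' @return list of class `breed_model`: `breeds`, `founder_freqs` (K x m),
#'   `map`, `chrom_morgans` (named), `chrom_bp`
#' @export
breed_model <- function(breeds = c("ANG", "CHA", "HOL", "LIM"),
                        n_chrom = 5, snps_per_chrom = 400,
                        chrom_length_bp = 4e6, chrom_length_morgan = 1,
                        fst = 0.2, n_islands = 2, island_snps = 60,
                        seed = 1) {
  stopifnot(length(breeds) >= 2, fst > 0, fst < 1)
  set.seed(seed)
  K <- length(breeds)
  maps <- vector("list", n_chrom)
  freqs <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    pos <- sort(sample.int(chrom_length_bp, snps_per_chrom))
    maps[[ch]] <- data.frame(
      snp_id = sprintf("snp%d_%d", ch, seq_len(snps_per_chrom)),
      chrom = as.character(ch), pos_bp = pos,
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
    anc <- stats::runif(snps_per_chrom, 0.05, 0.95)
    shape <- (1 - fst) / fst
    f <- t(vapply(seq_len(K), function(k) {
      stats::rbeta(snps_per_chrom, anc * shape, (1 - anc) * shape)
    }, numeric(snps_per_chrom)))
    if (n_islands > 0 && island_snps > 1) {
      starts <- round(seq(1, snps_per_chrom - island_snps + 1,
                          length.out = n_islands + 2))[-c(1, n_islands + 2)]
      for (s in starts) {
        cols <- s:(s + island_snps - 1L)
        lo <- stats::runif(length(cols), 0.005, 0.03)
        for (k in seq_len(K)) {
          # alternate near-fixed alleles by breed parity so breed pairs differ
          f[k, cols] <- if (k %% 2 == 1) lo else 1 - lo
        }
      }
    }
    freqs[[ch]] <- f
  }
  map <- do.call(rbind, maps)
  founder_freqs <- do.call(cbind, freqs)
  founder_freqs <- pmin(pmax(founder_freqs, 0.001), 0.999)
  dimnames(founder_freqs) <- list(breeds, map$snp_id)
  structure(list(breeds = breeds, founder_freqs = founder_freqs, map = map,
                 chrom_morgans = stats::setNames(
                   rep(chrom_length_morgan, n_chrom),
                   as.character(seq_len(n_chrom))),
                 chrom_bp = chrom_length_bp),
            class = "breed_model")
}

#' Simulate purebred founder animals
#'
#' Founder haplotype alleles are drawn independently per locus as
#' Bernoulli(breed frequency); dosages are the haplotype sums, i.e.
#' Binomial(2, frequency). Founders are flagged in the pedigree with their
#' purebred composition.
#'
#' @param bm a [breed_model()]
#' @param n_per_breed founders per breed (>= 1)
#' @param seed RNG seed
#' @return list of class `sim_pop`: `hap1`, `hap2` (animals x SNPs 0/1),
#'   `map`, `chrom_morgans`, `pedigree` (animal_id/sire_id/dam_id),
#'   `comp` (animals x breeds)
#' @export
simulate_founders <- function(bm, n_per_breed, seed = 1) {
  stopifnot(inherits(bm, "breed_model"), n_per_breed >= 1)
  if (any(bm$founder_freqs <= 0 | bm$founder_freqs >= 1)) {
    stop("founder frequencies must lie strictly inside (0, 1)")
  }
  set.seed(seed)
  K <- length(bm$breeds)
  m <- nrow(bm$map)
  n <- K * n_per_breed
  ids <- as.vector(vapply(bm$breeds, function(b) {
    sprintf("%s_%02d", b, seq_len(n_per_breed))
  }, character(n_per_breed)))
  hap1 <- hap2 <- matrix(0L, n, m, dimnames = list(ids, bm$map$snp_id))
  for (k in seq_len(K)) {
    rows <- ((k - 1) * n_per_breed + 1):(k * n_per_breed)
    f <- bm$founder_freqs[k, ]
    hap1[rows, ] <- matrix(stats::rbinom(n_per_breed * m, 1L,
                                         rep(f, each = n_per_breed)),
                           n_per_breed, m)
    hap2[rows, ] <- matrix(stats::rbinom(n_per_breed * m, 1L,
                                         rep(f, each = n_per_breed)),
                           n_per_breed, m)
  }
  comp <- matrix(0, n, K, dimnames = list(ids, bm$breeds))
  comp[cbind(seq_len(n), rep(seq_len(K), each = n_per_breed))] <- 1
  structure(list(hap1 = hap1, hap2 = hap2, map = bm$map,
                 chrom_morgans = bm$chrom_morgans,
                 pedigree = data.frame(animal_id = ids,
                                       sire_id = NA_character_,
                                       dam_id = NA_character_,
                                       stringsAsFactors = FALSE),
                 comp = comp),
            class = "sim_pop")
}

# one recombinant gamete from a parent's two haplotypes
.gamete <- function(h1, h2, map, chrom_morgans) {
  out <- integer(length(h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_bp[idx]
    span <- max(pos)
    n_x <- stats::rpois(1, chrom_morgans[[ch]])
    breaks <- sort(stats::runif(n_x, 0, span))
    seg <- findInterval(pos, breaks)
    phase <- (seg + stats::rbinom(1, 1, 0.5)) %% 2
    out[idx] <- ifelse(phase == 0, h1[idx], h2[idx])
  }
  out
}

#' Mate pairs of animals, with per-chromosome recombination
#'
#' Each offspring receives one recombinant gamete from each parent:
#' crossover counts are Poisson with the chromosome's genetic length (no
#' interference), breakpoints uniform along the physical map, starting
#' haplotype random. Offspring breed composition is the parental mean.
#' Self-mating is allowed but reported.
#'
#' @param pop a `sim_pop`
#' @param pairs two-column matrix or data.frame of (sire_id, dam_id)
#' @param ids offspring ids (default auto-generated)
#' @param seed RNG seed
#' @return the extended `sim_pop`
#' @export
mate <- function(pop, pairs, ids = NULL, seed = 1) {
  stopifnot(inherits(pop, "sim_pop"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  sires <- as.character(pairs[, 1])
  dams <- as.character(pairs[, 2])
  unknown <- setdiff(c(sires, dams), rownames(pop$hap1))
  if (length(unknown)) {
    stop("unknown parent(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(sires == dams)) {
    message("mate: ", sum(sires == dams), " self-mating(s)")
  }
  set.seed(seed)
  n_off <- nrow(pairs)
  if (is.null(ids)) {
    ids <- sprintf("off%04d_%d", seq_len(n_off), nrow(pop$hap1))
  }
  stopifnot(!any(ids %in% rownames(pop$hap1)))
  m <- ncol(pop$hap1)
  h1 <- h2 <- matrix(0L, n_off, m, dimnames = list(ids, colnames(pop$hap1)))
  for (i in seq_len(n_off)) {
    h1[i, ] <- .gamete(pop$hap1[sires[i], ], pop$hap2[sires[i], ],
                       pop$map, pop$chrom_morgans)
    h2[i, ] <- .gamete(pop$hap1[dams[i], ], pop$hap2[dams[i], ],
                       pop$map, pop$chrom_morgans)
  }
  pop$hap1 <- rbind(pop$hap1, h1)
  pop$hap2 <- rbind(pop$hap2, h2)
  pop$pedigree <- rbind(pop$pedigree,
                        data.frame(animal_id = ids, sire_id = sires,
                                   dam_id = dams, stringsAsFactors = FALSE))
  pop$comp <- rbind(pop$comp,
                    (pop$comp[sires, , drop = FALSE] +
                       pop$comp[dams, , drop = FALSE]) / 2)
  rownames(pop$comp) <- pop$pedigree$animal_id
  pop
}

#' Genotypes of a simulated population
#'
#' @param pop a `sim_pop`
#' @param animals optional subset of animal ids
#' @param missing_rate per-call missingness rate (default 0)
#' @param seed RNG seed for missingness masking
#' @return a [geno_matrix()]
#' @export
as_geno_matrix <- function(pop, animals = NULL, missing_rate = 0, seed = 1) {
  stopifnot(inherits(pop, "sim_pop"))
  if (is.null(animals)) animals <- rownames(pop$hap1)
  D <- pop$hap1[animals, , drop = FALSE] + pop$hap2[animals, , drop = FALSE]
  if (missing_rate > 0) {
    set.seed(seed)
    D[stats::runif(length(D)) < missing_rate] <- NA_integer_
  }
  geno_matrix(D, pop$map)
}

#' Trait architecture for phenotype simulation
#'
#' @param qtl_add named numeric: SNP id -> additive effect (trait units per
#'   copy of allele b)
#' @param qtl_dom named numeric: SNP id -> dominance effect (trait units
#'   for the heterozygote)
#' @param h2_poly fraction of total variance from the within-breed
#'   polygenic term, in [0, 1); the polygenic SD is derived so this
#'   fraction holds against the realized QTL variance plus `sigma_e^2`
#' @param breed_mean_sd SD of per-breed polygenic means, in trait units
#'   (breeds genuinely differ in polygenic merit -- the reason founder
#'   genetic groups exist in the association model); 0 switches breed
#'   means off
#' @param sigma_e residual SD
#' @param intercept trait intercept
#' @param fixed_effect_levels named list of per-level effects for
#'   `dam_parity` (levels 1..5+), `birth_herd` (beef/dairy), `twin` (0/1)
#'   and `rec_class` (0..6)
#' @return list of class `trait_architecture`
#' @export
trait_architecture <- function(qtl_add = numeric(), qtl_dom = numeric(),
                               h2_poly = 0.3, breed_mean_sd = 1,
                               sigma_e = 1, intercept = 0,
                               fixed_effect_levels = NULL) {
  stopifnot(h2_poly >= 0, h2_poly < 1, sigma_e >= 0, breed_mean_sd >= 0)
  if (is.null(fixed_effect_levels)) {
    fixed_effect_levels <- list(
      dam_parity = c("1" = 0, "2" = 0.3, "3" = 0.45, "4" = 0.5, "5+" = 0.5),
      birth_herd = c(beef = 0, dairy = -0.6),
      twin = c("0" = 0, "1" = -0.8),
      rec_class = stats::setNames(seq(0, 0.3, length.out = 7) * 0,
                                  as.character(0:6)))
  }
  structure(list(qtl_add = qtl_add, qtl_dom = qtl_dom, h2_poly = h2_poly,
                 breed_mean_sd = breed_mean_sd, sigma_e = sigma_e,
                 intercept = intercept,
                 fixed_effect_levels = fixed_effect_levels),
            class = "trait_architecture")
}

#' Simulate phenotypes with known truth components
#'
#' Trait = intercept + fixed effects + sum(additive QTL dosages x effects)
#' + sum(dominance QTL heterozygosity x effects) + polygenic value +
#' Normal(0, sigma_e^2). The polygenic value is gene-dropped down the
#' pedigree (founders: their breed's polygenic mean plus
#' N(0, sigma_p^2); offspring = parent average + Mendelian sampling
#' N(0, sigma_p^2 / 2)), independent of the markers, so marker QTL and
#' polygene are separable; the breed-mean component is what the
#' genetic-group terms of the association model and the breed-composition
#' structure of the GRM absorb. Dam parity, birth herd and twin
#' status are sampled per animal; the recombination-loss class is the
#' animal's true class from its parents' breed compositions. Contemporary
#' groups are assigned by block randomization.
#'
#' @param pop a `sim_pop`
#' @param arch a [trait_architecture()]
#' @param animals phenotyped animals (default: all non-founders)
#' @param group_size target contemporary-group size
#' @param seed RNG seed
#' @return list: `pheno` (data.frame animal_id, trait_value, dam_parity,
#'   birth_herd, twin, rec_class, contemporary_group), `truth` (per-animal
#'   components: fixed, qtl_add, qtl_dom, polygenic, residual) and
#'   `sigma_poly`
#' @export
simulate_phenotypes <- function(pop, arch, animals = NULL, group_size = 10,
                                seed = 1) {
  stopifnot(inherits(pop, "sim_pop"), inherits(arch, "trait_architecture"))
  set.seed(seed)
  ped <- pop$pedigree
  if (is.null(animals)) {
    animals <- ped$animal_id[!is.na(ped$sire_id) & !is.na(ped$dam_id)]
  }
  if (!length(animals)) stop("no phenotyped animals")
  D <- pop$hap1 + pop$hap2

  # QTL genetic values over the whole population (phenotypes need only the
  # cohort, but keeping all rows keeps indexing simple)
  gv_add <- numeric(nrow(D))
  if (length(arch$qtl_add)) {
    j <- match(names(arch$qtl_add), colnames(D))
    if (anyNA(j)) stop("additive QTL id(s) not in the map")
    gv_add <- as.numeric(D[, j, drop = FALSE] %*% arch$qtl_add)
  }
  gv_dom <- numeric(nrow(D))
  if (length(arch$qtl_dom)) {
    j <- match(names(arch$qtl_dom), colnames(D))
    if (anyNA(j)) stop("dominance QTL id(s) not in the map")
    H <- (D[, j, drop = FALSE] == 1L) * 1
    gv_dom <- as.numeric(H %*% arch$qtl_dom)
  }

  cohort <- match(animals, ped$animal_id)
  var_qtl <- stats::var(gv_add[cohort] + gv_dom[cohort])
  if (!is.finite(var_qtl)) var_qtl <- 0
  sigma_p2 <- if (arch$h2_poly > 0) {
    arch$h2_poly / (1 - arch$h2_poly) * (var_qtl + arch$sigma_e^2)
  } else 0

  # polygenic gene drop (pedigree order: parents precede offspring);
  # founders start at their breed's polygenic mean
  breed_means <- stats::rnorm(ncol(pop$comp), 0, arch$breed_mean_sd)
  names(breed_means) <- colnames(pop$comp)
  poly <- stats::setNames(numeric(nrow(ped)), ped$animal_id)
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$sire_id[i]) || is.na(ped$dam_id[i])) {
      poly[i] <- sum(pop$comp[ped$animal_id[i], ] * breed_means) +
        stats::rnorm(1, 0, sqrt(sigma_p2))
    } else {
      pa <- (poly[ped$sire_id[i]] + poly[ped$dam_id[i]]) / 2
      poly[i] <- pa + stats::rnorm(1, 0, sqrt(sigma_p2 / 2))
    }
  }
  poly_breed <- as.numeric(pop$comp %*% breed_means)
  names(poly_breed) <- rownames(pop$comp)

  fe <- arch$fixed_effect_levels
  n <- length(animals)
  dam_parity <- sample(names(fe$dam_parity), n, replace = TRUE,
                       prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
  birth_herd <- sample(names(fe$birth_herd), n, replace = TRUE,
                       prob = c(0.65, 0.35))
  twin <- sample(names(fe$twin), n, replace = TRUE, prob = c(0.98, 0.02))

  co <- pedigree_coefficients(ped, pop$comp[is.na(ped$sire_id) &
                                              is.na(ped$dam_id), ,
                                            drop = FALSE])
  rec_class <- co$rec_class[match(animals, co$animal_id)]
  if (anyNA(rec_class)) stop("phenotyped animal(s) without both parents")

  cg <- sprintf("cg%02d", ceiling(sample.int(n) / group_size))

  fixed <- arch$intercept + fe$dam_parity[dam_parity] +
    fe$birth_herd[birth_herd] + fe$twin[twin] +
    fe$rec_class[as.character(rec_class)]
  residual <- stats::rnorm(n, 0, arch$sigma_e)
  trait <- fixed + gv_add[cohort] + gv_dom[cohort] + poly[animals] + residual

  pheno <- data.frame(animal_id = animals, trait_value = as.numeric(trait),
                      dam_parity = dam_parity, birth_herd = birth_herd,
                      twin = twin, rec_class = rec_class,
                      contemporary_group = cg, stringsAsFactors = FALSE)
  truth <- data.frame(animal_id = animals, fixed = as.numeric(fixed),
                      qtl_add = gv_add[cohort], qtl_dom = gv_dom[cohort],
                      polygenic = as.numeric(poly[animals]),
                      poly_breed = as.numeric(poly_breed[animals]),
                      residual = residual, stringsAsFactors = FALSE)
  list(pheno = pheno, truth = truth, sigma_poly = sqrt(sigma_p2),
       breed_means = breed_means)
}

#' Simulate a crossbred cohort with a spread of heterosis coefficients
#'
#' Convenience scenario builder: purebred founders of each breed, then a
#' phenotyped generation mixing purebred matings (heterosis 0), F1 crosses
#' (heterosis 1), F2 and first backcrosses (heterosis 0.5) and three-way
#' crosses (heterosis 1, recombination loss 0.25), so the cohort spans the
#' coefficient range the pedigree analysis expects.
#'
#' @param bm a [breed_model()] (a default one is built when `NULL`)
#' @param n_per_breed founders per breed
#' @param n_purebred,n_f1,n_f2,n_backcross,n_threeway cohort sizes by cross
#'   type (F2/backcross/three-way require intermediate F1s, generated
#'   internally and excluded from the cohort)
#' @param seed RNG seed
#' @return list: `pop` (the `sim_pop`), `cohort` (phenotyped animal ids),
#'   `coefficients` (pedigree heterosis / recombination loss for the whole
#'   pedigree)
#' @export
sim_crossbred <- function(bm = NULL, n_per_breed = 12, n_purebred = 24,
                          n_f1 = 24, n_f2 = 24, n_backcross = 24,
                          n_threeway = 24, seed = 1) {
  if (is.null(bm)) bm <- breed_model(seed = seed)
  set.seed(seed + 1)
  pop <- simulate_founders(bm, n_per_breed, seed = seed + 2)
  K <- length(bm$breeds)
  by_breed <- split(pop$pedigree$animal_id, rep(bm$breeds, each = n_per_breed))
  pick2 <- function(b1, b2) {
    c(sample(by_breed[[b1]], 1), sample(by_breed[[b2]], 1))
  }
  breed_pair <- function() sample(bm$breeds, 2)

  # intermediate F1s used as parents of F2 / backcross / three-way animals
  n_parent_f1 <- max(8, ceiling((n_f2 * 2 + n_backcross + n_threeway) / 3))
  pf1 <- t(vapply(seq_len(n_parent_f1), function(i) {
    bp <- breed_pair()
    pick2(bp[1], bp[2])
  }, character(2)))
  pf1_ids <- sprintf("f1p_%03d", seq_len(n_parent_f1))
  pop <- mate(pop, pf1, ids = pf1_ids, seed = seed + 3)

  cohort_pairs <- list()
  add_pairs <- function(tag, n, fn) {
    if (n <= 0) return(NULL)
    p <- t(vapply(seq_len(n), function(i) fn(), character(2)))
    ids <- sprintf("%s_%03d", tag, seq_len(n))
    cohort_pairs[[length(cohort_pairs) + 1L]] <<- list(pairs = p, ids = ids)
    NULL
  }
  add_pairs("pb", n_purebred, function() {
    b <- sample(bm$breeds, 1)
    sample(by_breed[[b]], 2)
  })
  add_pairs("f1", n_f1, function() {
    bp <- breed_pair()
    pick2(bp[1], bp[2])
  })
  add_pairs("f2", n_f2, function() sample(pf1_ids, 2))
  add_pairs("bc", n_backcross, function() {
    c(sample(pf1_ids, 1), sample(by_breed[[sample(bm$breeds, 1)]], 1))
  })
  add_pairs("x3", n_threeway, function() {
    f1 <- sample(pf1_ids, 1)
    parents <- pop$pedigree[pop$pedigree$animal_id == f1, ]
    f1_breeds <- bm$breeds[pop$comp[f1, ] > 0]
    other <- sample(setdiff(bm$breeds, f1_breeds), 1)
    c(f1, sample(by_breed[[other]], 1))
  })
  pairs <- do.call(rbind, lapply(cohort_pairs, `[[`, "pairs"))
  ids <- unlist(lapply(cohort_pairs, `[[`, "ids"))
  pop <- mate(pop, pairs, ids = ids, seed = seed + 4)

  founders <- pop$pedigree$animal_id[is.na(pop$pedigree$sire_id)]
  co <- pedigree_coefficients(pop$pedigree,
                              pop$comp[founders, , drop = FALSE])
  list(pop = pop, cohort = ids, coefficients = co)
}
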