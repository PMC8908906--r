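#' Pedigree utilities, heterosis/recombination-loss coefficients, and the
#' numerator relationship matrix with phantom-parent genetic groups.
#'
#' A pedigree is a data.frame with character columns `animal_id`, `sire_id`,
#' `dam_id`; `NA` marks an unknown parent. Founder breed compositions are a
#' numeric matrix with one row per founder (rownames = animal ids) and one
#' column per breed; rows sum to 1.
#' @name pedigree
NULL

.check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("animal_id", "sire_id", "dam_id") %in% names(ped)))
  ped$animal_id <- as.character(ped$animal_id)
  ped$sire_id <- as.character(ped$sire_id)
  ped$dam_id <- as.character(ped$dam_id)
  if (anyDuplicated(ped$animal_id)) stop("duplicate animal_id in pedigree")
  ped
}

#' Sort a pedigree so parents precede offspring
#'
#' Errors on cycles or on parents absent from the pedigree.
#' @param ped pedigree data.frame (see [pedigree])
#' @return the reordered pedigree
#' @export
sort_pedigree <- function(ped) {
  ped <- .check_pedigree(ped)
  ids <- ped$animal_id
  parents <- cbind(match(ped$sire_id, ids), match(ped$dam_id, ids))
  known <- !is.na(ped$sire_id) | !is.na(ped$dam_id)
  miss <- (!is.na(ped$sire_id) & is.na(parents[, 1])) |
          (!is.na(ped$dam_id) & is.na(parents[, 2]))
  if (any(miss)) {
    stop("parent(s) not in pedigree for: ",
         paste(utils::head(ids[miss], 5), collapse = ", "))
  }
  depth <- rep(NA_integer_, nrow(ped))
  depth[!known] <- 0L
  # iterative longest-path depth; bounded by n passes, detects cycles
  for (pass in seq_len(nrow(ped) + 1L)) {
    pending <- which(is.na(depth))
    if (!length(pending)) break
    if (pass > nrow(ped)) stop("pedigree contains a cycle")
    for (i in pending) {
      dp <- depth[parents[i, ]]
      dp[is.na(parents[i, ])] <- 0L
      if (!anyNA(dp)) depth[i] <- max(dp) + 1L
    }
  }
  if (anyNA(depth)) stop("pedigree contains a cycle")
  ped[order(depth, seq_len(nrow(ped))), , drop = FALSE]
}

#' Breed composition of every animal in a pedigree
#'
#' A non-founder's composition is the mean of its parents' compositions,
#' recursively. Animals with exactly one known parent are refused unless
#' `phantom_purebred = TRUE`, in which case the unknown parent is taken as a
#' purebred of the known parent's majority breed.
#'
#' @param ped pedigree data.frame
#' @param founder_comp matrix of founder breed fractions (rows sum to 1;
#'   rownames are founder ids)
#' @param phantom_purebred how to treat a single unknown parent
#' @return numeric matrix, one row per pedigree animal, columns = breeds
#' @export
breed_composition <- function(ped, founder_comp, phantom_purebred = FALSE) {
  ped <- sort_pedigree(ped)
  stopifnot(is.matrix(founder_comp), !is.null(rownames(founder_comp)))
  if (any(founder_comp < 0) || any(abs(rowSums(founder_comp) - 1) > 1e-9)) {
    stop("founder compositions must be non-negative and sum to 1")
  }
  breeds <- colnames(founder_comp)
  comp <- matrix(NA_real_, nrow(ped), length(breeds),
                 dimnames = list(ped$animal_id, breeds))
  for (i in seq_len(nrow(ped))) {
    id <- ped$animal_id[i]
    s <- ped$sire_id[i]
    d <- ped$dam_id[i]
    if (is.na(s) && is.na(d)) {
      if (!id %in% rownames(founder_comp)) {
        stop("founder ", id, " has no breed composition")
      }
      comp[id, ] <- founder_comp[id, ]
    } else if (is.na(s) || is.na(d)) {
      if (!phantom_purebred) {
        stop("animal ", id, " has one unknown parent; set phantom_purebred ",
             "= TRUE to assign a purebred phantom of the known parent's ",
             "majority breed")
      }
      known <- comp[if (is.na(s)) d else s, ]
      phantom <- numeric(length(known))
      phantom[.majority_breed(known)] <- 1
      comp[id, ] <- (known + phantom) / 2
    } else {
      comp[id, ] <- (comp[s, ] + comp[d, ]) / 2
    }
  }
  comp
}

# index of the majority breed; ties broken by lexicographic breed label
.majority_breed <- function(frac) {
  top <- which(frac == max(frac))
  if (length(top) > 1) top <- top[order(names(frac)[top])][1]
  top
}

#' Pedigree heterosis coefficient
#'
#' `1 - sum_i B_S_i * B_D_i` over the union of breeds, where `B_S` and `B_D`
#' are the sire's and dam's breed fractions. 0 for matings within a pure
#' breed, 1 for a fully outcrossed mating; symmetric in sire and dam.
#'
#' @param sire,dam named numeric vectors of breed fractions (each sums to 1)
#' @return real in [0, 1]
#' @export
heterosis_coefficient <- function(sire, dam) {
  fr <- .align_comps(sire, dam)
  max(0, min(1, 1 - sum(fr$s * fr$d)))
}

#' Dickerson recombination-loss coefficient
#'
#' `1 - sum_i (B_S_i^2 + B_D_i^2) / 2`: the expected fraction of loci pairs
#' at which parental epistatic combinations are broken up. 0 when both
#' parents are purebred; 0.5 when both parents are F1s.
#'
#' @inheritParams heterosis_coefficient
#' @return real in [0, 1]
#' @export
recombination_loss <- function(sire, dam) {
  fr <- .align_comps(sire, dam)
  max(0, min(1, 1 - sum(fr$s^2 + fr$d^2) / 2))
}

.align_comps <- function(sire, dam) {
  for (v in list(sire, dam)) {
    if (is.null(names(v)) || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("breed compositions must be named, non-negative and sum to 1")
    }
  }
  breeds <- union(names(sire), names(dam))
  s <- d <- stats::setNames(numeric(length(breeds)), breeds)
  s[names(sire)] <- sire
  d[names(dam)] <- dam
  list(s = s, d = d)
}

#' Bin a recombination-loss coefficient into its 0-6 class
#'
#' Classes: 0 -> 0; (0, 0.10] -> 1; (0.10, 0.20] -> 2; ... (0.40, 0.50] -> 5;
#' > 0.50 -> 6. Boundaries are right-closed.
#'
#' @param r recombination-loss value(s) in [0, 1]
#' @return integer class(es) 0-6
#' @export
bin_recombination_class <- function(r) {
  if (any(r < 0 | r > 1)) stop("recombination loss must be in [0, 1]")
  cls <- as.integer(ceiling(pmax(r, 0) / 0.10 - 1e-12))
  cls[r == 0] <- 0L
  pmin(cls, 6L)
}

#' Heterosis and recombination-loss coefficients for a whole pedigree
#'
#' @param ped pedigree data.frame
#' @param founder_comp founder breed-fraction matrix
#' @param phantom_purebred passed to [breed_composition()]
#' @return data.frame with `animal_id`, `heterosis`, `rec_loss`, `rec_class`;
#'   founders (both parents unknown) get `NA` coefficients
#' @export
pedigree_coefficients <- function(ped, founder_comp, phantom_purebred = FALSE) {
  ped <- sort_pedigree(ped)
  comp <- breed_composition(ped, founder_comp, phantom_purebred)
  out <- data.frame(animal_id = ped$animal_id, heterosis = NA_real_,
                    rec_loss = NA_real_, rec_class = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire_id[i]
    d <- ped$dam_id[i]
    if (is.na(s) || is.na(d)) next  # phantom case already resolved in comp
    out$heterosis[i] <- heterosis_coefficient(comp[s, ], comp[d, ])
    out$rec_loss[i] <- recombination_loss(comp[s, ], comp[d, ])
  }
  has <- !is.na(out$rec_loss)
  out$rec_class[has] <- bin_recombination_class(out$rec_loss[has])
  out
}

#' Numerator relationship matrix with breed-based genetic groups
#'
#' Builds the pedigree numerator relationship matrix A by the tabular
#' (Henderson) recursion, and the genetic-group incidence matrix Q by
#' Westell-style accumulation: each founder's unknown parents are replaced by
#' phantom parents belonging to the group of the founder's majority breed
#' (ties broken lexicographically), and a non-founder's group fractions are
#' the mean of its parents'. Every row of Q sums to 1.
#'
#' @param ped pedigree data.frame
#' @param founder_comp founder breed-fraction matrix (used for group
#'   assignment); alternatively `groups` may give an explicit group label per
#'   founder
#' @param groups optional named character vector: founder id -> group label
#' @return list of class `ped_model` with `A` (n x n), `Q` (n x G),
#'   `group_labels` and `animal_ids`
#' @export
build_nrm_with_groups <- function(ped, founder_comp = NULL, groups = NULL) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$animal_id
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * a_sd
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  is_founder <- is.na(si) & is.na(di)
  if (is.null(groups)) {
    if (is.null(founder_comp)) stop("supply founder_comp or explicit groups")
    fids <- ids[is_founder]
    miss <- setdiff(fids, rownames(founder_comp))
    if (length(miss)) stop("no breed composition for founder(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    groups <- vapply(fids, function(id) {
      colnames(founder_comp)[.majority_breed(founder_comp[id, ])]
    }, character(1))
  }
  # half-founders: phantom group from the known side is not defined here;
  # sort_pedigree admits them but group accumulation needs both sides known
  glab <- sort(unique(groups))
  Q <- matrix(0, n, length(glab), dimnames = list(ids, glab))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (is.na(s) && is.na(d)) {
      Q[i, groups[[ids[i]]]] <- 1
    } else if (is.na(s) || is.na(d)) {
      stop("animal ", ids[i], " has exactly one known parent; assign its ",
           "phantom group explicitly via `groups`")
    } else {
      Q[i, ] <- (Q[s, ] + Q[d, ]) / 2
    }
  }
  structure(list(A = A, Q = Q, group_labels = glab, animal_ids = ids),
            class = "ped_model")
}
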