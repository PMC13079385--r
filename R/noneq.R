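#' Parameters of the nonequilibrium binding score
#'
#' Bundles the dissociation threshold `dG_star`, the thermal scale `kT`, the
#' attempt frequency `k` defining the characteristic time
#' `t* = exp(-dG_star/kT)/k`, the contact-region grammar, and the
#' accessibility-estimation settings.
#'
#' @param dG_star dissociation threshold in kcal/mol; contacts stronger
#'   (more negative) than `dG_star` tend to survive to time t*.
#' @param kT thermal energy in kcal/mol (default: 37 C).
#' @param attempt_rate_k bond dissociation attempt frequency, per second.
#' @param min_region_len minimum complementary-region length in the contact
#'   set (same grammar as the palindrome enumeration).
#' @param pfree_mode `"sampled"` (default, as in large-scale use) or
#'   `"exact"` (constrained partition functions).
#' @param n_samples structures sampled per molecule in sampled mode.
#' @param seed seed for sampled accessibilities.
#' @return object of class `noneq_params`.
#' @export
noneq_params <- function(dG_star = -12, kT = KB_KCAL * 310.15,
                         attempt_rate_k = 1e7, min_region_len = 4,
                         pfree_mode = c("sampled", "exact"),
                         n_samples = 10000, seed = 1) {
  pfree_mode <- match.arg(pfree_mode)
  stopifnot(attempt_rate_k > 0, n_samples >= 1)
  structure(list(dG_star = dG_star, kT = kT,
                 attempt_rate_k = attempt_rate_k,
                 min_region_len = as.integer(min_region_len),
                 pfree_mode = pfree_mode, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "noneq_params")
}

#' Probability that an initial contact survives to the characteristic time
#'
#' `exp(-exp((dGij - dG_star)/kT))`: the probability that a bond of strength
#' `dGij` does not dissociate within `t* = exp(-dG_star/kT)/k`, waiting times
#' being exponential in the bond's Boltzmann factor. Strictly decreasing in
#' `dGij`; 1 for very strong bonds, 0 for very weak ones, `exp(-1)` at
#' `dGij = dG_star`.
#'
#' @param dGij contact free energy, kcal/mol (vectorized).
#' @param p a [noneq_params()] object.
#' @return survival probability in \[0, 1\].
#' @export
survival_probability <- function(dGij, p) {
  z <- (dGij - p$dG_star) / p$kT
  out <- ifelse(z > 700, 0, exp(-exp(z)))
  unname(out)
}

#' Characteristic survival time t*
#'
#' @param p a [noneq_params()] object.
#' @return `exp(-dG_star/kT)/attempt_rate_k`, in seconds.
#' @export
characteristic_time <- function(p) {
  exp(-p$dG_star / p$kT) / p$attempt_rate_k
}

# accessibility of each (start, length) region (rows of `regions`) in the
# monomer ensemble of `seq`; one shared structure sample per molecule
region_pfree_map <- function(seq, regions, p, params) {
  if (nrow(regions) == 0) return(numeric(0))
  s <- as_rna(seq)
  if (p$pfree_mode == "exact") {
    return(vapply(seq_len(nrow(regions)), function(r) {
      region_pfree(s, c(regions$start[r], regions$length[r]), params,
                   mode = "exact")
    }, numeric(1)))
  }
  smp <- sample_structures(s, p$n_samples, seed = p$seed, params = params)
  vapply(seq_len(nrow(regions)), function(r) {
    idx <- regions$start[r] + seq_len(regions$length[r])
    mean(rowSums(smp$partner[, idx, drop = FALSE] >= 0) == 0)
  }, numeric(1))
}

#' Nonequilibrium binding strength of two folded molecules
#'
#' Scores the strength of an initial intermolecular binding event that does
#' not require unfolding: over all complementary region pairs \{i, j\}, the
#' weight `sum p_free_i * p_free_j * exp(-exp((dGij - dG_star)/kT))`, where
#' `p_free` is the probability the region is unpaired in its molecule's own
#' equilibrium ensemble. Returns `dG_noneq = -kT log(weight)` (`+Inf` when
#' the contact set is empty or fully inaccessible).
#'
#' @param seq1,seq2 the two molecules; pass the same sequence for the
#'   self-binding score of a homodimer contact.
#' @param p a [noneq_params()] object.
#' @param params an [energy_params()] object.
#' @return list with `dG` (kcal/mol), `weight` (`exp(-dG/kT)`), and
#'   `contacts`: a data.frame of contact candidates (`start1`, `start2`,
#'   `length`, `dGij`, `p_free_i`, `p_free_j`, `survival`, `self`).
#' @export
noneq_binding_strength <- function(seq1, seq2, p = noneq_params(),
                                   params = default_params()) {
  s1 <- as_rna(seq1); s2 <- as_rna(seq2)
  contacts <- find_complementary_pairs(s1, s2, p$min_region_len,
                                       maximal_only = TRUE, params = params)
  if (nrow(contacts) == 0) {
    return(list(dG = Inf, weight = 0,
                contacts = cbind(contacts, p_free_i = numeric(0),
                                 p_free_j = numeric(0),
                                 survival = numeric(0))))
  }
  reg1 <- data.frame(start = contacts$start1, length = contacts$length)
  reg2 <- data.frame(start = contacts$start2, length = contacts$length)
  contacts$p_free_i <- region_pfree_map(s1, reg1, p, params)
  contacts$p_free_j <- if (identical(s1$bases, s2$bases)) {
    region_pfree_map(s1, reg2, p, params) # same molecule, same ensemble
  } else {
    region_pfree_map(s2, reg2, p, params)
  }
  contacts$survival <- survival_probability(contacts$dGij, p)
  weight <- sum(contacts$p_free_i * contacts$p_free_j * contacts$survival)
  list(dG = if (weight > 0) -p$kT * log(weight) else Inf,
       weight = weight, contacts = contacts)
}

#' Nonequilibrium weight of palindromic self-contacts
#'
#' The same accessibility-weighted survival sum as
#' [noneq_binding_strength()] of a molecule with itself, restricted to
#' contacts in which region i and region j are the same palindrome:
#' `Wpal = sum_s p_free_s^2 * exp(-exp((dGs - dG_star)/kT))`. Zero for
#' palindrome-free sequences.
#'
#' @param seq the molecule.
#' @inheritParams noneq_binding_strength
#' @return the dimensionless weight `Wpal` (not a free energy).
#' @export
palindromic_noneq_weight <- function(seq, p = noneq_params(),
                                     params = default_params()) {
  s <- as_rna(seq)
  pal <- find_palindromes(s, min_len = p$min_region_len, maximal_only = TRUE,
                          params = params)
  if (nrow(pal) == 0) return(0)
  pf <- region_pfree_map(s, pal, p, params)
  sum(pf^2 * survival_probability(pal$dGs, p))
}

#' Census of strong, accessible palindromes
#'
#' Palindromic regions that both bind strongly (self-duplex `dGs <= dG_star`)
#' and are highly accessible (`p_free >= pfree_min`) in the monomer ensemble.
#'
#' @param seq the molecule.
#' @param dG_star binding-strength threshold, kcal/mol.
#' @param pfree_min accessibility threshold.
#' @inheritParams noneq_binding_strength
#' @return list with `count` and `palindromes` (the annotated data.frame
#'   with a `p_free` column).
#' @export
accessible_strong_palindromes <- function(seq, dG_star = -12,
                                          pfree_min = 0.1,
                                          p = noneq_params(dG_star = dG_star),
                                          params = default_params()) {
  s <- as_rna(seq)
  pal <- find_palindromes(s, min_len = p$min_region_len, maximal_only = TRUE,
                          params = params)
  if (nrow(pal) == 0) return(list(count = 0L, palindromes = cbind(pal, p_free = numeric(0))))
  pal$p_free <- region_pfree_map(s, pal, p, params)
  keep <- pal$dGs <= dG_star & pal$p_free >= pfree_min
  list(count = sum(keep), palindromes = pal[keep, , drop = FALSE])
}

# log of a weight with symbolic handling of zeros: returns list(lz, nzero)
.llog <- function(w) {
  if (w > 0) list(l = log(w), z = 0L) else list(l = 0, z = 1L)
}

#' Nonequilibrium heterodimer-versus-homodimer propensity
#'
#' `2 dG12_noneq - (dG11_noneq + dG22_noneq)`: positive values mean the pair
#' prefers homodimer contacts, negative values heterodimer contacts. Zero
#' weights (no contacts) are treated as a common limit `eps -> 0`: the sign
#' of the net `eps` exponent decides `+Inf`/`-Inf`, and equal counts cancel,
#' so an identical pair gives exactly 0.
#'
#' @inheritParams noneq_binding_strength
#' @return kcal/mol (possibly `+Inf`/`-Inf`; `0` for identical sequences).
#' @export
homo_vs_hetero_noneq <- function(seq1, seq2, p = noneq_params(),
                                 params = default_params()) {
  s1 <- as_rna(seq1); s2 <- as_rna(seq2)
  if (identical(s1$bases, s2$bases)) return(0)
  w11 <- noneq_binding_strength(s1, s1, p, params)$weight
  w22 <- noneq_binding_strength(s2, s2, p, params)$weight
  w12 <- noneq_binding_strength(s1, s2, p, params)$weight
  a <- .llog(w11); b <- .llog(w22); h <- .llog(w12)
  zexp <- a$z + b$z - 2L * h$z # net epsilon exponent in w11*w22/w12^2
  if (zexp > 0) return(-Inf)
  if (zexp < 0) return(Inf)
  p$kT * (a$l + b$l - 2 * h$l)
}

#' Wpal as a function of the dissociation threshold
#'
#' Evaluates [palindromic_noneq_weight()] on a grid of `dG_star` values,
#' computing palindromes and accessibilities once. Wpal is non-decreasing in
#' `dG_star` (every survival term is).
#'
#' @param seq the molecule.
#' @param dG_star_grid numeric vector of thresholds, kcal/mol.
#' @inheritParams noneq_binding_strength
#' @return data.frame with columns `dG_star`, `Wpal`.
#' @export
wpal_curve <- function(seq, dG_star_grid, p = noneq_params(),
                       params = default_params()) {
  s <- as_rna(seq)
  pal <- find_palindromes(s, min_len = p$min_region_len, maximal_only = TRUE,
                          params = params)
  if (nrow(pal) == 0) {
    return(data.frame(dG_star = dG_star_grid, Wpal = 0))
  }
  pf <- region_pfree_map(s, pal, p, params)
  wp <- vapply(dG_star_grid, function(g) {
    pg <- p; pg$dG_star <- g
    sum(pf^2 * survival_probability(pal$dGs, pg))
  }, numeric(1))
  data.frame(dG_star = dG_star_grid, Wpal = wp)
}
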