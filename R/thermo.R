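#' Free energy of a perfect RNA duplex
#'
#' Nearest-neighbor free energy of two exactly reverse-complementary regions
#' bound in a full helix: the sum of stacking terms along the helix, plus
#' duplex initiation, terminal AU penalties, and the symmetry correction when
#' the duplex is self-complementary (two copies of the same palindromic
#' sequence).
#'
#' @param a,b character or [rna_seq]; `b` must be the strict Watson-Crick
#'   reverse complement of `a`, length >= 2.
#' @param params an [energy_params()] object.
#' @return free energy in kcal/mol.
#' @examples
#' duplex_energy("GCAUGC", "GCAUGC") # palindrome bound to itself
#' @export
duplex_energy <- function(a, b, params = default_params()) {
  ca <- seq_chars(as_rna(a))
  cb <- seq_chars(as_rna(b))
  n <- length(ca)
  if (n < 2) stop("duplex regions must have length >= 2")
  if (length(cb) != n || any(unname(WC_COMP[ca]) != rev(cb))) {
    stop("regions are not reverse-complementary (strict Watson-Crick)")
  }
  # pair k joins a[k] with b[n + 1 - k]
  pt <- pair_type(ca, rev(cb))
  e <- params$duplex_init
  for (k in seq_len(n - 1)) {
    e <- e + params$stack[pt[k], pt[k + 1]]
  }
  au <- function(t) if (PAIR_NAMES[t] %in% c("AU", "UA", "GU", "UG"))
    params$terminal_au else 0
  e <- e + au(pt[1]) + au(pt[n])
  if (paste(ca, collapse = "") == paste(cb, collapse = "")) {
    e <- e + params$symmetry_correction
  }
  e
}

# shared driver for the compiled engine
engine_logq <- function(ints, nicks, params, mask = integer(0),
                        forbid = c(-1L, -1L)) {
  pf_logq_cpp(ints, as.integer(nicks), cpp_params(params),
              as.integer(mask), as.integer(forbid[1]), as.integer(forbid[2]))
}

#' Single-strand partition function
#'
#' Boltzmann-weighted sum over all legal nested secondary structures of one
#' strand (including the open chain), under the package's nearest-neighbor
#' model, via an O(n^3) dynamic program.
#'
#' @param seq character or [rna_seq].
#' @param params an [energy_params()] object.
#' @return list with `logQ`, `Q` and the ensemble free energy `dG`
#'   (kcal/mol, `-kT log Q`, always <= 0).
#' @examples
#' partition_function("GCAUGC")
#' @export
partition_function <- function(seq, params = default_params()) {
  s <- as_rna(seq)
  lq <- engine_logq(seq_ints(s), integer(0), params)
  list(logQ = lq, Q = exp(lq), dG = -params$kT * lq)
}

#' Equilibrium base-pair probabilities
#'
#' Exact probabilities that bases i and j are paired in the equilibrium
#' ensemble, and per-base unpaired probabilities. Pair probabilities are
#' computed as `(Q - Q_without_pair)/Q` with the pair forbidden in the
#' dynamic program; unpaired probabilities independently as constrained
#' partition-function ratios, so that the row normalization
#' `p_unpaired(i) + sum_j p_pair(i,j) = 1` is a genuine cross-check.
#'
#' @inheritParams partition_function
#' @return list of class `pair_probabilities` with `p_pair` (n x n matrix,
#'   0-based coordinates in dimnames) and `p_unpaired` (length-n vector).
#' @export
pair_probabilities <- function(seq, params = default_params()) {
  s <- as_rna(seq)
  out <- pair_probs_cpp(seq_ints(s), integer(0), cpp_params(params))
  dimnames(out$p_pair) <- list(0:(s$n - 1), 0:(s$n - 1))
  names(out$p_unpaired) <- 0:(s$n - 1)
  structure(out, class = "pair_probabilities", seq_id = s$id)
}

#' Sample secondary structures from the Boltzmann ensemble
#'
#' Stochastic traceback of the partition-function tables: i.i.d. draws from
#' the equilibrium distribution of structures.
#'
#' @inheritParams partition_function
#' @param n number of samples (>= 1).
#' @param seed integer seed (required, for reproducibility).
#' @return object of class `structure_sample`: a list with `partner`
#'   (n x length integer matrix, 0-based partner index or -1 for unpaired)
#'   and `n_bases`. `[[` extracts one structure as a two-column 0-based pair
#'   matrix; `length()` gives the number of samples.
#' @export
sample_structures <- function(seq, n, seed, params = default_params()) {
  stopifnot(n >= 1)
  s <- as_rna(seq)
  partner <- with_seed(seed, {
    pf_sample_cpp(seq_ints(s), integer(0), cpp_params(params), as.integer(n))
  })
  structure(list(partner = partner, n_bases = s$n, seq_id = s$id),
            class = "structure_sample")
}

#' @export
length.structure_sample <- function(x) nrow(x$partner)

#' @export
`[[.structure_sample` <- function(x, i) {
  pr <- x$partner[i, ]
  idx <- which(pr > seq_along(pr) - 1L) # i < partner, 0-based
  cbind(i = idx - 1L, j = pr[idx])
}

#' @export
print.structure_sample <- function(x, ...) {
  cat(sprintf("<structure_sample> %d structures of %s (%d nt)\n",
              nrow(x$partner), x$seq_id, x$n_bases))
  invisible(x)
}

# empirical pair frequency matrix from a structure_sample
sample_pair_frequencies <- function(smp) {
  n <- smp$n_bases
  m <- matrix(0, n, n)
  pr <- smp$partner
  for (k in seq_len(nrow(pr))) {
    idx <- which(pr[k, ] >= 0)
    for (i in idx) {
      if (pr[k, i] > i - 1L) m[i, pr[k, i] + 1L] <- m[i, pr[k, i] + 1L] + 1
    }
  }
  m <- m + t(m)
  m / nrow(pr)
}

#' Probability that a region is entirely unpaired
#'
#' Accessibility of a region in the monomer equilibrium ensemble. In exact
#' mode this is the constrained partition function (all region bases forced
#' unpaired) divided by the full partition function; in sampled mode, the
#' fraction of Boltzmann-sampled structures in which the whole region is
#' unpaired.
#'
#' @inheritParams partition_function
#' @param region `c(start, length)`, 0-based start on the 5'-to-3' strand.
#' @param mode `"exact"` or `"sampled"`.
#' @param n number of samples (sampled mode).
#' @param seed seed for sampled mode.
#' @param sample optionally, a precomputed [sample_structures()] result to
#'   reuse (sampled mode).
#' @return probability in \[0, 1\].
#' @export
region_pfree <- function(seq, region, params = default_params(),
                         mode = c("exact", "sampled"), n = 10000,
                         seed = NULL, sample = NULL) {
  mode <- match.arg(mode)
  s <- as_rna(seq)
  start <- as.integer(region[1]); len <- as.integer(region[2])
  if (len < 1 || start < 0 || start + len > s$n) {
    stop("region out of bounds: (", start, ", ", len, ") on ", s$n, " nt")
  }
  idx <- start:(start + len - 1L)
  if (mode == "exact") {
    lq0 <- engine_logq(seq_ints(s), integer(0), params)
    lqc <- engine_logq(seq_ints(s), integer(0), params, mask = idx)
    return(exp(lqc - lq0))
  }
  if (is.null(sample)) {
    if (is.null(seed)) stop("sampled mode needs a seed (or a sample)")
    sample <- sample_structures(s, n, seed, params)
  }
  mean(rowSums(sample$partner[, idx + 1L, drop = FALSE] >= 0) == 0)
}
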