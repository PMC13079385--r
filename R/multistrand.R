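#' Specify a multi-strand complex
#'
#' An ordered (circular) list of strands with its rotational symmetry factor.
#' For a homomultimer of m identical strands the symmetry factor is m; in
#' general it is the number of rotations of the ordering that map the strand
#' list onto itself.
#'
#' @param strands a list of [rna_seq] (or character) in circular order, or a
#'   single sequence.
#' @param symmetry_factor override the automatically computed factor.
#' @return object of class `complex_spec`.
#' @export
complex_spec <- function(strands, symmetry_factor = NULL) {
  cc <- concat_strands(strands)
  m <- cc$m
  keys <- vapply(cc$seqs, function(s) s$bases, character(1))
  auto <- sum(vapply(0:(m - 1), function(r) {
    all(keys == keys[(seq_len(m) + r - 1) %% m + 1])
  }, logical(1)))
  sf <- as.integer(symmetry_factor %||% auto)
  if (m %% sf != 0) stop("symmetry_factor must divide the strand count")
  structure(list(strands = cc$seqs, concat = cc, symmetry_factor = sf,
                 size = m), class = "complex_spec")
}

#' Partition function and free energy of a complex
#'
#' Boltzmann sum over all nested, nick-legal, *connected* secondary
#' structures of the given circular strand ordering (every strand linked
#' through base pairs; no loop contains more than one nick), divided by the
#' rotational symmetry factor. Each strand beyond the first contributes one
#' duplex-initiation penalty. A single-strand spec reduces exactly to
#' [partition_function()].
#'
#' @param spec a `complex_spec`, or anything accepted by [complex_spec()].
#' @param params an [energy_params()] object.
#' @param max_total_length resource guard on the concatenated length.
#' @return object of class `complex_free_energy`: list with `Q`, `logQ`,
#'   `dG` (kcal/mol; `+Inf` when no connected structure exists), `size` and
#'   `symmetry_factor`.
#' @export
complex_partition_function <- function(spec, params = default_params(),
                                       max_total_length = 400) {
  if (!inherits(spec, "complex_spec")) spec <- complex_spec(spec)
  cc <- spec$concat
  if (cc$n > max_total_length) {
    stop("total complex length ", cc$n, " exceeds cap ", max_total_length,
         " (raise max_total_length if intended)")
  }
  lq <- engine_logq(cc$ints, cc$nicks1 - 1L, params) # engine nicks are 0-based
  logQ <- lq - (cc$m - 1) * params$duplex_init / params$kT -
    log(spec$symmetry_factor)
  structure(list(Q = exp(logQ), logQ = logQ, dG = -params$kT * logQ,
                 size = cc$m, symmetry_factor = spec$symmetry_factor),
            class = "complex_free_energy")
}

#' @export
print.complex_free_energy <- function(x, ...) {
  cat(sprintf("<complex_free_energy> size %d (sym %d): dG = %.4f kcal/mol\n",
              x$size, x$symmetry_factor, x$dG))
  invisible(x)
}

#' Homodimer and heterodimer free energies of a sequence pair
#'
#' `dG11` and `dG22` are homodimer free energies (symmetry factor 2);
#' `dG12` is the heterodimer free energy (symmetry factor 1). Equilibrium
#' dimerization preference compares `dG11 + dG22` against `2 dG12`.
#'
#' @param seq1,seq2 sequences.
#' @inheritParams complex_partition_function
#' @return list with `dG11`, `dG22`, `dG12` (kcal/mol, `+Inf` sentinels when
#'   a dimer admits no interstrand pairing).
#' @export
dimer_energies <- function(seq1, seq2, params = default_params(),
                           max_total_length = 400) {
  s1 <- as_rna(seq1); s2 <- as_rna(seq2)
  cpf <- function(strands, sym) {
    complex_partition_function(complex_spec(strands, symmetry_factor = sym),
                               params, max_total_length)$dG
  }
  # the heterodimer spec always carries symmetry factor 1, even for the
  # degenerate call with two copies of the same sequence
  list(dG11 = cpf(list(s1, s1), 2), dG22 = cpf(list(s2, s2), 2),
       dG12 = cpf(list(s1, s2), 1))
}

#' Homomultimer free energies up to a maximum cluster size
#'
#' Free energy of the m-mer of a single sequence for m = 1..max_size, each
#' from the single circular ordering of m identical strands with symmetry
#' factor m.
#'
#' @param seq the sequence.
#' @param max_size largest cluster size considered.
#' @inheritParams complex_partition_function
#' @return data.frame with columns `m`, `logQ`, `dG`.
#' @export
homomultimer_energies <- function(seq, max_size = 10,
                                  params = default_params(),
                                  max_total_length = 400) {
  stopifnot(max_size >= 1)
  s <- as_rna(seq)
  if (s$n * max_size > max_total_length) {
    stop("max_size * length exceeds cap ", max_total_length)
  }
  res <- lapply(seq_len(max_size), function(m) {
    cf <- complex_partition_function(
      complex_spec(rep(list(s), m), symmetry_factor = m),
      params, max_total_length)
    data.frame(m = m, logQ = cf$logQ, dG = cf$dG)
  })
  do.call(rbind, res)
}

# single-species mass action on log scale; energies: data.frame(m, logQ)
cluster_distribution_from_energies <- function(energies, total_conc) {
  stopifnot(total_conc > 0)
  m <- energies$m
  lw <- energies$logQ # ln Q_m, reference concentration 1 M
  keep <- is.finite(lw)
  lctot <- log(total_conc)
  f <- function(u) logsumexp(log(m[keep]) + lw[keep] + m[keep] * u) - lctot
  hi <- lctot # Q_1 >= 1 so f(hi) >= 0, with equality iff pure monomer
  if (f(hi) <= 1e-15) {
    u <- hi
  } else {
    lo <- lctot
    while (f(lo) > 0) lo <- lo - 5
    u <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
  frac <- rep(0, length(m))
  frac[keep] <- exp(log(m[keep]) + lw[keep] + m[keep] * u - lctot)
  if (abs(sum(frac) - 1) > 1e-9) {
    stop("mass-action solve failed to conserve strands (residual ",
         format(sum(frac) - 1), ")")
  }
  structure(list(fraction_in_size = setNames(frac, m),
                 monomer_conc = exp(u), total_conc = total_conc),
            class = "cluster_distribution")
}

#' Equilibrium cluster-size distribution of a single sequence
#'
#' Solves the single-species law of mass action: the m-mer concentration is
#' proportional to `exp(-dG_m/kT) x1^m` (1 M standard state), with the
#' monomer concentration x1 found by monotone root-finding so that total
#' strand concentration is conserved.
#'
#' @param seq the sequence.
#' @param total_conc total strand concentration in mol/L.
#' @param max_size largest cluster size considered.
#' @param params an [energy_params()] object.
#' @param energies optional precomputed [homomultimer_energies()] table.
#' @return object of class `cluster_distribution`: `fraction_in_size`
#'   (named vector over m = 1..max_size summing to 1), `monomer_conc`,
#'   `total_conc`.
#' @export
equilibrium_cluster_distribution <- function(seq, total_conc, max_size = 10,
                                             params = default_params(),
                                             energies = NULL) {
  energies <- energies %||% homomultimer_energies(seq, max_size, params)
  cluster_distribution_from_energies(energies, total_conc)
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat(sprintf("<cluster_distribution> total %.3g M, monomer %.3g M\n",
              x$total_conc, x$monomer_conc))
  print(round(x$fraction_in_size, 4))
  invisible(x)
}

#' Fraction of strands in higher-order clusters
#'
#' @param dist a [equilibrium_cluster_distribution()] result.
#' @param threshold minimum cluster size counted as higher-order.
#' @return the summed strand fraction in clusters of size >= threshold.
#' @export
higher_order_fraction <- function(dist, threshold = 4) {
  sizes <- as.integer(names(dist$fraction_in_size))
  sum(dist$fraction_in_size[sizes >= threshold])
}
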