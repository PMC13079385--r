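#' Experiment configuration
#'
#' Bundles the knobs of the in-silico experiment pipelines with desk-scale
#' defaults. `concentration_rule` sets the total strand concentration for a
#' sequence of length L to `prefactor * (ref_length / L)^exponent` (mol/L),
#' controlling for the length dependence of clustering.
#'
#' @param seed master seed; sub-seeds for each pipeline stage are derived
#'   deterministically.
#' @param n_pairs sequence pairs in the dimerization experiment.
#' @param n_seqs sequences in the multimerization screen.
#' @param lengths sequence lengths used by the screens.
#' @param dG_star_grid thresholds for Wpal curves, kcal/mol.
#' @param concentration_rule `c(prefactor, ref_length, exponent)`; default
#'   4 mM at 20 nt with exponent 2.5.
#' @param max_cluster_size largest homomultimer considered.
#' @param higher_order_threshold minimum size counted as higher-order.
#' @param bin_width free-energy bin width for averaged curves, kcal/mol.
#' @param min_bin_count bins with fewer points are dropped.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1, n_pairs = 500, n_seqs = 300,
                              lengths = 20:25,
                              dG_star_grid = seq(-12.5, -8.5, by = 0.5),
                              concentration_rule = c(4e-3, 20, 2.5),
                              max_cluster_size = 10,
                              higher_order_threshold = 4,
                              bin_width = 2, min_bin_count = 30) {
  stopifnot(n_pairs >= 1, n_seqs >= 1, bin_width > 0)
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 n_seqs = as.integer(n_seqs), lengths = as.integer(lengths),
                 dG_star_grid = dG_star_grid,
                 concentration_rule = concentration_rule,
                 max_cluster_size = as.integer(max_cluster_size),
                 higher_order_threshold = as.integer(higher_order_threshold),
                 bin_width = bin_width,
                 min_bin_count = as.integer(min_bin_count)),
            class = "experiment_config")
}

length_concentration <- function(L, rule) {
  rule[1] * (rule[2] / L)^rule[3]
}

#' Homodimer-versus-heterodimer equilibrium experiment
#'
#' Draws random sequence pairs, computes homodimer and heterodimer free
#' energies, and classifies each pair by the sign of
#' `(dG11 + dG22) - 2 dG12` at 1e-9 kcal/mol resolution. With
#' `palindrome_free = TRUE` the ensemble is rejection-sampled to contain no
#' palindrome of length >= 4, which is expected to invert the preference.
#'
#' @param n_pairs number of random pairs.
#' @param length sequence length, nt.
#' @param seed integer seed.
#' @param palindrome_free use the palindrome-free null ensemble.
#' @param params an [energy_params()] object.
#' @param tie_tol resolution below which a comparison counts as a tie.
#' @return list with `frac_homo`, `frac_hetero`, `frac_tie`, `ratio`
#'   (homo/hetero) and the per-pair `table`.
#' @export
homo_vs_hetero_experiment <- function(n_pairs = 500, length = 30, seed = 1,
                                      palindrome_free = FALSE,
                                      params = default_params(),
                                      tie_tol = 1e-9) {
  seeds <- derive_seeds(seed, 2)
  gen <- if (palindrome_free) palindrome_free_sequences else random_sequences
  sa <- gen(n_pairs, length, seeds[1])
  sb <- gen(n_pairs, length, seeds[2])
  cls <- character(n_pairs)
  gap <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    if (identical(sa[[k]]$bases, sb[[k]]$bases)) {
      # a dimer of identical molecules is a homodimer by definition
      cls[k] <- "homo"; gap[k] <- -Inf
      next
    }
    de <- dimer_energies(sa[[k]], sb[[k]], params)
    hom <- de$dG11 + de$dG22; het <- 2 * de$dG12
    gap[k] <- hom - het
    cls[k] <- if (is.infinite(hom) && is.infinite(het)) "tie"
    else if (hom < het - tie_tol) "homo"
    else if (het < hom - tie_tol) "hetero"
    else "tie"
  }
  tab <- data.frame(pair = seq_len(n_pairs), gap = gap, class = cls)
  n_h <- sum(cls == "homo"); n_e <- sum(cls == "hetero")
  list(frac_homo = n_h / n_pairs, frac_hetero = n_e / n_pairs,
       frac_tie = sum(cls == "tie") / n_pairs,
       ratio = n_h / n_e, table = tab)
}

#' Homomultimerization screen against palindrome binding strength
#'
#' For each random sequence: the palindrome binding strength `dGpal`
#' and the equilibrium fraction of strands in higher-order clusters
#' (size >= threshold) at the length-controlled concentration
#' `4 (20/L)^2.5 mM`. Reports the per-length binned mean curve (bins of
#' `bin_width` kcal/mol in `dGpal`, bins with fewer than `min_bin_count`
#' points dropped) and the rank correlation between binding strength
#' (`-dGpal`) and the higher-order fraction.
#'
#' @param cfg an [experiment_config()].
#' @param params an [energy_params()] object.
#' @return list with `table` (seq_id, L, dGpal, higher_order_fraction),
#'   `curve` (L, bin midpoint, mean fraction, n), and `correlation`
#'   (Spearman rho and p-value of `-dGpal` vs the fraction; positive rho
#'   means stronger palindromes multimerize more).
#' @export
multimer_screen <- function(cfg = experiment_config(),
                            params = default_params()) {
  lens <- rep(cfg$lengths, length.out = cfg$n_seqs)
  seeds <- derive_seeds(cfg$seed, length(cfg$lengths))
  seqs <- list()
  for (i in seq_along(cfg$lengths)) {
    seqs <- c(seqs, random_sequences(sum(lens == cfg$lengths[i]),
                                     cfg$lengths[i], seeds[i]))
  }
  rows <- lapply(seqs, function(s) {
    en <- homomultimer_energies(s, cfg$max_cluster_size, params)
    dist <- cluster_distribution_from_energies(
      en, length_concentration(s$n, cfg$concentration_rule))
    data.frame(seq_id = s$id, L = s$n,
               dGpal = palindrome_binding_strength(s, params),
               higher_order_fraction =
                 higher_order_fraction(dist, cfg$higher_order_threshold))
  })
  tab <- do.call(rbind, rows)
  fin <- is.finite(tab$dGpal)
  curve <- NULL
  if (any(fin)) {
    bin <- floor(tab$dGpal[fin] / cfg$bin_width)
    agg <- aggregate(tab$higher_order_fraction[fin],
                     by = list(L = tab$L[fin], bin = bin),
                     FUN = function(x) c(mean = mean(x), n = length(x)))
    curve <- data.frame(L = agg$L,
                        dGpal_mid = (agg$bin + 0.5) * cfg$bin_width,
                        mean_fraction = agg$x[, "mean"], n = agg$x[, "n"])
    curve <- curve[curve$n >= cfg$min_bin_count, , drop = FALSE]
  }
  ct <- suppressWarnings(cor.test(-tab$dGpal, tab$higher_order_fraction,
                                  method = "spearman", exact = FALSE))
  list(table = tab, curve = curve,
       correlation = list(rho = unname(ct$estimate), p_value = ct$p.value))
}

#' Homodimer free-energy gap against palindrome binding strength
#'
#' For each sequence (random by default, or user-supplied), the monomer free
#' energy `dG1`, the homodimer free energy `dG11`, and `dGpal`; reports the
#' Pearson correlation between the gap `dG11 - 2 dG1` and `dGpal` on rows
#' where both are finite (sentinel rows counted and excluded).
#'
#' @param n_per_length random sequences per length.
#' @param lengths sequence lengths.
#' @param seed integer seed.
#' @param extra_seqs optional list of [rna_seq] (e.g. natural transcripts
#'   from FASTA) appended to the screen.
#' @param params an [energy_params()] object.
#' @return list with `table`, `pearson_r`, `p_value`, `n_used`,
#'   `n_excluded`.
#' @export
dimer_gap_screen <- function(n_per_length = 20, lengths = c(20, 25, 30, 35),
                             seed = 1, extra_seqs = NULL,
                             params = default_params()) {
  seeds <- derive_seeds(seed, length(lengths))
  seqs <- list()
  for (i in seq_along(lengths)) {
    seqs <- c(seqs, random_sequences(n_per_length, lengths[i], seeds[i]))
  }
  seqs <- c(seqs, lapply(extra_seqs %||% list(), as_rna))
  rows <- lapply(seqs, function(s) {
    dG1 <- partition_function(s, params)$dG
    dG11 <- complex_partition_function(complex_spec(list(s, s)), params)$dG
    data.frame(seq_id = s$id, L = s$n, dG1 = dG1, dG11 = dG11,
               dGpal = palindrome_binding_strength(s, params),
               gap = dG11 - 2 * dG1)
  })
  tab <- do.call(rbind, rows)
  fin <- is.finite(tab$gap) & is.finite(tab$dGpal)
  if (sum(fin) < 3 || stats::sd(tab$gap[fin]) == 0) {
    return(list(table = tab, pearson_r = NA_real_, p_value = NA_real_,
                n_used = sum(fin), n_excluded = sum(!fin)))
  }
  ct <- cor.test(tab$gap[fin], tab$dGpal[fin], method = "pearson")
  list(table = tab, pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_used = sum(fin), n_excluded = sum(!fin))
}

#' All-pairs nonequilibrium dimerization screen
#'
#' Builds the matrix of `2 dG12_noneq - (dG11_noneq + dG22_noneq)` between
#' two sequence groups (the heterodimer-versus-homodimer propensity of each
#' pair), as used to compare focal transcripts against length-matched
#' ensembles.
#'
#' @param group_a,group_b lists of [rna_seq] (e.g. from [read_fasta()] or
#'   [random_sequences()]).
#' @param p a [noneq_params()] object.
#' @param params an [energy_params()] object.
#' @return list with `matrix` (|A| x |B|) and tidy `table`
#'   (id_a, id_b, value); attribute `dG_star` records the threshold used.
#' @export
noneq_screen <- function(group_a, group_b, p = noneq_params(),
                         params = default_params()) {
  group_a <- lapply(group_a, as_rna)
  group_b <- lapply(group_b, as_rna)
  # cache self-weights
  wself <- function(s) noneq_binding_strength(s, s, p, params)$weight
  wa <- vapply(group_a, wself, numeric(1))
  wb <- vapply(group_b, wself, numeric(1))
  M <- matrix(NA_real_, length(group_a), length(group_b),
              dimnames = list(vapply(group_a, `[[`, "", "id"),
                              vapply(group_b, `[[`, "", "id")))
  for (i in seq_along(group_a)) for (j in seq_along(group_b)) {
    if (identical(group_a[[i]]$bases, group_b[[j]]$bases)) {
      M[i, j] <- 0
      next
    }
    w12 <- noneq_binding_strength(group_a[[i]], group_b[[j]], p, params)$weight
    a <- .llog(wa[i]); b <- .llog(wb[j]); h <- .llog(w12)
    zexp <- a$z + b$z - 2L * h$z
    M[i, j] <- if (zexp > 0) -Inf else if (zexp < 0) Inf
    else p$kT * (a$l + b$l - 2 * h$l)
  }
  tab <- data.frame(id_a = rep(rownames(M), times = ncol(M)),
                    id_b = rep(colnames(M), each = nrow(M)),
                    value = as.vector(M))
  structure(list(matrix = M, table = tab), dG_star = p$dG_star)
}

#' Smith-Waterman local alignment score
#'
#' Best local-alignment score with linear gap penalty; defaults to the
#' match/mismatch/gap scoring triple (+1, -2, -2) used for near-duplicate
#' screening of length-matched transcript sets.
#'
#' @param seq1,seq2 sequences.
#' @param match,mismatch,gap score contributions.
#' @return the best score (0 when nothing aligns).
#' @export
smith_waterman <- function(seq1, seq2, match = 1, mismatch = -2, gap = -2) {
  a <- as_rna(seq1); b <- as_rna(seq2)
  sw_score_cpp(seq_ints(a), seq_ints(b), match, mismatch, gap)
}

#' Select length-matched sequences and drop near-duplicates
#'
#' Keeps sequences whose length L satisfies the strict window
#' `target_length - window < L < target_length + window`, then compares all
#' pairs by Smith-Waterman score and drops one member of every near-duplicate
#' pair (score >= `dedup_frac * min(L1, L2)`; unrelated sequences of these
#' lengths score far lower).
#'
#' @param seqs list of [rna_seq] (e.g. from [read_fasta()]).
#' @param target_length centre of the length window, nt.
#' @param window half-width of the strict length window.
#' @param dedup_frac near-duplicate threshold as a fraction of the shorter
#'   length.
#' @return the retained list, with attributes `n_window` (sequences passing
#'   the length filter) and `dropped` (ids removed as near-duplicates).
#' @export
select_length_matched <- function(seqs, target_length, window = 5,
                                  dedup_frac = 0.8) {
  seqs <- lapply(seqs, as_rna)
  lens <- vapply(seqs, function(s) s$n, integer(1))
  keep <- lens > target_length - window & lens < target_length + window
  sel <- seqs[keep]
  dropped <- character(0)
  if (length(sel) > 1) {
    alive <- rep(TRUE, length(sel))
    for (i in seq_along(sel)) {
      if (!alive[i]) next
      for (j in seq_along(sel)) {
        if (j <= i || !alive[j]) next
        thr <- dedup_frac * min(sel[[i]]$n, sel[[j]]$n)
        if (smith_waterman(sel[[i]], sel[[j]]) >= thr) {
          alive[j] <- FALSE
          dropped <- c(dropped, sel[[j]]$id)
        }
      }
    }
    sel <- sel[alive]
  }
  structure(sel, n_window = sum(keep), dropped = dropped)
}
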