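p <- PARAMS

test_that("random sequence generators are seeded and unbiased", {
  expect_identical(random_sequences(0, 10, seed = 1), list())
  a <- random_sequences(5, 12, seed = 3)
  b <- random_sequences(5, 12, seed = 3)
  expect_identical(lapply(a, `[[`, "bases"), lapply(b, `[[`, "bases"))
  # per-position base frequencies within 3 sigma of 0.25
  big <- random_sequences(1500, 30, seed = 4)
  mat <- do.call(rbind, lapply(big, seq_chars))
  freq <- colMeans(mat == "G")
  se <- sqrt(0.25 * 0.75 / 1500)
  expect_true(all(abs(freq - 0.25) < 3.5 * se))
})

test_that("palindrome-free generator passes the brute-force screen", {
  pf <- palindrome_free_sequences(40, 30, seed = 5)
  for (s in pf) expect_identical(nrow(brute_palindromes(s$bases)), 0L)
  pf2 <- palindrome_free_sequences(40, 30, seed = 5)
  expect_identical(lapply(pf, `[[`, "bases"), lapply(pf2, `[[`, "bases"))
  short <- palindrome_free_sequences(5, 2, seed = 6)
  expect_length(short, 5)
})

test_that("dimerization experiment classifies and tallies coherently", {
  r <- homo_vs_hetero_experiment(n_pairs = 40, length = 25, seed = 9,
                                 params = p)
  expect_equal(r$frac_homo + r$frac_hetero + r$frac_tie, 1)
  expect_identical(nrow(r$table), 40L)
  # identical-pair convention: never counted as heterodimer-favored
  s <- random_sequences(1, 30, seed = 10)[[1]]
  de <- dimer_energies(s, s, p)
  expect_equal(de$dG11, de$dG22)
})

test_that("multimer screen outputs a table, curve rule, and correlation", {
  cfg <- experiment_config(seed = 11, n_seqs = 24, lengths = c(20, 21),
                           min_bin_count = 5)
  ms <- multimer_screen(cfg, p)
  expect_identical(nrow(ms$table), 24L)
  expect_true(all(ms$table$higher_order_fraction >= 0 &
                    ms$table$higher_order_fraction <= 1))
  if (!is.null(ms$curve) && nrow(ms$curve) > 0) {
    expect_true(all(ms$curve$n >= cfg$min_bin_count))
  }
  expect_true(is.numeric(ms$correlation$rho))
})

test_that("dimer gap screen excludes sentinels and reports r", {
  dg <- dimer_gap_screen(n_per_length = 6, lengths = c(20, 25), seed = 12,
                         params = p)
  expect_identical(nrow(dg$table), 12L)
  expect_identical(dg$n_used + dg$n_excluded, 12L)
  fin <- is.finite(dg$table$gap) & is.finite(dg$table$dGpal)
  expect_identical(sum(fin), dg$n_used)
  # degenerate input: pairless sequences only -> undefined r, flagged
  dg0 <- dimer_gap_screen(n_per_length = 0, lengths = 20, seed = 1,
                          extra_seqs = list(rna_seq("AAAAAAAAAA"),
                                            rna_seq("AAAAAAAAAC")),
                          params = p)
  expect_true(is.na(dg0$pearson_r))
  expect_identical(dg0$n_used, 0L)
})

test_that("homodimer gap agrees with an enumeration recomputation", {
  # the Fig-style gap dG11 - 2 dG1 recomputed entirely from the oracle
  set.seed(13)
  for (k in 1:6) {
    s <- random_bases(8)
    dG1 <- partition_function(s, p)$dG
    dG11 <- complex_partition_function(complex_spec(list(s, s)), p)$dG
    lq_conn <- oracle_logq(list(s, s), p, connected_only = TRUE)
    dG11_o <- if (is.infinite(lq_conn)) Inf
    else -p$kT * (lq_conn - p$duplex_init / p$kT - log(2))
    dG1_o <- -p$kT * oracle_logq(s, p)
    if (is.infinite(dG11)) {
      expect_identical(dG11_o, Inf)
    } else {
      expect_equal(dG11 - 2 * dG1, dG11_o - 2 * dG1_o, tolerance = 1e-9)
    }
  }
})

test_that("noneq screen matrix is compositional with zero diagonal", {
  np <- noneq_params(dG_star = -6, kT = p$kT, pfree_mode = "exact")
  gs <- random_sequences(3, 25, seed = 14)
  sc <- noneq_screen(gs, gs, np, p)
  expect_identical(dim(sc$matrix), c(3L, 3L))
  expect_true(all(diag(sc$matrix) == 0))
  v <- homo_vs_hetero_noneq(gs[[1]], gs[[2]], np, p)
  expect_equal(sc$matrix[1, 2], v, tolerance = 1e-12)
  expect_identical(attr(sc, "dG_star"), -6)
  one <- noneq_screen(gs[1], gs[1], np, p)
  expect_identical(unname(one$matrix[1, 1]), 0)
})

test_that("Smith-Waterman matches hand-worked scores", {
  expect_equal(smith_waterman("GCAUGC", "GCAUGC"), 6)
  set.seed(15)
  for (L in c(5, 12, 30)) {
    s <- random_bases(L)
    expect_equal(smith_waterman(s, s), L)
  }
  # frozen hand-computed dynamic-programming table value
  expect_equal(smith_waterman("GCAUGC", "GCUUGC"), 3)
  expect_equal(smith_waterman("A", "G"), 0)
})

test_that("length-matched selection filters and deduplicates", {
  set.seed(16)
  base100 <- random_bases(100)
  seqs <- list(rna_seq(base100, id = "dup1"),
               rna_seq(base100, id = "dup2"),
               rna_seq(random_bases(99), id = "other"),
               rna_seq(random_bases(150), id = "long"))
  sel <- select_length_matched(seqs, 100, window = 5)
  expect_identical(vapply(sel, `[[`, "", "id"), c("dup1", "other"))
  expect_identical(attr(sel, "dropped"), "dup2")
  expect_identical(attr(sel, "n_window"), 3L)
  # strict window: boundary lengths excluded
  sel2 <- select_length_matched(seqs, 105, window = 5)
  expect_false("other" %in% vapply(sel2, `[[`, "", "id")) # 99 = 105 - 6
  expect_length(select_length_matched(seqs, 300, window = 5), 0)
  # no duplicates: input unchanged
  sel3 <- select_length_matched(seqs[3:4], 100, window = 60)
  expect_length(sel3, 2)
})

test_that("config round-trips through YAML", {
  cfg <- experiment_config(seed = 3, n_pairs = 7, lengths = c(20, 22))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 3, n_pairs = 7, lengths = c(20, 22)), path)
  got <- read_config(path)
  expect_identical(got$n_pairs, cfg$n_pairs)
  expect_identical(got$lengths, cfg$lengths)
  yaml::write_yaml(list(bogus_key = 1), path)
  expect_error(read_config(path), "unknown config keys")
})
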