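p <- PARAMS
CENSUS_40MER <- "AGGGCGCCCUGUUCGCAGGGCGCCCUAAUAGCAUGCAAUA"

test_that("survival probability has the double-exponential analytics", {
  np <- noneq_params(dG_star = -12, kT = p$kT)
  expect_equal(survival_probability(-12, np), exp(-1), tolerance = 1e-12)
  expect_equal(survival_probability(-1e6, np), 1)
  expect_equal(survival_probability(1e6, np), 0)
  expect_equal(survival_probability(-12 + 5 * p$kT, np), exp(-exp(5)),
               tolerance = 1e-12)
  # strictly decreasing where representable, non-increasing everywhere
  g <- seq(-14, -10, by = 0.5)
  expect_true(all(diff(survival_probability(g, np)) < 0))
  wide <- seq(-24, 0, by = 1)
  expect_true(all(diff(survival_probability(wide, np)) <= 0))
})

test_that("characteristic time follows t* = exp(-dG*/kT)/k", {
  np0 <- noneq_params(dG_star = 0, kT = p$kT)
  expect_equal(characteristic_time(np0), 1e-7)
  np <- noneq_params(dG_star = -12, kT = 0.6163, attempt_rate_k = 1e7)
  t_star <- characteristic_time(np)
  expect_equal(t_star, exp(12 / 0.6163) / 1e7, tolerance = 1e-12)
  expect_gt(t_star, 25); expect_lt(t_star, 32) # about half a minute
  np2 <- noneq_params(dG_star = -12, kT = 0.6163, attempt_rate_k = 2e7)
  expect_equal(characteristic_time(np2), t_star / 2)
})

test_that("nonequilibrium binding strength sums accessibility-weighted contacts", {
  # pairless pair: empty contact set, +Inf sentinel
  nb0 <- noneq_binding_strength("AAAA", "AAAA", noneq_params(kT = p$kT), p)
  expect_identical(nb0$dG, Inf)
  expect_identical(nrow(nb0$contacts), 0L)
  # single fully-accessible contact at dGij = dG*: dG_noneq = kT exactly
  # (AAAA/UUUU has one 4-nt contact and both molecules are unstructured)
  dGij <- duplex_energy("AAAA", "UUUU", p)
  np <- noneq_params(dG_star = dGij, kT = p$kT, pfree_mode = "exact")
  nb <- noneq_binding_strength("AAAA", "UUUU", np, p)
  expect_identical(nrow(nb$contacts), 1L)
  expect_equal(nb$contacts$p_free_i, 1)
  expect_equal(nb$dG, p$kT, tolerance = 1e-12)
  # the reported free energy is the log of the summed contact weights
  set.seed(701)
  for (k in 1:10) {
    s1 <- random_bases(30); s2 <- random_bases(30)
    np2 <- noneq_params(dG_star = -6, kT = p$kT, pfree_mode = "exact")
    nb2 <- noneq_binding_strength(s1, s2, np2, p)
    w <- sum(nb2$contacts$p_free_i * nb2$contacts$p_free_j *
               exp(-exp((nb2$contacts$dGij + 6) / p$kT)))
    if (w > 0) expect_equal(exp(-nb2$dG / p$kT), w, tolerance = 1e-12)
    else expect_identical(nb2$dG, Inf)
    # symmetric in the two molecules
    nb2r <- noneq_binding_strength(s2, s1, np2, p)
    expect_equal(nb2$weight, nb2r$weight, tolerance = 1e-12)
  }
})

test_that("weight is monotone in dG* with the correct limits", {
  set.seed(702)
  for (k in 1:8) {
    s1 <- random_bases(25); s2 <- random_bases(25)
    ws <- vapply(seq(-14, 2, by = 2), function(g) {
      noneq_binding_strength(
        s1, s2, noneq_params(dG_star = g, kT = p$kT, pfree_mode = "exact"),
        p)$weight
    }, numeric(1))
    expect_true(all(diff(ws) >= -1e-15))
    # dG* -> +Inf limit: all survivals -> 1
    nbL <- noneq_binding_strength(
      s1, s2, noneq_params(dG_star = 1e4, kT = p$kT, pfree_mode = "exact"), p)
    lim <- sum(nbL$contacts$p_free_i * nbL$contacts$p_free_j)
    expect_equal(nbL$weight, lim, tolerance = 1e-12)
    # dG* -> -Inf limit: zero weight
    nbZ <- noneq_binding_strength(
      s1, s2, noneq_params(dG_star = -1e4, kT = p$kT, pfree_mode = "exact"), p)
    expect_identical(nbZ$weight, 0)
  }
})

test_that("palindromic weight is a restriction of the full self sum", {
  np <- noneq_params(dG_star = -4, kT = p$kT, pfree_mode = "exact")
  expect_identical(palindromic_noneq_weight("AAGGAACCAA", np, p), 0)
  set.seed(703)
  for (k in 1:8) {
    s <- random_bases(30)
    wp <- palindromic_noneq_weight(s, np, p)
    wself <- noneq_binding_strength(s, s, np, p)$weight
    expect_lte(wp, wself + 1e-12)
  }
  # single fully-accessible palindrome at its own threshold: Wpal = e^-1
  dGs <- duplex_energy("GCAUGC", "GCAUGC", p)
  np1 <- noneq_params(dG_star = dGs, kT = p$kT, pfree_mode = "exact")
  wp1 <- palindromic_noneq_weight("GCAUGC", np1, p)
  pf <- region_pfree("GCAUGC", c(0, 6), p, mode = "exact")
  expect_equal(wp1, pf^2 * exp(-1), tolerance = 1e-12)
})

test_that("homo-vs-hetero propensity is zero for identical molecules", {
  np <- noneq_params(dG_star = -6, kT = p$kT, pfree_mode = "exact")
  s <- random_sequences(1, 30, seed = 70)[[1]]
  expect_identical(homo_vs_hetero_noneq(s, s, np, p), 0)
  # compositional: equals recomputation from the three contact sums
  s2 <- random_sequences(1, 30, seed = 71)[[1]]
  v <- homo_vs_hetero_noneq(s, s2, np, p)
  w11 <- noneq_binding_strength(s, s, np, p)$weight
  w22 <- noneq_binding_strength(s2, s2, np, p)$weight
  w12 <- noneq_binding_strength(s, s2, np, p)$weight
  expect_equal(v, p$kT * (log(w11) + log(w22) - 2 * log(w12)),
               tolerance = 1e-12)
  # sentinel case: pairless molecule versus a self-binding one
  v2 <- homo_vs_hetero_noneq("AAAAAAAA", "GGCAUGCC", np, p)
  expect_identical(v2, Inf) # heterodimer contacts are impossible
})

test_that("census separates buried from exposed palindromes", {
  np <- noneq_params(dG_star = -5, kT = p$kT, pfree_mode = "exact")
  cen <- accessible_strong_palindromes(CENSUS_40MER, dG_star = -5,
                                       pfree_min = 0.1, p = np, params = p)
  # the fixture has two strong palindromes buried in a perfect stem and one
  # exposed palindrome in an unstructured region; only the latter passes
  expect_identical(cen$count, 1L)
  expect_identical(cen$palindromes$subseq, "GCAUGC")
  expect_gt(cen$palindromes$p_free, 0.9)
  all_pal <- find_palindromes(CENSUS_40MER, params = p)
  expect_gte(nrow(all_pal), 3L)
  # no filters: every palindrome returned
  cen_all <- accessible_strong_palindromes(CENSUS_40MER, dG_star = Inf,
                                           pfree_min = 0, p = np, params = p)
  expect_identical(cen_all$count, nrow(all_pal))
  # palindrome-free sequence: zero
  expect_identical(
    accessible_strong_palindromes("AAGGAACCAA", -5, 0.1, np, p)$count, 0L)
})

test_that("Wpal curves are monotone and reduce to the point evaluation", {
  np <- noneq_params(kT = p$kT, pfree_mode = "exact")
  s <- "GGCAUGCCAAAGCGCAAA"
  cur <- wpal_curve(s, seq(-14, -2, by = 1), np, p)
  expect_true(all(diff(cur$Wpal) >= -1e-15))
  np1 <- noneq_params(dG_star = -6, kT = p$kT, pfree_mode = "exact")
  expect_equal(wpal_curve(s, -6, np1, p)$Wpal,
               palindromic_noneq_weight(s, np1, p), tolerance = 1e-12)
  curve0 <- wpal_curve("AAGGAACCAA", seq(-12, -8, by = 1), np, p)
  expect_true(all(curve0$Wpal == 0))
})
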