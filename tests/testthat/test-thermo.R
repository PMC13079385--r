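p <- PARAMS

test_that("duplex energies equal explicit hand sums over the table", {
  # GC bound to GC: one stack, initiation, symmetry (self-complementary)
  expect_equal(duplex_energy("GC", "GC", p),
               p$duplex_init + p$stack["GC", "CG"] + p$symmetry_correction)
  # GCAUGC bound to itself: pair sequence GC,CG,AU,UA,GC,CG; five stacks;
  # GC helix ends carry no terminal penalty
  hand <- p$duplex_init + p$symmetry_correction +
    p$stack["GC", "CG"] + p$stack["CG", "AU"] + p$stack["AU", "UA"] +
    p$stack["UA", "GC"] + p$stack["GC", "CG"]
  expect_equal(duplex_energy("GCAUGC", "GCAUGC", p), hand)
  # ACAUGU: pair sequence AU,CG,AU,UA,GC,UA; AU/UA helix ends pay the
  # terminal penalty twice
  hand2 <- p$duplex_init + p$symmetry_correction + 2 * p$terminal_au +
    p$stack["AU", "CG"] + p$stack["CG", "AU"] + p$stack["AU", "UA"] +
    p$stack["UA", "GC"] + p$stack["GC", "UA"]
  expect_equal(duplex_energy("ACAUGU", "ACAUGU", p), hand2)
  # non-complementary or too-short input is rejected
  expect_error(duplex_energy("AAAA", "GGGG", p), "not reverse-complementary")
  expect_error(duplex_energy("A", "U", p), "length >= 2")
})

test_that("duplex energy is invariant under reverse complementation", {
  set.seed(401)
  for (k in 1:25) {
    a <- random_bases(sample(2:12, 1))
    b <- revcomp(a)
    expect_equal(duplex_energy(a, b, p),
                 duplex_energy(revcomp(b), revcomp(a), p))
  }
})

test_that("pairless sequences have a trivial ensemble", {
  pf <- partition_function("AAAA", p)
  expect_identical(pf$Q, 1)
  expect_identical(pf$dG, 0)
  pp <- pair_probabilities("AAAA", p)
  expect_true(all(pp$p_pair == 0))
  expect_true(all(pp$p_unpaired == 1))
  smp <- sample_structures("AAAA", 25, seed = 1, params = p)
  expect_true(all(smp$partner == -1L))
  expect_equal(region_pfree("AAAA", c(0, 4), p, mode = "exact"), 1)
})

test_that("partition function matches exhaustive enumeration", {
  set.seed(402)
  for (k in 1:30) {
    s <- random_bases(sample(6:14, 1))
    lq <- partition_function(s, p)$logQ
    expect_equal(lq, oracle_logq(s, p), tolerance = 1e-11, label = s)
  }
  # a sequence with a single legal hairpin has Q strictly above 1
  expect_gt(partition_function("GCAUGC", p)$Q, 1)
})

test_that("hand enumeration of GAAAC: open chain plus one hairpin", {
  en <- enumerate_structures("GAAAC", p)
  expect_length(en$energy, 2)
  sizes <- vapply(en$structures, nrow, integer(1))
  expect_setequal(sizes, c(0L, 1L))
  hp <- en$structures[[which(sizes == 1)]]
  expect_equal(unname(hp[1, ]), c(0L, 4L))
  # its energy is the 3-loop hairpin closure with a GC closing pair
  expect_equal(en$energy[sizes == 1], p$hairpin[4])
})

test_that("enumeration weight sum equals the dynamic program on 12-mers", {
  set.seed(403)
  for (k in 1:5) {
    s <- random_bases(12)
    expect_equal(partition_function(s, p)$logQ, oracle_logq(s, p),
                 tolerance = 1e-11)
  }
})

test_that("pair probabilities match enumeration and normalize", {
  set.seed(404)
  for (s in c("GGGAAACCC", replicate(6, random_bases(sample(6:12, 1))))) {
    got <- pair_probabilities(s, p)
    exp_ <- oracle_pair_probs(s, p)
    expect_lt(max(abs(got$p_pair - exp_$p_pair)), 1e-9)
    expect_lt(max(abs(got$p_unpaired - exp_$p_unpaired)), 1e-9)
    expect_lt(max(abs(got$p_unpaired + rowSums(got$p_pair) - 1)), 1e-9)
  }
})

test_that("stochastic sampling is seeded, reproducible and consistent", {
  a <- sample_structures("GGGAAACCC", 100, seed = 7, params = p)
  b <- sample_structures("GGGAAACCC", 100, seed = 7, params = p)
  expect_identical(a$partner, b$partner)
  # empirical pair frequencies track exact probabilities (3 binomial SE)
  s <- "GGCAUGCAAAGGCAUCC"
  n <- 4000
  smp <- sample_structures(s, n, seed = 8, params = p)
  f <- rnapal:::sample_pair_frequencies(smp)
  pp <- pair_probabilities(s, p)$p_pair
  se <- sqrt(pp * (1 - pp) / n)
  idx <- pp > 0
  expect_gt(mean(abs(f - pp)[idx] <= 3 * se[idx] + 1e-12), 0.95)
})

test_that("region accessibility: exact mode equals enumeration, modes agree", {
  s <- "GGGAAACCCAU"
  for (reg in list(c(0, 3), c(3, 3), c(9, 2), c(0, 11))) {
    ex <- region_pfree(s, reg, p, mode = "exact")
    expect_equal(ex, oracle_region_pfree(s, reg, p), tolerance = 1e-9)
    sm <- region_pfree(s, reg, p, mode = "sampled", n = 4000, seed = 5)
    expect_lt(abs(sm - ex), 3 * sqrt(ex * (1 - ex) / 4000) + 0.01)
  }
  # single-base region coincides with the unpaired probability
  pu <- pair_probabilities(s, p)$p_unpaired
  expect_equal(region_pfree(s, c(4, 1), p, mode = "exact"), unname(pu[5]),
               tolerance = 1e-9)
  expect_error(region_pfree(s, c(9, 5), p), "out of bounds")
})
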