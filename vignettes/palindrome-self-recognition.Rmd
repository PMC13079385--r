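---
title: "Palindromes and RNA self-recognition: models and methods"
author: "rnapal"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `rnapal`: what is computed, under
which assumptions, which knobs matter, and where the package's design was
genuinely open and a choice had to be made.

## The scientific question

Homotypic RNA clusters — assemblies of many copies of one transcript — occur
in germ granules and other condensates. The package operationalizes one
candidate mechanism: *palindromic* (self-complementary) subsequences let a
molecule base-pair with identical copies of itself at regions whose
complement is guaranteed to exist on the partner. Everything in the package
serves three quantities:

1. `dGpal`, an equilibrium aggregate of palindrome self-duplex energies
   (one number per sequence);
2. equilibrium multimerization propensities from multi-strand partition
   functions and mass action;
3. `dG_noneq` and `Wpal`, nonequilibrium initial-contact scores that weight
   each complementary contact by the accessibility of its regions in the
   folded monomers and by a survival probability.

## The energy model

Structures are nested sets of Watson–Crick and G·U pairs (no pseudoknots) on
one or more strands. The loop decomposition assigns:

* stacking free energies for adjacent pairs (Turner 2004 table, including
  wobble stacks);
* size-indexed hairpin, bulge and interior-loop penalties (tables to 30 nt,
  logarithmic extrapolation `E(30) + 1.079 log(n/30)` beyond);
* a terminal penalty of 0.50 kcal/mol for each AU or G·U pair at a helix
  end, charged once per side facing a non-stack loop;
* a duplex initiation penalty of 4.10 kcal/mol per strand beyond the first
  in a complex;
* a symmetry correction of 0.43 kcal/mol for self-complementary duplexes,
  and division of a homomultimer's partition function by its rotational
  symmetry (the two conventions agree: `kT ln 2 = 0.43` at 37 °C).

Deliberate simplifications, chosen to keep the ensemble simple and exactly
enumerable: no dangling ends, no terminal or loop mismatch terms, no coaxial
stacking, no single-bulge helix continuity, multiloops cost zero, and
interior/bulge loops are capped at 30 unpaired nucleotides. Temperature is
fixed at 37 °C (`kT = 0.6163 kcal/mol`), configurable through
`energy_params()`. Absolute agreement with any particular folding engine is
*not* a goal; the package's claims are statistical and every quantitative
test is internal-consistency against brute-force enumeration of the same
model. Minimum hairpin size is 3 nt; hairpins may not contain a strand
break.

Multi-strand ensembles use the standard polymer-graph convention: a
structure of a circular strand ordering is connected exactly when no loop
contains more than one nick; nick-containing (exterior-type) loops carry no
size penalty. Homomultimers need only their single circular ordering;
heteromultimers beyond dimers are out of scope because no experiment here
needs them.

## Algorithms and numerics

The partition function is an `O(n^3)` inside recursion (compiled, Rcpp) over
`Q_b(i,j)` (pair-closed intervals) and a tiled exterior/multiloop state
`Q_x(i,j; branches, nicks)`. Boltzmann weights carry a per-base scaling
factor to avoid overflow on long complexes (a 250-nt 10-mer reaches
`ln Q ~ 400`); the factor cancels from every reported quantity and is
auto-adjusted on overflow or underflow. Stochastic structure sampling is the
usual traceback through the same tables using R's RNG, so `set.seed`
reproducibility holds end to end.

Pair probabilities are computed exactly as `(Q - Q_forbid(i,j))/Q`,
forbidding one pair per dynamic program, and unpaired probabilities
independently as constrained-ratio `Q_mask(i)/Q`. This is `O(n^5)` rather
than an outside algorithm, a deliberate trade: it is only used at small `n`
(tests, accessibilities of short regions), and it makes the row
normalization `p_unpaired(i) + sum_j p_pair(i,j) = 1` a genuine cross-check
between two independent computations rather than an identity of one
algorithm.

Accessibility `p_free` of a region is the probability that *every* base of
the region is unpaired in the monomer ensemble: exactly by constrained
partition function, or as the fraction of sampled structures (default
10,000 samples; large-scale work historically used 10^5, and the default is
configurable via `noneq_params()`). Exact mode is mandatory in the package's
own tests on short sequences.

Mass action for a single species solves
`sum_m m Q_m x1^m = c_total` (1 M standard state) by monotone root-finding
on `log x1`, entirely in log space; strand conservation is verified to
1e-9 and violation is an error, not a warning. The pure-monomer boundary
case (the root at the bracket edge) is handled explicitly.

The enumeration oracle generates every nested structure of a short input
(default cap 16 nt total) and scores it by explicit loop decomposition in R.
It shares the model *definition* with the compiled engine but none of its
code paths, which is what makes the `1e-9` relative agreement tests between
the two informative.

## Region grammar and sentinel conventions

Which regions enter the palindrome sum and the contact sum is genuinely
underdetermined; the package fixes one grammar for both: *maximal* perfect
strict-WC complementary runs of length ≥ 4 (wobble pairs participate in
folding ensembles but not in region identity). `find_palindromes()` and
`find_complementary_pairs()` expose `maximal_only = FALSE` for sensitivity
analysis with all sub-regions; because the Boltzmann sum is dominated
exponentially by the strongest region, `dGpal` is insensitive to the choice.
Using one grammar for both sums keeps `Wpal` a strict restriction of the
full self-contact sum (an invariant the tests check). For two copies of the
same molecule the contact set is the ordered set of region pairs, so a
cross-contact appears twice (once per orientation) and a palindromic
self-contact once.

Empty sums are represented as weight 0, serialized as free energy `inf`:
this keeps `dGpal` and `dG_noneq` total. Differences of sentinel quantities
(the heterodimer-vs-homodimer propensity `2 dG12 - dG11 - dG22`) are
evaluated on weights with all zeros treated as one common limit
`eps -> 0`: the net `eps` exponent decides `+Inf`/`-Inf` and equal counts
cancel, so two identical pairless molecules give exactly 0. Survival factors
below double-precision underflow (`exp(-exp(z))` with `z > ~6.5`) are 0.

## Experiment pipelines and their scales

The pipelines mirror the in-silico experiments the package is built around,
at desk scale by default (full scale is one `experiment_config()` away):

* dimerization preference: 500 random 30-nt pairs per seed (ensembles of
  10^4 are the full-scale setting), classifying `dG11 + dG22` against
  `2 dG12` at 1e-9 kcal/mol resolution with ties reported separately.
  An identical pair is classified homo-favored by convention: a dimer of
  identical molecules is a homodimer, so the heterodimer label cannot apply.
* multimer screen: 300 sequences of 20–25 nt (vs 5×10^4 full-scale), cluster
  sizes to 10, total concentration `4 (20/L)^2.5 mM` so that length effects
  cancel, higher-order defined as ≥ 4 strands, binned curves of width
  2 kcal/mol dropping bins under 30 points. The screen reports a Spearman
  rank correlation: the higher-order fraction is bounded and strongly
  nonlinear in `dGpal`, and palindrome-free sequences carry `dGpal = +Inf`,
  which ranks accommodate without ad hoc imputation.
* dimer gap screen: four lengths, 20 sequences each; the lengths 20/25/30/35
  are the package's choice of a realistic short-RNA range. Pearson `r` is
  computed on finite rows only, with sentinel rows counted and reported.
* near-duplicate removal for natural sequence sets: strict length window,
  all-pairs Smith–Waterman (+1/−2/−2), and a duplicate threshold of
  `0.8 × min(L1, L2)` — near-duplicates score close to their length while
  unrelated sequences of these lengths score an order of magnitude lower,
  so the exact fraction is uncritical; it is a configurable policy.

Every pipeline takes an explicit master seed and fans out sub-seeds
deterministically; reruns are byte-identical, which is why output metadata
headers carry seed, config digest and parameter-table version but no
timestamp by default.

## What the synthetic ensembles do and do not show

The iid-uniform generator reproduces the random-sequence ensembles the
method was characterized on; the rejection sampler produces the
palindrome-free null. Passing tests on these ensembles demonstrate the
mechanism — palindromes driving self-preference — not accuracy on natural
transcripts: real mRNAs have biased composition, modified bases, protein
occupancy, and lengths at which secondary-structure prediction itself
degrades, and `p_free` inherits all of that uncertainty. Natural sequences
enter through FASTA inputs and are treated identically downstream.

## Known limitations

* The energy model omits dangles/mismatch terms; absolute free energies
  differ from engines that include them, by design.
* `pair_probabilities()` is `O(n^5)`; for long sequences use sampling.
* Heterocomplexes beyond dimers and pseudoknots are unsupported.
* The homodimer preference ratio of random 30-mers measures ~1.5–1.7 under
  this model (direction robust, and the palindrome-free null inverts);
  models with richer duplex terms report values nearer 2.
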