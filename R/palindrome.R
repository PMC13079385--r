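# all even-length self-complementary substrings, via expansion around the
# n-1 inter-base centers; returns center-maximal (start, length) pairs 1-based
center_maximal_palindromes <- function(ch) {
  n <- length(ch)
  comp <- unname(WC_COMP[ch])
  out <- list()
  for (p in seq_len(max(n - 1, 0))) { # center between p and p+1
    h <- 0
    while (p - h >= 1 && p + 1 + h <= n && comp[p - h] == ch[p + 1 + h]) {
      h <- h + 1
    }
    if (h > 0) out[[length(out) + 1]] <- c(start = p - h + 1, len = 2 * h)
  }
  out
}

#' Find self-complementary regions (palindromes)
#'
#' Enumerates substrings equal to their own strict Watson-Crick reverse
#' complement (A-U, G-C only; no wobble in the identity test), e.g. GCAUGC or
#' ACAUGU. By default only containment-maximal palindromes are reported; with
#' `maximal_only = FALSE` every palindromic substring of length >=
#' `min_len` is listed. Each palindrome is annotated with the free energy of
#' two copies of it bound to one another ([duplex_energy()], which includes
#' the self-complementarity symmetry correction).
#'
#' @param seq character or [rna_seq].
#' @param min_len minimum palindrome length; must be even (no strict-WC
#'   palindrome has odd length).
#' @param maximal_only drop palindromes contained inside a longer one.
#' @param params an [energy_params()] object.
#' @return data.frame with columns `seq_id`, `start` (0-based), `length`,
#'   `subseq`, `dGs` (kcal/mol), sorted by `start`; zero rows if none.
#' @examples
#' find_palindromes("GCAUGC")
#' @export
find_palindromes <- function(seq, min_len = 4, maximal_only = TRUE,
                             params = default_params()) {
  if (min_len %% 2 != 0 || min_len < 2) {
    stop("min_len must be even and >= 2 (strict-WC palindromes have even length)")
  }
  s <- as_rna(seq)
  ch <- seq_chars(s)
  cand <- center_maximal_palindromes(ch)
  regs <- list()
  for (cm in cand) {
    if (!maximal_only) {
      # every concentric sub-palindrome of this center
      h_max <- cm["len"] %/% 2
      for (h in seq_len(h_max)) {
        if (2 * h >= min_len) {
          regs[[length(regs) + 1]] <- c(cm["start"] + (h_max - h), 2 * h)
        }
      }
    } else if (cm["len"] >= min_len) {
      regs[[length(regs) + 1]] <- c(cm["start"], cm["len"])
    }
  }
  if (length(regs) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      length = integer(0), subseq = character(0),
                      dGs = numeric(0)))
  }
  m <- do.call(rbind, regs)
  if (maximal_only && nrow(m) > 1) {
    contained <- vapply(seq_len(nrow(m)), function(r) {
      any(m[-r, 1] <= m[r, 1] & m[-r, 1] + m[-r, 2] >= m[r, 1] + m[r, 2])
    }, logical(1))
    m <- m[!contained, , drop = FALSE]
  }
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  sub <- vapply(seq_len(nrow(m)), function(r) {
    paste(ch[m[r, 1]:(m[r, 1] + m[r, 2] - 1)], collapse = "")
  }, character(1))
  dGs <- vapply(sub, function(x) duplex_energy(x, x, params), numeric(1),
                USE.NAMES = FALSE)
  data.frame(seq_id = s$id, start = as.integer(m[, 1] - 1L),
             length = as.integer(m[, 2]), subseq = sub, dGs = dGs)
}

#' Palindrome binding strength of a sequence
#'
#' Aggregates the self-duplex free energies of all palindromic regions into a
#' single binding strength by a Boltzmann log-sum:
#' `dGpal = -kT log( sum_s exp(-dGs/kT) )`. A sequence without palindromes
#' has zero aggregate weight and returns `+Inf`.
#'
#' @inheritParams find_palindromes
#' @return `dGpal` in kcal/mol (`+Inf` sentinel for the empty set).
#' @export
palindrome_binding_strength <- function(seq, params = default_params(),
                                        min_len = 4, maximal_only = TRUE) {
  pal <- find_palindromes(seq, min_len, maximal_only, params)
  if (nrow(pal) == 0) return(Inf)
  -params$kT * logsumexp(-pal$dGs / params$kT)
}

#' Find complementary region pairs between two molecules
#'
#' All maximal perfectly Watson-Crick-complementary region pairs of length at
#' least `min_region_len`: region i on molecule 1 base-pairs region j on
#' molecule 2 along a full helix. Each pair carries its duplex free energy.
#' Comparing a sequence against itself enumerates the ordered contact set of
#' two copies of the same molecule; entries with `start1 == start2` and
#' `self = TRUE` are exactly the palindromic self-contacts.
#'
#' @param seq1,seq2 the two molecules (may be the same sequence).
#' @param min_region_len minimum helix length.
#' @param maximal_only report only runs not extendable on either side; with
#'   `FALSE`, every sub-region pair of length >= `min_region_len` too.
#' @param params an [energy_params()] object.
#' @return data.frame with columns `start1`, `start2` (0-based), `length`,
#'   `dGij` (kcal/mol) and `self` (palindromic self-contact in self mode).
#' @export
find_complementary_pairs <- function(seq1, seq2, min_region_len = 4,
                                     maximal_only = TRUE,
                                     params = default_params()) {
  s1 <- as_rna(seq1); s2 <- as_rna(seq2)
  c1 <- seq_chars(s1); c2 <- seq_chars(s2)
  n1 <- length(c1); n2 <- length(c2)
  # M[x, y]: base x of molecule 1 can strict-WC pair base y of molecule 2
  M <- outer(unname(WC_COMP[c1]), c2, "==")
  self_mode <- identical(s1$bases, s2$bases)
  regs <- list()
  add <- function(x0, y_end, len) { # x runs up, y runs down; 1-based
    regs[[length(regs) + 1]] <<- c(x0, y_end, len)
  }
  for (d in 2:(n1 + n2)) { # anti-diagonal x + y = d
    xs <- max(1, d - n2):min(n1, d - 1)
    if (length(xs) < min_region_len) next
    run <- M[cbind(xs, d - xs)]
    r <- rle(run)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_region_len) next
      x_end <- xs[ends[k]]
      len <- r$lengths[k]
      x0 <- x_end - len + 1
      if (maximal_only) {
        add(x0, d - x_end, len)
      } else {
        for (l2 in min_region_len:len) for (off in 0:(len - l2)) {
          add(x0 + off, d - (x0 + off + l2 - 1), l2)
        }
      }
    }
  }
  if (length(regs) == 0) {
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      length = integer(0), dGij = numeric(0),
                      self = logical(0)))
  }
  m <- unique(do.call(rbind, regs))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dG <- numeric(nrow(m))
  selfflag <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    a <- paste(c1[m[r, 1]:(m[r, 1] + m[r, 3] - 1)], collapse = "")
    b <- paste(c2[m[r, 2]:(m[r, 2] + m[r, 3] - 1)], collapse = "")
    dG[r] <- duplex_energy(a, b, params)
    selfflag[r] <- self_mode && m[r, 1] == m[r, 2]
  }
  data.frame(start1 = as.integer(m[, 1] - 1L), start2 = as.integer(m[, 2] - 1L),
             length = as.integer(m[, 3]), dGij = dG, self = selfflag)
}
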