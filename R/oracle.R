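# Brute-force structure enumeration and explicit loop-decomposition energies.
# This is the package's independent oracle: it shares the model *definition*
# with the dynamic program (same tables, same legality rules) but none of its
# recursions.

# Concatenate one or more strands; nicks are 1-based boundaries b meaning
# "between positions b and b+1".
concat_strands <- function(strands) {
  if (inherits(strands, "rna_seq") || is.character(strands)) {
    strands <- list(strands)
  }
  seqs <- lapply(strands, as_rna)
  lens <- vapply(seqs, function(s) s$n, integer(1))
  list(seqs = seqs,
       chars = unlist(lapply(seqs, seq_chars), use.names = FALSE),
       ints = unlist(lapply(seqs, seq_ints), use.names = FALSE),
       n = sum(lens),
       m = length(seqs),
       nicks1 = if (length(seqs) > 1) cumsum(lens)[-length(lens)] else integer(0))
}

hairpin_energy <- function(u, params) {
  if (u <= 30) params$hairpin[u + 1]
  else params$hairpin[31] + params$lxc * log(u / 30)
}

#' Energy of one secondary structure
#'
#' Explicit loop decomposition of a nested structure on one or more strands:
#' stacks, hairpin/bulge/interior penalties, terminal AU/GU penalties at helix
#' ends, zero-cost multiloops and nick-containing loops. Used as the
#' independent oracle against the dynamic-programming partition function.
#'
#' @param pairs two-column matrix of 0-based pair indices (i < j) on the
#'   concatenation of `strands`; zero rows for the open chain.
#' @param strands an [rna_seq] (or character), or a list of them (a nicked
#'   complex in the given order).
#' @param params an [energy_params()] object.
#' @return list with `energy` (kcal/mol, `NA` if the structure is illegal
#'   under the model) and `connected` (are all strands linked through pairs,
#'   with every loop containing at most one nick).
#' @export
structure_energy <- function(pairs, strands, params = default_params()) {
  cc <- concat_strands(strands)
  n <- cc$n
  pairs <- matrix(as.integer(pairs), ncol = 2) + 1L # to 1-based
  bad <- list(energy = NA_real_, connected = FALSE)
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] >= pairs[, 2]) || any(pairs < 1) || any(pairs > n)) {
      stop("malformed pair list")
    }
    if (anyDuplicated(c(pairs))) stop("an index occurs in more than one pair")
  }
  pt <- rep(NA_integer_, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pt[r] <- pair_type(cc$chars[pairs[r, 1]], cc$chars[pairs[r, 2]])
    if (is.na(pt[r])) return(bad)
  }
  # nesting check + children via a scan over sorted pairs
  if (nrow(pairs) > 1) {
    o <- order(pairs[, 1])
    p <- pairs[o, , drop = FALSE]
    stk <- integer(0)
    for (r in seq_len(nrow(p))) {
      while (length(stk) > 0 && p[stk[length(stk)], 2] < p[r, 1]) {
        stk <- stk[-length(stk)]
      }
      if (length(stk) > 0 && p[r, 2] > p[stk[length(stk)], 2]) {
        stop("pairs are not nested (pseudoknot)")
      }
      stk <- c(stk, r)
    }
  }
  au_pen <- function(t) if (t >= 3) params$terminal_au else 0
  nick_between <- function(a, b) { # nick boundaries within [a, b]
    if (a > b) return(0L)
    sum(cc$nicks1 >= a & cc$nicks1 <= b)
  }
  # direct children of interval (i, j) among pairs (exclusive)
  children_of <- function(i, j) {
    inside <- which(pairs[, 1] > i & pairs[, 2] < j)
    if (length(inside) == 0) return(integer(0))
    keep <- vapply(inside, function(r) {
      !any(pairs[inside, 1] < pairs[r, 1] & pairs[inside, 2] > pairs[r, 2])
    }, logical(1))
    inside[keep]
  }
  loop_nicks <- function(i, j, kids) {
    tot <- nick_between(i, j - 1)
    for (r in kids) tot <- tot - nick_between(pairs[r, 1], pairs[r, 2] - 1)
    tot
  }
  energy <- 0
  connected <- TRUE
  # interior loops of each pair
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- children_of(i, j)
    nk <- loop_nicks(i, j, kids)
    if (nk >= 2) connected <- FALSE # a loop with 2+ nicks splits the complex
    if (length(kids) == 0) {
      u <- j - i - 1
      if (nk == 0) { # hairpin
        if (u < params$min_hairpin) return(bad)
        energy <- energy + hairpin_energy(u, params) + au_pen(pt[r])
      } else {
        energy <- energy + au_pen(pt[r]) # nick loop, no size penalty
      }
    } else if (length(kids) == 1) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      u1 <- k - i - 1; u2 <- j - l - 1
      if (nk == 0) {
        if (u1 == 0 && u2 == 0) {
          energy <- energy + params$stack[pt[r], pt[kids]]
        } else if (u1 + u2 <= params$max_interior_loop) {
          tab <- if (u1 == 0 || u2 == 0) params$bulge else params$internal
          energy <- energy + tab[u1 + u2 + 1] +
            au_pen(pt[r]) + au_pen(pt[kids])
        } else {
          return(bad) # nick-free interior loop beyond the cap: excluded
        }
      } else {
        energy <- energy + au_pen(pt[r]) + au_pen(pt[kids])
      }
    } else {
      # multiloop (or nicked multiloop): no size cost
      energy <- energy + au_pen(pt[r]) + sum(vapply(kids, function(k)
        au_pen(pt[k]), numeric(1)))
    }
  }
  # exterior loop
  top <- if (nrow(pairs) == 0) integer(0) else children_of(0L, n + 1L)
  nk_ext <- loop_nicks(0L, n + 1L, top)
  if (nk_ext > 0) connected <- FALSE
  energy <- energy + sum(vapply(top, function(k) au_pen(pt[k]), numeric(1)))
  list(energy = energy, connected = connected)
}

#' Exhaustively enumerate nested secondary structures
#'
#' Every legal nested structure of a strand (or a small nicked complex),
#' exactly once, with its energy under the same model the dynamic program
#' uses. Intended as a test oracle; guarded by a length cap.
#'
#' @inheritParams structure_energy
#' @param cap maximum total length (guards against combinatorial blow-up).
#' @return list with `structures` (list of 0-based pair matrices), `energy`
#'   (kcal/mol, `NA` dropped: only legal structures are returned) and
#'   `connected` (logical vector).
#' @export
enumerate_structures <- function(strands, params = default_params(),
                                 cap = 16) {
  cc <- concat_strands(strands)
  if (cc$n > cap) {
    stop("total length ", cc$n, " exceeds enumeration cap ", cap)
  }
  n <- cc$n
  P <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) P[i, j] <- !is.na(pair_type(cc$chars[i], cc$chars[j]))
  }
  nickfree <- function(a, b) !any(cc$nicks1 >= a & cc$nicks1 <= b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(NULL))
    key <- sprintf("%d_%d", i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)
    for (l in (i + 1L):j) {
      if (!P[i, l]) next
      if (l - i - 1L < params$min_hairpin && nickfree(i, l - 1L)) next
      inner <- rec(i + 1L, l - 1L)
      outer <- rec(l + 1L, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, l), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  all_s <- rec(1L, n)
  res_e <- numeric(0); res_c <- logical(0); res_s <- list()
  for (st in all_s) {
    m0 <- if (is.null(st)) matrix(integer(0), 0, 2) else st - 1L
    en <- structure_energy(m0, strands, params)
    if (is.na(en$energy)) next
    res_s[[length(res_s) + 1L]] <- m0
    res_e <- c(res_e, en$energy)
    res_c <- c(res_c, en$connected)
  }
  list(structures = res_s, energy = res_e, connected = res_c)
}
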