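# Shared oracles for the suite, independent of the engine's recursions.

PARAMS <- default_params()

# log partition function by exhaustive enumeration
oracle_logq <- function(strands, params = PARAMS, connected_only = FALSE,
                        cap = 16) {
  en <- enumerate_structures(strands, params, cap = cap)
  e <- en$energy
  if (connected_only) e <- e[en$connected]
  if (length(e) == 0) return(-Inf)
  m <- max(-e / params$kT)
  m + log(sum(exp(-e / params$kT - m)))
}

# pair and unpaired probabilities by exhaustive enumeration
oracle_pair_probs <- function(seq, params = PARAMS) {
  s <- rnapal::rna_seq(seq)
  en <- enumerate_structures(s, params)
  w <- exp(-en$energy / params$kT)
  Q <- sum(w)
  n <- s$n
  pp <- matrix(0, n, n)
  pu <- rep(0, n)
  for (k in seq_along(w)) {
    st <- en$structures[[k]]
    unp <- rep(TRUE, n)
    if (nrow(st) > 0) for (r in seq_len(nrow(st))) {
      i <- st[r, 1] + 1; j <- st[r, 2] + 1
      pp[i, j] <- pp[i, j] + w[k]; pp[j, i] <- pp[j, i] + w[k]
      unp[c(i, j)] <- FALSE
    }
    pu[unp] <- pu[unp] + w[k]
  }
  list(p_pair = pp / Q, p_unpaired = pu / Q)
}

# region accessibility by exhaustive enumeration
oracle_region_pfree <- function(seq, region, params = PARAMS) {
  s <- rnapal::rna_seq(seq)
  en <- enumerate_structures(s, params)
  w <- exp(-en$energy / params$kT)
  idx <- region[1] + seq_len(region[2]) # 1-based bases of the region
  free <- vapply(en$structures, function(st) {
    nrow(st) == 0 || !any((st + 1) %in% idx)
  }, logical(1))
  sum(w[free]) / sum(w)
}

# every palindromic substring of length >= min_len, by quadratic scan over
# (start, even length) with whole-string reverse complement lookup
brute_palindromes <- function(bases, min_len = 4) {
  n <- nchar(bases)
  rc <- revcomp(bases)
  out <- NULL
  for (len in seq(min_len, n, by = 2)) {
    for (i in seq_len(n - len + 1)) {
      sub <- substr(bases, i, i + len - 1)
      mirror <- substr(rc, n - (i + len - 1) + 1, n - i + 1)
      if (sub == mirror) {
        out <- rbind(out, c(start = i - 1L, length = as.integer(len)))
      }
    }
  }
  if (is.null(out)) {
    return(matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("start", "length"))))
  }
  storage.mode(out) <- "integer"
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# canonical (start, length) integer matrix from a palindrome data.frame
pal_matrix <- function(df) {
  unname(cbind(as.integer(df$start), as.integer(df$length)))
}

# containment-maximal rows of a (start, length) palindrome matrix
maximal_rows <- function(m) {
  if (nrow(m) < 2) return(m)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[-r, 1] <= m[r, 1] & m[-r, 1] + m[-r, 2] >= m[r, 1] + m[r, 2])
  }, logical(1))
  m[keep, , drop = FALSE]
}

random_bases <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}
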