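RNA_BASES <- c("A", "C", "G", "U")
# strict Watson-Crick complement
WC_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Create an RNA sequence object
#'
#' An `rna_seq` is an identified 5'-to-3' string over the alphabet A, C, G, U.
#' DNA-style input containing T is rejected unless `transliterate_t = TRUE`,
#' in which case T is converted to U.
#'
#' @param bases character scalar with the sequence (case-insensitive), or an
#'   existing `rna_seq` (returned unchanged apart from `id`).
#' @param id short text label.
#' @param transliterate_t convert T to U instead of rejecting it.
#' @return an object of class `rna_seq` with fields `id`, `bases` and `n`.
#' @examples
#' rna_seq("gcaugc", id = "pal6")
#' @export
rna_seq <- function(bases, id = "seq", transliterate_t = FALSE) {
  if (inherits(bases, "rna_seq")) {
    bases$id <- id
    return(bases)
  }
  stopifnot(is.character(bases), length(bases) == 1)
  b <- toupper(bases)
  if (transliterate_t) b <- gsub("T", "U", b, fixed = TRUE)
  if (nchar(b) < 1) stop("sequence must have length >= 1")
  chars <- strsplit(b, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), RNA_BASES)
  if (length(bad) > 0) {
    stop("invalid characters in RNA sequence: ", paste(bad, collapse = ", "))
  }
  structure(list(id = as.character(id), bases = b, n = nchar(b)),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  b <- if (x$n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<rna_seq> %s (%d nt)\n  5'-%s-3'\n", x$id, x$n, b))
  invisible(x)
}

#' @export
as.character.rna_seq <- function(x, ...) x$bases

seq_chars <- function(seq) strsplit(as_rna(seq)$bases, "", fixed = TRUE)[[1]]

# integer encoding used by the compiled engine: A=1 C=2 G=3 U=4
seq_ints <- function(seq) {
  match(seq_chars(seq), RNA_BASES)
}

as_rna <- function(x, id = "seq") {
  if (inherits(x, "rna_seq")) x else rna_seq(x, id = id)
}

#' Reverse complement of an RNA sequence
#'
#' Strict Watson-Crick complement (A-U, C-G), reversed.
#'
#' @param seq an `rna_seq` or character scalar.
#' @return a character scalar.
#' @examples
#' revcomp("GCAUGC") # palindromic: equals its input
#' @export
revcomp <- function(seq) {
  ch <- seq_chars(seq)
  paste(rev(unname(WC_COMP[ch])), collapse = "")
}

#' Random iid-uniform RNA sequences
#'
#' Each nucleotide is drawn independently and uniformly from A, C, G, U
#' (25% each).
#'
#' @param n number of sequences (0 allowed).
#' @param length sequence length in nt.
#' @param seed integer seed; the call is reproducible and leaves the caller's
#'   RNG state untouched.
#' @return list of [rna_seq] objects.
#' @export
random_sequences <- function(n, length, seed) {
  stopifnot(n >= 0, length >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rna_seq(paste(sample(RNA_BASES, length, replace = TRUE), collapse = ""),
              id = sprintf("rand_L%d_%04d", length, i))
    })
  })
}

#' Random RNA sequences free of palindromes
#'
#' Rejection sampling: iid-uniform sequences are redrawn until they contain no
#' palindrome of length at least `min_len`.
#'
#' @inheritParams random_sequences
#' @param min_len minimum palindrome length screened against (even, >= 2).
#' @param max_attempts per-sequence cap on redraws before giving up.
#' @return list of [rna_seq] objects, each verified palindrome-free.
#' @export
palindrome_free_sequences <- function(n, length, seed, min_len = 4,
                                      max_attempts = 100000) {
  stopifnot(n >= 0, length >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (att in seq_len(max_attempts)) {
        s <- paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
        if (!has_palindrome(s, min_len)) {
          return(rna_seq(s, id = sprintf("palfree_L%d_%04d", length, i)))
        }
      }
      stop("rejection sampling failed after ", max_attempts,
           " attempts (length ", length, ")")
    })
  })
}

# fast check used by the rejection sampler: any strict-WC palindrome of
# length >= min_len is detectable from half-length min_len/2 seeds
has_palindrome <- function(bases, min_len = 4) {
  ch <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  n <- length(ch)
  h <- min_len %/% 2
  if (min_len %% 2 != 0 || min_len < 2) stop("min_len must be even and >= 2")
  if (n < min_len) return(FALSE)
  comp <- WC_COMP[ch]
  for (p in h:(n - h)) { # center between p and p+1 (1-based)
    ok <- TRUE
    for (k in seq_len(h)) {
      if (comp[p - k + 1] != ch[p + k]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}
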