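PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")
KB_KCAL <- 0.0019872 # kcal / (mol K)

pair_type <- function(x, y) {
  match(paste0(x, y), PAIR_NAMES) # NA if not WC or wobble
}

#' Load nearest-neighbor energy parameters
#'
#' Reads the plain-text parameter table shipped with the package (Turner 2004
#' free energies at 37 C by default) and returns a validated parameter object.
#' The table holds helix stacking free energies for all Watson-Crick and G.U
#' pair steps (keyed by 5'-to-3' dimers), size-indexed hairpin, bulge and
#' interior loop penalties (extrapolated logarithmically beyond 30 nt), the
#' duplex initiation penalty, the terminal AU/GU penalty, and the symmetry
#' correction for self-complementary duplexes.
#'
#' @param file path to a parameter table; default: the shipped table.
#' @param temperature temperature in kelvin. Loop and stack free energies are
#'   used as tabulated (37 C values); the temperature sets kBT for all
#'   Boltzmann weights.
#' @return object of class `rna_energy_params`.
#' @export
energy_params <- function(file = NULL, temperature = NULL) {
  file <- file %||% system.file("extdata", "nn_params_v1.tsv",
                                package = "rnapal", mustWork = TRUE)
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "numeric"))
  names(tab) <- c("section", "key1", "key2", "value")
  sc <- tab[tab$section == "scalar", ]
  scalar <- setNames(sc$value, sc$key1)
  temperature <- temperature %||% unname(scalar[["temperature"]])

  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  st <- tab[tab$section == "stack", ]
  for (r in seq_len(nrow(st))) {
    top <- strsplit(st$key1[r], "")[[1]] # bases i, i+1
    bot <- strsplit(st$key2[r], "")[[1]] # bases j-1, j
    p1 <- pair_type(top[1], bot[2])
    p2 <- pair_type(top[2], bot[1])
    if (is.na(p1) || is.na(p2)) stop("bad stack key: ", st$key1[r], "/", st$key2[r])
    stack[p1, p2] <- st$value[r]
  }
  if (anyNA(stack)) stop("incomplete stack table")

  loop_table <- function(section, min_size) {
    v <- rep(Inf, 31) # index = size + 1, sizes 0..30
    rows <- tab[tab$section == section, ]
    v[as.integer(rows$key1) + 1] <- rows$value
    if (any(!is.finite(v[(min_size + 1):31]))) {
      stop("incomplete ", section, " table")
    }
    v
  }
  min_hairpin <- as.integer(scalar[["min_hairpin"]])
  p <- structure(list(
    temperature = temperature,
    kT = KB_KCAL * temperature,
    stack = stack,
    hairpin = loop_table("hairpin", min_hairpin),
    bulge = loop_table("bulge", 1L),
    internal = loop_table("internal", 2L),
    lxc = unname(scalar[["lxc"]]),
    duplex_init = unname(scalar[["duplex_init"]]),
    terminal_au = unname(scalar[["terminal_au"]]),
    symmetry_correction = unname(scalar[["symmetry_correction"]]),
    min_hairpin = min_hairpin,
    max_interior_loop = as.integer(scalar[["max_interior_loop"]]),
    version = basename(file)
  ), class = "rna_energy_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(abs(p$kT - KB_KCAL * p$temperature) < 1e-9)
  stopifnot(p$symmetry_correction > 0)
  stopifnot(p$min_hairpin >= 1, p$max_interior_loop >= 2)
  # physical 180-degree rotation symmetry of the stack table
  revp <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU", AU = "UA", UA = "AU")
  for (a in PAIR_NAMES) for (b in PAIR_NAMES) {
    stopifnot(p$stack[a, b] == p$stack[revp[b], revp[a]])
  }
  # logarithmic extrapolation beyond the table end is non-decreasing
  stopifnot(p$lxc > 0)
  invisible(p)
}

#' @export
print.rna_energy_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<rna_energy_params> %s\n  T = %.2f K (kBT = %.4f kcal/mol)\n",
    "  duplex init %.2f, terminal AU/GU %.2f, symmetry %.2f kcal/mol\n",
    "  min hairpin %d nt, interior loops capped at %d nt\n"),
    x$version, x$temperature, x$kT, x$duplex_init, x$terminal_au,
    x$symmetry_correction, x$min_hairpin, x$max_interior_loop))
  invisible(x)
}

# parameter list consumed by the compiled engine
cpp_params <- function(p) {
  list(kT = p$kT, stack = unname(p$stack), hairpin = p$hairpin,
       bulge = p$bulge, internal = p$internal, lxc = p$lxc,
       terminal_au = p$terminal_au, min_hairpin = p$min_hairpin,
       max_interior_loop = p$max_interior_loop)
}

.rnapal_env <- new.env(parent = emptyenv())

#' Default energy parameters (cached)
#' @return the shipped `rna_energy_params` object.
#' @export
default_params <- function() {
  if (is.null(.rnapal_env$params)) .rnapal_env$params <- energy_params()
  .rnapal_env$params
}
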