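#' Read RNA sequences from a FASTA file
#'
#' Parses FASTA via Biostrings, normalizes case, and validates the alphabet.
#' DNA-style T is transliterated to U with a warning by default (set
#' `transliterate_t = FALSE` to reject it).
#'
#' @param path FASTA file.
#' @param transliterate_t convert T to U (with one warning) instead of
#'   rejecting it.
#' @return list of [rna_seq] in file order; empty list (with a warning) for
#'   an empty file.
#' @export
read_fasta <- function(path, transliterate_t = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e))
                  })
  if (length(set) == 0) {
    warning("no records in FASTA file: ", path)
    return(list())
  }
  out <- vector("list", length(set))
  warned <- FALSE
  for (k in seq_along(set)) {
    b <- toupper(as.character(set[[k]]))
    if (grepl("T", b, fixed = TRUE)) {
      if (!transliterate_t) stop("record ", names(set)[k], " contains T")
      if (!warned) {
        warning("T transliterated to U in ", path)
        warned <- TRUE
      }
    }
    id <- sub("\\s.*$", "", names(set)[k])
    out[[k]] <- rna_seq(b, id = id, transliterate_t = TRUE)
  }
  out
}

#' Reproducibility metadata for an output table
#'
#' @param seed the seed the run used.
#' @param config a named list of configuration values; its digest is stable
#'   under key reordering.
#' @param params an [energy_params()] object (for the table version).
#' @param timestamp include a wall-clock timestamp (off by default so that
#'   reruns are byte-identical).
#' @return named character vector of metadata fields.
#' @export
run_metadata <- function(seed = NA, config = list(),
                         params = default_params(), timestamp = FALSE) {
  keys <- sort(names(config))
  digest <- fnv1a32(paste0(keys, "=", vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1))))
  md <- c(tool = paste0("rnapal ",
                        as.character(utils::packageVersion("rnapal"))),
          seed = as.character(seed), config_digest = digest,
          parameter_table = params$version)
  if (timestamp) md <- c(md, timestamp = format(Sys.time(), tz = "UTC"))
  md
}

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.infinite(x), ifelse(x > 0, "inf", "-inf"),
                  ifelse(is.na(x), "NA", format(x, digits = 10)))
    return(out)
  }
  as.character(x)
}

#' Write a result table with a metadata header
#'
#' Tab-separated output with `#`-prefixed metadata lines; numeric columns at
#' 10 significant digits, infinity sentinels serialized as `inf`/`-inf`.
#' [read_result_table()] restores them losslessly.
#'
#' @param df data.frame.
#' @param path output file.
#' @param metadata named character vector, e.g. from [run_metadata()].
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, metadata = run_metadata()) {
  if (identical(path, "-")) {
    con <- stdout()
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  for (k in names(metadata)) {
    cat(sprintf("# %s: %s\n", k, metadata[[k]]), file = con)
  }
  out <- as.data.frame(lapply(df, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (nrow(df) == 0) out <- df[0, , drop = FALSE]
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path file path.
#' @return data.frame with numeric columns (including `inf` sentinels)
#'   restored; metadata header returned in attribute `metadata`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  md <- setNames(sub("^# [^:]+: ?", "", meta_lines),
                 sub("^# ([^:]+):.*$", "\\1", meta_lines))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.character(v)) next
    w <- v
    w[w == "inf"] <- "Inf"; w[w == "-inf"] <- "-Inf"
    num <- suppressWarnings(as.numeric(w))
    if (!any(is.na(num) & !(w %in% c("NA", NA)))) df[[j]] <- num
  }
  attr(df, "metadata") <- md
  df
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return an [experiment_config()] object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, vals)
}
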