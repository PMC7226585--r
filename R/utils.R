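#' @keywords internal
"_PACKAGE"

# ---- sequence helpers -------------------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Upper-cases and maps T to U. Any character outside {A,C,G,U} raises an
#' error reporting the first offending position.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector over {A,C,G,U}.
#' @export
as_rna <- function(x, what = "sequence") {
  x <- chartr("acgut T", "ACGUU U", toupper(x))
  x <- gsub(" ", "", x, fixed = TRUE)
  x <- chartr("T", "U", x)
  bad <- regexpr("[^ACGU]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character in %s %d at position %d: '%s'",
                 what, i, bad[i], substr(x[i], bad[i], bad[i])))
  }
  x
}

#' Reverse complement of an RNA string
#' @param x character vector over {A,C,G,U}.
#' @return reverse-complemented character vector.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# complement of a single base
rna_comp1 <- function(b) chartr("ACGU", "UGCA", b)

# ---- seeded evaluation ------------------------------------------------------

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps user-facing functions free of
# global RNG side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# ---- tabular IO -------------------------------------------------------------

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the conventions used throughout the package:
#' tab-separated, header line, no quoting, no row names.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv()` returns a data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path input path.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# ---- minimal TOML-subset config reader -------------------------------------

#' Read a flat TOML-subset configuration file
#'
#' Supports the subset of TOML used by pipeline configs: `[section]` headers,
#' `key = value` pairs with string, integer, float, boolean and flat array
#' values, and `#` comments. Nested tables and multi-line values are not
#' supported.
#'
#' @param path file path.
#' @return nested named list (one element per section; top-level keys before
#'   any section header live at the top of the list).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  parse_scalar <- function(v) {
    v <- trimws(v)
    if (grepl('^".*"$', v) || grepl("^'.*'$", v)) return(substr(v, 2, nchar(v) - 1))
    if (v %in% c("true", "false")) return(v == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) return(n)
    v
  }
  parse_value <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      inner <- trimws(substr(v, 2, nchar(v) - 1))
      if (!nzchar(inner)) return(list())
      parts <- strsplit(inner, ",")[[1]]
      vals <- lapply(parts, parse_scalar)
      return(unlist(vals))
    }
    parse_scalar(v)
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- trimws(substr(ln, 2, nchar(ln) - 1))
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- parse_value(substr(ln, eq + 1, nchar(ln)))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  out
}
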