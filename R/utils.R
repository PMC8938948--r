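# Internal helpers shared across modules.

# Valid sequence alphabet. Ambiguity codes other than N are rejected because
# hotspot and optimizer semantics are undefined for them.
.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' @noRd
.seq_chars <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Validate and normalize a raw DNA string.
#'
#' Upper-cases, converts U to T (with a warning), and rejects ambiguity codes
#' other than N.
#' @noRd
.normalize_sequence <- function(sequence, id = "<sequence>") {
  s <- toupper(sequence)
  if (grepl("U", s, fixed = TRUE)) {
    warning(sprintf("sequence '%s': U converted to T", id), call. = FALSE)
    s <- gsub("U", "T", s, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), .SEQ_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf(
      "sequence '%s' contains unsupported characters: %s (only A/C/G/T/N allowed)",
      id, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  if (nchar(s) == 0) stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  s
}

#' @noRd
.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Run code with a temporary RNG seed, restoring prior RNG state.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' GC fraction of a character vector of bases (N ignored in the denominator).
#' @noRd
.gc_fraction <- function(chars) {
  informative <- chars != "N"
  if (!any(informative)) return(NA_real_)
  sum(chars == "G" | chars == "C") / sum(informative)
}

# Spans are stored 0-based half-open: c(start, end), end exclusive.

#' @noRd
.span_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

#' @noRd
.span_within <- function(inner_start, inner_end, outer_start, outer_end) {
  inner_start >= outer_start & inner_end <= outer_end
}

#' Parse "key = value" plain-text config lines into a named character vector.
#' Lines starting with '#' and blank lines are ignored.
#' @noRd
.parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(character(0))
  hits <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(hits, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(hits, `[`, "", 2L))
  vals <- trimws(vapply(hits, `[`, "", 3L))
  stats::setNames(vals, keys)
}
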