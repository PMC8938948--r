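# Parsing of MEME-minimal motif files, PPM -> log-odds PSSM conversion, and
# double-stranded scanning for high-scoring motif sites (methylation motifs
# by default, any user PSSM set in general).

.BASES <- c("A", "C", "G", "T")

#' Parse motifs from a MEME minimal-format file
#'
#' Reads position probability matrices (PPMs) from MEME minimal format.
#' Both the standard layout (`MOTIF name` followed by a
#' `letter-probability matrix: alength= 4 w= ... nsites= ... E= ...` header
#' and one probability row per motif position, columns ordered A,C,G,T) and
#' the compact layout (a name line, then a line with alphabet length, width,
#' nsites and E-value, then the rows) are accepted. A
#' `Background letter frequencies` section, if present, is honored;
#' otherwise a uniform background of 0.25 per base is assumed.
#'
#' @param path Path to a motif file (or a character vector of its lines via
#'   `text`).
#' @param text Optional character vector of lines, used instead of `path`.
#' @return A list with elements `motifs` (list of `motif_matrix` objects:
#'   `name`, `alphabet_length`, `width`, `nsites`, `evalue`, `ppm` a
#'   width x 4 matrix with columns A,C,G,T) and `background` (named
#'   4-vector).
#' @export
parse_meme_minimal <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  trimmed <- trimws(lines)

  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", trimmed, ignore.case = TRUE)
  if (length(bg_at) == 1 && bg_at < length(trimmed)) {
    toks <- strsplit(trimmed[bg_at + 1L], "[[:space:]]+")[[1]]
    if (length(toks) >= 8) {
      vals <- suppressWarnings(as.numeric(toks[seq(2, 8, by = 2)]))
      names(vals) <- toupper(toks[seq(1, 7, by = 2)])
      if (!anyNA(vals) && setequal(names(vals), .BASES)) {
        background <- vals[.BASES]
        background <- background / sum(background)
      }
    }
  }

  is_num_row <- function(ln) {
    grepl("^[0-9.eE+ \t-]+$", ln) && !grepl("^[[:space:]]*$", ln)
  }
  parse_nums <- function(ln) {
    suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
  }

  motifs <- list()
  i <- 1L
  n_lines <- length(trimmed)
  while (i <= n_lines) {
    ln <- trimmed[i]
    header <- NULL
    name <- NULL
    if (grepl("^MOTIF\\b", ln)) {
      name <- strsplit(ln, "[[:space:]]+")[[1]][2]
      if (is.na(name)) name <- sprintf("motif_%d", length(motifs) + 1L)
      # advance to the letter-probability header (or a bare numbers line)
      j <- i + 1L
      while (j <= n_lines &&
             !grepl("^letter-probability matrix", trimmed[j]) &&
             !is_num_row(trimmed[j])) {
        j <- j + 1L
      }
      if (j > n_lines) stop(sprintf("motif '%s': no probability matrix found", name),
                            call. = FALSE)
      if (grepl("^letter-probability matrix", trimmed[j])) {
        grab <- function(key) {
          m <- regmatches(trimmed[j],
                          regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), trimmed[j]))[[1]]
          if (length(m) == 2) as.numeric(m[2]) else NA_real_
        }
        header <- c(alength = grab("alength"), w = grab("w"),
                    nsites = grab("nsites"), E = grab("E"))
        i <- j + 1L
      } else {
        nums <- parse_nums(trimmed[j])
        header <- c(alength = nums[1], w = nums[2], nsites = nums[3], E = nums[4])
        i <- j + 1L
      }
    } else if (nzchar(ln) && !is_num_row(ln) && i < n_lines &&
               is_num_row(trimmed[i + 1L]) &&
               length(parse_nums(trimmed[i + 1L])) == 4 &&
               !grepl("^(MEME|ALPHABET|strands|Background)", ln, ignore.case = TRUE) &&
               (i + 2L) <= n_lines && is_num_row(trimmed[i + 2L])) {
      # compact layout: name line, then "alength width nsites evalue" line
      name <- strsplit(ln, "[[:space:]]+")[[1]][1]
      nums <- parse_nums(trimmed[i + 1L])
      header <- c(alength = nums[1], w = nums[2], nsites = nums[3], E = nums[4])
      i <- i + 2L
    } else {
      i <- i + 1L
      next
    }

    if (is.na(header[["alength"]]) || header[["alength"]] != 4) {
      stop(sprintf("motif '%s' (line %d): alphabet length must be 4", name, i),
           call. = FALSE)
    }
    w <- as.integer(header[["w"]])
    if (is.na(w) || w < 1) {
      stop(sprintf("motif '%s' (line %d): invalid width", name, i), call. = FALSE)
    }
    rows <- matrix(NA_real_, nrow = w, ncol = 4,
                   dimnames = list(NULL, .BASES))
    for (r in seq_len(w)) {
      if (i > n_lines || !is_num_row(trimmed[i])) {
        stop(sprintf("motif '%s': expected %d probability rows, found %d (line %d)",
                     name, w, r - 1L, i), call. = FALSE)
      }
      vals <- parse_nums(trimmed[i])
      if (length(vals) != 4 || anyNA(vals)) {
        stop(sprintf("motif '%s': row %d (line %d) does not have 4 numeric entries",
                     name, r, i), call. = FALSE)
      }
      if (any(vals < 0) || any(vals > 1) || abs(sum(vals) - 1) > 1e-3) {
        stop(sprintf("motif '%s': row %d (line %d) is not a probability distribution (sum %.6f)",
                     name, r, i, sum(vals)), call. = FALSE)
      }
      rows[r, ] <- vals
      i <- i + 1L
    }
    if (i <= n_lines && is_num_row(trimmed[i]) &&
        length(parse_nums(trimmed[i])) == 4) {
      stop(sprintf("motif '%s': more probability rows than declared width %d (line %d)",
                   name, w, i), call. = FALSE)
    }
    motifs[[length(motifs) + 1L]] <- structure(
      list(name = name, alphabet_length = 4L, width = w,
           nsites = header[["nsites"]], evalue = header[["E"]], ppm = rows),
      class = "motif_matrix"
    )
  }
  if (length(motifs) == 0) stop("no motifs found in file", call. = FALSE)
  list(motifs = motifs, background = background)
}

#' Convert a position probability matrix to a log-odds PSSM
#'
#' Each probability is normalized by the background frequency of its base and
#' log2-transformed: `scores[i, b] = log2((ppm[i, b] + eps) / (bg[b] + eps))`.
#' The pseudocount `eps` guards against exact zeros in the PPM (common in
#' motif databases) without materially shifting score ranks.
#'
#' @param motif A `motif_matrix` from [parse_meme_minimal()].
#' @param background Named or ordered (A,C,G,T) frequency 4-vector summing
#'   to 1.
#' @param pseudocount Small positive constant added before the log
#'   (default 1e-6).
#' @return An object of class `pssm`: `name`, `width`, `scores`
#'   (width x 4 log2-odds matrix), `background`.
#' @export
ppm_to_pssm <- function(motif, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        pseudocount = 1e-6) {
  bg <- as.numeric(background)
  if (length(bg) != 4 || abs(sum(bg) - 1) > 1e-6) {
    stop("background must be 4 frequencies summing to 1", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && (any(bg == 0) || any(motif$ppm == 0))) {
    stop("zero probabilities require a positive pseudocount", call. = FALSE)
  }
  scores <- log2(sweep(motif$ppm + pseudocount, 2, bg + pseudocount, "/"))
  colnames(scores) <- .BASES
  structure(
    list(name = motif$name, width = motif$width, scores = scores,
         background = stats::setNames(bg, .BASES)),
    class = "pssm"
  )
}

# Per-start-position scores of one PSSM along one strand of an
# integer-encoded sequence (A=1..T=4, N=5 scoring 0). Returns a numeric
# vector of length n - w + 1.
.pssm_scan_scores <- function(codes, pssm) {
  n <- length(codes)
  w <- pssm$width
  if (n < w) return(numeric(0))
  sc <- cbind(pssm$scores, N = 0)
  total <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    total <- total + unname(sc[j, codes[j:(n - w + j)]])
  }
  total
}

.encode_seq <- function(sequence) {
  match(.seq_chars(sequence), c(.BASES, "N"))
}

#' Scan a sequence for motif hits on both strands
#'
#' Scores every start position of the sequence against every PSSM on the
#' forward strand and on the reverse complement. At each start index only
#' the best-scoring (motif, strand) combination is kept (ties prefer the
#' forward strand, then the earlier motif in `pssms`), and only positions
#' with score > 0 — i.e. more likely under the motif than under the
#' background — are reported. Reverse-strand hits are reported in
#' forward-strand coordinates. N bases contribute the background expectation
#' (score 0).
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pssms List of `pssm` objects (see [ppm_to_pssm()]).
#' @return Data frame with columns `motif`, `start` (0-based), `width`,
#'   `strand` (`+`/`-`), `score`, sorted by `start`.
#' @export
scan_sequence <- function(sequence, pssms) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  n <- nchar(sequence)
  if (n == 0 || length(pssms) == 0) {
    return(data.frame(motif = character(0), start = integer(0),
                      width = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  codes_fwd <- .encode_seq(sequence)
  codes_rev <- .encode_seq(.revcomp(sequence))

  best_score <- rep(-Inf, n)
  best_motif <- rep(NA_integer_, n)
  best_strand <- rep(NA_character_, n)
  best_width <- rep(NA_integer_, n)

  for (m in seq_along(pssms)) {
    p <- pssms[[m]]
    w <- p$width
    if (w > n) next
    fwd <- .pssm_scan_scores(codes_fwd, p)
    rev <- .pssm_scan_scores(codes_rev, p)
    # reverse-scan start i (1-based in revcomp coords) maps to forward start
    # n - w - i + 2
    rev_fwdcoord <- rev(rev)  # index k corresponds to forward start k
    starts <- seq_len(n - w + 1L)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd else rev_fwdcoord
      upd <- sc > best_score[starts]
      if (any(upd)) {
        at <- starts[upd]
        best_score[at] <- sc[upd]
        best_motif[at] <- m
        best_strand[at] <- strand
        best_width[at] <- w
      }
    }
  }

  keep <- which(is.finite(best_score) & best_score > 0)
  data.frame(
    motif = vapply(best_motif[keep], function(m) pssms[[m]]$name, ""),
    start = keep - 1L,
    width = best_width[keep],
    strand = best_strand[keep],
    score = best_score[keep],
    stringsAsFactors = FALSE
  )
}

#' Consensus sequence of a motif
#'
#' The highest-probability base at each motif position (ties resolved in
#' A,C,G,T order).
#'
#' @param motif A `motif_matrix`.
#' @return A DNA string of length `motif$width`.
#' @export
motif_consensus <- function(motif) {
  paste(.BASES[apply(motif$ppm, 1, which.max)], collapse = "")
}

#' Load the packaged methylation motif set
#'
#' Returns the PSSMs of the bundled methylation-motif fixture file
#' (a small synthetic stand-in, in MEME minimal format, for large published
#' methylation-motif databases; users with such a database can pass its file
#' to [parse_meme_minimal()] instead).
#'
#' @param pseudocount Passed to [ppm_to_pssm()].
#' @return List of `pssm` objects.
#' @export
methylation_pssms <- function(pseudocount = 1e-6) {
  path <- system.file("extdata", "methylation_motifs_synthetic.meme",
                      package = "seqstab", mustWork = TRUE)
  parsed <- parse_meme_minimal(path)
  lapply(parsed$motifs, ppm_to_pssm, background = parsed$background,
         pseudocount = pseudocount)
}
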