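# Minimal GenBank flat-file reader and writer.
#
# Covers the subset of the format the batch pipeline needs: LOCUS name,
# simple FEATURES locations (`a..b` and `complement(a..b)`) with /label,
# /gene or /product qualifiers, and the ORIGIN sequence block. Multi-record
# files (// separated) are supported. Feature spans are converted to
# 0-based half-open on read and back to 1-based inclusive on write.

#' @noRd
.read_genbank_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  rec_breaks <- which(trimws(lines) == "//")
  if (length(rec_breaks) == 0) rec_breaks <- length(lines) + 1L
  records <- list()
  start <- 1L
  for (brk in rec_breaks) {
    chunk <- lines[start:(brk - 1L)]
    start <- brk + 1L
    if (!any(nzchar(trimws(chunk)))) next
    records[[length(records) + 1L]] <- .parse_genbank_chunk(chunk, path)
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)])))) {
    records[[length(records) + 1L]] <-
      .parse_genbank_chunk(lines[start:length(lines)], path)
  }
  if (length(records) == 0) stop("no GenBank records in ", path, call. = FALSE)
  records
}

#' @noRd
.parse_genbank_chunk <- function(chunk, path) {
  locus_line <- grep("^LOCUS", chunk, value = TRUE)
  id <- if (length(locus_line) >= 1) {
    strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "[[:space:]]+")[[1]][1]
  } else {
    "unnamed"
  }

  # FEATURES table
  features <- data.frame(label = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  feat_at <- grep("^FEATURES", chunk)
  origin_at <- grep("^ORIGIN", chunk)
  if (length(feat_at) == 1) {
    feat_end <- if (length(origin_at) >= 1) origin_at[1] - 1L else length(chunk)
    flines <- chunk[(feat_at + 1L):feat_end]
    # feature starts: a key in column 6 with a location
    key_rows <- grep("^ {1,10}\\S+ {2,}\\S", flines)
    key_rows <- key_rows[!grepl("^ {21}", flines[key_rows])]
    for (ki in seq_along(key_rows)) {
      row <- key_rows[ki]
      last <- if (ki < length(key_rows)) key_rows[ki + 1L] - 1L else length(flines)
      toks <- strsplit(trimws(flines[row]), "[[:space:]]+")[[1]]
      key <- toks[1]
      loc <- paste(toks[-1], collapse = "")
      m <- regmatches(loc, regexec("(complement\\()?<?([0-9]+)\\.\\.>?([0-9]+)", loc))[[1]]
      if (length(m) != 4) next
      a <- as.integer(m[3]); b <- as.integer(m[4])
      label <- key
      quals <- flines[seq(row, last)]
      for (qname in c("label", "gene", "product", "note")) {
        qm <- grep(sprintf("^/%s=", qname), trimws(quals), value = TRUE)
        if (length(qm) >= 1) {
          label <- gsub('^"|"$', "", sub(sprintf("^/%s=", qname), "", qm[1]))
          break
        }
      }
      features <- rbind(features, data.frame(
        label = label, start = a - 1L, end = b, stringsAsFactors = FALSE))
    }
  }

  # ORIGIN block
  if (length(origin_at) == 0) stop("GenBank record without ORIGIN block in ", path,
                                   call. = FALSE)
  seq_lines <- chunk[(origin_at[1] + 1L):length(chunk)]
  seq_txt <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))
  list(id = id, sequence = seq_txt, features = features)
}

#' @noRd
.write_genbank <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    n <- nchar(rec$sequence)
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     linear   %s",
                          rec$id, n, format(Sys.Date(), "%d-%b-%Y")))
    out <- c(out, sprintf("DEFINITION  %s.", rec$id))
    feats <- rec$features
    out <- c(out, "FEATURES             Location/Qualifiers")
    out <- c(out, sprintf("     %-16s%d..%d", "source", 1L, n))
    if (!is.null(feats) && nrow(feats) > 0) {
      for (i in seq_len(nrow(feats))) {
        out <- c(out,
                 sprintf("     %-16s%d..%d", "misc_feature",
                         feats$start[i] + 1L, feats$end[i]),
                 sprintf("                     /label=\"%s\"", feats$label[i]))
      }
    }
    out <- c(out, "ORIGIN")
    s <- tolower(rec$sequence)
    pos <- seq(1, n, by = 60)
    for (p in pos) {
      stretch <- substr(s, p, min(p + 59, n))
      blocks <- substring(stretch,
                          seq(1, nchar(stretch), by = 10),
                          pmin(seq(10, nchar(stretch) + 9, by = 10), nchar(stretch)))
      out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}
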