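# Batch input discovery, record reading, and output-bundle writing.
#
# Inputs are directories of FASTA (.fa/.fasta) and GenBank (.gb/.gbk) files,
# optionally gzip-compressed or collected in zip archives. Outputs mirror
# the input directory hierarchy: one folder per input file, holding per-type
# site CSVs, optimized sequences, and a change summary, plus a joined
# multi-record sequence file next to the folder.

.FASTA_EXT <- c("fa", "fasta", "fna")
.GENBANK_EXT <- c("gb", "gbk", "genbank")

#' @noRd
.strip_gz <- function(path) sub("\\.gz$", "", path)

#' @noRd
.file_format <- function(path) {
  base <- tolower(.strip_gz(path))
  ext <- sub(".*\\.", "", base)
  if (ext %in% .FASTA_EXT) return("FASTA")
  if (ext %in% .GENBANK_EXT) return("GENBANK")
  NA_character_
}

#' Discover sequence files in an input directory
#'
#' Recursively lists a directory and routes every file recognized as FASTA,
#' GenBank, or a gzip/zip-compressed variant. Zip archives are expanded into
#' a temporary directory and each member routed by extension. Unrecognized
#' files are skipped with a warning. Format is inferred from the extension,
#' then confirmed by content sniffing (`>` header vs `LOCUS`).
#'
#' @param path Input directory.
#' @return Data frame with columns `path` (readable file, possibly inside an
#'   expanded archive), `rel_path` (position relative to the input root,
#'   used to mirror the hierarchy on output), and `format`
#'   (`"FASTA"`/`"GENBANK"`).
#' @export
scan_input_directory <- function(path) {
  if (!dir.exists(path)) stop("input directory does not exist: ", path, call. = FALSE)
  files <- list.files(path, recursive = TRUE, full.names = FALSE)
  rows <- list()
  skipped <- character(0)
  for (f in files) {
    full <- file.path(path, f)
    if (grepl("\\.zip$", tolower(f))) {
      exdir <- file.path(tempfile("seqstab_zip_"))
      dir.create(exdir, recursive = TRUE)
      members <- utils::unzip(full, exdir = exdir)
      for (m in members) {
        fmt <- .file_format(m)
        if (is.na(fmt)) { skipped <- c(skipped, file.path(f, basename(m))); next }
        rows[[length(rows) + 1L]] <- data.frame(
          path = m,
          rel_path = file.path(dirname(f), .strip_gz(basename(m))),
          format = fmt, stringsAsFactors = FALSE)
      }
      next
    }
    fmt <- .file_format(f)
    if (is.na(fmt)) { skipped <- c(skipped, f); next }
    fmt_sniffed <- .sniff_format(full)
    if (!is.na(fmt_sniffed) && fmt_sniffed != fmt) fmt <- fmt_sniffed
    rows[[length(rows) + 1L]] <- data.frame(
      path = full, rel_path = .strip_gz(f), format = fmt,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("skipped non-sequence file(s): ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  if (length(rows) == 0) stop("no input sequences found in ", path, call. = FALSE)
  out <- do.call(rbind, rows)
  out[order(out$rel_path), , drop = FALSE]
}

#' @noRd
.sniff_format <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  head <- tryCatch(readLines(con, n = 5), error = function(e) character(0))
  head <- head[nzchar(trimws(head))]
  if (length(head) == 0) return(NA_character_)
  if (startsWith(head[1], ">")) return("FASTA")
  if (any(grepl("^LOCUS", head))) return("GENBANK")
  NA_character_
}

#' Read all sequence records from one file
#'
#' Parses a FASTA or GenBank file into `seqstab_record` objects. Records get
#' a running index `seq_num` (1..n within the file), sequences are
#' upper-cased, U is converted to T with a warning, and ambiguity codes
#' other than N are rejected. GenBank feature spans are carried through as a
#' `features` data frame (`label`, `start`, `end`; 0-based half-open).
#'
#' @param filepath Path to the file (may be gzip-compressed).
#' @param format `"FASTA"` or `"GENBANK"` (default: inferred from extension).
#' @return List of `seqstab_record` objects, each with fields `id`,
#'   `sequence`, `source_path`, `seq_num`, `features`.
#' @export
read_records <- function(filepath, format = .file_format(filepath)) {
  if (is.na(format)) stop("cannot infer format of ", filepath, call. = FALSE)
  empty_features <- data.frame(label = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
  if (format == "FASTA") {
    # read as raw strings so U and invalid characters reach our own
    # normalization instead of being silently altered
    set <- Biostrings::readBStringSet(filepath, format = "fasta")
    if (length(set) == 0) stop("no sequences in ", filepath, call. = FALSE)
    raw <- as.character(set)
    ids <- sub("[[:space:]].*$", "", names(set))
    recs <- lapply(seq_along(raw), function(i) {
      list(id = ids[i],
           sequence = .normalize_sequence(raw[[i]], ids[i]),
           source_path = filepath, seq_num = i, features = empty_features)
    })
  } else {
    gb <- .read_genbank_records(filepath)
    recs <- lapply(seq_along(gb), function(i) {
      list(id = gb[[i]]$id,
           sequence = .normalize_sequence(gb[[i]]$sequence, gb[[i]]$id),
           source_path = filepath, seq_num = i, features = gb[[i]]$features)
    })
  }
  lapply(recs, function(r) structure(r, class = "seqstab_record"))
}

#' Deterministic identity token for a sequence
#'
#' A short hash-derived token standing in for a visual sequence icon: equal
#' sequences always map to the same token, and any single-base change yields
#' a different token with overwhelming probability. Stable across platforms
#' and sessions.
#'
#' @param sequence DNA string.
#' @return A 12-character hex token.
#' @export
sequence_identicon <- function(sequence) {
  if (nchar(sequence) == 0) stop("sequence must be non-empty", call. = FALSE)
  tf <- tempfile("seqicon_")
  on.exit(unlink(tf))
  writeLines(toupper(sequence), tf, sep = "")
  substr(unname(tools::md5sum(tf)), 1, 12)
}

# 1-based inclusive site tables for CSV output. Coordinates in the in-memory
# frames are 0-based half-open; this is the only place they are converted.
#' @noRd
.site_csv_table <- function(sites, type, seq_id, seq_num) {
  empty <- data.frame(
    seq_id = character(0), seq_num = integer(0), type = character(0),
    start_1based = integer(0), end_1based_inclusive = integer(0),
    length = integer(0), detail = character(0), rate_or_score = numeric(0),
    rank = integer(0), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0) return(empty)
  rank <- if ("rank" %in% names(sites)) sites$rank else rep(NA_integer_, nrow(sites))
  if (type == "ssr") {
    data.frame(
      seq_id = seq_id, seq_num = seq_num, type = "ssr",
      start_1based = sites$start + 1L, end_1based_inclusive = sites$end,
      length = sites$end - sites$start,
      detail = sprintf("unit=%s;N=%d", sites$unit, sites$N),
      rate_or_score = sites$rate, rank = rank, stringsAsFactors = FALSE)
  } else if (type == "rmd") {
    data.frame(
      seq_id = seq_id, seq_num = seq_num, type = "rmd",
      start_1based = sites$first_start + 1L,
      end_1based_inclusive = sites$second_start + sites$repeat_len,
      length = sites$repeat_len,
      detail = sprintf("repeat_len=%d;spacer=%d;second_start=%d",
                       sites$repeat_len, sites$spacer, sites$second_start + 1L),
      rate_or_score = sites$rate, rank = rank, stringsAsFactors = FALSE)
  } else {
    data.frame(
      seq_id = seq_id, seq_num = seq_num, type = "motif",
      start_1based = sites$start + 1L,
      end_1based_inclusive = sites$start + sites$width,
      length = sites$width,
      detail = sprintf("motif=%s;strand=%s", sites$motif, sites$strand),
      rate_or_score = sites$score, rank = rank, stringsAsFactors = FALSE)
  }
}

#' @noRd
.versioned_dir <- function(dir) {
  if (!dir.exists(dir) && !file.exists(dir)) return(dir)
  i <- 1L
  repeat {
    cand <- sprintf("%s-%d", dir, i)
    if (!dir.exists(cand) && !file.exists(cand)) {
      message("output folder exists; using ", cand)
      return(cand)
    }
    i <- i + 1L
  }
}

#' Write the per-input output bundle
#'
#' Creates one folder per input file holding the per-type site CSV tables
#' (`sites_ssr.csv`, `sites_rmd.csv`, `sites_motif.csv`; coordinates
#' 1-based inclusive as stated in the headers), the optimized sequences in
#' every requested format, a change summary, and identity tokens. A joined
#' multi-record sequence file matching the input file is written next to the
#' folder. Existing folders are never overwritten; a versioned suffix is
#' used instead.
#'
#' @param bundle A list with elements `records` (list of `seqstab_record`,
#'   optimized or original), `ssr`, `rmd`, `motif` (per-record lists of site
#'   tables), `changes` (data frame `position`, `old_base`, `new_base`,
#'   `reason`; may be empty), `identicon_before`, `identicon_after`
#'   (character vectors), and `notes` (character).
#' @param outdir Parent output directory (created if needed).
#' @param name Bundle folder name (typically the input file's base name).
#' @param formats Character subset of `c("FASTA", "GENBANK")`.
#' @return Invisible character vector of written paths.
#' @export
write_output_bundle <- function(bundle, outdir, name,
                                formats = "FASTA") {
  stopifnot(all(formats %in% c("FASTA", "GENBANK")))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  folder <- .versioned_dir(file.path(outdir, name))
  dir.create(folder, recursive = TRUE)
  written <- character(0)

  per_rec <- function(tables, type) {
    parts <- lapply(seq_along(bundle$records), function(i) {
      .site_csv_table(tables[[i]], type,
                      bundle$records[[i]]$id, bundle$records[[i]]$seq_num)
    })
    do.call(rbind, parts)
  }
  for (type in c("ssr", "rmd", "motif")) {
    tab <- per_rec(bundle[[type]], type)
    f <- file.path(folder, sprintf("sites_%s.csv", type))
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }

  seqs <- vapply(bundle$records, `[[`, "", "sequence")
  ids <- vapply(bundle$records, `[[`, "", "id")
  if ("FASTA" %in% formats) {
    f <- file.path(folder, "optimized.fasta")
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- ids
    Biostrings::writeXStringSet(set, f, width = 70)
    written <- c(written, f)
  }
  if ("GENBANK" %in% formats) {
    f <- file.path(folder, "optimized.gb")
    gb_recs <- lapply(bundle$records, function(r) {
      feats <- r$features
      if (length(bundle$change_features) >= r$seq_num &&
          !is.null(bundle$change_features[[r$seq_num]])) {
        feats <- rbind(feats, bundle$change_features[[r$seq_num]])
      }
      list(id = r$id, sequence = r$sequence, features = feats)
    })
    .write_genbank(gb_recs, f)
    written <- c(written, f)
  }

  sm <- file.path(folder, "summary.txt")
  lines <- c(
    sprintf("records: %d", length(bundle$records)),
    sprintf("identicon before: %s",
            paste(bundle$identicon_before, collapse = ", ")),
    sprintf("identicon after: %s",
            paste(bundle$identicon_after, collapse = ", ")),
    "note: rates are per-generation, E. coli-calibrated; rankings, not absolute values, transfer to other organisms.",
    bundle$notes
  )
  if (!is.null(bundle$changes) && nrow(bundle$changes) > 0) {
    lines <- c(lines, "changes (position is 1-based):",
               sprintf("  %d %s->%s %s", bundle$changes$position + 1L,
                       bundle$changes$old_base, bundle$changes$new_base,
                       bundle$changes$reason))
  } else {
    lines <- c(lines, "changes: none")
  }
  writeLines(lines, sm)
  written <- c(written, sm)

  # joined multi-record output next to the folder, matching the input file
  joined <- file.path(outdir, paste0(name, ".optimized.fasta"))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, joined, width = 70)
  written <- c(written, joined)

  # zip archive of the bundle when a zip tool is available
  if (nzchar(Sys.which("zip"))) {
    zf <- paste0(folder, ".zip")
    old <- setwd(dirname(folder))
    on.exit(setwd(old), add = TRUE)
    utils::zip(zf, files = basename(folder), flags = "-qr")
    written <- c(written, zf)
  }
  invisible(written)
}
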