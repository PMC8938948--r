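# Batch orchestration: scan a directory, detect hotspots in every record,
# optionally optimize, and write the mirrored output hierarchy.

#' Batch run configuration
#'
#' @param input_dir Directory of FASTA/GenBank files (possibly compressed).
#' @param output_dir Output directory (created; mirrors the input tree).
#' @param motif_mode `"methylation"` (bundled motif set), `"custom"`
#'   (requires `custom_motif_path`), or `"none"`.
#' @param custom_motif_path MEME-minimal file for `motif_mode = "custom"`.
#' @param sites_per_type Per-type site budget (default 10).
#' @param optimize `FALSE` for report-only mode: detection CSVs only, no
#'   sequence design.
#' @param output_formats Subset of `c("FASTA", "GENBANK")`.
#' @param full_report Also write the per-sequence constraint report.
#' @param organism,method,gc_min,gc_max,gc_window See [optimization_spec()].
#' @param orf_regions,locked_regions Lists of `c(seq_num, start, end)` with
#'   1-based inclusive coordinates (the command-line/report convention);
#'   converted internally and applied to the record with that `seq_num` in
#'   each input file.
#' @param seed Integer seed (default 0).
#' @param iterate Repeat detection/removal rounds (default `FALSE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       motif_mode = c("methylation", "custom", "none"),
                       custom_motif_path = NULL,
                       sites_per_type = 10L,
                       optimize = TRUE,
                       output_formats = "FASTA",
                       full_report = FALSE,
                       organism = NULL, method = "use_best_codon",
                       gc_min = 0, gc_max = 1, gc_window = 50L,
                       orf_regions = list(), locked_regions = list(),
                       seed = 0L, iterate = FALSE) {
  motif_mode <- match.arg(motif_mode)
  if (motif_mode == "custom" && is.null(custom_motif_path)) {
    stop("motif_mode = 'custom' requires custom_motif_path", call. = FALSE)
  }
  stopifnot(all(output_formats %in% c("FASTA", "GENBANK")))
  for (sp in c(orf_regions, locked_regions)) {
    if (length(sp) != 3) {
      stop("ORF/locked spans must be c(seq_num, start, end), 1-based inclusive",
           call. = FALSE)
    }
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         motif_mode = motif_mode, custom_motif_path = custom_motif_path,
         sites_per_type = as.integer(sites_per_type),
         optimize = isTRUE(optimize),
         output_formats = output_formats, full_report = isTRUE(full_report),
         organism = organism, method = method,
         gc_min = gc_min, gc_max = gc_max, gc_window = as.integer(gc_window),
         orf_regions = orf_regions, locked_regions = locked_regions,
         seed = as.integer(seed), iterate = isTRUE(iterate)),
    class = "run_config"
  )
}

#' Read a run configuration from a plain-text file
#'
#' `key = value` lines mirroring the command-line flags: `input_dir`,
#' `output_dir`, `motifs`, `motif_file`, `sites_per_type`, `optimize`,
#' `organism`, `method`, `gc_min`, `gc_max`, `format`, `seed`, `iterate`,
#' `full_report`, and repeatable `orf`/`lock` entries written as
#' `SEQNUM:START-END` (1-based inclusive), comma-separated.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
run_config_from_file <- function(path) {
  kv <- .parse_kv_file(path)
  get <- function(key, default = NULL) {
    if (key %in% names(kv)) kv[[key]] else default
  }
  parse_spans <- function(key) {
    raw <- get(key)
    if (is.null(raw) || !nzchar(raw)) return(list())
    lapply(strsplit(raw, ",")[[1]], .parse_span_flag)
  }
  fmt <- toupper(get("format", "fasta"))
  formats <- if (fmt == "BOTH") c("FASTA", "GENBANK") else fmt
  run_config(
    input_dir = get("input_dir"), output_dir = get("output_dir"),
    motif_mode = get("motifs", "methylation"),
    custom_motif_path = get("motif_file"),
    sites_per_type = as.integer(get("sites_per_type", "10")),
    optimize = !identical(tolower(get("optimize", "true")), "false"),
    output_formats = formats,
    full_report = identical(tolower(get("full_report", "false")), "true"),
    organism = get("organism"),
    method = get("method", "use_best_codon"),
    gc_min = as.numeric(get("gc_min", "0")),
    gc_max = as.numeric(get("gc_max", "1")),
    orf_regions = parse_spans("orf"),
    locked_regions = parse_spans("lock"),
    seed = as.integer(get("seed", "0")),
    iterate = identical(tolower(get("iterate", "false")), "true")
  )
}

#' @noRd
.parse_span_flag <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([0-9]+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4) {
    stop("bad span '", txt, "'; expected SEQNUM:START-END (1-based inclusive)",
         call. = FALSE)
  }
  as.integer(m[2:4])
}

#' @noRd
.spans_for_record <- function(spans, seq_num) {
  out <- list()
  for (sp in spans) {
    if (sp[1] == seq_num) out[[length(out) + 1L]] <- c(sp[2] - 1L, sp[3])
  }
  out
}

#' Run the batch pipeline
#'
#' For every sequence in every input file: detect SSR, RMD and (per
#' `motif_mode`) motif sites, write the per-type CSV tables, and — unless in
#' report-only mode — run the two-pass optimizer and write the optimized
#' sequences, change summaries and identity tokens in a folder hierarchy
#' mirroring the input. Per-file failures are logged and skipped without
#' aborting the batch; a machine-readable run manifest is written to the
#' output directory.
#'
#' @param config A [run_config()].
#' @param model A [rate_model()].
#' @return Invisible list: `status` (0 iff no file-level errors), `errors`
#'   (character vector), `results` (per-file lists of per-record outputs).
#' @export
run_pipeline <- function(config, model = rate_model()) {
  files <- scan_input_directory(config$input_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  pssms <- switch(config$motif_mode,
    methylation = methylation_pssms(),
    custom = {
      parsed <- parse_meme_minimal(config$custom_motif_path)
      lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
    },
    none = NULL
  )

  errors <- character(0)
  results <- list()
  for (fi in seq_len(nrow(files))) {
    rel <- files$rel_path[fi]
    message("processing ", rel)
    recs <- tryCatch(
      read_records(files$path[fi], files$format[fi]),
      error = function(e) {
        errors <<- c(errors, sprintf("%s: %s", rel, conditionMessage(e)))
        NULL
      })
    if (is.null(recs)) next

    bundle <- list(records = recs, ssr = list(), rmd = list(), motif = list(),
                   changes = NULL, change_features = list(),
                   identicon_before = character(0),
                   identicon_after = character(0), notes = character(0))
    rec_results <- list()
    all_changes <- list()
    for (ri in seq_along(recs)) {
      rec <- recs[[ri]]
      res <- tryCatch({
        if (config$optimize) {
          spec <- optimization_spec(
            organism = config$organism, method = config$method,
            gc_min = config$gc_min, gc_max = config$gc_max,
            gc_window = config$gc_window,
            orf_regions = .spans_for_record(config$orf_regions, rec$seq_num),
            locked_regions = .spans_for_record(config$locked_regions,
                                               rec$seq_num),
            site_budget = config$sites_per_type, seed = config$seed)
          optimize_sequence(rec$sequence, spec, pssms = pssms, model = model,
                            iterate = config$iterate)
        } else {
          list(sequence = rec$sequence,
               targets = list(
                 ssr = rank_sites(find_ssr_sites(rec$sequence, model),
                                  config$sites_per_type),
                 rmd = rank_sites(find_rmd_sites(rec$sequence, model),
                                  config$sites_per_type),
                 motif = if (!is.null(pssms)) {
                   rank_sites(scan_sequence(rec$sequence, pssms),
                              config$sites_per_type)
                 } else {
                   NULL
                 }),
               changes = NULL)
        }
      }, error = function(e) {
        errors <<- c(errors,
                     sprintf("%s seq %d: %s", rel, ri, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        bundle$ssr[ri] <- list(NULL); bundle$rmd[ri] <- list(NULL)
        bundle$motif[ri] <- list(NULL)
        bundle$identicon_before[ri] <- bundle$identicon_after[ri] <- "failed"
        next
      }
      bundle$ssr[ri] <- list(res$targets$ssr)
      bundle$rmd[ri] <- list(res$targets$rmd)
      bundle$motif[ri] <- list(res$targets$motif)
      bundle$identicon_before[ri] <- sequence_identicon(rec$sequence)
      bundle$identicon_after[ri] <- sequence_identicon(res$sequence)
      if (!is.null(res$changes) && nrow(res$changes) > 0) {
        all_changes[[length(all_changes) + 1L]] <- res$changes
        bundle$change_features[[rec$seq_num]] <- data.frame(
          label = paste0("changed:", res$changes$reason),
          start = res$changes$position,
          end = res$changes$position + 1L,
          stringsAsFactors = FALSE)
      }
      bundle$records[[ri]]$sequence <- res$sequence
      rec_results[[ri]] <- res
    }
    bundle$changes <- if (length(all_changes)) do.call(rbind, all_changes) else NULL
    if (config$full_report && config$optimize) {
      bundle$notes <- c(bundle$notes, "see constraint_report.csv")
    }

    out_parent <- file.path(config$output_dir, dirname(rel))
    name <- basename(rel)
    written <- write_output_bundle(bundle, out_parent, name,
                                   formats = config$output_formats)
    if (config$full_report && config$optimize) {
      reports <- do.call(rbind, lapply(rec_results, function(r) {
        if (!is.null(r$constraint_report)) r$constraint_report else NULL
      }))
      if (!is.null(reports)) {
        utils::write.csv(reports,
                         file.path(dirname(written[1]), "constraint_report.csv"),
                         row.names = FALSE)
      }
    }
    results[[rel]] <- rec_results
  }

  manifest <- list(
    inputs = files$rel_path,
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    package_version = as.character(utils::packageVersion("seqstab")),
    seed = config$seed,
    errors = errors
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = if (length(errors)) 1L else 0L,
                 errors = errors, results = results))
}
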