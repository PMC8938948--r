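# Per-sequence orchestration of the two passes plus the independent audit.

#' Optimize one sequence end to end
#'
#' Runs the full per-sequence procedure: pass 1 (codon objective and GC
#' regulation), hotspot detection on the pass-1 output (SSR, RMD, and motif
#' scanning when PSSMs are given), ranking and per-type budget cut,
#' constraint derivation, and pass 2 (hotspot removal). With
#' `iterate = TRUE`, detection and removal are repeated (up to
#' `max_iterations` rounds) while new removable sites keep appearing.
#' The returned result has been audited by [verify_result()].
#'
#' @param sequence DNA string.
#' @param spec An [optimization_spec()].
#' @param pssms Optional list of `pssm` objects for motif removal.
#' @param model A [rate_model()].
#' @param iterate Re-detect and remove repeatedly (default `FALSE`).
#' @param max_iterations Iteration cap when `iterate = TRUE` (default 4).
#' @return An `optimization_result` with additional fields: `original`
#'   (input sequence), `targets` (the ranked site tables that were
#'   targeted), `site_counts` (targeted/removed/skipped per type),
#'   `unsatisfiable_windows` (from pass 1), `objective_before`/`_after`
#'   (codon objective, `NA` without an organism), `rip_before`/`rip_after`,
#'   and `audit` (the [verify_result()] summary).
#' @export
optimize_sequence <- function(sequence, spec, pssms = NULL,
                              model = rate_model(), iterate = FALSE,
                              max_iterations = 4L) {
  sequence <- .normalize_sequence(sequence)
  p1 <- first_pass(sequence, spec)
  work <- p1$sequence
  all_events <- p1$changes
  reports <- list()
  targets <- list(ssr = NULL, rmd = NULL, motif = NULL)

  rounds <- if (iterate) max_iterations else 1L
  for (round in seq_len(rounds)) {
    ssr <- rank_sites(find_ssr_sites(work, model), spec$site_budget)
    rmd <- rank_sites(find_rmd_sites(work, model), spec$site_budget)
    motif <- if (!is.null(pssms)) {
      rank_sites(scan_sequence(work, pssms), spec$site_budget)
    } else {
      NULL
    }
    n_sites <- sum(nrow(ssr), nrow(rmd), if (is.null(motif)) 0 else nrow(motif))
    if (n_sites == 0) break
    if (round == 1L) targets <- list(ssr = ssr, rmd = rmd, motif = motif)
    constraints <- derive_avoid_constraints(
      list(ssr = ssr, rmd = rmd, motif = motif), spec, pssms)
    p2 <- second_pass(work, spec, constraints)
    work <- p2$sequence
    all_events <- rbind(all_events, p2$changes)
    reports[[round]] <- p2$constraint_report
    if (!any(p2$constraint_report$status == "satisfied")) break
  }

  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(kind = character(0), start_1based = integer(0),
               end_1based = integer(0), status = character(0),
               detail = character(0), stringsAsFactors = FALSE)

  # net per-position changes (last event wins; unchanged positions dropped)
  orig_chars <- .seq_chars(sequence)
  final_chars <- .seq_chars(work)
  diff_pos <- which(orig_chars != final_chars) - 1L
  reason_at <- function(p) {
    ev <- all_events[all_events$position == p, , drop = FALSE]
    if (nrow(ev) == 0) "unattributed" else ev$reason[nrow(ev)]
  }
  net_changes <- data.frame(
    position = diff_pos,
    old_base = orig_chars[diff_pos + 1L],
    new_base = final_chars[diff_pos + 1L],
    reason = vapply(diff_pos, reason_at, ""),
    stringsAsFactors = FALSE)

  obj <- c(NA_real_, NA_real_)
  if (!is.null(spec$organism) && length(spec$orf_regions) > 0) {
    table <- build_codon_table(spec$organism)
    score_all <- function(s) {
      vals <- vapply(spec$orf_regions, function(sp) {
        codon_objective_score(s, sp, table, spec$method,
                              original_sequence = sequence)
      }, 0)
      wts <- vapply(spec$orf_regions, function(sp) (sp[2] - sp[1]) / 3, 0)
      sum(vals * wts) / sum(wts)
    }
    obj <- c(score_all(sequence), score_all(work))
  }

  rip_of <- function(s) {
    rip_score(nchar(s), find_ssr_sites(s, model), find_rmd_sites(s, model),
              model)
  }

  counts <- do.call(rbind, lapply(c("ssr_units", "recombination_15mer",
                                    "motif_span"), function(k) {
    sub <- report[report$kind == k, , drop = FALSE]
    data.frame(kind = k,
               targeted = nrow(sub),
               removed = sum(sub$status == "satisfied"),
               skipped_locked = sum(sub$status == "skipped (locked)"),
               unsatisfied = sum(sub$status == "unsatisfied"),
               stringsAsFactors = FALSE)
  }))

  result <- structure(
    list(sequence = work, original = sequence, changes = net_changes,
         events = all_events, constraint_report = report,
         targets = targets, site_counts = counts,
         unsatisfiable_windows = p1$unsatisfiable_windows,
         objective_before = obj[1], objective_after = obj[2],
         rip_before = rip_of(sequence), rip_after = rip_of(work),
         pssms = pssms, seed = spec$seed),
    class = "optimization_result")
  result$audit <- verify_result(sequence, result, spec)
  result
}

#' Independent audit of an optimization result
#'
#' Re-checks, from scratch, every invariant the optimizer promises:
#' amino-acid translation of each ORF unchanged, locked regions
#' byte-identical, each GC window within bounds (except windows reported
#' unsatisfiable), every constraint reported satisfied truly absent on
#' re-detection, and the change log consistent with the Hamming distance
#' between input and output. Any violation raises an error — this is a bug
#' trap, not a warning.
#'
#' @param original The pre-optimization sequence.
#' @param result An `optimization_result` with final `sequence`, net
#'   `changes` and `constraint_report`.
#' @param spec The [optimization_spec()] used.
#' @return Invisible summary list: `n_changes`, `changes_by_reason`,
#'   `gc_ok`, `translation_ok`, `locks_ok`, `targets_ok`.
#' @export
verify_result <- function(original, result, spec) {
  final <- result$sequence
  n <- nchar(original)
  if (nchar(final) != n) stop("audit: sequence length changed", call. = FALSE)
  o <- .seq_chars(original)
  f <- .seq_chars(final)

  for (sp in spec$orf_regions) {
    tr <- function(s) {
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, sp[1] + 1L, sp[2])),
        no.init.codon = TRUE, if.fuzzy.codon = "solve"))
    }
    if (tr(original) != tr(final)) {
      stop("audit: translation changed in ORF ", sp[1], "..", sp[2],
           call. = FALSE)
    }
  }
  for (sp in spec$locked_regions) {
    if (substr(original, sp[1] + 1L, sp[2]) != substr(final, sp[1] + 1L, sp[2])) {
      stop("audit: locked region ", sp[1], "..", sp[2], " was edited",
           call. = FALSE)
    }
  }

  wins <- .gc_windows(n, spec$gc_window)
  exempt <- result$unsatisfiable_windows$window_start_1based
  for (wi in seq_len(nrow(wins))) {
    if ((wins[wi, 1] + 1L) %in% exempt) next
    g <- .window_gc(f, wins[wi, ])
    if (!is.na(g) && (g < spec$gc_min - 1e-9 || g > spec$gc_max + 1e-9)) {
      stop("audit: GC window ", wins[wi, 1] + 1L, "..", wins[wi, 2],
           " out of bounds (", round(g, 3), ")", call. = FALSE)
    }
  }

  rep <- result$constraint_report
  sat <- rep[rep$status == "satisfied", , drop = FALSE]
  if (nrow(sat) > 0) {
    ssr_now <- find_ssr_sites(final, model = NULL)
    for (i in seq_len(nrow(sat))) {
      s0 <- sat$start_1based[i] - 1L
      e0 <- sat$end_1based[i]
      if (sat$kind[i] == "ssr_units") {
        if (nrow(ssr_now) > 0 &&
            any(.span_overlaps(ssr_now$start, ssr_now$end, s0, e0))) {
          stop("audit: targeted SSR at ", s0, "..", e0, " still present",
               call. = FALSE)
        }
      } else if (sat$kind[i] == "recombination_15mer") {
        # no >= 16 identity may survive anywhere along the first copy's
        # original diagonal; check first copy against the whole sequence
        seg <- substr(final, s0 + 1L, e0)
        kms <- substring(seg, 1:(nchar(seg) - 15L), 16:nchar(seg))
        for (k in seq_along(kms)) {
          if (grepl("N", kms[k], fixed = TRUE)) next
          hits <- gregexpr(kms[k], final, fixed = TRUE)[[1]]
          if (length(hits) > 1) {
            stop("audit: targeted RMD 16-mer at ", s0 + k - 1L,
                 " still duplicated", call. = FALSE)
          }
        }
      }
      else if (sat$kind[i] == "motif_span" && !is.null(result$pssms)) {
        m <- regmatches(sat$detail[i],
                        regexec("motif=([^;]+);strand=([+-])", sat$detail[i]))[[1]]
        if (length(m) == 3) {
          pssm_names <- vapply(result$pssms, `[[`, "", "name")
          pssm <- result$pssms[[match(m[2], pssm_names)]]
          sc <- .motif_score_at(f, s0, pssm, m[3])
          if (sc > 0) {
            stop("audit: targeted motif hit at ", s0, " still scores ",
                 round(sc, 3), call. = FALSE)
          }
        }
      }
    }
  }

  diff_pos <- which(o != f) - 1L
  if (!setequal(diff_pos, result$changes$position)) {
    stop("audit: change log does not match observed differences", call. = FALSE)
  }
  if (nrow(result$changes) != length(diff_pos)) {
    stop("audit: change count != Hamming distance", call. = FALSE)
  }

  invisible(list(
    n_changes = length(diff_pos),
    changes_by_reason = if (nrow(result$changes)) {
      table(result$changes$reason)
    } else {
      table(character(0))
    },
    gc_ok = TRUE, translation_ok = TRUE, locks_ok = TRUE, targets_ok = TRUE
  ))
}
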