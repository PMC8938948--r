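# Two-pass constrained sequence optimization.
#
# Pass 1 codon-optimizes ORFs toward the host usage table and regulates GC
# content in fixed 50-nt windows; pass 2 re-edits the sequence so that the
# top-ranked instability sites (SSR runs, RMD repeat pairs, motif hits)
# disappear, while translation of every ORF, all locked regions, and the GC
# window bounds are preserved. Constraint resolution is a localized, seeded
# hill-climb over synonymous codon choices inside ORFs and free bases
# outside them, with bounded randomized restarts; candidate edits that would
# create a new qualifying SSR or a new duplicated 16-mer are rejected.

#' Optimization run specification
#'
#' @param organism Host organism for codon optimization (one of
#'   [supported_organisms()]), or `NULL` to resolve constraints only.
#' @param method Codon objective: `"use_best_codon"`, `"match_codon_usage"`
#'   or `"harmonize_rca"`.
#' @param gc_min,gc_max GC-content bounds as fractions in `[0, 1]`, enforced
#'   on every window.
#' @param gc_window Window length in nt (non-overlapping windows anchored at
#'   position 0; default 50).
#' @param orf_regions List of 0-based half-open spans `c(start, end)` with
#'   length divisible by 3; amino-acid translation is preserved there.
#' @param locked_regions List of 0-based half-open spans left byte-identical.
#' @param site_budget Sites targeted per hotspot type (default 10).
#' @param seed Integer seed making the whole optimization deterministic
#'   (default 0).
#' @return An object of class `optimization_spec`.
#' @export
optimization_spec <- function(organism = NULL,
                              method = "use_best_codon",
                              gc_min = 0, gc_max = 1, gc_window = 50L,
                              orf_regions = list(),
                              locked_regions = list(),
                              site_budget = 10L,
                              seed = 0L) {
  method <- match.arg(method,
                      c("use_best_codon", "match_codon_usage", "harmonize_rca"))
  if (!is.null(organism)) {
    if (!organism %in% names(.ORGANISM_ALIASES)) {
      stop("unknown organism '", organism, "'; supported: ",
           paste(supported_organisms(), collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(gc_min <= gc_max, gc_min >= 0, gc_max <= 1, gc_window >= 1)
  orf_regions <- lapply(orf_regions, as.integer)
  locked_regions <- lapply(locked_regions, as.integer)
  for (sp in orf_regions) {
    if (length(sp) != 2 || sp[2] <= sp[1]) stop("bad ORF span", call. = FALSE)
    if ((sp[2] - sp[1]) %% 3 != 0) {
      stop("ORF length must be divisible by 3 (span ",
           sp[1], "..", sp[2], ")", call. = FALSE)
    }
  }
  if (length(orf_regions) > 1) {
    starts <- vapply(orf_regions, `[`, 0L, 1L)
    ends <- vapply(orf_regions, `[`, 0L, 2L)
    o <- order(starts)
    if (any(starts[o][-1] < ends[o][-length(o)])) {
      stop("ORF regions must not overlap", call. = FALSE)
    }
  }
  for (sp in locked_regions) {
    if (length(sp) != 2 || sp[2] <= sp[1]) stop("bad locked span", call. = FALSE)
  }
  structure(
    list(organism = organism, method = method,
         gc_min = gc_min, gc_max = gc_max, gc_window = as.integer(gc_window),
         orf_regions = orf_regions, locked_regions = locked_regions,
         site_budget = as.integer(site_budget), seed = as.integer(seed)),
    class = "optimization_spec"
  )
}

#' @noRd
.validate_spec_against <- function(spec, n) {
  for (sp in c(spec$orf_regions, spec$locked_regions)) {
    if (sp[1] < 0 || sp[2] > n) {
      stop("region ", sp[1], "..", sp[2],
           " outside sequence of length ", n, call. = FALSE)
    }
  }
}

# Per-position editing context.
#' @noRd
.edit_context <- function(n, spec, table = NULL) {
  locked <- logical(n)
  for (sp in spec$locked_regions) locked[(sp[1] + 1L):sp[2]] <- TRUE
  orf_id <- rep(NA_integer_, n)
  codon_start <- rep(NA_integer_, n)  # 0-based start of containing codon
  for (k in seq_along(spec$orf_regions)) {
    sp <- spec$orf_regions[[k]]
    idx <- (sp[1] + 1L):sp[2]
    orf_id[idx] <- k
    codon_start[idx] <- sp[1] + ((idx - 1L - sp[1]) %/% 3L) * 3L
  }
  # a codon is editable only if none of its three bases is locked
  codon_editable <- rep(NA, n)
  in_orf <- !is.na(orf_id)
  if (any(in_orf)) {
    cs <- unique(codon_start[in_orf])
    for (c0 in cs) {
      ed <- !any(locked[(c0 + 1L):(c0 + 3L)])
      codon_editable[(c0 + 1L):(c0 + 3L)] <- ed
    }
  }
  list(n = n, locked = locked, orf_id = orf_id, codon_start = codon_start,
       codon_editable = codon_editable, in_orf = in_orf, table = table,
       code = .genetic_code())
}

#' @noRd
.gc_windows <- function(n, win) {
  starts <- seq(0L, n - 1L, by = win)
  cbind(start = starts, end = pmin(starts + win, n))
}

#' @noRd
.window_gc <- function(chars, w) {
  .gc_fraction(chars[(w[1] + 1L):w[2]])
}

# Candidate edits touching 0-based position p. Each move is
# list(span = c(start0, end0), new = character vector).
#' @noRd
.moves_at <- function(chars, ctx, p) {
  p1 <- p + 1L
  if (ctx$locked[p1]) return(list())
  if (!ctx$in_orf[p1]) {
    cur <- chars[p1]
    alts <- setdiff(c("A", "C", "G", "T"), cur)
    return(lapply(alts, function(b) list(span = c(p, p + 1L), new = b)))
  }
  if (!isTRUE(ctx$codon_editable[p1])) return(list())
  c0 <- ctx$codon_start[p1]
  cur_codon <- paste(chars[(c0 + 1L):(c0 + 3L)], collapse = "")
  aa <- ctx$code[[cur_codon]]
  syn <- setdiff(ctx$table$aa_to_codons[[aa]], cur_codon)
  if (length(syn) == 0) return(list())
  # prefer host-frequent codons (keeps the codon objective active in pass 2)
  syn <- syn[order(-ctx$table$codon_freq[syn], syn)]
  lapply(syn, function(cd) {
    list(span = c(c0, c0 + 3L), new = strsplit(cd, "")[[1]])
  })
}

#' @noRd
.apply_move <- function(chars, move) {
  chars[(move$span[1] + 1L):move$span[2]] <- move$new
  chars
}

#' @noRd
.changed_positions <- function(before, after, span) {
  idx <- (span[1] + 1L):span[2]
  span[1] - 1L + which(before[idx] != after[idx]) + 1L - 1L
}

# Safety audit of a candidate edit: GC windows touched stay in (or improve
# toward) bounds; no new qualifying SSR outside the protected span; no new
# duplicated 16-mer containing a changed base.
#' @noRd
.move_safe <- function(before, after, span, ctx, spec,
                       protected = c(-1L, -1L), check_gc = TRUE) {
  n <- ctx$n
  changed <- .changed_positions(before, after, span)
  if (length(changed) == 0) return(TRUE)

  if (check_gc) {
    wins <- .gc_windows(n, spec$gc_window)
    touch <- which(wins[, 1] < span[2] & span[1] < wins[, 2])
    for (wi in touch) {
      g_after <- .window_gc(after, wins[wi, ])
      if (is.na(g_after)) next
      if (g_after < spec$gc_min - 1e-12 || g_after > spec$gc_max + 1e-12) {
        g_before <- .window_gc(before, wins[wi, ])
        dev_b <- max(spec$gc_min - g_before, g_before - spec$gc_max, 0)
        dev_a <- max(spec$gc_min - g_after, g_after - spec$gc_max, 0)
        if (dev_a > dev_b + 1e-12) return(FALSE)
      }
    }
  }

  # local SSR check
  lo <- max(0L, min(changed) - 62L)
  hi <- min(n, max(changed) + 1L + 62L)
  seg_before <- paste(before[(lo + 1L):hi], collapse = "")
  seg_after <- paste(after[(lo + 1L):hi], collapse = "")
  key <- function(x) if (nrow(x) == 0) character(0) else
    sprintf("%d:%s:%d", x$start, x$unit, x$N)
  sa <- find_ssr_sites(seg_after, model = NULL)
  if (nrow(sa) > 0) {
    sa <- sa[!.span_overlaps(sa$start + lo, sa$end + lo,
                             protected[1], protected[2]), , drop = FALSE]
  }
  if (nrow(sa) > 0) {
    sb <- find_ssr_sites(seg_before, model = NULL)
    fresh <- setdiff(key(sa), key(sb))
    if (length(fresh) > 0) {
      # a reshaped (shrunk/rotated) run overlapping a pre-existing site is
      # not a creation; only sites in previously clean regions are
      for (k in fresh) {
        row <- sa[key(sa) == k, , drop = FALSE][1, ]
        overlaps_old <- nrow(sb) > 0 &&
          any(.span_overlaps(row$start, row$end, sb$start, sb$end))
        if (!overlaps_old) return(FALSE)
      }
    }
  }

  # new duplicated 16-mers through changed bases
  if (n >= 32) {
    full_after <- paste(after, collapse = "")
    for (p in changed) {
      w_lo <- max(0L, p - 15L)
      w_hi <- min(p, n - 16L)
      if (w_hi < w_lo) next
      for (ws in w_lo:w_hi) {
        km <- substr(full_after, ws + 1L, ws + 16L)
        if (grepl("N", km, fixed = TRUE)) next
        hits <- gregexpr(km, full_after, fixed = TRUE)[[1]]
        if (length(hits) > 1) return(FALSE)
      }
    }
  }
  TRUE
}

#' First optimization pass: codon objective plus GC regulation
#'
#' Rewrites each ORF toward the codon objective of the spec (skipping codons
#' that overlap locked regions), then repairs any GC window outside
#' `[gc_min, gc_max]` by synonymous swaps inside ORFs and free base changes
#' outside them. If no organism is given, only the constraints are resolved.
#' Deterministic given the spec.
#'
#' @param sequence DNA string.
#' @param spec An [optimization_spec()].
#' @return List with `sequence` (the rewritten string), `changes` (edit
#'   event data frame: `position` 0-based, `old_base`, `new_base`,
#'   `reason`), and `unsatisfiable_windows` (data frame naming, 1-based,
#'   any GC window that could not be brought within bounds, with its final
#'   GC fraction).
#' @export
first_pass <- function(sequence, spec) {
  sequence <- .normalize_sequence(sequence)
  n <- nchar(sequence)
  .validate_spec_against(spec, n)
  table <- if (!is.null(spec$organism)) build_codon_table(spec$organism) else NULL
  ctx <- .edit_context(n, spec, table)
  chars <- .seq_chars(sequence)
  orig <- chars
  events <- list()
  log_event <- function(pos0, old, new, reason) {
    events[[length(events) + 1L]] <<- data.frame(
      position = pos0, old_base = old, new_base = new, reason = reason,
      stringsAsFactors = FALSE)
  }

  if (!is.null(table)) {
    source_table <- build_codon_table("E. coli")
    for (k in seq_along(spec$orf_regions)) {
      sp <- spec$orf_regions[[k]]
      codons <- .split_codons(paste(chars, collapse = ""), sp[1], sp[2])
      aas <- .check_internal_stops(codons, ctx$code)
      starts0 <- sp[1] + (seq_along(codons) - 1L) * 3L
      editable <- vapply(starts0, function(c0) isTRUE(ctx$codon_editable[c0 + 1L]),
                         TRUE)
      targets <- .codon_targets(codons, aas, editable, table, spec$method,
                                source_table)
      for (i in which(targets != codons & editable)) {
        newc <- strsplit(targets[i], "")[[1]]
        oldc <- chars[(starts0[i] + 1L):(starts0[i] + 3L)]
        diffs <- which(newc != oldc)
        chars[(starts0[i] + 1L):(starts0[i] + 3L)] <- newc
        for (d in diffs) {
          log_event(starts0[i] + d - 1L, oldc[d], newc[d], "codon_optimization")
        }
      }
    }
  }

  # GC window repair
  wins <- .gc_windows(n, spec$gc_window)
  unsat <- list()
  for (wi in seq_len(nrow(wins))) {
    w <- wins[wi, ]
    guard <- 0L
    repeat {
      g <- .window_gc(chars, w)
      if (is.na(g) || (g >= spec$gc_min - 1e-12 && g <= spec$gc_max + 1e-12)) break
      need_up <- g < spec$gc_min
      guard <- guard + 1L
      if (guard > spec$gc_window * 3L) break
      move <- .find_gc_move(chars, ctx, spec, w, need_up)
      if (is.null(move)) break
      before <- chars
      chars <- .apply_move(chars, move)
      for (p in .changed_positions(before, chars, move$span)) {
        log_event(p, before[p + 1L], chars[p + 1L], "gc_regulation")
      }
    }
    g <- .window_gc(chars, w)
    if (!is.na(g) && (g < spec$gc_min - 1e-12 || g > spec$gc_max + 1e-12)) {
      unsat[[length(unsat) + 1L]] <- data.frame(
        window_start_1based = w[1] + 1L, window_end_1based = w[2],
        gc = g, stringsAsFactors = FALSE)
    }
  }

  list(
    sequence = paste(chars, collapse = ""),
    changes = if (length(events)) do.call(rbind, events) else
      data.frame(position = integer(0), old_base = character(0),
                 new_base = character(0), reason = character(0),
                 stringsAsFactors = FALSE),
    unsatisfiable_windows = if (length(unsat)) do.call(rbind, unsat) else
      data.frame(window_start_1based = integer(0), window_end_1based = integer(0),
                 gc = numeric(0), stringsAsFactors = FALSE)
  )
}

# Target codon assignment for one ORF under the chosen objective.
#' @noRd
.codon_targets <- function(codons, aas, editable, table, method, source_table) {
  targets <- codons
  if (method == "use_best_codon") {
    best <- vapply(table$aa_to_codons, function(cods) {
      cods[which.max(table$codon_freq[cods])]
    }, "")
    targets[editable] <- best[aas[editable]]
    return(targets)
  }
  if (method == "harmonize_rca") {
    for (i in which(editable)) {
      src <- source_table$aa_to_codons[[aas[i]]]
      src <- src[order(-source_table$codon_freq[src], src)]
      host <- table$aa_to_codons[[aas[i]]]
      host <- host[order(-table$codon_freq[host], host)]
      targets[i] <- host[match(codons[i], src)]
    }
    return(targets)
  }
  # match_codon_usage: largest-remainder quotas per family, keeping original
  # codons wherever quota allows (minimal-change preference)
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    cods <- table$aa_to_codons[[aa]]
    if (length(cods) == 1) next
    m <- length(idx)
    raw <- table$codon_freq[cods] * m
    quota <- floor(raw)
    rem <- m - sum(quota)
    if (rem > 0) {
      frac_order <- order(-(raw - quota), cods)
      quota[frac_order[seq_len(rem)]] <- quota[frac_order[seq_len(rem)]] + 1L
    }
    # locked codons consume quota first
    for (i in idx[!editable[idx]]) {
      if (quota[codons[i]] > 0) quota[codons[i]] <- quota[codons[i]] - 1L
    }
    pending <- integer(0)
    for (i in idx[editable[idx]]) {
      if (quota[codons[i]] > 0) {
        quota[codons[i]] <- quota[codons[i]] - 1L
      } else {
        pending <- c(pending, i)
      }
    }
    fill <- cods[order(-table$codon_freq[cods], cods)]
    for (i in pending) {
      avail <- fill[quota[fill] > 0]
      if (length(avail) == 0) break
      targets[i] <- avail[1]
      quota[avail[1]] <- quota[avail[1]] - 1L
    }
  }
  targets
}

# One safe GC-adjusting move inside window w, or NULL.
#' @noRd
.find_gc_move <- function(chars, ctx, spec, w, need_up) {
  at <- c("A", "T"); gcb <- c("G", "C")
  for (p in w[1]:(w[2] - 1L)) {
    p1 <- p + 1L
    if (ctx$locked[p1] || ctx$in_orf[p1]) next
    cur <- chars[p1]
    if (need_up && cur %in% at) {
      for (b in if (p %% 2 == 0) c("G", "C") else c("C", "G")) {
        move <- list(span = c(p, p1), new = b)
        after <- .apply_move(chars, move)
        if (.move_safe(chars, after, move$span, ctx, spec, check_gc = FALSE)) {
          return(move)
        }
      }
    } else if (!need_up && cur %in% gcb) {
      for (b in if (p %% 2 == 0) c("A", "T") else c("T", "A")) {
        move <- list(span = c(p, p1), new = b)
        after <- .apply_move(chars, move)
        if (.move_safe(chars, after, move$span, ctx, spec, check_gc = FALSE)) {
          return(move)
        }
      }
    }
  }
  # synonymous swaps
  if (!is.null(ctx$table)) {
    for (p in w[1]:(w[2] - 1L)) {
      p1 <- p + 1L
      if (!ctx$in_orf[p1] || !isTRUE(ctx$codon_editable[p1])) next
      if (ctx$codon_start[p1] != p) next  # visit each codon once
      for (move in .moves_at(chars, ctx, p)) {
        after <- .apply_move(chars, move)
        idx <- (w[1] + 1L):w[2]
        gain <- sum(after[idx] %in% gcb) - sum(chars[idx] %in% gcb)
        if ((need_up && gain > 0) || (!need_up && gain < 0)) {
          if (.move_safe(chars, after, move$span, ctx, spec, check_gc = FALSE)) {
            return(move)
          }
        }
      }
    }
  }
  NULL
}

#' Derive avoid-pattern constraints from ranked hotspot sites
#'
#' Converts the top-ranked sites of each type into localized pattern
#' constraints for the second pass: for an RMD pair, every 15-nt subsequence
#' of the first repeat copy must change (so no 16-mer identity can survive);
#' for a motif hit, the hit span must lose its positive score; for an SSR
#' run, alternating unit copies (2nd, 4th, ...) are targeted so tandem
#' identity breaks. Constraints whose span lies fully inside a locked region
#' are dropped with a warning and reported as skipped.
#'
#' @param ranked A list with data-frame elements `ssr`, `rmd`, `motif`
#'   (each possibly `NULL` or empty), as returned by the detectors after
#'   [rank_sites()].
#' @param spec An [optimization_spec()] (for locked regions).
#' @param pssms The PSSM list used for motif scanning (needed to re-score
#'   motif spans); may be `NULL` when no motif sites are given.
#' @return List of `pattern_constraint` objects with fields `kind`
#'   (`"ssr_units"`, `"recombination_15mer"`, `"motif_span"`), `span`,
#'   `status` (`"pending"` or `"skipped_locked"`), and kind-specific data.
#' @export
derive_avoid_constraints <- function(ranked, spec, pssms = NULL) {
  constraints <- list()
  fully_locked <- function(s, e) {
    any(vapply(spec$locked_regions,
               function(sp) .span_within(s, e, sp[1], sp[2]), TRUE))
  }
  add <- function(x) constraints[[length(constraints) + 1L]] <<- x

  if (!is.null(ranked$ssr) && nrow(ranked$ssr) > 0) {
    for (i in seq_len(nrow(ranked$ssr))) {
      s <- ranked$ssr[i, ]
      st <- if (fully_locked(s$start, s$end)) "skipped_locked" else "pending"
      if (st == "skipped_locked") {
        warning("SSR constraint at ", s$start, "..", s$end,
                " fully locked; skipped", call. = FALSE)
      }
      add(structure(list(kind = "ssr_units", span = c(s$start, s$end),
                         unit = s$unit, L = s$L, N = s$N, status = st),
                    class = "pattern_constraint"))
    }
  }
  if (!is.null(ranked$rmd) && nrow(ranked$rmd) > 0) {
    for (i in seq_len(nrow(ranked$rmd))) {
      s <- ranked$rmd[i, ]
      span <- c(s$first_start, s$first_start + s$repeat_len)
      st <- if (fully_locked(span[1], span[2])) "skipped_locked" else "pending"
      if (st == "skipped_locked") {
        warning("RMD constraint at ", span[1], "..", span[2],
                " fully locked; skipped", call. = FALSE)
      }
      add(structure(list(kind = "recombination_15mer", span = span,
                         second_start = s$second_start,
                         repeat_len = s$repeat_len, status = st),
                    class = "pattern_constraint"))
    }
  }
  if (!is.null(ranked$motif) && nrow(ranked$motif) > 0) {
    if (is.null(pssms)) stop("motif sites given but no pssms", call. = FALSE)
    pssm_names <- vapply(pssms, `[[`, "", "name")
    for (i in seq_len(nrow(ranked$motif))) {
      s <- ranked$motif[i, ]
      span <- c(s$start, s$start + s$width)
      st <- if (fully_locked(span[1], span[2])) "skipped_locked" else "pending"
      if (st == "skipped_locked") {
        warning("motif constraint at ", span[1], "..", span[2],
                " fully locked; skipped", call. = FALSE)
      }
      add(structure(list(kind = "motif_span", span = span, motif = s$motif,
                         strand = s$strand,
                         pssm = pssms[[match(s$motif, pssm_names)]],
                         status = st),
                    class = "pattern_constraint"))
    }
  }
  constraints
}

# PSSM score of the window starting at 0-based `start` on the given strand
# (forward coordinates).
#' @noRd
.motif_score_at <- function(chars, start, pssm, strand) {
  w <- pssm$width
  window <- paste(chars[(start + 1L):(start + w)], collapse = "")
  if (strand == "-") window <- .revcomp(window)
  codes <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T", "N"))
  sc <- cbind(pssm$scores, N = 0)
  sum(sc[cbind(seq_len(w), codes)])
}

#' Second optimization pass: remove targeted hotspot patterns
#'
#' Processes the derived constraints left to right, satisfying each through
#' synonymous codon substitutions inside ORFs and free nucleotide changes
#' outside them (never touching locked regions), while maintaining the GC
#' window bounds of pass 1. Unsatisfiable constraints are reported, never
#' silently dropped. Deterministic given `spec$seed`.
#'
#' @param sequence DNA string (typically [first_pass()] output).
#' @param spec An [optimization_spec()].
#' @param constraints From [derive_avoid_constraints()].
#' @param max_restarts Randomized retry budget per constraint (default 20).
#' @return An object of class `optimization_result`: `sequence`, `changes`
#'   (event log), `constraint_report` (one row per constraint: kind, 1-based
#'   span, status, detail), `seed`.
#' @export
second_pass <- function(sequence, spec, constraints, max_restarts = 20L) {
  sequence <- .normalize_sequence(sequence)
  n <- nchar(sequence)
  .validate_spec_against(spec, n)
  table <- if (!is.null(spec$organism)) build_codon_table(spec$organism) else {
    # synonymous edits inside ORFs still need a codon map; use E. coli order
    build_codon_table("E. coli")
  }
  ctx <- .edit_context(n, spec, table)
  chars <- .seq_chars(sequence)
  events <- list()
  report <- list()

  ord <- order(vapply(constraints, function(cn) cn$span[1], 0L))
  states <- vector("list", length(constraints))

  run_one <- function(ci, chars) {
    cn <- constraints[[ci]]
    out <- NULL
    for (attempt in 0:max_restarts) {
      res <- .with_seed(spec$seed * 1000L + ci * 100L + attempt, {
        .satisfy_constraint(chars, ctx, spec, cn, shuffle = attempt > 0)
      })
      if (res$ok) { out <- res; break }
      if (is.null(out)) out <- res
    }
    out
  }

  for (ci in ord) {
    cn <- constraints[[ci]]
    if (cn$status == "skipped_locked") {
      states[[ci]] <- list(status = "skipped (locked)", detail = "")
      next
    }
    out <- run_one(ci, chars)
    if (out$ok) chars <- out$chars
    for (ev in out$events) events[[length(events) + 1L]] <- ev
    states[[ci]] <- list(status = if (out$ok) "satisfied" else "unsatisfied",
                         detail = out$detail)
  }

  # repair sweeps: later edits can regress an earlier satisfied constraint
  # (e.g. re-raise a motif score); re-satisfy until stable
  for (sweep in 1:3) {
    regressed <- Filter(function(ci) {
      identical(states[[ci]]$status, "satisfied") &&
        !.constraint_holds(chars, ctx, constraints[[ci]])
    }, ord)
    if (length(regressed) == 0) break
    for (ci in regressed) {
      out <- run_one(ci, chars)
      if (out$ok) chars <- out$chars
      for (ev in out$events) events[[length(events) + 1L]] <- ev
      states[[ci]] <- list(status = if (out$ok) "satisfied" else "unsatisfied",
                           detail = if (out$ok) "" else
                             paste("regressed by a later edit;", out$detail))
    }
  }

  # anything still regressed after the sweeps is reported, not claimed
  for (ci in ord) {
    if (identical(states[[ci]]$status, "satisfied") &&
        !.constraint_holds(chars, ctx, constraints[[ci]])) {
      states[[ci]] <- list(status = "unsatisfied",
                           detail = "regressed by a later conflicting edit")
    }
  }

  for (ci in ord) {
    cn <- constraints[[ci]]
    detail <- states[[ci]]$detail
    if (cn$kind == "motif_span") {
      tag <- sprintf("motif=%s;strand=%s", cn$motif, cn$strand)
      detail <- if (nzchar(detail)) paste(tag, detail, sep = "; ") else tag
    }
    report[[length(report) + 1L]] <- data.frame(
      kind = cn$kind, start_1based = cn$span[1] + 1L, end_1based = cn$span[2],
      status = states[[ci]]$status, detail = detail, stringsAsFactors = FALSE)
  }

  structure(
    list(
      sequence = paste(chars, collapse = ""),
      changes = if (length(events)) do.call(rbind, events) else
        data.frame(position = integer(0), old_base = character(0),
                   new_base = character(0), reason = character(0),
                   stringsAsFactors = FALSE),
      constraint_report = if (length(report)) do.call(rbind, report) else
        data.frame(kind = character(0), start_1based = integer(0),
                   end_1based = integer(0), status = character(0),
                   detail = character(0), stringsAsFactors = FALSE),
      seed = spec$seed
    ),
    class = "optimization_result"
  )
}

# Does the constraint currently hold on `chars`?
#' @noRd
.constraint_holds <- function(chars, ctx, cn) {
  if (cn$kind == "ssr_units") {
    lo <- max(0L, cn$span[1] - 60L)
    hi <- min(ctx$n, cn$span[2] + 60L)
    seg <- paste(chars[(lo + 1L):hi], collapse = "")
    hits <- find_ssr_sites(seg, model = NULL)
    return(!(nrow(hits) > 0 &&
               any(.span_overlaps(hits$start + lo, hits$end + lo,
                                  cn$span[1], cn$span[2]))))
  }
  if (cn$kind == "recombination_15mer") {
    a <- chars[(cn$span[1] + 1L):cn$span[2]]
    b <- chars[(cn$second_start + 1L):(cn$second_start + cn$repeat_len)]
    r <- rle(a == b & a != "N")
    return(!any(r$values & r$lengths >= 16L))
  }
  .motif_score_at(chars, cn$span[1], cn$pssm, cn$strand) <= 0
}

# Attempt to satisfy one constraint on a working character vector. Returns
# list(ok, chars, events, detail).
#' @noRd
.satisfy_constraint <- function(chars, ctx, spec, cn, shuffle = FALSE) {
  events <- list()
  log_edit <- function(before, after, span, reason) {
    for (p in .changed_positions(before, after, span)) {
      events[[length(events) + 1L]] <<- data.frame(
        position = p, old_base = before[p + 1L], new_base = after[p + 1L],
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  maybe_shuffle <- function(x) if (shuffle && length(x) > 1) sample(x) else x

  if (cn$kind == "ssr_units") {
    s <- cn$span[1]; L <- cn$L; N <- cn$N
    satisfied <- function(chars) {
      lo <- max(0L, s - 60L); hi <- min(ctx$n, cn$span[2] + 60L)
      seg <- paste(chars[(lo + 1L):hi], collapse = "")
      hits <- find_ssr_sites(seg, model = NULL)
      !(nrow(hits) > 0 &&
          any(.span_overlaps(hits$start + lo, hits$end + lo,
                             cn$span[1], cn$span[2])))
    }
    if (satisfied(chars)) {
      return(list(ok = TRUE, chars = chars, events = events, detail = ""))
    }
    # phase 1: alternating unit copies (2, 4, ...); phase 2: every copy.
    # After each successful edit, stop as soon as no qualifying run overlaps
    # the original span.
    phases <- list(seq(2L, N, by = 2L), seq_len(N))
    for (phase in seq_along(phases)) {
      for (copy in maybe_shuffle(phases[[phase]])) {
        cs <- s + (copy - 1L) * L
        cur <- paste(chars[(cs + 1L):(cs + L)], collapse = "")
        if (cur != cn$unit) next  # already broken
        done <- FALSE
        for (p in maybe_shuffle(cs:(cs + L - 1L))) {
          for (move in .moves_at(chars, ctx, p)) {
            after <- .apply_move(chars, move)
            new_copy <- paste(after[(cs + 1L):(cs + L)], collapse = "")
            if (new_copy == cn$unit) next
            if (!.move_safe(chars, after, move$span, ctx, spec,
                            protected = cn$span)) next
            log_edit(chars, after, move$span, "ssr_removal")
            chars <- after
            done <- TRUE
            break
          }
          if (done) break
        }
        if (done && satisfied(chars)) {
          return(list(ok = TRUE, chars = chars, events = events, detail = ""))
        }
      }
      if (satisfied(chars)) {
        return(list(ok = TRUE, chars = chars, events = events, detail = ""))
      }
    }
    # phase 3: generic fallback — any safe edit inside the span that
    # removes the overlap (handles runs reshaped by earlier constraints)
    for (p in maybe_shuffle(cn$span[1]:(cn$span[2] - 1L))) {
      for (move in .moves_at(chars, ctx, p)) {
        after <- .apply_move(chars, move)
        if (identical(after, chars)) next
        if (!.move_safe(chars, after, move$span, ctx, spec,
                        protected = cn$span)) next
        if (!satisfied(after)) next
        log_edit(chars, after, move$span, "ssr_removal")
        chars <- after
        return(list(ok = TRUE, chars = chars, events = events, detail = ""))
      }
    }
    return(list(ok = FALSE, chars = chars, events = events,
                detail = "tandem run could not be broken (no feasible edits)"))
  }

  if (cn$kind == "recombination_15mer") {
    fs <- cn$span[1]; fe <- cn$span[2]
    cur <- fs
    orig <- chars
    while (cur + 15L <= fe) {
      placed <- FALSE
      for (p in (min(cur + 14L, fe - 1L)):cur) {
        if (chars[p + 1L] != orig[p + 1L]) { # already changed in this window
          cur <- p + 1L; placed <- TRUE; break
        }
        for (move in maybe_shuffle(.moves_at(chars, ctx, p))) {
          after <- .apply_move(chars, move)
          ch <- .changed_positions(chars, after, move$span)
          ch_in <- ch[ch >= cur & ch < cur + 15L & ch < fe]
          if (length(ch_in) == 0) next
          if (!.move_safe(chars, after, move$span, ctx, spec)) next
          log_edit(chars, after, move$span, "rmd_removal")
          chars <- after
          cur <- max(ch_in) + 1L
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) {
        return(list(ok = FALSE, chars = chars, events = events,
                    detail = sprintf(
                      "no feasible edit in 15-mer window at %d", cur + 1L)))
      }
    }
    # verify no >=16 identity with the second copy remains
    a <- chars[(fs + 1L):fe]
    b <- chars[(cn$second_start + 1L):(cn$second_start + cn$repeat_len)]
    r <- rle(a == b & a != "N")
    if (any(r$values & r$lengths >= 16L)) {
      return(list(ok = FALSE, chars = chars, events = events,
                  detail = "16-mer identity with second copy survived"))
    }
    return(list(ok = TRUE, chars = chars, events = events, detail = ""))
  }

  # motif_span: exhaustive search over the editable units (codons / free
  # bases) overlapping the hit span — the span covers only a handful of
  # units, so full enumeration is cheap and complete.
  s <- cn$span[1]
  if (.motif_score_at(chars, s, cn$pssm, cn$strand) <= 0) {
    return(list(ok = TRUE, chars = chars, events = events, detail = ""))
  }
  units <- list()
  seen_codons <- integer(0)
  for (p in s:(cn$span[2] - 1L)) {
    p1 <- p + 1L
    if (ctx$locked[p1]) next
    if (ctx$in_orf[p1]) {
      c0 <- ctx$codon_start[p1]
      if (c0 %in% seen_codons || !isTRUE(ctx$codon_editable[p1])) next
      seen_codons <- c(seen_codons, c0)
    }
    mv <- .moves_at(chars, ctx, p)
    if (length(mv) > 0) units[[length(units) + 1L]] <- mv
  }
  if (length(units) > 0) {
    n_opts <- vapply(units, length, 0L) + 1L  # +1 for "keep"
    if (prod(n_opts) <= 50000) {
      combos <- expand.grid(lapply(n_opts, function(k) seq_len(k) - 1L))
      combos <- combos[order(rowSums(combos > 0)), , drop = FALSE]
      for (r in seq_len(nrow(combos))) {
        pick <- as.integer(combos[r, ])
        if (all(pick == 0L)) next
        after <- chars
        for (u in which(pick > 0L)) {
          after <- .apply_move(after, units[[u]][[pick[u]]])
        }
        if (.motif_score_at(after, s, cn$pssm, cn$strand) > 0) next
        hull <- range(which(after != chars)) - 1L
        if (!.move_safe(chars, after, c(hull[1], hull[2] + 1L), ctx, spec)) next
        log_edit(chars, after, c(hull[1], hull[2] + 1L), "motif_removal")
        chars <- after
        break
      }
    } else {
      # too many combinations: greedy steepest descent
      repeat {
        cur_sc <- .motif_score_at(chars, s, cn$pssm, cn$strand)
        if (cur_sc <= 0) break
        best_move <- NULL; best_score <- cur_sc
        for (u in maybe_shuffle(seq_along(units))) {
          for (move in units[[u]]) {
            after <- .apply_move(chars, move)
            sc <- .motif_score_at(after, s, cn$pssm, cn$strand)
            if (sc < best_score - 1e-12 &&
                .move_safe(chars, after, move$span, ctx, spec)) {
              best_score <- sc; best_move <- move
            }
          }
        }
        if (is.null(best_move)) break
        after <- .apply_move(chars, best_move)
        log_edit(chars, after, best_move$span, "motif_removal")
        chars <- after
      }
    }
  }
  if (.motif_score_at(chars, s, cn$pssm, cn$strand) > 0) {
    return(list(ok = FALSE, chars = chars, events = events,
                detail = "motif score could not be brought below 0"))
  }
  list(ok = TRUE, chars = chars, events = events, detail = "")
}
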