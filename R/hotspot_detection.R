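# Detection of mutational hotspots: SSR tandem runs (polymerase slippage)
# and RMD direct-repeat pairs (recombination-mediated deletion).
#
# All coordinates in returned frames are 0-based half-open; report writers
# convert to 1-based inclusive.

.empty_ssr <- function() {
  data.frame(start = integer(0), end = integer(0), unit = character(0),
             L = integer(0), N = integer(0), rate = numeric(0),
             stringsAsFactors = FALSE)
}

.empty_rmd <- function() {
  data.frame(first_start = integer(0), second_start = integer(0),
             repeat_len = integer(0), spacer = integer(0), rate = numeric(0),
             stringsAsFactors = FALSE)
}

# TRUE iff `unit` (character scalar) cannot be written as a whole number of
# copies of a shorter string.
.is_primitive_unit <- function(unit) {
  L <- nchar(unit)
  if (L == 1) return(TRUE)
  for (p in seq_len(L - 1)) {
    if (L %% p == 0 &&
        unit == strrep(substr(unit, 1, p), L %/% p)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find simple-sequence-repeat (SSR) sites
#'
#' Enumerates all maximal tandem runs of a short unit (unit length
#' `1 <= L <= 15`) that qualify as slippage-prone: `N >= 3` copies for
#' `L >= 2`, `N >= 4` copies for homopolymers (`L = 1`). Runs are reported
#' once, at their leftmost start with their smallest primitive unit (so
#' `AAAAAA` is one `L = 1, N = 6` run, never also `L = 2, N = 3`), and only
#' whole unit copies are counted. N bases mismatch everything and therefore
#' break runs.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param model A [rate_model()] used to score each run; `NULL` to skip
#'   rate annotation (rates set to `NA`).
#' @return Data frame with columns `start`, `end` (0-based half-open span of
#'   the full-unit run), `unit`, `L`, `N`, `rate`, sorted by `start`.
#' @examples
#' find_ssr_sites("GGATATATATGG")  # one (AT) x 4 run
#' @export
find_ssr_sites <- function(sequence, model = rate_model()) {
  if (nchar(sequence) == 0) return(.empty_ssr())
  s <- .seq_chars(sequence)
  n <- length(s)
  res <- list()
  for (L in 1:15) {
    min_n <- if (L == 1) 4L else 3L
    if (n < L * min_n) next
    lead <- s[seq_len(n - L)]
    lag <- s[(L + 1):n]
    ok <- lead == lag & lead != "N"
    r <- rle(ok)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= L * (min_n - 1L))
    for (k in keep) {
      i <- run_starts[k]                  # 1-based start of the match run
      span <- r$lengths[k] + L            # total periodic stretch length
      N <- span %/% L
      if (N < min_n) next
      unit <- paste(s[i:(i + L - 1L)], collapse = "")
      if (!.is_primitive_unit(unit)) next
      res[[length(res) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + N * L, unit = unit,
        L = L, N = N, rate = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) return(.empty_ssr())
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$L), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(model)) out$rate <- ssr_rate(out$L, out$N, model)
  out
}

#' Find repeat-mediated-deletion (RMD) sites
#'
#' Indexes all 16-mers of the sequence, groups identical ones, and merges
#' hits at consecutive offsets (simultaneously in both copies) into maximal
#' direct repeats. One site is emitted per ordered pair of copies of each
#' maximal repeat, with repeat length `L >= 16` and spacer
#' `Ls = second_start - (first_start + L) >= 0`; pairs whose maximal extents
#' overlap are not reported (those regions are periodic and handled as SSRs).
#' Only same-strand (direct) repeats are considered; 16-mers containing N
#' never match.
#'
#' @inheritParams find_ssr_sites
#' @return Data frame with columns `first_start`, `second_start` (0-based),
#'   `repeat_len`, `spacer`, `rate`, sorted by `first_start`, `second_start`.
#' @export
find_rmd_sites <- function(sequence, model = rate_model()) {
  n <- nchar(sequence)
  if (n < 32) return(.empty_rmd())
  kmers <- substring(sequence, 1:(n - 15), 16:n)
  valid <- !grepl("N", kmers, fixed = TRUE)
  pos <- which(valid)
  groups <- split(pos, kmers[pos])
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0) return(.empty_rmd())

  # Collect (first, diagonal) for every ordered pair of occurrences.
  firsts <- integer(0); diags <- integer(0)
  for (g in groups) {
    g <- sort(g)
    m <- length(g)
    for (a in seq_len(m - 1L)) {
      firsts <- c(firsts, rep.int(g[a], m - a))
      diags <- c(diags, g[(a + 1L):m] - g[a])
    }
  }

  res <- list()
  for (d in unique(diags)) {
    ii <- sort(firsts[diags == d])
    # runs of consecutive starts on this diagonal = maximal repeats
    brk <- c(0L, which(diff(ii) != 1L), length(ii))
    for (b in seq_len(length(brk) - 1L)) {
      i0 <- ii[brk[b] + 1L]
      m <- brk[b + 1L] - brk[b]
      repeat_len <- m + 15L
      spacer <- d - repeat_len
      if (spacer < 0L) next
      res[[length(res) + 1L]] <- data.frame(
        first_start = i0 - 1L, second_start = i0 - 1L + d,
        repeat_len = repeat_len, spacer = spacer, rate = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) return(.empty_rmd())
  out <- do.call(rbind, res)
  out <- out[order(out$first_start, out$second_start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(model)) out$rate <- rmd_rate(out$repeat_len, out$spacer, model)
  out
}

#' Keep the highest-rate sites of a type
#'
#' Orders a site table by descending rate (or motif score), breaking ties by
#' ascending start position, and returns at most `budget` rows with a `rank`
#' column attached. The default budget of 10 sites per type matches the
#' intended use of targeting only the most mutation-prone sites.
#'
#' @param sites Data frame from [find_ssr_sites()], [find_rmd_sites()] or
#'   [scan_sequence()].
#' @param budget Maximum number of sites to keep (default 10).
#' @return The top rows, ranked 1..k.
#' @export
rank_sites <- function(sites, budget = 10L) {
  if (is.null(sites) || nrow(sites) == 0) {
    if (!is.null(sites)) sites$rank <- integer(0)
    return(sites)
  }
  key <- if ("rate" %in% names(sites)) sites$rate else sites$score
  start <- if ("start" %in% names(sites)) sites$start else sites$first_start
  ord <- order(-key, start)
  out <- sites[ord[seq_len(min(budget, nrow(sites)))], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
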