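# Brute-force reference enumerators. These deliberately take slow, direct
# routes (per-position unit counting; exhaustive per-diagonal scans) and are
# used to validate the production detectors and to certify hotspot-free
# fixture sequences. They share only the site definitions with the fast
# detectors, not their algorithms.

#' Brute-force SSR enumeration
#'
#' For every (start, unit length L <= 15) pair, counts whole tandem unit
#' copies by direct substring comparison and reports qualifying maximal runs
#' (leftmost phase, primitive unit). Reference implementation for
#' [find_ssr_sites()].
#'
#' @inheritParams find_ssr_sites
#' @return Same schema as [find_ssr_sites()].
#' @export
ssr_sites_bruteforce <- function(sequence, model = rate_model()) {
  if (nchar(sequence) == 0) return(.empty_ssr())
  s <- .seq_chars(sequence)
  n <- length(s)
  res <- list()
  for (L in 1:15) {
    min_n <- if (L == 1) 4L else 3L
    if (n < L * min_n) next
    units <- substring(sequence, 1:(n - L + 1), L:n)
    unit_has_n <- grepl("N", units, fixed = TRUE)
    for (i in seq_len(n - L * min_n + 1L)) {
      if (unit_has_n[i]) next
      # leftmost phase: position i-1 must break the period-L identity
      if (i > 1L && s[i - 1L] != "N" && s[i - 1L] == s[i + L - 1L]) next
      unit <- units[i]
      if (!.is_primitive_unit(unit)) next
      N <- 1L
      while (i + N * L + L - 1L <= n &&
             !unit_has_n[i + N * L] &&
             units[i + N * L] == unit) {
        N <- N + 1L
      }
      if (N < min_n) next
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

#' Brute-force RMD enumeration
#'
#' Scans every diagonal offset of the sequence-against-itself comparison for
#' maximal stretches of single-base identity of length >= 16, reporting one
#' site per ordered pair exactly as [find_rmd_sites()] defines them
#' (non-overlapping copies only). Quadratic; intended for sequences up to a
#' few kilobases.
#'
#' @inheritParams find_ssr_sites
#' @return Same schema as [find_rmd_sites()].
#' @export
rmd_sites_bruteforce <- function(sequence, model = rate_model()) {
  n <- nchar(sequence)
  if (n < 32) return(.empty_rmd())
  s <- .seq_chars(sequence)
  res <- list()
  for (d in seq_len(n - 16L)) {
    lead <- s[seq_len(n - d)]
    lag <- s[(d + 1L):n]
    ok <- lead == lag & lead != "N"
    r <- rle(ok)
    if (!any(r$values & r$lengths >= 16L)) next
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 16L)) {
      repeat_len <- r$lengths[k]
      spacer <- d - repeat_len
      if (spacer < 0L) next
      res[[length(res) + 1L]] <- data.frame(
        first_start = run_starts[k] - 1L,
        second_start = run_starts[k] - 1L + d,
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
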