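#' Per-generation mutation-rate model
#'
#' Bundles the empirical constants used to score instability hotspots:
#' the spontaneous base-pair-substitution (BPS) rate, the constants of the
#' repeat-mediated-deletion (RMD) recombination-rate curve, and the
#' coefficients of the log-linear simple-sequence-repeat (SSR) slippage fits.
#' All rates are per generation, calibrated on *Escherichia coli* data; for
#' other organisms the absolute values shift but the ranking of hypermutable
#' sites is approximately maintained, so scores should be read as rankings,
#' not absolute probabilities.
#'
#' SSR slippage follows a log-linear law, `log10(mu) = slope * N + intercept`,
#' with separate coefficient sets for homopolymer runs (unit length `L = 1`)
#' and multimer runs (`L >= 2`), mirroring the different qualification
#' thresholds and empirical fits of the two regimes.
#'
#' RMD recombination between two identical direct repeats of length `L`
#' separated by `Ls` nucleotides follows
#' `mu = 1 / ((1 + exp((alpha - L) / A)) * (B + Ls))`:
#' a logistic efficiency term in repeat length (with midpoint `alpha`, the
#' scale of the minimal efficient processing segment for homologous
#' recombination) damped hyperbolically by the inter-repeat distance.
#'
#' @param mu_bps Per-base, per-generation substitution rate. Default 2.2e-10.
#' @param rmd_A Slope scale of the logistic length term. Default 5.8.
#' @param rmd_B Distance offset of the spacer term, in nt. Default 1465.6.
#' @param rmd_alpha Midpoint of the logistic length term, in nt. Default 29.0.
#' @param ssr_homopolymer Named numeric `c(slope=, intercept=)` for `L = 1`.
#' @param ssr_multimer Named numeric `c(slope=, intercept=)` for `L >= 2`.
#' @return An object of class `rate_model`.
#' @examples
#' m <- rate_model()
#' bps_rate(1000, m)
#' @export
rate_model <- function(mu_bps = 2.2e-10,
                       rmd_A = 5.8,
                       rmd_B = 1465.6,
                       rmd_alpha = 29.0,
                       ssr_homopolymer = c(slope = 0.729, intercept = -12.915),
                       ssr_multimer = c(slope = 0.063, intercept = -4.749)) {
  stopifnot(mu_bps > 0, rmd_A > 0, rmd_B > 0, rmd_alpha > 0)
  stopifnot(ssr_homopolymer[["slope"]] > 0, ssr_multimer[["slope"]] > 0)
  structure(
    list(
      mu_bps = mu_bps,
      rmd_A = rmd_A, rmd_B = rmd_B, rmd_alpha = rmd_alpha,
      ssr_homopolymer = ssr_homopolymer,
      ssr_multimer = ssr_multimer
    ),
    class = "rate_model"
  )
}

#' Load rate-model constants from a plain-text config file
#'
#' Recognized keys (`key = value`, '#' comments allowed): `mu_bps`, `rmd_A`,
#' `rmd_B`, `rmd_alpha`, `ssr_homopolymer_slope`, `ssr_homopolymer_intercept`,
#' `ssr_multimer_slope`, `ssr_multimer_intercept`. Unset keys keep their
#' defaults.
#'
#' @param path Path to the config file.
#' @return A `rate_model`.
#' @export
rate_model_from_file <- function(path) {
  kv <- .parse_kv_file(path)
  num <- function(key, default) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  d <- rate_model()
  rate_model(
    mu_bps = num("mu_bps", d$mu_bps),
    rmd_A = num("rmd_A", d$rmd_A),
    rmd_B = num("rmd_B", d$rmd_B),
    rmd_alpha = num("rmd_alpha", d$rmd_alpha),
    ssr_homopolymer = c(
      slope = num("ssr_homopolymer_slope", d$ssr_homopolymer[["slope"]]),
      intercept = num("ssr_homopolymer_intercept", d$ssr_homopolymer[["intercept"]])
    ),
    ssr_multimer = c(
      slope = num("ssr_multimer_slope", d$ssr_multimer[["slope"]]),
      intercept = num("ssr_multimer_intercept", d$ssr_multimer[["intercept"]])
    )
  )
}

#' Whole-sequence spontaneous substitution rate
#'
#' The BPS baseline: sequence length times the per-base substitution rate.
#'
#' @param seq_length Sequence length in nt (>= 0).
#' @param model A [rate_model()].
#' @return Per-generation rate.
#' @export
bps_rate <- function(seq_length, model = rate_model()) {
  if (any(seq_length < 0)) stop("seq_length must be >= 0", call. = FALSE)
  seq_length * model$mu_bps
}

#' SSR slippage rate for a tandem run
#'
#' @param L Repeat-unit length in nt (1..15).
#' @param N Number of tandem unit copies. Sites must qualify:
#'   `N >= 3` for `L >= 2`, `N >= 4` for `L = 1`.
#' @param model A [rate_model()].
#' @return Per-generation slippage rate (vectorized over `L`, `N`).
#' @export
ssr_rate <- function(L, N, model = rate_model()) {
  if (length(L) != length(N)) {
    lens <- c(length(L), length(N))
    if (min(lens) != 1L) stop("L and N lengths differ", call. = FALSE)
    L <- rep_len(L, max(lens)); N <- rep_len(N, max(lens))
  }
  if (any(L < 1 | L > 15)) stop("unit length L must be in 1..15", call. = FALSE)
  qual <- (L == 1 & N >= 4) | (L >= 2 & N >= 3)
  if (any(!qual)) {
    stop("non-qualifying SSR site: need N >= 4 for L = 1 or N >= 3 for L >= 2",
         call. = FALSE)
  }
  slope <- ifelse(L == 1, model$ssr_homopolymer[["slope"]],
                  model$ssr_multimer[["slope"]])
  intercept <- ifelse(L == 1, model$ssr_homopolymer[["intercept"]],
                      model$ssr_multimer[["intercept"]])
  10^(slope * N + intercept)
}

#' RMD recombination rate for a direct-repeat pair
#'
#' @param repeat_len Length `L` of each repeat copy in nt (>= 16).
#' @param spacer Distance `Ls` between the end of the first copy and the
#'   start of the second, in nt (>= 0).
#' @param model A [rate_model()].
#' @return Per-generation recombination rate (vectorized).
#' @export
rmd_rate <- function(repeat_len, spacer, model = rate_model()) {
  if (any(repeat_len < 16)) stop("repeat_len must be >= 16", call. = FALSE)
  if (any(spacer < 0)) stop("spacer must be >= 0", call. = FALSE)
  1 / ((1 + exp((model$rmd_alpha - repeat_len) / model$rmd_A)) *
         (model$rmd_B + spacer))
}

#' Relative instability score of a sequence
#'
#' Ratio of the total predicted per-generation mutation rate (BPS baseline
#' plus all SSR slippage and RMD recombination rates) to the BPS-only rate.
#' Answers: how much more likely is the sequence to mutate when its slippage
#' and recombination hotspots are considered, relative to spontaneous
#' substitutions alone? Takes its minimal value of exactly 1 when the
#' sequence carries no qualifying SSR and no RMD site.
#'
#' @param seq_length Sequence length in nt (> 0).
#' @param ssr_sites Data frame from [find_ssr_sites()] (or any frame with a
#'   `rate` column); may have zero rows.
#' @param rmd_sites Data frame from [find_rmd_sites()]; may have zero rows.
#' @param model A [rate_model()].
#' @return Dimensionless score >= 1.
#' @export
rip_score <- function(seq_length, ssr_sites = NULL, rmd_sites = NULL,
                      model = rate_model()) {
  if (seq_length <= 0) stop("seq_length must be > 0 (ratio undefined)", call. = FALSE)
  site_rates <- function(x) {
    if (is.null(x) || nrow(x) == 0) 0 else sum(x$rate)
  }
  baseline <- bps_rate(seq_length, model)
  (baseline + site_rates(ssr_sites) + site_rates(rmd_sites)) / baseline
}
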