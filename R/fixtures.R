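# Deterministic synthetic-sequence generation with planted hotspots at
# known coordinates. These generators back the whole test harness: every
# detector and the optimizer can be exercised against exact planted truth
# with no external data.

#' Seeded random DNA sequence
#'
#' @param length Sequence length (> 0).
#' @param gc_fraction Target GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed; identical arguments always give identical
#'   sequences, and the caller's RNG state is untouched.
#' @return A DNA string.
#' @export
random_sequence <- function(length, gc_fraction = 0.5, seed = 0L) {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  .with_seed(seed, {
    probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
               G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

#' Hotspot-free random sequence
#'
#' Generates a random sequence and locally resamples it until it contains no
#' qualifying SSR run and no duplicated 16-mer, then (by default) certifies
#' the result against the brute-force enumerators. The relative-instability
#' score of such a sequence is exactly 1.
#'
#' @param length Sequence length (>= 16).
#' @param seed Integer seed.
#' @param verify Certify with [ssr_sites_bruteforce()] and
#'   [rmd_sites_bruteforce()] before returning (default `TRUE`).
#' @param max_rounds Resampling round cap (default 200).
#' @return A DNA string free of SSR and RMD hotspots.
#' @export
hotspot_free_sequence <- function(length, seed = 0L, verify = TRUE,
                                  max_rounds = 200L) {
  stopifnot(length >= 16)
  .with_seed(seed, {
    chars <- strsplit(random_sequence(length, 0.5, seed = seed + 1L), "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (round in seq_len(max_rounds)) {
      seq_str <- paste(chars, collapse = "")
      ssr <- find_ssr_sites(seq_str, model = NULL)
      rmd <- find_rmd_sites(seq_str, model = NULL)
      if (nrow(ssr) == 0 && nrow(rmd) == 0) break
      spans <- rbind(
        if (nrow(ssr)) cbind(ssr$start, ssr$end),
        if (nrow(rmd)) cbind(rmd$second_start, rmd$second_start + rmd$repeat_len)
      )
      for (r in seq_len(nrow(spans))) {
        idx <- (spans[r, 1] + 1L):spans[r, 2]
        for (i in idx) {
          # avoid immediate period-1/2 extension; keep >= 2 random choices
          # so no long-range forced periodicity arises
          forbidden <- unique(chars[max(i - 2, 1):max(i - 1, 1)])
          chars[i] <- sample(setdiff(bases, forbidden), 1)
        }
      }
    }
    seq_str <- paste(chars, collapse = "")
    if (nrow(find_ssr_sites(seq_str, model = NULL)) > 0 ||
        nrow(find_rmd_sites(seq_str, model = NULL)) > 0) {
      stop("failed to generate a hotspot-free sequence after ",
           max_rounds, " rounds", call. = FALSE)
    }
    if (verify) {
      if (nrow(ssr_sites_bruteforce(seq_str, model = NULL)) > 0 ||
          nrow(rmd_sites_bruteforce(seq_str, model = NULL)) > 0) {
        stop("brute-force certification failed (detector disagreement)",
             call. = FALSE)
      }
    }
    seq_str
  })
}

#' @noRd
.check_plant_span <- function(truth, start, end, n) {
  if (start < 0 || end > n) stop("planted span outside sequence", call. = FALSE)
  if (!is.null(truth) && nrow(truth) > 0 &&
      any(.span_overlaps(truth$start, truth$end, start, end))) {
    stop("planted span overlaps an existing planted feature", call. = FALSE)
  }
}

#' @noRd
.truth_row <- function(type, start, end, detail) {
  data.frame(type = type, start = start, end = end, detail = detail,
             stringsAsFactors = FALSE)
}

#' Plant a tandem-repeat (SSR) run
#'
#' Replaces the subsequence at `position` with `N` copies of `unit` and
#' repairs the immediate flanks so the run's maximal extent equals its
#' declared extent (the flanking bases are forced to break the period).
#'
#' @param sequence DNA string.
#' @param unit Repeat unit (1-15 nt).
#' @param N Copy number; must qualify (`N >= 3` for units >= 2 nt,
#'   `N >= 4` for single-base units).
#' @param position 0-based start of the run.
#' @param truth Optional existing planted-truth data frame to append to.
#' @return List `sequence`, `truth` (data frame `type`, `start`, `end`,
#'   `detail`).
#' @export
plant_ssr <- function(sequence, unit, N, position, truth = NULL) {
  L <- nchar(unit)
  stopifnot(L >= 1, L <= 15)
  if (!((L == 1 && N >= 4) || (L >= 2 && N >= 3))) {
    stop("planted SSR must qualify: N >= 4 for L = 1, N >= 3 for L >= 2",
         call. = FALSE)
  }
  n <- nchar(sequence)
  end <- position + L * N
  .check_plant_span(truth, position, end, n)
  chars <- .seq_chars(sequence)
  chars[(position + 1L):end] <- rep(strsplit(unit, "")[[1]], N)
  # flank repair: break the period-L identity one base before and after
  if (position >= 1L && chars[position] == chars[position + L]) {
    chars[position] <- setdiff(c("A", "C", "G", "T"),
                               c(chars[position + L],
                                 if (position >= 2L) chars[position - 1L]))[1]
  }
  if (end < n && chars[end + 1L] == chars[end + 1L - L]) {
    chars[end + 1L] <- setdiff(c("A", "C", "G", "T"),
                               c(chars[end + 1L - L],
                                 if (end + 2L <= n) chars[end + 2L]))[1]
  }
  list(sequence = paste(chars, collapse = ""),
       truth = rbind(truth, .truth_row("ssr", position, end,
                                       sprintf("unit=%s;N=%d", unit, N))))
}

#' Plant a direct-repeat (RMD) pair
#'
#' Writes a random repeat block of length `L` at `position`, a spacer of the
#' requested length, and an identical second copy, then repairs the flanks
#' and spacer edges so the maximal repeat length is exactly `L`.
#'
#' @param sequence DNA string.
#' @param L Repeat length (>= 16).
#' @param spacer Gap between the copies in nt (>= 0).
#' @param position 0-based start of the first copy.
#' @param seed Seed for the repeat block content.
#' @param truth Optional truth table to append to.
#' @return List `sequence`, `truth`.
#' @export
plant_rmd <- function(sequence, L, spacer, position, seed = 0L, truth = NULL) {
  stopifnot(L >= 16, spacer >= 0)
  n <- nchar(sequence)
  end <- position + 2L * L + spacer
  .check_plant_span(truth, position, end, n)
  chars <- .seq_chars(sequence)
  first <- position; second <- position + L + spacer
  block <- .with_seed(seed, {
    # rejection-sample a repeat block that carries no SSR of its own and
    # whose 16-mers occur nowhere else in the sequence
    ok_block <- NULL
    for (attempt in 1:50) {
      b <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      if (nrow(find_ssr_sites(b, model = NULL)) > 0) next
      trial <- chars
      trial[(first + 1L):(first + L)] <- strsplit(b, "")[[1]]
      trial_str <- paste(trial, collapse = "")
      kms <- substring(b, 1:(L - 15L), 16:L)
      n_hits <- vapply(kms, function(k) {
        length(gregexpr(k, trial_str, fixed = TRUE)[[1]])
      }, 0L)
      if (all(n_hits == 1L)) { ok_block <- b; break }
    }
    if (is.null(ok_block)) {
      stop("could not sample a clean repeat block", call. = FALSE)
    }
    strsplit(ok_block, "")[[1]]
  })
  chars[(first + 1L):(first + L)] <- block
  chars[(second + 1L):(second + L)] <- block
  # flank repair: the bases immediately around both copies must break
  # identity so the maximal repeat is exactly L
  fix <- function(chars, pos_a, pos_b) {
    # force chars[pos_a] != chars[pos_b] (1-based; skip if out of range)
    if (pos_a >= 1L && pos_a <= n && pos_b >= 1L && pos_b <= n &&
        chars[pos_a] == chars[pos_b]) {
      chars[pos_a] <- setdiff(c("A", "C", "G", "T"),
                              c(chars[pos_b],
                                chars[max(1L, pos_a - 1L)],
                                chars[min(n, pos_a + 1L)]))[1]
    }
    chars
  }
  chars <- fix(chars, first, second)                       # before copies
  chars <- fix(chars, first + L + 1L, second + L + 1L)     # after copies
  list(sequence = paste(chars, collapse = ""),
       truth = rbind(truth, .truth_row("rmd", first, end,
                                       sprintf("L=%d;spacer=%d;second_start=%d",
                                               L, spacer, second))))
}

#' Plant a motif consensus site
#'
#' Writes the consensus sequence of a motif (or its reverse complement for
#' the minus strand) at the given position.
#'
#' @param sequence DNA string.
#' @param motif A `motif_matrix` from [parse_meme_minimal()].
#' @param position 0-based start of the site (forward coordinates).
#' @param strand `"+"` or `"-"`.
#' @param truth Optional truth table to append to.
#' @return List `sequence`, `truth`.
#' @export
plant_motif <- function(sequence, motif, position, strand = "+", truth = NULL) {
  stopifnot(strand %in% c("+", "-"))
  w <- motif$width
  n <- nchar(sequence)
  .check_plant_span(truth, position, position + w, n)
  site <- motif_consensus(motif)
  if (strand == "-") site <- .revcomp(site)
  chars <- .seq_chars(sequence)
  chars[(position + 1L):(position + w)] <- strsplit(site, "")[[1]]
  list(sequence = paste(chars, collapse = ""),
       truth = rbind(truth, .truth_row("motif", position, position + w,
                                       sprintf("motif=%s;strand=%s",
                                               motif$name, strand))))
}

#' Detection test fixture: hotspot-free background with three planted sites
#'
#' Builds a sequence on a hotspot-free background carrying exactly one
#' planted SSR run, one planted RMD pair (repeat length 20, spacer 30), and
#' one planted motif consensus site, at seed-dependent non-overlapping
#' coordinates. The SSR unit and copy number, the motif, and the motif
#' strand all rotate with the seed.
#'
#' @param seed Integer seed.
#' @param length Total sequence length (default 600).
#' @param motifs Motif list from [parse_meme_minimal()]; defaults to the
#'   bundled methylation set.
#' @return List `sequence`, `truth` (planted-truth data frame).
#' @export
detection_fixture <- function(seed, length = 600L, motifs = NULL) {
  if (is.null(motifs)) {
    motifs <- parse_meme_minimal(
      system.file("extdata", "methylation_motifs_synthetic.meme",
                  package = "seqstab", mustWork = TRUE))$motifs
  }
  bg <- hotspot_free_sequence(length, seed = seed, verify = FALSE)
  units <- c("A", "AT", "CAG", "TG", "C")
  unit <- units[(seed %% length(units)) + 1L]
  N <- if (nchar(unit) == 1) 4L + (seed %% 4L) else 3L + (seed %% 3L)
  # motifs with SSR-free consensus only, so planted spans stay exact
  ok_motifs <- Filter(function(m) {
    nrow(find_ssr_sites(motif_consensus(m), model = NULL)) == 0
  }, motifs)
  motif <- ok_motifs[[(seed %% length(ok_motifs)) + 1L]]
  strand <- if (seed %% 2 == 0) "+" else "-"

  p <- plant_ssr(bg, unit, N, position = 50L)
  p <- plant_rmd(p$sequence, L = 20L, spacer = 30L, position = 150L,
                 seed = seed + 7L, truth = p$truth)
  p <- plant_motif(p$sequence, motif, position = 300L, strand = strand,
                   truth = p$truth)
  p
}

#' Optimizer test fixture: an ORF with removable planted hotspots
#'
#' Builds `5' UTR + ORF + 3' UTR` where the ORF carries a planted
#' homopolymer run spanning lysine codons (`AAA AAA AAA`) and a duplicated
#' seven-codon block (a 21-nt direct repeat), and the 3' UTR carries a
#' planted motif consensus. All planted sites are removable: the SSR and
#' RMD sit on synonymously editable codons, the motif in freely editable
#' non-coding sequence. Intended for end-to-end optimizer runs in
#' custom-motif mode with the returned `motif`.
#'
#' @param seed Integer seed.
#' @param n_codons ORF length in sense codons (default 150).
#' @param utr5,utr3 UTR lengths in nt (defaults 60 and 90).
#' @param motifs Motif list; defaults to the bundled methylation set.
#' @return List `sequence`, `orf_span` (0-based half-open), `truth`,
#'   `motif` (the planted `motif_matrix`), `motif_strand`.
#' @export
stability_fixture <- function(seed, n_codons = 150L, utr5 = 60L, utr3 = 90L,
                              motifs = NULL) {
  if (is.null(motifs)) {
    motifs <- parse_meme_minimal(
      system.file("extdata", "methylation_motifs_synthetic.meme",
                  package = "seqstab", mustWork = TRUE))$motifs
  }
  ok_motifs <- Filter(function(m) {
    nrow(find_ssr_sites(motif_consensus(m), model = NULL)) == 0
  }, motifs)
  motif <- ok_motifs[[(seed %% length(ok_motifs)) + 1L]]
  strand <- if (seed %% 2 == 0) "+" else "-"

  aa_pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q",
               "R", "S", "T", "V", "Y")
  aas <- .with_seed(seed + 1L, sample(aa_pool, n_codons, replace = TRUE))
  k_at <- n_codons %/% 3L             # codon index (0-based) of the Lys run
  aas[(k_at + 1L):(k_at + 3L)] <- "K"
  # flanking codons must neither start nor end with A in any synonymous
  # form, so breaking the run by AAA->AAG swaps is always feasible
  aas[k_at] <- "D"        # GAY
  aas[k_at + 4L] <- "V"   # GTN
  orf <- random_orf_sequence(n_codons, seed = seed + 2L,
                             aa_string = paste(aas, collapse = ""))
  chars <- .seq_chars(orf)
  chars[(k_at * 3L + 1L):(k_at * 3L + 9L)] <- "A"  # force AAA AAA AAA
  # duplicate a seven-codon block: codons b1..b1+6 -> codons b2..b2+6
  b1 <- 4L
  b2 <- min(n_codons - 8L, 2L * n_codons %/% 3L)
  block <- chars[(b1 * 3L + 1L):(b1 * 3L + 21L)]
  chars[(b2 * 3L + 1L):(b2 * 3L + 21L)] <- block
  orf <- paste(chars, collapse = "")

  pre <- hotspot_free_sequence(utr5, seed = seed + 3L, verify = FALSE)
  post <- hotspot_free_sequence(utr3, seed = seed + 4L, verify = FALSE)
  seq <- paste0(pre, orf, post)
  n_orf <- nchar(orf)
  orf_span <- c(utr5, utr5 + n_orf)

  truth <- rbind(
    .truth_row("ssr", utr5 + k_at * 3L, utr5 + k_at * 3L + 9L, "unit=A;N=9"),
    .truth_row("rmd", utr5 + b1 * 3L, utr5 + b2 * 3L + 21L,
               sprintf("L=21;second_start=%d", utr5 + b2 * 3L))
  )
  p <- plant_motif(seq, motif, position = utr5 + n_orf + utr3 - 30L,
                   strand = strand, truth = truth)
  list(sequence = p$sequence, orf_span = orf_span, truth = p$truth,
       motif = motif, motif_strand = strand)
}

#' Random ORF sequence from an amino-acid string
#'
#' Builds a coding sequence codon by codon from a supplied (or random)
#' amino-acid sequence, guaranteeing divisibility by 3 and no internal
#' stops; codons are drawn uniformly from each family.
#'
#' @param n_codons Number of sense codons (a TAA stop is appended when
#'   `stop = TRUE`).
#' @param seed Integer seed.
#' @param aa_string Optional amino-acid string (one-letter codes) to encode;
#'   random if `NULL`.
#' @param stop Append a stop codon (default `TRUE`).
#' @return A DNA string of length `3 * (n_codons + stop)`.
#' @export
random_orf_sequence <- function(n_codons, seed = 0L, aa_string = NULL,
                                stop = TRUE) {
  code <- .genetic_code()
  aa_to_codons <- split(names(code), code)
  .with_seed(seed, {
    aas <- if (is.null(aa_string)) {
      sample(setdiff(names(aa_to_codons), "*"), n_codons, replace = TRUE)
    } else {
      strsplit(aa_string, "")[[1]]
    }
    if (any(aas == "*")) stop("internal stop in aa_string", call. = FALSE)
    codons <- vapply(aas, function(a) {
      cods <- aa_to_codons[[a]]
      cods[sample.int(length(cods), 1)]
    }, "")
    paste0(paste(codons, collapse = ""), if (stop) "TAA" else "")
  })
}
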