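# Host codon-usage tables and codon-level optimization objectives.
#
# Usage values are within-synonymous-family relative frequencies transcribed
# (rounded to two decimals) from standard published codon-usage
# compilations; they are renormalized exactly per family at load. Only the
# within-family ordering and rough proportions matter to the optimizer.

.CODON_ORGANISMS <- c("b_subtilis", "c_elegans", "d_melanogaster", "e_coli",
                      "g_gallus", "h_sapiens", "m_musculus", "s_cerevisiae")

# columns: b_subtilis c_elegans d_melanogaster e_coli g_gallus h_sapiens
#          m_musculus s_cerevisiae
.CODON_USAGE_RAW <- c(
  "TTT 0.68 0.49 0.37 0.57 0.42 0.46 0.43 0.59",
  "TTC 0.32 0.51 0.63 0.43 0.58 0.54 0.57 0.41",
  "TTA 0.21 0.11 0.05 0.13 0.06 0.08 0.06 0.28",
  "TTG 0.16 0.23 0.18 0.13 0.13 0.13 0.13 0.29",
  "CTT 0.23 0.25 0.10 0.10 0.12 0.13 0.13 0.13",
  "CTC 0.11 0.17 0.15 0.10 0.19 0.20 0.20 0.06",
  "CTA 0.05 0.09 0.09 0.04 0.07 0.07 0.08 0.14",
  "CTG 0.24 0.15 0.43 0.50 0.43 0.39 0.40 0.10",
  "ATT 0.49 0.53 0.34 0.51 0.32 0.36 0.34 0.46",
  "ATC 0.37 0.31 0.47 0.42 0.53 0.47 0.50 0.26",
  "ATA 0.14 0.16 0.19 0.07 0.15 0.17 0.16 0.28",
  "ATG 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00",
  "GTT 0.28 0.39 0.18 0.26 0.17 0.18 0.17 0.39",
  "GTC 0.26 0.22 0.24 0.22 0.23 0.24 0.25 0.21",
  "GTA 0.20 0.16 0.11 0.15 0.11 0.12 0.12 0.21",
  "GTG 0.26 0.23 0.47 0.37 0.49 0.46 0.46 0.19",
  "TCT 0.20 0.21 0.08 0.15 0.15 0.19 0.19 0.26",
  "TCC 0.13 0.13 0.24 0.15 0.22 0.22 0.22 0.16",
  "TCA 0.19 0.15 0.09 0.12 0.12 0.15 0.14 0.21",
  "TCG 0.13 0.15 0.20 0.15 0.06 0.05 0.05 0.10",
  "AGT 0.17 0.15 0.11 0.15 0.15 0.15 0.15 0.16",
  "AGC 0.18 0.21 0.28 0.28 0.30 0.24 0.25 0.11",
  "CCT 0.28 0.18 0.13 0.16 0.29 0.29 0.31 0.31",
  "CCC 0.09 0.09 0.33 0.12 0.32 0.32 0.30 0.15",
  "CCA 0.20 0.53 0.25 0.19 0.27 0.28 0.28 0.42",
  "CCG 0.43 0.20 0.29 0.53 0.12 0.11 0.11 0.12",
  "ACT 0.16 0.33 0.17 0.17 0.26 0.25 0.25 0.35",
  "ACC 0.35 0.18 0.38 0.43 0.36 0.36 0.35 0.22",
  "ACA 0.30 0.34 0.19 0.13 0.28 0.28 0.29 0.30",
  "ACG 0.19 0.15 0.26 0.27 0.10 0.11 0.11 0.13",
  "GCT 0.29 0.36 0.19 0.16 0.27 0.27 0.29 0.38",
  "GCC 0.21 0.20 0.45 0.27 0.41 0.40 0.38 0.22",
  "GCA 0.28 0.31 0.17 0.21 0.22 0.23 0.23 0.29",
  "GCG 0.22 0.13 0.19 0.36 0.10 0.11 0.10 0.11",
  "TAT 0.65 0.56 0.37 0.57 0.40 0.44 0.43 0.56",
  "TAC 0.35 0.44 0.63 0.43 0.60 0.56 0.57 0.44",
  "TAA 0.61 0.44 0.41 0.64 0.27 0.30 0.28 0.47",
  "TAG 0.15 0.17 0.33 0.07 0.22 0.24 0.23 0.23",
  "TGA 0.24 0.39 0.26 0.29 0.51 0.46 0.49 0.30",
  "CAT 0.68 0.61 0.40 0.57 0.41 0.42 0.40 0.64",
  "CAC 0.32 0.39 0.60 0.43 0.59 0.58 0.60 0.36",
  "CAA 0.52 0.66 0.30 0.35 0.26 0.27 0.25 0.69",
  "CAG 0.48 0.34 0.70 0.65 0.74 0.73 0.75 0.31",
  "AAT 0.56 0.62 0.44 0.45 0.42 0.47 0.43 0.59",
  "AAC 0.44 0.38 0.56 0.55 0.58 0.53 0.57 0.41",
  "AAA 0.70 0.59 0.30 0.77 0.40 0.43 0.39 0.58",
  "AAG 0.30 0.41 0.70 0.23 0.60 0.57 0.61 0.42",
  "GAT 0.64 0.68 0.53 0.63 0.43 0.46 0.44 0.65",
  "GAC 0.36 0.32 0.47 0.37 0.57 0.54 0.56 0.35",
  "GAA 0.68 0.62 0.33 0.69 0.39 0.42 0.40 0.70",
  "GAG 0.32 0.38 0.67 0.31 0.61 0.58 0.60 0.30",
  "TGT 0.46 0.55 0.29 0.44 0.41 0.46 0.48 0.63",
  "TGC 0.54 0.45 0.71 0.56 0.59 0.54 0.52 0.37",
  "TGG 1.00 1.00 1.00 1.00 1.00 1.00 1.00 1.00",
  "CGT 0.18 0.21 0.16 0.38 0.08 0.08 0.09 0.14",
  "CGC 0.20 0.10 0.33 0.40 0.18 0.18 0.18 0.06",
  "CGA 0.10 0.23 0.15 0.06 0.11 0.11 0.12 0.07",
  "CGG 0.17 0.09 0.15 0.10 0.21 0.20 0.19 0.04",
  "AGA 0.25 0.29 0.09 0.04 0.21 0.21 0.21 0.48",
  "AGG 0.10 0.08 0.12 0.02 0.21 0.22 0.21 0.21",
  "GGT 0.19 0.20 0.21 0.34 0.19 0.16 0.18 0.47",
  "GGC 0.34 0.12 0.43 0.41 0.37 0.34 0.33 0.19",
  "GGA 0.31 0.60 0.26 0.11 0.27 0.25 0.26 0.22",
  "GGG 0.16 0.08 0.10 0.14 0.17 0.25 0.23 0.12"
)

# Canonical organism display names -> internal keys. M. musculus domesticus
# shares the M. musculus table.
.ORGANISM_ALIASES <- c(
  "B. subtilis" = "b_subtilis",
  "Bacillus subtilis" = "b_subtilis",
  "C. elegans" = "c_elegans",
  "Caenorhabditis elegans" = "c_elegans",
  "D. melanogaster" = "d_melanogaster",
  "Drosophila melanogaster" = "d_melanogaster",
  "E. coli" = "e_coli",
  "Escherichia coli" = "e_coli",
  "G. gallus" = "g_gallus",
  "Gallus gallus" = "g_gallus",
  "H. sapiens" = "h_sapiens",
  "Homo sapiens" = "h_sapiens",
  "M. musculus" = "m_musculus",
  "Mus musculus" = "m_musculus",
  "M. musculus domesticus" = "m_musculus",
  "Mus musculus domesticus" = "m_musculus",
  "S. cerevisiae" = "s_cerevisiae",
  "Saccharomyces cerevisiae" = "s_cerevisiae"
)

#' @noRd
.codon_usage_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    toks <- strsplit(.CODON_USAGE_RAW, "[[:space:]]+")
    codons <- vapply(toks, `[`, "", 1L)
    vals <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(8)))
    dimnames(vals) <- list(codons, .CODON_ORGANISMS)
    cache <<- vals
    cache
  }
})

#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

#' Supported codon-optimization organisms
#'
#' @return Character vector of accepted organism names.
#' @export
supported_organisms <- function() {
  c("B. subtilis", "C. elegans", "D. melanogaster", "E. coli", "G. gallus",
    "H. sapiens", "M. musculus", "M. musculus domesticus", "S. cerevisiae")
}

#' Build the codon-usage table for a host organism
#'
#' Returns within-family relative codon frequencies (each synonymous family,
#' including the stop family, sums to exactly 1) together with the
#' amino-acid-to-codon map.
#'
#' @param organism One of [supported_organisms()] (full binomials accepted).
#' @return An object of class `codon_table`: `organism`, `codon_freq`
#'   (named numeric over all 64 codons), `codon_to_aa`, `aa_to_codons`
#'   (list keyed by amino-acid letter, `*` for stop).
#' @export
build_codon_table <- function(organism) {
  key <- .ORGANISM_ALIASES[organism]
  if (is.na(key)) {
    stop("unknown organism '", organism, "'; supported: ",
         paste(supported_organisms(), collapse = ", "), call. = FALSE)
  }
  usage <- .codon_usage_matrix()[, key]
  code <- .genetic_code()
  aa_to_codons <- split(names(code), code)
  # renormalize exactly within each family
  for (aa in names(aa_to_codons)) {
    cods <- aa_to_codons[[aa]]
    usage[cods] <- usage[cods] / sum(usage[cods])
  }
  structure(
    list(organism = organism, codon_freq = usage,
         codon_to_aa = code, aa_to_codons = aa_to_codons),
    class = "codon_table"
  )
}

#' @noRd
.split_codons <- function(sequence, orf_start, orf_end) {
  len <- orf_end - orf_start
  if (len %% 3 != 0) stop("ORF length must be divisible by 3", call. = FALSE)
  substring(sequence, orf_start + 1L + seq(0, len - 3, by = 3),
            orf_start + seq(3, len, by = 3))
}

#' @noRd
.check_internal_stops <- function(codons, code) {
  aas <- code[codons]
  internal <- aas[-length(aas)]
  if (any(internal == "*")) {
    stop("internal stop codon at ORF codon ",
         which(internal == "*")[1], call. = FALSE)
  }
  aas
}

#' Relative adaptiveness of codons (frequency / family maximum).
#' @noRd
.relative_adaptiveness <- function(table) {
  w <- table$codon_freq
  for (aa in names(table$aa_to_codons)) {
    cods <- table$aa_to_codons[[aa]]
    w[cods] <- w[cods] / max(w[cods])
  }
  w
}

#' Score an ORF against a codon-usage objective
#'
#' Three objectives are supported, named after the standard codon
#' optimization modes:
#' \describe{
#'   \item{use_best_codon}{Fraction of codons that are their synonymous
#'     family's highest-frequency codon; 1 is optimal.}
#'   \item{match_codon_usage}{Negative L1 distance between the ORF's
#'     observed within-family codon frequencies and the host table,
#'     weighted by each amino acid's count in the ORF; 0 is optimal.}
#'   \item{harmonize_rca}{Mean agreement (1 minus absolute difference)
#'     between each codon's relative adaptiveness under the host table and
#'     the original codon's relative adaptiveness under a source table;
#'     1 is optimal.}
#' }
#'
#' @param sequence DNA string.
#' @param orf_span 0-based half-open `c(start, end)`; length divisible by 3;
#'   no internal stop codons.
#' @param table Host [build_codon_table()].
#' @param method One of `"use_best_codon"`, `"match_codon_usage"`,
#'   `"harmonize_rca"`.
#' @param original_sequence For `harmonize_rca`: the sequence whose codons
#'   define the original ranks (default: `sequence` itself).
#' @param source_table For `harmonize_rca`: table of the sequence's source
#'   organism (default *E. coli*).
#' @return Numeric objective value (larger is better for all methods).
#' @export
codon_objective_score <- function(sequence, orf_span, table, method,
                                  original_sequence = sequence,
                                  source_table = NULL) {
  method <- match.arg(method,
                      c("use_best_codon", "match_codon_usage", "harmonize_rca"))
  codons <- .split_codons(sequence, orf_span[1], orf_span[2])
  aas <- .check_internal_stops(codons, table$codon_to_aa)

  if (method == "use_best_codon") {
    best <- vapply(table$aa_to_codons, function(cods) {
      cods[which.max(table$codon_freq[cods])]
    }, "")
    return(mean(codons == best[aas]))
  }

  if (method == "match_codon_usage") {
    total <- 0
    for (aa in unique(aas)) {
      cods <- table$aa_to_codons[[aa]]
      if (length(cods) == 1) next
      obs <- table(factor(codons[aas == aa], levels = cods))
      obs <- as.numeric(obs) / sum(obs)
      total <- total + sum(aas == aa) * sum(abs(obs - table$codon_freq[cods]))
    }
    return(-total / length(codons))
  }

  # harmonize_rca
  if (is.null(source_table)) source_table <- build_codon_table("E. coli")
  orig_codons <- .split_codons(original_sequence, orf_span[1], orf_span[2])
  w_host <- .relative_adaptiveness(table)
  w_source <- .relative_adaptiveness(source_table)
  mean(1 - abs(w_host[codons] - w_source[orig_codons]))
}
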