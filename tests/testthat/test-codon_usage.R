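test_that("every supported organism loads a normalized usage table", {
  for (org in supported_organisms()) {
    tab <- build_codon_table(org)
    expect_equal(length(tab$codon_freq), 64L)
    for (aa in names(tab$aa_to_codons)) {
      expect_equal(sum(tab$codon_freq[tab$aa_to_codons[[aa]]]), 1,
                   tolerance = 1e-9)
    }
  }
  expect_error(build_codon_table("X. laevis"), "unknown organism")
  # the murine subspecies shares the M. musculus table
  expect_equal(build_codon_table("M. musculus domesticus")$codon_freq,
               build_codon_table("M. musculus")$codon_freq)
})

test_that("use_best_codon scores 1 for an all-best ORF and less otherwise", {
  tab <- build_codon_table("E. coli")
  best <- vapply(tab$aa_to_codons, function(cods) {
    cods[which.max(tab$codon_freq[cods])]
  }, "")
  orf <- paste0(best[["K"]], best[["L"]], best[["G"]], best[["*"]])
  expect_equal(codon_objective_score(orf, c(0L, 12L), tab, "use_best_codon"), 1)
  worst <- paste0("AAG", "CTA", "GGG", "TAA")
  expect_lt(codon_objective_score(worst, c(0L, 12L), tab, "use_best_codon"), 1)
  expect_error(
    codon_objective_score("ATGTAAAAATAA", c(0L, 12L), tab, "use_best_codon"),
    "internal stop")
})

test_that("match_codon_usage distance is 0 at the table frequencies", {
  # single two-codon family: Lys AAA/AAG; an ORF matching the table exactly
  tab <- build_codon_table("E. coli")
  tab$codon_freq[c("AAA", "AAG")] <- c(0.75, 0.25)
  orf <- paste0(strrep("AAA", 3), "AAG")  # 3:1 = table ratio
  expect_equal(
    codon_objective_score(orf, c(0L, 12L), tab, "match_codon_usage"), 0)
  skewed <- strrep("AAG", 4)
  expect_lt(
    codon_objective_score(skewed, c(0L, 12L), tab, "match_codon_usage"), 0)
})

test_that("objectives improve under greedy replacement toward each target", {
  tab <- build_codon_table("E. coli")
  orf <- random_orf_sequence(60, seed = 21)
  span <- c(0L, nchar(orf))

  # use_best_codon: every replacement by the family's best codon strictly
  # improves the score
  cur <- orf
  prev <- codon_objective_score(cur, span, tab, "use_best_codon")
  for (step in 1:25) {
    codons <- substring(cur, seq(1, nchar(cur) - 2, 3), seq(3, nchar(cur), 3))
    aas <- tab$codon_to_aa[codons]
    best <- vapply(tab$aa_to_codons, function(cods) {
      cods[which.max(tab$codon_freq[cods])]
    }, "")
    improvable <- which(codons != best[aas])
    if (length(improvable) == 0) break
    codons[improvable[1]] <- best[aas[improvable[1]]]
    cur <- paste(codons, collapse = "")
    sc <- codon_objective_score(cur, span, tab, "use_best_codon")
    expect_gt(sc, prev)
    prev <- sc
  }

  # match_codon_usage: the first-pass quota assignment never worsens the
  # distance to the host usage
  spec <- optimization_spec(organism = "E. coli",
                            method = "match_codon_usage",
                            orf_regions = list(span))
  out <- first_pass(orf, spec)
  expect_gte(codon_objective_score(out$sequence, span, tab, "match_codon_usage"),
             codon_objective_score(orf, span, tab, "match_codon_usage"))
})

test_that("harmonize_rca is maximal when ranks are preserved", {
  host <- build_codon_table("H. sapiens")
  src <- build_codon_table("E. coli")
  # an ORF already written in each family's source-rank-1 codon, re-coded to
  # the host's rank-1 codons, scores 1
  orig <- paste0("AAA", "GAA")           # E. coli best Lys, Glu
  harmonized <- paste0("AAG", "GAG")     # human best Lys, Glu
  sc <- codon_objective_score(harmonized, c(0L, 6L), host, "harmonize_rca",
                              original_sequence = orig, source_table = src)
  expect_equal(sc, 1)
  worse <- codon_objective_score(paste0("AAA", "GAA"), c(0L, 6L), host,
                                 "harmonize_rca",
                                 original_sequence = orig, source_table = src)
  expect_lt(worse, sc)
})
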