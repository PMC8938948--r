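test_that("spec validation enforces frame, bounds and GC ordering", {
  expect_error(optimization_spec(orf_regions = list(c(0L, 10L))), "divisible")
  expect_error(optimization_spec(gc_min = 0.6, gc_max = 0.4), "gc_min")
  expect_error(optimization_spec(organism = "Vulcan"), "unknown organism")
  spec <- optimization_spec(orf_regions = list(c(0L, 9L)))
  expect_error(first_pass("ACGTT", spec), "outside sequence")
})

test_that("first pass is a fixed point on an already-optimal sequence", {
  tab <- build_codon_table("E. coli")
  best <- vapply(tab$aa_to_codons, function(cods) {
    cods[which.max(tab$codon_freq[cods])]
  }, "")
  orf <- paste0(best[["M"]], best[["D"]], best[["V"]], best[["L"]], best[["*"]])
  spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                            orf_regions = list(c(0L, nchar(orf))))
  out <- first_pass(orf, spec)
  expect_identical(out$sequence, orf)
  expect_equal(nrow(out$changes), 0L)
})

test_that("first pass lifts AT-rich windows to the GC floor, keeping translation", {
  # AT-rich but non-periodic ORF: random draws from AT-coded amino acids
  # (plus Leu/Ser/Arg whose synonym sets allow raising GC)
  aa <- seqstab:::.with_seed(10, paste(
    sample(c("K", "N", "I", "F", "Y", "L", "S", "T"), 60, replace = TRUE),
    collapse = ""))
  orf <- random_orf_sequence(60, seed = 3, aa_string = aa)
  spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                            gc_min = 0.35, gc_max = 1,
                            orf_regions = list(c(0L, nchar(orf))))
  out <- first_pass(orf, spec)
  expect_equal(nrow(out$unsatisfiable_windows), 0L)
  chars <- strsplit(out$sequence, "")[[1]]
  wins <- seqstab:::.gc_windows(nchar(orf), 50L)
  for (i in seq_len(nrow(wins))) {
    gc <- seqstab:::.window_gc(chars, wins[i, ])
    expect_gte(gc, 0.35)
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  expect_identical(tr(out$sequence), tr(orf))
})

test_that("impossible GC bounds are reported with the window named", {
  locked_at <- strrep("A", 50)  # a fully locked all-A window
  s <- paste0(locked_at, random_dna(50, 2))
  spec <- optimization_spec(gc_min = 0.3, gc_max = 0.7,
                            locked_regions = list(c(0L, 50L)))
  out <- first_pass(s, spec)
  expect_equal(out$unsatisfiable_windows$window_start_1based, 1L)
})

test_that("avoid-constraints follow the per-type derivation rules", {
  ssr <- data.frame(start = 10L, end = 18L, unit = "AT", L = 2L, N = 4L,
                    rate = 1e-6, rank = 1L)
  rmd <- data.frame(first_start = 30L, second_start = 80L, repeat_len = 20L,
                    spacer = 30L, rate = 1e-5, rank = 1L)
  parsed <- bundled_motifs()
  pssms <- lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
  motif <- data.frame(motif = pssms[[1]]$name, start = 120L, width = 8L,
                      strand = "-", score = 9.1, rank = 1L)
  spec <- optimization_spec()
  cons <- derive_avoid_constraints(list(ssr = ssr, rmd = rmd, motif = motif),
                                   spec, pssms)
  kinds <- vapply(cons, `[[`, "", "kind")
  expect_setequal(kinds, c("ssr_units", "recombination_15mer", "motif_span"))
  rc <- cons[[which(kinds == "recombination_15mer")]]
  expect_equal(rc$span, c(30L, 50L))  # first copy only
  expect_equal(rc$second_start, 80L)

  # a fully locked site is dropped with a warning and counted as skipped
  spec_locked <- optimization_spec(locked_regions = list(c(115L, 130L)))
  expect_warning(
    cons2 <- derive_avoid_constraints(list(ssr = NULL, rmd = NULL,
                                           motif = motif),
                                      spec_locked, pssms),
    "locked")
  expect_equal(cons2[[1]]$status, "skipped_locked")
  res <- second_pass(random_dna(200, 5), spec_locked, cons2)
  expect_equal(res$constraint_report$status, "skipped (locked)")
})

test_that("a lysine-run homopolymer is broken by synonymous swaps only", {
  # D-KKK-V context: AAA AAA AAA flanked by GAY and GTN codons
  orf <- paste0("ATG", "GAT", "AAA", "AAA", "AAA", "GTT", "CTG", "TAA")
  spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                            orf_regions = list(c(0L, nchar(orf))), seed = 2L)
  res <- optimize_sequence(orf, spec)
  expect_equal(nrow(find_ssr_sites(res$sequence)), 0L)
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  expect_identical(tr(res$sequence), tr(orf))
  # the lysines are still encoded by Lys codons (AAA/AAG mixtures)
  expect_true(grepl("^ATG(GA[TC])(AA[AG]){3}", res$sequence))
})

test_that("a duplicated in-frame 21-mer is removed on re-detection", {
  fx <- stability_fixture(3)
  spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                            gc_min = 0.25, gc_max = 0.75,
                            orf_regions = list(fx$orf_span), seed = 3L)
  res <- optimize_sequence(fx$sequence, spec,
                           pssms = list(ppm_to_pssm(fx$motif)))
  rmd_now <- find_rmd_sites(res$sequence)
  tr_rmd <- fx$truth[fx$truth$type == "rmd", ]
  if (nrow(rmd_now) > 0) {
    expect_false(any(rmd_now$first_start < tr_rmd$start + 21L &
                       rmd_now$first_start + rmd_now$repeat_len > tr_rmd$start))
  } else {
    succeed()
  }
})

test_that("a sequence with no detected sites passes through unchanged", {
  s <- hotspot_free_sequence(400, seed = 44, verify = FALSE)
  spec <- optimization_spec(seed = 1L)  # no organism: constraints only
  res <- optimize_sequence(s, spec)
  expect_identical(res$sequence, s)
  expect_equal(nrow(res$changes), 0L)
  expect_equal(res$rip_after, 1)
})

test_that("locked regions are never edited and lock beats constraint", {
  bg <- hotspot_free_sequence(300, seed = 55, verify = FALSE)
  p <- plant_ssr(bg, "CA", 5L, 100L)
  spec <- optimization_spec(locked_regions = list(c(95L, 115L)), seed = 4L)
  expect_warning(res <- optimize_sequence(p$sequence, spec), "locked")
  expect_identical(substr(res$sequence, 96, 115), substr(p$sequence, 96, 115))
  expect_equal(res$site_counts$skipped_locked[
    res$site_counts$kind == "ssr_units"], 1L)
})

test_that("optimization is deterministic given the seed", {
  fx <- stability_fixture(8)
  spec <- optimization_spec(organism = "S. cerevisiae",
                            method = "match_codon_usage",
                            gc_min = 0.25, gc_max = 0.75,
                            orf_regions = list(fx$orf_span), seed = 11L)
  pssms <- list(ppm_to_pssm(fx$motif))
  r1 <- optimize_sequence(fx$sequence, spec, pssms = pssms)
  r2 <- optimize_sequence(fx$sequence, spec, pssms = pssms)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$changes, r2$changes)
})

test_that("the audit traps tampered results", {
  fx <- stability_fixture(5)
  spec <- optimization_spec(organism = "E. coli", method = "use_best_codon",
                            orf_regions = list(fx$orf_span),
                            locked_regions = list(c(2L, 12L)), seed = 5L)
  res <- optimize_sequence(fx$sequence, spec,
                           pssms = list(ppm_to_pssm(fx$motif)))
  # a change-log entry whose position was never edited
  bad <- res
  bad$changes <- rbind(bad$changes,
                       data.frame(position = 0L, old_base = "A",
                                  new_base = "C", reason = "tamper"))
  expect_error(verify_result(fx$sequence, bad, spec), "change log|Hamming")
  # an edit inside the locked region
  bad2 <- res
  substr(bad2$sequence, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                         substr(bad2$sequence, 5, 5))[1]
  expect_error(verify_result(fx$sequence, bad2, spec), "locked|change log")
  # audit reports the change count as the Hamming distance
  o <- strsplit(fx$sequence, "")[[1]]; f <- strsplit(res$sequence, "")[[1]]
  expect_equal(res$audit$n_changes, sum(o != f))
  expect_equal(nrow(res$changes), sum(o != f))
})
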