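test_that("random sequences are seeded, reproducible, and GC-controlled", {
  expect_identical(random_sequence(1000, 0.5, seed = 7),
                   random_sequence(1000, 0.5, seed = 7))
  expect_false(identical(random_sequence(1000, 0.5, seed = 7),
                         random_sequence(1000, 0.5, seed = 8)))
  gc_only <- random_sequence(500, 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", gc_only))
  s <- random_sequence(10000, 0.5, seed = 3)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 10000
  expect_gte(gc, 0.48); expect_lte(gc, 0.52)
  # generator does not disturb the caller's RNG stream
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(random_sequence(100, 0.5, 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("hotspot-free sequences are certified clean and score exactly 1", {
  s <- hotspot_free_sequence(3000, seed = 4)  # verify = TRUE runs the oracles
  expect_equal(nrow(find_ssr_sites(s)), 0L)
  expect_equal(nrow(find_rmd_sites(s)), 0L)
  expect_identical(rip_score(nchar(s), find_ssr_sites(s), find_rmd_sites(s)), 1)
  expect_identical(hotspot_free_sequence(500, seed = 9, verify = FALSE),
                   hotspot_free_sequence(500, seed = 9, verify = FALSE))
})

test_that("planted SSR runs have exactly the declared maximal extent", {
  bg <- hotspot_free_sequence(400, seed = 15, verify = FALSE)
  p <- plant_ssr(bg, "AT", 4L, 100L)
  s <- find_ssr_sites(p$sequence)
  hit <- s[s$start == 100L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "AT")
  expect_equal(hit$N, 4L)
  expect_equal(hit$end, 108L)
  expect_error(plant_ssr(p$sequence, "A", 4L, 102L, truth = p$truth),
               "overlaps")
  expect_error(plant_ssr(bg, "A", 3L, 0L), "must qualify")
})

test_that("planted RMD pairs match their declared length and spacer", {
  bg <- hotspot_free_sequence(400, seed = 16, verify = FALSE)
  p <- plant_rmd(bg, L = 20L, spacer = 30L, position = 50L, seed = 2L)
  r <- find_rmd_sites(p$sequence)
  expect_equal(nrow(r), 1L)
  expect_equal(r$repeat_len, 20L)
  expect_equal(r$spacer, 30L)
  expect_equal(r$first_start, 50L)
})

test_that("detection fixtures give 100% recall at exact coordinates", {
  parsed <- bundled_motifs()
  pssms <- lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
  for (seed in 1:10) {
    fx <- detection_fixture(seed)
    ssr <- find_ssr_sites(fx$sequence)
    rmd <- find_rmd_sites(fx$sequence)
    hits <- scan_sequence(fx$sequence, pssms)
    tr <- fx$truth
    ssr_t <- tr[tr$type == "ssr", ]
    expect_true(any(ssr$start == ssr_t$start & ssr$end == ssr_t$end))
    rmd_t <- tr[tr$type == "rmd", ]
    expect_true(any(rmd$first_start == rmd_t$start &
                      rmd$repeat_len == 20L & rmd$spacer == 30L))
    mot_t <- tr[tr$type == "motif", ]
    strand <- sub(".*strand=", "", mot_t$detail)
    expect_true(any(hits$start == mot_t$start & hits$strand == strand))
  }
})

test_that("ORF generator respects the amino-acid string and avoids stops", {
  orf <- random_orf_sequence(50, seed = 31)
  expect_equal(nchar(orf) %% 3, 0)
  aas <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                            no.init.codon = TRUE))
  expect_false(grepl("\\*", substr(aas, 1, nchar(aas) - 1)))
  expect_equal(substr(aas, nchar(aas), nchar(aas)), "*")

  orf2 <- random_orf_sequence(3, seed = 1, aa_string = "MKL")
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(orf2),
                                                  no.init.codon = TRUE)),
               "MKL*")
})
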