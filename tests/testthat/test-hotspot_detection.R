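test_that("qualifying thresholds and canonical examples are honored", {
  # (AT) x 4: unit length 2, four copies
  s <- find_ssr_sites("ATATATAT")
  expect_equal(nrow(s), 1L)
  expect_equal(s$unit, "AT")
  expect_equal(s$L, 2L)
  expect_equal(s$N, 4L)
  expect_equal(s$start, 0L)
  expect_equal(s$end, 8L)

  # homopolymers need four copies
  expect_equal(find_ssr_sites("AAAA")$N, 4L)
  expect_equal(nrow(find_ssr_sites("AAA")), 0L)
  # two copies of a 4-mer are below threshold
  expect_equal(nrow(find_ssr_sites("ACGTACGT")), 0L)
})

test_that("runs are reported once: leftmost phase, smallest primitive unit", {
  # AAAAAA is one homopolymer run, never also an (AA) x 3 run
  s <- find_ssr_sites("GGAAAAAAGG")
  expect_equal(nrow(s), 1L)
  expect_equal(s$L, 1L)
  expect_equal(s$N, 6L)

  # 7-nt ATATATA: start 0, unit AT, three full copies; trailing base ignored
  s <- find_ssr_sites("ATATATA")
  expect_equal(s$start, 0L)
  expect_equal(s$unit, "AT")
  expect_equal(s$N, 3L)
})

test_that("N bases break tandem runs and repeats", {
  expect_equal(nrow(find_ssr_sites("AANAA")), 0L)
  expect_equal(nrow(find_ssr_sites("ATATNATAT")), 0L)
  expect_equal(nrow(find_ssr_sites(strrep("N", 40))), 0L)
  expect_equal(nrow(find_rmd_sites(paste0(strrep("N", 20), "ACGT",
                                          strrep("N", 20)))), 0L)
})

test_that("planted RMD pairs are recovered with exact length and spacer", {
  base <- random_dna(200, seed = 41)
  p <- plant_rmd(base, L = 20L, spacer = 30L, position = 50L, seed = 3L)
  r <- find_rmd_sites(p$sequence)
  expect_equal(nrow(r), 1L)
  expect_equal(r$first_start, 50L)
  expect_equal(r$repeat_len, 20L)
  expect_equal(r$spacer, 30L)
  expect_equal(r$second_start, 100L)

  # a 17-nt repeat is merged from two consecutive shared 16-mers,
  # not reported as two 16-nt hits
  p17 <- plant_rmd(base, L = 17L, spacer = 40L, position = 60L, seed = 9L)
  r17 <- find_rmd_sites(p17$sequence)
  expect_equal(nrow(r17), 1L)
  expect_equal(r17$repeat_len, 17L)
})

test_that("reported RMD spans are identical substrings (no false merges)", {
  for (seed in 1:10) {
    s <- random_dna(800, seed = seed)
    s <- plant_rmd(s, L = 16L + seed, spacer = 10L * seed, position = 100L,
                   seed = seed)$sequence
    r <- find_rmd_sites(s)
    for (i in seq_len(nrow(r))) {
      expect_identical(
        substr(s, r$first_start[i] + 1L, r$first_start[i] + r$repeat_len[i]),
        substr(s, r$second_start[i] + 1L, r$second_start[i] + r$repeat_len[i]))
    }
  }
})

test_that("three copies of a repeat yield all ordered pairs", {
  base <- hotspot_free_sequence(300, seed = 77, verify = FALSE)
  block <- substr(plant_rmd(base, 20L, 10L, 0L, seed = 5L)$sequence, 1, 20)
  chars <- strsplit(base, "")[[1]]
  for (at in c(20L, 100L, 200L)) chars[(at + 1L):(at + 20L)] <- strsplit(block, "")[[1]]
  s <- paste(chars, collapse = "")
  r <- find_rmd_sites(s)
  r <- r[r$repeat_len >= 20L, ]  # flank coincidences may extend the repeat
  expect_equal(nrow(r), 3L)      # (1,2), (1,3), (2,3)
})

test_that("detectors reproduce the brute-force enumerators on random DNA", {
  for (seed in 1:20) {
    s <- random_dna(1000, seed = 1000 + seed)
    expect_same_sites(find_ssr_sites(s), ssr_sites_bruteforce(s))
    expect_same_sites(find_rmd_sites(s), rmd_sites_bruteforce(s))
  }
})

test_that("maximality: extending any reported run or repeat breaks identity", {
  for (seed in 1:8) {
    s <- random_dna(1000, seed = 300 + seed)
    chars <- strsplit(s, "")[[1]]
    n <- nchar(s)
    ssr <- find_ssr_sites(s)
    for (i in seq_len(nrow(ssr))) {
      L <- ssr$L[i]
      before <- ssr$start[i] - L
      if (before >= 0) {
        expect_false(substr(s, before + 1L, before + L) == ssr$unit[i] &&
                       !grepl("N", substr(s, before + 1L, before + L)))
      }
      if (ssr$end[i] + L <= n) {
        expect_false(substr(s, ssr$end[i] + 1L, ssr$end[i] + L) == ssr$unit[i])
      }
    }
    rmd <- find_rmd_sites(s)
    for (i in seq_len(nrow(rmd))) {
      f <- rmd$first_start[i]; sc <- rmd$second_start[i]; L <- rmd$repeat_len[i]
      if (f > 0 && sc > 0) expect_false(chars[f] == chars[sc])
      if (sc + L < n) expect_false(chars[f + L + 1L] == chars[sc + L + 1L])
    }
  }
})

test_that("rank_sites keeps the top-budget sites with stable tie-breaking", {
  sites <- data.frame(start = c(30L, 10L, 20L), end = c(34L, 14L, 24L),
                      unit = "A", L = 1L, N = 4L,
                      rate = c(2e-9, 1e-9, 2e-9))
  top <- rank_sites(sites, budget = 2L)
  expect_equal(top$start, c(20L, 30L))  # equal rates: earlier start first
  expect_equal(top$rank, 1:2)
  expect_equal(nrow(rank_sites(sites, budget = 10L)), 3L)
  expect_equal(nrow(rank_sites(sites[0, ], budget = 10L)), 0L)
})
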