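test_that("MEME minimal parsing handles both layouts and backgrounds", {
  parsed <- bundled_motifs()
  expect_equal(length(parsed$motifs), 4L)
  for (m in parsed$motifs) {
    expect_equal(ncol(m$ppm), 4L)
    expect_equal(nrow(m$ppm), m$width)
    expect_true(all(abs(rowSums(m$ppm) - 1) < 1e-3))
  }
  expect_equal(unname(parsed$background), rep(0.25, 4))

  compact <- parse_meme_minimal(text = compact_meme_text())
  expect_equal(length(compact$motifs), 2L)
  expect_equal(compact$motifs[[1]]$name, "testMotif-1")
  expect_equal(compact$motifs[[1]]$width, 3L)
  expect_equal(compact$motifs[[2]]$width, 2L)
})

test_that("malformed motif files fail with the motif named", {
  bad_width <- c("MOTIF shortie",
                 "letter-probability matrix: alength= 4 w= 6 nsites= 5 E= 1",
                 "0.25 0.25 0.25 0.25",
                 "0.25 0.25 0.25 0.25")
  expect_error(parse_meme_minimal(text = bad_width), "shortie")

  bad_sum <- c("MOTIF lopsided",
               "letter-probability matrix: alength= 4 w= 1 nsites= 5 E= 1",
               "0.50 0.30 0.30 0.30")
  expect_error(parse_meme_minimal(text = bad_sum), "lopsided")

  bad_alpha <- c("MOTIF protein",
                 "letter-probability matrix: alength= 20 w= 3 nsites= 5 E= 1")
  expect_error(parse_meme_minimal(text = bad_alpha), "alphabet")
})

test_that("log-odds conversion matches hand arithmetic", {
  # uniform rows on uniform background: all scores exactly 0
  u <- ppm_to_pssm(uniform_ppm(), pseudocount = 0)
  expect_true(all(u$scores == 0))

  # a (1,0,0,0) row approaches log2(4) = 2 for A as the pseudocount vanishes
  ppm <- uniform_ppm(1L)
  ppm$ppm[1, ] <- c(1, 0, 0, 0)
  p <- ppm_to_pssm(ppm, pseudocount = 1e-12)
  expect_equal(unname(p$scores[1, "A"]), 2, tolerance = 1e-9)

  # doubling the pseudocount shrinks all magnitudes toward 0
  p1 <- ppm_to_pssm(sharp_ppm3(), pseudocount = 1e-3)
  p2 <- ppm_to_pssm(sharp_ppm3(), pseudocount = 2e-3)
  expect_true(all(abs(p2$scores) < abs(p1$scores)))

  # zero entries with no pseudocount are an error
  expect_error(ppm_to_pssm(ppm, pseudocount = 0), "pseudocount")
})

test_that("planted consensus sites are found on the declared strand", {
  parsed <- bundled_motifs()
  pssms <- lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
  bg <- hotspot_free_sequence(300, seed = 5, verify = FALSE)

  p <- plant_motif(bg, parsed$motifs[[2]], position = 100L, strand = "+")
  hits <- scan_sequence(p$sequence, pssms)
  hit <- hits[hits$start == 100L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$motif, parsed$motifs[[2]]$name)
  # consensus score equals the sum of consensus-column scores, and is the
  # maximum achievable for that PSSM
  pssm <- pssms[[2]]
  expect_equal(hit$score, sum(apply(pssm$scores, 1, max)))

  p2 <- plant_motif(bg, parsed$motifs[[4]], position = 200L, strand = "-")
  hits2 <- scan_sequence(p2$sequence, pssms)
  hit2 <- hits2[hits2$start == 200L, ]
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$score, sum(apply(pssms[[4]]$scores, 1, max)))
})

test_that("strand symmetry: revcomp scanning gives the same score multiset", {
  parsed <- bundled_motifs()
  pssms <- lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
  s <- random_dna(400, seed = 8)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (k in seq_along(pssms)) {
    h1 <- scan_sequence(s, pssms[k])
    h2 <- scan_sequence(rc, pssms[k])
    expect_equal(sort(h1$score), sort(h2$score))
  }
})

test_that("scores agree with the Biostrings PWM scorer", {
  parsed <- bundled_motifs()
  pssm <- ppm_to_pssm(parsed$motifs[[1]], parsed$background)
  s <- random_dna(200, seed = 13)
  pw <- t(pssm$scores)
  for (at in c(1L, 50L, 150L)) {
    own <- seqstab:::.pssm_scan_scores(seqstab:::.encode_seq(s), pssm)[at]
    ref <- Biostrings::PWMscoreStartingAt(pw, Biostrings::DNAString(s),
                                          starting.at = at)
    expect_equal(own, unname(ref), tolerance = 1e-12)
  }
})

test_that("N-only sequence yields no hits and random background scores <= 0", {
  parsed <- bundled_motifs()
  pssms <- lapply(parsed$motifs, ppm_to_pssm, background = parsed$background)
  expect_equal(nrow(scan_sequence(strrep("N", 100), pssms)), 0L)

  # mean per-position log-odds on background-distributed sequence is <= 0
  # (Kullback-Leibler argument), within 3 standard errors at n = 1e5
  s <- random_dna(100000, seed = 99)
  sc <- seqstab:::.pssm_scan_scores(seqstab:::.encode_seq(s), pssms[[1]])
  se <- sd(sc) / sqrt(length(sc))
  expect_lt(mean(sc), 0 + 3 * se)
})
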