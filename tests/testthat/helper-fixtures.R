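# Shared helpers for building small in-code fixtures.

random_dna <- function(n, seed) random_sequence(n, 0.5, seed = seed)

# uniform 3-position PPM used in hand-check tests
uniform_ppm <- function(w = 3L) {
  structure(
    list(name = "uniform", alphabet_length = 4L, width = w,
         nsites = 1, evalue = 1,
         ppm = matrix(0.25, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))),
    class = "motif_matrix")
}

# small sharp PPM (3 positions, consensus ACG)
sharp_ppm3 <- function() {
  ppm <- rbind(c(0.97, 0.01, 0.01, 0.01),
               c(0.01, 0.97, 0.01, 0.01),
               c(0.01, 0.01, 0.97, 0.01))
  colnames(ppm) <- c("A", "C", "G", "T")
  structure(
    list(name = "acg3", alphabet_length = 4L, width = 3L, nsites = 10,
         evalue = 0.001, ppm = ppm),
    class = "motif_matrix")
}

bundled_motifs <- function() {
  parse_meme_minimal(system.file("extdata", "methylation_motifs_synthetic.meme",
                                 package = "seqstab", mustWork = TRUE))
}

# compact-layout MEME minimal text (name line + header-numbers line + rows)
compact_meme_text <- function() {
  c("testMotif-1",
    "4 3 12 0.001",
    "0.70 0.10 0.10 0.10",
    "0.10 0.70 0.10 0.10",
    "0.10 0.10 0.10 0.70",
    "",
    "testMotif-2",
    "4 2 8 0.01",
    "0.25 0.25 0.25 0.25",
    "0.40 0.20 0.20 0.20")
}

write_fasta <- function(path, seqs) {
  lines <- unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]])))
  writeLines(lines, path)
  path
}

expect_same_sites <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a, b)
}
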