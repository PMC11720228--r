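# Shared fixture builders for the test suite. Everything is generated in
# code; nothing binary ships with the package.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Build a domain sequence from explicit ml residues and gap lengths,
# with single-letter spacer/flank filler.
make_motif <- function(residues, gaps, flank_n = 20L, flank_c = 20L,
                       filler = "A") {
  stopifnot(length(residues) == 8L, length(gaps) == 7L)
  parts <- character(15)
  parts[seq(1, 15, 2)] <- residues
  parts[seq(2, 14, 2)] <- vapply(gaps, function(g) strrep(filler, g),
                                 character(1))
  paste0(strrep(filler, flank_n), paste(parts, collapse = ""),
         strrep(filler, flank_c))
}

# The RING-H2 standard motif C-X2-C-X15-C-X1-H-X2-H-X2-C-X12-C-X2-C
# carried by the GhZFRG1-style zinc finger.
ring_h2_motif <- function(filler = "A") {
  make_motif(c("C", "C", "C", "H", "H", "C", "C", "C"),
             c(2L, 15L, 1L, 2L, 2L, 12L, 2L), filler = filler)
}

# A random in-frame CDS: ATG + (n_codons - 2) random sense codons + TAA.
random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"),
                              stringsAsFactors = FALSE),
                  1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

write_temp_fasta <- function(records, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = envir)
  ringkit::write_fasta(records, path)
  path
}
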