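test_that("the standard C3H2C3 motif yields exactly one RING-H2 hit", {
  hits <- enumerate_ring_matches(ring_h2_motif(), protein_id = "zfrg1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$type, "RING-H2")
  expect_equal(unlist(hits[, paste0("g", 1:7)], use.names = FALSE),
               c(2L, 15L, 1L, 2L, 2L, 12L, 2L))
  expect_equal(hits$start, 21L)   # after the 20-residue flank
  expect_equal(hits$end, hits$ml8)
})

test_that("sequences without ligand residues never match", {
  expect_equal(nrow(enumerate_ring_matches(strrep("A", 200))), 0L)
  expect_equal(nrow(enumerate_ring_matches("")), 0L)
})

test_that("hits satisfy their own type constraints (grammar closure)", {
  withr::local_seed(101)
  g <- ring_grammar()
  sim <- simulate_ring_cohort(
    c("RING-H2" = 6, "RING-HCb" = 3, "RING-C2" = 3, "RING-S/T" = 2),
    alphabet = "full", seed = 29L)
  seqs <- c(replicate(20, random_protein(250)), sim$proteins$sequence)
  for (seq in seqs) {
    hits <- enumerate_ring_matches(seq, g)
    if (nrow(hits) == 0L) next
    chars <- strsplit(seq, "")[[1]]
    for (r in seq_len(nrow(hits))) {
      spec <- g[g$type == hits$type[[r]], ]
      ml <- unlist(hits[r, paste0("ml", 1:8)])
      gaps <- unlist(hits[r, paste0("g", 1:7)])
      expect_equal(unname(gaps), unname(diff(ml)) - 1L)
      for (k in 1:8) expect_true(chars[ml[[k]]] %in% spec$residues[[1]][[k]])
      for (j in 1:7) expect_true(gaps[[j]] %in% spec$gaps[[1]][[j]])
    }
  }
})

test_that("scanner agrees with the brute-force join oracle on random sequences", {
  withr::local_seed(202)
  n_checked <- 0L
  for (rep in 1:60) {
    seq <- random_protein(150)
    got <- canonical_hits(enumerate_ring_matches(seq))
    want <- oracle_matches(seq)
    expect_equal(got$type, want$type)
    expect_equal(unname(as.matrix(got[, -1])), unname(as.matrix(want[, -1])))
    n_checked <- n_checked + nrow(want)
  }
  # planted full-alphabet cohorts guarantee matches (and ambiguous ones)
  sim <- simulate_ring_cohort(
    c("RING-H2" = 10, "RING-HCa" = 8, "RING-v" = 3, "RING-D" = 2),
    n_multi2 = 4L, alphabet = "full", seed = 23L)
  for (s in sim$proteins$sequence) {
    got <- canonical_hits(enumerate_ring_matches(s))
    want <- oracle_matches(s)
    expect_equal(got$type, want$type)
    expect_equal(unname(as.matrix(got[, -1])), unname(as.matrix(want[, -1])))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 20L)
})

test_that("scan output is deterministic", {
  withr::local_seed(7)
  seqs <- tibble::tibble(id = sprintf("p%d", 1:10),
                         sequence = replicate(10, random_protein(200,
                           alphabet = c("C", "H", "A", "D", "E"))))
  s1 <- scan_ring_domains(seqs)
  s2 <- scan_ring_domains(seqs)
  expect_identical(s1$hits, s2$hits)
})

test_that("non-overlapping domains are both retained after resolution", {
  two <- paste0(ring_h2_motif(), ring_h2_motif())
  hits <- resolve_ring_hits(enumerate_ring_matches(two, protein_id = "p"))
  expect_equal(nrow(hits), 2L)
  expect_true(hits$start[2] > hits$end[1])
})

test_that("a RING-D-compatible domain outranks RING-HCa on identical positions", {
  # gaps (2,12,1,2,2,10,2) lie inside RING-HCa's ranges AND match RING-D
  seqd <- make_motif(c("C", "C", "C", "H", "C", "C", "C", "C"),
                     c(2L, 12L, 1L, 2L, 2L, 10L, 2L))
  raw <- enumerate_ring_matches(seqd, protein_id = "p")
  expect_setequal(raw$type, c("RING-D", "RING-HCa"))
  expect_equal(nrow(raw), 2L)
  resolved <- resolve_ring_hits(raw)
  expect_equal(nrow(resolved), 1L)
  expect_equal(resolved$type, "RING-D")
})

test_that("unknown resolution policy is an error", {
  hits <- enumerate_ring_matches(ring_h2_motif(), protein_id = "p")
  expect_error(resolve_ring_hits(hits, "keep-everything"), "policy")
})

test_that("policy 'all' returns raw matches unchanged", {
  seqd <- make_motif(c("C", "C", "C", "H", "C", "C", "C", "C"),
                     c(2L, 12L, 1L, 2L, 2L, 10L, 2L))
  raw <- enumerate_ring_matches(seqd, protein_id = "p")
  expect_identical(resolve_ring_hits(raw, "all"), raw)
})

test_that("multi-domain proteins are counted per planted cohort shape", {
  # 9 two-domain and 2 three-domain proteins, like a scan of a real cohort
  sim <- simulate_ring_cohort(
    c("RING-H2" = 20, "RING-HCa" = 4),
    n_multi2 = 9L, n_multi3 = 2L, seed = 5L)
  scan <- scan_ring_domains(sim$proteins)
  expect_equal(sum(scan$proteins$n_domains == 2L), 9L)
  expect_equal(sum(scan$proteins$n_domains == 3L), 2L)
  expect_equal(nrow(scan$hits), 24L)
})

test_that("per-type totals equal planted counts in non-ligand mode", {
  counts <- c("RING-H2" = 12, "RING-HCa" = 7, "RING-v" = 3, "RING-G" = 1)
  sim <- simulate_ring_cohort(counts, seed = 9L)
  scan <- scan_ring_domains(sim$proteins)
  got <- stats::setNames(scan$type_counts$n_domains, scan$type_counts$type)
  expect_equal(got[names(counts)], counts)
})

test_that("empty input gives an empty summary", {
  scan <- scan_ring_domains(tibble::tibble(id = character(),
                                           sequence = character()))
  expect_equal(nrow(scan$hits), 0L)
  expect_equal(nrow(scan$proteins), 0L)
  expect_equal(glance(scan)$n_domains, 0L)
})

test_that("tidy and glance expose the hit table and summary", {
  sim <- simulate_ring_cohort(c("RING-H2" = 3), seed = 2L)
  scan <- scan_ring_domains(sim$proteins)
  expect_identical(tidy(scan), scan$hits)
  gl <- glance(scan)
  expect_equal(gl$n_ring_proteins, 3L)
  expect_equal(gl$n_domains, 3L)
  expect_s3_class(autoplot(scan), "ggplot")
})
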