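# Expected site counts below are hand-derived by enumerating all nine
# single-base changes of a codon against the standard genetic code.

test_that("per-codon site counts match enumeration of single-base changes", {
  tt <- count_codon_sites("TTT")            # Phe: only T->C at pos 3 is silent
  expect_equal(tt[["syn"]], 1 / 3, tolerance = 1e-12)
  expect_equal(count_codon_sites("ATG")[["syn"]], 0)  # Met: none
  # four-fold degenerate third position
  expect_equal(count_codon_sites("GGG")[["syn"]], 1, tolerance = 1e-12)
  expect_error(count_codon_sites("TAA"), "stop")
  expect_error(count_codon_sites("ANA"), "codon")
})

test_that("site counts partition each codon into 3 sites", {
  for (cd in ringkit:::sense_codons()) {
    s <- count_codon_sites(cd)
    expect_equal(s[["syn"]] + s[["nonsyn"]], 3, tolerance = 1e-12)
  }
})

test_that("identical sequences give zero distances and an undefined call", {
  a <- strrep("ATGGCT", 30)
  res <- kaks_pair(a, a)
  expect_equal(res$ka, 0)
  expect_equal(res$ks, 0)
  expect_true(is.na(res$ratio))
  expect_equal(res$selection, "undefined")
})

test_that("a single synonymous difference reproduces the hand NG86 values", {
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  res <- kaks_pair(a, b)
  expect_equal(res$syn_sites, 10 / 3, tolerance = 1e-12)
  expect_equal(res$syn_diffs, 1)
  expect_equal(res$nonsyn_diffs, 0)
  expect_equal(res$ps, 0.3, tolerance = 1e-12)
  expect_equal(res$ks, -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(res$ka, 0)
  expect_equal(res$ratio, 0)
  expect_equal(res$selection, "purifying")
})

test_that("a single nonsynonymous difference yields a positive call", {
  a <- strrep("ATG", 10)
  b <- paste0("ATA", strrep("ATG", 9))  # Met -> Ile
  res <- kaks_pair(a, b)
  expect_equal(res$nonsyn_diffs, 1)
  expect_equal(res$syn_diffs, 0)
  expect_equal(res$ks, 0)
  expect_equal(res$ratio, Inf)
  expect_equal(res$selection, "positive")
})

test_that("kaks_pair is symmetric in its arguments", {
  withr::local_seed(77)
  sim <- simulate_codon_pairs(5, 300, 0.05, 0.7, seed = 8)
  for (i in seq_len(nrow(sim$pairs))) {
    s1 <- sim$cds$sequence[[2 * i - 1]]
    s2 <- sim$cds$sequence[[2 * i]]
    f <- kaks_pair(s1, s2)
    r <- kaks_pair(s2, s1)
    for (col in c("syn_sites", "nonsyn_sites", "syn_diffs", "nonsyn_diffs",
                  "ks", "ka")) {
      expect_equal(f[[col]], r[[col]], tolerance = 1e-12)
    }
  }
})

test_that("site totals conserve 3 x compared codons", {
  withr::local_seed(88)
  sim <- simulate_codon_pairs(5, 200, 0.05, 1, seed = 12)
  res <- kaks(sim$cds, sim$pairs)
  expect_true(all(abs(res$syn_sites + res$nonsyn_sites -
                        3 * res$n_codons) < 1e-9))
})

test_that("codons with N or gaps are skipped pairwise", {
  a <- paste0("ATG", "AAN", "GGG")
  b <- paste0("ATG", "AAA", "GGG")
  res <- kaks_pair(a, b)
  expect_equal(res$n_skipped, 1L)
  expect_equal(res$n_codons, 2L)
  expect_equal(res$syn_diffs + res$nonsyn_diffs, 0)
})

test_that("selection classes tabulate with fractions", {
  res <- tibble::tibble(selection = c("purifying", "purifying", "positive"))
  tab <- classify_selection(res)
  expect_equal(tab$fraction[tab$selection == "purifying"], 2 / 3)
  expect_equal(tab$fraction[tab$selection == "positive"], 1 / 3)
  allsame <- classify_selection(tibble::tibble(selection = rep("undefined", 4)))
  expect_equal(allsame$fraction, 1)
})

test_that("a mixed-omega cohort recovers the planted purifying fraction", {
  pur <- simulate_codon_pairs(45, 400, 0.03, 0.2, seed = 31)
  pos <- simulate_codon_pairs(5, 400, 0.03, 2, seed = 32)
  res <- dplyr::bind_rows(kaks(pur$cds, pur$pairs), kaks(pos$cds, pos$pairs))
  frac_pur <- mean(res$selection == "purifying")
  expect_gt(frac_pur, 0.85)
  expect_lt(frac_pur, 0.95)
})

test_that("neutral simulation at small scale centres near ratio 1", {
  sim <- simulate_codon_pairs(40, 2000, 0.02, 1, seed = 13)
  res <- kaks(sim$cds, sim$pairs)
  expect_gt(mean(res$ratio), 0.85)
  expect_lt(mean(res$ratio), 1.15)
  gl <- glance(res)
  expect_equal(gl$n_pairs, 40L)
})

test_that("kaks names missing CDS records", {
  cds <- tibble::tibble(id = "x_a", sequence = "ATG")
  pairs <- tibble::tibble(gene_a = "x_a", gene_b = "x_b")
  expect_error(kaks(cds, pairs), "x_b")
})
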