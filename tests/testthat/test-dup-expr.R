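test_that("tandem classification follows same-chromosome adjacency", {
  ord <- tibble::tibble(
    gene_id = c("a1", "a2", "a3", "a4", "b1"),
    chromosome = c("A13", "A13", "A13", "A13", "D05"),
    start = c(100, 200, 300, 900, 50)
  )
  pairs <- tibble::tibble(
    gene_a = c("a1", "a1", "a1"),
    gene_b = c("a2", "b1", "a4")
  )
  out <- classify_tandem(pairs, ord)
  expect_equal(out$mode, c("tandem", "nontandem", "nontandem"))
  # max_gap semantics: ranks 1 and 4 need max_gap >= 2
  expect_equal(classify_tandem(pairs[3, ], ord, max_gap = 3)$mode, "tandem")
  expect_equal(classify_tandem(pairs[3, ], ord, max_gap = 0)$mode, "nontandem")
})

test_that("tandem classification names genes missing from the order table", {
  ord <- tibble::tibble(gene_id = "a1", chromosome = "A13", start = 100)
  expect_error(
    classify_tandem(tibble::tibble(gene_a = "a1", gene_b = "zz"), ord),
    "zz")
})

test_that("planted tandem and nontandem pairs are classified back", {
  sim <- simulate_gene_order(n_genes = 120, n_tandem = 6, n_nontandem = 6,
                             seed = 14)
  out <- classify_tandem(sim$pairs, sim$gene_order)
  expect_equal(out$mode, sim$pairs$mode)
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::local_seed(15)
  p <- stats::runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
})

test_that("DEG thresholds are inclusive exactly as printed", {
  r <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    timepoint = 1,
    log2fc = c(1.0, 0.99, -1.0, 3),
    padj = c(0.05, 0.001, 0.05, 0.051)
  )
  out <- call_degs(r)
  expect_equal(out$deg, c("up", "none", "down", "none"))
})

test_that("records with missing values are excluded and counted", {
  r <- tibble::tibble(gene_id = c("g1", "g2"), timepoint = 1,
                      log2fc = c(2, NA), padj = c(0.01, 0.01))
  out <- call_degs(r)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("raising the fold-change threshold never adds DEGs", {
  withr::local_seed(16)
  r <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200), timepoint = 1,
    log2fc = stats::rnorm(200, sd = 2), padj = stats::runif(200)
  )
  n_deg <- function(lfc) sum(call_degs(r, lfc = lfc)$deg != "none")
  counts <- vapply(c(0.5, 1, 1.5, 2, 3), n_deg, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # idempotence: re-calling on called records changes nothing
  once <- call_degs(r)
  twice <- call_degs(once)
  expect_equal(once$deg, twice$deg)
})

test_that("multi-timepoint sets nest and split by direction", {
  r <- tibble::tibble(
    gene_id = rep(c("both", "mixed", "single", "allup"), each = 4),
    timepoint = rep(c(1, 3, 12, 48), 4),
    log2fc = c(2, 2, 0, 0,     2, 2, 2, -2,   2, 0, 0, 0,   2, 3, 2, 4),
    padj = 0.01
  )
  sets <- multi_timepoint_sets(call_degs(r))
  row_of <- function(g) sets[sets$gene_id == g, ]
  expect_true(row_of("both")$min_k)
  expect_false(row_of("both")$all_up)
  expect_true(row_of("mixed")$min_k)       # direction-mixed still counts
  expect_false(row_of("mixed")$all_up)
  expect_false(row_of("mixed")$all_down)
  expect_false(row_of("single")$min_k)
  expect_true(row_of("allup")$all_up)
  # nesting: all-timepoint set within the >=2 set within the >=1 set
  expect_true(all(sets$min_k[sets$all_up | sets$all_down]))
  expect_true(all(sets$n_deg_timepoints >= 1))
})

test_that("pair concordance distinguishes matching, opposing and untested", {
  r <- tibble::tibble(
    gene_id = rep(c("u1", "u2", "d1", "quiet"), each = 2),
    timepoint = rep(c(1, 3), 4),
    log2fc = c(2, 2,  3, 2,  -2, 2,  0, 0),
    padj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2, 0.01, 0.01)
  )
  called <- call_degs(r)
  pairs <- tibble::tibble(
    gene_a = c("u1", "u1", "u1", "u1"),
    gene_b = c("u2", "d1", "quiet", "ghost")
  )
  out <- pair_concordance(pairs, called)
  expect_equal(attr(out, "n_skipped"), 1L)   # ghost has no expression rows
  expect_equal(out$concordance, c("concordant", "discordant", "untested"))
})

test_that("Livak relative expression follows the closed form", {
  expect_equal(livak(20, 20, 20, 20), 1)
  expect_equal(livak(24, 18, 25, 18), 2)    # ddCt = -1
  expect_equal(livak(22, 18, 20, 18), 0.25) # ddCt = 2
  expect_error(livak(Inf, 18, 20, 18), "finite")
})

test_that("naive FPKM fold change uses the pseudocount", {
  expect_equal(naive_log2fc(3, 1), 1)
  expect_equal(naive_log2fc(0, 0), 0)
})
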