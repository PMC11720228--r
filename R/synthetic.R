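# Seeded generators producing fixtures with exact ground truth for every
# pipeline stage. Each generator runs in a private RNG stream (the caller's
# .Random.seed is untouched) so the same seed always gives byte-identical
# output.

with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

NON_LIGAND_AA <- c("A", "R", "N", "D", "E", "Q", "I", "L", "K", "M",
                   "F", "P", "V", "W", "Y")
ALL_AA <- c(NON_LIGAND_AA, "C", "H", "S", "T", "G")

rand_aa <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

satisfies_spec <- function(ml_res, gaps, residues, gap_sets) {
  all(mapply(function(r, set) r %in% set, ml_res, residues)) &&
    all(mapply(function(g, set) g %in% set, gaps, gap_sets))
}

# Build one domain of `type`: returns list(sequence, ml_offsets (1-based
# within the domain), gaps, type). A sampled domain that would also satisfy
# a higher-precedence type (e.g. a RING-HCa draw landing exactly on
# RING-D's fixed gaps) is redrawn, so planted domains always scan back to
# their planted label.
build_domain <- function(spec_row, alphabet, spacers = NULL,
                         grammar = NULL) {
  residues <- spec_row$residues[[1]]
  gap_sets <- spec_row$gaps[[1]]
  higher <- if (!is.null(grammar)) {
    grammar[grammar$precedence < spec_row$precedence, , drop = FALSE]
  } else {
    NULL
  }
  for (attempt in 1:100) {
    gaps <- integer(7)
    for (j in 1:7) {
      pool <- if (!is.null(spacers)) spacers[[j]] else gap_sets[[j]]
      if (!all(pool %in% gap_sets[[j]])) {
        stop("requested spacer length(s) for ", spec_row$type,
             " gap ", j, " outside the grammar range", call. = FALSE)
      }
      gaps[[j]] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    ml_res <- vapply(residues, function(set)
      if (length(set) == 1L) set else sample(set, 1L), character(1))
    ambiguous <- !is.null(higher) && nrow(higher) > 0 &&
      any(vapply(seq_len(nrow(higher)), function(k)
        satisfies_spec(ml_res, gaps, higher$residues[[k]], higher$gaps[[k]]),
        logical(1)))
    if (!ambiguous) break
    if (attempt == 100L) {
      stop("could not draw an unambiguous ", spec_row$type, " domain",
           call. = FALSE)
    }
  }
  parts <- character(15)
  parts[seq(1, 15, 2)] <- ml_res
  parts[seq(2, 14, 2)] <- vapply(gaps, rand_aa, character(1),
                                 alphabet = alphabet)
  ml_off <- cumsum(c(1L, gaps + 1L))
  list(sequence = paste(parts, collapse = ""), ml_offsets = ml_off,
       gaps = gaps, type = spec_row$type)
}

#' Simulate a protein cohort with planted RING domains
#'
#' Generates proteins carrying RING domains of requested types at known
#' positions. Spacer lengths are drawn uniformly from each type's grammar
#' range unless overridden. In `"non-ligand"` alphabet mode (the default),
#' spacers and flanks avoid C/H/S/T/G entirely, so the planted domains are
#' the only grammar matches and scans recover them exactly; `"full"` mode
#' draws from all 20 residues for stress-testing overlap resolution.
#'
#' @param counts Named integer vector of domains to plant per type, e.g.
#'   `c("RING-H2" = 5, "RING-v" = 2)`. Names must be grammar types.
#' @param n_multi2,n_multi3 Number of proteins carrying 2 (resp. 3) planted
#'   domains; the remaining domains go one per protein. Requires
#'   `sum(counts) >= 3 * n_multi3 + 2 * n_multi2`.
#' @param alphabet `"non-ligand"` or `"full"` for spacer/flank residues.
#' @param flank_range Length range (inclusive) of N-/C-terminal flanks and
#'   inter-domain linkers.
#' @param spacers Optional named list (by type) of 7 integer vectors to
#'   draw spacer lengths from; must lie within the grammar ranges.
#' @param grammar A `ring_grammar`, default [ring_grammar()].
#' @param seed Integer seed; same seed, same output.
#' @return List with `proteins` (tibble `id`, `sequence`, `description`)
#'   and `truth` (tibble `protein_id`, `type`, `start`, `end`,
#'   `ml1`..`ml8`, `g1`..`g7`).
#' @examples
#' sim <- simulate_ring_cohort(c("RING-H2" = 3), seed = 1)
#' sim$truth$type
#' @export
simulate_ring_cohort <- function(counts, n_multi2 = 0L, n_multi3 = 0L,
                                 alphabet = c("non-ligand", "full"),
                                 flank_range = c(10L, 30L), spacers = NULL,
                                 grammar = ring_grammar(), seed = 1L) {
  alphabet <- match.arg(alphabet)
  ab <- if (alphabet == "non-ligand") NON_LIGAND_AA else ALL_AA
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), grammar$type)
  if (length(bad)) stop("unknown RING type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  total <- sum(counts)
  if (total == 0L) {
    return(list(proteins = tibble::tibble(id = character(),
                                          sequence = character(),
                                          description = character()),
                truth = empty_hits()))
  }
  if (total < 3L * n_multi3 + 2L * n_multi2) {
    stop("not enough planted domains for the requested multi-domain proteins",
         call. = FALSE)
  }
  with_private_seed(seed, {
    type_pool <- sample(rep(names(counts), counts))
    sizes <- c(rep(3L, n_multi3), rep(2L, n_multi2))
    n_single <- total - sum(sizes)
    sizes <- c(sizes, rep(1L, n_single))
    prot_rows <- vector("list", length(sizes))
    truth_rows <- vector("list", length(sizes))
    k <- 0L
    for (i in seq_along(sizes)) {
      id <- sprintf("synth%04d", i)
      doms <- lapply(seq_len(sizes[[i]]), function(j) {
        type <- type_pool[[k + j]]
        row <- grammar[grammar$type == type, ]
        build_domain(row, ab, spacers[[type]], grammar)
      })
      k <- k + sizes[[i]]
      # inter-domain linkers must exceed the widest grammar gap so no
      # spurious match can straddle two planted domains and fuse their
      # overlap clusters during resolution
      min_linker <- max(unlist(grammar$gaps)) + 1L
      n_seg <- sizes[[i]] + 1L
      flanks <- vapply(seq_len(n_seg), function(j) {
        len <- if (j == 1L || j == n_seg) {
          sample(flank_range[[1]]:flank_range[[2]], 1L)
        } else {
          min_linker + sample(0:30, 1L)
        }
        rand_aa(len, ab)
      }, character(1))
      seq_parts <- character(0)
      offset <- 0L
      dom_truth <- vector("list", length(doms))
      for (j in seq_along(doms)) {
        seq_parts <- c(seq_parts, flanks[[j]])
        offset <- offset + nchar(flanks[[j]])
        ml <- doms[[j]]$ml_offsets + offset
        dom_truth[[j]] <- tibble::tibble(
          protein_id = id, type = doms[[j]]$type,
          start = ml[[1]], end = ml[[8]],
          !!!stats::setNames(as.list(ml), paste0("ml", 1:8)),
          !!!stats::setNames(as.list(doms[[j]]$gaps), paste0("g", 1:7))
        )
        seq_parts <- c(seq_parts, doms[[j]]$sequence)
        offset <- offset + nchar(doms[[j]]$sequence)
      }
      seq_parts <- c(seq_parts, flanks[[length(flanks)]])
      prot_rows[[i]] <- tibble::tibble(
        id = id, sequence = paste(seq_parts, collapse = ""),
        description = NA_character_)
      truth_rows[[i]] <- dplyr::bind_rows(dom_truth)
    }
    list(proteins = dplyr::bind_rows(prot_rows),
         truth = dplyr::bind_rows(truth_rows))
  })
}

sense_codons <- function() {
  codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                  1, paste, collapse = "")
  setdiff(codons, STOP_CODONS)
}

#' Simulate codon-sequence pairs evolved at a target dN/dS
#'
#' Each pair is an ancestor of uniformly drawn sense codons plus a
#' descendant in which every nucleotide site mutates with the given
#' probability: a proposed change that would create a stop codon is
#' redrawn among the remaining bases, a nonsynonymous change is accepted
#' with probability `min(1, omega)`, and a synonymous change with
#' probability `min(1, 1 / omega)` (i.e. always, for `omega <= 1`; for
#' `omega > 1` the synonymous rate is damped so the realized dN/dS exceeds
#' one). Rejected proposals leave the site unchanged.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence.
#' @param p_sub Per-site mutation probability (< 0.1; the low-divergence
#'   regime where the Jukes-Cantor correction is valid).
#' @param omega Target dN/dS (> 0).
#' @param seed Integer seed.
#' @return List with `cds` (tibble `id`, `sequence`; two records per pair,
#'   ids `<pair>_a` / `<pair>_b`), `pairs` (tibble `pair_id`, `gene_a`,
#'   `gene_b`) and `truth` (tibble `pair_id`, `omega`).
#' @export
simulate_codon_pairs <- function(n_pairs, n_codons, p_sub, omega, seed = 1L) {
  stopifnot(p_sub >= 0, p_sub < 0.1, omega > 0)
  sense <- sense_codons()
  with_private_seed(seed, {
    recs <- vector("list", 2L * n_pairs)
    pair_ids <- sprintf("pair%04d", seq_len(n_pairs))
    for (i in seq_len(n_pairs)) {
      anc <- sample(sense, n_codons, replace = TRUE)
      der <- anc
      sites <- which(stats::runif(3L * n_codons) < p_sub)
      for (s in sites) {
        ci <- (s - 1L) %/% 3L + 1L
        pos <- (s - 1L) %% 3L + 1L
        cur <- der[[ci]]
        cand <- setdiff(BASES, substr(cur, pos, pos))
        repeat {
          b <- if (length(cand) == 1L) cand else sample(cand, 1L)
          mut <- cur
          substr(mut, pos, pos) <- b
          if (!(mut %in% STOP_CODONS)) break
          cand <- setdiff(cand, b)
          if (!length(cand)) { mut <- cur; break }
        }
        if (mut == cur) next
        syn <- aa_of(mut) == aa_of(cur)
        p_acc <- if (syn) min(1, 1 / omega) else min(1, omega)
        if (stats::runif(1) < p_acc) der[[ci]] <- mut
      }
      recs[[2L * i - 1L]] <- tibble::tibble(
        id = paste0(pair_ids[[i]], "_a"),
        sequence = paste(anc, collapse = ""))
      recs[[2L * i]] <- tibble::tibble(
        id = paste0(pair_ids[[i]], "_b"),
        sequence = paste(der, collapse = ""))
    }
    list(
      cds = dplyr::bind_rows(recs),
      pairs = tibble::tibble(pair_id = pair_ids,
                             gene_a = paste0(pair_ids, "_a"),
                             gene_b = paste0(pair_ids, "_b")),
      truth = tibble::tibble(pair_id = pair_ids, omega = omega)
    )
  })
}

#' Simulate a salt-stress expression table with planted DEG structure
#'
#' Builds a gene x time-point table of log2 fold changes and adjusted
#' p-values in which a planted set of gene/time-point cells satisfies the
#' DEG cutoff (|log2FC| >= 1 and P-adj <= 0.05, with margin) and every
#' other cell violates it. The planted structure fixes: per-time-point DEG
#' counts, the number of genes DE at two or more time points, directional
#' all-time-point genes, and duplicate pairs that are direction-concordant
#' (or discordant) at shared DEG time points. Defaults reproduce the shape
#' of a salt-stress root time course in upland cotton: 914 genes, four
#' time points (1, 3, 12, 48 h), 107/153/273/90 DEGs per time point, 393
#' DEG genes in total of which 144 are DE at >= 2 time points and 13 at all
#' four (10 up, 3 down), and 45 concordant duplicate pairs.
#'
#' @param n_genes Number of genes.
#' @param timepoints Ordered time points (hours).
#' @param tp_counts DEG count per time point (same length as
#'   `timepoints`).
#' @param n_deg_total Total genes that are a DEG at >= 1 time point.
#' @param n_min2 Genes DE at >= 2 time points (includes the all-time-point
#'   genes).
#' @param n_all_up,n_all_down Genes up (resp. down) at every time point.
#' @param n_pairs_concordant,n_pairs_discordant Duplicate pairs planted
#'   with matching (resp. opposing) directions at identical DEG
#'   time-point sets; drawn from the >= 2 time-point genes.
#' @param seed Integer seed.
#' @return List with `expr` (tibble `gene_id`, `timepoint`, `log2fc`,
#'   `padj`), `pairs` (tibble `gene_a`, `gene_b`, `concordance`), and
#'   `truth` (list: `deg` tibble of planted DEG cells with direction,
#'   `tp_counts`, `n_min2`, `all_up`/`all_down` gene IDs).
#' @export
simulate_expression <- function(n_genes = 914L,
                                timepoints = c(1, 3, 12, 48),
                                tp_counts = c(107L, 153L, 273L, 90L),
                                n_deg_total = 393L,
                                n_min2 = 144L,
                                n_all_up = 10L, n_all_down = 3L,
                                n_pairs_concordant = 45L,
                                n_pairs_discordant = 0L,
                                seed = 1L) {
  n_tp <- length(timepoints)
  stopifnot(length(tp_counts) == n_tp, n_deg_total <= n_genes,
            all(tp_counts <= n_deg_total))
  n_all <- n_all_up + n_all_down
  n_multi <- n_min2 - n_all            # >=2-tp genes that are not all-tp
  n_single <- n_deg_total - n_min2     # exactly one DEG time point
  assign_left <- sum(tp_counts) - n_all * n_tp - n_single
  if (n_multi < 0 || n_single < 0 || assign_left < 2L * n_multi ||
      (n_multi > 0 && assign_left > (n_tp - 1L) * n_multi)) {
    stop("planted DEG set sizes are mutually infeasible", call. = FALSE)
  }
  n_pairs <- n_pairs_concordant + n_pairs_discordant
  if (2L * n_pairs > n_multi) {
    stop("not enough multi-time-point genes to form the requested pairs",
         call. = FALSE)
  }
  # split the n_multi genes into sizes {2,3}: n3 genes get 3 time points
  n3 <- assign_left - 2L * n_multi
  if (n3 > n_multi) stop("planted DEG set sizes need gap sizes above 3",
                         call. = FALSE)
  n2 <- n_multi - n3
  # pairs take identical time-point sets, so pair sizes come in twos
  p3 <- min(n3 %/% 2L, n_pairs)
  p2 <- n_pairs - p3
  if (2L * p2 > n2) stop("cannot allocate pair time-point sets", call. = FALSE)
  s3 <- n3 - 2L * p3
  s2 <- n2 - 2L * p2

  with_private_seed(seed, {
    ids <- sprintf("gene%04d", seq_len(n_genes))
    deg_genes <- sample(ids, n_deg_total)
    all_up_ids <- deg_genes[seq_len(n_all_up)]
    all_down_ids <- deg_genes[n_all_up + seq_len(n_all_down)]
    multi_ids <- deg_genes[n_all + seq_len(n_multi)]
    single_ids <- deg_genes[n_all + n_multi + seq_len(n_single)]

    caps <- tp_counts - n_all
    take_tps <- function(k, w) {
      sel <- order(caps, decreasing = TRUE)[seq_len(k)]
      if (any(caps[sel] < w)) stop("capacity exhausted while planting DEGs",
                                   call. = FALSE)
      caps[sel] <<- caps[sel] - w
      sort(sel)
    }
    # units: pairs first (weight 2 per time point), then unpaired multi genes
    unit_sizes <- c(rep(3L, p3), rep(2L, p2))
    pair_sets <- lapply(unit_sizes, take_tps, w = 2L)
    solo_sets <- lapply(c(rep(3L, s3), rep(2L, s2)), take_tps, w = 1L)
    single_tps <- rep(seq_len(n_tp), caps)
    caps[] <- 0L
    stopifnot(length(single_tps) == n_single)

    pair_members <- matrix(multi_ids[seq_len(2L * n_pairs)], ncol = 2L,
                           byrow = TRUE)
    solo_ids <- multi_ids[setdiff(seq_len(n_multi),
                                  seq_len(2L * n_pairs))]

    dirs <- c("up", "down")
    cells <- list()
    add_cells <- function(gene, tps, direction) {
      cells[[length(cells) + 1L]] <<- tibble::tibble(
        gene_id = gene, timepoint = timepoints[tps], direction = direction)
    }
    for (g in all_up_ids) add_cells(g, seq_len(n_tp), "up")
    for (g in all_down_ids) add_cells(g, seq_len(n_tp), "down")
    pair_dir <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      d1 <- sample(dirs, 1L)
      concordant <- i <= n_pairs_concordant
      d2 <- if (concordant) d1 else setdiff(dirs, d1)
      pair_dir[[i]] <- if (concordant) "concordant" else "discordant"
      add_cells(pair_members[i, 1L], pair_sets[[i]], d1)
      add_cells(pair_members[i, 2L], pair_sets[[i]], d2)
    }
    for (j in seq_along(solo_ids)) {
      add_cells(solo_ids[[j]], solo_sets[[j]], sample(dirs, 1L))
    }
    for (j in seq_along(single_ids)) {
      add_cells(single_ids[[j]], single_tps[[j]], sample(dirs, 1L))
    }
    deg_cells <- if (length(cells)) dplyr::bind_rows(cells) else
      tibble::tibble(gene_id = character(), timepoint = double(),
                     direction = character())

    expr <- tidyr::expand_grid(gene_id = ids, timepoint = timepoints) |>
      dplyr::left_join(deg_cells, by = c("gene_id", "timepoint"))
    n_cells <- nrow(expr)
    is_deg <- !is.na(expr$direction)
    sign_fc <- ifelse(expr$direction == "down", -1, 1)
    lfc <- numeric(n_cells)
    padj <- numeric(n_cells)
    lfc[is_deg] <- sign_fc[is_deg] * stats::runif(sum(is_deg), 1.1, 6)
    padj[is_deg] <- stats::runif(sum(is_deg), 1e-6, 0.04)
    # non-DEG cells violate at least one threshold
    mode <- sample(1:3, sum(!is_deg), replace = TRUE)
    small_fc <- stats::runif(sum(!is_deg), -0.9, 0.9)
    big_fc <- sample(c(-1, 1), sum(!is_deg), TRUE) *
      stats::runif(sum(!is_deg), 1.1, 4)
    small_p <- stats::runif(sum(!is_deg), 0.001, 0.049)
    big_p <- stats::runif(sum(!is_deg), 0.051, 0.999)
    lfc[!is_deg] <- ifelse(mode == 3, big_fc, small_fc)
    padj[!is_deg] <- ifelse(mode == 1, small_p, big_p)
    expr$log2fc <- lfc
    expr$padj <- padj

    list(
      expr = dplyr::select(expr, "gene_id", "timepoint", "log2fc", "padj"),
      pairs = tibble::tibble(gene_a = pair_members[, 1L],
                             gene_b = pair_members[, 2L],
                             concordance = pair_dir),
      truth = list(
        deg = deg_cells,
        tp_counts = stats::setNames(tp_counts, timepoints),
        n_deg_total = n_deg_total,
        n_min2 = n_min2,
        all_up = all_up_ids,
        all_down = all_down_ids
      )
    )
  })
}

#' Simulate a gene-order table with planted tandem pairs
#'
#' Lays out genes in order along chromosomes and nominates duplicate pairs
#' that are adjacent (tandem) or separated / on different chromosomes
#' (non-tandem).
#'
#' @param n_genes Total genes.
#' @param n_chromosomes Number of chromosomes (genes split evenly).
#' @param n_tandem,n_nontandem Number of planted pairs of each mode.
#' @param seed Integer seed.
#' @return List with `gene_order` (tibble `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`) and `pairs` (tibble `gene_a`, `gene_b`,
#'   `mode`).
#' @export
simulate_gene_order <- function(n_genes = 100L, n_chromosomes = 4L,
                                n_tandem = 5L, n_nontandem = 5L, seed = 1L) {
  with_private_seed(seed, {
    chrom <- rep(sprintf("A%02d", seq_len(n_chromosomes)),
                 length.out = n_genes)
    chrom <- sort(chrom)
    per <- table(chrom)
    start <- unlist(lapply(per, function(k)
      cumsum(sample(2000:9000, k, replace = TRUE))), use.names = FALSE)
    gene_order <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chromosome = chrom,
      start = start,
      end = start + sample(500:1999, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    by_chr <- split(gene_order$gene_id, gene_order$chromosome)
    tandem <- lapply(seq_len(n_tandem), function(i) {
      chr <- by_chr[[(i - 1L) %% length(by_chr) + 1L]]
      j <- sample(length(chr) - 1L, 1L)
      c(chr[[j]], chr[[j + 1L]])
    })
    nontandem <- lapply(seq_len(n_nontandem), function(i) {
      if (i %% 2L == 0L && length(by_chr) > 1L) {
        c(by_chr[[1L]][[sample(length(by_chr[[1L]]), 1L)]],
          by_chr[[2L]][[sample(length(by_chr[[2L]]), 1L)]])
      } else {
        chr <- by_chr[[(i - 1L) %% length(by_chr) + 1L]]
        j <- sample(length(chr) - 3L, 1L)
        c(chr[[j]], chr[[j + 3L]])
      }
    })
    pairs <- tibble::tibble(
      gene_a = c(vapply(tandem, `[[`, character(1), 1L),
                 vapply(nontandem, `[[`, character(1), 1L)),
      gene_b = c(vapply(tandem, `[[`, character(1), 2L),
                 vapply(nontandem, `[[`, character(1), 2L)),
      mode = c(rep("tandem", n_tandem), rep("nontandem", n_nontandem))
    )
    list(gene_order = gene_order, pairs = pairs)
  })
}
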