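# Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
# correction and equal pathway weighting. Site and pathway counts exclude
# changes to/from stop codons.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.ng_cache <- new.env(parent = emptyenv())

aa_of <- function(codon) {
  tab <- get_codon_tab()
  unname(tab[codon])
}

get_codon_tab <- function() {
  if (is.null(.ng_cache$tab)) .ng_cache$tab <- codon_table()
  .ng_cache$tab
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the fraction of the three possible
#' single-nucleotide changes that are synonymous, with changes to stop
#' codons excluded from the denominator. Site fractions sum to 1 per
#' position, so synonymous + nonsynonymous sites = 3 per codon.
#'
#' @param codon A 3-letter codon over A/C/G/T; must not be a stop codon.
#' @return Named numeric vector `c(syn, nonsyn)`, summing to 3.
#' @examples
#' count_codon_sites("TTT")  # syn = 1/3
#' count_codon_sites("ATG")  # syn = 0
#' @export
count_codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("not an unambiguous codon: '", codon, "'", call. = FALSE)
  }
  if (codon %in% STOP_CODONS) {
    stop("stop codon '", codon, "' has no site counts", call. = FALSE)
  }
  aa0 <- aa_of(codon)
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(BASES, substr(codon, pos, pos)), function(b) {
      m <- codon
      substr(m, pos, pos) <- b
      m
    }, character(1))
    valid <- muts[!(muts %in% STOP_CODONS)]
    if (length(valid)) {
      syn <- syn + sum(aa_of(valid) == aa0) / length(valid)
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Per-codon syn-site lookup over the 61 sense codons.
syn_site_table <- function() {
  if (is.null(.ng_cache$sites)) {
    codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                    1, paste, collapse = "")
    sense <- setdiff(codons, STOP_CODONS)
    .ng_cache$sites <- vapply(sense, function(cd) count_codon_sites(cd)[["syn"]],
                              numeric(1))
  }
  .ng_cache$sites
}

# Average syn/nonsyn difference counts between two sense codons over all
# orderings of the single-step pathways, excluding pathways that pass
# through a stop codon. Returns c(sd, nd) or NULL when every pathway is
# blocked. Memoized.
codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- get0(key, envir = .ng_cache, inherits = FALSE)
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) {
    val <- c(sd = 0, nd = 0)
  } else {
    orders <- if (d == 1L) list(pos) else
      if (d == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
    paths <- list()
    for (ord in orders) {
      cur <- c1
      sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
        if (aa_of(cur) == aa_of(nxt)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) paths[[length(paths) + 1L]] <- c(sd, nd)
    }
    if (!length(paths)) {
      .ng_cache[[key]] <- FALSE
      return(NULL)
    }
    m <- do.call(rbind, paths)
    val <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  }
  .ng_cache[[key]] <- val
  val
}

jc_correct <- function(p, what) {
  if (p >= 3 / 4) {
    stop("substitution proportion ", what, " = ", signif(p, 4),
         " is saturated (>= 3/4); Jukes-Cantor correction undefined",
         call. = FALSE)
  }
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Ka/Ks of one codon-aligned sequence pair (Nei-Gojobori 1986)
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (equal-weight averaging over all orderings of
#' single-step pathways for multi-substitution codons, pathways through
#' stop codons excluded), converts proportions to distances with the
#' Jukes-Cantor correction, and calls the selection class from the Ka/Ks
#' ratio: `purifying` below 1, `positive` above 1, `neutral` at exact
#' equality, `undefined` when both distances are zero. `ks = 0` with
#' `ka > 0` yields an infinite ratio and a positive call.
#'
#' Codon columns containing `N`, a gap (`-`), or a stop codon in either
#' sequence are skipped pairwise; the number skipped is reported.
#'
#' @param cds1,cds2 In-frame, codon-aligned nucleotide strings of equal
#'   length divisible by 3.
#' @param pair_id Identifier recorded in the result row.
#' @return One-row tibble: `pair_id`, `n_codons` (compared), `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `ps`, `pn`, `ks`, `ka`,
#'   `ratio`, `selection`, `n_skipped`.
#' @examples
#' a <- strrep("TTT", 10)
#' b <- paste0(strrep("TTT", 9), "TTC")
#' kaks_pair(a, b)
#' @export
kaks_pair <- function(cds1, cds2, pair_id = "pair") {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  n <- nchar(cds1)
  if (n != nchar(cds2)) stop("sequences of pair '", pair_id,
                             "' differ in length", call. = FALSE)
  if (n == 0L || n %% 3L != 0L) {
    stop("alignment length of pair '", pair_id,
         "' is not a positive multiple of 3", call. = FALSE)
  }
  starts <- seq(1L, n, 3L)
  cod1 <- substring(cds1, starts, starts + 2L)
  cod2 <- substring(cds2, starts, starts + 2L)
  clean <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2) &
    !(cod1 %in% STOP_CODONS) & !(cod2 %in% STOP_CODONS)
  n_skipped <- sum(!clean)
  cod1 <- cod1[clean]; cod2 <- cod2[clean]
  sites <- syn_site_table()
  S <- (sum(sites[cod1]) + sum(sites[cod2])) / 2
  N <- 3 * length(cod1) - S
  Sd <- 0; Nd <- 0; n_blocked <- 0L
  diff_idx <- which(cod1 != cod2)
  for (i in diff_idx) {
    dd <- codon_pair_diffs(cod1[[i]], cod2[[i]])
    if (is.null(dd)) {
      # every pathway passes through a stop: drop the codon entirely
      n_blocked <- n_blocked + 1L
      s_i <- (sites[[cod1[[i]]]] + sites[[cod2[[i]]]]) / 2
      S <- S - s_i
      N <- N - (3 - s_i)
      next
    }
    Sd <- Sd + dd[["sd"]]
    Nd <- Nd + dd[["nd"]]
  }
  n_skipped <- n_skipped + n_blocked
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps, "ps")
  ka <- jc_correct(pn, "pn")
  if (ks == 0 && ka == 0) {
    ratio <- NA_real_; selection <- "undefined"
  } else if (ks == 0) {
    ratio <- Inf; selection <- "positive"
  } else {
    ratio <- ka / ks
    selection <- if (abs(ratio - 1) <= 1e-12) "neutral"
                 else if (ratio < 1) "purifying" else "positive"
  }
  tibble::tibble(
    pair_id = pair_id,
    n_codons = length(cod1) - n_blocked,
    syn_sites = S, nonsyn_sites = N,
    syn_diffs = Sd, nonsyn_diffs = Nd,
    ps = ps, pn = pn, ks = ks, ka = ka,
    ratio = ratio, selection = selection,
    n_skipped = n_skipped
  )
}

#' Ka/Ks for a table of duplicate pairs
#'
#' Looks up each pair's coding sequences and runs [kaks_pair()].
#'
#' @param cds Tibble of CDS records (`id`, `sequence`).
#' @param pairs Tibble with columns `gene_a`, `gene_b` and optionally
#'   `pair_id` (default `gene_a:gene_b`).
#' @return A `kaks_tbl` tibble, one row per pair (see [kaks_pair()]).
#' @export
kaks <- function(cds, pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  ids <- if ("pair_id" %in% names(pairs)) pairs$pair_id else
    paste0(pairs$gene_a, ":", pairs$gene_b)
  seq_of <- stats::setNames(cds$sequence, cds$id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seq_of))
  if (length(missing)) {
    stop("CDS missing for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::pmap(list(pairs$gene_a, pairs$gene_b, ids),
                     function(a, b, id) kaks_pair(seq_of[[a]], seq_of[[b]], id)) |>
    dplyr::bind_rows()
  class(out) <- c("kaks_tbl", class(out))
  out
}

#' Selection-class summary of Ka/Ks results
#'
#' @param results A tibble of [kaks_pair()] rows (e.g. from [kaks()]).
#' @return Tibble `selection`, `n`, `fraction` over
#'   purifying/neutral/positive/undefined classes present.
#' @examples
#' classify_selection(tibble::tibble(
#'   selection = c("purifying", "purifying", "positive")))
#' @export
classify_selection <- function(results) {
  stopifnot("selection" %in% names(results))
  results |>
    dplyr::count(selection = .data$selection, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' One-row summary of a Ka/Ks table
#' @param x A `kaks_tbl`.
#' @param ... Unused.
#' @return Tibble with pair count, mean/median finite ratio and the
#'   purifying/positive fractions.
#' @exportS3Method generics::glance
glance.kaks_tbl <- function(x, ...) {
  fin <- x$ratio[is.finite(x$ratio)]
  tibble::tibble(
    n_pairs = nrow(x),
    mean_ratio = mean(fin),
    median_ratio = stats::median(fin),
    frac_purifying = mean(x$selection == "purifying"),
    frac_positive = mean(x$selection == "positive")
  )
}

#' Histogram of Ka/Ks ratios
#' @param object A `kaks_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kaks_tbl <- function(object, ...) {
  dat <- dplyr::filter(object, is.finite(.data$ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 40, fill = "darkorange", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Ka/Ks", y = "gene pairs") +
    ggplot2::theme_minimal()
}
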