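#' Classify duplicate gene pairs as tandem or non-tandem
#'
#' A pair is tandem when both genes lie on the same chromosome within
#' `max_gap` intervening genes of each other in chromosomal gene order
#' (rank difference at most `max_gap + 1`). The default `max_gap = 0`
#' requires strict adjacency. All other pairs are flagged
#' `"nontandem"` (segmental-duplication candidates; actual collinearity
#' block assignment is taken as external input when available).
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param gene_order Tibble with `gene_id`, `chromosome`, `start` (used to
#'   rank genes within each chromosome), e.g. from [read_gene_order()].
#' @param max_gap Maximum number of intervening genes allowed (default 0).
#' @return `pairs` with an added `mode` column (`"tandem"`/`"nontandem"`).
#' @examples
#' ord <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                       chromosome = "A13", start = c(100, 200, 900))
#' classify_tandem(tibble::tibble(gene_a = "g1", gene_b = "g2"), ord)
#' @export
classify_tandem <- function(pairs, gene_order, max_gap = 0L) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)),
            all(c("gene_id", "chromosome", "start") %in% names(gene_order)))
  ranked <- gene_order |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(rank = rank(.data$start, ties.method = "first")) |>
    dplyr::ungroup()
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ranked$gene_id)
  if (length(missing)) {
    stop("gene(s) absent from gene-order table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chrom <- stats::setNames(ranked$chromosome, ranked$gene_id)
  rk <- stats::setNames(ranked$rank, ranked$gene_id)
  pairs |>
    dplyr::mutate(
      mode = unname(ifelse(
        chrom[.data$gene_a] == chrom[.data$gene_b] &
          abs(rk[.data$gene_a] - rk[.data$gene_b]) <= max_gap + 1L,
        "tandem", "nontandem"))
    )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, preserving input
#' order (a thin validated front on `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes at an inclusive threshold
#'
#' Flags each gene x time point record `up` when `log2fc >= lfc` and
#' `padj <= padj_max`, `down` when `log2fc <= -lfc` and `padj <= padj_max`,
#' else `none`. Thresholds are inclusive. Records with a missing `log2fc`
#' or `padj` are excluded, with the exclusion count attached as attribute
#' `n_excluded`.
#'
#' @param records Expression tibble with columns `gene_id`, `timepoint`,
#'   `log2fc`, `padj`.
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @return The records with an added `deg` column, attribute `n_excluded`.
#' @examples
#' r <- tibble::tibble(gene_id = "g", timepoint = 1,
#'                     log2fc = c(1, 0.99), padj = c(0.05, 0.001))
#' call_degs(r)$deg
#' @export
call_degs <- function(records, lfc = 1, padj_max = 0.05) {
  stopifnot(all(c("gene_id", "timepoint", "log2fc", "padj") %in% names(records)))
  ok <- !is.na(records$log2fc) & !is.na(records$padj)
  out <- records[ok, , drop = FALSE] |>
    dplyr::mutate(deg = dplyr::case_when(
      .data$log2fc >= lfc & .data$padj <= padj_max ~ "up",
      .data$log2fc <= -lfc & .data$padj <= padj_max ~ "down",
      TRUE ~ "none"
    ))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Per-timepoint DEG counts
#'
#' @param records Output of [call_degs()].
#' @return Tibble `timepoint`, `n_up`, `n_down`, `n_deg`.
#' @export
deg_counts <- function(records) {
  stopifnot("deg" %in% names(records))
  records |>
    dplyr::group_by(timepoint = .data$timepoint) |>
    dplyr::summarise(
      n_up = sum(.data$deg == "up"),
      n_down = sum(.data$deg == "down"),
      n_deg = sum(.data$deg != "none"),
      .groups = "drop"
    )
}

#' Multi-timepoint DEG set membership
#'
#' For each gene, counts the time points at which it is a DEG (either
#' direction) and flags membership in the "DE at >= k time points" set and
#' the directional all-timepoint sets. A gene is all-timepoint up only when
#' it is `up` at every configured time point; mixed-direction genes belong
#' to neither directional set (but do count toward the >= k set).
#'
#' @param records Output of [call_degs()].
#' @param k Minimum number of DEG time points for the `min_k` set
#'   (default 2).
#' @param timepoints The configured time points; defaults to those present
#'   in `records`.
#' @return Tibble `gene_id`, `n_deg_timepoints`, `min_k`, `all_up`,
#'   `all_down` (one row per gene with at least one DEG call).
#' @export
multi_timepoint_sets <- function(records, k = 2L, timepoints = NULL) {
  stopifnot("deg" %in% names(records))
  if (is.null(timepoints)) timepoints <- sort(unique(records$timepoint))
  n_tp <- length(timepoints)
  records |>
    dplyr::filter(.data$timepoint %in% timepoints) |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(
      n_deg_timepoints = sum(.data$deg != "none"),
      all_up = sum(.data$deg == "up") == n_tp,
      all_down = sum(.data$deg == "down") == n_tp,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_deg_timepoints > 0L) |>
    dplyr::mutate(min_k = .data$n_deg_timepoints >= k) |>
    dplyr::select("gene_id", "n_deg_timepoints", "min_k", "all_up", "all_down")
}

#' Expression-direction concordance of duplicate pairs
#'
#' A pair is `concordant` when, at every time point where both genes are
#' DEGs, their directions agree; `discordant` when any shared DEG time
#' point has opposite directions. Pairs with no time point at which both
#' genes are DEGs are vacuously concordant and flagged `untested`. Pairs
#' with a gene absent from the expression table are dropped, with the
#' count in attribute `n_skipped`.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param records Output of [call_degs()].
#' @return `pairs` with an added `concordance` column
#'   (`concordant`/`discordant`/`untested`); attribute `n_skipped`.
#' @export
pair_concordance <- function(pairs, records) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)),
            "deg" %in% names(records))
  present <- unique(records$gene_id)
  keep <- pairs$gene_a %in% present & pairs$gene_b %in% present
  out <- pairs[keep, , drop = FALSE]
  deg_of <- records |>
    dplyr::select("gene_id", "timepoint", "deg")
  flag <- purrr::map2_chr(out$gene_a, out$gene_b, function(a, b) {
    da <- deg_of[deg_of$gene_id == a, ]
    db <- deg_of[deg_of$gene_id == b, ]
    shared <- dplyr::inner_join(da, db, by = "timepoint",
                                suffix = c("_a", "_b")) |>
      dplyr::filter(.data$deg_a != "none", .data$deg_b != "none")
    if (nrow(shared) == 0L) return("untested")
    if (any(shared$deg_a != shared$deg_b)) "discordant" else "concordant"
  })
  out$concordance <- flag
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Livak relative expression (2^-ddCt)
#'
#' Converts qPCR cycle thresholds of a target and reference gene under
#' treatment and control into relative expression:
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Finite Ct values (vectorized).
#' @return Relative expression level(s).
#' @examples
#' livak(24, 18, 25, 18)  # one cycle earlier under treatment -> 2.0
#' @export
livak <- function(ct_target_treated, ct_ref_treated,
                  ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Naive log2 fold change from FPKM values
#'
#' `log2((fpkm_treated + pseudocount) / (fpkm_control + pseudocount))`.
#' A convenience for tables that carry FPKM only; not equivalent to a
#' shrinkage-based model fit, and labelled as such.
#'
#' @param fpkm_treated,fpkm_control Non-negative expression values.
#' @param pseudocount Stabilizing constant, default 1.
#' @return log2 fold changes.
#' @export
naive_log2fc <- function(fpkm_treated, fpkm_control, pseudocount = 1) {
  log2((fpkm_treated + pseudocount) / (fpkm_control + pseudocount))
}

#' Bar chart of per-timepoint DEG counts
#'
#' @param records Output of [call_degs()].
#' @return A ggplot of up/down DEG counts per time point.
#' @export
plot_deg_counts <- function(records) {
  dat <- deg_counts(records) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$timepoint), y = .data$n,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "time point (h)", y = "DEGs") +
    ggplot2::theme_minimal()
}
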