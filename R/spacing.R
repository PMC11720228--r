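#' Spacing-pattern profile between metal-ligand pairs
#'
#' Tabulates, for each RING type and each of the seven inter-ligand gaps,
#' how many domains show each spacer length, together with the fraction of
#' that stratum's domains. An `"ALL"` stratum pools every type, mirroring
#' the usual presentation of per-type and overall spacing panels.
#'
#' @param hits Hit tibble carrying `type` and `g1`..`g7` columns (e.g.
#'   `tidy()` of a [scan_ring_domains()] result).
#' @return A `spacing_profile` tibble: `type` (a RING type or `"ALL"`),
#'   `gap_index` (1-7), `spacer_length`, `count`, `fraction`. Fractions
#'   within each (type, gap_index) stratum sum to 1. Empty input yields an
#'   empty table.
#' @examples
#' hits <- tibble::tibble(type = c("RING-H2", "RING-H2"),
#'   g1 = 2, g2 = c(15, 14), g3 = 1, g4 = 2, g5 = 2, g6 = c(10, 10), g7 = 2)
#' spacing_profile(hits)
#' @export
spacing_profile <- function(hits) {
  gcols <- paste0("g", 1:7)
  if (nrow(hits) == 0L) {
    out <- tibble::tibble(type = character(), gap_index = integer(),
                          spacer_length = integer(), count = integer(),
                          fraction = double())
    class(out) <- c("spacing_profile", class(out))
    return(out)
  }
  stopifnot(all(c("type", gcols) %in% names(hits)))
  long <- hits |>
    dplyr::select("type", dplyr::all_of(gcols)) |>
    tidyr::pivot_longer(dplyr::all_of(gcols), names_to = "gap_index",
                        values_to = "spacer_length") |>
    dplyr::mutate(gap_index = as.integer(sub("^g", "", .data$gap_index)))
  long <- dplyr::bind_rows(long, dplyr::mutate(long, type = "ALL"))
  out <- long |>
    dplyr::count(.data$type, .data$gap_index, .data$spacer_length,
                 name = "count") |>
    dplyr::group_by(.data$type, .data$gap_index) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$type, .data$gap_index, .data$spacer_length)
  class(out) <- c("spacing_profile", class(out))
  out
}

#' Modal spacer length of a stratum
#'
#' Returns the most frequent spacer length for one (type, gap) stratum of a
#' spacing profile. Ties are broken by the smaller length (a deterministic
#' convention; the choice is documented rather than meaningful).
#'
#' @param profile A [spacing_profile()] table.
#' @param type_name A RING type name or `"ALL"`.
#' @param gap_index Gap number 1-7 (gap k separates ml-k from ml-k+1).
#' @return One-row tibble `spacer_length`, `count`.
#' @export
modal_spacing <- function(profile, type_name, gap_index) {
  stratum <- dplyr::filter(profile, .data$type == type_name,
                           .data$gap_index == !!as.integer(gap_index))
  if (nrow(stratum) == 0L) {
    stop("empty stratum: type '", type_name, "', gap ", gap_index,
         call. = FALSE)
  }
  stratum |>
    dplyr::arrange(dplyr::desc(.data$count), .data$spacer_length) |>
    dplyr::slice(1L) |>
    dplyr::select("spacer_length", "count")
}

#' Plot a spacing profile
#'
#' Faceted bar chart of spacer-length distributions, per type and gap.
#'
#' @param object A `spacing_profile` tibble.
#' @param gaps Which gap indices to show (default the variable loops 2 and 6).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spacing_profile <- function(object, gaps = c(2L, 6L), ...) {
  dat <- dplyr::filter(object, .data$gap_index %in% gaps)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$spacer_length, y = .data$count,
                                    fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ gap_index, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "spacer length (aa)", y = "domains") +
    ggplot2::theme_minimal()
}
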