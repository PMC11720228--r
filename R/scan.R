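#' Enumerate every RING-domain match in one protein sequence
#'
#' Exhaustively finds every distinct (type, ml-position 8-tuple) in a
#' sequence that satisfies a grammar type's residue constraints at the eight
#' metal-ligand positions and its spacer-length constraints between
#' consecutive positions. Equivalent to brute-force enumeration of all
#' increasing 8-tuples; implemented as an incremental frontier extension so
#' it scales. Spacer residues are unconstrained (they may themselves be
#' ligand letters); nonstandard residues (X, B, Z, U, *) never satisfy an
#' ml constraint. Matching is case-insensitive.
#'
#' @param sequence A single amino-acid sequence string.
#' @param grammar A `ring_grammar` tibble, default [ring_grammar()].
#' @param protein_id ID recorded in the output rows.
#' @return Tibble with one row per match: `protein_id`, `type`, `start`,
#'   `end`, `ml1`..`ml8` (1-based positions) and `g1`..`g7` (spacer
#'   lengths), sorted by ascending `start`, then `end`, then grammar
#'   precedence.
#' @examples
#' motif <- paste0(strrep("A", 5), "CAAC", strrep("A", 15), "CAHAAHAAC",
#'                 strrep("A", 12), "CAAC", strrep("A", 5))
#' enumerate_ring_matches(motif)
#' @export
enumerate_ring_matches <- function(sequence, grammar = ring_grammar(),
                                   protein_id = "<seq>") {
  validate_grammar(grammar)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos_of <- lapply(c(C = "C", H = "H", S = "S", T = "T", G = "G"),
                   function(l) which(chars == l))
  rows <- vector("list", nrow(grammar))
  for (i in seq_len(nrow(grammar))) {
    residues <- grammar$residues[[i]]
    gaps <- grammar$gaps[[i]]
    allowed <- lapply(residues, function(set) {
      ok <- logical(n)
      ok[unlist(pos_of[set], use.names = FALSE)] <- TRUE
      ok
    })
    frontier <- matrix(which(allowed[[1]]), ncol = 1L)
    for (j in 1:7) {
      if (nrow(frontier) == 0L) break
      last <- frontier[, ncol(frontier)]
      cand <- outer(last, gaps[[j]] + 1L, `+`)          # rows x gap choices
      valid <- cand <= n & cand >= 1L
      valid[valid] <- allowed[[j + 1L]][cand[valid]]
      hit <- which(valid, arr.ind = TRUE)
      if (nrow(hit) == 0L) {
        frontier <- frontier[0, , drop = FALSE]
        break
      }
      frontier <- cbind(frontier[hit[, 1L], , drop = FALSE],
                        cand[hit])
    }
    if (nrow(frontier) && ncol(frontier) == 8L) {
      colnames(frontier) <- paste0("ml", 1:8)
      tb <- tibble::as_tibble(frontier)
      tb$type <- grammar$type[[i]]
      tb$precedence <- grammar$precedence[[i]]
      rows[[i]] <- tb
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_hits())
  out <- dplyr::bind_rows(rows)
  out$protein_id <- protein_id
  out$start <- out$ml1
  out$end <- out$ml8
  for (j in 1:7) {
    out[[paste0("g", j)]] <- out[[paste0("ml", j + 1L)]] - out[[paste0("ml", j)]] - 1L
  }
  out <- dplyr::arrange(out, .data$start, .data$end, .data$precedence)
  dplyr::select(out, "protein_id", "type", "start", "end",
                dplyr::all_of(paste0("ml", 1:8)),
                dplyr::all_of(paste0("g", 1:7)))
}

empty_hits <- function() {
  cols <- c("protein_id", "type")
  out <- tibble::tibble(protein_id = character(), type = character(),
                        start = integer(), end = integer())
  for (nm in c(paste0("ml", 1:8), paste0("g", 1:7))) out[[nm]] <- integer()
  out
}

#' Resolve overlapping RING-domain hits
#'
#' Partitions hits on each protein into clusters of mutually overlapping
#' intervals (`start`..`end` sharing any position, by transitive closure)
#' and keeps a single hit per cluster: the highest-precedence type first,
#' then the leftmost `ml1`, then the smallest span. The default `"resolved"`
#' policy therefore returns non-overlapping hits; policy `"all"` returns the
#' input unchanged.
#'
#' @param hits Hit tibble from [enumerate_ring_matches()] (may span several
#'   proteins).
#' @param policy `"resolved"` (default) or `"all"`.
#' @param grammar Grammar supplying type precedence.
#' @return Hit tibble, one row per retained hit.
#' @export
resolve_ring_hits <- function(hits, policy = c("resolved", "all"),
                              grammar = ring_grammar()) {
  if (!is.character(policy) || !all(policy %in% c("resolved", "all"))) {
    stop("unknown overlap policy: ", paste(setdiff(policy, c("resolved", "all")),
                                           collapse = ", "), call. = FALSE)
  }
  policy <- match.arg(policy)
  if (policy == "all" || nrow(hits) == 0L) return(hits)
  prec <- stats::setNames(grammar$precedence, grammar$type)
  unknown <- setdiff(unique(hits$type), names(prec))
  if (length(unknown)) {
    stop("hit type(s) not in grammar: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hits |>
    dplyr::mutate(.prec = prec[.data$type]) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(.cluster = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                             default = -1L))) |>
    dplyr::group_by(.data$protein_id, .data$.cluster) |>
    dplyr::arrange(.data$.prec, .data$start,
                   .data$end - .data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$protein_id, .data$start) |>
    dplyr::select(-".cluster", -".prec")
}

#' Scan a protein collection for RING domains and classify them
#'
#' Runs [enumerate_ring_matches()] on every protein, applies the overlap
#' policy via [resolve_ring_hits()], and summarises domain counts per
#' protein and per RING type. Proteins with no hit are excluded from the
#' RING set (but counted as scanned).
#'
#' @param proteins Tibble of protein records (`id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param grammar A `ring_grammar`, default [ring_grammar()].
#' @param policy Overlap policy passed to [resolve_ring_hits()].
#' @return A `ring_scan` object: list with `hits` (per-domain tibble),
#'   `proteins` (per-protein tibble `protein_id`, `n_domains`, `types`),
#'   and `type_counts` (per-type domain totals). Use [generics::tidy()] for
#'   the hit table and [generics::glance()] for a one-row summary.
#' @examples
#' p <- tibble::tibble(id = "demo",
#'   sequence = paste0("MNNNN", "CDKC", strrep("E", 15), "CRHDDHKKC",
#'                     strrep("Q", 12), "CPPC", "NNNN"))
#' scan <- scan_ring_domains(p)
#' tidy(scan)
#' glance(scan)
#' @export
scan_ring_domains <- function(proteins, grammar = ring_grammar(),
                              policy = c("resolved", "all")) {
  policy <- match.arg(policy)
  validate_grammar(grammar)
  if (nrow(proteins) == 0L) {
    hits <- empty_hits()
  } else {
    hits <- purrr::map2(proteins$sequence, proteins$id,
                        ~ enumerate_ring_matches(.x, grammar, .y)) |>
      dplyr::bind_rows()
  }
  hits <- resolve_ring_hits(hits, policy, grammar)
  per_protein <- hits |>
    dplyr::group_by(protein_id = .data$protein_id) |>
    dplyr::summarise(n_domains = dplyr::n(),
                     types = paste(.data$type, collapse = ";"),
                     .groups = "drop")
  type_counts <- hits |>
    dplyr::count(type = .data$type, name = "n_domains") |>
    dplyr::arrange(dplyr::desc(.data$n_domains))
  structure(
    list(hits = hits, proteins = per_protein, type_counts = type_counts,
         n_scanned = nrow(proteins), policy = policy),
    class = "ring_scan"
  )
}

#' @export
print.ring_scan <- function(x, ...) {
  cat("RING domain scan (policy: ", x$policy, ")\n", sep = "")
  cat("  proteins scanned: ", x$n_scanned,
      "; RING proteins: ", nrow(x$proteins),
      "; domains: ", nrow(x$hits), "\n", sep = "")
  print(x$type_counts)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-domain hit table of a RING scan
#' @param x A `ring_scan` object.
#' @param ... Unused.
#' @return The hit tibble (one row per resolved domain).
#' @exportS3Method generics::tidy
tidy.ring_scan <- function(x, ...) x$hits

#' One-row summary of a RING scan
#' @param x A `ring_scan` object.
#' @param ... Unused.
#' @return Tibble with `n_scanned`, `n_ring_proteins`, `n_domains`,
#'   `n_types`, and the maximum domains found on one protein.
#' @exportS3Method generics::glance
glance.ring_scan <- function(x, ...) {
  tibble::tibble(
    n_scanned = x$n_scanned,
    n_ring_proteins = nrow(x$proteins),
    n_domains = nrow(x$hits),
    n_types = nrow(x$type_counts),
    max_domains_per_protein = if (nrow(x$proteins)) max(x$proteins$n_domains) else 0L
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of RING-type domain totals
#' @param object A `ring_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ring_scan <- function(object, ...) {
  ggplot2::ggplot(object$type_counts,
                  ggplot2::aes(x = stats::reorder(.data$type, -.data$n_domains),
                               y = .data$n_domains)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "RING type", y = "domains") +
    ggplot2::theme_minimal()
}

#' Write a hit table to TSV
#' @param hits Hit tibble (or `ring_scan`, whose hits are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (inherits(hits, "ring_scan")) hits <- hits$hits
  readr::write_tsv(hits, path)
  invisible(path)
}

#' Read a hit table written by [write_hits()]
#' @param path TSV path.
#' @return Hit tibble.
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
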