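#' The default RING-domain metal-ligand grammar
#'
#' Eight type specifications describing the residue allowed at each of the
#' eight metal-ligand (ml) positions of a RING zinc finger and the allowed
#' spacer lengths between consecutive ml residues. The canonical types
#' RING-H2 (C3H2C3) and RING-HC (C3HC4, split into HCa and HCb by the
#' ml7-ml8 spacing) are joined by the modified types RING-v, RING-C2,
#' RING-S/T, RING-D and RING-G.
#'
#' Specs are ordered by matching precedence: fixed-gap / rare-residue types
#' are checked before the broad ranged types (G, D, S/T, C2, v, HCb, H2,
#' HCa), so a special case is never absorbed by a more general pattern when
#' overlap resolution picks one label. The RING-HCb ml7-ml8 spacer is fixed
#' at 4 residues, the feature that separates HCb from HCa.
#'
#' @return A `ring_grammar` tibble with columns `type`, `precedence`,
#'   `residues` (list of 8 character vectors of allowed residues at
#'   ml1..ml8) and `gaps` (list of 7 integer vectors of allowed spacer
#'   lengths g1..g7).
#' @examples
#' g <- ring_grammar()
#' g$type
#' g$gaps[[which(g$type == "RING-v")]][[4]]  # ml4-ml5 spacer, always 7
#' @export
ring_grammar <- function() {
  rng <- function(a, b) seq.int(a, b)
  spec <- function(type, residues, gaps) {
    list(type = type, residues = residues, gaps = gaps)
  }
  specs <- list(
    spec("RING-G",
         list("C", "C", "C", "H", "G", "C", "C", "C"),
         list(2L, 16L, 1L, 2L, 2L, 13L, 2L)),
    spec("RING-D",
         list("C", "C", "C", "H", "C", "C", "C", "C"),
         list(2L, 12L, 1L, 2L, 2L, 10L, 2L)),
    spec("RING-S/T",
         list("C", c("S", "T"), "C", "H", "C", c("C", "S"), "C", "C"),
         list(2L, rng(10, 14), 1L, c(2L, 3L), 2L, c(6L, 13L), 2L)),
    spec("RING-C2",
         list("C", "C", "C", "C", "C", "C", "C", "C"),
         list(2L, rng(13, 15), 1L, 4L, 2L, rng(10, 36), 2L)),
    spec("RING-v",
         list("C", "C", "C", "C", "H", "C", "C", "C"),
         list(2L, rng(11, 27), 1L, 7L, 2L, rng(12, 15), 4L)),
    spec("RING-HCb",
         list("C", "C", "C", "H", "C", "C", "C", "C"),
         list(2L, rng(11, 13), 1L, 2L, 2L, rng(11, 18), 4L)),
    spec("RING-H2",
         list("C", "C", "C", "H", "H", "C", "C", "C"),
         list(2L, rng(11, 28), 1L, 2L, 2L, rng(7, 45), 2L)),
    spec("RING-HCa",
         list("C", "C", "C", "H", "C", "C", "C", "C"),
         list(2L, rng(9, 20), 1L, c(2L, 3L), 2L, rng(6, 29), c(1L, 2L)))
  )
  out <- tibble::tibble(
    type = vapply(specs, `[[`, character(1), "type"),
    precedence = seq_along(specs),
    residues = lapply(specs, `[[`, "residues"),
    gaps = lapply(specs, function(s) lapply(s$gaps, as.integer))
  )
  class(out) <- c("ring_grammar", class(out))
  validate_grammar(out)
}

validate_grammar <- function(grammar) {
  stopifnot(all(c("type", "precedence", "residues", "gaps") %in% names(grammar)))
  if (anyDuplicated(grammar$type)) {
    stop("grammar type names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(grammar))) {
    res <- grammar$residues[[i]]
    gaps <- grammar$gaps[[i]]
    if (length(res) != 8L) {
      stop("type '", grammar$type[[i]], "': need 8 residue sets", call. = FALSE)
    }
    if (length(gaps) != 7L) {
      stop("type '", grammar$type[[i]], "': need 7 gap sets", call. = FALSE)
    }
    ok_res <- vapply(res, function(r)
      length(r) > 0 && all(r %in% c("C", "H", "S", "T", "G")), logical(1))
    if (!all(ok_res)) {
      stop("type '", grammar$type[[i]],
           "': residue sets must be non-empty subsets of {C,H,S,T,G}",
           call. = FALSE)
    }
    ok_gap <- vapply(gaps, function(g) length(g) > 0 && all(g >= 0), logical(1))
    if (!all(ok_gap)) {
      stop("type '", grammar$type[[i]],
           "': gap sets must be non-empty and non-negative", call. = FALSE)
    }
  }
  grammar
}

#' Read a RING grammar from JSON
#'
#' The JSON file is a list of specs, each with fields `type`, `residues`
#' (8 arrays of residue letters) and `gaps` (7 arrays of allowed spacer
#' lengths). Precedence follows file order.
#'
#' @param path Path to a grammar JSON file, e.g. written by
#'   [write_grammar()].
#' @return A `ring_grammar` tibble (see [ring_grammar()]).
#' @export
read_grammar <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- tibble::tibble(
    type = vapply(raw, function(s) unlist(s$type)[[1]], character(1)),
    precedence = seq_along(raw),
    residues = lapply(raw, function(s)
      lapply(s$residues, function(r) toupper(unlist(r, use.names = FALSE)))),
    gaps = lapply(raw, function(s)
      lapply(s$gaps, function(g) as.integer(unlist(g, use.names = FALSE))))
  )
  class(out) <- c("ring_grammar", class(out))
  validate_grammar(out)
}

#' Write a RING grammar to JSON
#'
#' @param grammar A `ring_grammar` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(grammar, path) {
  validate_grammar(grammar)
  out <- lapply(seq_len(nrow(grammar)), function(i) {
    list(type = grammar$type[[i]],
         residues = lapply(grammar$residues[[i]], identity),
         gaps = lapply(grammar$gaps[[i]], identity))
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
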