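#' Read a FASTA file into a tibble
#'
#' Reads protein or nucleotide FASTA (wrapped or unwrapped lines) and returns
#' one row per record. The record ID is the first whitespace-delimited token
#' of the header; the remainder of the header, if any, becomes `description`.
#' Sequences are uppercased and stripped of whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `description`.
#'   An empty file yields a zero-row tibble with a warning.
#' @details Duplicated record IDs are an error (IDs must be unique within a
#'   collection). A sequence line appearing before any `>` header is a
#'   format error.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 demo", "acgT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L || !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), sequence = character(),
                          description = character()))
  }
  first <- trimws(readLines(path, n = 50L, warn = FALSE))
  first <- first[nzchar(first)]
  if (length(first) && !startsWith(first[[1]], ">")) {
    stop("malformed FASTA (sequence line before any '>' header): ", path,
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated FASTA record ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = unname(seqs), description = desc)
}

#' Write a tibble of sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Codon -> amino acid lookup built from the standard genetic code.
# Codons containing N (or any ambiguity) translate to "X".
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

translate_one <- function(sequence, id = "<cds>") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length of '", id, "' (", n, " nt) is not a positive multiple of 3",
         call. = FALSE)
  }
  codons <- substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"   # codons with N or other ambiguity
  n_cod <- length(aa)
  internal_stop <- which(aa[-n_cod] == "*")
  if (length(internal_stop)) {
    stop("internal stop codon in '", id, "' at codon ", internal_stop[[1]],
         call. = FALSE)
  }
  if (aa[n_cod] == "*") aa <- aa[-n_cod]
  paste(aa, collapse = "")
}

#' Translate in-frame coding sequences
#'
#' Translates each CDS from position 1 with the standard genetic code. A
#' terminal stop codon is dropped, so a CDS of `3k` nucleotides ending in a
#' stop yields a protein of `k - 1` residues. Codons containing `N` become
#' `X`. An internal stop codon is an error naming the codon index.
#'
#' @param cds Tibble with columns `id` and `sequence` (nucleotides over
#'   A/C/G/T/N), as returned by [read_fasta()].
#' @return Tibble of protein records (`id`, `sequence`, `description`).
#' @examples
#' translate_cds(tibble::tibble(id = "g1", sequence = "ATGTGGTAA"))
#' @export
translate_cds <- function(cds) {
  stopifnot(all(c("id", "sequence") %in% names(cds)))
  prot <- purrr::map2_chr(cds$sequence, cds$id, ~ translate_one(.x, .y))
  tibble::tibble(
    id = cds$id,
    sequence = prot,
    description = if ("description" %in% names(cds)) cds$description else NA_character_
  )
}

#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 subset restricted to `gene`, `mRNA` and `exon` features and
#' returns one row per gene with its coordinates and an exon count taken from
#' the first-listed mRNA of the gene (genes without an mRNA but with exons
#' parented directly on the gene use those; genes with neither get
#' `exon_count = 1`).
#'
#' @param path Path to a GFF3 file.
#' @return Tibble `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'   `exon_count`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path, call. = FALSE)
  gff <- rtracklayer::readGFF(path,
                              filter = list(type = c("gene", "mRNA", "exon")))
  gff <- tibble::as_tibble(as.data.frame(gff))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[[1]] else NA_character_, character(1))
  genes <- dplyr::filter(gff, .data$type == "gene")
  mrnas <- dplyr::filter(gff, .data$type == "mRNA")
  exons <- dplyr::filter(gff, .data$type == "exon")
  # first-listed mRNA per gene, in file order
  first_mrna <- mrnas |>
    dplyr::group_by(.data$Parent) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(gene_id = "Parent", mrna_id = "ID")
  exon_by_parent <- exons |>
    dplyr::count(.data$Parent, name = "n_exon")
  counts <- first_mrna |>
    dplyr::left_join(exon_by_parent, by = c(mrna_id = "Parent"))
  gene_tbl <- tibble::tibble(
    gene_id = as.character(genes$ID),
    chromosome = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  gene_tbl <- gene_tbl |>
    dplyr::left_join(dplyr::select(counts, "gene_id", "n_exon"), by = "gene_id") |>
    dplyr::left_join(dplyr::rename(exon_by_parent, n_exon_direct = "n_exon"),
                     by = c(gene_id = "Parent")) |>
    dplyr::mutate(
      exon_count = dplyr::coalesce(.data$n_exon, .data$n_exon_direct, 1L)
    ) |>
    dplyr::select(-"n_exon", -"n_exon_direct")
  gene_tbl
}

#' Read a tabular gene-order file
#'
#' @param path TSV with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (header required).
#' @return Tibble with those columns.
#' @export
read_gene_order <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "chromosome", "start")
  if (!all(need %in% names(tbl))) {
    stop("gene-order table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Exon-count histogram and intronless count
#'
#' Tabulates the number of genes at each exon count; intronless genes are
#' those with a single exon. The intronless count is attached as attribute
#' `intronless` and returned in the printed summary.
#'
#' @param models Tibble of gene models with an `exon_count` column
#'   (e.g. from [read_gff_genes()]).
#' @return Tibble `exon_count`, `n_genes`, sorted by `exon_count`, with
#'   attribute `intronless` (number of single-exon genes).
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"), exon_count = c(1, 1, 5))
#' exon_stats(m)
#' @export
exon_stats <- function(models) {
  if (nrow(models) == 0L) {
    out <- tibble::tibble(exon_count = integer(), n_genes = integer())
    attr(out, "intronless") <- 0L
    return(out)
  }
  stopifnot("exon_count" %in% names(models))
  out <- models |>
    dplyr::count(exon_count = as.integer(.data$exon_count), name = "n_genes") |>
    dplyr::arrange(.data$exon_count)
  attr(out, "intronless") <- sum(out$n_genes[out$exon_count == 1L])
  out
}
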