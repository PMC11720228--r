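# Average residue masses (Da) for the 20 standard amino acids, plus the mass
# of one water added per peptide chain. Average (not monoisotopic) masses,
# as used for whole-protein MW prediction.
AA_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01524

#' Bjellqvist-style pK table for isoelectric-point calculation
#'
#' The pK set used by the common Compute pI/MW style of calculation:
#' side-chain pK values for D, E, C, Y, H, K, R, a C-terminal carboxyl pK,
#' and an N-terminal amino pK with residue-specific overrides for the first
#' residue. Swap in a different table via the `pk` argument of
#' [isoelectric_point()].
#'
#' @return A list with elements `cterm` (scalar), `nterm_default` (scalar),
#'   `nterm` (named overrides by first residue), `positive` (named: H, K, R),
#'   `negative` (named: D, E, C, Y).
#' @export
pk_bjellqvist <- function() {
  list(
    cterm = 3.55,
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7, G = 7.5),
    positive = c(H = 5.98, K = 10.0, R = 12.0),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  )
}

#' Average molecular weight of proteins
#'
#' Sum of average residue masses plus one water mass per chain.
#'
#' @param sequence Character vector of amino-acid sequences (20 standard
#'   letters; case-insensitive).
#' @param permissive If `TRUE`, nonstandard residues (X, B, Z, U, *) are
#'   assigned the mean of the 20 standard residue masses instead of
#'   erroring.
#' @return Numeric vector of masses in Da.
#' @examples
#' molecular_weight("G")    # 75.07 Da
#' molecular_weight("GG")   # 132.12 Da
#' @export
molecular_weight <- function(sequence, permissive = FALSE) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    if (!nzchar(s)) stop("empty sequence has no molecular weight", call. = FALSE)
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- AA_MASS[aa]
    if (anyNA(m)) {
      if (permissive) {
        m[is.na(m)] <- mean(AA_MASS)
      } else {
        bad <- which(is.na(m))[[1]]
        stop("unknown residue '", aa[bad], "' at position ", bad,
             " (use permissive = TRUE for a mean-mass fallback)",
             call. = FALSE)
      }
    }
    sum(m) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge over the free N-terminus, free
#' C-terminus and the ionizable side chains (D, E, C, Y negative; H, K, R
#' positive) with the supplied pK set.
#'
#' @param sequence Single amino-acid sequence.
#' @param ph pH value(s) at which to evaluate the charge.
#' @param pk pK table, default [pk_bjellqvist()].
#' @return Numeric vector of net charges, one per `ph`.
#' @export
net_charge <- function(sequence, ph, pk = pk_bjellqvist()) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence has no charge", call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  first <- aa[[1]]
  nterm_pk <- if (first %in% names(pk$nterm)) pk$nterm[[first]] else pk$nterm_default
  pos_pk <- c(nterm_pk, unname(pk$positive[aa[aa %in% names(pk$positive)]]))
  neg_pk <- c(pk$cterm, unname(pk$negative[aa[aa %in% names(pk$negative)]]))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pk))) - sum(1 / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on \[0, 14\]. Iterated until the residual charge is below 1e-9
#' (or 100 halvings), so `net_charge(s, isoelectric_point(s))` is ~0.
#'
#' @inheritParams net_charge
#' @return The pI in pH units.
#' @examples
#' isoelectric_point("ACDEFGHIKLMNPQRSTVWY")
#' @export
isoelectric_point <- function(sequence, pk = pk_bjellqvist()) {
  lo <- 0; hi <- 14
  # charge is strictly decreasing in pH: positive at 0, negative at 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pk)
    if (abs(q) < 1e-9) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physico-chemical summary of a protein collection
#'
#' Length, average molecular weight and theoretical pI for each record.
#'
#' @param proteins Tibble of protein records (`id`, `sequence`).
#' @param permissive Passed to [molecular_weight()]; when `TRUE`,
#'   nonstandard residues get a mean-mass fallback and are skipped for
#'   charge.
#' @param pk pK table for the pI computation, default [pk_bjellqvist()].
#' @return Tibble `protein_id`, `length`, `mw_da`, `pi`.
#' @export
physchem <- function(proteins, permissive = FALSE, pk = pk_bjellqvist()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  seqs <- toupper(proteins$sequence)
  clean <- if (permissive) {
    gsub("[^GASPVTCLINDQKEMHFRYW]", "", seqs)
  } else {
    seqs
  }
  tibble::tibble(
    protein_id = proteins$id,
    length = nchar(seqs),
    mw_da = molecular_weight(seqs, permissive = permissive),
    pi = vapply(clean, isoelectric_point, numeric(1), pk = pk,
                USE.NAMES = FALSE)
  )
}
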