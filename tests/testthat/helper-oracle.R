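# Independent brute-force oracle for the RING-domain scanner. Enumerates
# all increasing 8-tuples of candidate positions by relational joins over
# consecutive position pairs -- a mechanism deliberately different from the
# scanner's frontier extension -- and filters on the gap constraints.

oracle_matches <- function(sequence, grammar = ringkit::ring_grammar()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_len(nrow(grammar))) {
    residues <- grammar$residues[[i]]
    gapsets <- grammar$gaps[[i]]
    cand <- lapply(residues, function(set) which(chars %in% set))
    if (any(lengths(cand) == 0L)) next
    df <- data.frame(p1 = cand[[1]])
    for (j in 1:7) {
      pairs <- expand.grid(a = unique(df[[paste0("p", j)]]),
                           b = cand[[j + 1L]])
      pairs <- pairs[(pairs$b - pairs$a - 1L) %in% gapsets[[j]], , drop = FALSE]
      names(pairs) <- paste0("p", c(j, j + 1L))
      df <- merge(df, pairs, by = paste0("p", j))
      if (nrow(df) == 0L) break
    }
    if (nrow(df) == 0L) next
    df <- df[, paste0("p", 1:8), drop = FALSE]
    names(df) <- paste0("ml", 1:8)
    df$type <- grammar$type[[i]]
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) {
    return(data.frame(type = character(),
                      matrix(integer(), 0, 8,
                             dimnames = list(NULL, paste0("ml", 1:8)))))
  }
  res <- do.call(rbind, out)
  res <- res[, c("type", paste0("ml", 1:8))]
  res <- res[do.call(order, res), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Canonical form of a scanner hit table for set comparison with the oracle.
canonical_hits <- function(hits) {
  df <- as.data.frame(hits[, c("type", paste0("ml", 1:8))])
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}
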