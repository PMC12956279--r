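# Independent brute-force oracles, deliberately kept free of any package
# internals: the folding oracle exhaustively walks every non-crossing
# structure by recursion (no DP table, no memoisation) and reports the best
# achievable score.

oracle_pair_weight <- function(a, b, weights) {
  ab <- paste0(sort(c(a, b)), collapse = "")
  switch(ab,
         "CG" = unname(weights["GC"]),
         "AT" = unname(weights["AT"]),
         "GT" = unname(weights["GT"]),
         0)
}

# Maximum total weight over all non-crossing pair sets of residues[i..j]
# (1-based), honouring min_loop and an optional 1-based masked index set.
oracle_best_score <- function(residues, min_loop = 3,
                              weights = c(GC = 3, AT = 2, GT = 1),
                              mask1 = integer(0)) {
  chars <- strsplit(toupper(residues), "")[[1]]
  n <- length(chars)
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)                      # i unpaired
    if (!(i %in% mask1)) {
      for (k in (i + min_loop + 1):j) {
        if (k %in% mask1) next
        w <- oracle_pair_weight(chars[i], chars[k], weights)
        if (w > 0)
          best <- max(best, w + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    best
  }
  rec(1, n)
}

# Enumerate every non-crossing structure of a short sequence as a list of
# 2-column 0-based pair matrices (used to assert uniqueness of ground-truth
# scaffolds on tiny cases).
oracle_enumerate <- function(residues, min_loop = 3,
                             weights = c(GC = 3, AT = 2, GT = 1)) {
  chars <- strsplit(toupper(residues), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1)
      return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (oracle_pair_weight(chars[i], chars[k], weights) <= 0) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  lapply(rec(1, length(chars)), function(p) {
    p <- matrix(as.integer(p), ncol = 2) - 1L
    if (nrow(p)) p[order(p[, 1]), , drop = FALSE] else p
  })
}

oracle_score_pairs <- function(residues, pairs0,
                               weights = c(GC = 3, AT = 2, GT = 1)) {
  chars <- strsplit(toupper(residues), "")[[1]]
  if (!nrow(pairs0)) return(0)
  sum(vapply(seq_len(nrow(pairs0)), function(r)
    oracle_pair_weight(chars[pairs0[r, 1] + 1L], chars[pairs0[r, 2] + 1L],
                       weights), numeric(1)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
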