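# Structure-guided cargo-insertion design for the retron msd.
#
# The msd portion of a retron ncRNA is reverse-transcribed into abundant
# single-stranded DNA in vivo. Inserting a functional cargo (e.g. a
# fluorogenic aptamer) into the msd works best at positions predicted to be
# single stranded or in loops, so that the cargo does not disrupt the native
# scaffold fold. This module predicts a maximum-weight non-crossing secondary
# structure for a DNA sequence, classifies positions, proposes and ranks
# insertion sites, builds fusion constructs, and scores how much of the
# scaffold structure survives insertion.

DNA_ALPHABET <- c("A", "C", "G", "T")

# Default pair weights: Watson-Crick G:C and A:T plus the G:T wobble, which
# is stable in DNA duplexes. Scores are dimensionless energy surrogates.
DEFAULT_PAIR_WEIGHTS <- c(GC = 3, AT = 2, GT = 1)

#' Construct a DNA sequence object
#'
#' @param residues character scalar over A/C/G/T (case-insensitive).
#' @param id label for the sequence.
#' @param mask optional length-2 integer vector `c(start, end)`: a closed
#'   0-based interval of positions excluded from pairing. Used for the
#'   msr-overlapping region of the msd, which is base-paired with the msr in
#'   the branched RT-DNA and must not be folded intramolecularly.
#' @return an object of class `dna_sequence`.
#' @export
dna_sequence <- function(residues, id = "seq", mask = NULL) {
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) < 1L)
    stop("`residues` must be a non-empty character scalar", call. = FALSE)
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% DNA_ALPHABET)
  if (length(bad))
    stop(sprintf("non-alphabet character '%s' at position %d",
                 chars[bad[1]], bad[1] - 1L), call. = FALSE)
  n <- nchar(residues)
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (length(mask) != 2L || mask[1] > mask[2] || mask[1] < 0L || mask[2] >= n)
      stop("`mask` must be c(start, end), 0-based, within the sequence",
           call. = FALSE)
  }
  structure(list(id = as.character(id), residues = residues, mask = mask),
            class = "dna_sequence")
}

as_dna_sequence <- function(x, id = "seq") {
  if (inherits(x, "dna_sequence")) x else dna_sequence(x, id = id)
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d nt%s)\n%s\n", x$id, nchar(x$residues),
              if (is.null(x$mask)) "" else
                sprintf(", mask %d..%d", x$mask[1], x$mask[2]),
              x$residues))
  invisible(x)
}

#' @export
length.dna_sequence <- function(x) nchar(x$residues)

# n x n matrix of pair weights for a sequence; 0 where the two bases cannot
# pair or either index is masked.
pair_weight_matrix <- function(chars, weights, mask1 = NULL) {
  key <- c(
    "AT" = unname(weights["AT"]), "TA" = unname(weights["AT"]),
    "GC" = unname(weights["GC"]), "CG" = unname(weights["GC"]),
    "GT" = unname(weights["GT"]), "TG" = unname(weights["GT"]))
  n <- length(chars)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    kk <- key[paste0(chars[i], chars)]
    kk[is.na(kk)] <- 0
    W[i, ] <- kk
  }
  if (!is.null(mask1)) {
    W[mask1, ] <- 0
    W[, mask1] <- 0
  }
  W
}

#' Predict a maximum-weight secondary structure (Nussinov-style DP)
#'
#' Computes the maximum-score non-crossing base-pair set for a DNA sequence
#' under per-pair-type weights, a minimum hairpin loop length, and an optional
#' pairing mask, then tracebacks deterministically (preferring the pair with
#' the smallest opening index, then the smallest closing index). The score is
#' a dimensionless surrogate for folding free energy: heavier pairs stand in
#' for more stable stacks. A full nearest-neighbour thermodynamic model is
#' deliberately out of scope; the `engine` argument accepts any external
#' folding engine instead.
#'
#' @param seq a `dna_sequence` (or a plain string).
#' @param min_loop minimum number of unpaired residues enclosed by a pair
#'   (default 3, the usual steric minimum for a hairpin loop).
#' @param weights named numeric vector of pair weights with names among
#'   `GC`, `AT`, `GT` (default `c(GC = 3, AT = 2, GT = 1)`).
#' @param engine optional external engine: a `function(seq, min_loop, weights)`
#'   returning a `fold_result`; the result is validated against the structural
#'   invariants (non-crossing, loop length, mask) before being returned.
#' @return a `fold_result`: list with `sequence`, `pairs` (2-column 0-based
#'   matrix, i < j), `dotbracket`, `score`, `engine`.
#' @examples
#' fold_mfe("GGGAAACCC")$dotbracket   # "(((...)))"
#' @export
fold_mfe <- function(seq, min_loop = 3L,
                     weights = DEFAULT_PAIR_WEIGHTS, engine = NULL) {
  seq <- as_dna_sequence(seq)
  if (min_loop < 0L) stop("`min_loop` must be >= 0", call. = FALSE)
  need <- c("GC", "AT", "GT")
  if (!all(need %in% names(weights)))
    stop("`weights` must be named with GC, AT and GT entries", call. = FALSE)
  if (!is.null(engine)) {
    res <- engine(seq, min_loop, weights)
    validate_fold_result(res, min_loop = min_loop)
    return(res)
  }

  chars <- strsplit(seq$residues, "")[[1]]
  n <- length(chars)
  mask1 <- if (is.null(seq$mask)) NULL else (seq$mask[1]:seq$mask[2]) + 1L
  W <- pair_weight_matrix(chars, weights, mask1)

  # M[i, j]: best score on the closed interval [i, j] (1-based).
  M <- matrix(0, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 2L):n) {
      for (i in seq_len(n - span + 1L)) {
        j <- i + span - 1L
        best <- M[i + 1L, j]          # i unpaired
        ks <- (i + min_loop + 1L):j   # candidate partners for i
        w <- W[i, ks]
        ok <- which(w > 0)
        if (length(ok)) {
          kk <- ks[ok]
          inner <- ifelse(kk - 1L >= i + 1L, M[cbind(i + 1L, pmax(kk - 1L, 1L))], 0)
          outer <- ifelse(kk + 1L <= j, M[cbind(pmin(kk + 1L, n), j)], 0)
          best <- max(best, w[ok] + inner + outer)
        }
        M[i, j] <- best
      }
    }
  }

  # Deterministic traceback: at [i, j], try pairing i with ascending k first.
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  eps <- 1e-9
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (j - i + 1L >= min_loop + 2L && M[i, j] > eps) {
      target <- M[i, j]
      found <- FALSE
      for (k in (i + min_loop + 1L):j) {
        if (W[i, k] <= 0) next
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0
        if (abs(W[i, k] + inner + outer - target) < eps) {
          pairs <- rbind(pairs, c(i, k))
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          found <- TRUE
          break
        }
      }
      if (!found) i <- i + 1L   # i is unpaired in the optimum
    }
  }

  pairs0 <- if (nrow(pairs)) pairs[order(pairs[, 1]), , drop = FALSE] - 1L else
    matrix(integer(0), ncol = 2)
  res <- structure(list(
    sequence = seq,
    pairs = pairs0,
    dotbracket = pairs_to_dotbracket(pairs0, n),
    score = M[1, n],
    engine = "nussinov"), class = "fold_result")
  validate_fold_result(res, min_loop = min_loop)
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(">%s [engine: %s, score %g, %d pairs]\n%s\n%s\n",
              x$sequence$id, x$engine, x$score, nrow(x$pairs),
              x$sequence$residues, x$dotbracket))
  invisible(x)
}

#' Validate the structural invariants of a fold result
#'
#' Checks non-crossing pairs, one partner per index, minimum loop length,
#' dot-bracket consistency and mask compliance. Called on every engine output.
#'
#' @param fold a `fold_result`.
#' @param min_loop minimum hairpin loop length to enforce.
#' @return the fold, invisibly; errors if any invariant fails.
#' @export
validate_fold_result <- function(fold, min_loop = 3L) {
  stopifnot(inherits(fold, "fold_result"))
  n <- nchar(fold$sequence$residues)
  p <- fold$pairs
  if (nchar(fold$dotbracket) != n)
    stop("dotbracket length differs from sequence length", call. = FALSE)
  if (nrow(p)) {
    if (any(p[, 1] >= p[, 2])) stop("pairs must have i < j", call. = FALSE)
    idx <- c(p[, 1], p[, 2])
    if (anyDuplicated(idx)) stop("an index occurs in two pairs", call. = FALSE)
    if (any(p[, 2] - p[, 1] - 1L < min_loop))
      stop("pair violates min_loop", call. = FALSE)
    if (nrow(p) > 1L) {
      for (a in seq_len(nrow(p) - 1L)) for (b in (a + 1L):nrow(p)) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
          stop("crossing pairs", call. = FALSE)
      }
    }
    m <- fold$sequence$mask
    if (!is.null(m) && any(idx >= m[1] & idx <= m[2]))
      stop("a masked index is paired", call. = FALSE)
  }
  if (!identical(dotbracket_to_pairs(fold$dotbracket), canonical_pairs(p)))
    stop("dotbracket inconsistent with pairs", call. = FALSE)
  invisible(fold)
}

canonical_pairs <- function(p) {
  p <- matrix(as.integer(p), ncol = 2)
  if (nrow(p)) p[order(p[, 1]), , drop = FALSE] else p
}

#' Serialize a base-pair set to dot-bracket notation
#'
#' @param pairs 2-column 0-based matrix of pairs (i < j).
#' @param n sequence length.
#' @return dot-bracket string of length `n`.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (length(pairs) && nrow(pairs)) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a base-pair set
#'
#' @param s string over `(`, `)` and `.`.
#' @return 2-column 0-based integer matrix of pairs, ordered by opening index.
#'   Round-trips with [pairs_to_dotbracket()].
#' @export
parse_dotbracket <- function(s) {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid character '%s' at index %d", chars[bad[1]],
                 bad[1] - 1L), call. = FALSE)
  dotbracket_to_pairs(s)
}

dotbracket_to_pairs <- function(s) {
  chars <- strsplit(s, "")[[1]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (!length(open))
        stop(sprintf("unbalanced ')' at index %d", i - 1L), call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop(sprintf("unbalanced '(' at index %d", open[1] - 1L), call. = FALSE)
  canonical_pairs(pairs - 1L)
}

#' Classify every position of a fold
#'
#' Positions are `paired`, `hairpin_loop` (unpaired, innermost enclosing pair
#' closes a loop containing no other pair), `internal_or_bulge` (unpaired
#' inside a pair whose interior contains further pairs: internal loops,
#' bulges and multiloop segments), or `exterior` (unpaired, not enclosed by
#' any pair). The classes are exhaustive and mutually exclusive.
#'
#' @param fold a `fold_result`.
#' @return data.frame with columns `index` (0-based) and `cls`.
#' @export
classify_positions <- function(fold) {
  stopifnot(inherits(fold, "fold_result"))
  n <- nchar(fold$sequence$residues)
  p <- fold$pairs
  cls <- rep("exterior", n)
  if (nrow(p)) {
    paired_idx <- c(p[, 1], p[, 2])
    cls[paired_idx + 1L] <- "paired"
    # hairpin-closing pairs: no paired index strictly inside
    hairpin <- vapply(seq_len(nrow(p)), function(a) {
      !any(paired_idx > p[a, 1] & paired_idx < p[a, 2])
    }, logical(1))
    for (idx in setdiff(0:(n - 1L), paired_idx)) {
      encl <- which(p[, 1] < idx & p[, 2] > idx)
      if (!length(encl)) next
      innermost <- encl[which.max(p[encl, 1])]
      cls[idx + 1L] <- if (hairpin[innermost]) "hairpin_loop" else
        "internal_or_bulge"
    }
  }
  data.frame(index = 0:(n - 1L), cls = cls, stringsAsFactors = FALSE)
}

#' Propose and rank cargo insertion sites
#'
#' Scans the fold for maximal runs of contiguous unpaired residues of length
#' at least `min_run`, places one candidate gap at each run's midpoint, and
#' ranks runs: longer runs first, then class priority hairpin_loop >
#' exterior > internal_or_bulge, then leftmost. The ranking is a reported
#' heuristic, not a biological assertion: longer single-stranded stretches
#' give an inserted cargo more room to fold without perturbing the scaffold.
#'
#' @param fold a `fold_result`.
#' @param min_run minimum unpaired run length to consider (default 3).
#' @param k maximum number of sites to return (default 4).
#' @return data.frame of class `insertion_sites` with columns `position`
#'   (0-based gap index: cargo is inserted before this residue), `run_start`,
#'   `run_length`, `cls`, `rank`; zero rows when no run qualifies.
#' @export
propose_insertion_sites <- function(fold, min_run = 3L, k = 4L) {
  if (min_run < 1L) stop("`min_run` must be >= 1", call. = FALSE)
  ann <- classify_positions(fold)
  unpaired <- ann$cls != "paired"
  # maximal runs of unpaired residues
  r <- rle(unpaired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L,
                     len = r$lengths[r$values])
  runs <- runs[runs$len >= min_run, , drop = FALSE]
  if (!nrow(runs))
    return(structure(data.frame(position = integer(0), run_start = integer(0),
                                run_length = integer(0), cls = character(0),
                                rank = integer(0)),
                     class = c("insertion_sites", "data.frame")))
  # a run of unpaired residues shares one innermost enclosing pair, so its
  # class is uniform; take it from the first residue
  runs$cls <- ann$cls[runs$start + 1L]
  runs$position <- runs$start + runs$len %/% 2L
  prio <- c(hairpin_loop = 1L, exterior = 2L, internal_or_bulge = 3L)
  ord <- order(-runs$len, prio[runs$cls], runs$position)
  runs <- runs[ord, , drop = FALSE]
  runs <- utils::head(runs, k)
  out <- data.frame(position = runs$position, run_start = runs$start,
                    run_length = runs$len, cls = runs$cls,
                    rank = seq_len(nrow(runs)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("insertion_sites", "data.frame"))
}

site_position <- function(site) {
  if (is.numeric(site)) return(as.integer(site))
  if (is.data.frame(site)) return(as.integer(site$position[1]))
  stop("`site` must be an insertion-site row or a gap index", call. = FALSE)
}

#' Insert a cargo sequence into a scaffold
#'
#' Gap-index semantics: the cargo is inserted before scaffold residue
#' `position`; `position = 0` prepends, `position = length(scaffold)` appends.
#'
#' @param scaffold,cargo `dna_sequence` objects (or strings).
#' @param site an insertion-site row from [propose_insertion_sites()] or a
#'   0-based gap index.
#' @return a `fusion_construct`: list with `scaffold_id`, `cargo_id`,
#'   `position`, `residues`, and a `sequence` (`dna_sequence`) field.
#' @export
build_fusion <- function(scaffold, cargo, site) {
  scaffold <- as_dna_sequence(scaffold, "scaffold")
  cargo <- as_dna_sequence(cargo, "cargo")
  pos <- site_position(site)
  n <- nchar(scaffold$residues)
  if (pos < 0L || pos > n)
    stop(sprintf("insertion position %d out of range [0, %d]", pos, n),
         call. = FALSE)
  res <- paste0(substr(scaffold$residues, 1L, pos), cargo$residues,
                substr(scaffold$residues, pos + 1L, n))
  fused <- dna_sequence(res, id = paste0(scaffold$id, "_", cargo$id,
                                         "_at", pos))
  structure(list(scaffold_id = scaffold$id, cargo_id = cargo$id,
                 position = pos, residues = res, sequence = fused),
            class = "fusion_construct")
}

#' @export
print.fusion_construct <- function(x, ...) {
  cat(sprintf("fusion %s + %s at gap %d (%d nt)\n%s\n", x$scaffold_id,
              x$cargo_id, x$position, nchar(x$residues), x$residues))
  invisible(x)
}

#' Fraction of scaffold base pairs preserved in a fusion fold
#'
#' Shifts every scaffold pair index at or beyond the insertion gap by the
#' cargo length and reports the fraction of scaffold pairs present in the
#' fusion's fold. A pairless scaffold is vacuously preserved (returns 1).
#'
#' @param scaffold_fold fold of the scaffold alone.
#' @param fusion_fold fold of the fusion construct.
#' @param site insertion-site row or 0-based gap index used to build the fusion.
#' @return fraction in `[0, 1]`.
#' @export
fold_preservation <- function(scaffold_fold, fusion_fold, site) {
  stopifnot(inherits(scaffold_fold, "fold_result"),
            inherits(fusion_fold, "fold_result"))
  pos <- site_position(site)
  n_sc <- nchar(scaffold_fold$sequence$residues)
  n_fu <- nchar(fusion_fold$sequence$residues)
  cargo_len <- n_fu - n_sc
  if (cargo_len < 0L)
    stop("fusion is shorter than scaffold; inconsistent inputs", call. = FALSE)
  p <- scaffold_fold$pairs
  if (!nrow(p)) return(1)
  shifted <- p
  shifted[shifted >= pos] <- shifted[shifted >= pos] + cargo_len
  key <- function(m) paste(m[, 1], m[, 2])
  mean(key(shifted) %in% key(fusion_fold$pairs))
}

#' Shorten the terminal stem of an aptamer cargo
#'
#' Fluorogenic aptamers such as Lettuce tolerate truncation of their terminal
#' (P1) stem: removing outer base pairs shortens the construct without
#' disrupting the fluorogen-binding core. Removes the residues of the
#' outermost `length(stem) - keep` pairs from both strands.
#'
#' @param cargo a `dna_sequence` (or string).
#' @param stem 2-column 0-based matrix of stem pairs, outermost first; pairs
#'   must be nested and contiguous (each inner pair is `(i+1, j-1)` of its
#'   predecessor).
#' @param keep number of innermost pairs to keep, `1 <= keep <= nrow(stem)`.
#' @return the truncated `dna_sequence` (length shrinks by
#'   `2 * (nrow(stem) - keep)`).
#' @export
truncate_stem <- function(cargo, stem, keep) {
  cargo <- as_dna_sequence(cargo)
  stem <- canonical_pairs(stem)
  if (!nrow(stem)) stop("`stem` must be non-empty", call. = FALSE)
  if (nrow(stem) > 1L) {
    d1 <- diff(stem[, 1]); d2 <- diff(stem[, 2])
    if (any(d1 != 1L) || any(d2 != -1L))
      stop("`stem` pairs must be nested and contiguous", call. = FALSE)
  }
  if (keep < 1L || keep > nrow(stem))
    stop(sprintf("`keep` must be in [1, %d]", nrow(stem)), call. = FALSE)
  n_drop <- nrow(stem) - keep
  if (n_drop == 0L) return(cargo)
  drop_idx <- c(stem[seq_len(n_drop), 1], stem[seq_len(n_drop), 2]) + 1L
  chars <- strsplit(cargo$residues, "")[[1]]
  dna_sequence(paste(chars[-drop_idx], collapse = ""),
               id = sprintf("%s_stem%d", cargo$id, keep))
}
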