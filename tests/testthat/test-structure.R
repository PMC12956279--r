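# Folding engine, dot-bracket plumbing, position classes, insertion design.

test_that("fold_mfe reproduces hand-checked structures and scores", {
  f <- fold_mfe("GGGAAACCC", min_loop = 3)
  expect_identical(f$dotbracket, "(((...)))")
  expect_equal(f$score, 9)

  # no pairable partner at min_loop = 3
  expect_identical(fold_mfe("AAAA")$dotbracket, "....")
  expect_equal(fold_mfe("AAAA")$score, 0)

  # masking removes the only Gs, so nothing can pair
  masked <- fold_mfe(dna_sequence("GGGAAACCC", mask = c(0, 2)))
  expect_equal(nrow(masked$pairs), 0)
  expect_lt(masked$score, 9)
})

test_that("fold_mfe rejects bad input", {
  expect_error(fold_mfe("GGXCC"), "non-alphabet")
  expect_error(fold_mfe("GGGAAACCC", min_loop = -1), "min_loop")
  expect_error(dna_sequence("GGG", mask = c(1, 5)), "mask")
})

test_that("DP score equals brute-force enumeration on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(5:16, 1)
    s <- random_dna(n)
    expect_equal(fold_mfe(s)$score, oracle_best_score(s), info = s)
  }
})

test_that("masked indices are never paired (property over random masks)", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(8:16, 1)
    s <- random_dna(n)
    a <- sample(0:(n - 2), 1)
    b <- sample(a:(n - 1), 1)
    f <- fold_mfe(dna_sequence(s, mask = c(a, b)))
    if (nrow(f$pairs)) {
      idx <- c(f$pairs[, 1], f$pairs[, 2])
      expect_false(any(idx >= a & idx <= b))
    }
    # masked optimum matches the oracle run with the same mask
    expect_equal(f$score, oracle_best_score(s, mask1 = (a:b) + 1L))
  }
})

test_that("traceback is deterministic and structures satisfy invariants", {
  set.seed(303)
  for (i in 1:20) {
    s <- random_dna(sample(8:18, 1))
    f1 <- fold_mfe(s)
    f2 <- fold_mfe(s)
    expect_identical(f1$dotbracket, f2$dotbracket)
    expect_silent(validate_fold_result(f1))
    # traceback score equals table score
    expect_equal(oracle_score_pairs(s, f1$pairs), f1$score)
  }
})

test_that("parse_dotbracket matches pairs and reports unbalanced input", {
  expect_equal(parse_dotbracket("(((...)))"),
               matrix(c(0L, 8L, 1L, 7L, 2L, 6L), ncol = 2, byrow = TRUE))
  expect_equal(nrow(parse_dotbracket(".........")), 0)
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(a)"), "invalid character")
})

test_that("dot-bracket round-trips for random valid structures", {
  set.seed(404)
  for (i in 1:25) {
    s <- random_dna(sample(8:18, 1))
    f <- fold_mfe(s)
    expect_equal(parse_dotbracket(pairs_to_dotbracket(f$pairs,
                                                      nchar(s))),
                 f$pairs)
  }
})

test_that("position classes follow the nesting structure and partition", {
  f <- fold_mfe("GGGAAACCC")
  ann <- classify_positions(f)
  expect_identical(ann$cls[4:6], rep("hairpin_loop", 3))
  expect_identical(ann$cls[c(1:3, 7:9)], rep("paired", 6))

  all_ext <- classify_positions(fold_mfe("AAAAAAAAA"))
  expect_true(all(all_ext$cls == "exterior"))

  # manual trace of "((..((...))..))"
  db <- "((..((...))..))"
  fold <- structure(list(sequence = dna_sequence(strrep("A", 15)),
                         pairs = parse_dotbracket(db), dotbracket = db,
                         score = 0, engine = "manual"),
                    class = "fold_result")
  ann <- classify_positions(fold)
  expect_identical(ann$cls[ann$index %in% c(2, 3, 11, 12)],
                   rep("internal_or_bulge", 4))
  expect_identical(ann$cls[ann$index %in% 6:8], rep("hairpin_loop", 3))

  # partition: class counts sum to sequence length
  set.seed(505)
  for (i in 1:10) {
    s <- random_dna(sample(8:18, 1))
    ann <- classify_positions(fold_mfe(s))
    expect_equal(sum(table(ann$cls)), nchar(s))
    expect_equal(sum(ann$cls == "paired"), 2 * nrow(fold_mfe(s)$pairs))
  }
})

test_that("insertion sites land at run midpoints and rank as documented", {
  one <- propose_insertion_sites(fold_mfe("GGGAAACCC"), min_run = 3)
  expect_equal(nrow(one), 1)
  expect_true(one$position %in% c(4, 5))
  expect_identical(one$cls, "hairpin_loop")

  ext <- propose_insertion_sites(fold_mfe("AAAA"), min_run = 3)
  expect_equal(nrow(ext), 1)
  expect_identical(ext$cls, "exterior")

  # two hairpin loops, lengths 3 and 5: longer run ranks first
  db <- "(((...)))..(((.....)))"
  fold <- structure(list(sequence = dna_sequence(strrep("A", 22)),
                         pairs = parse_dotbracket(db), dotbracket = db,
                         score = 0, engine = "manual"),
                    class = "fold_result")
  sites <- propose_insertion_sites(fold, min_run = 3)
  expect_equal(sites$run_length[sites$rank == 1], 5)
  expect_identical(sites$cls[sites$rank == 1], "hairpin_loop")
  expect_identical(sort(sites$rank), seq_len(nrow(sites)))

  # no qualifying run: empty table, not an error
  none <- propose_insertion_sites(fold_mfe("GGGAAACCC"), min_run = 4)
  expect_equal(nrow(none), 0)
})

test_that("build_fusion concatenates with gap-index semantics", {
  expect_identical(build_fusion("AAAA", "GG", 2)$residues, "AAGGAA")
  expect_identical(build_fusion("AAAA", "GG", 0)$residues, "GGAAAA")
  expect_identical(build_fusion("AAAA", "GG", 4)$residues, "AAAAGG")
  expect_error(build_fusion("AAAA", "GG", 5), "out of range")

  # 67-nt scaffold + 67-nt cargo gives a 134-nt fusion
  sc <- random_dna(67); ca <- random_dna(67)
  expect_equal(nchar(build_fusion(sc, ca, 30)$residues), 134)
})

test_that("fold_preservation counts shifted scaffold pairs", {
  scaffold <- gen_scaffold(1, loop_lens = 6, stem_lens = 4,
                           cfg = generator_config(seed = 1))
  sf <- fold_mfe(scaffold$sequence)
  sites <- propose_insertion_sites(sf, min_run = 3)
  # cargo that folds on its own and leaves the scaffold stem intact
  cargo <- "GGGGTTTTCCCC"
  fu <- build_fusion(scaffold$sequence, cargo, sites[1, ])
  ff <- fold_mfe(fu$sequence)
  expect_equal(fold_preservation(sf, ff, sites[1, ]), 1.0)

  # no scaffold pair retained
  empty_fold <- structure(list(sequence = fu$sequence,
                               pairs = matrix(integer(0), ncol = 2),
                               dotbracket = strrep(".", nchar(fu$residues)),
                               score = 0, engine = "manual"),
                          class = "fold_result")
  expect_equal(fold_preservation(sf, empty_fold, sites[1, ]), 0.0)

  # pairless scaffold: vacuously preserved
  pairless <- fold_mfe("AAAA")
  fu2 <- build_fusion("AAAA", "GG", 2)
  expect_equal(fold_preservation(pairless, fold_mfe(fu2$sequence), 2), 1.0)

  # zero-length cargo (fusion identical to scaffold): everything preserved
  expect_equal(fold_preservation(sf, fold_mfe(scaffold$sequence), 5), 1.0)
})

test_that("truncate_stem removes outer pairs symmetrically", {
  ten <- "GCGCAAAGCG"  # arbitrary residues; stem given explicitly
  stem2 <- matrix(c(0L, 9L, 1L, 8L), ncol = 2, byrow = TRUE)
  out <- truncate_stem(ten, stem2, keep = 1)
  expect_equal(nchar(out$residues), 8)
  expect_identical(out$residues, substr(ten, 2, 9))

  # keep = all pairs is the identity
  expect_identical(truncate_stem(ten, stem2, keep = 2)$residues, ten)

  # 11-pair stem truncated to 4 shrinks the sequence by 14
  n <- 30
  s <- random_dna(n)
  stem11 <- cbind(0:10, (n - 1):(n - 11))
  out4 <- truncate_stem(s, stem11, keep = 4)
  expect_equal(nchar(out4$residues), n - 14)
  expect_error(truncate_stem(s, stem11, keep = 0), "keep")
  expect_error(truncate_stem(s, stem11, keep = 12), "keep")
})

test_that("external engines are validated through the pluggable interface", {
  lying_engine <- function(seq, min_loop, weights) {
    # returns a crossing structure: must be rejected
    structure(list(sequence = seq,
                   pairs = matrix(c(0L, 5L, 2L, 8L), ncol = 2, byrow = TRUE),
                   dotbracket = "(.(..).).", score = 1, engine = "lying"),
              class = "fold_result")
  }
  expect_error(fold_mfe("GCGCGCGCG", engine = lying_engine))

  honest_engine <- function(seq, min_loop, weights) fold_mfe(seq, min_loop,
                                                             weights)
  f <- fold_mfe("GGGAAACCC", engine = honest_engine)
  expect_identical(f$dotbracket, "(((...)))")
})
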