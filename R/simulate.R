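# Seeded synthetic-data generators for every pipeline input.
#
# Each generator is a pure function of (parameters, seed): the session RNG
# is never touched. Noise models: additive Normal on CT cycles (the standard
# error model for cycle thresholds), multiplicative Normal everywhere else
# (fluorescence and OD errors scale with signal). The noise-free mode of
# every generator round-trips exactly through its fitter/estimator, which is
# the backbone of the test suite.

#' Generator configuration
#'
#' @param seed integer RNG seed.
#' @param ct_sd additive CT noise SD, cycles (default 0.15, a typical
#'   technical-replicate spread).
#' @param titration_noise relative multiplicative noise on fluorescence
#'   (default 0.02).
#' @param od_noise relative multiplicative noise on OD600 (default 0.02).
#' @param decay_noise relative multiplicative noise on qPCR fold change in
#'   decay series (default 0.05).
#' @param noise_free if `TRUE`, all generators emit exact model values.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, ct_sd = 0.15, titration_noise = 0.02,
                             od_noise = 0.02, decay_noise = 0.05,
                             noise_free = FALSE) {
  stopifnot(ct_sd >= 0, titration_noise >= 0, od_noise >= 0, decay_noise >= 0)
  structure(list(seed = as.integer(seed), ct_sd = ct_sd,
                 titration_noise = titration_noise, od_noise = od_noise,
                 decay_noise = decay_noise, noise_free = isTRUE(noise_free)),
            class = "generator_config")
}

#' Named parameter presets for the retron/aptamer system
#'
#' `FL`: the unembedded full-length Lettuce aptamer binding DFHBI-1T
#' (Kd 0.12 uM). `4LEv4`: the 4-bp-P1 Lettuce embedded at msd position v4
#' (Kd 6 uM). Both use a 1 uM fluorogen concentration; the plateau values
#' are on a typical plate-reader scale. `eco2_default`: plasmid copy number
#' 17 per cell, 120 RT-DNA molecules per cell, cytoplasmic volume 7e-16 L.
#'
#' @return named list of preset parameter lists.
#' @export
retron_presets <- function() {
  list(
    FL = list(kd = 0.12, c0 = 100, c1 = 4000, bt = 1),
    `4LEv4` = list(kd = 6, c0 = 100, c1 = 4000, bt = 1),
    eco2_default = list(plasmid_copies = 17, rtdna_copies = 120,
                        volume_l = 7e-16)
  )
}

#' Default 12-point logarithmic titration grid
#'
#' @param n number of points (default 12).
#' @param from,to grid limits in uM (default 0.05 to 40).
#' @return numeric vector of DNA concentrations, uM.
#' @export
titration_grid <- function(n = 12L, from = 0.05, to = 40) {
  exp(seq(log(from), log(to), length.out = n))
}

mult_noise <- function(n, rel, cfg) {
  if (cfg$noise_free || rel == 0) rep(1, n) else 1 + stats::rnorm(n, 0, rel)
}

#' Generate a synthetic qPCR CT table
#'
#' CT is modelled as `base_ct - log2(templates)` plus additive Normal noise:
#' the inside amplicon templates on `n_rt + n_p` molecules when induced and
#' `n_p` when uninduced; the outside amplicon always on `n_p`. The base
#' intercept (35 cycles for one template at efficiency 2) cancels in ddCT
#' by construction.
#'
#' @param n_rt RT-DNA molecules per cell in the induced condition (>= 0).
#' @param n_p plasmid copies per cell (> 0).
#' @param replicates biological replicates (default 3).
#' @param cfg a [generator_config()].
#' @param base_ct CT intercept for a single template copy (default 35).
#' @return data.frame with columns `sample`, `condition`, `primer_set`,
#'   `replicate`, `ct` — the schema [analyze_qpcr()] consumes.
#' @export
gen_qpcr_run <- function(n_rt, n_p, replicates = 3L,
                         cfg = generator_config(), base_ct = 35) {
  assert_number(n_rt, "n_rt", nonneg = TRUE)
  assert_number(n_p, "n_p", positive = TRUE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      primer_set = c("inside", "outside"),
                      condition = c("induced", "uninduced"),
                      stringsAsFactors = FALSE)
  templates <- ifelse(grid$primer_set == "outside", n_p,
                      ifelse(grid$condition == "induced", n_rt + n_p, n_p))
  eps <- with_seed(cfg$seed,
    if (cfg$noise_free || cfg$ct_sd == 0) rep(0, nrow(grid)) else
      stats::rnorm(nrow(grid), 0, cfg$ct_sd))
  data.frame(sample = "synthetic", condition = grid$condition,
             primer_set = grid$primer_set, replicate = grid$replicate,
             ct = base_ct - log2(templates) + eps,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic fluorogen titration series
#'
#' Fluorescence is the tight-binding [isotherm()] value times a
#' multiplicative Normal noise factor.
#'
#' @param kd,c0,c1,bt isotherm parameters (uM / fluorescence units); pass a
#'   preset from [retron_presets()] via `preset` instead if preferred.
#' @param grid DNA concentrations, uM (default [titration_grid()]).
#' @param cfg a [generator_config()].
#' @param construct label for the series.
#' @param preset optional preset name (`"FL"` or `"4LEv4"`); overrides
#'   `kd`, `c0`, `c1`, `bt`.
#' @return data.frame with columns `construct`, `bt_nominal_uM`, `at_uM`,
#'   `fluorescence` — the schema [fit_global()] consumes.
#' @export
gen_titration <- function(kd = 1, c0 = 0, c1 = 1000, bt = 1,
                          grid = titration_grid(), cfg = generator_config(),
                          construct = "synthetic", preset = NULL) {
  if (!is.null(preset)) {
    p <- retron_presets()[[preset]]
    if (is.null(p)) stop(sprintf("unknown preset '%s'", preset),
                         call. = FALSE)
    kd <- p$kd; c0 <- p$c0; c1 <- p$c1; bt <- p$bt
    if (construct == "synthetic") construct <- preset
  }
  f <- isotherm(grid, c0, c1, bt, kd)
  eta <- with_seed(cfg$seed, mult_noise(length(grid), cfg$titration_noise,
                                        cfg))
  data.frame(construct = construct, bt_nominal_uM = bt, at_uM = grid,
             fluorescence = f * eta, stringsAsFactors = FALSE)
}

#' Generate a synthetic logistic growth curve
#'
#' @param od_max,r,t0 logistic parameters (see [logistic_od()]).
#' @param times sampling times, minutes.
#' @param cfg a [generator_config()].
#' @return data.frame with columns `time_min`, `od600`.
#' @export
gen_growth <- function(od_max, r, t0, times = seq(0, 300, by = 15),
                       cfg = generator_config()) {
  od <- logistic_od(times, od_max, r, t0)
  eta <- with_seed(cfg$seed, mult_noise(length(times), cfg$od_noise, cfg))
  data.frame(time_min = times, od600 = od * eta)
}

#' Generate a synthetic RT-DNA fold-change decay series
#'
#' Emulates the washout experiment: fold change follows the
#' dilution-corrected [decay_curve()] with degradation rate `k` (use
#' `k = 0` for the pure-dilution regime) times multiplicative noise.
#'
#' @param a amplitude (initial fold change above the plasmid floor).
#' @param k degradation rate constant, 1/min.
#' @param logistic a `logistic_fit` describing growth after washout.
#' @param times sampling times, minutes.
#' @param cfg a [generator_config()].
#' @param t_ref dilution reference time (default first sampling time).
#' @return data.frame with columns `time_min`, `fold_change`.
#' @export
gen_decay_series <- function(a, k, logistic, times = seq(0, 240, by = 20),
                             cfg = generator_config(), t_ref = NULL) {
  assert_number(a, "a", nonneg = TRUE)
  assert_number(k, "k", nonneg = TRUE)
  t_ref <- t_ref %||% times[1]
  c_true <- decay_curve(times, a, k, logistic, t_ref)
  eta <- with_seed(cfg$seed, mult_noise(length(times), cfg$decay_noise, cfg))
  data.frame(time_min = times, fold_change = c_true * eta)
}

#' Generate a toy msd-like scaffold with known ground-truth structure
#'
#' Builds a sequence of GC-clamped hairpin stems separated by short A
#' linkers, with A-only loops. Stem orientation alternates (odd stems open
#' with G, even stems with C) so that cross-stem G:C pairings cannot tie the
#' designed structure: the designed pair set is the unique maximum-score
#' structure under the default engine weights (no A:T or G:T pair is even
#' possible, as the sequence contains no T). A stand-in for real msd
#' sequences; synthetic by construction.
#'
#' @param n_stems number of hairpin stems (>= 1).
#' @param loop_lens hairpin loop lengths (recycled to `n_stems`); each must
#'   be >= `min_loop`.
#' @param stem_lens stem lengths in base pairs (recycled); default: seeded
#'   draw from 3-5.
#' @param linker_len length of the A linker between stems (default 2).
#' @param cfg a [generator_config()] (seeds the default stem lengths).
#' @param min_loop minimum loop length the ground truth must respect
#'   (default 3).
#' @return list with `sequence` (a `dna_sequence`) and `fold` (the
#'   ground-truth `fold_result`, scored with the default weights).
#' @export
gen_scaffold <- function(n_stems = 2L, loop_lens = 4L, stem_lens = NULL,
                         linker_len = 2L, cfg = generator_config(),
                         min_loop = 3L) {
  if (n_stems < 1L) stop("`n_stems` must be >= 1", call. = FALSE)
  loop_lens <- rep_len(loop_lens, n_stems)
  if (any(loop_lens < min_loop))
    stop("every loop length must be >= min_loop", call. = FALSE)
  if (is.null(stem_lens))
    stem_lens <- with_seed(cfg$seed,
                           sample(3:5, n_stems, replace = TRUE))
  stem_lens <- rep_len(as.integer(stem_lens), n_stems)
  if (any(stem_lens < 1L)) stop("stem lengths must be >= 1", call. = FALSE)

  seq_parts <- character(0)
  pairs <- matrix(integer(0), ncol = 2)
  pos <- 0L
  for (s in seq_len(n_stems)) {
    L <- stem_lens[s]
    open_base <- if (s %% 2L == 1L) "G" else "C"
    close_base <- if (s %% 2L == 1L) "C" else "G"
    left <- pos
    right <- pos + L + loop_lens[s]
    pairs <- rbind(pairs,
                   cbind(left + 0:(L - 1L), right + (L - 1L):0))
    seq_parts <- c(seq_parts, strrep(open_base, L), strrep("A", loop_lens[s]),
                   strrep(close_base, L))
    pos <- pos + 2L * L + loop_lens[s]
    if (s < n_stems) {
      seq_parts <- c(seq_parts, strrep("A", linker_len))
      pos <- pos + linker_len
    }
  }
  residues <- paste(seq_parts, collapse = "")
  seq <- dna_sequence(residues, id = sprintf("synthetic_scaffold_%dstem",
                                             n_stems))
  pairs <- canonical_pairs(pairs)
  score <- sum(DEFAULT_PAIR_WEIGHTS["GC"]) * nrow(pairs)
  fold <- structure(list(sequence = seq, pairs = pairs,
                         dotbracket = pairs_to_dotbracket(pairs,
                                                          nchar(residues)),
                         score = unname(score), engine = "ground_truth"),
                    class = "fold_result")
  validate_fold_result(fold, min_loop = min_loop)
  list(sequence = seq, fold = fold)
}
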