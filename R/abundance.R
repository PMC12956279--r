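# RT-DNA abundance from qPCR, gel densitometry and plate-reader data.
#
# Comparative-CT quantification with an inside/outside primer design: the
# inside amplicon templates on both single-stranded RT-DNA and the plasmid,
# the outside amplicon on the plasmid only, so the induced-vs-uninduced
# ddCT fold enrichment measures RT-DNA over plasmid background. Fold
# enrichment is back-calculated to per-cell copy number and intracellular
# molar concentration.

#' Delta-CT between the inside (RT-DNA) and outside (plasmid) primer sets
#'
#' Technical replicate CTs may be supplied as vectors; they are averaged
#' (arithmetic mean) before the difference is taken.
#'
#' @param inside CT cycles of the inside amplicon (RT-DNA + plasmid template).
#' @param outside CT cycles of the outside amplicon (plasmid-only template).
#' @return delta-CT in cycles: `mean(inside) - mean(outside)`.
#' @export
delta_ct <- function(inside, outside) {
  assert_number(inside, "inside", positive = TRUE)
  assert_number(outside, "outside", positive = TRUE)
  mean(inside) - mean(outside)
}

#' Fold enrichment of RT-DNA over plasmid by the comparative-CT method
#'
#' `ddct = dct_induced - dct_uninduced`; fold `= efficiency^(-ddct)`, i.e.
#' the classic `2^-ddCT` at the default per-cycle efficiency of 2. Presence
#' of RT-DNA gives fold > 1.
#'
#' @param dct_induced,dct_uninduced delta-CT (cycles) of the induced and
#'   uninduced conditions.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return a `fold_enrichment` list: `dct_induced`, `dct_uninduced`, `ddct`,
#'   `fold`.
#' @examples
#' fold_enrichment(-3, 0)$fold  # 8
#' @export
fold_enrichment <- function(dct_induced, dct_uninduced, efficiency = 2) {
  assert_number(dct_induced, "dct_induced")
  assert_number(dct_uninduced, "dct_uninduced")
  assert_number(efficiency, "efficiency", positive = TRUE)
  ddct <- dct_induced - dct_uninduced
  structure(list(dct_induced = dct_induced, dct_uninduced = dct_uninduced,
                 ddct = ddct, fold = efficiency^(-ddct)),
            class = "fold_enrichment")
}

#' @export
print.fold_enrichment <- function(x, ...) {
  cat(sprintf("ddCT = %.3f cycles -> fold enrichment %.3f\n", x$ddct, x$fold))
  invisible(x)
}

#' RT-DNA molecules per cell from fold enrichment
#'
#' The inside amplicon counts RT-DNA plus plasmid templates and the outside
#' amplicon plasmid alone, so `fold = (N_rt + N_p) / N_p` and
#' `N_rt = (fold - 1) * N_p`. A fold below 1 (legitimate in uninduced
#' samples) is clamped to 0 copies with a warning.
#'
#' @param fold fold enrichment (dimensionless, from [fold_enrichment()]).
#' @param plasmid_copies plasmid copies per cell (scalar or vector of bounds,
#'   e.g. `c(15, 20)` for a pBR322-origin vector).
#' @return RT-DNA molecules per cell, same length as `plasmid_copies`.
#' @examples
#' copies_per_cell(8, c(15, 20))  # 105 140
#' @export
copies_per_cell <- function(fold, plasmid_copies) {
  assert_number(fold, "fold", nonneg = TRUE)
  assert_number(plasmid_copies, "plasmid_copies", positive = TRUE)
  if (fold < 1) {
    warning("fold enrichment below 1 (no RT-DNA signal above background); ",
            "reporting 0 copies", call. = FALSE)
    return(rep(0, length(plasmid_copies)))
  }
  (fold - 1) * plasmid_copies
}

#' Molar concentration of a per-cell molecule count
#'
#' @param molecules molecules per cell (>= 0).
#' @param volume cell volume in liters; the E. coli cytoplasm is about
#'   7e-16 L.
#' @return concentration in mol/L.
#' @examples
#' molar_concentration(200, 7e-16) * 1e9  # ~474 nM
#' @export
molar_concentration <- function(molecules, volume) {
  assert_number(molecules, "molecules", nonneg = TRUE)
  assert_number(volume, "volume")
  if (any(volume <= 0)) stop("`volume` must be > 0", call. = FALSE)
  molecules / (AVOGADRO * volume)
}

#' Full copy-number and concentration estimate from a fold enrichment
#'
#' @param fold fold enrichment.
#' @param plasmid_copies plasmid copy-number bounds per cell (default 15-20).
#' @param volume cytoplasmic volume in liters (default 7e-16).
#' @return a `copy_estimate` list: `fold`, `plasmid_copies`, `rtdna`
#'   (molecules per cell, per bound), `volume`, `conc` (mol/L) and `conc_nM`.
#' @export
copy_estimate <- function(fold, plasmid_copies = c(15, 20), volume = 7e-16) {
  rtdna <- copies_per_cell(fold, plasmid_copies)
  conc <- molar_concentration(rtdna, volume)
  structure(list(fold = fold, plasmid_copies = plasmid_copies, rtdna = rtdna,
                 volume = volume, conc = conc, conc_nM = conc * 1e9),
            class = "copy_estimate")
}

#' @export
print.copy_estimate <- function(x, ...) {
  cat(sprintf(
    "fold %.2f, plasmid %s copies -> %s RT-DNA molecules/cell -> %s nM\n",
    x$fold, paste(x$plasmid_copies, collapse = "-"),
    paste(round(x$rtdna), collapse = "-"),
    paste(signif(x$conc_nM, 3), collapse = "-")))
  invisible(x)
}

#' Length-corrected fold change of gel band intensities
#'
#' Densitometry intensity scales with both molecule number and molecule
#' length, so lane intensities are divided by RT-DNA length before the
#' fold change relative to a reference lane is taken.
#'
#' @param lanes data.frame with columns `label`, `intensity` (>= 0) and
#'   `length_nt` (>= 1).
#' @param reference label of the reference lane (e.g. the endogenous Eco1
#'   band).
#' @return named numeric vector of length-corrected folds;
#'   `fold[reference] == 1`.
#' @export
length_corrected_fold <- function(lanes, reference) {
  stopifnot(is.data.frame(lanes),
            all(c("label", "intensity", "length_nt") %in% names(lanes)))
  if (any(lanes$intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  if (any(lanes$length_nt < 1)) stop("length_nt must be >= 1", call. = FALSE)
  ref <- which(lanes$label == reference)
  if (!length(ref)) stop(sprintf("reference lane '%s' not found", reference),
                         call. = FALSE)
  ref <- ref[1]
  if (lanes$intensity[ref] <= 0)
    stop("reference lane intensity must be > 0", call. = FALSE)
  dens <- lanes$intensity / lanes$length_nt
  out <- dens / dens[ref]
  names(out) <- lanes$label
  out
}

#' OD-normalized bulk fluorescence
#'
#' Culture fluorescence divided by the undiluted-equivalent OD600
#' (`od600 * dilution`), so readings taken on diluted cultures are comparable
#' per unit of cell density.
#'
#' @param fluorescence raw fluorescence (arbitrary units).
#' @param od600 measured optical density of the (possibly diluted) sample.
#' @param dilution dilution factor applied before the OD read (>= 1).
#' @return fluorescence per undiluted OD unit.
#' @export
od_normalized_fluorescence <- function(fluorescence, od600, dilution = 1) {
  assert_number(fluorescence, "fluorescence", nonneg = TRUE)
  assert_number(od600, "od600")
  if (any(od600 <= 0)) stop("`od600` must be > 0", call. = FALSE)
  assert_number(dilution, "dilution", positive = TRUE)
  fluorescence / (od600 * dilution)
}

#' Comparative-CT analysis of a qPCR CT table
#'
#' For each biological replicate, technical CTs are averaged per
#' condition/primer set, delta-CT (inside - outside) is formed per condition,
#' and the induced-vs-uninduced fold enrichment is computed; replicate folds
#' are summarized by mean and SD.
#'
#' @param ct_table data.frame with columns `sample`, `condition`
#'   (`induced`/`uninduced`), `primer_set` (`inside`/`outside`), `replicate`,
#'   `ct`.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return list with `per_replicate` (data.frame: replicate, dct_induced,
#'   dct_uninduced, ddct, fold), `fold_mean`, `fold_sd`.
#' @export
analyze_qpcr <- function(ct_table, efficiency = 2) {
  need <- c("condition", "primer_set", "replicate", "ct")
  stopifnot(is.data.frame(ct_table), all(need %in% names(ct_table)))
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("CT values must be finite and > 0", call. = FALSE)
  reps <- sort(unique(ct_table$replicate))
  rows <- lapply(reps, function(r) {
    sub <- ct_table[ct_table$replicate == r, ]
    dct <- function(cond) {
      ins <- sub$ct[sub$condition == cond & sub$primer_set == "inside"]
      out <- sub$ct[sub$condition == cond & sub$primer_set == "outside"]
      if (!length(ins) || !length(out))
        stop(sprintf("replicate %s lacks %s inside/outside CTs", r, cond),
             call. = FALSE)
      delta_ct(ins, out)
    }
    fe <- fold_enrichment(dct("induced"), dct("uninduced"), efficiency)
    data.frame(replicate = r, dct_induced = fe$dct_induced,
               dct_uninduced = fe$dct_uninduced, ddct = fe$ddct,
               fold = fe$fold)
  })
  per <- do.call(rbind, rows)
  list(per_replicate = per, fold_mean = mean(per$fold),
       fold_sd = stats::sd(per$fold))
}
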