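# I/O at the package boundary: FASTA, Vienna-style structure text, the CSV
# schemas the analyses consume, and JSON reports.

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return list of `dna_sequence` objects.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i)
    dna_sequence(as.character(set[[i]]), id = names(set)[i]))
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs a `dna_sequence` or list of them (plain strings accepted).
#' @param path output path.
#' @export
write_dna_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_sequence")) seqs <- list(seqs)
  seqs <- lapply(seqs, as_dna_sequence)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Vienna-style structure file
#'
#' Plain-text dialect: an optional `>id` header, then the sequence line and
#' the dot-bracket line (an appended free-energy field after whitespace is
#' ignored).
#'
#' @param path file path.
#' @return a `fold_result` (score is the field after the dot-bracket if
#'   parseable, else `NA`).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  id <- "seq"
  if (startsWith(lines[1], ">")) {
    id <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2L)
    stop("Vienna file needs a sequence line and a structure line",
         call. = FALSE)
  seq <- dna_sequence(trimws(lines[1]), id = id)
  toks <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  db <- toks[1]
  score <- if (length(toks) > 1L)
    suppressWarnings(as.numeric(gsub("[()]", "", toks[2]))) else NA_real_
  if (nchar(db) != nchar(seq$residues))
    stop("structure length differs from sequence length", call. = FALSE)
  structure(list(sequence = seq, pairs = parse_dotbracket(db),
                 dotbracket = db, score = score, engine = "file"),
            class = "fold_result")
}

#' Write a fold as Vienna-style structure text
#'
#' @param fold a `fold_result`.
#' @param path output path.
#' @export
write_vienna <- function(fold, path) {
  stopifnot(inherits(fold, "fold_result"))
  writeLines(c(paste0(">", fold$sequence$id), fold$sequence$residues,
               sprintf("%s (%g)", fold$dotbracket, fold$score)), path)
  invisible(path)
}

read_schema_csv <- function(path, need) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("%s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read a qPCR CT table (sample,condition,primer_set,replicate,ct)
#' @param path CSV path.
#' @return data.frame for [analyze_qpcr()].
#' @export
read_ct_table <- function(path)
  read_schema_csv(path, c("sample", "condition", "primer_set", "replicate",
                          "ct"))

#' Read a titration table (construct,bt_nominal_uM,at_uM,fluorescence)
#' @param path CSV path.
#' @return data.frame for [fit_global()].
#' @export
read_titration_table <- function(path)
  read_schema_csv(path, c("construct", "bt_nominal_uM", "at_uM",
                          "fluorescence"))

#' Read a growth curve (time_min,od600)
#' @param path CSV path.
#' @return data.frame for [fit_logistic()].
#' @export
read_growth_curve <- function(path)
  read_schema_csv(path, c("time_min", "od600"))

#' Read a decay series (time_min,fold_change)
#' @param path CSV path.
#' @return data.frame for [fit_decay()].
#' @export
read_decay_series <- function(path)
  read_schema_csv(path, c("time_min", "fold_change"))

#' Read a gel lane table (label,intensity,length_nt)
#' @param path CSV path.
#' @return data.frame for [length_corrected_fold()].
#' @export
read_gel_table <- function(path)
  read_schema_csv(path, c("label", "intensity", "length_nt"))

#' Write an insertion-design report as JSON
#'
#' @param scaffold_fold the scaffold `fold_result`.
#' @param sites the `insertion_sites` table.
#' @param fusions optional list of `fusion_construct`s with an optional
#'   `preservation` attribute each.
#' @param path output JSON path.
#' @export
write_design_report <- function(scaffold_fold, sites, fusions = NULL,
                                path) {
  rep <- list(
    scaffold = list(id = scaffold_fold$sequence$id,
                    residues = scaffold_fold$sequence$residues,
                    dotbracket = scaffold_fold$dotbracket,
                    score = scaffold_fold$score,
                    engine = scaffold_fold$engine),
    sites = sites)
  if (!is.null(fusions)) {
    rep$fusions <- lapply(fusions, function(fu) {
      out <- list(scaffold_id = fu$scaffold_id, cargo_id = fu$cargo_id,
                  position = fu$position, residues = fu$residues)
      if (!is.null(attr(fu, "preservation")))
        out$fold_preservation <- attr(fu, "preservation")
      out
    })
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
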