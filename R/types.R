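# Domain types. Lightweight S3: constructors validate invariants once, the
# rest of the package trusts the objects. All residue positions are 1-based
# and inclusive; all retention times are minutes.

#' Construct an MS/MS spectrum
#'
#' @param spectrum_id Character scalar key.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer precursor charge, >= 1.
#' @param observed_rt Observed retention time in minutes (RTe), >= 0.
#' @param peaks Two-column numeric matrix (mz, intensity). Re-sorted
#'   ascending by mz; negative intensities are rejected.
#' @return Object of class `phos_spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                     observed_rt, peaks) {
  stopifnot(is.character(spectrum_id), length(spectrum_id) == 1L)
  if (!is.matrix(peaks) || ncol(peaks) != 2L)
    stop("peaks must be a two-column (mz, intensity) matrix")
  if (nrow(peaks) > 0 && any(peaks[, 2] < 0))
    stop("spectrum '", spectrum_id, "': negative peak intensity")
  if (any(!is.finite(peaks)))
    stop("spectrum '", spectrum_id, "': non-finite peak values")
  if (is.na(observed_rt) || observed_rt < 0)
    stop("spectrum '", spectrum_id, "': observed_rt must be >= 0 minutes")
  if (precursor_charge < 1)
    stop("spectrum '", spectrum_id, "': precursor_charge must be >= 1")
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  structure(
    list(spectrum_id = spectrum_id,
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = as.integer(precursor_charge),
         observed_rt = as.numeric(observed_rt),
         peaks = peaks),
    class = "phos_spectrum"
  )
}

#' Construct a peptide-spectrum match record
#'
#' @param spectrum_id Spectrum key the match refers to.
#' @param peptide Uppercase amino-acid string.
#' @param fixed_mods,variable_mods Data frames with columns `position`
#'   (1-based within the peptide; 0 denotes the N terminus), `mass_delta`
#'   (Da) and `name`. Phospho mods must sit on S/T/Y.
#' @param charge Assumed precursor charge of the match.
#' @param engine_scores Named numeric vector of search-engine scores.
#' @param is_decoy Logical decoy flag.
#' @param protein_ids Character vector of protein accessions.
#' @param quantity Optional named numeric vector of per-channel quantities.
#' @return Object of class `phos_psm`.
#' @export
psm_record <- function(spectrum_id, peptide,
                       fixed_mods = empty_mods(), variable_mods = empty_mods(),
                       charge = 2L, engine_scores = c(score = 0),
                       is_decoy = FALSE, protein_ids = character(),
                       quantity = NULL) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (!grepl("^[A-Z]+$", peptide))
    stop("peptide must be an uppercase amino-acid string: ", peptide)
  n <- nchar(peptide)
  for (mods in list(fixed_mods, variable_mods)) {
    if (nrow(mods) == 0) next
    if (any(mods$position < 0 | mods$position > n))
      stop("modification position outside 1..", n, " for peptide ", peptide)
    ph <- mods$name == "Phospho"
    if (any(ph)) {
      res <- substring(peptide, mods$position[ph], mods$position[ph])
      if (!all(res %in% STY))
        stop("phospho modification on non-S/T/Y residue in peptide ", peptide)
    }
  }
  structure(
    list(spectrum_id = spectrum_id, peptide = peptide,
         fixed_mods = fixed_mods, variable_mods = variable_mods,
         charge = as.integer(charge), engine_scores = engine_scores,
         is_decoy = isTRUE(is_decoy), protein_ids = protein_ids,
         quantity = quantity),
    class = "phos_psm"
  )
}

#' Empty modification table
#'
#' @return Zero-row data frame with columns `position`, `mass_delta`, `name`.
#' @export
empty_mods <- function() {
  data.frame(position = integer(), mass_delta = numeric(),
             name = character(), stringsAsFactors = FALSE)
}

#' Modification table constructor
#'
#' @param position 1-based positions within the peptide (0 = N terminus).
#' @param mass_delta Mass deltas in Da.
#' @param name Modification names.
#' @return Data frame usable as `fixed_mods`/`variable_mods`.
#' @export
mods_table <- function(position, mass_delta, name) {
  data.frame(position = as.integer(position),
             mass_delta = as.numeric(mass_delta),
             name = as.character(name), stringsAsFactors = FALSE)
}

#' Number of phospho groups on a PSM
#' @param psm A `phos_psm`.
#' @return Integer count of phospho modifications.
#' @export
phospho_count <- function(psm) {
  sum(psm$fixed_mods$name == "Phospho") +
    sum(psm$variable_mods$name == "Phospho")
}

#' Phospho positions reported by the search engine for a PSM
#' @param psm A `phos_psm`.
#' @return Sorted integer vector of 1-based positions.
#' @export
reported_phospho_positions <- function(psm) {
  sort(c(psm$fixed_mods$position[psm$fixed_mods$name == "Phospho"],
         psm$variable_mods$position[psm$variable_mods$name == "Phospho"]))
}

#' Non-phospho modifications of a PSM
#' @param psm A `phos_psm`.
#' @return Modification table of everything except phospho.
#' @export
other_mods <- function(psm) {
  all <- rbind(psm$fixed_mods, psm$variable_mods)
  all[all$name != "Phospho", , drop = FALSE]
}

#' Construct a phosphopeptide positional isoform
#'
#' A peptide sequence with one specific placement of its phospho groups;
#' the unit of site-localization scoring.
#'
#' @param peptide Uppercase amino-acid string.
#' @param phospho_positions 1-based positions of the phospho groups; must
#'   all be S/T/Y residues.
#' @param other_mods Modification table for non-phospho mods.
#' @return Object of class `phos_isoform`.
#' @export
phospho_isoform <- function(peptide, phospho_positions,
                            other_mods = empty_mods()) {
  phospho_positions <- sort(as.integer(phospho_positions))
  if (length(phospho_positions)) {
    res <- substring(peptide, phospho_positions, phospho_positions)
    if (!all(res %in% STY))
      stop("phospho positions must be S/T/Y residues (peptide ", peptide, ")")
  }
  structure(
    list(peptide = peptide, phospho_positions = phospho_positions,
         other_mods = other_mods),
    class = "phos_isoform"
  )
}

#' Canonical key of an isoform's site placement
#' @param isoform A `phos_isoform` (or integer positions).
#' @return Character key such as `"3;7"` (`""` when unmodified).
#' @export
position_key <- function(isoform) {
  pos <- if (inherits(isoform, "phos_isoform")) isoform$phospho_positions
         else sort(as.integer(isoform))
  paste(pos, collapse = ";")
}

# Prediction lookup key: empty-string names never match in R list
# indexing, so unmodified peptides use a sentinel.
pred_key <- function(key) if (nzchar(key)) key else ".unmod"

#' Modified-sequence string of an isoform
#'
#' Phospho placements rendered inline, e.g. `"AAS[ph]TK"`; used as the
#' collapse key in site-level quantification and as the peptide-level key
#' in rescoring.
#'
#' @param peptide Peptide string.
#' @param phospho_positions 1-based phospho positions.
#' @return Character scalar.
#' @export
modified_sequence <- function(peptide, phospho_positions) {
  if (!length(phospho_positions)) return(peptide)
  aa <- strsplit(peptide, "")[[1]]
  aa[phospho_positions] <- paste0(aa[phospho_positions], "[ph]")
  paste(aa, collapse = "")
}

#' Construct a predictor output record
#'
#' One record per isoform from an RT/fragment-intensity predictor (or the
#' bundled mock predictor).
#'
#' @param isoform A `phos_isoform`.
#' @param predicted_rt Predicted retention time in minutes (RTp).
#' @param predicted_peaks Named numeric vector of relative intensities in
#'   \[0,1\], keyed by ion label (see [ion_label()]).
#' @return Object of class `phos_prediction`.
#' @export
prediction_record <- function(isoform, predicted_rt, predicted_peaks) {
  if (any(predicted_peaks < 0 | predicted_peaks > 1))
    stop("predicted intensities must lie in [0,1]")
  if (!any(predicted_peaks > 0))
    stop("prediction must contain at least one nonzero peak")
  structure(
    list(isoform = isoform, predicted_rt = as.numeric(predicted_rt),
         predicted_peaks = predicted_peaks),
    class = "phos_prediction"
  )
}

#' Ground-truth phosphopeptide library
#'
#' @param peptide Character vector of peptide sequences.
#' @param phospho_positions List of integer vectors (parallel to `peptide`).
#' @return Object of class `phos_library`: a data frame with a canonical
#'   `key` column (`peptide|positions`), unique entries.
#' @export
ground_truth_library <- function(peptide, phospho_positions) {
  key <- paste0(peptide, "|", vapply(phospho_positions, position_key, ""))
  df <- data.frame(peptide = peptide,
                   positions = vapply(phospho_positions, position_key, ""),
                   key = key, stringsAsFactors = FALSE)
  df <- df[!duplicated(df$key), , drop = FALSE]
  structure(df, class = c("phos_library", "data.frame"))
}

#' @export
print.phos_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s: %d peaks, precursor %.4f Th z=%d, RT %.2f min>\n",
              x$spectrum_id, nrow(x$peaks), x$precursor_mz,
              x$precursor_charge, x$observed_rt))
  invisible(x)
}

#' @export
print.phos_isoform <- function(x, ...) {
  cat(sprintf("<isoform %s>\n",
              modified_sequence(x$peptide, x$phospho_positions)))
  invisible(x)
}
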