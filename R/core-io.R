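# Readers/writers for the standard formats the pipeline touches: MGF in,
# PSM tables in (generic TSV dialect + MaxQuant msms.txt subset), Percolator
# PIN out, FASTA in (via Biostrings).

#' Read an MGF file
#'
#' Parses the MGF dialect with TITLE, PEPMASS, CHARGE and RTINSECONDS
#' headers. RTINSECONDS is converted to minutes (the package-wide RT unit);
#' peaks are returned sorted ascending by m/z.
#'
#' @param path Path to an MGF file.
#' @return List of [spectrum()] objects, one per BEGIN IONS block.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS blocks")
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    kv <- regmatches(headers, regexpr("=", headers), invert = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    named <- stats::setNames(vals, keys)
    if (!"TITLE" %in% keys) stop("MGF block ", b, ": missing TITLE")
    if (!"PEPMASS" %in% keys) stop("MGF block ", b, ": missing PEPMASS")
    if (!"RTINSECONDS" %in% keys)
      stop("MGF block ", b, ": missing RTINSECONDS (RT is required)")
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", named[["CHARGE"]]))
    } else 2L
    peak_lines <- block[!is_header]
    peaks <- if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      m <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
      if (any(is.na(m))) stop("MGF block ", b, ": unparseable peak line")
      m
    } else matrix(numeric(0), ncol = 2)
    out[[b]] <- spectrum(
      spectrum_id = named[["TITLE"]],
      precursor_mz = as.numeric(strsplit(named[["PEPMASS"]], "[ \t]+")[[1]][1]),
      precursor_charge = charge,
      observed_rt = as.numeric(named[["RTINSECONDS"]]) / 60,
      peaks = peaks
    )
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @param header Optional comment lines written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$precursor_charge),
      sprintf("RTINSECONDS=%.4f", sp$observed_rt * 60),
      sprintf("%.5f %.4f", sp$peaks[, 1], sp$peaks[, 2]),
      "END IONS"
    ), con)
  }
  invisible(path)
}

# Parse a "pos:mass:Name;pos:mass:Name" modification string.
parse_mod_string <- function(s, peptide) {
  if (is.na(s) || !nzchar(s)) return(empty_mods())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, ":", fixed = TRUE)
  pos <- as.integer(vapply(fields, `[`, "", 1L))
  mass <- as.numeric(vapply(fields, `[`, "", 2L))
  name <- vapply(fields, `[`, "", 3L)
  known <- name %in% names(MOD_MASSES)
  if (!all(known))
    stop("unknown modification name(s): ",
         paste(unique(name[!known]), collapse = ", "))
  if (any(pos < 0 | pos > nchar(peptide)))
    stop("modification position off peptide ", peptide)
  mods_table(pos, mass, name)
}

#' Read a PSM table
#'
#' Two dialects are supported. `generic_tsv` expects columns
#' `spectrum_id`, `peptide`, `modifications` (semicolon-separated
#' `pos:mass:Name` entries), `charge`, `score`, `proteins`
#' (semicolon-separated accessions) and optionally `delta_score` and any
#' number of `quant_*` columns. `maxquant_msms` reads a subset of MaxQuant's
#' msms.txt: `Scan number`/`id`, `Modified sequence` (e.g. `_AAS(ph)TK_`),
#' `Charge`, `Score`, `Delta score`, `Proteins`, `Reverse`.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"generic_tsv"` or `"maxquant_msms"`.
#' @param decoy_prefix Protein-accession prefix marking decoys
#'   (default `"REV_"`).
#' @return List of [psm_record()] objects.
#' @export
read_psm_table <- function(path, dialect = c("generic_tsv", "maxquant_msms"),
                           decoy_prefix = "REV_") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("PSM table ", path, " contains no rows")
    return(list())
  }
  if (dialect == "generic_tsv") read_generic_psms(df, decoy_prefix)
  else read_maxquant_psms(df, decoy_prefix)
}

read_generic_psms <- function(df, decoy_prefix) {
  needed <- c("spectrum_id", "peptide", "modifications", "charge",
              "score", "proteins")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("generic PSM table lacks column(s): ", paste(miss, collapse = ", "))
  quant_cols <- grep("^quant_", names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    prot <- strsplit(df$proteins[i], ";", fixed = TRUE)[[1]]
    scores <- c(score = df$score[i])
    if ("delta_score" %in% names(df))
      scores <- c(scores, delta_score = df$delta_score[i])
    quant <- if (length(quant_cols)) {
      stats::setNames(as.numeric(df[i, quant_cols]),
                      sub("^quant_", "", quant_cols))
    } else NULL
    psm_record(
      spectrum_id = as.character(df$spectrum_id[i]),
      peptide = df$peptide[i],
      variable_mods = parse_mod_string(df$modifications[i], df$peptide[i]),
      charge = df$charge[i],
      engine_scores = scores,
      is_decoy = all(startsWith(prot, decoy_prefix)),
      protein_ids = prot,
      quantity = quant
    )
  })
}

# MaxQuant lowercase mod codes -> canonical names.
MAXQUANT_MOD_CODES <- c(ph = "Phospho", ox = "Oxidation",
                        ca = "Carbamidomethyl", cam = "Carbamidomethyl")

parse_maxquant_modseq <- function(modseq) {
  s <- gsub("^_|_$", "", modseq)
  aa <- character(); pos <- integer(); name <- character()
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(s, i, n), fixed = TRUE)
      code <- substr(s, i + 1L, i + j - 2L)
      if (!code %in% names(MAXQUANT_MOD_CODES))
        stop("unknown modification name(s): ", code)
      cname <- MAXQUANT_MOD_CODES[[code]]
      pos <- c(pos, length(aa))
      name <- c(name, cname)
      i <- i + j
    } else {
      aa <- c(aa, ch)
      i <- i + 1L
    }
  }
  list(peptide = paste(aa, collapse = ""),
       mods = mods_table(pos, unname(MOD_MASSES[name]), name))
}

read_maxquant_psms <- function(df, decoy_prefix) {
  if (!"Modified sequence" %in% names(df))
    stop("maxquant_msms table lacks column: Modified sequence")
  id_col <- if ("Scan number" %in% names(df)) "Scan number" else "id"
  lapply(seq_len(nrow(df)), function(i) {
    parsed <- parse_maxquant_modseq(df[["Modified sequence"]][i])
    prot <- strsplit(as.character(df$Proteins[i] %||% ""), ";")[[1]]
    is_rev <- identical(as.character(df$Reverse[i] %||% ""), "+") ||
      (length(prot) > 0 && all(startsWith(prot, decoy_prefix)))
    scores <- c(score = as.numeric(df$Score[i] %||% 0))
    if ("Delta score" %in% names(df))
      scores <- c(scores, delta_score = as.numeric(df[["Delta score"]][i]))
    psm_record(
      spectrum_id = as.character(df[[id_col]][i]),
      peptide = parsed$peptide,
      variable_mods = parsed$mods,
      charge = as.integer(df$Charge[i] %||% 2L),
      engine_scores = scores,
      is_decoy = is_rev,
      protein_ids = prot
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Percolator PIN file
#'
#' @param feature_table Data frame as produced by [assemble_feature_table()]:
#'   must contain `spectrum_id`, `is_decoy`, `peptide`, `proteins` and the
#'   feature columns named in `features`.
#' @param path Output path.
#' @param features Character vector naming the feature columns, in the
#'   (deterministic) order they should be written.
#' @return `path`, invisibly.
#' @export
write_pin <- function(feature_table, path, features = NULL) {
  if (is.null(features))
    features <- setdiff(names(feature_table),
                        c("spectrum_id", "is_decoy", "peptide", "proteins",
                          "positions", "modified_sequence"))
  features <- sort(features)
  for (f in features) {
    if (!f %in% names(feature_table))
      stop("missing feature column: ", f)
    bad <- which(!is.finite(feature_table[[f]]))
    if (length(bad))
      stop("PSM ", feature_table$spectrum_id[bad[1]],
           " lacks a finite value for feature ", f)
  }
  out <- data.frame(
    SpecId = feature_table$spectrum_id,
    Label = ifelse(feature_table$is_decoy, -1L, 1L),
    ScanNr = seq_len(nrow(feature_table)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (f in features) out[[f]] <- feature_table[[f]]
  out$Peptide <- feature_table$peptide
  out$Proteins <- feature_table$proteins %||%
    rep("unknown", nrow(feature_table))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write a protein FASTA
#'
#' @param seqs Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
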