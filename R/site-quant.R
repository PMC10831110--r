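# Phosphosite-level quantification: collapse PSMs to unique modified
# sequences (summing quantities, keeping the best score), expand to one
# record per phospho position, derive 15-mer flanking identifiers on each
# matching protein, sum within (protein, 15-mer) groups, then log2 +
# median normalization. Missing measurements are encoded as NA, distinct
# from zero.

quant_cols <- function(df) grep("^quant_", names(df), value = TRUE)

#' Collapse PSMs to unique modified sequences
#'
#' Different scans with the same modified sequence (peptide + full site
#' placement) merge into one record: quantities are summed per sample and
#' the best search score is kept.
#'
#' @param psm_table Data frame with `modified_sequence`, `peptide`,
#'   `positions`, a score column (`discriminant` or `engine_score`) and
#'   `quant_*` columns.
#' @return Data frame unique on `modified_sequence`.
#' @export
collapse_modified_sequences <- function(psm_table) {
  score_col <- if ("discriminant" %in% names(psm_table)) "discriminant"
               else "engine_score"
  qc <- quant_cols(psm_table)
  rows <- lapply(split(psm_table, psm_table$modified_sequence), function(g) {
    out <- g[which.max(g[[score_col]]), c("modified_sequence", "peptide",
                                          "positions", score_col)]
    names(out)[4] <- "best_score"
    for (s in qc) out[[s]] <- {
      v <- g[[s]]
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand a collapsed table to one record per phospho position
#'
#' A doubly phosphorylated modified sequence becomes two records, one per
#' position, each carrying the full quantity vector.
#'
#' @param collapsed Output of [collapse_modified_sequences()].
#' @return Data frame with a `site_in_peptide` column.
#' @export
expand_per_site <- function(collapsed) {
  rows <- lapply(seq_len(nrow(collapsed)), function(i) {
    pos <- as.integer(strsplit(collapsed$positions[i], ";")[[1]])
    if (!length(pos))
      stop("record without phospho position: ",
           collapsed$modified_sequence[i])
    out <- collapsed[rep(i, length(pos)), , drop = FALSE]
    out$site_in_peptide <- pos
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 15-mer flanking site identifier
#'
#' The site residue with 7 flanking residues on each side, '-'-padded
#' beyond the protein termini.
#'
#' @param protein_seq Protein sequence string.
#' @param site_position 1-based position of an S/T/Y residue.
#' @return 15-character identifier with the site residue at the center.
#' @export
flanking_15mer <- function(protein_seq, site_position) {
  res <- substr(protein_seq, site_position, site_position)
  if (!res %in% STY)
    stop("site residue at position ", site_position, " is ", res,
         ", not S/T/Y")
  n <- nchar(protein_seq)
  lo <- site_position - 7L
  hi <- site_position + 7L
  core <- substr(protein_seq, max(1L, lo), min(n, hi))
  paste0(strrep("-", max(0L, 1L - lo)), core, strrep("-", max(0L, hi - n)))
}

#' Sum per-site records into a site-level quantification table
#'
#' Peptides are mapped to proteins by exact substring search of the FASTA
#' (Leu/Ile not conflated); a peptide matching several proteins contributes
#' to each independently. Quantities are summed within each (protein,
#' 15-mer) group. Unmapped peptides are excluded and reported via the
#' `"unmapped"` attribute.
#'
#' @param per_site Output of [expand_per_site()].
#' @param proteome Named character vector of protein sequences (see
#'   [read_protein_fasta()]).
#' @return Data frame with `protein_id`, `site_position`, `residue`,
#'   `flanking_15mer`, `best_score` and `quant_*` columns; attribute
#'   `"unmapped"` lists peptides not found in any protein.
#' @export
sum_by_15mer <- function(per_site, proteome) {
  qc <- quant_cols(per_site)
  peptides <- unique(per_site$peptide)
  hits <- lapply(peptides, function(pep) {
    m <- lapply(proteome, function(s) {
      starts <- integer(0)
      from <- 1L
      repeat {
        p <- regexpr(pep, substr(s, from, nchar(s)), fixed = TRUE)
        if (p == -1L) break
        starts <- c(starts, from + p - 1L)
        from <- from + p
      }
      starts
    })
    m[lengths(m) > 0]
  })
  names(hits) <- peptides
  unmapped <- peptides[lengths(hits) == 0]
  rows <- list()
  for (i in seq_len(nrow(per_site))) {
    pep <- per_site$peptide[i]
    h <- hits[[pep]]
    if (!length(h)) next
    for (prot in names(h)) {
      for (start in h[[prot]]) {
        sp <- start + per_site$site_in_peptide[i] - 1L
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(protein_id = prot, site_position = sp,
                     residue = substr(proteome[[prot]], sp, sp),
                     flanking_15mer = flanking_15mer(proteome[[prot]], sp),
                     best_score = per_site$best_score[i],
                     stringsAsFactors = FALSE),
          per_site[i, qc, drop = FALSE])
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(protein_id = character(), site_position = integer(),
                      residue = character(), flanking_15mer = character(),
                      best_score = numeric())
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  long <- do.call(rbind, rows)
  grp <- paste0(long$protein_id, "|", long$flanking_15mer, "|",
                long$site_position)
  agg <- lapply(split(long, grp), function(g) {
    out <- g[1, c("protein_id", "site_position", "residue",
                  "flanking_15mer"), drop = FALSE]
    out$best_score <- max(g$best_score)
    for (s in qc) out[[s]] <- {
      v <- g[[s]]
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$protein_id, out$site_position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Log2-transform and median-normalize site quantities
#'
#' Zeros become missing (NA); each sample column is log2-transformed and
#' its median (over non-missing values) subtracted.
#'
#' @param site_table Output of [sum_by_15mer()].
#' @return The table with transformed `quant_*` columns.
#' @export
normalize_site_table <- function(site_table) {
  for (s in quant_cols(site_table)) {
    v <- site_table[[s]]
    v[!is.na(v) & v <= 0] <- NA
    if (all(is.na(v)))
      stop("sample ", sub("^quant_", "", s), " has no quantified sites")
    lv <- log2(v)
    site_table[[s]] <- lv - stats::median(lv, na.rm = TRUE)
  }
  site_table
}

#' Filter sites by per-group quantification coverage
#'
#' @param site_table Site-level table with `quant_*` columns.
#' @param sample_groups Named character vector mapping sample name (the
#'   part after `quant_`) to group label.
#' @param min_per_group Minimum non-missing measurements required in every
#'   group (default 0 = keep all).
#' @return Filtered table.
#' @export
quantifiability_filter <- function(site_table, sample_groups,
                                   min_per_group = 0L) {
  qc <- quant_cols(site_table)
  samples <- sub("^quant_", "", qc)
  unknown <- setdiff(samples, names(sample_groups))
  if (length(unknown))
    stop("sample(s) missing from group map: ", paste(unknown, collapse = ", "))
  if (min_per_group <= 0) return(site_table)
  groups <- unique(sample_groups[samples])
  keep <- vapply(seq_len(nrow(site_table)), function(i) {
    all(vapply(groups, function(g) {
      cols <- qc[sample_groups[samples] == g]
      sum(!is.na(as.numeric(site_table[i, cols]))) >= min_per_group
    }, logical(1)))
  }, logical(1))
  site_table[keep, , drop = FALSE]
}
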