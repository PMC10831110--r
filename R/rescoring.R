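# Feature assembly, semi-supervised linear-SVM rescoring in the Percolator
# style (cross-validated, positives re-selected each iteration at 1% FDR,
# decoys as negatives), and target-decoy q-values at PSM and peptide level.

# Feature columns fed to the SVM, in deterministic order. DL features are
# appended when use_dl_features = TRUE.
BASE_FEATURES <- c("engine_score", "delta_score", "peptide_length",
                   "mass_error_ppm", "charge2", "charge3", "charge4plus",
                   "missed_cleavages", "frac_matched", "log_matched_intensity")
DL_FEATURES <- c("ss", "rtr")

#' Number of missed tryptic cleavages in a peptide
#' @param peptide Peptide string.
#' @return Integer count of internal K/R not followed by P.
#' @export
missed_cleavages <- function(peptide) {
  n <- nchar(peptide)
  if (n < 2) return(0L)
  aa <- strsplit(peptide, "")[[1]]
  sum(aa[1:(n - 1)] %in% c("K", "R") & aa[2:n] != "P")
}

#' Assemble the rescoring feature vector for one PSM
#'
#' Combines search-engine features (primary score, delta to second best),
#' engine-independent features (peptide length, precursor mass error in
#' ppm, charge one-hot, missed cleavages, fraction of theoretical ions
#' matched, log total matched intensity) and the deep-learning-derived
#' features (spectrum similarity and RTR of the chosen isoform).
#'
#' @param loc A `phos_localization` from [localize()].
#' @param psm The matching [psm_record()].
#' @param spec The matching [spectrum()].
#' @param tol_da Fragment matching tolerance in Da.
#' @return One-row data frame with identifier columns (`spectrum_id`,
#'   `peptide`, `positions`, `modified_sequence`, `is_decoy`, `proteins`,
#'   `observed_rt`, `min_site_probability`, `matched_ions`, quantity
#'   columns when present) and all feature columns.
#' @export
assemble_features <- function(loc, psm, spec, tol_da = 0.02) {
  row <- loc$table[loc$chosen, , drop = FALSE]
  iso <- phospho_isoform(psm$peptide,
                         as.integer(strsplit(row$positions, ";")[[1]]),
                         other_mods(psm))
  frags <- theoretical_fragments(iso, psm$charge)
  pair <- align_peaks(frags, stats::setNames(numeric(0), character(0)),
                      spec, tol_da)
  theo_mz <- isoform_mz(iso, psm$charge)
  z <- psm$charge
  matched <- pair$Ie > 0
  feats <- data.frame(
    spectrum_id = psm$spectrum_id,
    peptide = psm$peptide,
    positions = row$positions,
    modified_sequence = modified_sequence(psm$peptide,
                                          iso$phospho_positions),
    is_decoy = psm$is_decoy,
    proteins = paste(psm$protein_ids, collapse = ";"),
    observed_rt = spec$observed_rt,
    min_site_probability = localization_summary(loc)$min_site_probability,
    matched_ions = paste(sprintf("%s:%.4f", pair$ion_labels[matched],
                                 pair$Ie[matched]), collapse = ";"),
    engine_score = unname(psm$engine_scores["score"]),
    delta_score = unname(psm$engine_scores["delta_score"] %||NA% 0),
    peptide_length = nchar(psm$peptide),
    mass_error_ppm = (spec$precursor_mz - theo_mz) / theo_mz * 1e6,
    charge2 = as.numeric(z == 2L),
    charge3 = as.numeric(z == 3L),
    charge4plus = as.numeric(z >= 4L),
    missed_cleavages = missed_cleavages(psm$peptide),
    frac_matched = mean(matched),
    log_matched_intensity = log1p(sum(pair$Ie)),
    ss = row$ss,
    rtr = row$rtr,
    stringsAsFactors = FALSE
  )
  if (!is.null(psm$quantity))
    for (s in names(psm$quantity))
      feats[[paste0("quant_", s)]] <- unname(psm$quantity[s])
  bad <- vapply(feats[c(BASE_FEATURES, DL_FEATURES)],
                function(x) !is.finite(x), logical(1))
  if (any(bad))
    stop("non-finite feature(s) for PSM ", psm$spectrum_id, ": ",
         paste(names(bad)[bad], collapse = ", "))
  feats
}

# value if not NA else default; engine tables may lack delta scores
`%||NA%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Assemble the feature table for a set of PSMs
#'
#' @param locs List of `phos_localization` results (parallel to `psms`).
#' @param psms List of [psm_record()]s.
#' @param spectra Named list of [spectrum()]s keyed by spectrum id.
#' @param tol_da Fragment matching tolerance in Da.
#' @return Data frame, one row per PSM (see [assemble_features()]).
#' @export
assemble_feature_table <- function(locs, psms, spectra, tol_da = 0.02) {
  rows <- mapply(function(loc, psm) {
    assemble_features(loc, psm, spectra[[psm$spectrum_id]], tol_da)
  }, locs, psms, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Target-decoy q-values for a ranked list
#'
#' FDR at rank r is #decoys(<=r) / #targets(<=r) (0 until the first
#' target); the q-value is the cumulative minimum from the bottom of the
#' list.
#'
#' @param is_decoy Logical vector in descending-score order.
#' @return Numeric q-values, parallel to the input.
#' @export
q_values <- function(is_decoy) {
  if (!length(is_decoy)) return(numeric(0))
  cum_d <- cumsum(is_decoy)
  cum_t <- cumsum(!is_decoy)
  fdr <- pmin(1, ifelse(cum_t == 0, 0, cum_d / cum_t))
  rev(cummin(rev(fdr)))
}

# Attach q-values to a table by descending score_col (ties broken by
# spectrum_id for determinism).
add_q_values <- function(df, score_col, q_col = "q_value") {
  ord <- order(-df[[score_col]], df$spectrum_id)
  q <- q_values(df$is_decoy[ord])
  df[[q_col]] <- NA_real_
  df[[q_col]][ord] <- q
  df
}

fit_linear_svm <- function(x, y) {
  # y: logical, TRUE = target
  fit <- e1071::svm(x = x, y = factor(ifelse(y, "target", "decoy"),
                                      levels = c("decoy", "target")),
                    kernel = "linear", cost = 1, scale = FALSE)
  fit
}

svm_decision <- function(fit, x, y_train, x_train) {
  d <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                       "decision.values"))
  # orient so targets score high
  d_train <- as.numeric(attr(stats::predict(fit, x_train,
                                            decision.values = TRUE),
                             "decision.values"))
  if (mean(d_train[y_train]) < mean(d_train[!y_train])) d <- -d
  d
}

#' Semi-supervised SVM rescoring (Percolator scheme)
#'
#' Cross-validated rescoring: within each training split, positives are the
#' targets passing 1% FDR under the current score (initially the search
#' engine score) and negatives are all decoys; a linear SVM (C = 1) is
#' refit `iterations` times with positives re-selected each round, and the
#' discriminant is computed for the held-out fold. Features are z-scored
#' over the dataset before fitting. Per-fold discriminants are standardized
#' against the fold's decoy distribution so folds are comparable.
#'
#' @param feature_table Data frame from [assemble_feature_table()].
#' @param folds Number of cross-validation folds (default 3).
#' @param iterations Positive-reselection rounds (default 10).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param use_dl_features Include the deep-learning features `ss`/`rtr`
#'   (default TRUE).
#' @param train_fdr FDR threshold for positive selection (default 0.01).
#' @return The feature table with columns `discriminant` and `q_value`
#'   added, sorted by descending discriminant.
#' @export
semi_supervised_rescore <- function(feature_table, folds = 3L,
                                    iterations = 10L, seed = 20230101L,
                                    use_dl_features = TRUE,
                                    train_fdr = 0.01) {
  df <- feature_table
  if (!any(df$is_decoy)) stop("no decoys: target-decoy rescoring undefined")
  if (!any(!df$is_decoy)) stop("no targets to rescore")
  if (folds < 2) stop("folds must be >= 2")
  feats <- c(BASE_FEATURES, if (use_dl_features) DL_FEATURES)
  x <- as.matrix(df[, feats])
  # z-score per dataset; constant columns stay 0
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(df)))
  disc <- numeric(nrow(df))
  target <- !df$is_decoy
  # Percolator-style initial direction: the single (z-scored) feature and
  # sign yielding the most targets at the training FDR.
  targets_at_fdr <- function(score, y) {
    ord <- order(-score)
    sum(q_values(!y[ord]) <= train_fdr & y[ord])
  }
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    y_tr <- target[tr]
    x_tr <- x[tr, , drop = FALSE]
    cand <- c(lapply(seq_len(ncol(x_tr)), function(j) x_tr[, j]),
              lapply(seq_len(ncol(x_tr)), function(j) -x_tr[, j]))
    n_pass <- vapply(cand, targets_at_fdr, numeric(1), y = y_tr)
    score <- cand[[which.max(n_pass)]]
    fit <- NULL
    for (it in seq_len(iterations)) {
      ord <- order(-score)
      q <- q_values(!y_tr[ord])
      pos_ranked <- ord[q <= train_fdr & y_tr[ord]]
      if (length(pos_ranked) < 2) {
        # degenerate training round: fall back to the top-ranked targets
        tgt_ranked <- ord[y_tr[ord]]
        pos_ranked <- tgt_ranked[seq_len(min(length(tgt_ranked),
                                             max(2L, length(tgt_ranked) %/%
                                                   10L)))]
      }
      if (length(pos_ranked) < 2) break
      sel <- c(pos_ranked, which(!y_tr))
      fit <- fit_linear_svm(x[tr, , drop = FALSE][sel, , drop = FALSE],
                            y_tr[sel])
      score <- svm_decision(fit, x[tr, , drop = FALSE], y_tr[sel],
                            x[tr, , drop = FALSE][sel, , drop = FALSE])
    }
    if (is.null(fit)) {
      disc[te] <- df$engine_score[te]
    } else {
      d_te <- svm_decision(fit, x[te, , drop = FALSE], y_tr,
                           x[tr, , drop = FALSE])
      d_tr <- svm_decision(fit, x[tr, , drop = FALSE], y_tr,
                           x[tr, , drop = FALSE])
      d_dec <- d_tr[!y_tr]
      s <- stats::sd(d_dec)
      if (!is.finite(s) || s == 0) s <- 1
      disc[te] <- (d_te - mean(d_dec)) / s
    }
  }
  df$discriminant <- disc
  df <- add_q_values(df, "discriminant")
  df[order(-df$discriminant, df$spectrum_id), ]
}

#' Filter rescored PSMs to the confident set
#'
#' A record passes when its PSM-level q-value, the q-value of its
#' (modified) peptide — taken from the best PSM per modified sequence, with
#' decoy peptides competing — and the minimum marginal site probability of
#' its chosen isoform all meet the thresholds.
#'
#' @param rescored Output of [semi_supervised_rescore()] (or any table with
#'   `discriminant`, `q_value`, `modified_sequence`, `is_decoy`,
#'   `min_site_probability`).
#' @param psm_q_max PSM-level q-value ceiling (default 0.01).
#' @param peptide_q_max Peptide-level q-value ceiling (default 0.01).
#' @param min_site_prob Site-probability floor; records must exceed it
#'   (default 0.75).
#' @return The table with `peptide_q_value` and logical `passes` added.
#' @export
filter_confident <- function(rescored, psm_q_max = 0.01,
                             peptide_q_max = 0.01, min_site_prob = 0.75) {
  best <- do.call(rbind, lapply(split(rescored, rescored$modified_sequence),
                                function(g)
                                  g[which.max(g$discriminant), , drop = FALSE]))
  best <- add_q_values(best, "discriminant", "peptide_q_value")
  map <- stats::setNames(best$peptide_q_value, best$modified_sequence)
  rescored$peptide_q_value <- unname(map[rescored$modified_sequence])
  sp <- rescored$min_site_probability
  sp_ok <- is.na(sp) | sp > min_site_prob
  rescored$passes <- !rescored$is_decoy &
    rescored$q_value <= psm_q_max &
    rescored$peptide_q_value <= peptide_q_max &
    sp_ok
  rescored
}

#' Split confident identifications into predictor fine-tuning sets
#'
#' Uniformly samples `test_n` identifications without replacement as the
#' held-out test set; the remainder is the training set.
#'
#' @param confident Data frame of confident identifications.
#' @param test_n Test-set size (default 500).
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_finetune_sets <- function(confident, test_n = 500L, seed = 20230101L) {
  n <- nrow(confident)
  if (n <= test_n)
    stop("too few confident identifications (", n, ") for a test set of ",
         test_n)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  test_idx <- sort(sample.int(n, test_n))
  list(train = confident[-test_idx, , drop = FALSE],
       test = confident[test_idx, , drop = FALSE])
}

#' Write predictor-interface fine-tuning TSVs
#'
#' Emits an RT-predictor-style table (`sequence`, `rt`) and a fragment-
#' intensity-predictor-style table (`sequence`, `charge`, `ions` as
#' semicolon-separated `label:intensity` pairs) for both splits.
#'
#' @param split List from [split_finetune_sets()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_finetune_tsvs <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (part in c("train", "test")) {
    df <- split[[part]]
    rt_path <- file.path(dir, paste0("rt_", part, ".tsv"))
    utils::write.table(
      data.frame(sequence = df$modified_sequence, rt = df$observed_rt),
      rt_path, sep = "\t", quote = FALSE, row.names = FALSE)
    ion_path <- file.path(dir, paste0("ions_", part, ".tsv"))
    charge <- 2L + df$charge3 + 2L * df$charge4plus
    utils::write.table(
      data.frame(sequence = df$modified_sequence, charge = charge,
                 ions = df$matched_ions),
      ion_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, rt_path, ion_path)
  }
  invisible(paths)
}
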