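test_that("isoform enumeration matches C(n,k) in lexicographic order", {
  psm1 <- toy_psm("SASTK", 3L)
  iso1 <- enumerate_isoforms(psm1)
  expect_length(iso1, 3)  # C(3,1): candidates 1, 3, 4
  expect_equal(vapply(iso1, position_key, ""), c("1", "3", "4"))

  psm2 <- psm_record("s", "SASTK",
                     variable_mods = mods_table(c(1, 3), MASS_PHOSPHO,
                                                "Phospho"))
  iso2 <- enumerate_isoforms(psm2)
  expect_equal(vapply(iso2, position_key, ""), c("1;3", "1;4", "3;4"))
})

test_that("enumeration errors when phospho count exceeds S/T/Y count", {
  psm <- psm_record("s", "SASTK",
                    variable_mods = mods_table(c(1, 3, 4), MASS_PHOSPHO,
                                               "Phospho"))
  # 3 phosphos on 3 candidates is fine; hack a 4th onto a T we do not have
  psm$variable_mods <- rbind(psm$variable_mods,
                             data.frame(position = 4L,
                                        mass_delta = MASS_PHOSPHO,
                                        name = "Phospho"))
  expect_error(enumerate_isoforms(psm), "inconsistent")
})

test_that("isoform counts agree with exhaustive bitmask enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    n_res <- sample(8:14, 1)
    pep <- paste(sample(c("A", "G", "L", "S", "T", "Y", "K"), n_res,
                        replace = TRUE), collapse = "")
    aa <- strsplit(pep, "")[[1]]
    cand <- which(aa %in% c("S", "T", "Y"))
    if (length(cand) < 1) next
    k <- sample(seq_len(min(3, length(cand))), 1)
    psm <- psm_record("s", pep,
                      variable_mods = mods_table(cand[seq_len(k)],
                                                 MASS_PHOSPHO, "Phospho"))
    # oracle: enumerate all subsets of residue positions via bitmask
    n <- nchar(pep)
    count <- 0L
    for (mask in 0:(2^n - 1)) {
      bits <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(bits) == k && all(bits %in% cand)) count <- count + 1L
    }
    expect_length(enumerate_isoforms(psm, max_isoforms = 10000L), count)
  }
})

test_that("enumeration cap returns the reported isoform flagged", {
  pep <- strrep("S", 12)
  psm <- psm_record("s", paste0(pep, "K"),
                    variable_mods = mods_table(c(1, 2, 3, 4, 5, 6),
                                               MASS_PHOSPHO, "Phospho"))
  iso <- enumerate_isoforms(psm, max_isoforms = 100L)  # C(12,6) = 924
  expect_length(iso, 1)
  expect_true(attr(iso, "unlocalizable"))
  expect_equal(iso[[1]]$phospho_positions, 1:6)
})

test_that("unmodified length-5 peptide yields 8 singly charged ions", {
  frags <- theoretical_fragments(phospho_isoform("AGLNK", integer(0)),
                                 charge = 1L)
  expect_equal(nrow(frags), 8)  # b1-b4, y1-y4
  expect_true(all(frags$charge == 1L))
  expect_false(any(frags$loss))
})

test_that("fragment m/z follows monoisotopic constants (TMT-tagged y1)", {
  iso <- phospho_isoform("AGSTK", 3L,
                         other_mods = mods_table(5L, MASS_TMT, "TMT"))
  frags <- theoretical_fragments(iso, charge = 1L)
  y1 <- frags$mz[frags$series == "y" & frags$index == 1 & !frags$loss]
  expect_equal(y1, 128.09496 + MASS_TMT + MASS_H2O + MASS_PROTON,
               tolerance = 1e-6)
})

test_that("phospho-containing fragments carry an H3PO4 loss variant", {
  frags <- theoretical_fragments(phospho_isoform("ASGLK", 2L), charge = 1L)
  b2 <- frags[frags$series == "b" & frags$index == 2, ]
  expect_setequal(b2$loss, c(TRUE, FALSE))
  expect_equal(b2$mz[!b2$loss] - b2$mz[b2$loss], MASS_H3PO4,
               tolerance = 1e-6)
  # b1 precedes the phospho: no loss variant
  expect_false(any(frags$loss[frags$series == "b" & frags$index == 1]))
})

test_that("b and y fragments are complementary to the precursor mass", {
  set.seed(21)
  for (rep in 1:10) {
    pep <- paste(sample(names(phosloc::RESIDUE_MASS), sample(7:15, 1),
                        replace = TRUE), collapse = "")
    aa <- strsplit(pep, "")[[1]]
    cand <- which(aa %in% c("S", "T", "Y"))
    iso <- phospho_isoform(pep, if (length(cand)) cand[1] else integer(0))
    frags <- theoretical_fragments(iso, charge = 1L)
    neutral <- isoform_neutral_mass(iso)
    n <- nchar(pep)
    for (i in seq_len(n - 1)) {
      b <- frags$mz[frags$series == "b" & frags$index == i & !frags$loss]
      y <- frags$mz[frags$series == "y" & frags$index == n - i &
                      !frags$loss]
      expect_equal((b - MASS_PROTON) + (y - MASS_PROTON), neutral,
                   tolerance = 1e-4)
    }
  }
})

test_that("align_peaks slots follow the theory list, not the spectrum", {
  iso <- phospho_isoform("SAGLK", 1L)
  frags <- theoretical_fragments(iso, charge = 1L)
  pred <- setNames(rep(0.5, nrow(frags)), frags$label)
  far <- toy_spectrum(c(1500.0, 1600.0))  # nothing near any theoretical ion
  pair <- align_peaks(frags, pred, far, tol_da = 0.02)
  expect_length(pair$Ie, nrow(frags))
  expect_true(all(pair$Ie == 0))
  expect_equal(pair$Ip, unname(pred[frags$label]))
  near <- toy_spectrum(frags$mz[1:3], c(10, 20, 30))
  pair2 <- align_peaks(frags, pred, near, tol_da = 0.02)
  expect_length(pair2$Ie, nrow(frags))  # length independent of content
  expect_equal(sort(pair2$Ie[pair2$Ie > 0]), c(10, 20, 30))
})

test_that("greedy alignment assigns a contested peak to the nearer ion", {
  theo <- data.frame(label = c("b1_z1", "b2_z1"), series = "b",
                     index = 1:2, charge = 1L, loss = FALSE,
                     mz = c(200.000, 200.015))
  spec <- toy_spectrum(200.012, 99)
  pair <- align_peaks(theo, setNames(c(1, 1), theo$label), spec, 0.02)
  expect_equal(pair$Ie, c(0, 99))  # 200.015 is nearer to 200.012
})

test_that("greedy most-intense-first matching agrees with a brute-force
           assignment oracle on a 3-peak toy", {
  theo <- data.frame(label = c("b1_z1", "b2_z1", "y1_z1"), series = "b",
                     index = 1:3, charge = 1L, loss = FALSE,
                     mz = c(100.00, 100.018, 250.00))
  spec <- toy_spectrum(c(100.005, 100.030, 250.010), c(50, 80, 10))
  pair <- align_peaks(theo, setNames(rep(1, 3), theo$label), spec, 0.02)
  # oracle: process peaks by descending intensity, assign nearest free ion
  # within 0.02: peak 100.030 (80) -> b2 (|0.012|); peak 100.005 (50) ->
  # b1 (|0.005|, b2 taken); peak 250.010 (10) -> y1.
  expect_equal(pair$Ie, c(50, 80, 10))
})

test_that("align_peaks validates inputs", {
  theo <- theoretical_fragments(phospho_isoform("SAGLK", 1L), 1L)
  pred <- setNames(rep(1, nrow(theo)), theo$label)
  empty <- structure(list(spectrum_id = "e", precursor_mz = 1,
                          precursor_charge = 2L, observed_rt = 1,
                          peaks = matrix(numeric(0), ncol = 2)),
                     class = "phos_spectrum")
  expect_error(align_peaks(theo, pred, empty), "empty spectrum")
  expect_error(align_peaks(theo, pred, toy_spectrum(100), tol_da = 0),
               "tol_da")
  # prediction lacking a theoretical label contributes Ip = 0
  pair <- align_peaks(theo, pred[-1], toy_spectrum(100))
  expect_equal(pair$Ip[1], 0)
})
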