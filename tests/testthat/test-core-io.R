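test_that("read_mgf parses blocks, converts RT to minutes, sorts peaks", {
  path <- write_toy_mgf(list(
    list(title = "scan1", pepmass = 500.25, charge = 2, rtinseconds = 600,
         peaks = cbind(c(300.1, 150.2, 200.3), c(10, 30, 20))),
    list(title = "scan2", pepmass = 601.3, charge = 3, rtinseconds = 90,
         peaks = cbind(400.5, 5))))
  sp <- read_mgf(path)
  expect_length(sp, 2)
  expect_equal(sp[[1]]$observed_rt, 10.0)
  expect_equal(sp[[2]]$observed_rt, 1.5)
  expect_equal(sp[[1]]$peaks[, "mz"], c(150.2, 200.3, 300.1))
  expect_equal(sp[[1]]$precursor_charge, 2L)
  expect_equal(sp[[2]]$spectrum_id, "scan2")
})

test_that("read_mgf rejects malformed blocks and missing RT", {
  path <- write_toy_mgf(list(
    list(title = "s1", pepmass = 500, charge = 2,
         peaks = cbind(100, 1))))  # no RTINSECONDS
  expect_error(read_mgf(path), "block 1")
  expect_error(read_mgf(tempfile()), "not found")
  bad <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x"), bad)  # no END IONS
  expect_error(read_mgf(bad), "unbalanced")
})

test_that("spectra round-trip through write_mgf/read_mgf", {
  sp <- toy_spectrum(c(111.04, 222.08, 333.12), c(5, 50, 500),
                     id = "rt1", rt = 42.5, charge = 3)
  path <- tempfile(fileext = ".mgf")
  write_mgf(list(sp), path)
  back <- read_mgf(path)[[1]]
  expect_equal(back$spectrum_id, "rt1")
  expect_equal(back$observed_rt, 42.5, tolerance = 1e-6)
  expect_equal(back$peaks[, "mz"], sp$peaks[, "mz"], tolerance = 1e-5)
  expect_equal(back$precursor_charge, 3L)
})

test_that("generic PSM table parses mods, decoy prefix, quantities", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "spectrum_id\tpeptide\tmodifications\tcharge\tscore\tproteins\tquant_a\tquant_b",
    "s1\tSASTK\t3:79.96633:Phospho\t2\t55.2\tP001\t3.5\t4.5",
    "s2\tSASTK\t1:79.96633:Phospho;3:79.96633:Phospho\t3\t44\tP001;P002\t1\t2",
    "s3\tMSSSR\t2:79.96633:Phospho\t2\t12\tREV_P003\t0\t0"), path)
  psms <- read_psm_table(path, "generic_tsv")
  expect_length(psms, 3)
  expect_equal(reported_phospho_positions(psms[[1]]), 3L)
  expect_equal(reported_phospho_positions(psms[[2]]), c(1L, 3L))
  expect_false(psms[[1]]$is_decoy)
  expect_true(psms[[3]]$is_decoy)
  expect_equal(psms[[2]]$protein_ids, c("P001", "P002"))
  expect_equal(psms[[1]]$quantity, c(a = 3.5, b = 4.5))
  expect_equal(unname(psms[[1]]$engine_scores["score"]), 55.2)
})

test_that("PSM readers reject bad modifications", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("spectrum_id\tpeptide\tmodifications\tcharge\tscore\tproteins",
               "s1\tSASTK\t3:79.96633:Wiggle\t2\t10\tP1"), path)
  expect_error(read_psm_table(path, "generic_tsv"), "Wiggle")
  writeLines(c("spectrum_id\tpeptide\tmodifications\tcharge\tscore\tproteins",
               "s1\tSASTK\t9:79.96633:Phospho\t2\t10\tP1"), path)
  expect_error(read_psm_table(path, "generic_tsv"), "off peptide")
  writeLines(c("spectrum_id\tpeptide\tmodifications\tcharge\tscore\tproteins",
               "s1\tSASTK\t2:79.96633:Phospho\t2\t10\tP1"), path)
  expect_error(read_psm_table(path, "generic_tsv"), "S/T/Y")
})

test_that("empty PSM table yields empty list with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines("spectrum_id\tpeptide\tmodifications\tcharge\tscore\tproteins",
             path)
  expect_warning(psms <- read_psm_table(path, "generic_tsv"), "no rows")
  expect_length(psms, 0)
})

test_that("MaxQuant msms.txt subset reader parses modified sequences", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Scan number", "Modified sequence", "Charge", "Score",
          "Delta score", "Proteins", "Reverse", sep = "\t"),
    paste("101", "_AAS(ph)TK_", "2", "88.1", "40", "P11", "", sep = "\t"),
    paste("102", "_M(ox)SS(ph)K_", "3", "50", "10", "P12", "", sep = "\t"),
    paste("103", "_KTSAA_", "2", "20", "5", "REV_P11", "+", sep = "\t")),
    path)
  psms <- read_psm_table(path, "maxquant_msms")
  expect_equal(psms[[1]]$peptide, "AASTK")
  expect_equal(reported_phospho_positions(psms[[1]]), 3L)
  expect_equal(psms[[2]]$peptide, "MSSK")
  expect_equal(reported_phospho_positions(psms[[2]]), 3L)
  expect_equal(other_mods(psms[[2]])$position, 1L)
  expect_equal(other_mods(psms[[2]])$name, "Oxidation")
  expect_true(psms[[3]]$is_decoy)
})

test_that("PSM records round-trip through the generic TSV dialect", {
  sim <- cached_sim(n_psms = 20)
  path <- tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(sim$psms, function(p) data.frame(
    spectrum_id = p$spectrum_id, peptide = p$peptide,
    modifications = paste(sprintf("%d:%.5f:%s", p$variable_mods$position,
                                  p$variable_mods$mass_delta,
                                  p$variable_mods$name), collapse = ";"),
    charge = p$charge, score = unname(p$engine_scores["score"]),
    proteins = paste(p$protein_ids, collapse = ";"))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_psm_table(path, "generic_tsv")
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$peptide, sim$psms[[i]]$peptide)
    expect_equal(reported_phospho_positions(back[[i]]),
                 reported_phospho_positions(sim$psms[[i]]))
    expect_equal(back[[i]]$charge, sim$psms[[i]]$charge)
    expect_equal(back[[i]]$is_decoy, sim$psms[[i]]$is_decoy)
  }
})

test_that("write_pin emits labels, deterministic bytes, and error paths", {
  ft <- data.frame(
    spectrum_id = sprintf("s%d", 1:5),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    peptide = rep("SASTK", 5), proteins = rep("P1", 5),
    f_alpha = rnorm(5), f_beta = rnorm(5))
  p1 <- tempfile(); p2 <- tempfile()
  write_pin(ft, p1, features = c("f_alpha", "f_beta"))
  write_pin(ft, p2, features = c("f_beta", "f_alpha"))
  tab <- read.delim(p1)
  expect_equal(tab$Label, c(1, 1, 1, -1, -1))
  expect_equal(nrow(tab), 5)
  expect_identical(readLines(p1), readLines(p2))  # column order canonical
  ft$f_alpha[2] <- NA
  expect_error(write_pin(ft, tempfile(), features = c("f_alpha", "f_beta")),
               "s2.*f_alpha")
})

test_that("spectrum constructor enforces invariants", {
  expect_error(toy_spectrum(c(100, 200), c(-1, 5)), "negative")
  expect_error(spectrum("x", 500, 2, -1, cbind(100, 1)), "observed_rt")
  expect_error(spectrum("x", 500, 0, 5, cbind(100, 1)), "charge")
  sp <- spectrum("x", 500, 2, 5, cbind(c(300, 100), c(1, 2)))
  expect_equal(sp$peaks[, "mz"], c(100, 300))
})

test_that("FASTA round-trips through Biostrings-backed readers", {
  seqs <- c(PROT1 = "MKTAYIAKQRQISFVK", PROT2 = "GGSSTTYYR")
  path <- tempfile(fileext = ".fasta")
  write_protein_fasta(seqs, path)
  expect_equal(read_protein_fasta(path), seqs)
})
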