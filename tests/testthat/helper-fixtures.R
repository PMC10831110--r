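# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# A minimal spectrum whose peaks exactly match the given m/z values.
toy_spectrum <- function(mz, intensity = rep(100, length(mz)),
                         id = "toy1", rt = 10, charge = 2L,
                         precursor_mz = 500) {
  spectrum(id, precursor_mz, charge, rt, cbind(mz, intensity))
}

# A singly phosphorylated PSM on the SASTK test peptide.
toy_psm <- function(peptide = "SASTK", pos = 3L, id = "toy1",
                    charge = 2L, score = 50, is_decoy = FALSE) {
  psm_record(id, peptide,
             variable_mods = mods_table(pos, MASS_PHOSPHO, "Phospho"),
             charge = charge,
             engine_scores = c(score = score, delta_score = 5),
             is_decoy = is_decoy,
             protein_ids = if (is_decoy) "REV_P1" else "P1")
}

# Write an MGF with the given blocks (list of lists with title, pepmass,
# charge, rtinseconds, peaks matrix) and return the path.
write_toy_mgf <- function(blocks, path = tempfile(fileext = ".mgf")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", b$title),
                 paste0("PEPMASS=", b$pepmass),
                 if (!is.null(b$charge)) paste0("CHARGE=", b$charge, "+"),
                 if (!is.null(b$rtinseconds))
                   paste0("RTINSECONDS=", b$rtinseconds),
                 apply(b$peaks, 1, paste, collapse = " "),
                 "END IONS"), con)
  }
  path
}

# Small deterministic simulated dataset, memoized per options so multiple
# test files can share it cheaply.
.sim_cache <- new.env()
cached_sim <- function(n_psms = 120, seed = 401, ...) {
  key <- paste(n_psms, seed, deparse(list(...)), collapse = "|")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(
      simulation_config(n_psms = n_psms, seed = seed, ...))
  .sim_cache[[key]]
}
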