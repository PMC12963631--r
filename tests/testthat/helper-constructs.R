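# Shared fixture builders. Everything is generated in code; no data
# files are read.

std_fv <- function(seed = 1L, ...) generate_fv(seed = seed, ...)

# a neutral Fv pair: both domains at net charge 0
neutral_fv <- function(seed = 1L) {
  generate_fv(seed = seed, vh_fr = 2L, vh_cdr = -2L, vl_fr = 0L, vl_cdr = 0L)
}

std_construct <- function(seed = 1L, linker = "(G4D)4",
                          tags = list("3xFLAG", "HA"), ...) {
  fv <- std_fv(seed, ...)
  assemble_scfv(fv$vl, fv$vh, linker = linker, tags = tags)
}

tag_seq <- function(name) tag_library()[[name]]$sequence

random_peptide <- function(len, letters_pool = scfvforge:::AA_CANONICAL) {
  paste(sample(letters_pool, len, replace = TRUE), collapse = "")
}

# independent dense-grid pI oracle: scan pH in 0.001 steps for the
# charge zero crossing under one pKa table, then average tables
grid_pi_oracle <- function(seq, step = 0.001) {
  counts <- scfvforge:::aa_counts(seq)
  ph <- seq(0, 14, by = step)
  mean(vapply(scfvforge:::PKA_TABLES, function(tab) {
    q <- scfvforge:::hh_charge(counts, ph, tab, free_termini = TRUE)
    i <- which(q <= 0)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    # linear interpolation across the crossing
    ph[i - 1] + step * q[i - 1] / (q[i - 1] - q[i])
  }, numeric(1)))
}
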