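# Shared fixtures and independent oracles.

AA_STD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_seq <- function(n, seed, pool = AA_STD) {
  set.seed(seed)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Independent per-residue lipophilicity: direct Henderson-Hasselbalch
# arithmetic on the raw scale/pKa tables, no package profile code.
oracle_residue_lipo <- function(aa, pH, scale = lipophilicity_scale(),
                                pka = ionization_table()) {
  vapply(aa, function(a) {
    ln <- scale[scale$aa == a, "neutral"]
    lc <- scale[scale$aa == a, "charged"]
    row <- pka[pka$group == a, ]
    if (nrow(row) == 0) return(ln)
    fn <- if (row$charge < 0) 1 / (1 + 10^(pH - row$pKa))
          else 1 / (1 + 10^(row$pKa - pH))
    fn * ln + (1 - fn) * lc
  }, numeric(1))
}

# Brute-force O(L*w) sliding-window enumeration.
oracle_profile <- function(seq_string, pH, window,
                           scale = lipophilicity_scale(),
                           pka = ionization_table()) {
  aa <- strsplit(seq_string, "")[[1]]
  l <- oracle_residue_lipo(aa, pH, scale, pka)
  L <- length(aa)
  half <- (window - 1) / 2
  centers <- (half + 1):(L - half)
  vapply(centers, function(c) mean(l[(c - half):(c + half)]), numeric(1))
}

# A scale with no charged-species penalty (pH-inert pipeline).
flat_scale <- function() {
  s <- as.data.frame(lipophilicity_scale())
  s$charged <- s$neutral
  pHsol:::validate_lipophilicity_scale(s, name = "flat")
}

reference_fasta <- function() {
  system.file("extdata", "reference_idps.fasta", package = "pHsol")
}

table1_params <- function() solubility_params()
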