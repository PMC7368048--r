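# Shared helpers: quick count-table construction, toy peptide tables, and an
# independent interval-classification oracle.

# Counts with equal-length autosomes so read counts map directly onto rates.
make_counts <- function(n_y, n_x, auto_reads = 4000, auto_len = 1e6,
                        x_len = 1e6, y_len = 1e6, sample_id = "toy") {
  canon <- canonical_chromosomes()
  lens <- setNames(c(rep(auto_len, 22), x_len, y_len), canon)
  if (length(auto_reads) == 1) auto_reads <- rep(auto_reads, 22)
  maps <- setNames(c(auto_reads, n_x, n_y), canon)
  chrom_counts(lens, maps, sample_id = sample_id)
}

write_idxstats <- function(path, names, lens, mapped, unmapped = 0) {
  df <- data.frame(names, lens, mapped, unmapped)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

write_peptide_csv <- function(path, sequence, intensity,
                              modifications = "", accession = "AMELX_SYNTH") {
  df <- data.frame(sequence = sequence, modifications = modifications,
                   intensity = intensity, protein_accession = accession)
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent decision oracle: decomposes the geometry by intersection with
# the CLOSED definitive regions (endpoint equality counts as touching), a
# different case decomposition from the implementation's.
oracle_classify <- function(lo, hi, orientation, t_female, t_male) {
  if (orientation == "male_high") {
    hits_m <- hi >= t_male      # interval meets closed male boundary
    hits_f <- lo <= t_female
    inside_m <- lo > t_male
    inside_f <- hi < t_female
  } else {                       # female_high (Rx): male low, female high
    hits_m <- lo <= t_male
    hits_f <- hi >= t_female
    inside_m <- hi < t_male
    inside_f <- lo > t_female
  }
  if (hits_m && hits_f) return(c("indeterminate", "none"))
  if (hits_m) return(if (inside_m) c("XY", "definitive") else c("XY", "conditional"))
  if (hits_f) return(if (inside_f) c("XX", "definitive") else c("XX", "conditional"))
  c("indeterminate", "none")
}

classify_with_package <- function(lo, hi, orientation, t_female, t_male) {
  if (orientation == "male_high") {
    est <- classify_interval((lo + hi) / 2, lo, hi,
                             male_region = list(bound = t_male, side = "above"),
                             female_region = list(bound = t_female, side = "below"))
  } else {
    est <- classify_interval((lo + hi) / 2, lo, hi,
                             male_region = list(bound = t_male, side = "below"),
                             female_region = list(bound = t_female, side = "above"))
  }
  c(est$sex, est$certainty)
}
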