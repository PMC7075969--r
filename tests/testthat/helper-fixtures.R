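# Shared fixtures and independent oracles.

# Brute-force KS tag-set statistic: evaluates the sup-difference between
# the tag empirical step function and the uniform reference at *every*
# rank of the list, instead of the closed form over tag indices. This is
# the independent oracle ks_statistic is checked against.
ks_oracle <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  F_at <- function(i) sum(tag_ranks <= i) / t
  a <- max(vapply(0:n, function(i) F_at(i) - i / n, numeric(1)))
  b <- max(vapply(1:n, function(i) i / n - F_at(i - 1), numeric(1)))
  if (a >= b) a else -b
}

# A tiny deterministic database: hand-picked amplitudes so tag positions
# are known exactly.
toy_profiles <- function() {
  probes <- paste0("p", sprintf("%02d", 1:10))
  amp <- function(v) stats::setNames(v, probes)
  list(
    # p01..p03 strongly up, p08..p10 strongly down
    rank_profile_from_amplitudes(amp(c(5, 4, 3, 1, 0.5, -0.5, -1, -3, -4, -5)),
                                 "i01", "drugA", "CL1"),
    # reversed pattern
    rank_profile_from_amplitudes(amp(c(-5, -4, -3, -1, -0.5, 0.5, 1, 3, 4, 5)),
                                 "i02", "drugA", "CL1"),
    # mild scramble
    rank_profile_from_amplitudes(amp(c(0.3, -0.2, 1.2, -1.1, 0.7, -0.9, 0.1,
                                       0.8, -0.4, 0.2)),
                                 "i03", "drugB", "CL1"),
    rank_profile_from_amplitudes(amp(c(-0.6, 1.4, -0.8, 0.9, -1.2, 0.4, -0.1,
                                       -0.3, 1.1, 0.6)),
                                 "i04", "drugB", "CL2"))
}

toy_db <- function() build_database(toy_profiles())

# Database of fresh uniform-random rank permutations (exchangeable null),
# with accession-style shuffled instance ids.
random_db <- function(n_probes, n_instances, n_compounds, seed) {
  set.seed(seed)
  probes <- sprintf("p%03d", seq_len(n_probes))
  ids <- sprintf("r%04d", sample.int(n_instances))
  profiles <- lapply(seq_len(n_instances), function(j) {
    amp <- stats::setNames(stats::rnorm(n_probes), probes)
    rank_profile_from_amplitudes(
      amp, ids[j],
      compound = sprintf("cmp%d", 1L + (j - 1L) %% n_compounds),
      cell_line = "CL")
  })
  build_database(profiles)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

de_table_file <- function() {
  write_lines_tmp(c(
    "gene_id\tlog2fc\tqvalue",
    "g1\t2.0\t0.01",
    "g2\t-1.5\t0.02",
    "g3\t0.5\t0.20",
    "g4\t-0.8\t0.04",
    "g5\t1.1\t0.03"))
}
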