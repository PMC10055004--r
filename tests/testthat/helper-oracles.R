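## Independent oracles and tiny fixture builders used across test files.

## Hudson F_ST, re-derived from allele counts (independent of the package
## implementation): ratio of averages with the finite-sample correction.
oracle_hudson_fst <- function(p1, p2, n1_chrom, n2_chrom) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1_chrom - 1) -
    p2 * (1 - p2) / (n2_chrom - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

## Forward Wright-Fisher two-population oracle: explicit per-generation
## binomial resampling of 2Ne chromosomes, followed by binomial sampling of
## individuals. Returns the oracle Hudson F_ST over the simulated sites.
oracle_wf_fst <- function(t, ne, n_sites = 5000, n_diploid = 200,
                          seed = 1) {
  set.seed(seed)
  a <- runif(n_sites, 0.05, 0.95)
  p1 <- a; p2 <- a
  for (g in seq_len(t)) {
    p1 <- rbinom(n_sites, 2 * ne, p1) / (2 * ne)
    p2 <- rbinom(n_sites, 2 * ne, p2) / (2 * ne)
  }
  f1 <- rbinom(n_sites, 2 * n_diploid, p1) / (2 * n_diploid)
  f2 <- rbinom(n_sites, 2 * n_diploid, p2) / (2 * n_diploid)
  keep <- pmin(f1, 1 - f1) > 0 | pmin(f2, 1 - f2) > 0
  oracle_hudson_fst(f1[keep], f2[keep], 2 * n_diploid, 2 * n_diploid)
}

## small deterministic two-group panel: group sizes n, dosage columns given
## as a list of per-individual vectors
make_panel <- function(dosages, labels, ...) {
  genotype_panel(dosages, labels, ...)
}

## balanced +/-1 test vector over N individuals (first half +1)
balanced_t <- function(N) {
  standardize_test_vector(rep(c(1, 0), each = N / 2), "population_indicator")
}
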