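# Small programmatic fixtures shared across test files.

tiny_map <- function(n = 10, chrom = "1", spacing = 1e5) {
  snp_map(rep(chrom, n), seq_len(n) * spacing)
}

# a small but realistic simulated study, cached per seed for the test run
small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 7, ...) {
  key <- paste0(seed, "_", paste(c(...), collapse = "_"))
  if (is.null(small_sim_cache[[key]])) {
    cfg <- sim_config(n_chromosomes = 2, n_snps = 300, n_founders = 15,
                      n_generations = 4,
                      n_purebred = c(S = 60, LR = 60, LW = 60),
                      n_f1 = 20, n_cross3 = 15, seed = seed, ...)
    small_sim_cache[[key]] <- simulate_three_cross(cfg)
  }
  small_sim_cache[[key]]
}

# write a minimal phased VCF from explicit genotype strings
write_test_vcf <- function(path, chrom, pos, gts, samples,
                           ref = "A", alt = "C") {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref, alt, ".", "PASS",
                              ".", "GT", gts[[i]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
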