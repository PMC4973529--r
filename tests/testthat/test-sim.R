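test_that("breed frequencies follow the Balding-Nichols moments", {
  set.seed(11)
  p <- rep(0.5, 10000)
  f <- draw_breed_frequencies(p, fst = 0.3, n_breeds = 2)
  # Var = p(1-p)*fst = 0.075
  expect_equal(var(f[, 1]), 0.075, tolerance = 0.1)
  expect_equal(mean(f[, 1]), 0.5, tolerance = 0.01)
  # E[(p1-p2)^2] = 2 p(1-p) fst = 0.15 for independent breeds
  expect_equal(mean((f[, 1] - f[, 2])^2), 0.15, tolerance = 0.05)
  # near-zero divergence: frequencies hug the base frequency
  f0 <- draw_breed_frequencies(p, fst = 1e-4, n_breeds = 1)
  expect_lt(max(abs(f0 - 0.5)), 0.1)
  expect_error(draw_breed_frequencies(p, fst = 0), "fst")
  expect_error(draw_breed_frequencies(p, fst = 1), "fst")
})

test_that("meiosis produces about one crossover per 100 cM", {
  map <- tiny_map(20, spacing = 5e6)  # 100 Mb -> 100 cM at 1 cM/Mb
  expect_equal(max(map$pos_cm) - min(map$pos_cm), 95, tolerance = 1e-6)
  set.seed(3)
  h1 <- rep(0L, 20); h2 <- rep(1L, 20)
  n_x <- replicate(10000, length(meiosis(h1, h2, map)$breakpoints[["1"]]))
  expect_equal(mean(n_x), 0.95, tolerance = 3 * sqrt(0.95 / 10000) / 0.95)
  # gametes alternate between parents exactly at the breakpoints
  m <- meiosis(h1, h2, map)
  expect_identical(m$gamete, ifelse(m$source == 1L, h1, h2))
})

test_that("a zero-length map copies one parental gamete unchanged", {
  map <- snp_map(rep("1", 30), 1:30, pos_cm = rep(0, 30))
  set.seed(5)
  h1 <- rbinom(30, 1, 0.5); h2 <- rbinom(30, 1, 0.5)
  for (i in 1:5) {
    m <- meiosis(h1, h2, map)
    expect_true(identical(m$gamete, h1) || identical(m$gamete, h2))
    expect_length(m$breakpoints[["1"]], 0)
  }
})

test_that("purebred simulation reduces to i.i.d. draws without mating", {
  map <- tiny_map(2000, spacing = 1e4)
  set.seed(9)
  freq <- rep(0.3, 2000)
  pop <- simulate_purebred_population(freq, n_founders = 5, n_generations = 0,
                                      n_output = 50, map)
  expect_equal(mean(pop$haplotypes$hap1), 0.3, tolerance = 0.02)
  expect_equal(nrow(pop$haplotypes$hap1), 50)
})

test_that("with no recombination, output haplotypes come from the founder pool", {
  map <- snp_map(rep("1", 50), 1:50, pos_cm = rep(0, 50))
  freq <- withr::with_seed(99, runif(50, 0.2, 0.8))
  set.seed(13)
  pop <- simulate_purebred_population(freq, n_founders = 2, n_generations = 6,
                                      n_output = 20, map)
  # reconstruct the founder gametes by rerunning the seeded draw
  set.seed(13)
  founders <- rbind(matrix(rbinom(2 * 50, 1L, rep(freq, each = 2)), nrow = 2),
                    matrix(rbinom(2 * 50, 1L, rep(freq, each = 2)), nrow = 2))
  pool <- apply(founders, 1, paste, collapse = "")
  out <- c(apply(pop$haplotypes$hap1, 1, paste, collapse = ""),
           apply(pop$haplotypes$hap2, 1, paste, collapse = ""))
  expect_true(all(out %in% pool))
})

test_that("cross offspring carry exact origin truth", {
  sim <- small_sim()
  # CROSS3 paternal gamete is S everywhere, maternal only LR/LW
  expect_true(all(sim$truth$paternal == "S"))
  expect_true(all(sim$truth$maternal %in% c("LR", "LW")))
  # F1 animals: one gamete entirely LR, the other entirely LW
  expect_true(all(rowSums(sim$f1_truth$track1 == "LR") %in%
                    c(0L, ncol(sim$f1_truth$track1))))
  expect_true(all(sim$f1_truth$track1 != sim$f1_truth$track2))
})

test_that("about half of maternal CROSS3 alleles descend from each dam line", {
  sim <- small_sim()
  frac_lr <- mean(sim$truth$maternal == "LR")
  expect_gt(frac_lr, 0.30)
  expect_lt(frac_lr, 0.70)
})

test_that("maternal truth switches exactly at the dam meiosis junctions", {
  # dam with gamete1 all-0/LR and gamete2 all-1/LW: the offspring's maternal
  # allele reveals the source gamete, which must match the truth label
  map <- tiny_map(200, spacing = 1e6)
  h0 <- matrix(0L, 1, 200, dimnames = list("dam", NULL))
  h1 <- matrix(1L, 1, 200, dimnames = list("dam", NULL))
  dam <- haplotype_set(h0, h1, map)
  sire <- haplotype_set(matrix(0L, 1, 200, dimnames = list("sire", NULL)),
                        matrix(0L, 1, 200, dimnames = list("sire", NULL)), map)
  set.seed(21)
  x <- make_cross(sire, dam, 30, design = "CROSS3", sire_origin = "S",
                  dam_origin = list(track1 = matrix("LR", 1, 200),
                                    track2 = matrix("LW", 1, 200)))
  expect_identical(unname(x$truth$maternal == "LW"),
                   unname(x$haplotypes$hap2 == 1L))
})

test_that("error injection matches its nominal rates and semantics", {
  sim <- small_sim()
  clean <- sim$haplotypes
  expect_identical(inject_errors(clean, 0, 0)$hap1, clean$hap1)
  set.seed(31)
  noisy <- inject_errors(clean, genotype_error_rate = 0.01,
                         switch_error_rate = 0)
  flipped <- mean(noisy$hap1 != clean$hap1, na.rm = TRUE)
  n <- sum(!is.na(clean$hap1))
  expect_equal(flipped, 0.01, tolerance = 4 * sqrt(0.01 * 0.99 / n) / 0.01)
})

test_that("a switch error exchanges the gametes downstream of the site", {
  map <- tiny_map(10)
  h1 <- matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), 1, 10,
               dimnames = list("a", NULL))
  h2 <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 0L), 1, 10,
               dimnames = list("a", NULL))
  hs <- haplotype_set(h1, h2, map)
  set.seed(1)
  # rate 1: a switch fires at every heterozygous site (4, 5, 6, 8); an even
  # number of upstream switches restores the original phase
  sw <- inject_errors(hs, 0, 1)
  het <- c(4, 5, 6, 8)
  parity <- (findInterval(1:10, het) %% 2) == 1
  expect_identical(sw$hap1[1, parity], h2[1, parity])
  expect_identical(sw$hap1[1, !parity], h1[1, !parity])
  # dosages are untouched by switches
  expect_identical(dosage_matrix(sw), dosage_matrix(hs))
})

test_that("panel masking blanks exactly the off-panel SNPs", {
  sim <- small_sim()
  g <- dosage_matrix(sim$haplotypes)
  expect_identical(mask_to_panel(g, sim$map$snp_id, sim$map), g)
  empty <- mask_to_panel(g, character(0), sim$map)
  expect_true(all(is.na(empty)))
  keep <- sim$map$snp_id[1:100]
  m <- mask_to_panel(g, keep, sim$map)
  expect_equal(sum(colSums(!is.na(m)) > 0), 100)
  expect_error(mask_to_panel(g, "no_such_snp", sim$map), "no_such_snp")
})

test_that("the generator is deterministic in its seed", {
  cfg <- sim_config(n_chromosomes = 1, n_snps = 100, n_founders = 6,
                    n_generations = 2, n_purebred = c(S = 10, LR = 10, LW = 10),
                    n_f1 = 4, n_cross3 = 4, seed = 99)
  a <- simulate_three_cross(cfg)
  b <- simulate_three_cross(cfg)
  expect_identical(a$haplotypes$hap1, b$haplotypes$hap1)
  expect_identical(a$truth$maternal, b$truth$maternal)
  expect_identical(a$map$pos_bp, b$map$pos_bp)
})

test_that("realized between-breed differentiation rises with fst", {
  med_fst <- vapply(c(0.05, 0.15, 0.3), function(fst) {
    vals <- vapply(1:3, function(s) {
      cfg <- sim_config(n_chromosomes = 1, n_snps = 400, n_founders = 30,
                        n_generations = 2,
                        n_purebred = c(S = 40, LR = 40, LW = 40),
                        n_f1 = 2, n_cross3 = 2, fst = fst, seed = 100 + s)
      sim <- simulate_three_cross(cfg)
      lr <- sim$pedigree$animal[sim$pedigree$population == "LR"]
      lw <- sim$pedigree$animal[sim$pedigree$population == "LW"]
      d <- dosage_matrix(sim$haplotypes)
      p1 <- colMeans(d[lr, ]) / 2
      p2 <- colMeans(d[lw, ]) / 2
      # Hudson-style ratio-of-averages estimator
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * length(lr) - 1) -
        p2 * (1 - p2) / (2 * length(lw) - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      sum(num) / sum(den)
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med_fst) > 0))
})
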