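test_that("the relaxation-factor rule assigns haplotype breeds", {
  expect_equal(assign_haplotype_breed(c(10, 0, 0), f_r = 0), "S")
  # 90% in one breed: unknown at f_r 0, assigned at f_r 20
  expect_equal(assign_haplotype_breed(c(9, 1, 0), f_r = 0), "UNKNOWN")
  expect_equal(assign_haplotype_breed(c(9, 1, 0), f_r = 20), "S")
  expect_equal(assign_haplotype_breed(c(0, 0, 0), f_r = 20), "UNKNOWN")
  expect_equal(assign_haplotype_breed(c(0, 3, 1), f_r = 25), "LR")
  # exact boundary: 80% with f_r = 20 qualifies
  expect_equal(assign_haplotype_breed(c(8, 2, 0), f_r = 20), "S")
  expect_equal(assign_haplotype_breed(c(79, 21, 0), f_r = 20), "UNKNOWN")
  # a tied majority never assigns
  expect_equal(assign_haplotype_breed(c(5, 5, 0), f_r = 60), "UNKNOWN")
  # minimum copy requirement
  expect_equal(assign_haplotype_breed(c(1, 0, 0), min_copies = 2), "UNKNOWN")
  # vectorised over rows
  m <- rbind(c(10, 0, 0), c(9, 1, 0), c(0, 0, 4))
  expect_equal(assign_haplotype_breed(m, f_r = 0), c("S", "UNKNOWN", "LW"))
})

test_that("window matching prefers exact hits and refuses ties", {
  lib <- c(strrep("0", 350), paste0(strrep("0", 349), "1"),
           paste0("11", strrep("0", 348)))
  # exact copy
  expect_equal(match_crossbred_window(lib[2], lib), 2L)
  # one mismatch in 350 SNPs (0.29% <= 1%) is tolerated
  q1 <- paste0("1", strrep("0", 349))
  expect_equal(match_crossbred_window(q1, lib[1]), 1L)
  # but not with exact matching demanded
  expect_true(is.na(match_crossbred_window(q1, lib[1],
                                           max_mismatch_fraction = 0)))
  # two equidistant candidates within tolerance: no match
  libAB <- c(strrep("0", 350), paste0("11", strrep("0", 348)))
  q2 <- paste0("1", strrep("0", 349))  # distance 1 to both entries
  expect_true(is.na(match_crossbred_window(q2, libAB,
                                           max_mismatch_fraction = 0.01)))
  # missing positions are excluded from the comparison
  q3 <- paste0("9", substr(lib[3], 2, 350))
  expect_equal(match_crossbred_window(q3, lib), 3L)
  # an all-missing query never matches
  expect_true(is.na(match_crossbred_window(strrep("9", 350), lib[1])))
})

test_that("library counting follows gamete copies per breed", {
  map <- tiny_map(30)
  h <- matrix(0L, 4, 30, dimnames = list(c("s1", "s2", "lr1", "lw1"), NULL))
  h2 <- h
  h2["lw1", ] <- 1L  # lw1's second gamete differs
  haps <- haplotype_set(h, h2, map)
  breeds <- c(s1 = "S", s2 = "S", lr1 = "LR", lw1 = "LW")
  cfg <- tibble::tibble(config_id = 1L, core_length = 30L, tail_length = 0L,
                        offset = FALSE)
  lib <- build_haplotype_library(haps, breeds, cfg)
  allzero <- strrep("0", 30)
  row <- lib[lib$haplotype == allzero, ]
  # two identical homozygous S animals contribute 4 copies
  expect_equal(row$n_S, 4L)
  expect_equal(row$n_LR, 2L)
  expect_equal(row$n_LW, 1L)
  expect_equal(lib[lib$haplotype == strrep("1", 30), ]$n_LW, 1L)
  # gametes with a missing allele contribute nothing
  h2["lr1", 5] <- NA
  lib2 <- build_haplotype_library(haplotype_set(h, h2, map), breeds, cfg)
  expect_equal(lib2[lib2$haplotype == allzero, ]$n_LR, 1L)
  expect_error(build_haplotype_library(haps, c(s1 = "S", s2 = "S",
                                               lr1 = "F1", lw1 = "LW"), cfg),
               "purebred")
})

test_that("library construction equals exhaustive enumeration on a toy", {
  sim <- small_sim(seed = 3)
  pure_ids <- sim$pedigree$animal[sim$pedigree$population %in%
                                    c("S", "LR", "LW")][1:30]
  haps <- subset_animals(sim$haplotypes, pure_ids)
  breeds <- sim$breeds[pure_ids]
  cfgs <- default_window_configs()[c(2, 11), ]
  lib <- build_haplotype_library(haps, breeds, cfgs)
  for (k in seq_len(nrow(cfgs))) {
    wins <- oracle_windows(haps$map, cfgs$core_length[k], cfgs$offset[k])
    for (w in wins) {
      oc <- oracle_window_library(haps, breeds, w$snps)
      sub <- lib[lib$config_id == cfgs$config_id[k] &
                   lib$snp_start == w$start, ]
      expect_setequal(sub$haplotype, oc$keys)
      o <- match(sub$haplotype, oc$keys)
      expect_equal(sub$n_S, vapply(oc$counts[o], `[[`, numeric(1), "S"))
      expect_equal(sub$n_LR, vapply(oc$counts[o], `[[`, numeric(1), "LR"))
      expect_equal(sub$n_LW, vapply(oc$counts[o], `[[`, numeric(1), "LW"))
    }
  }
})

test_that("gamete parentage follows the S-majority and pedigree precedence", {
  p <- infer_gamete_parentage(c(40L, 0L, 3L), c(0L, 0L, 3L))
  expect_equal(p$orientation, c(1L, NA, NA))
  expect_equal(p$source, c("s_majority", "unordered", "unordered"))
  # pedigree wins over a conflicting S-majority, and the conflict is flagged
  p2 <- infer_gamete_parentage(c(40L, 1L), c(0L, 5L),
                               pedigree_orientation = c(2L, 2L))
  expect_equal(p2$orientation, c(2L, 2L))
  expect_equal(p2$conflict, c(TRUE, FALSE))
})

test_that("unordered animals receive no assignment at all", {
  sim <- small_sim()
  x3 <- sim$pedigree$animal[sim$pedigree$population == "CROSS3"][1:3]
  keep <- c(sim$pedigree$animal[sim$pedigree$population %in%
                                  c("S", "LR", "LW")], x3)
  haps <- subset_animals(sim$haplotypes, keep)
  # blank out every S window source: replace the paternal gamete by a copy
  # of the maternal one so both gametes carry maternal (LR/LW) material
  haps$hap1[x3, ] <- haps$hap2[x3, ]
  res <- assign_breed_origin(haps, sim$breeds)
  expect_true(all(res$origins$paternal[x3, ] == "UNKNOWN"))
  expect_true(all(res$origins$maternal[x3, ] == "UNKNOWN"))
  expect_true(all(is.na(res$parentage$orientation) |
                    res$parentage$source != "pedigree"))
})

test_that("composition and zygosity invariants hold on pipeline output", {
  for (seed in c(7, 3)) {
    sim <- small_sim(seed = seed)
    res <- assign_breed_origin(sim$haplotypes, sim$breeds,
                               pedigree = sim$pedigree)
    x3 <- sim$pedigree$animal[sim$pedigree$population == "CROSS3"]
    pat <- res$origins$paternal[x3, ]
    mat <- res$origins$maternal[x3, ]
    expect_true(all(pat %in% c("S", "UNKNOWN")))
    expect_true(all(mat %in% c("LR", "LW", "UNKNOWN")))
    # no locus with an assigned maternal allele and an unknown paternal one
    expect_false(any(mat != "UNKNOWN" & pat == "UNKNOWN"))
  }
})

test_that("a maternal vote forces the paternal assignment at that locus", {
  # construct a crossbred whose paternal gamete is unmatchable (all missing)
  # while the maternal gamete matches the library: the zygosity rule must
  # still assign the paternal allele to S
  sim <- small_sim()
  x3 <- sim$pedigree$animal[sim$pedigree$population == "CROSS3"][1]
  keep <- c(sim$pedigree$animal[sim$pedigree$population %in%
                                  c("S", "LR", "LW")], x3)
  haps <- subset_animals(sim$haplotypes, keep)
  haps$hap1[x3, ] <- NA_integer_
  res <- assign_breed_origin(haps, sim$breeds, pedigree = sim$pedigree)
  mat <- res$origins$maternal[x3, ]
  pat <- res$origins$paternal[x3, ]
  expect_gt(sum(mat != "UNKNOWN"), 0)
  expect_true(all(pat[mat != "UNKNOWN"] == "S"))
  # and nowhere else: the paternal gamete itself could not be matched
  expect_true(all(pat[mat == "UNKNOWN"] == "UNKNOWN"))
})

test_that("a paternal vote does not force the maternal assignment", {
  sim <- small_sim()
  x3 <- sim$pedigree$animal[sim$pedigree$population == "CROSS3"][1]
  keep <- c(sim$pedigree$animal[sim$pedigree$population %in%
                                  c("S", "LR", "LW")], x3)
  haps <- subset_animals(sim$haplotypes, keep)
  haps$hap2[x3, ] <- NA_integer_  # maternal gamete unmatchable
  res <- assign_breed_origin(haps, sim$breeds, pedigree = sim$pedigree)
  expect_gt(sum(res$origins$paternal[x3, ] == "S"), 0)
  # the algorithm cannot choose between the two maternal purebred lines
  expect_true(all(res$origins$maternal[x3, ] == "UNKNOWN"))
})

test_that("strict consensus assigns on unanimity and balks at conflict", {
  map <- tiny_map(4)
  votes <- structure(list(
    pat_count = matrix(c(12L, 0L, 2L, 1L), 1, 4, dimnames = list("x", NULL)),
    mat_LR = matrix(c(3L, 9L, 0L, 0L), 1, 4, dimnames = list("x", NULL)),
    mat_LW = matrix(c(0L, 9L, 0L, 1L), 1, 4, dimnames = list("x", NULL)),
    pat_breed = "S",
    parentage = tibble::tibble(animal = "x", orientation = 1L,
                               source = "s_majority", conflict = FALSE),
    animals = "x", map = map, provenance = list()), class = "boa_votes")
  om <- consensus_origins(votes)
  expect_equal(unname(om$paternal[1, ]), c("S", "UNKNOWN", "S", "S"))
  expect_equal(unname(om$maternal[1, ]),
               c("LR", "UNKNOWN", "UNKNOWN", "LW"))
  # majority rule resolves the 9-9 split only above threshold
  om2 <- consensus_origins(votes, vote_rule = "majority",
                           majority_threshold = 0.5)
  expect_equal(unname(om2$maternal[1, 2]), "UNKNOWN")
  votes$mat_LW[1, 2] <- 3L
  om3 <- consensus_origins(votes, vote_rule = "majority",
                           majority_threshold = 0.5)
  expect_equal(unname(om3$maternal[1, 2]), "LR")
})

test_that("the full pipeline matches the brute-force reference", {
  for (seed in 1:4) {
    cfg <- sim_config(n_chromosomes = sample(1:2, 1), n_snps = 100,
                      n_founders = 6, n_generations = 2,
                      n_purebred = c(S = 12, LR = 12, LW = 12),
                      n_f1 = 4, n_cross3 = 5, seed = seed)
    sim <- simulate_three_cross(cfg)
    ids <- sim$pedigree$animal[sim$pedigree$population != "F1"]
    haps <- subset_animals(sim$haplotypes, ids)
    f_r <- c(0, 20)[seed %% 2 + 1]
    res <- assign_breed_origin(haps, sim$breeds, f_r = f_r)
    oracle <- oracle_boa(haps, sim$breeds, f_r = f_r)
    x3 <- animals(oracle)
    expect_identical(res$origins$paternal[x3, ], oracle$paternal)
    expect_identical(res$origins$maternal[x3, ], oracle$maternal)
  }
})

test_that("assignments at f_r 0 are preserved and extended at f_r 20", {
  sim <- small_sim()
  pure_ids <- sim$pedigree$animal[sim$pedigree$population %in%
                                    c("S", "LR", "LW")]
  lib <- build_haplotype_library(subset_animals(sim$haplotypes, pure_ids),
                                 sim$breeds[pure_ids],
                                 default_window_configs()[c(1, 5, 14), ])
  counts <- cbind(lib$n_S, lib$n_LR, lib$n_LW)
  lab0 <- assign_haplotype_breed(counts, f_r = 0)
  lab20 <- assign_haplotype_breed(counts, f_r = 20)
  assigned0 <- lab0 != "UNKNOWN"
  expect_true(all(lab20[assigned0] == lab0[assigned0]))
  expect_gte(sum(lab20 != "UNKNOWN"), sum(assigned0))
})

test_that("identical inputs give identical assignments", {
  sim <- small_sim()
  a <- assign_breed_origin(sim$haplotypes, sim$breeds, pedigree = sim$pedigree)
  b <- assign_breed_origin(sim$haplotypes, sim$breeds, pedigree = sim$pedigree)
  expect_identical(a$origins$paternal, b$origins$paternal)
  expect_identical(a$origins$maternal, b$origins$maternal)
})

test_that("assignment recovers simulated truth on clean data", {
  sim <- small_sim()
  res <- assign_breed_origin(sim$haplotypes, sim$breeds,
                             pedigree = sim$pedigree)
  x3 <- rownames(sim$truth$paternal)
  st <- assignment_stats(subset_origins(res$origins, x3), truth = sim$truth)
  expect_gt(mean(st$pct_assigned), 75)
  expect_gt(mean(st$pct_correct), 98)
})

test_that("missing purebred lines or crossbreds are rejected", {
  sim <- small_sim()
  ids_no_lw <- sim$pedigree$animal[sim$pedigree$population != "LW"]
  expect_error(assign_breed_origin(
    subset_animals(sim$haplotypes, ids_no_lw), sim$breeds), "LW")
  pure <- sim$pedigree$animal[sim$pedigree$population %in% c("S", "LR", "LW")]
  expect_error(assign_breed_origin(
    subset_animals(sim$haplotypes, pure), sim$breeds), "crossbred")
})
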