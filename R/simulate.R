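#' Simulation configuration for a three-way cross
#'
#' Bundles all parameters of the synthetic three-way-cross generator. The
#' defaults emulate the study design the package targets: three diverged
#' purebred pig lines (terminal sire line S, maternal lines LR and LW),
#' F1 = LR x LW dams in both reciprocal directions, and terminal crosses
#' S x F1 with exact per-allele breed-of-origin truth.
#'
#' @param n_chromosomes Number of autosomes.
#' @param n_snps SNPs per chromosome.
#' @param map_length_cm Genetic length per chromosome in centimorgans; the
#'   default 100 cM gives on average one recombination per chromosome and
#'   meiosis.
#' @param fst Balding-Nichols divergence between the breeds; the default 0.25
#'   emulates distantly related breeds.
#' @param n_founders Founders per breed.
#' @param n_generations Generations of random mating within each breed after
#'   the founders; creates the within-breed haplotype sharing that makes
#'   window haplotypes breed-characteristic.
#' @param n_purebred Named vector: genotyped animals per purebred line.
#' @param n_f1 Number of F1 animals (half LR x LW, half LW x LR).
#' @param n_cross3 Number of three-way cross animals.
#' @param genotype_error_rate Per-allele flip probability.
#' @param switch_error_rate Per-heterozygous-site phasing switch probability.
#' @param base_freq_range Range of the ancestral allele frequencies (drawn
#'   uniformly per SNP).
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5,
                       n_snps = 2000,
                       map_length_cm = 100,
                       fst = 0.25,
                       n_founders = 50,
                       n_generations = 8,
                       n_purebred = c(S = 500, LR = 500, LW = 500),
                       n_f1 = 200,
                       n_cross3 = 200,
                       genotype_error_rate = 0,
                       switch_error_rate = 0,
                       base_freq_range = c(0.1, 0.9),
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory in sim_config()")
  stopifnot(fst > 0, fst < 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            switch_error_rate >= 0, switch_error_rate <= 1,
            n_chromosomes >= 1, n_snps >= 2, n_founders >= 2,
            all(n_purebred >= 1), n_f1 >= 1, n_cross3 >= 1)
  stopifnot(identical(sort(names(n_purebred)), sort(BREEDS)))
  structure(as.list(environment()), class = "sim_config")
}

#' Draw diverged per-breed allele frequencies
#'
#' Balding-Nichols model: each breed's frequency at a SNP is an independent
#' Beta draw with mean equal to the ancestral frequency p and variance
#' p(1-p) * fst.
#'
#' @param base_frequencies Ancestral allele frequencies in (0, 1).
#' @param fst Divergence parameter in (0, 1).
#' @param n_breeds Number of breeds to draw.
#' @param seed Optional seed.
#' @return Matrix of frequencies, SNPs x breeds.
#' @export
draw_breed_frequencies <- function(base_frequencies, fst, n_breeds = 3,
                                   seed = NULL) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  stopifnot(all(base_frequencies > 0), all(base_frequencies < 1))
  if (!is.null(seed)) set.seed(seed)
  p <- base_frequencies
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  n <- length(p)
  out <- matrix(0, nrow = n, ncol = n_breeds)
  for (k in seq_len(n_breeds)) out[, k] <- rbeta(n, a, b)
  out
}

# chromosome row-index blocks of a map, in map order
chrom_blocks <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean equal to the genetic
#' length in Morgans (Haldane's model, no interference); breakpoint positions
#' are uniform on the genetic map. The gamete alternates between the two
#' parental gametes at the breakpoints.
#'
#' @param h1,h2 The parent's two phased gametes (vectors over the map's SNPs).
#' @param map A [snp_map()] with cM positions.
#' @return A list: `gamete` (allele vector), `source` (1/2 per SNP: which
#'   parental gamete it came from), `breakpoints` (per chromosome, cM
#'   positions of the crossovers).
#' @export
meiosis <- function(h1, h2, map) {
  source <- integer(nrow(map))
  bps <- list()
  for (blk in chrom_blocks(map)) {
    cm <- map$pos_cm[blk]
    len <- max(cm) - min(cm)
    n_x <- rpois(1, len / 100)
    bp <- sort(runif(n_x, min(cm), max(cm)))
    start <- sample.int(2, 1)
    source[blk] <- ((start - 1L + findInterval(cm, bp)) %% 2L) + 1L
    bps[[length(bps) + 1]] <- bp
  }
  names(bps) <- unique(map$chrom)
  gamete <- ifelse(source == 1L, h1, h2)
  list(gamete = gamete, source = source, breakpoints = bps)
}

#' Simulate a purebred population by random mating
#'
#' Founder haplotypes are drawn site-wise from the breed's allele frequencies;
#' each subsequent generation is produced by random mating with meiosis, so
#' output animals carry mosaics of founder haplotypes and the breed shows
#' realistic within-breed haplotype sharing.
#'
#' @param frequencies Per-SNP allele frequencies of the breed.
#' @param n_founders Founders (generation 0).
#' @param n_generations Generations of random mating; 0 returns site-wise
#'   independent draws.
#' @param n_output Animals in the returned (final) generation.
#' @param map A [snp_map()].
#' @param prefix Prefix for animal identifiers.
#' @return A list: `haplotypes` ([haplotype_set()] of the final generation)
#'   and `pedigree` (internal tibble of matings, generation by generation).
#' @export
simulate_purebred_population <- function(frequencies, n_founders,
                                         n_generations, n_output, map,
                                         prefix = "A") {
  if (n_output < 1) stop("n_output must be >= 1")
  stopifnot(n_founders >= 2)
  n_snps <- nrow(map)
  draw_pool <- function(n) {
    h <- function() matrix(rbinom(n * n_snps, 1L, rep(frequencies, each = n)),
                           nrow = n)
    list(hap1 = h(), hap2 = h())
  }
  if (n_generations == 0) {
    pool <- draw_pool(n_output)
  } else {
    pool <- draw_pool(n_founders)
    sizes <- c(rep(n_founders, n_generations - 1), n_output)
    ped <- list()
    for (g in seq_len(n_generations)) {
      n_next <- sizes[g]
      n_par <- nrow(pool$hap1)
      sire <- sample.int(n_par, n_next, replace = TRUE)
      dam <- sample.int(n_par, n_next, replace = TRUE)
      clash <- dam == sire
      while (any(clash) && n_par > 1) {
        dam[clash] <- sample.int(n_par, sum(clash), replace = TRUE)
        clash <- dam == sire
      }
      nh1 <- matrix(0L, n_next, n_snps)
      nh2 <- matrix(0L, n_next, n_snps)
      for (i in seq_len(n_next)) {
        nh1[i, ] <- meiosis(pool$hap1[sire[i], ], pool$hap2[sire[i], ], map)$gamete
        nh2[i, ] <- meiosis(pool$hap1[dam[i], ], pool$hap2[dam[i], ], map)$gamete
      }
      ped[[g]] <- tibble::tibble(generation = g, offspring = seq_len(n_next),
                                 sire = sire, dam = dam)
      pool <- list(hap1 = nh1, hap2 = nh2)
    }
  }
  ids <- sprintf("%s%04d", prefix, seq_len(nrow(pool$hap1)))
  rownames(pool$hap1) <- rownames(pool$hap2) <- ids
  haps <- haplotype_set(pool$hap1, pool$hap2, map,
                        gamete_roles = "paternal_maternal")
  ped_tbl <- if (n_generations == 0) tibble::tibble() else dplyr::bind_rows(ped)
  list(haplotypes = haps, pedigree = ped_tbl)
}

#' Cross two parental pools
#'
#' Produces offspring whose paternal gamete is a meiosis product of a random
#' sire and whose maternal gamete is a meiosis product of a random dam, with
#' per-allele breed-of-origin truth propagated through the recombination
#' breakpoints. `design = "F1"` crosses two purebred pools; `design =
#' "CROSS3"` crosses a purebred sire pool onto F1 dams whose gamete-level
#' truth must be supplied.
#'
#' @param sires,dams [haplotype_set()] pools of the parents.
#' @param n_offspring Number of offspring.
#' @param design `"F1"` or `"CROSS3"`.
#' @param sire_origin A single breed label (purebred sire pool), or a list
#'   with character matrices `track1`, `track2` (animals x SNPs) giving the
#'   per-allele origin of each sire gamete.
#' @param dam_origin Same, for the dams; for `design = "CROSS3"` this must be
#'   the gamete-level truth of the F1 dams.
#' @param prefix Prefix for offspring identifiers.
#' @return A list: `haplotypes` (offspring [haplotype_set()], gamete 1
#'   paternal), `truth` (an [origin_matrix()]-shaped truth track, never
#'   `UNKNOWN`), `pedigree` (tibble rows: animal, sire, dam).
#' @export
make_cross <- function(sires, dams, n_offspring, design = c("F1", "CROSS3"),
                       sire_origin, dam_origin, prefix = "X") {
  design <- match.arg(design)
  if (design == "CROSS3" && !is.list(dam_origin)) {
    stop("CROSS3 requires F1 dams with gamete-level origin truth")
  }
  map <- sires$map
  n_snps <- nrow(map)
  origin_of <- function(origin, idx, source) {
    if (is.character(origin) && length(origin) == 1) {
      rep(origin, n_snps)
    } else {
      ifelse(source == 1L, origin$track1[idx, ], origin$track2[idx, ])
    }
  }
  hp <- matrix(0L, n_offspring, n_snps)
  hm <- matrix(0L, n_offspring, n_snps)
  tp <- matrix("", n_offspring, n_snps)
  tm <- matrix("", n_offspring, n_snps)
  si <- sample.int(nrow(sires$hap1), n_offspring, replace = TRUE)
  di <- sample.int(nrow(dams$hap1), n_offspring, replace = TRUE)
  for (i in seq_len(n_offspring)) {
    ms <- meiosis(sires$hap1[si[i], ], sires$hap2[si[i], ], map)
    md <- meiosis(dams$hap1[di[i], ], dams$hap2[di[i], ], map)
    hp[i, ] <- ms$gamete
    hm[i, ] <- md$gamete
    tp[i, ] <- origin_of(sire_origin, si[i], ms$source)
    tm[i, ] <- origin_of(dam_origin, di[i], md$source)
  }
  ids <- sprintf("%s%04d", prefix, seq_len(n_offspring))
  rownames(hp) <- rownames(hm) <- rownames(tp) <- rownames(tm) <- ids
  haps <- haplotype_set(hp, hm, map, gamete_roles = "paternal_maternal")
  truth <- origin_matrix(tp, tm, map, provenance = list(design = design))
  ped <- tibble::tibble(animal = ids,
                        sire = animals(sires)[si],
                        dam = animals(dams)[di],
                        population = design)
  list(haplotypes = haps, truth = truth, pedigree = ped)
}

#' Inject genotype and phasing-switch errors
#'
#' Each allele is flipped independently with probability
#' `genotype_error_rate`. Independently, at each heterozygous site of an
#' animal, with probability `switch_error_rate` the two gametes are exchanged
#' from that site to the end of the chromosome (a phasing switch error;
#' switches at homozygous sites are unobservable and not simulated). Truth
#' tracks are never modified.
#'
#' @param haps A [haplotype_set()].
#' @param genotype_error_rate,switch_error_rate Rates in `[0, 1]`.
#' @return A new [haplotype_set()] with errors applied.
#' @export
inject_errors <- function(haps, genotype_error_rate = 0.01,
                          switch_error_rate = 0.01) {
  stopifnot(genotype_error_rate >= 0, genotype_error_rate <= 1,
            switch_error_rate >= 0, switch_error_rate <= 1)
  h1 <- haps$hap1
  h2 <- haps$hap2
  if (genotype_error_rate > 0) {
    for (nm in c("h1", "h2")) {
      h <- get(nm)
      flip <- matrix(runif(length(h)) < genotype_error_rate, nrow = nrow(h))
      flip[is.na(h)] <- FALSE
      h[flip] <- 1L - h[flip]
      assign(nm, h)
    }
  }
  if (switch_error_rate > 0) {
    blocks <- chrom_blocks(haps$map)
    for (i in seq_len(nrow(h1))) {
      for (blk in blocks) {
        het <- blk[which(h1[i, blk] != h2[i, blk])]
        if (length(het) == 0) next
        sw <- het[runif(length(het)) < switch_error_rate]
        if (length(sw) == 0) next
        swapped <- blk[(findInterval(blk, sw) %% 2L) == 1L]
        tmp <- h1[i, swapped]
        h1[i, swapped] <- h2[i, swapped]
        h2[i, swapped] <- tmp
      }
    }
  }
  haplotype_set(h1, h2, haps$map, gamete_roles = unname(haps$gamete_roles))
}

#' Mask genotypes down to a lower-density panel
#'
#' Sets the dosages of all SNPs not on the given panel to missing, emulating
#' the masking protocol used to validate imputation.
#'
#' @param genotypes Integer animals x SNPs dosage matrix.
#' @param panel_snp_ids SNP identifiers to keep.
#' @param map The [snp_map()] aligned with `genotypes`.
#' @return The masked dosage matrix.
#' @export
mask_to_panel <- function(genotypes, panel_snp_ids, map) {
  unknown <- setdiff(panel_snp_ids, map$snp_id)
  if (length(unknown) > 0) {
    stop("panel SNP id(s) not on the map: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  out <- genotypes
  out[, !(map$snp_id %in% panel_snp_ids)] <- NA_integer_
  out
}

#' Simulate a full three-way-cross study
#'
#' Runs the whole generator: ancestral frequencies, Balding-Nichols breed
#' divergence, random-mating purebred histories for S, LR and LW, reciprocal
#' F1 = LR x LW dams, terminal CROSS3 = S x F1 offspring with exact
#' per-allele breed-of-origin truth, and optional genotype/switch error
#' injection into the observed haplotypes (truth is kept clean).
#'
#' @param config A [sim_config()].
#' @return A list: `map`, `haplotypes` (all animals; purebreds, F1 and
#'   CROSS3), `pedigree` (validated tibble), `breeds` (named vector:
#'   population label per animal), `truth` (CROSS3 truth [origin_matrix()]),
#'   `f1_truth` (F1 gamete-level truth), `breed_frequencies`, `config`.
#' @export
simulate_three_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- config$n_chromosomes * config$n_snps
  base <- runif(n_total, config$base_freq_range[1], config$base_freq_range[2])
  freqs <- draw_breed_frequencies(base, config$fst, n_breeds = 3)
  colnames(freqs) <- BREEDS
  chrom_len_bp <- as.integer(round(config$map_length_cm * 1e6))
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(chrom_len_bp, config$n_snps))
    tibble::tibble(chrom = as.character(ch), pos_bp = pos)
  })
  mm <- dplyr::bind_rows(maps)
  map <- snp_map(mm$chrom, mm$pos_bp)

  pure <- lapply(BREEDS, function(b) {
    simulate_purebred_population(freqs[, b], config$n_founders,
                                 config$n_generations,
                                 config$n_purebred[[b]], map, prefix = b)
  })
  names(pure) <- BREEDS

  # reciprocal F1: half LR sires x LW dams, half LW sires x LR dams
  n_a <- ceiling(config$n_f1 / 2)
  n_b <- config$n_f1 - n_a
  f1a <- make_cross(pure$LR$haplotypes, pure$LW$haplotypes, n_a,
                    design = "F1", sire_origin = "LR", dam_origin = "LW",
                    prefix = "F1A")
  f1_parts <- list(f1a)
  if (n_b > 0) {
    f1b <- make_cross(pure$LW$haplotypes, pure$LR$haplotypes, n_b,
                      design = "F1", sire_origin = "LW", dam_origin = "LR",
                      prefix = "F1B")
    f1_parts <- c(f1_parts, list(f1b))
  }
  f1_haps <- do.call(bind_haplotypes, lapply(f1_parts, `[[`, "haplotypes"))
  f1_truth <- list(
    track1 = do.call(rbind, lapply(f1_parts, function(p) p$truth$paternal)),
    track2 = do.call(rbind, lapply(f1_parts, function(p) p$truth$maternal)))

  x3 <- make_cross(pure$S$haplotypes, f1_haps, config$n_cross3,
                   design = "CROSS3", sire_origin = "S",
                   dam_origin = f1_truth, prefix = "X")

  haps <- bind_haplotypes(pure$S$haplotypes, pure$LR$haplotypes,
                          pure$LW$haplotypes, f1_haps, x3$haplotypes)
  if (config$genotype_error_rate > 0 || config$switch_error_rate > 0) {
    haps <- inject_errors(haps, config$genotype_error_rate,
                          config$switch_error_rate)
  }

  ped <- dplyr::bind_rows(
    tibble::tibble(animal = animals(pure$S$haplotypes), sire = NA_character_,
                   dam = NA_character_, population = "S"),
    tibble::tibble(animal = animals(pure$LR$haplotypes), sire = NA_character_,
                   dam = NA_character_, population = "LR"),
    tibble::tibble(animal = animals(pure$LW$haplotypes), sire = NA_character_,
                   dam = NA_character_, population = "LW"),
    dplyr::bind_rows(lapply(f1_parts, `[[`, "pedigree")) |>
      dplyr::mutate(population = "F1"),
    x3$pedigree)
  ped <- validate_pedigree(ped)
  breeds <- setNames(ped$population, ped$animal)

  list(map = map, haplotypes = haps, pedigree = ped, breeds = breeds,
       truth = x3$truth, f1_truth = f1_truth,
       breed_frequencies = freqs, config = config)
}
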