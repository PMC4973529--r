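# Method core: haplotype library over purebreds, breed assignment of window
# haplotypes with the relaxation factor, window matching for crossbreds,
# gamete parentage, per-allele votes under zygosity/breed-composition
# constraints, and consensus.

# per-chromosome haplotype strings for one gamete matrix ('9' = missing)
hap_strings <- function(h, blocks) {
  ch <- h
  storage.mode(ch) <- "character"
  ch[is.na(ch)] <- "9"
  lapply(blocks, function(blk) {
    do.call(paste0, lapply(blk, function(j) ch[, j]))
  })
}

# substring of every gamete's chromosome string for a window given global
# 0-based half-open indices
window_keys <- function(chr_strings, blocks_start, cores_row) {
  ch <- cores_row$chrom
  s <- cores_row$snp_start - blocks_start[[ch]] + 1L
  e <- cores_row$snp_end - blocks_start[[ch]]
  substr(chr_strings[[ch]], s, e)
}

#' Assign a breed to a haplotype from its purebred copy counts
#'
#' A haplotype is assigned the breed holding the majority of its purebred
#' copies, provided that breed holds at least `(100 - f_r)` percent of all
#' copies and the total copy count is at least `min_copies`; otherwise the
#' breed-of-origin is unknown. `f_r` is the relaxation factor: the maximum
#' percentage of copies that may be observed in other purebred populations.
#'
#' @param counts Numeric vector of 3 (S, LR, LW), or a matrix with those
#'   three columns (one haplotype per row).
#' @param f_r Relaxation percentage in `[0, 100]`, default 20.
#' @param min_copies Minimum total purebred copies, default 1.
#' @return Character vector of labels (`S`, `LR`, `LW` or `UNKNOWN`).
#' @export
assign_haplotype_breed <- function(counts, f_r = 20, min_copies = 1) {
  stopifnot(f_r >= 0, f_r <= 100)
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == 3, all(counts >= 0))
  tot <- rowSums(counts)
  mx <- pmax(counts[, 1], counts[, 2], counts[, 3])
  n_at_max <- (counts[, 1] == mx) + (counts[, 2] == mx) + (counts[, 3] == mx)
  ok <- tot >= min_copies & 100 * mx >= (100 - f_r) * tot & n_at_max == 1 & tot > 0
  lab <- rep(UNKNOWN, nrow(counts))
  lab[ok] <- BREEDS[max.col(counts, ties.method = "first")][ok]
  lab
}

#' Match crossbred window haplotypes to a window's library
#'
#' An exact match wins; otherwise the unique library haplotype at minimal
#' mismatch fraction (over the query's non-missing positions) within
#' `max_mismatch_fraction` is returned. Two library haplotypes tied at the
#' minimal distance, or no qualifying haplotype, give no match.
#'
#' @param queries Character vector of window haplotypes (`0`/`1`, `9` for a
#'   missing allele).
#' @param library_haplotypes Character vector of the window's library
#'   haplotypes (no missing alleles).
#' @param max_mismatch_fraction Tolerance, default 0.01 (echoing the 1
#'   percent genotype-error allowance of the phasing the window scheme
#'   derives from); 0 demands exact agreement over non-missing positions.
#' @return Integer vector: index into `library_haplotypes`, `NA` = no match.
#' @export
match_crossbred_window <- function(queries, library_haplotypes,
                                   max_mismatch_fraction = 0.01) {
  stopifnot(max_mismatch_fraction >= 0, max_mismatch_fraction <= 1)
  idx <- match_windows_cpp(queries, library_haplotypes, max_mismatch_fraction)
  idx[idx == 0L] <- NA_integer_
  idx
}

#' Build the purebred haplotype library
#'
#' For every window of every configuration, each gamete of each purebred
#' animal contributes one copy of its window allele sequence to its breed's
#' count; gametes with a missing allele anywhere in the window contribute
#' nothing to that window.
#'
#' @param haps A [haplotype_set()] of purebred animals only.
#' @param breeds Named character vector: breed (`S`/`LR`/`LW`) per animal.
#' @param configs Window configurations, see [default_window_configs()].
#' @return A tibble: `config_id`, `chrom`, `snp_start`, `snp_end`,
#'   `haplotype`, `n_S`, `n_LR`, `n_LW`.
#' @export
build_haplotype_library <- function(haps, breeds,
                                    configs = default_window_configs()) {
  ids <- animals(haps)
  breeds <- breeds[ids]
  if (any(is.na(breeds)) || !all(breeds %in% BREEDS)) {
    stop("all animals must be labelled with a purebred population (S/LR/LW)")
  }
  blocks <- chrom_blocks(haps$map)
  blocks_start <- vapply(blocks, function(b) b[1] - 1L, integer(1))
  s1 <- hap_strings(haps$hap1, blocks)
  s2 <- hap_strings(haps$hap2, blocks)
  gam_breed <- factor(c(breeds, breeds), levels = BREEDS)
  out <- list()
  for (k in seq_len(nrow(configs))) {
    cores <- define_cores(haps$map, configs$core_length[k], configs$offset[k])
    for (w in seq_len(nrow(cores))) {
      keys <- c(window_keys(s1, blocks_start, cores[w, ]),
                window_keys(s2, blocks_start, cores[w, ]))
      lib <- window_counts(keys, gam_breed)
      if (nrow(lib) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        config_id = configs$config_id[k], chrom = cores$chrom[w],
        snp_start = cores$snp_start[w], snp_end = cores$snp_end[w],
        haplotype = lib$haplotype, n_S = lib$n_S, n_LR = lib$n_LR,
        n_LW = lib$n_LW)
    }
  }
  dplyr::bind_rows(out)
}

# distinct complete window haplotypes with per-breed gamete copy counts
window_counts <- function(keys, gam_breed) {
  valid <- !grepl("9", keys, fixed = TRUE)
  if (!any(valid)) {
    return(tibble::tibble(haplotype = character(), n_S = integer(),
                          n_LR = integer(), n_LW = integer()))
  }
  f <- factor(keys[valid])
  b <- gam_breed[valid]
  tibble::tibble(haplotype = levels(f),
                 n_S = tabulate(f[b == "S"], nbins = nlevels(f)),
                 n_LR = tabulate(f[b == "LR"], nbins = nlevels(f)),
                 n_LW = tabulate(f[b == "LW"], nbins = nlevels(f)))
}

#' Serialize / read a haplotype library
#'
#' Tab-separated with a header; the library can be reused across runs without
#' rebuilding it from the purebred reference.
#'
#' @param library The tibble from [build_haplotype_library()].
#' @param path File path.
#' @return `read_haplotype_library()` returns the library tibble.
#' @export
write_haplotype_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_library
#' @export
read_haplotype_library <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = c(haplotype = "character"),
                                      stringsAsFactors = FALSE))
}

#' Infer which gamete of each crossbred is paternal
#'
#' Without a pedigree, the gamete carrying the larger genome-wide number of
#' windows labelled with the terminal sire breed S (summed over all
#' configurations) is declared paternal; a tie, including zero S windows on
#' both gametes, leaves the animal unordered and all its alleles unassigned.
#' A pedigree-derived orientation, when available, takes precedence; a
#' conflict with the S-majority rule is kept (pedigree wins) and counted.
#'
#' @param s_windows_g1,s_windows_g2 Integer vectors: per animal, the number
#'   of S-labelled windows on gamete 1 and gamete 2.
#' @param pedigree_orientation Optional integer vector (1 or 2, `NA` if
#'   unknown): which gamete the pedigree says is paternal.
#' @return A tibble: `orientation` (1/2/`NA`), `source`
#'   (`pedigree`/`s_majority`/`unordered`), `conflict` (logical).
#' @export
infer_gamete_parentage <- function(s_windows_g1, s_windows_g2,
                                   pedigree_orientation = NULL) {
  n <- length(s_windows_g1)
  maj <- rep(NA_integer_, n)
  maj[s_windows_g1 > s_windows_g2] <- 1L
  maj[s_windows_g2 > s_windows_g1] <- 2L
  orientation <- maj
  source <- ifelse(is.na(maj), "unordered", "s_majority")
  conflict <- rep(FALSE, n)
  if (!is.null(pedigree_orientation)) {
    use <- !is.na(pedigree_orientation)
    conflict[use] <- !is.na(maj[use]) & maj[use] != pedigree_orientation[use]
    orientation[use] <- pedigree_orientation[use]
    source[use] <- "pedigree"
  }
  tibble::tibble(orientation = orientation, source = source,
                 conflict = conflict)
}

#' Collect per-allele breed-of-origin votes for crossbred animals
#'
#' The full voting stage: builds the purebred window library for every
#' configuration, matches each crossbred gamete's window haplotypes to it,
#' assigns window breeds under the relaxation factor, infers which gamete is
#' paternal, and turns window labels into per-allele votes under the breed
#' composition of the cross (the paternal gamete of a three-way cross only
#' accepts the sire breed S, the maternal gamete only LR or LW; an F1 gamete
#' only its own purebred parent's breed) and the zygosity completion rule:
#' whenever the allele on the other gamete receives a vote at a locus and
#' this gamete admits a single breed, this gamete's allele receives that
#' breed's vote in the same configuration.
#'
#' @param haps A [haplotype_set()] holding purebred and crossbred animals.
#' @param breeds Named character vector per animal: `S`, `LR`, `LW`, `F1` or
#'   `CROSS3`.
#' @param pedigree Optional validated pedigree; enables pedigree-based gamete
#'   orientation and F1 per-gamete breed constraints.
#' @param configs Window configurations ([default_window_configs()]).
#' @param f_r Relaxation percentage, default 20.
#' @param min_copies Minimum purebred copies for a haplotype to be
#'   assignable, default 1.
#' @param max_mismatch_fraction Window matching tolerance, default 0.01.
#' @return An object of class `boa_votes`: per-breed vote-count matrices per
#'   oriented gamete, parentage, and provenance.
#' @export
assign_allele_origins <- function(haps, breeds, pedigree = NULL,
                                  configs = default_window_configs(),
                                  f_r = 20, min_copies = 1,
                                  max_mismatch_fraction = 0.01) {
  ids <- animals(haps)
  breeds <- breeds[ids]
  if (any(is.na(breeds))) stop("every animal needs a population label")
  pure_ids <- ids[breeds %in% BREEDS]
  cross_ids <- ids[breeds %in% c("F1", "CROSS3")]
  if (length(pure_ids) == 0) stop("no purebred animals: library impossible")
  missing_breed <- setdiff(BREEDS, unique(breeds[pure_ids]))
  if (length(missing_breed) > 0) {
    stop("no purebred animals of breed ",
         paste(missing_breed, collapse = ", "), ": library impossible")
  }
  if (length(cross_ids) == 0) stop("no crossbred (F1/CROSS3) animals to assign")
  map <- haps$map
  n_snps <- nrow(map)
  n_cross <- length(cross_ids)
  blocks <- chrom_blocks(map)
  blocks_start <- vapply(blocks, function(b) b[1] - 1L, integer(1))

  pure <- subset_animals(haps, pure_ids)
  cross <- subset_animals(haps, cross_ids)
  gam_breed <- factor(rep(breeds[pure_ids], 2), levels = BREEDS)
  ps1 <- hap_strings(pure$hap1, blocks)
  ps2 <- hap_strings(pure$hap2, blocks)
  cs1 <- hap_strings(cross$hap1, blocks)
  cs2 <- hap_strings(cross$hap2, blocks)

  # stage 1: per config, per window, a breed label for each crossbred gamete
  n_cfg <- nrow(configs)
  lab1 <- vector("list", n_cfg)
  lab2 <- vector("list", n_cfg)
  win_of_snp <- vector("list", n_cfg)
  for (k in seq_len(n_cfg)) {
    cores <- define_cores(map, configs$core_length[k], configs$offset[k])
    nw <- nrow(cores)
    l1 <- matrix(UNKNOWN, n_cross, nw)
    l2 <- matrix(UNKNOWN, n_cross, nw)
    for (w in seq_len(nw)) {
      lib <- window_counts(
        c(window_keys(ps1, blocks_start, cores[w, ]),
          window_keys(ps2, blocks_start, cores[w, ])), gam_breed)
      if (nrow(lib) == 0) next
      lib_lab <- assign_haplotype_breed(
        cbind(lib$n_S, lib$n_LR, lib$n_LW), f_r = f_r,
        min_copies = min_copies)
      k1 <- window_keys(cs1, blocks_start, cores[w, ])
      k2 <- window_keys(cs2, blocks_start, cores[w, ])
      uq <- unique(c(k1, k2))
      hit <- match(uq, lib$haplotype)
      todo <- which(is.na(hit))
      if (length(todo) > 0) {
        hit[todo] <- match_crossbred_window(uq[todo], lib$haplotype,
                                            max_mismatch_fraction)
      }
      uq_lab <- ifelse(is.na(hit), UNKNOWN, lib_lab[hit])
      l1[, w] <- uq_lab[match(k1, uq)]
      l2[, w] <- uq_lab[match(k2, uq)]
    }
    lab1[[k]] <- l1
    lab2[[k]] <- l2
    win_of_snp[[k]] <- rep.int(seq_len(nw), cores$snp_end - cores$snp_start)
  }

  # stage 2: gamete parentage
  s1 <- Reduce(`+`, lapply(lab1, function(l) rowSums(l == "S")))
  s2 <- Reduce(`+`, lapply(lab2, function(l) rowSums(l == "S")))
  ped_orient <- pedigree_orientation(haps, breeds, pedigree, cross_ids)
  parentage <- infer_gamete_parentage(s1, s2, ped_orient)
  parentage <- dplyr::mutate(parentage, animal = cross_ids, .before = 1)

  # per-gamete admissible breeds: CROSS3 paternal {S}, maternal {LR, LW};
  # F1 paternal {sire breed}, maternal {dam breed} (needs a pedigree)
  allowed <- gamete_constraints(breeds, cross_ids, pedigree)

  # stage 3: expand window labels to per-allele votes and accumulate counts.
  # Element-wise comparison of an (animals x SNPs) matrix with a per-animal
  # vector recycles the vector down the columns, i.e. per animal, as needed.
  orient <- parentage$orientation
  o1 <- !is.na(orient) & orient == 1L
  o2 <- !is.na(orient) & orient == 2L
  cnt_pat <- matrix(0L, n_cross, n_snps)   # votes for the paternal breed
  cnt_mat_LR <- matrix(0L, n_cross, n_snps)
  cnt_mat_LW <- matrix(0L, n_cross, n_snps)
  for (k in seq_len(n_cfg)) {
    vp <- matrix(UNKNOWN, n_cross, n_snps)
    vm <- matrix(UNKNOWN, n_cross, n_snps)
    vp[o1, ] <- lab1[[k]][o1, win_of_snp[[k]], drop = FALSE]
    vp[o2, ] <- lab2[[k]][o2, win_of_snp[[k]], drop = FALSE]
    vm[o1, ] <- lab2[[k]][o1, win_of_snp[[k]], drop = FALSE]
    vm[o2, ] <- lab1[[k]][o2, win_of_snp[[k]], drop = FALSE]
    # breed-composition constraint: discard inadmissible proposals
    vp_keep <- vp == allowed$pat_breed
    mat_ok <- (!allowed$mat_single & (vm == "LR" | vm == "LW")) |
      (allowed$mat_single & vm == allowed$mat_breed)
    mat_ok[is.na(mat_ok)] <- FALSE
    vm[!mat_ok] <- UNKNOWN
    # zygosity completion: a vote on the maternal allele fixes the paternal
    # allele to the (unique) paternal breed in the same configuration
    pat_vote <- vp_keep | vm != UNKNOWN
    # symmetric completion when the maternal breed set is a singleton (F1)
    if (any(allowed$mat_single)) {
      fill <- allowed$mat_single & vp_keep & vm == UNKNOWN
      vm[fill] <- matrix(allowed$mat_breed, n_cross, n_snps)[fill]
    }
    cnt_pat <- cnt_pat + pat_vote
    cnt_mat_LR <- cnt_mat_LR + (vm == "LR")
    cnt_mat_LW <- cnt_mat_LW + (vm == "LW")
  }
  structure(list(pat_count = cnt_pat, mat_LR = cnt_mat_LR,
                 mat_LW = cnt_mat_LW,
                 pat_breed = allowed$pat_breed,
                 parentage = parentage, animals = cross_ids, map = map,
                 provenance = list(f_r = f_r, min_copies = min_copies,
                                   max_mismatch_fraction = max_mismatch_fraction,
                                   pedigree_used = !is.null(pedigree),
                                   n_configs = n_cfg,
                                   parentage_conflicts = sum(parentage$conflict))),
            class = "boa_votes")
}

# orientation (which gamete is paternal) from pedigree information:
# trust carried gamete roles when a pedigree confirms parentage; otherwise
# trio-phase against genotyped parents and pick the more consistent gamete.
pedigree_orientation <- function(haps, breeds, pedigree, cross_ids) {
  if (is.null(pedigree)) return(NULL)
  orient <- rep(NA_integer_, length(cross_ids))
  roles <- haps$gamete_roles[cross_ids]
  orient[roles == "paternal_maternal"] <- 1L
  todo <- which(is.na(orient))
  if (length(todo) > 0) {
    dos <- dosage_matrix(haps)
    ped <- pedigree[match(cross_ids, pedigree$animal), ]
    for (i in todo) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (is.na(s) || is.na(d) || !(s %in% rownames(dos)) ||
          !(d %in% rownames(dos))) next
      tp <- trio_phase(dos[cross_ids[i], ], dos[s, ], dos[d, ])
      dec <- !is.na(tp$paternal)
      if (!any(dec)) next
      a1 <- sum(haps$hap1[cross_ids[i], dec] == tp$paternal[dec], na.rm = TRUE)
      a2 <- sum(haps$hap2[cross_ids[i], dec] == tp$paternal[dec], na.rm = TRUE)
      if (a1 > a2) orient[i] <- 1L else if (a2 > a1) orient[i] <- 2L
    }
  }
  orient
}

# admissible breeds per oriented gamete of each crossbred animal
gamete_constraints <- function(breeds, cross_ids, pedigree) {
  n <- length(cross_ids)
  pat_breed <- rep("S", n)
  mat_single <- rep(FALSE, n)
  mat_breed <- rep(NA_character_, n)
  is_f1 <- breeds[cross_ids] == "F1"
  if (any(is_f1)) {
    if (is.null(pedigree)) {
      stop("assigning F1 animals requires a pedigree (per-gamete parent breeds)")
    }
    pop <- setNames(pedigree$population, pedigree$animal)
    ped <- pedigree[match(cross_ids, pedigree$animal), ]
    sire_b <- unname(pop[ped$sire])
    dam_b <- unname(pop[ped$dam])
    bad <- is_f1 & (is.na(sire_b) | is.na(dam_b))
    if (any(bad)) {
      stop("F1 animal(s) without genotyped/labelled parents: ",
           paste(head(cross_ids[bad], 5), collapse = ", "))
    }
    pat_breed[is_f1] <- sire_b[is_f1]
    mat_single[is_f1] <- TRUE
    mat_breed[is_f1] <- dam_b[is_f1]
  }
  list(pat_breed = pat_breed, mat_single = mat_single, mat_breed = mat_breed)
}

#' Consensus breed-of-origin over the per-configuration votes
#'
#' Under the default `strict` rule an allele is assigned a breed if and only
#' if it received at least one vote and all its votes agree; any conflict
#' leaves it unknown. Under `majority`, the modal breed is assigned when its
#' share of the allele's votes is at least `majority_threshold` (a tie never
#' assigns). Animals whose gametes could not be ordered are entirely
#' unassigned.
#'
#' @param votes A `boa_votes` object from [assign_allele_origins()].
#' @param vote_rule `"strict"` (default) or `"majority"`.
#' @param majority_threshold Minimal vote share under `majority`, default 0.5.
#' @return An [origin_matrix()] for the crossbred animals.
#' @export
consensus_origins <- function(votes, vote_rule = c("strict", "majority"),
                              majority_threshold = 0.5) {
  vote_rule <- match.arg(vote_rule)
  n <- length(votes$animals)
  n_snps <- nrow(votes$map)
  pat <- matrix(UNKNOWN, n, n_snps, dimnames = list(votes$animals, NULL))
  mat <- matrix(UNKNOWN, n, n_snps, dimnames = list(votes$animals, NULL))
  ordered <- !is.na(votes$parentage$orientation)
  # paternal votes are all for the animal's unique paternal breed
  pat_assigned <- votes$pat_count > 0 & ordered
  pat[pat_assigned] <- matrix(votes$pat_breed, n, n_snps)[pat_assigned]
  lr <- votes$mat_LR
  lw <- votes$mat_LW
  if (vote_rule == "strict") {
    mat[lr > 0 & lw == 0 & ordered] <- "LR"
    mat[lw > 0 & lr == 0 & ordered] <- "LW"
  } else {
    tot <- lr + lw
    mat[tot > 0 & lr > lw & lr >= majority_threshold * tot & ordered] <- "LR"
    mat[tot > 0 & lw > lr & lw >= majority_threshold * tot & ordered] <- "LW"
  }
  origin_matrix(pat, mat, votes$map,
                provenance = c(votes$provenance,
                               list(vote_rule = vote_rule,
                                    majority_threshold =
                                      if (vote_rule == "majority")
                                        majority_threshold else NA)))
}

#' Assign breed-of-origin of alleles, end to end
#'
#' Convenience wrapper running [assign_allele_origins()] followed by
#' [consensus_origins()]: library construction over the purebreds under all
#' window configurations, window matching for the crossbreds, relaxation-
#' factor breed assignment, gamete parentage, composition- and zygosity-
#' constrained voting, and consensus.
#'
#' @inheritParams assign_allele_origins
#' @inheritParams consensus_origins
#' @return A list of class `boa_result`: `origins` (an [origin_matrix()]),
#'   `votes` (the `boa_votes` object), `parentage` (a tibble).
#' @export
assign_breed_origin <- function(haps, breeds, pedigree = NULL,
                                configs = default_window_configs(),
                                f_r = 20, min_copies = 1,
                                max_mismatch_fraction = 0.01,
                                vote_rule = c("strict", "majority"),
                                majority_threshold = 0.5) {
  votes <- assign_allele_origins(haps, breeds, pedigree = pedigree,
                                 configs = configs, f_r = f_r,
                                 min_copies = min_copies,
                                 max_mismatch_fraction = max_mismatch_fraction)
  origins <- consensus_origins(votes, vote_rule = vote_rule,
                               majority_threshold = majority_threshold)
  structure(list(origins = origins, votes = votes,
                 parentage = votes$parentage),
            class = "boa_result")
}

#' @export
print.boa_result <- function(x, ...) {
  print(x$origins)
  p <- x$origins$provenance
  cat("  f_r = ", p$f_r, "%, vote rule ", p$vote_rule, ", pedigree ",
      if (p$pedigree_used) "used" else "not used", ", ",
      p$n_configs, " window configurations\n", sep = "")
  invisible(x)
}
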