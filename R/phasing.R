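#' Phase one offspring from its parents' genotypes
#'
#' Mendelian trio phasing: at each site the two alleles of the child are
#' assigned to the paternal and maternal gamete wherever the logic is
#' decisive — the child is homozygous, or the child is heterozygous and at
#' least one parent is homozygous (both parents genotyped). Undecidable sites
#' (all three heterozygous, or a missing parent genotype) are set missing on
#' both gametes. Mendelian-inconsistent sites are set missing and counted,
#' never "corrected".
#'
#' @param child,sire,dam Dosage vectors (0/1/2, `NA` missing) on one map.
#' @return A list: `paternal`, `maternal` (0/1/`NA` allele vectors),
#'   `n_inconsistent`, and `inconsistent` (logical per site).
#' @export
trio_phase <- function(child, sire, dam) {
  n <- length(child)
  stopifnot(length(sire) == n, length(dam) == n)
  pat <- rep(NA_integer_, n)
  mat <- rep(NA_integer_, n)
  hom <- function(g) !is.na(g) & g != 1L
  incons <- (!is.na(child) & child == 0L & ((!is.na(sire) & sire == 2L) |
                                              (!is.na(dam) & dam == 2L))) |
    (!is.na(child) & child == 2L & ((!is.na(sire) & sire == 0L) |
                                      (!is.na(dam) & dam == 0L))) |
    (!is.na(child) & child == 1L & hom(sire) & hom(dam) & sire == dam)
  i0 <- !is.na(child) & child == 0L & !incons
  i2 <- !is.na(child) & child == 2L & !incons
  pat[i0] <- 0L; mat[i0] <- 0L
  pat[i2] <- 1L; mat[i2] <- 1L
  het <- !is.na(child) & child == 1L & !incons & !is.na(sire) & !is.na(dam)
  hs <- het & hom(sire)
  pat[hs] <- sire[hs] %/% 2L
  mat[hs] <- 1L - pat[hs]
  hd <- het & !hom(sire) & hom(dam)
  mat[hd] <- dam[hd] %/% 2L
  pat[hd] <- 1L - mat[hd]
  list(paternal = pat, maternal = mat,
       n_inconsistent = sum(incons), inconsistent = incons)
}

#' Switch-error rate of an estimated phasing against truth
#'
#' For each animal, the fraction of consecutive pairs of evaluable
#' heterozygous sites (within a chromosome) whose relative phase in the
#' estimate disagrees with the truth. A global exchange of the two gametes
#' changes no relative phase and yields rate 0. Sites that are missing, or
#' not heterozygous in both estimate and truth, are skipped.
#'
#' @param estimated,truth [haplotype_set()]s over the same animals and map;
#'   the truth must be fully phased.
#' @return A tibble: `animal`, `n_pairs`, `n_switches`, `rate` (`NA` when an
#'   animal has fewer than two evaluable heterozygous sites).
#' @export
switch_error_rate <- function(estimated, truth) {
  stopifnot(identical(animals(estimated), animals(truth)),
            ncol(estimated$hap1) == ncol(truth$hap1))
  blocks <- chrom_blocks(estimated$map)
  ids <- animals(estimated)
  res <- purrr::map(seq_along(ids), function(i) {
    n_pairs <- 0L
    n_sw <- 0L
    for (blk in blocks) {
      e1 <- estimated$hap1[i, blk]; e2 <- estimated$hap2[i, blk]
      t1 <- truth$hap1[i, blk];     t2 <- truth$hap2[i, blk]
      use <- !is.na(e1) & !is.na(e2) & !is.na(t1) & !is.na(t2) &
        e1 != e2 & t1 != t2
      if (sum(use) < 2) next
      ph <- e1[use] == t1[use]  # gamete-1 agreement at each het site
      n_pairs <- n_pairs + length(ph) - 1L
      n_sw <- n_sw + sum(ph[-1] != ph[-length(ph)])
    }
    tibble::tibble(animal = ids[i], n_pairs = n_pairs, n_switches = n_sw,
                   rate = if (n_pairs > 0) n_sw / n_pairs else NA_real_)
  })
  dplyr::bind_rows(res)
}
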