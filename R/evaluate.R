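# Metrics over origin matrices (assignment accounting, scenario comparison),
# imputation accuracy, and G-matrix PCA screening.

#' Per-animal assignment accounting
#'
#' For every crossbred animal, the percentage of its alleles (two per SNP)
#' assigned a breed-of-origin, split by gamete and by breed. With a truth
#' track, the percentage of correct labels among the assigned alleles is
#' added. Animals (or chromosomes, with `by_chromosome = TRUE`) below the
#' assignment threshold are flagged.
#'
#' @param origins An [origin_matrix()].
#' @param truth Optional truth track of the same shape (never unknown).
#' @param by_chromosome Split the accounting per chromosome?
#' @param threshold Flag when the assigned percentage falls below this value
#'   (default 80).
#' @return A tibble with one row per animal (or animal x chromosome):
#'   `pct_assigned`, `pct_paternal`, `pct_maternal`, `pct_S`, `pct_LR`,
#'   `pct_LW`, `pct_correct` (`NA` without truth or without assigned
#'   alleles), `low_assignment`.
#' @export
assignment_stats <- function(origins, truth = NULL, by_chromosome = FALSE,
                             threshold = 80) {
  if (!is.null(truth)) {
    stopifnot(identical(dim(origins$paternal), dim(truth$paternal)))
  }
  map <- origins$map
  groups <- if (by_chromosome) chrom_blocks(map) else
    list(genome = seq_len(nrow(map)))
  ids <- animals(origins)
  res <- list()
  for (g in seq_along(groups)) {
    j <- groups[[g]]
    pat <- origins$paternal[, j, drop = FALSE]
    mat <- origins$maternal[, j, drop = FALSE]
    n_alleles <- 2 * length(j)
    a_pat <- unname(rowSums(pat != UNKNOWN))
    a_mat <- unname(rowSums(mat != UNKNOWN))
    cnt <- function(b) unname(rowSums(pat == b) + rowSums(mat == b))
    pct_correct <- rep(NA_real_, length(ids))
    if (!is.null(truth)) {
      tp <- truth$paternal[, j, drop = FALSE]
      tm <- truth$maternal[, j, drop = FALSE]
      n_corr <- unname(rowSums(pat != UNKNOWN & pat == tp) +
                         rowSums(mat != UNKNOWN & mat == tm))
      n_ass <- a_pat + a_mat
      pct_correct[n_ass > 0] <- 100 * n_corr[n_ass > 0] / n_ass[n_ass > 0]
    }
    tbl <- tibble::tibble(
      animal = ids,
      n_alleles = n_alleles,
      pct_assigned = 100 * (a_pat + a_mat) / n_alleles,
      pct_paternal = 100 * a_pat / n_alleles,
      pct_maternal = 100 * a_mat / n_alleles,
      pct_S = 100 * cnt("S") / n_alleles,
      pct_LR = 100 * cnt("LR") / n_alleles,
      pct_LW = 100 * cnt("LW") / n_alleles,
      pct_correct = pct_correct)
    tbl$low_assignment <- tbl$pct_assigned < threshold
    if (by_chromosome) tbl <- dplyr::mutate(tbl, chrom = names(groups)[g],
                                            .after = "animal")
    res[[g]] <- tbl
  }
  dplyr::bind_rows(res)
}

#' Summarise assignment over animals
#'
#' Mean and standard deviation (across animals) of the per-animal assignment
#' percentages, in the layout of a per-scenario summary table.
#'
#' @param stats The tibble from [assignment_stats()].
#' @return A one-row tibble of means with `sd_` columns.
#' @export
summarize_assignment <- function(stats) {
  num <- c("pct_assigned", "pct_paternal", "pct_maternal",
           "pct_S", "pct_LR", "pct_LW", "pct_correct")
  means <- lapply(stats[num], mean, na.rm = TRUE)
  sds <- lapply(stats[num], stats::sd, na.rm = TRUE)
  names(sds) <- paste0("sd_", num)
  tibble::as_tibble(c(list(n_animals = length(unique(stats$animal))),
                      means, sds))
}

#' Cross-classify two assignment scenarios
#'
#' Per-allele comparison of two origin matrices over the same animals and
#' SNPs: concordance (same breed, or unassigned in both), assigned in the
#' first scenario only, assigned in the second only, and disagreement (both
#' assigned, different breeds). The four percentages sum to 100.
#'
#' @param a,b [origin_matrix()] objects of identical shape.
#' @return A one-row tibble with counts and percentages of each category.
#' @export
compare_scenarios <- function(a, b) {
  if (!identical(dim(a$paternal), dim(b$paternal)) ||
      !identical(animals(a), animals(b))) {
    stop("the two origin matrices must cover the same animals and SNPs")
  }
  la <- c(a$paternal, a$maternal)
  lb <- c(b$paternal, b$maternal)
  aa <- la != UNKNOWN
  ab <- lb != UNKNOWN
  n <- length(la)
  n_conc <- sum(la == lb | (!aa & !ab))
  n_a_only <- sum(aa & !ab)
  n_b_only <- sum(!aa & ab)
  n_dis <- sum(aa & ab & la != lb)
  tibble::tibble(
    n_alleles = n,
    concordance = 100 * n_conc / n,
    assigned_a_only = 100 * n_a_only / n,
    assigned_b_only = 100 * n_b_only / n,
    disagreement = 100 * n_dis / n)
}

#' Imputation accuracy: concordance and MAF-corrected correlation
#'
#' Compares imputed against observed genotypes at the evaluated (masked)
#' loci. Concordance is the fraction of identical genotype codes, per SNP
#' (across animals) and per animal (across SNPs). The Pearson correlation is
#' computed between genotypes corrected for minor allele frequency, i.e.
#' `genotype - 2*MAF`, with the MAF estimated from the observed genotypes of
#' the evaluated animals. Per SNP the correction is a constant shift and
#' leaves the correlation unchanged; per animal (across SNPs) it re-centres
#' every SNP and does matter, so both are reported. SNPs with concordance
#' below `flag_below` are flagged for removal.
#'
#' @param real,imputed Integer dosage matrices (animals x SNPs) of identical
#'   shape; `NA` entries (in either) are excluded site-wise.
#' @param map Optional [snp_map()] supplying SNP identifiers.
#' @param flag_below Per-SNP concordance threshold, default 0.80.
#' @return A list of class `imputation_metrics`: `per_snp` and `per_animal`
#'   tibbles. Correlations on zero-variance vectors are reported `NA`.
#' @export
imputation_metrics <- function(real, imputed, map = NULL, flag_below = 0.80) {
  stopifnot(identical(dim(real), dim(imputed)))
  use <- !is.na(real) & !is.na(imputed)
  p <- colSums(real * use, na.rm = TRUE) / (2 * pmax(colSums(use), 1L))
  maf <- pmin(p, 1 - p)
  safe_cor <- function(x, y) {
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else cor(x, y)
  }
  n_an <- nrow(real)
  n_snp <- ncol(real)
  snp_conc <- snp_cor <- numeric(n_snp)
  for (j in seq_len(n_snp)) {
    i <- use[, j]
    if (!any(i)) { snp_conc[j] <- NA_real_; snp_cor[j] <- NA_real_; next }
    snp_conc[j] <- mean(real[i, j] == imputed[i, j])
    snp_cor[j] <- safe_cor(real[i, j] - 2 * maf[j], imputed[i, j] - 2 * maf[j])
  }
  an_conc <- an_cor <- numeric(n_an)
  for (i in seq_len(n_an)) {
    j <- use[i, ]
    if (!any(j)) { an_conc[i] <- NA_real_; an_cor[i] <- NA_real_; next }
    an_conc[i] <- mean(real[i, j] == imputed[i, j])
    an_cor[i] <- safe_cor(real[i, j] - 2 * maf[j], imputed[i, j] - 2 * maf[j])
  }
  snp_id <- if (!is.null(map)) map$snp_id else
    colnames(real) %||% paste0("snp", seq_len(n_snp))
  structure(list(
    per_snp = tibble::tibble(snp_id = snp_id, maf = maf,
                             concordance = snp_conc, correlation = snp_cor,
                             flagged = !is.na(snp_conc) &
                               snp_conc < flag_below),
    per_animal = tibble::tibble(animal = rownames(real) %||%
                                  paste0("animal", seq_len(n_an)),
                                concordance = an_conc, correlation = an_cor)),
    class = "imputation_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Yang-style genomic relationship matrix
#'
#' Off-diagonal entries average, over SNPs, the products of genotypes centred
#' by twice the allele frequency and scaled by `2p(1-p)`; diagonal entries
#' use the dedicated estimator `1 + (x^2 - (1+2p)x + 2p^2) / (2p(1-p))`
#' averaged over SNPs. Monomorphic SNPs are skipped and counted.
#'
#' @param genotypes Integer dosage matrix (animals x SNPs), no missing
#'   values.
#' @param frequencies Optional per-SNP allele frequencies; estimated from
#'   `genotypes` when absent.
#' @return A list: `G` (animals x animals), `n_snps_used`, `n_monomorphic`.
#' @export
grm_yang <- function(genotypes, frequencies = NULL) {
  X <- genotypes
  storage.mode(X) <- "double"
  p <- frequencies %||% (colMeans(X) / 2)
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(X)
  if (m == 0) stop("no polymorphic SNPs")
  den <- 2 * p * (1 - p)
  W <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(den), "/")
  G <- tcrossprod(W) / m
  # Yang diagonal: 1 + mean_i (x^2 - (1+2p)x + 2p^2) / (2p(1-p))
  num <- X^2 - sweep(X, 2, 1 + 2 * p, "*") + rep(2 * p^2, each = nrow(X))
  diag(G) <- 1 + rowMeans(sweep(num, 2, den, "/"))
  list(G = G, n_snps_used = m, n_monomorphic = sum(!poly))
}

#' PCA of the G-matrix with population-outlier flagging
#'
#' Eigendecomposition of the Yang-style genomic relationship matrix;
#' component scores are eigenvectors scaled by the square roots of their
#' eigenvalues. Within each labelled population, every animal gets a robust
#' z-score per leading component (distance to the population median in
#' units of the population's median absolute deviation); an animal is
#' flagged when its largest component z-score exceeds `k`, the usual
#' smartpca-style rule for detecting individuals that do not belong to
#' their labelled cluster. A single deviating component is what mislabelling
#' produces (a purebred recorded as a cross shifts along the axis separating
#' its true line), while the cross population legitimately spreads along the
#' maternal-line axis, so the per-component rule is used rather than a
#' pooled Euclidean distance.
#'
#' @param genotypes Integer dosage matrix (animals x SNPs).
#' @param labels Named character vector: population label per animal.
#' @param n_components Number of leading components, default 3.
#' @param k Robust z-score threshold, default 6 (the conventional
#'   6-standard-deviation cut).
#' @return A list of class `boa_pca`: `scores` tibble (`animal`, `label`,
#'   `PC1..`, `dist` = the largest component z-score, `flagged`),
#'   `var_explained`, `n_monomorphic`.
#' @export
grm_pca_outliers <- function(genotypes, labels, n_components = 3, k = 6) {
  ids <- rownames(genotypes) %||% paste0("animal", seq_len(nrow(genotypes)))
  if (!is.null(names(labels))) labels <- labels[ids]
  g <- grm_yang(genotypes)
  e <- eigen(g$G, symmetric = TRUE)
  nc <- min(n_components, sum(e$values > 1e-8))
  sc <- e$vectors[, seq_len(nc), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(nc)]), nc)
  colnames(sc) <- paste0("PC", seq_len(nc))
  dist <- numeric(length(ids))
  flagged <- logical(length(ids))
  for (lab in unique(labels)) {
    i <- which(labels == lab)
    z <- vapply(seq_len(nc), function(cmp) {
      v <- sc[i, cmp]
      s <- stats::mad(v)
      if (s < 1e-12) s <- stats::sd(v) + 1e-12
      abs(v - median(v)) / s
    }, numeric(length(i)))
    z <- matrix(z, nrow = length(i))
    d <- apply(z, 1, max)
    dist[i] <- d
    flagged[i] <- d > k
  }
  scores <- tibble::as_tibble(as.data.frame(sc))
  scores <- dplyr::mutate(scores, animal = ids, label = unname(labels),
                          dist = dist, flagged = flagged, .before = 1)
  structure(list(scores = scores,
                 var_explained = e$values / sum(pmax(e$values, 0)),
                 n_monomorphic = g$n_monomorphic),
            class = "boa_pca")
}
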