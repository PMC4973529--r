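#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a breed-of-origin result
#'
#' @param x A `boa_result` from [assign_breed_origin()].
#' @param truth Optional truth track; adds `pct_correct`.
#' @param ... Passed to [assignment_stats()].
#' @return Per-animal assignment tibble.
#' @method tidy boa_result
#' @export
tidy.boa_result <- function(x, truth = NULL, ...) {
  assignment_stats(x$origins, truth = truth, ...)
}

#' One-row summary of a breed-of-origin result
#'
#' @param x A `boa_result`.
#' @param ... Unused.
#' @return A one-row tibble: animal/SNP counts, overall assignment
#'   percentages, and the settings used.
#' @method glance boa_result
#' @export
glance.boa_result <- function(x, ...) {
  st <- summarize_assignment(assignment_stats(x$origins))
  p <- x$origins$provenance
  tibble::tibble(
    n_animals = st$n_animals,
    n_snps = ncol(x$origins$paternal),
    pct_assigned = st$pct_assigned,
    pct_paternal = st$pct_paternal,
    pct_maternal = st$pct_maternal,
    f_r = p$f_r, vote_rule = p$vote_rule,
    pedigree_used = p$pedigree_used,
    n_unordered = sum(is.na(x$parentage$orientation)),
    parentage_conflicts = p$parentage_conflicts)
}

#' Tidy a G-matrix PCA
#'
#' @param x A `boa_pca` from [grm_pca_outliers()].
#' @param ... Unused.
#' @return The per-animal score tibble.
#' @method tidy boa_pca
#' @export
tidy.boa_pca <- function(x, ...) x$scores

#' @method glance boa_pca
#' @export
glance.boa_pca <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$scores),
                 n_flagged = sum(x$scores$flagged),
                 var_pc1 = x$var_explained[1],
                 var_pc2 = x$var_explained[2],
                 var_pc3 = x$var_explained[3],
                 n_monomorphic = x$n_monomorphic)
}

#' Tidy imputation metrics
#'
#' @param x An `imputation_metrics` object.
#' @param unit `"snp"` or `"animal"`.
#' @param ... Unused.
#' @return The per-SNP or per-animal tibble.
#' @method tidy imputation_metrics
#' @export
tidy.imputation_metrics <- function(x, unit = c("snp", "animal"), ...) {
  unit <- match.arg(unit)
  if (unit == "snp") x$per_snp else x$per_animal
}

#' @method glance imputation_metrics
#' @export
glance.imputation_metrics <- function(x, ...) {
  tibble::tibble(
    mean_snp_concordance = mean(x$per_snp$concordance, na.rm = TRUE),
    mean_snp_correlation = mean(x$per_snp$correlation, na.rm = TRUE),
    mean_animal_concordance = mean(x$per_animal$concordance, na.rm = TRUE),
    mean_animal_correlation = mean(x$per_animal$correlation, na.rm = TRUE),
    n_flagged_snps = sum(x$per_snp$flagged, na.rm = TRUE))
}
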