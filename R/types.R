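#' @useDynLib crossboa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rbinom rbeta rpois runif median cor setNames
#' @importFrom utils head tail
"_PACKAGE"

# Breed labels used throughout: the terminal sire line S and the two maternal
# lines LR (Landrace) and LW (Large White). UNKNOWN is the only label that may
# mean "not assigned".
BREEDS <- c("S", "LR", "LW")
UNKNOWN <- "UNKNOWN"
POPULATIONS <- c("S", "LR", "LW", "F1", "CROSS3")

#' Build a SNP map
#'
#' A SNP map records, in genome order, the chromosome, physical position and
#' (optionally) genetic position of every SNP. All other containers in the
#' package are column-aligned with a map.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param pos_bp Integer vector of physical positions in base pairs; strictly
#'   increasing within a chromosome.
#' @param pos_cm Optional numeric genetic positions in centimorgans,
#'   non-decreasing within a chromosome. When `NULL`, positions are derived
#'   from `pos_bp` at 1 cM/Mb.
#' @param snp_id Optional SNP identifiers; generated as `chrom_pos` when absent.
#' @return A tibble of class `snp_map` with columns `chrom`, `pos_bp`,
#'   `pos_cm`, `snp_id`.
#' @export
snp_map <- function(chrom, pos_bp, pos_cm = NULL, snp_id = NULL) {
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (is.null(pos_cm)) pos_cm <- pos_bp * 1e-6
  if (is.null(snp_id)) snp_id <- paste0(chrom, "_", pos_bp)
  map <- tibble::tibble(chrom = chrom, pos_bp = pos_bp,
                        pos_cm = as.numeric(pos_cm),
                        snp_id = as.character(snp_id))
  validate_snp_map(map)
  class(map) <- c("snp_map", class(map))
  map
}

validate_snp_map <- function(map) {
  stopifnot(all(c("chrom", "pos_bp", "pos_cm", "snp_id") %in% names(map)))
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE)) {
      stop("SNP positions are not strictly increasing on chromosome ", ch)
    }
    if (is.unsorted(sub$pos_cm)) {
      stop("cM positions are not non-decreasing on chromosome ", ch)
    }
  }
  if (anyDuplicated(paste(map$chrom, map$pos_bp))) {
    stop("duplicated (chromosome, position) pairs in SNP map")
  }
  invisible(map)
}

#' Construct a phased haplotype set
#'
#' Holds the two phased allele sequences (gametes) of each animal, aligned to
#' a SNP map. Allele codes are 0/1 with `NA` for missing; when the gametes of
#' an animal are ordered, gamete 1 is the paternal and gamete 2 the maternal
#' gamete.
#'
#' @param hap1,hap2 Integer matrices (animals x SNPs) of 0/1/`NA` allele
#'   codes; rownames are animal identifiers.
#' @param map A [snp_map()] with one row per column of the matrices.
#' @param gamete_roles Per-animal `"paternal_maternal"` (gamete 1 paternal) or
#'   `"unordered"`.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(hap1, hap2, map,
                          gamete_roles = rep("unordered", nrow(hap1))) {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            identical(dim(hap1), dim(hap2)),
            ncol(hap1) == nrow(map),
            !is.null(rownames(hap1)))
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  rownames(hap2) <- rownames(hap1)
  ok <- hap1 %in% c(0L, 1L, NA)
  stopifnot(all(ok))
  stopifnot(all(hap2 %in% c(0L, 1L, NA)))
  gamete_roles <- match.arg(gamete_roles, c("unordered", "paternal_maternal"),
                            several.ok = TRUE)
  gamete_roles <- rep_len(gamete_roles, nrow(hap1))
  structure(list(hap1 = hap1, hap2 = hap2, map = map,
                 gamete_roles = setNames(gamete_roles, rownames(hap1))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$hap1), " animals x ", ncol(x$hap1),
      " SNPs (", length(unique(x$map$chrom)), " chromosomes), ",
      sum(x$gamete_roles == "paternal_maternal"), " with ordered gametes\n",
      sep = "")
  invisible(x)
}

#' Animal identifiers of a container
#' @param x A `haplotype_set`, `origin_matrix` or genotype matrix.
#' @return Character vector of animal ids.
#' @export
animals <- function(x) UseMethod("animals")
#' @export
animals.haplotype_set <- function(x) rownames(x$hap1)
#' @export
animals.origin_matrix <- function(x) rownames(x$paternal)
#' @export
animals.default <- function(x) rownames(x)

#' Genotype dosages of a haplotype set
#'
#' @param haps A [haplotype_set()].
#' @return Integer matrix (animals x SNPs) of 0/1/2 dosages, `NA` where either
#'   gamete is missing.
#' @export
dosage_matrix <- function(haps) {
  haps$hap1 + haps$hap2
}

#' Subset a haplotype set by animal
#' @param haps A [haplotype_set()].
#' @param ids Animal identifiers (or logical/integer index).
#' @return A `haplotype_set` with the selected animals.
#' @export
subset_animals <- function(haps, ids) {
  if (is.character(ids)) ids <- match(ids, animals(haps))
  haplotype_set(haps$hap1[ids, , drop = FALSE],
                haps$hap2[ids, , drop = FALSE],
                haps$map,
                gamete_roles = unname(haps$gamete_roles[ids]))
}

#' Combine haplotype sets sharing one SNP map
#' @param ... `haplotype_set` objects on the same map.
#' @return One `haplotype_set` with the animals stacked.
#' @export
bind_haplotypes <- function(...) {
  sets <- list(...)
  map <- sets[[1]]$map
  haplotype_set(do.call(rbind, lapply(sets, `[[`, "hap1")),
                do.call(rbind, lapply(sets, `[[`, "hap2")),
                map,
                gamete_roles = unlist(lapply(sets, function(s) unname(s$gamete_roles))))
}

#' Construct a breed-of-origin matrix
#'
#' Per animal, per gamete and per SNP, the assigned breed label. For the
#' three-way cross design only `S`/`UNKNOWN` can appear on the paternal gamete
#' and only `LR`/`LW`/`UNKNOWN` on the maternal gamete.
#'
#' @param paternal,maternal Character matrices (animals x SNPs) of labels in
#'   `S`, `LR`, `LW`, `UNKNOWN`; rownames are animal ids.
#' @param map The [snp_map()] the columns align with.
#' @param provenance Named list recording how the matrix was produced (e.g.
#'   `f_r`, vote rule, pedigree use).
#' @return An object of class `origin_matrix`.
#' @export
origin_matrix <- function(paternal, maternal, map, provenance = list()) {
  stopifnot(is.matrix(paternal), identical(dim(paternal), dim(maternal)),
            ncol(paternal) == nrow(map),
            nrow(paternal) == 0 || !is.null(rownames(paternal)))
  if (is.null(rownames(paternal))) rownames(paternal) <- character(0)
  bad <- !(paternal %in% c(BREEDS, UNKNOWN)) | !(maternal %in% c(BREEDS, UNKNOWN))
  if (any(bad)) stop("invalid breed label in origin matrix")
  rownames(maternal) <- rownames(paternal)
  structure(list(paternal = paternal, maternal = maternal, map = map,
                 provenance = provenance),
            class = "origin_matrix")
}

#' @export
print.origin_matrix <- function(x, ...) {
  n <- length(x$paternal) + length(x$maternal)
  assigned <- sum(x$paternal != UNKNOWN) + sum(x$maternal != UNKNOWN)
  cat("<origin_matrix> ", nrow(x$paternal), " animals x ", ncol(x$paternal),
      " SNPs; ", sprintf("%.1f%%", 100 * assigned / n), " of alleles assigned\n",
      sep = "")
  invisible(x)
}

#' Validate a pedigree table
#'
#' Checks population labels, asserts the three-way cross structure (F1 animals
#' have one LR and one LW parent, three-way cross animals an S sire and an F1
#' dam, when those parents are present in the table) and rejects cycles.
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam`, `population`;
#'   unknown parents as `NA` or `"0"`.
#' @return The pedigree as a validated tibble.
#' @export
validate_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam", "population") %in% names(ped)))
  ped$animal <- as.character(ped$animal)
  ped$sire <- dplyr::na_if(as.character(ped$sire), "0")
  ped$dam <- dplyr::na_if(as.character(ped$dam), "0")
  bad <- setdiff(unique(ped$population), POPULATIONS)
  if (length(bad) > 0) {
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  pop <- setNames(ped$population, ped$animal)
  check_parent <- function(rows, parent, allowed, what) {
    p <- ped[[parent]][rows]
    known <- !is.na(p) & p %in% names(pop)
    wrong <- known & !(pop[p] %in% allowed)
    if (any(wrong)) {
      stop(what, " for animal(s) ", paste(ped$animal[rows][wrong], collapse = ", "))
    }
  }
  i3 <- which(ped$population == "CROSS3")
  check_parent(i3, "sire", "S", "three-way cross animal without an S sire")
  check_parent(i3, "dam", "F1", "three-way cross animal without an F1 dam")
  if1 <- which(ped$population == "F1")
  check_parent(if1, "sire", c("LR", "LW"), "F1 animal without an LR/LW sire")
  check_parent(if1, "dam", c("LR", "LW"), "F1 animal without an LR/LW dam")
  # cycle check: repeatedly peel animals whose parents are all peeled
  remaining <- setNames(rep(TRUE, nrow(ped)), ped$animal)
  repeat {
    idx <- which(remaining)
    if (length(idx) == 0) break
    peelable <- vapply(idx, function(i) {
      ps <- c(ped$sire[i], ped$dam[i])
      ps <- ps[!is.na(ps) & ps %in% names(remaining)]
      all(!remaining[ps])
    }, logical(1))
    if (!any(peelable)) {
      stop("pedigree contains a cycle involving: ",
           paste(head(names(remaining)[remaining], 5), collapse = ", "))
    }
    remaining[idx[peelable]] <- FALSE
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}
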