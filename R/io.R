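#' Read phased genotypes from a VCF file
#'
#' Reads a phased, biallelic SNP VCF into the package's containers. Unphased
#' or half-missing calls are set to missing on both gametes of that animal at
#' that site, since downstream haplotype matching needs known gametes.
#' Records on chromosomes named `X` or `Y` are dropped with a warning;
#' only autosomes are analysed.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @return A list with elements `map` ([snp_map()]), `haplotypes`
#'   ([haplotype_set()]) and `dosages` (integer animals x SNPs matrix).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | nchar(fix$REF) != 1 |
    nchar(fix$ALT) != 1
  if (any(multi)) {
    stop("non-biallelic-SNP record(s) at: ",
         paste(head(paste0(fix$CHROM, ":", fix$POS)[multi], 5), collapse = ", "))
  }
  sex <- toupper(fix$CHROM) %in% c("X", "Y", "CHRX", "CHRY", "SSCX", "SSCY")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(sex)) {
    warning("dropping ", sum(sex), " record(s) on sex chromosomes")
    fix <- fix[!sex, , drop = FALSE]
    gt <- gt[!sex, , drop = FALSE]
  }
  pos <- as.integer(fix$POS)
  for (ch in unique(fix$CHROM)) {
    if (is.unsorted(pos[fix$CHROM == ch], strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  map <- snp_map(fix$CHROM, pos, snp_id = ifelse(
    is.na(fix$ID) | fix$ID == ".", paste0(fix$CHROM, "_", pos), fix$ID))
  # decode GT strings via a lookup over the distinct values present
  codes <- unique(as.vector(gt))
  a1 <- rep(NA_integer_, length(codes))
  a2 <- rep(NA_integer_, length(codes))
  phased <- grepl("^[01]\\|[01]$", codes)
  a1[phased] <- as.integer(substr(codes[phased], 1, 1))
  a2[phased] <- as.integer(substr(codes[phased], 3, 3))
  idx <- match(gt, codes)
  hap1 <- matrix(a1[idx], nrow = nrow(gt))
  hap2 <- matrix(a2[idx], nrow = nrow(gt))
  # vcfR is SNPs x samples; containers are animals x SNPs
  hap1 <- t(hap1); hap2 <- t(hap2)
  rownames(hap1) <- rownames(hap2) <- colnames(gt)
  haps <- haplotype_set(hap1, hap2, map)
  list(map = map, haplotypes = haps, dosages = dosage_matrix(haps))
}

#' Write a haplotype set as a phased VCF
#'
#' Emits a minimal VCFv4.2 with GT-only genotypes; alleles 0/1 map to REF `A`
#' and ALT `C`, missing gametes to `.`.
#'
#' @param haps A [haplotype_set()].
#' @param path Output path.
#' @export
write_phased_vcf <- function(haps, path) {
  map <- haps$map
  ids <- animals(haps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(map$chrom), ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  g1 <- t(haps$hap1); g2 <- t(haps$hap2)  # SNPs x animals
  gs <- matrix(paste0(ifelse(is.na(g1), ".", g1), "|",
                      ifelse(is.na(g2), ".", g2)), nrow = nrow(g1))
  gs[is.na(g1) | is.na(g2)] <- ".|."
  body <- paste(map$chrom, map$pos_bp, map$snp_id, "A", "C", ".", "PASS", ".",
                "GT", sep = "\t")
  writeLines(paste(body, apply(gs, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read a pedigree table
#'
#' Accepts a comma- or whitespace-delimited table with header columns
#' `animal`, `sire`, `dam`, `population`; population labels must be one of
#' `S`, `LR`, `LW`, `F1`, `CROSS3`. Unknown parents are written as `NA`, `0`
#' or an empty field.
#'
#' @param path Path to the table.
#' @return A validated pedigree tibble (see [validate_pedigree()]).
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  ped <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(ped) <- tolower(names(ped))
  validate_pedigree(ped)
}

#' Write a pedigree table
#' @param ped A pedigree tibble.
#' @param path Output path (CSV).
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' Write breed-of-origin tracks as a BED-like table
#'
#' One row per maximal run of a constant breed label on one gamete of one
#' animal: tab-separated columns `chrom`, `start_bp`, `end_bp` (half-open,
#' ending one past the last SNP of the run), `animal`, `gamete`
#' (`paternal`/`maternal`), `breed`. `UNKNOWN` runs are written too, so the
#' file round-trips losslessly through [read_origin_track()].
#'
#' @param origins An [origin_matrix()].
#' @param path Output path.
#' @export
write_origin_track <- function(origins, path) {
  utils::write.table(as.data.frame(origin_runs(origins)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximal constant-label runs of an origin matrix
#'
#' @param origins An [origin_matrix()].
#' @return A tibble: `chrom`, `start_bp`, `end_bp` (half-open), `animal`,
#'   `gamete`, `breed` — one row per maximal run of one label on one gamete.
#' @export
origin_runs <- function(origins) {
  map <- origins$map
  rows <- list()
  chroms <- unique(map$chrom)
  for (gamete in c("paternal", "maternal")) {
    m <- origins[[gamete]]
    for (a in rownames(m)) {
      for (ch in chroms) {
        j <- which(map$chrom == ch)
        labs <- m[a, j]
        r <- rle(labs)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = ch,
          start_bp = map$pos_bp[j][starts],
          end_bp = map$pos_bp[j][ends] + 1L,
          animal = a, gamete = gamete, breed = r$values)
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(chrom = character(), start_bp = integer(),
                   end_bp = integer(), animal = character(),
                   gamete = character(), breed = character())
}

#' Read breed-of-origin tracks written by [write_origin_track()]
#'
#' @param path Path to the track file.
#' @param map The [snp_map()] the track refers to.
#' @param provenance Optional provenance list to attach.
#' @return An [origin_matrix()].
#' @export
read_origin_track <- function(path, map, provenance = list()) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(tr$animal)
  blank <- matrix(UNKNOWN, nrow = length(ids), ncol = nrow(map),
                  dimnames = list(ids, NULL))
  mats <- list(paternal = blank, maternal = blank)
  for (gamete in c("paternal", "maternal")) {
    sub <- tr[tr$gamete == gamete, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      j <- which(map$chrom == sub$chrom[k] &
                   map$pos_bp >= sub$start_bp[k] & map$pos_bp < sub$end_bp[k])
      mats[[gamete]][sub$animal[k], j] <- sub$breed[k]
    }
  }
  origin_matrix(mats$paternal, mats$maternal, map, provenance = provenance)
}
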