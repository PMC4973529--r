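#' The default 18 haplotype window configurations
#'
#' The nine core:tail length combinations 350:50, 250:100, 300:100, 350:100,
#' 150:200, 200:200, 250:200, 300:200 and 350:200, each run in both the
#' NotOffset and the Offset mode (windows shifted by half a core length), so
#' that every allele can be considered 18 times through haplotypes of
#' variable length. Tail lengths are carried as metadata: they matter to the
#' long-range phasing tool the window scheme originates from, not to library
#' matching, which operates on core windows.
#'
#' @return A tibble: `config_id` (1..18), `core_length`, `tail_length`,
#'   `offset` (logical).
#' @export
default_window_configs <- function() {
  core <- c(350L, 250L, 300L, 350L, 150L, 200L, 250L, 300L, 350L)
  tail <- c(50L, 100L, 100L, 100L, 200L, 200L, 200L, 200L, 200L)
  tibble::tibble(config_id = 1:18,
                 core_length = rep(core, 2),
                 tail_length = rep(tail, 2),
                 offset = rep(c(FALSE, TRUE), each = 9))
}

#' Segment the genome into core windows
#'
#' Tiles every chromosome with consecutive windows of `core_length` SNPs; the
#' final window of a chromosome is truncated at the chromosome end. In offset
#' mode the tiling is shifted by half a core length and a leading half-length
#' window is emitted so that every SNP stays covered. Windows never span
#' chromosomes.
#'
#' @param map A [snp_map()].
#' @param core_length Window length in SNPs (at least 2).
#' @param offset Logical: shift the tiling by half a core?
#' @return A tibble: `chrom`, `snp_start`, `snp_end` (0-based half-open
#'   indices into the map rows, i.e. genome-wide SNP indices).
#' @export
define_cores <- function(map, core_length, offset = FALSE) {
  if (core_length < 2) stop("core_length must be at least 2")
  core_length <- as.integer(core_length)
  out <- lapply(chrom_blocks(map), function(blk) {
    n <- length(blk)
    base <- blk[1] - 1L  # global 0-based offset of this chromosome
    half <- core_length %/% 2L
    if (offset && half < n) {
      starts <- c(0L, seq.int(half, n - 1L, by = core_length))
    } else {
      starts <- seq.int(0L, n - 1L, by = core_length)
    }
    ends <- pmin(starts + c(diff(starts), core_length), n)
    tibble::tibble(chrom = map$chrom[blk[1]],
                   snp_start = base + starts, snp_end = base + ends)
  })
  dplyr::bind_rows(out)
}

#' Number of potential breed-of-origin votes per SNP
#'
#' Counts, for every SNP, the number of windows covering it across a set of
#' window configurations. With the default 18 configurations every SNP is
#' covered exactly once per configuration, so every allele has exactly 18
#' potential votes.
#'
#' @param map A [snp_map()].
#' @param configs A window-configuration tibble, see
#'   [default_window_configs()].
#' @return Integer vector, one count per map row.
#' @export
count_potential_votes <- function(map, configs = default_window_configs()) {
  counts <- integer(nrow(map))
  for (k in seq_len(nrow(configs))) {
    cores <- define_cores(map, configs$core_length[k], configs$offset[k])
    for (w in seq_len(nrow(cores))) {
      idx <- (cores$snp_start[w] + 1L):cores$snp_end[w]
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}
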