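# Independent brute-force reference for the method core: plain nested loops,
# no shared code with the package internals. Used to validate library
# construction, haplotype breed assignment and the full allele consensus.

oracle_windows <- function(map, core, offset) {
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    half <- core %/% 2
    if (offset && half < n) {
      starts <- c(0, seq(half, n - 1, by = core))
    } else {
      starts <- seq(0, n - 1, by = core)
    }
    for (s in starts) {
      e <- if (offset && s == 0 && half < n) half else min(s + core, n)
      res[[length(res) + 1]] <- list(chrom = ch, start = idx[1] - 1 + s,
                                     end = idx[1] - 1 + e,
                                     snps = idx[(s + 1):e])
    }
  }
  res
}

oracle_breed_of_counts <- function(cc, f_r, min_copies) {
  tot <- sum(cc)
  if (tot < min_copies || tot == 0) return("UNKNOWN")
  mx <- max(cc)
  if (sum(cc == mx) != 1) return("UNKNOWN")
  if (100 * mx < (100 - f_r) * tot) return("UNKNOWN")
  names(cc)[which.max(cc)]
}

oracle_window_library <- function(haps, breeds, snps) {
  keys <- character(0)
  counts <- list()
  for (a in animals(haps)) {
    for (g in 1:2) {
      h <- if (g == 1) haps$hap1[a, snps] else haps$hap2[a, snps]
      if (any(is.na(h))) next
      key <- paste(h, collapse = "")
      pos <- match(key, keys)
      if (is.na(pos)) {
        keys <- c(keys, key)
        counts[[length(counts) + 1]] <- c(S = 0, LR = 0, LW = 0)
        pos <- length(keys)
      }
      counts[[pos]][[breeds[[a]]]] <- counts[[pos]][[breeds[[a]]]] + 1
    }
  }
  list(keys = keys, counts = counts)
}

oracle_match <- function(h, lib_keys, tol) {
  inf <- !is.na(h)
  if (!any(inf) || length(lib_keys) == 0) return(NA_integer_)
  maxmm <- floor(tol * sum(inf) + 1e-9)
  d <- vapply(lib_keys, function(key) {
    lv <- as.integer(strsplit(key, "")[[1]])
    sum(lv[inf] != h[inf])
  }, numeric(1))
  qual <- which(d <= maxmm)
  if (length(qual) == 0) return(NA_integer_)
  dmin <- min(d[qual])
  best <- which(d == dmin)
  if (length(best) != 1) return(NA_integer_)
  best
}

# full pipeline: window labels -> S-majority parentage -> composition and
# zygosity constrained votes -> strict consensus, for CROSS3 animals only
oracle_boa <- function(haps, breeds, configs = default_window_configs(),
                       f_r = 20, min_copies = 1, tol = 0.01) {
  map <- haps$map
  ids <- animals(haps)
  pure_ids <- ids[breeds[ids] %in% c("S", "LR", "LW")]
  cross_ids <- ids[breeds[ids] == "CROSS3"]
  pure <- subset_animals(haps, pure_ids)
  pure_breeds <- breeds[pure_ids]
  n_cfg <- nrow(configs)
  win_sets <- lapply(seq_len(n_cfg), function(k) {
    oracle_windows(map, configs$core_length[k], configs$offset[k])
  })
  # window labels: labels[[k]][[g]] is animals x windows
  labels <- lapply(seq_len(n_cfg), function(k) {
    nw <- length(win_sets[[k]])
    list(matrix("UNKNOWN", length(cross_ids), nw),
         matrix("UNKNOWN", length(cross_ids), nw))
  })
  for (k in seq_len(n_cfg)) {
    for (w in seq_along(win_sets[[k]])) {
      snps <- win_sets[[k]][[w]]$snps
      lib <- oracle_window_library(pure, pure_breeds, snps)
      lib_breed <- vapply(lib$counts, oracle_breed_of_counts, character(1),
                          f_r = f_r, min_copies = min_copies)
      for (ci in seq_along(cross_ids)) {
        for (g in 1:2) {
          h <- if (g == 1) haps$hap1[cross_ids[ci], snps]
               else haps$hap2[cross_ids[ci], snps]
          m <- oracle_match(h, lib$keys, tol)
          if (!is.na(m)) labels[[k]][[g]][ci, w] <- lib_breed[m]
        }
      }
    }
  }
  # parentage by genome-wide S-window majority over all configurations
  n <- length(cross_ids)
  pat <- matrix("UNKNOWN", n, nrow(map), dimnames = list(cross_ids, NULL))
  mat <- matrix("UNKNOWN", n, nrow(map), dimnames = list(cross_ids, NULL))
  for (ci in seq_len(n)) {
    s1 <- sum(vapply(seq_len(n_cfg),
                     function(k) sum(labels[[k]][[1]][ci, ] == "S"), numeric(1)))
    s2 <- sum(vapply(seq_len(n_cfg),
                     function(k) sum(labels[[k]][[2]][ci, ] == "S"), numeric(1)))
    if (s1 == s2) next  # unordered: everything stays UNKNOWN
    pg <- if (s1 > s2) 1 else 2
    mg <- 3 - pg
    # per-allele votes
    votes_p <- matrix(0, 1, nrow(map))
    votes_lr <- matrix(0, 1, nrow(map))
    votes_lw <- matrix(0, 1, nrow(map))
    for (k in seq_len(n_cfg)) {
      for (w in seq_along(win_sets[[k]])) {
        snps <- win_sets[[k]][[w]]$snps
        lp <- labels[[k]][[pg]][ci, w]
        lm <- labels[[k]][[mg]][ci, w]
        pat_vote <- lp == "S"           # composition: paternal accepts only S
        lr_vote <- lm == "LR"           # maternal accepts only LR/LW
        lw_vote <- lm == "LW"
        if (lr_vote || lw_vote) pat_vote <- TRUE  # zygosity completion
        votes_p[snps] <- votes_p[snps] + pat_vote
        votes_lr[snps] <- votes_lr[snps] + lr_vote
        votes_lw[snps] <- votes_lw[snps] + lw_vote
      }
    }
    pat[ci, votes_p > 0] <- "S"  # strict: all paternal votes are S
    mat[ci, votes_lr > 0 & votes_lw == 0] <- "LR"
    mat[ci, votes_lw > 0 & votes_lr == 0] <- "LW"
  }
  origin_matrix(pat, mat, map)
}
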