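# Independent brute-force oracles used by module tests and the
# oracle-equivalence acceptance criterion. These deliberately use naive
# per-base / per-pair / per-cell algorithms, not the package's code paths.

suppressPackageStartupMessages({
  library(Biostrings)
})

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# O(n*w) direct windowed mean (centered, truncated)
oracle_rolling <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    l <- max(1, i - floor((w - 1) / 2))
    r <- min(n, i + ceiling((w - 1) / 2))
    mean(x[l:r])
  }, 0)
}

# O(n*m) pairwise overlap pruning
oracle_prune <- function(cand, prim, frac) {
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    w <- cand$end[i] - cand$start[i] + 1
    for (j in seq_len(nrow(prim))) {
      ov <- min(cand$end[i], prim$end[j]) -
        max(cand$start[i], prim$start[j]) + 1
      if (ov > 0 && ov / w > frac) return(FALSE)
    }
    TRUE
  }, TRUE)
  cand[keep, , drop = FALSE]
}

# per-base boolean-mask coding density and intergenic complement
oracle_mask <- function(orfs, region) {
  mask <- logical(region$end - region$start + 1)
  for (i in seq_len(nrow(orfs))) {
    a <- max(orfs$start[i], region$start) - region$start + 1
    b <- min(orfs$end[i], region$end) - region$start + 1
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

oracle_intergenic <- function(orfs, region, min_len) {
  mask <- oracle_mask(orfs, region)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- !r$values & r$lengths >= min_len
  data.frame(start = starts[keep] + region$start - 1,
             end = ends[keep] + region$start - 1)
}

# per-base pileup coverage, binned
oracle_coverage_bins <- function(aln, L, bin) {
  depth <- integer(L)
  for (i in seq_len(nrow(aln))) {
    a <- aln$tstart[i] + 1
    b <- aln$tend[i]
    depth[a:b] <- depth[a:b] + 1L
  }
  starts <- seq(1, L, by = bin)
  vapply(starts, function(s) mean(depth[s:min(s + bin - 1, L)]), 0)
}

# naive per-frame six-frame STOP-to-STOP scan
oracle_s2s_orfs <- function(seq_chr, min_aa) {
  out <- list()
  L <- nchar(seq_chr)
  rc <- as.character(reverseComplement(DNAString(seq_chr)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_chr else rc
    for (frame in 0:2) {
      run_start <- NA
      n_aa <- 0
      pos <- frame + 1
      while (pos + 2 <= L) {
        codon <- substr(s, pos, pos + 2)
        if (codon %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(run_start) && n_aa >= min_aa) {
            out[[length(out) + 1]] <- c(run_start, pos - 1, frame,
                                        strand == "+")
          }
          run_start <- NA
          n_aa <- 0
        } else {
          if (is.na(run_start)) run_start <- pos
          n_aa <- n_aa + 1
        }
        pos <- pos + 3
      }
      if (!is.na(run_start) && n_aa >= min_aa) {
        out[[length(out) + 1]] <- c(run_start, run_start + 3 * n_aa - 1,
                                    frame, strand == "+")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), strand = character(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2], frame = m[, 3],
                   strand = ifelse(m[, 4] == 1, "+", "-"))
  flip <- df$strand == "-"
  tmp <- df$start[flip]
  df$start[flip] <- L - df$end[flip] + 1
  df$end[flip] <- L - tmp + 1
  df <- df[order(df$start, df$end, df$strand, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# textbook affine-gap Smith-Waterman (Gotoh), naive cell-by-cell; a gap
# of length k costs open + k*ext, matching the package's convention
oracle_sw_score <- function(query, subject, open = 11, ext = 1) {
  B <- get_blosum62()
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H_prev <- numeric(m + 1)
  E_prev <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    H_row <- numeric(m + 1)
    E_row <- rep(-Inf, m + 1)
    F_val <- -Inf
    for (j in seq_len(m)) {
      E_row[j + 1] <- max(H_prev[j + 1] - (open + ext),
                          E_prev[j + 1] - ext)
      F_val <- max(H_row[j] - (open + ext), F_val - ext)
      H_row[j + 1] <- max(0, H_prev[j] + B[q[i], s[j]], E_row[j + 1],
                          F_val)
      if (H_row[j + 1] > best) best <- H_row[j + 1]
    }
    H_prev <- H_row
    E_prev <- E_row
  }
  best
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# best translated-search score for one nucleotide query against a db,
# via the DP oracle over all six frames and all subjects
oracle_translated_best <- function(query_chr, db_chr) {
  qs <- DNAString(query_chr)
  best <- 0
  for (s in list(qs, reverseComplement(qs))) {
    L <- length(s)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < 1) next
      aa <- as.character(suppressWarnings(translate(
        subseq(s, f + 1, f + 3 * n_cod), if.fuzzy.codon = "solve")))
      for (p in db_chr) {
        best <- max(best, oracle_sw_score(aa, p))
      }
    }
  }
  best
}
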