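# Insertion validation: junction-spanning reads, coverage, Hi-C contact
# enrichment, cross-strain comparison.

#' Detect junction-spanning reads
#'
#' A read witnesses a boundary iff a single contiguous alignment covers at
#' least `min_anchor` bp strictly inside the region and at least
#' `min_anchor` bp strictly outside it across that boundary. One read may
#' witness both boundaries. Strand-agnostic.
#'
#' @param alignments PAF-style data.frame (see [read_paf()]); target
#'   coordinates 0-based half-open
#' @param region single-row interval table (1-based inclusive) on the
#'   alignments' target contig
#' @param min_anchor minimum anchor on each side in bp (default 1000,
#'   above typical repeat-unit scale)
#' @return data.frame `read_id`, `boundary` (`left`/`right`), `viral_bp`,
#'   `host_bp`, sorted by read id then boundary
#' @export
detect_junction_reads <- function(alignments, region, min_anchor = 1000) {
  check_one_region(region)
  rs <- region$start; re <- region$end
  if (nrow(alignments) > 0 && any(alignments$tend > alignments$tlen)) {
    stop("alignment beyond contig bounds")
  }
  if (nrow(alignments) > 0 && re > alignments$tlen[1]) {
    stop("region outside contig bounds")
  }
  t1 <- alignments$tstart + 1 # 1-based inclusive
  t2 <- alignments$tend
  out <- list()
  # left boundary: host side [t1, rs-1], viral side [rs, min(t2, re)]
  covers_left <- t1 < rs & t2 >= rs
  host_l <- rs - t1
  viral_l <- pmin(t2, re) - rs + 1
  sel <- which(covers_left & host_l >= min_anchor & viral_l >= min_anchor)
  if (length(sel)) {
    out[[1]] <- data.frame(read_id = alignments$qname[sel],
                           boundary = "left", viral_bp = viral_l[sel],
                           host_bp = host_l[sel], stringsAsFactors = FALSE)
  }
  # right boundary: viral side [max(t1, rs), re], host side [re+1, t2]
  covers_right <- t1 <= re & t2 > re
  viral_r <- re - pmax(t1, rs) + 1
  host_r <- t2 - re
  sel <- which(covers_right & host_r >= min_anchor & viral_r >= min_anchor)
  if (length(sel)) {
    out[[length(out) + 1]] <-
      data.frame(read_id = alignments$qname[sel], boundary = "right",
                 viral_bp = viral_r[sel], host_bp = host_r[sel],
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(0), boundary = character(0),
                      viral_bp = numeric(0), host_bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$read_id, res$boundary), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-bin read coverage profile
#'
#' Mean per-base alignment depth in consecutive bins, plus the global mean
#' depth (total aligned bases / contig length).
#'
#' @param alignments PAF-style data.frame
#' @param contig_length contig length in bp
#' @param bin bin size in bp (default 1000)
#' @return list with `bins` (data.frame `start`, `end`, `depth`) and
#'   `global_mean`
#' @export
coverage_profile <- function(alignments, contig_length, bin = 1000) {
  if (bin < 1) stop("bin must be >= 1")
  L <- as.integer(contig_length)
  cov <- if (nrow(alignments) == 0) {
    Rle(0L, L)
  } else {
    coverage(IRanges(alignments$tstart + 1, alignments$tend), width = L)
  }
  starts <- seq.int(1L, L, by = bin)
  ends <- pmin(starts + bin - 1L, L)
  depth <- viewMeans(Views(cov, start = starts, end = ends))
  list(bins = data.frame(start = starts, end = ends,
                         depth = as.numeric(depth)),
       global_mean = sum(as.numeric(runLength(cov)) *
                           as.numeric(runValue(cov))) / L)
}

#' Coverage contrast inside vs outside a region
#'
#' Bin means are averaged with bins weighted by their bp of overlap with
#' the region (or its complement); a single-copy chromosomal insertion
#' shows a ratio near 1.
#'
#' @param profile output of [coverage_profile()]
#' @param region single-row interval table
#' @return list `region_mean`, `complement_mean`, `ratio` (`NA` if the
#'   complement has zero coverage)
#' @export
coverage_contrast <- function(profile, region) {
  check_one_region(region)
  b <- profile$bins
  if (region$end > max(b$end)) stop("profile does not cover region")
  ov <- pmax(0, pmin(b$end, region$end) - pmax(b$start, region$start) + 1)
  w <- b$end - b$start + 1
  out_w <- w - ov
  region_mean <- if (sum(ov) == 0) NA_real_ else
    sum(b$depth * ov) / sum(ov)
  complement_mean <- if (sum(out_w) == 0) NA_real_ else
    sum(b$depth * out_w) / sum(out_w)
  ratio <- if (is.na(complement_mean) || complement_mean == 0) {
    NA_real_
  } else {
    region_mean / complement_mean
  }
  list(region_mean = region_mean, complement_mean = complement_mean,
       ratio = ratio)
}

#' Hi-C contact enrichment of a region
#'
#' Within-region mean contact over bin pairs both fully inside the region
#' (diagonal excluded) vs the mean over pairs both outside; also reports
#' the fraction of within-region pairs above a display threshold.
#'
#' @param matrix square symmetric contact matrix (bins along the contig)
#' @param resolution bin size in bp
#' @param region single-row interval table
#' @param display_threshold contact value marking "high contact" (1 by
#'   convention for normalized maps)
#' @return list `within_mean`, `background_mean`, `ratio`,
#'   `frac_above_threshold`
#' @export
contact_enrichment <- function(matrix, resolution, region,
                               display_threshold = 1) {
  check_one_region(region)
  if (resolution <= 0) stop("resolution must be positive")
  if (!isSymmetric(unname(matrix), tol = 1e-6)) {
    stop("contact matrix must be symmetric")
  }
  n <- nrow(matrix)
  bin_start <- (seq_len(n) - 1) * resolution + 1
  bin_end <- seq_len(n) * resolution
  inside <- bin_start >= region$start & bin_end <= region$end
  if (!any(inside)) stop("region smaller than one full bin at this resolution")
  off_diag <- upper.tri(matrix, diag = FALSE)
  wmask <- outer(inside, inside, `&`) & off_diag
  bmask <- outer(!inside, !inside, `&`) & off_diag
  within_mean <- mean(matrix[wmask])
  background_mean <- if (any(bmask)) mean(matrix[bmask]) else NA_real_
  ratio <- if (is.na(background_mean) || background_mean == 0) {
    NA_real_
  } else {
    within_mean / background_mean
  }
  list(within_mean = within_mean, background_mean = background_mean,
       ratio = ratio,
       frac_above_threshold = mean(matrix[wmask] > display_threshold))
}

# 6-frame translation of a DNAString -> character vector of 3+3 proteins
six_frame_translate <- function(seq) {
  seqs <- list(seq, reverseComplement(seq))
  out <- character(0)
  for (s in seqs) {
    L <- length(s)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < 1) next
      out <- c(out, translate_fast(subseq(s, f + 1, f + 3 * n_cod)))
    }
  }
  out
}

aa_kmers <- function(prots, k) {
  out <- character(0)
  for (p in prots) {
    n <- nchar(p)
    if (n < k) next
    out <- c(out, substring(p, 1:(n - k + 1), k:n))
  }
  out
}

# six-frame aa k-mers of a whole sequence together with the genomic start
# (leftmost) coordinate of each k-mer
positioned_kmers <- function(seq, k) {
  L <- length(seq)
  kmer <- character(0)
  pos <- integer(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverseComplement(seq)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < k) next
      aa <- translate_fast(subseq(s, f + 1, f + 3 * n_cod))
      n_aa <- nchar(aa)
      km <- substring(aa, 1:(n_aa - k + 1), k:n_aa)
      i <- seq_along(km)
      p <- if (strand == "+") {
        f + 3 * (i - 1) + 1
      } else {
        L - f - 3 * (i + k - 1) + 1
      }
      kmer <- c(kmer, km)
      pos <- c(pos, p)
    }
  }
  list(kmer = kmer, pos = pos)
}

#' Compare two strain chromosomes at the amino-acid level
#'
#' A deterministic surrogate for translated dot-plot comparison: each
#' `window` of A is translated in six frames and declared matching iff it
#' shares at least `min_shared` distinct amino-acid k-mers with the
#' six-frame k-mer index of B. Maximal runs of at least `min_run`
#' non-matching windows are reported as candidate strain-specific
#' insertions in A.
#'
#' The k-mer length controls the chance-collision rate: with random-codon
#' amino-acid composition the per-position identity is about 0.06, so a
#' window of ~10,000 distinct k-mers against an index of |B| k-mers
#' expects about `1e4 * |B| * 0.06^k` chance collisions. Short k-mers
#' (6-mers) saturate against any chromosome-scale index; the default of
#' 12 keeps the expectation far below 1 even against a 100-Mb genome
#' while near-identical strain sequence still shares thousands of exact
#' 12-mers per window.
#'
#' @param a,b chromosome sequences (`DNAString` or character)
#' @param window window size on A in bp (default 5000)
#' @param kmer amino-acid k-mer size (default 12)
#' @param min_shared distinct shared k-mers required for a window match
#'   (default 5)
#' @param min_run minimum run of unmatched windows reported (default 10)
#' @return list with `windows` (data.frame `start`, `end`, `n_shared`,
#'   `matched`) and `insertions` (interval table of unmatched runs in A)
#' @export
compare_strain_chromosomes <- function(a, b, window = 5000, kmer = 12,
                                       min_shared = 5, min_run = 10) {
  a <- as_dna(a); b <- as_dna(b)
  if (length(a) == 0 || length(b) == 0) stop("sequences must be non-empty")
  b_set <- unique(positioned_kmers(b, kmer)$kmer)
  starts <- seq.int(1L, length(a), by = window)
  ends <- pmin(starts + window - 1L, length(a))
  ak <- positioned_kmers(a, kmer)
  grp <- (ak$pos - 1L) %/% as.integer(window) + 1L
  # distinct k-mers per window
  dup <- duplicated(paste0(grp, "\r", ak$kmer))
  grp <- grp[!dup]
  hit <- ak$kmer[!dup] %in% b_set
  n_shared <- integer(length(starts))
  if (length(grp)) {
    tab <- tapply(hit, grp, sum)
    n_shared[as.integer(names(tab))] <- as.integer(tab)
  }
  matched <- n_shared >= min_shared
  wins <- data.frame(start = starts, end = ends, n_shared = n_shared,
                     matched = matched)
  r <- rle(!matched)
  re_ <- cumsum(r$lengths); rs_ <- re_ - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  insertions <- if (any(keep)) {
    intervals("A", starts[rs_[keep]], ends[re_[keep]])
  } else {
    intervals(character(0), numeric(0), numeric(0))
  }
  list(windows = wins, insertions = insertions)
}
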