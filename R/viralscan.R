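# Rolling-window viral score track, region calling, GC and marker
# summaries.

#' Per-ORF raw viral score
#'
#' `(viral bitscore or 0) - (cellular bitscore or 0)`: high values mark
#' viral ORFs, low values cellular ORFs. Vectorized; `NA` means "no hit".
#'
#' @param viral_bitscore,cellular_bitscore non-negative bitscores or `NA`
#' @return raw score in bits
#' @export
orf_raw_score <- function(viral_bitscore, cellular_bitscore) {
  v <- ifelse(is.na(viral_bitscore), 0, viral_bitscore)
  c_ <- ifelse(is.na(cellular_bitscore), 0, cellular_bitscore)
  if (any(v < 0) || any(c_ < 0)) stop("bitscores must be >= 0")
  v - c_
}

#' Centered rolling mean over ORF-ordered scores
#'
#' Window `i` covers up to `w` ORFs centered on ORF `i`
#' (`floor((w-1)/2)` to the left, `ceiling((w-1)/2)` to the right),
#' truncated at the ends so every ORF gets a score.
#'
#' @param raw numeric vector of raw scores in chromosome order
#' @param w window size in ORFs (default 150)
#' @return numeric vector of the same length
#' @export
rolling_window_scores <- function(raw, w = 150) {
  if (w < 1) stop("w must be >= 1")
  n <- length(raw)
  if (n == 0) return(numeric(0))
  i <- seq_len(n)
  l <- pmax(1L, i - floor((w - 1) / 2))
  r <- pmin(n, i + ceiling((w - 1) / 2))
  cs <- c(0, cumsum(raw))
  (cs[r + 1] - cs[l]) / (r - l + 1)
}

#' Build a per-ORF score track
#'
#' @param scores data.frame with `contig`, `start`, `end` and either
#'   `viral_bitscore`/`cellular_bitscore` columns or a precomputed `raw`
#'   column; one contig at a time
#' @param w rolling window size in ORFs
#' @return the input sorted by start with `raw` and `rolling` columns and
#'   attribute `w`
#' @export
score_track <- function(scores, w = 150) {
  if (length(unique(scores$contig)) > 1) {
    stop("score_track expects a single contig")
  }
  scores <- scores[order(scores$start, scores$end), , drop = FALSE]
  if (!"raw" %in% names(scores)) {
    scores$raw <- orf_raw_score(scores$viral_bitscore,
                                scores$cellular_bitscore)
  }
  scores$rolling <- rolling_window_scores(scores$raw, w)
  attr(scores, "w") <- w
  rownames(scores) <- NULL
  scores
}

#' Call viral regions from a score track
#'
#' Maximal runs of consecutive ORFs with rolling score strictly greater
#' than `threshold` become regions spanning first-ORF start to last-ORF
#' end. Runs shorter than `min_orfs` are dropped; output is sorted by
#' start and non-overlapping.
#'
#' @param track output of [score_track()]
#' @param threshold rolling-score call threshold in bits (default 0)
#' @param min_orfs minimum ORFs per region (default 1)
#' @return region table: interval columns plus `n_orfs`,
#'   `mean_rolling_score`
#' @export
call_viral_regions <- function(track, threshold = 0, min_orfs = 1) {
  empty <- {
    df <- intervals(character(0), numeric(0), numeric(0))
    df$n_orfs <- integer(0); df$mean_rolling_score <- numeric(0)
    df
  }
  if (nrow(track) == 0) return(empty)
  above <- track$rolling > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_orfs
  if (!any(keep)) return(empty)
  a <- starts[keep]; b <- ends[keep]
  out <- intervals(track$contig[a], track$start[a], track$end[b])
  out$n_orfs <- b - a + 1L
  out$mean_rolling_score <- mapply(function(i, j) {
    mean(track$rolling[i:j])
  }, a, b)
  out[order(out$start), , drop = FALSE]
}

#' Windowed GC profile
#'
#' Non-overlapping windows tiled from position 1 (final partial window
#' included). GC is `(G+C)/(A+C+G+T)` per window; N bases are excluded
#' from the denominator and an all-N window yields `NA`.
#'
#' @param sequence `DNAString` or character
#' @param window window size in bp (default 50,000, large enough to damp
#'   the effect of repeats)
#' @return data.frame `start`, `end`, `gc`
#' @export
gc_profile <- function(sequence, window = 50000) {
  if (window < 1) stop("window must be >= 1")
  sequence <- as_dna(sequence)
  L <- length(sequence)
  starts <- seq.int(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  v <- Views(sequence, start = starts, end = ends)
  freq <- letterFrequency(v, c("G", "C", "A", "T"))
  gc_bases <- freq[, "G"] + freq[, "C"]
  acgt <- rowSums(freq)
  gc <- ifelse(acgt == 0, NA_real_, gc_bases / acgt)
  data.frame(start = starts, end = ends, gc = gc)
}

gc_of <- function(sequence, from, to) {
  f <- letterFrequency(subseq(sequence, from, to), c("G", "C", "A", "T"))
  acgt <- sum(f)
  if (acgt == 0) return(NA_real_)
  (f[["G"]] + f[["C"]]) / acgt
}

#' GC contrast between a region and the rest of its contig
#'
#' @param sequence contig `DNAString` or character
#' @param region single-row interval table within the contig
#' @return list `region_gc`, `complement_gc` (`NA` when the region covers
#'   the whole contig)
#' @export
region_gc_contrast <- function(sequence, region) {
  check_one_region(region)
  sequence <- as_dna(sequence)
  L <- length(sequence)
  if (region$start < 1 || region$end > L) {
    stop("region exceeds contig bounds")
  }
  region_gc <- gc_of(sequence, region$start, region$end)
  comp_n <- L - iv_width(region)
  complement_gc <- if (comp_n == 0) {
    NA_real_
  } else {
    f <- letterFrequency(sequence, c("G", "C", "A", "T"))
    fr <- letterFrequency(subseq(sequence, region$start, region$end),
                          c("G", "C", "A", "T"))
    rest <- f - fr
    acgt <- sum(rest)
    if (acgt == 0) NA_real_ else (rest[["G"]] + rest[["C"]]) / acgt
  }
  list(region_gc = unname(region_gc), complement_gc = unname(complement_gc))
}

#' Tally marker genes inside a region
#'
#' A marker belongs to the region iff its interval midpoint lies inside
#' (robust to markers straddling a called boundary).
#'
#' @param markers interval table with a `marker` column
#' @param region single-row interval table
#' @return named integer vector (multiset of marker labels)
#' @export
tally_markers <- function(markers, region) {
  check_one_region(region)
  if (nrow(markers) == 0) return(setNames(integer(0), character(0)))
  mid <- floor((markers$start + markers$end) / 2)
  inside <- mid >= region$start & mid <= region$end &
    markers$contig == region$contig
  tab <- table(markers$marker[inside])
  setNames(as.integer(tab), names(tab))
}

#' Scan a chromosome for viral regions
#'
#' Convenience wrapper: build the score track, call regions, and attach
#' per-region GC, coding density (over the scored ORFs) and marker tally.
#'
#' @param sequence contig sequence
#' @param scores per-ORF score table (see [score_track()])
#' @param w,threshold,min_orfs see [call_viral_regions()]
#' @param gc_window GC profile window (bp)
#' @param markers optional marker interval table
#' @return list with `track`, `regions` (with `gc`, `coding_density` and
#'   `markers` columns), `gc_profile`
#' @export
scan_chromosome <- function(sequence, scores, w = 150, threshold = 0,
                            min_orfs = 1, gc_window = 50000,
                            markers = NULL) {
  sequence <- as_dna(sequence)
  track <- score_track(scores, w)
  regions <- call_viral_regions(track, threshold, min_orfs)
  if (nrow(regions) > 0) {
    regions$gc <- vapply(seq_len(nrow(regions)), function(i) {
      gc_of(sequence, regions$start[i], regions$end[i])
    }, 0)
    regions$coding_density <- vapply(seq_len(nrow(regions)), function(i) {
      coding_density(track, regions[i, , drop = FALSE])
    }, 0)
    regions$markers <- vapply(seq_len(nrow(regions)), function(i) {
      if (is.null(markers)) return("")
      tal <- tally_markers(markers, regions[i, , drop = FALSE])
      paste(sprintf("%s:%d", names(tal), tal), collapse = ",")
    }, "")
  }
  list(track = track, regions = regions,
       gc_profile = gc_profile(sequence, gc_window))
}
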