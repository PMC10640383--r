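# STOP-to-STOP ORF inventory: six-frame extraction, overlap pruning,
# coding density and intergenic extraction.

# stop-codon mask for one frame of one strand; codons containing N (or any
# ambiguity) never count as stops
frame_orf_runs <- function(seq_chr, L, frame, min_aa) {
  starts <- seq.int(frame + 1L, L - 2L, by = 3L)
  if (length(starts) == 0) return(NULL)
  codons <- substring(seq_chr, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  r <- rle(is_stop)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- !r$values & r$lengths >= min_aa
  if (!any(keep)) return(NULL)
  cbind(start = starts[starts_idx[keep]],
        end = starts[ends_idx[keep]] + 2L,
        aa = r$lengths[keep])
}

#' Call STOP-to-STOP ORFs in six frames
#'
#' Maximal stretches between stop codons (TAA/TAG/TGA on the reading
#' strand) in each of the six frames; sequence ends act as boundaries.
#' Intervals exclude the bounding stop codons and are trimmed to whole
#' codons, so `aa_length = length/3` exactly. Codons containing N are
#' treated as non-stop (conservative: keeps potential coding stretches
#' intact). Stretches of at least `min_aa` codons are returned, matching
#' the conventional ">50 aa" filter at the default.
#'
#' @param sequence `DNAString` or character over `{A,C,G,T,N}`
#' @param min_aa minimum ORF length in residues (default 50)
#' @param contig contig name recorded in the output
#' @return ORF table: interval columns plus `frame` (0--2 on its own
#'   strand), `aa_length`, `source = "stop2stop"`
#' @export
call_stop_to_stop_orfs <- function(sequence, min_aa = 50,
                                   contig = "seq") {
  sequence <- as_dna(sequence)
  L <- length(sequence)
  empty <- {
    df <- intervals(character(0), numeric(0), numeric(0))
    df$frame <- integer(0); df$aa_length <- integer(0)
    df$source <- character(0)
    df
  }
  if (L < 3 * min_aa) return(empty)
  fwd <- as.character(sequence)
  rev <- as.character(reverseComplement(sequence))
  rows <- list()
  for (strand in c("+", "-")) {
    s_chr <- if (strand == "+") fwd else rev
    for (frame in 0:2) {
      m <- frame_orf_runs(s_chr, L, frame, min_aa)
      if (is.null(m)) next
      if (strand == "+") {
        a <- m[, "start"]; b <- m[, "end"]
      } else {
        a <- L - m[, "end"] + 1L; b <- L - m[, "start"] + 1L
      }
      df <- intervals(contig, a, b, strand)
      df$frame <- frame
      df$aa_length <- as.integer(m[, "aa"])
      df$source <- "stop2stop"
      rows[[length(rows) + 1]] <- df
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune ORFs overlapping primary gene calls
#'
#' A candidate is removed iff its overlap with any single primary record
#' exceeds `max_overlap_frac` of the candidate's own length. Comparison is
#' strand-agnostic (nucleotide spans only); retained rows are returned
#' unmodified.
#'
#' @param candidates,primary ORF/interval tables on one contig
#' @param max_overlap_frac removal threshold (default 0.5; an overlap of
#'   exactly half is kept)
#' @return the retained subset of `candidates`
#' @export
prune_overlapping_orfs <- function(candidates, primary,
                                   max_overlap_frac = 0.5) {
  if (nrow(candidates) == 0 || nrow(primary) == 0) return(candidates)
  ci <- as_ir(candidates); pr <- as_ir(primary)
  hits <- findOverlaps(ci, pr)
  if (length(hits) == 0) return(candidates)
  ov <- width(pintersect(ci[queryHits(hits)], pr[subjectHits(hits)]))
  frac <- ov / width(ci)[queryHits(hits)]
  worst <- tapply(frac, queryHits(hits), max)
  drop_idx <- as.integer(names(worst))[worst > max_overlap_frac]
  if (length(drop_idx) == 0) return(candidates)
  candidates[-drop_idx, , drop = FALSE]
}

#' Coding density of a region
#'
#' Fraction of `region` covered by the union of ORF intervals
#' (overlapping ORFs counted once).
#'
#' @param orfs ORF/interval table
#' @param region single-row interval table
#' @return fraction in `[0, 1]`
#' @export
coding_density <- function(orfs, region) {
  check_one_region(region)
  union_width_in(orfs, region) / iv_width(region)
}

#' Extract intergenic intervals
#'
#' Maximal sub-intervals of `region` covered by no ORF, of length at least
#' `min_len` (a gap of exactly `min_len` is kept), sorted by start.
#'
#' @inheritParams coding_density
#' @param min_len minimum gap length in bp (default 100)
#' @return interval table of intergenic gaps
#' @export
extract_intergenic <- function(orfs, region, min_len = 100) {
  check_one_region(region)
  reg_ir <- IRanges(region$start, region$end)
  cov <- if (nrow(orfs) == 0) IRanges() else reduce(as_ir(orfs))
  gaps <- setdiff(reg_ir, cov)
  gaps <- gaps[width(gaps) >= min_len]
  out <- intervals(rep(region$contig, length(gaps)), start(gaps),
                   end(gaps))
  out[order(out$start), , drop = FALSE]
}
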