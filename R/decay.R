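# Gene-decay annotation: pseudogene/intron-candidate clustering of
# fragmented ORFs, intergenic gene traces, repeat density, taxonomy.

#' Assign best database hits to ORFs
#'
#' Extracts each ORF's coding-strand sequence and aligns its own
#' reading-frame translation ([translated_search()] in `"forward0"`
#' mode) against a protein database, merging the best hit (subject,
#' aligned coordinates, orientation) back into the ORF table. Searching
#' only the ORF's own frame matters: a STOP-to-STOP ORF from another
#' frame or strand that overlaps a real gene would otherwise pick up
#' that gene's protein through a cross-frame translation of its window,
#' and every intact gene would masquerade as a fragment cluster. The
#' k-mer prefilter is on by default here: decay annotation aligns many
#' junk ORFs that share no seed with any protein.
#'
#' @param orfs ORF table (see [call_stop_to_stop_orfs()])
#' @param sequence contig sequence the ORF coordinates refer to
#' @param db protein database (`AAStringSet` or named character)
#' @param e_threshold,prefilter_k see [translated_search()]
#' @return `orfs` with hit columns appended (`subject`, `hit_strand`,
#'   `hit_frame`, `q_aa_start`, `q_aa_end`, `s_start`, `s_end`,
#'   `evalue`); `NA` where no hit
#' @export
assign_orf_hits <- function(orfs, sequence, db, e_threshold = 1e-5,
                            prefilter_k = 5) {
  sequence <- as_dna(sequence)
  orfs$orf_id <- sprintf("orf_%05d", seq_len(nrow(orfs)))
  hit_cols <- c("subject", "hit_strand", "hit_frame", "q_aa_start",
                "q_aa_end", "s_start", "s_end", "evalue")
  for (cl in hit_cols) {
    orfs[[cl]] <- if (cl %in% c("subject", "hit_strand")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  if (nrow(orfs) == 0) return(orfs)
  qs <- as(Views(sequence, start = orfs$start, end = orfs$end),
           "DNAStringSet")
  minus <- orfs$strand == "-"
  if (any(minus)) qs[minus] <- reverseComplement(qs[minus])
  names(qs) <- orfs$orf_id
  hits <- translated_search(qs, db, e_threshold = e_threshold,
                            prefilter_k = prefilter_k, mode = "forward0")
  if (nrow(hits) > 0) {
    idx <- match(hits$query, orfs$orf_id)
    orfs$subject[idx] <- hits$subject
    orfs$hit_strand[idx] <- orfs$strand[idx]
    orfs$hit_frame[idx] <- 0
    orfs$q_aa_start[idx] <- hits$q_aa_start
    orfs$q_aa_end[idx] <- hits$q_aa_end
    orfs$s_start[idx] <- hits$s_start
    orfs$s_end[idx] <- hits$s_end
    orfs$evalue[idx] <- hits$evalue
  }
  orfs
}

# genomic coordinates of a member's aligned block, from its interval and
# its hit orientation/frame/aa range
aligned_block <- function(row) {
  if (row$hit_strand == "+") {
    off1 <- row$hit_frame + 3 * (row$q_aa_start - 1)
    off2 <- row$hit_frame + 3 * row$q_aa_end - 1
    c(row$start + off1, row$start + off2)
  } else {
    off1 <- row$hit_frame + 3 * (row$q_aa_start - 1)
    off2 <- row$hit_frame + 3 * row$q_aa_end - 1
    c(row$end - off2, row$end - off1)
  }
}

coding_phase <- function(row) {
  if (row$hit_strand == "+") {
    (row$start + row$hit_frame) %% 3
  } else {
    (row$end - row$hit_frame) %% 3
  }
}

#' Cluster fragmented ORFs sharing a homology subject
#'
#' Neighboring ORFs with the same orientation and the same best-hit
#' subject, separated by at most `max_gap` bp, with subject coverage in
#' collinear non-nested order, are merged into candidate decayed-gene
#' clusters. Singletons are not clusters. ORFs without hits are ignored
#' (they may sit between members without breaking a cluster).
#'
#' @param orfs ORF table with hit columns (see [assign_orf_hits()])
#' @param max_gap maximum genomic gap between consecutive members in bp
#' @return list of `pseudogene_cluster` objects (fields `members`,
#'   `subject`, `strand`, `contig`)
#' @export
cluster_fragmented_orfs <- function(orfs, max_gap = 5000) {
  x <- orfs[!is.na(orfs$subject), , drop = FALSE]
  if (nrow(x) == 0) return(list())
  x <- x[order(x$contig, x$start, x$end), , drop = FALSE]
  key <- paste(x$contig, x$hit_strand, x$subject, sep = "\r")
  clusters <- list()
  for (grp in split(seq_len(nrow(x)), key)) {
    g <- x[grp, , drop = FALSE]
    if (nrow(g) < 2) next
    plus <- g$hit_strand[1] == "+"
    run_start <- 1
    flush <- function(a, b) {
      if (b - a + 1 >= 2) {
        clusters[[length(clusters) + 1]] <<- structure(
          list(members = g[a:b, , drop = FALSE],
               subject = g$subject[1], strand = g$hit_strand[1],
               contig = g$contig[1]),
          class = "pseudogene_cluster")
      }
    }
    for (i in seq_len(nrow(g) - 1)) {
      gap <- g$start[i + 1] - g$end[i] - 1
      collinear <- if (plus) {
        g$s_start[i + 1] >= g$s_start[i] && g$s_end[i + 1] >= g$s_end[i]
      } else {
        g$s_start[i + 1] <= g$s_start[i] && g$s_end[i + 1] <= g$s_end[i]
      }
      if (gap > max_gap || !collinear) {
        flush(run_start, i)
        run_start <- i + 1
      }
    }
    flush(run_start, nrow(g))
  }
  # sort clusters by start
  if (length(clusters) > 1) {
    clusters <- clusters[order(vapply(clusters,
                                      function(cl) cl$members$start[1], 0))]
  }
  clusters
}

#' @export
print.pseudogene_cluster <- function(x, ...) {
  cat(sprintf("pseudogene cluster: %d ORFs on %s(%s) hitting %s\n",
              nrow(x$members), x$contig, x$strand, x$subject))
  invisible(x)
}

# find a GT..AG splice motif in a coding-strand gap sequence (already
# padded with `slack` bp of flanking context by the caller): the donor GT
# must start within the first 2*slack+2 bp and the acceptor AG must end
# within the last 2*slack+2 bp
find_splice_motif <- function(gap_seq, slack) {
  glen <- nchar(gap_seq)
  if (glen < 4) return(FALSE)
  win <- min(2 * slack + 2, glen)
  head_win <- substr(gap_seq, 1, win)
  gt <- gregexpr("GT", head_win, fixed = TRUE)[[1]]
  gt <- gt[gt > 0]
  tail_from <- glen - win + 1
  tail_win <- substr(gap_seq, tail_from, glen)
  ag <- gregexpr("AG", tail_win, fixed = TRUE)[[1]]
  ag <- ag[ag > 0]
  if (length(gt) == 0 || length(ag) == 0) return(FALSE)
  ag_end <- max(ag) + tail_from
  min(gt) + 3 <= ag_end
}

#' Classify a fragmented-ORF cluster
#'
#' A cluster is an `intron_candidate` iff, for every adjacent member pair
#' (in protein order), the subject coverage is contiguous (gap/overlap at
#' most `max_cov_gap` residues) and the nucleotide gap between the
#' aligned blocks carries a GT..AG splice motif on the coding strand
#' (donor/acceptor within `splice_slack` bp of the block edges, absorbing
#' local-alignment end fuzziness). Otherwise it is a `pseudogene`, with
#' disruptions enumerated per junction: differing coding phase ->
#' `frameshift`; same phase with an in-frame stop in the gap ->
#' `stop_gain`; otherwise `gap`.
#'
#' @param cluster a `pseudogene_cluster`
#' @param sequence contig sequence
#' @param splice_slack bp of slack when locating GT/AG (default 6)
#' @param max_cov_gap maximum subject-coverage gap/overlap in residues
#'   (default 10)
#' @return list `classification` (`"intron_candidate"` or
#'   `"pseudogene"`) and `disruptions` (data.frame `junction`, `kind`)
#' @export
classify_cluster <- function(cluster, sequence, splice_slack = 6,
                             max_cov_gap = 10) {
  stopifnot(inherits(cluster, "pseudogene_cluster"))
  sequence <- as_dna(sequence)
  m <- cluster$members
  if (is.unsorted(m$start)) stop("cluster members out of order")
  plus <- cluster$strand == "+"
  ord <- if (plus) seq_len(nrow(m)) else rev(seq_len(nrow(m)))
  m <- m[ord, , drop = FALSE] # protein order
  all_intron <- TRUE
  dis <- list()
  for (i in seq_len(nrow(m) - 1)) {
    prev <- m[i, , drop = FALSE]; nxt <- m[i + 1, , drop = FALSE]
    bp <- aligned_block(prev); bn <- aligned_block(nxt)
    if (plus) {
      g1 <- bp[2] + 1; g2 <- bn[1] - 1
    } else {
      g1 <- bn[2] + 1; g2 <- bp[1] - 1
    }
    # pad with slack context so overshooting alignments still expose GT/AG
    gap_seq <- if (g2 >= g1) {
      s <- subseq(sequence, max(1, g1 - splice_slack),
                  min(length(sequence), g2 + splice_slack))
      if (!plus) s <- reverseComplement(s)
      as.character(s)
    } else {
      ""
    }
    raw_gap_seq <- if (g2 >= g1) {
      s <- subseq(sequence, max(1, g1), min(length(sequence), g2))
      if (!plus) s <- reverseComplement(s)
      as.character(s)
    } else {
      ""
    }
    cov_gap <- nxt$s_start - prev$s_end - 1
    contiguous <- abs(cov_gap) <= max_cov_gap
    # a credible intron needs a non-trivial gap (GT..AG must fit)
    splice <- contiguous && g2 - g1 + 1 >= 4 &&
      find_splice_motif(gap_seq, splice_slack)
    if (splice) next
    all_intron <- FALSE
    kind <- if (coding_phase(prev) != coding_phase(nxt)) {
      "frameshift"
    } else {
      # scan the gap on the members' codon grid for an in-frame stop
      glen <- nchar(raw_gap_seq)
      found_stop <- FALSE
      if (glen >= 3) {
        cods <- substring(raw_gap_seq, seq(1, glen - 2, by = 3),
                          seq(3, glen, by = 3))
        found_stop <- any(cods %in% STOP_CODONS)
      }
      if (found_stop) "stop_gain" else "gap"
    }
    dis[[length(dis) + 1]] <- data.frame(junction = i, kind = kind,
                                         stringsAsFactors = FALSE)
  }
  list(classification = if (all_intron) "intron_candidate" else "pseudogene",
       disruptions = if (length(dis)) {
         do.call(rbind, dis)
       } else {
         data.frame(junction = integer(0), kind = character(0),
                    stringsAsFactors = FALSE)
       })
}

#' Summarize gene traces in intergenic regions
#'
#' Counts and percentages (1 decimal) of intergenic queries with hits in
#' a primary protein database, in a second database, and in both.
#'
#' @param query_ids character vector of all query identifiers
#' @param hits_db1,hits_db2 [translated_search()] outputs (or character
#'   vectors of query ids with hits)
#' @return list of counts and percentages
#' @export
summarize_gene_traces <- function(query_ids, hits_db1,
                                  hits_db2 = character(0)) {
  ids1 <- unique(if (is.data.frame(hits_db1)) hits_db1$query else hits_db1)
  ids2 <- unique(if (is.data.frame(hits_db2)) hits_db2$query else hits_db2)
  n <- length(query_ids)
  pct <- function(k) if (n == 0) NA_real_ else round(100 * k / n, 1)
  n1 <- sum(ids1 %in% query_ids)
  n2 <- sum(ids2 %in% query_ids)
  n12 <- length(intersect(intersect(ids1, ids2), query_ids))
  list(n_queries = n,
       n_db1 = n1, pct_db1 = pct(n1),
       n_db2 = n2, pct_db2 = pct(n2),
       n_both = n12, pct_both = pct(n12))
}

#' Repeat and TE density of a region
#'
#' Fractions of the region covered by repeat bases overall, by repeat
#' bases inside the ORF-union (coding) mask, by repeat bases outside it,
#' and by TE-classed repeats only. All four are fractions of the region
#' length, so coding + non-coding = total exactly.
#'
#' @param repeats interval table with a `class` column (`"repeat"` or
#'   `"TE:<family>"`); absent column means all rows are plain repeats
#' @param region single-row interval table
#' @param orfs ORF/interval table defining the coding mask
#' @return list `total`, `coding`, `noncoding`, `te`
#' @export
repeat_density <- function(repeats, region, orfs) {
  check_one_region(region)
  W <- iv_width(region)
  if (nrow(repeats) == 0) {
    return(list(total = 0, coding = 0, noncoding = 0, te = 0))
  }
  cls <- repeats$class %||% rep("repeat", nrow(repeats))
  if (is.null(repeats$class)) repeats$class <- cls
  rep_ir <- reduce(clip_to_region(as_ir(repeats), region))
  orf_ir <- if (nrow(orfs) == 0) {
    IRanges()
  } else {
    reduce(clip_to_region(as_ir(orfs), region))
  }
  total_bp <- sum(width(rep_ir))
  coding_bp <- sum(width(intersect(rep_ir, orf_ir)))
  te <- repeats[grepl("^TE", repeats$class), , drop = FALSE]
  te_bp <- if (nrow(te) == 0) {
    0
  } else {
    sum(width(reduce(clip_to_region(as_ir(te), region))))
  }
  list(total = total_bp / W, coding = coding_bp / W,
       noncoding = (total_bp - coding_bp) / W, te = te_bp / W)
}

#' Taxonomic breakdown of best hits
#'
#' @param hits data.frame with a `taxon` column drawn from
#'   `{eukaryote, prokaryote, virus}` (anything else is counted under
#'   `unclassified` with a warning) and an optional `lineage` column
#' @return list `counts` (named integer), `fractions`, and `lineage`
#'   drill-down (data.frame `taxon`, `lineage`, `n`)
#' @export
taxonomy_breakdown <- function(hits) {
  vocab <- c("eukaryote", "prokaryote", "virus")
  taxon <- if (nrow(hits) == 0) character(0) else as.character(hits$taxon)
  bad <- !(taxon %in% vocab)
  if (any(bad)) {
    warning(sum(bad), " hit(s) with unknown taxon label counted as ",
            "'unclassified'")
    taxon[bad] <- "unclassified"
  }
  levels <- c(vocab, if (any(bad)) "unclassified")
  counts <- setNames(integer(length(levels)), levels)
  tab <- table(taxon)
  counts[names(tab)] <- as.integer(tab)
  fractions <- if (length(taxon) == 0) {
    counts * NA_real_
  } else {
    counts / length(taxon)
  }
  lineage <- if (nrow(hits) > 0 && !is.null(hits$lineage)) {
    agg <- as.data.frame(table(taxon = taxon, lineage = hits$lineage),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    names(agg)[3] <- "n"
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(taxon = character(0), lineage = character(0),
               n = integer(0), stringsAsFactors = FALSE)
  }
  list(counts = counts, fractions = fractions, lineage = lineage)
}

#' Annotate decay in a region end-to-end
#'
#' STOP-to-STOP ORF calling within the region, best-hit assignment,
#' clustering and classification, returning a per-cluster summary table.
#'
#' @param sequence contig sequence
#' @param region single-row interval table
#' @param db protein database
#' @param min_aa,e_threshold,max_gap,prefilter_k stage parameters
#' @return list `orfs` (with hits), `clusters` (objects) and `summary`
#'   (data.frame, one row per cluster)
#' @export
annotate_decay <- function(sequence, region, db, min_aa = 50,
                           e_threshold = 1e-5, max_gap = 5000,
                           prefilter_k = 5) {
  sequence <- as_dna(sequence)
  sub <- subseq(sequence, region$start, region$end)
  orfs <- call_stop_to_stop_orfs(sub, min_aa = min_aa,
                                 contig = region$contig)
  orfs$start <- orfs$start + region$start - 1
  orfs$end <- orfs$end + region$start - 1
  orfs <- assign_orf_hits(orfs, sequence, db, e_threshold = e_threshold,
                          prefilter_k = prefilter_k)
  clusters <- cluster_fragmented_orfs(orfs, max_gap = max_gap)
  rows <- lapply(clusters, function(cl) {
    cf <- classify_cluster(cl, sequence)
    data.frame(contig = cl$contig, start = min(cl$members$start),
               end = max(cl$members$end), strand = cl$strand,
               subject = cl$subject, n_members = nrow(cl$members),
               classification = cf$classification,
               disruptions = paste(cf$disruptions$kind, collapse = ","),
               stringsAsFactors = FALSE)
  })
  summary <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), subject = character(0),
               n_members = integer(0), classification = character(0),
               disruptions = character(0), stringsAsFactors = FALSE)
  }
  list(orfs = orfs, clusters = clusters, summary = summary)
}
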