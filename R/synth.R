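# Synthetic endogenization generator: host chromosome, decayed viral
# insert, long reads and per-ORF scores, each with full ground truth.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = base_probs(gc))
}

# Per-base GC of a random codon conditioned on it not being a stop codon.
# Rejecting stops (which are AT-rich) biases composition upward, so gene
# sequences are sampled at a corrected base GC g' solving
# E[GC | non-stop](g') = target.
nonstop_gc <- function(g) {
  pa <- (1 - g) / 2; pg <- g / 2
  p_tag <- pa * pa * pg  # T,A,G -> one GC base
  p_tga <- pa * pg * pa  # T,G,A -> one GC base
  p_stop <- pa * pa * pa + p_tag + p_tga # TAA contributes no GC bases
  (3 * g - (p_tag + p_tga)) / (1 - p_stop) / 3
}

codon_gc_adjust <- function(target_gc) {
  if (target_gc <= 0 || target_gc >= 1) return(target_gc)
  uniroot(function(g) nonstop_gc(g) - target_gc,
          lower = 1e-4, upper = 1 - 1e-4, tol = 1e-9)$root
}

# n_codons stop-free codons as a character vector of bases
random_coding_bases <- function(n_codons, gc) {
  g <- codon_gc_adjust(gc)
  b <- random_bases(3 * n_codons, g)
  repeat {
    codons <- paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
                     b[c(FALSE, FALSE, TRUE)])
    bad <- which(codons %in% STOP_CODONS)
    if (length(bad) == 0) break
    idx <- rep((bad - 1) * 3, each = 3) + 1:3
    b[idx] <- random_bases(3 * length(bad), g)
  }
  b
}

#' Generate a synthetic host chromosome
#'
#' Background sequence is i.i.d. with `P(G) = P(C) = gc/2`; tandem repeat
#' tracts (several copies of a per-tract random unit, same composition)
#' are overlaid until `repeat_fraction` of the sequence is covered.
#'
#' @param model a [host_model()]
#' @param seed integer RNG seed; output is deterministic per seed
#' @return list with `sequence` (a `DNAString`), `repeats` (interval
#'   table of repeat tracts) and `gc` (realized GC fraction)
#' @export
generate_host_sequence <- function(model, seed) {
  stopifnot(inherits(model, "geve_host_model"))
  with_seed(seed, {
    L <- model$length
    bases <- random_bases(L, model$gc)
    tracts <- list()
    if (model$repeat_fraction > 0) {
      target <- round(model$repeat_fraction * L)
      occupied <- logical(L)
      covered <- 0
      attempts <- 0
      max_attempts <- 200 + 50 * ceiling(target / model$repeat_unit_length)
      while (covered < target && attempts < max_attempts) {
        attempts <- attempts + 1
        copies <- sample(3:12, 1)
        tlen <- min(model$repeat_unit_length * copies, L,
                    target - covered + model$repeat_unit_length)
        if (tlen < model$repeat_unit_length) tlen <- model$repeat_unit_length
        if (tlen > L) break
        a <- sample.int(L - tlen + 1, 1)
        b <- a + tlen - 1
        if (any(occupied[a:b])) next
        unit <- random_bases(model$repeat_unit_length, model$gc)
        bases[a:b] <- rep_len(unit, tlen)
        occupied[a:b] <- TRUE
        covered <- covered + tlen
        tracts[[length(tracts) + 1]] <- c(a, b)
      }
    }
    reps <- if (length(tracts)) {
      m <- do.call(rbind, tracts)
      m <- m[order(m[, 1]), , drop = FALSE]
      intervals("host", m[, 1], m[, 2])
    } else {
      intervals(character(0), numeric(0), numeric(0))
    }
    seq <- DNAString(paste(bases, collapse = ""))
    gc <- sum(letterFrequency(seq, c("G", "C"))) / L
    list(sequence = seq, repeats = reps, gc = gc)
  })
}

# --- decay machinery (operates on the coding-strand gene sequence) ------

apply_decay_to_gene <- function(coding, decay, gc) {
  events <- list()
  rec <- function(kind, pos) {
    events[[length(events) + 1]] <<- list(kind = kind, pos = pos)
  }
  # fixed order: deletions, frameshifts, stop-gains, introns
  if (runif(1) < decay$deletion_rate && length(coding) >= 120) {
    dlen <- max(3, round(runif(1, 0.1, 0.3) * length(coding)))
    dlen <- min(dlen, length(coding) - 60)
    a <- sample.int(length(coding) - dlen - 29, 1) + 15
    coding <- coding[-(a:(a + dlen - 1))]
    rec("deletion", a)
  }
  if (runif(1) < decay$frameshift_rate && length(coding) >= 90) {
    flen <- sample(1:2, 1)
    a <- sample.int(length(coding) - flen - 59, 1) + 30
    coding <- coding[-(a:(a + flen - 1))]
    rec("frameshift", a)
  }
  if (decay$stop_gain_rate > 0) {
    n_cod <- length(coding) %/% 3
    hits <- which(runif(n_cod) < decay$stop_gain_rate)
    for (ci in hits) {
      stop_codon <- strsplit(sample(STOP_CODONS, 1), "")[[1]]
      coding[(3 * ci - 2):(3 * ci)] <- stop_codon
      rec("stop_gain", 3 * ci - 2)
    }
  }
  if (runif(1) < decay$intron_rate && length(coding) >= 120) {
    ilen <- round(runif(1, decay$intron_length_range[1],
                        decay$intron_length_range[2]))
    ilen <- max(ilen, 4L)
    n_cod <- length(coding) %/% 3
    cb <- sample(15:(n_cod - 15), 1) # codon boundary, away from ends
    at <- 3 * cb
    intron <- c("G", "T", random_bases(ilen - 4, gc), "A", "G")
    coding <- append(coding, intron, after = at)
    rec("intron", at + 1)
  }
  kinds <- vapply(events, `[[`, "", "kind")
  status <- if (any(kinds %in% c("deletion", "frameshift", "stop_gain"))) {
    "pseudogene"
  } else if (any(kinds == "intron")) {
    "intron_bearing"
  } else {
    "intact"
  }
  list(coding = coding, events = events, status = status)
}

#' Generate a decayed viral insert with ground truth
#'
#' Genes are stop-free reading frames placed without overlap, separated by
#' random intergenic spacers; decay events (deletions, frameshifts,
#' stop-gains, GT..AG intron insertions, in that fixed order) are applied
#' per gene and recorded. Pre-decay protein translations are retained as
#' the homology database for downstream decay annotation.
#'
#' @param model an [insert_model()]
#' @param decay a [decay_model()]
#' @param seed integer RNG seed
#' @return list with `sequence` (DNAString), `gene_models` (interval table
#'   with `status`, `marker`, `gene_id` columns; coordinates within the
#'   insert), `decay_events` (data.frame `gene_id`, `kind`, `pos`),
#'   `proteins` (AAStringSet of pre-decay translations) and `gc`
#' @export
generate_viral_insert <- function(model, decay, seed) {
  stopifnot(inherits(model, "geve_insert_model"),
            inherits(decay, "geve_decay_model"))
  with_seed(seed, {
    n <- model$n_genes
    mean_cod <- max(50, round(model$gene_length_mean / 3))
    codons <- pmax(50L, as.integer(round(rnorm(n, mean_cod, mean_cod / 4))))
    if (3 * sum(codons) > model$length) {
      stop("capacity error: total gene length exceeds insert length")
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    markers <- rep(NA_character_, n)
    if (n > 0 && length(model$marker_names) > 0) {
      markers[sample.int(n, length(model$marker_names))] <- model$marker_names
    }

    gene_seqs <- vector("list", n)
    proteins <- character(n)
    statuses <- character(n)
    ev_rows <- list()
    for (i in seq_len(n)) {
      coding <- random_coding_bases(codons[i], model$gc)
      proteins[i] <- as.character(translate(DNAString(
        paste(coding, collapse = ""))))
      d <- apply_decay_to_gene(coding, decay, model$gc)
      statuses[i] <- d$status
      for (e in d$events) {
        ev_rows[[length(ev_rows) + 1]] <-
          data.frame(gene_id = paste0("gene_", i), kind = e$kind,
                     pos = e$pos, stringsAsFactors = FALSE)
      }
      gs <- d$coding
      if (strands[i] == "-") {
        gs <- rev(chartr("ACGT", "TGCA", gs))
      }
      gene_seqs[[i]] <- gs
    }

    gene_lens <- vapply(gene_seqs, length, 0L)
    spacer_total <- model$length - sum(gene_lens)
    if (spacer_total < n + 1) {
      stop("capacity error: no room for intergenic spacers")
    }
    # random proportional split of the non-coding budget into n+1 spacers
    w <- runif(n + 1, 0.2, 1)
    spac <- floor(spacer_total * w / sum(w))
    spac[1] <- spac[1] + (spacer_total - sum(spac))

    pieces <- vector("list", 2 * n + 1)
    starts <- integer(n)
    pos <- 0L
    for (i in seq_len(n + 1)) {
      pieces[[2 * i - 1]] <- random_bases(spac[i], model$gc)
      pos <- pos + spac[i]
      if (i <= n) {
        starts[i] <- pos + 1L
        pieces[[2 * i]] <- gene_seqs[[i]]
        pos <- pos + gene_lens[i]
      }
    }
    seq <- DNAString(paste(unlist(pieces), collapse = ""))

    gm <- intervals(rep("insert", n), starts, starts + gene_lens - 1,
                    strands)
    gm$status <- statuses
    gm$marker <- markers
    gm$gene_id <- paste0("gene_", seq_len(n))
    events <- if (length(ev_rows)) {
      do.call(rbind, ev_rows)
    } else {
      data.frame(gene_id = character(0), kind = character(0),
                 pos = numeric(0), stringsAsFactors = FALSE)
    }
    gc <- sum(letterFrequency(seq, c("G", "C"))) / length(seq)
    list(sequence = seq, gene_models = gm, decay_events = events,
         proteins = setNames(AAStringSet(proteins), gm$gene_id), gc = gc)
  })
}

#' Insert a viral segment into a host chromosome
#'
#' @param host_seq host `DNAString` (or character)
#' @param insert_seq insert `DNAString` (or character)
#' @param insertion_point 0-based offset after which the insert is placed
#'   (`0` = insert becomes a prefix; `length(host)` = suffix)
#' @return list with `sequence` and `insert_interval` (1-based inclusive)
#' @export
assemble_genome <- function(host_seq, insert_seq, insertion_point) {
  host_seq <- as_dna(host_seq); insert_seq <- as_dna(insert_seq)
  hl <- length(host_seq); il <- length(insert_seq)
  if (insertion_point < 0 || insertion_point > hl) {
    stop("insertion_point out of range [0, host length]")
  }
  p <- as.integer(insertion_point)
  seq <- Biostrings::xscat(subseq(host_seq, 1, p), insert_seq,
                           subseq(host_seq, p + 1, hl))
  list(sequence = seq,
       insert_interval = intervals("genome", p + 1, p + il))
}

# shift host-coordinate intervals across an insertion; tracts spanning the
# point are split
shift_across_insertion <- function(x, point, insert_len) {
  if (nrow(x) == 0) return(x)
  out <- list()
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]; e <- x$end[i]
    if (e <= point) {
      out[[length(out) + 1]] <- c(s, e)
    } else if (s > point) {
      out[[length(out) + 1]] <- c(s + insert_len, e + insert_len)
    } else {
      out[[length(out) + 1]] <- c(s, point)
      out[[length(out) + 1]] <- c(point + 1 + insert_len, e + insert_len)
    }
  }
  m <- do.call(rbind, out)
  intervals("genome", m[, 1], m[, 2])
}

#' Simulate a complete endogenization scenario
#'
#' Convenience wrapper running host generation, insert generation,
#' assembly and (optionally) read simulation and per-ORF score simulation
#' into one ground-truth object with genome-level coordinates.
#'
#' @param host a [host_model()]
#' @param insert an [insert_model()]
#' @param decay a [decay_model()]
#' @param reads a [read_sim_model()] or `NULL` to skip read simulation
#' @param scores a score model list (see [simulate_orf_scores()]) or
#'   `NULL` to skip score simulation
#' @param insertion_point 0-based insertion offset; default places the
#'   insert at a seed-determined position in the middle half of the host
#' @param host_orfs number of host ORFs carried by the simulated score
#'   table
#' @param seed master RNG seed
#' @return object of class `synthetic_truth`
#' @export
simulate_endogenization <- function(host = host_model(),
                                    insert = insert_model(),
                                    decay = decay_model(),
                                    reads = NULL, scores = NULL,
                                    insertion_point = NULL,
                                    host_orfs = 2500, seed = 1) {
  h <- generate_host_sequence(host, seed)
  v <- generate_viral_insert(insert, decay, seed + 1L)
  if (is.null(insertion_point)) {
    insertion_point <- with_seed(seed + 2L, {
      sample.int(floor(host$length / 2), 1) + floor(host$length / 4)
    })
  }
  g <- assemble_genome(h$sequence, v$sequence, insertion_point)
  gm <- v$gene_models
  gm$start <- gm$start + insertion_point
  gm$end <- gm$end + insertion_point
  gm$contig <- "genome"
  truth <- structure(list(
    genome = g$sequence,
    insert_interval = g$insert_interval,
    gene_models = gm,
    decay_events = v$decay_events,
    proteins = v$proteins,
    repeats = shift_across_insertion(h$repeats, insertion_point,
                                     length(v$sequence)),
    host_gc = h$gc, insert_gc = v$gc,
    reads = NULL, alignments = NULL, orf_scores = NULL,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
  if (!is.null(reads)) {
    rs <- simulate_long_reads(truth$genome, reads)
    truth$reads <- rs$reads
    truth$alignments <- rs$paf
  }
  if (!is.null(scores) || !is.null(host_orfs)) {
    truth$orf_scores <- simulate_orf_scores(
      truth, host_orfs = host_orfs,
      score_model = scores %||% orf_score_model(), seed = seed + 3L)
  }
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic endogenization truth\n")
  cat(sprintf("  genome: %s bp (host GC %.4f, insert GC %.4f)\n",
              format(length(x$genome), big.mark = ","), x$host_gc,
              x$insert_gc))
  cat(sprintf("  insert: %s-%s (%s bp), %d genes (%s)\n",
              format(x$insert_interval$start, big.mark = ",",
                     scientific = FALSE),
              format(x$insert_interval$end, big.mark = ",",
                     scientific = FALSE),
              format(iv_width(x$insert_interval), big.mark = ",",
                     scientific = FALSE),
              nrow(x$gene_models),
              paste(names(table(x$gene_models$status)),
                    table(x$gene_models$status),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$alignments)) {
    cat(sprintf("  reads: %d\n", nrow(x$alignments)))
  }
  invisible(x)
}

#' Simulate long reads over a genome
#'
#' Reads are sampled uniformly (forward strand by default), lengths are
#' normal with a 200 bp floor, substitution errors are injected at
#' `error_rate`, and the true sampled interval of every read is emitted as
#' a PAF record. Depth is defined as total read bases / genome size.
#'
#' @param genome `DNAString` (or character)
#' @param model a [read_sim_model()]
#' @return list with `reads` (named `DNAStringSet`) and `paf` (data.frame
#'   in PAF column order; target coordinates 0-based half-open)
#' @export
simulate_long_reads <- function(genome, model) {
  stopifnot(inherits(model, "geve_read_sim_model"))
  genome <- as_dna(genome)
  L <- length(genome)
  if (L == 0) stop("genome is empty")
  with_seed(model$seed, {
    n <- max(1L, as.integer(round(model$depth * L / model$read_length_mean)))
    lens <- pmax(200, round(rnorm(n, model$read_length_mean,
                                  model$read_length_sd)))
    lens <- as.integer(pmin(lens, L))
    starts <- as.integer(floor(runif(n) * (L - lens + 1)) + 1)
    strands <- if (model$both_strands) {
      sample(c("+", "-"), n, replace = TRUE)
    } else {
      rep("+", n)
    }
    reads <- as(Views(genome, start = starts, width = lens),
                "DNAStringSet")
    n_err <- stats::rbinom(n, lens, model$error_rate)
    for (i in which(n_err > 0)) {
      p <- sample.int(lens[i], n_err[i])
      old <- strsplit(as.character(reads[[i]]), "")[[1]]
      repl <- vapply(old[p], function(b) sample(setdiff(BASES, b), 1), "")
      old[p] <- repl
      reads[[i]] <- DNAString(paste(old, collapse = ""))
    }
    rc <- strands == "-"
    if (any(rc)) reads[rc] <- reverseComplement(reads[rc])
    names(reads) <- sprintf("read_%06d", seq_len(n))
    paf <- data.frame(
      qname = names(reads), qlen = lens, qstart = 0L, qend = lens,
      strand = strands, tname = "genome", tlen = L,
      tstart = starts - 1L, tend = starts - 1L + lens,
      nmatch = lens - n_err, alnlen = lens, mapq = 60L,
      stringsAsFactors = FALSE)
    list(reads = reads, paf = paf)
  })
}

#' Per-ORF score model
#'
#' Parameters of the simulated HMM-search bitscores: ORFs of viral origin
#' draw viral bitscores around `viral_mean` and cellular bitscores around
#' `low_mean`; host ORFs the reverse (cellular around `cellular_mean`).
#' Draws are normal with common `sd`, floored at 0.
#'
#' @param viral_mean,cellular_mean,low_mean,sd bitscore distribution
#'   parameters (bits)
#' @export
orf_score_model <- function(viral_mean = 100, cellular_mean = 100,
                            low_mean = 10, sd = 20) {
  if (sd <= 0) stop("sd must be positive")
  list(viral_mean = viral_mean, cellular_mean = cellular_mean,
       low_mean = low_mean, sd = sd)
}

#' Simulate a per-ORF viral/cellular bitscore table
#'
#' Emulates the output of an upstream HMM search: each insert gene gets a
#' viral-skewed score pair, and `host_orfs` synthetic host ORFs placed
#' outside the insert get cellular-skewed pairs.
#'
#' @param truth a `synthetic_truth` object (needs `gene_models`,
#'   `insert_interval` and genome length)
#' @param host_orfs number of host ORFs to place
#' @param score_model an [orf_score_model()]
#' @param seed RNG seed
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `viral_bitscore`, `cellular_bitscore`, `origin`, sorted by start
#' @export
simulate_orf_scores <- function(truth, host_orfs = 2500,
                                score_model = orf_score_model(),
                                seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sm <- score_model
  with_seed(seed, {
    L <- length(truth$genome)
    ins <- truth$insert_interval
    # host ORF placements: uniform midpoints outside the insert
    lens <- as.integer(round(runif(host_orfs, 300, 900)))
    host_space <- L - iv_width(ins)
    mids <- sort(sample.int(host_space, host_orfs, replace = TRUE))
    mids <- ifelse(mids >= ins$start, mids + iv_width(ins), mids)
    hs <- pmax(1, mids - lens %/% 2)
    he <- pmin(L, hs + lens - 1)
    host_df <- data.frame(contig = "genome", start = hs, end = he,
                          strand = ".",
                          viral_bitscore = pmax(0, rnorm(host_orfs,
                                                         sm$low_mean, sm$sd)),
                          cellular_bitscore = pmax(0, rnorm(host_orfs,
                                                            sm$cellular_mean,
                                                            sm$sd)),
                          origin = "host", stringsAsFactors = FALSE)
    gm <- truth$gene_models
    ins_df <- data.frame(contig = gm$contig, start = gm$start, end = gm$end,
                         strand = gm$strand,
                         viral_bitscore = pmax(0, rnorm(nrow(gm),
                                                        sm$viral_mean, sm$sd)),
                         cellular_bitscore = pmax(0, rnorm(nrow(gm),
                                                           sm$low_mean,
                                                           sm$sd)),
                         origin = "insert", stringsAsFactors = FALSE)
    out <- rbind(host_df, ins_df)
    out[order(out$start, out$end), , drop = FALSE]
  })
}
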