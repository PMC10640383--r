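# Translated homology search: six-frame Smith-Waterman (BLOSUM62, affine
# gaps) with Karlin-Altschul E-values.

# gapped BLOSUM62 (open 11, extend 1) extreme-value parameters
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
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

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` with the gapped BLOSUM62 (11/1)
#' parameters; `n` carries the database-size correction (total database
#' residues).
#'
#' @param score raw local-alignment score
#' @param m query length in residues
#' @param n total database residues
#' @return expected number of chance hits at this score
#' @export
karlin_altschul_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

# local alignment of one AA query against one AA subject; returns score
# plus 1-based aligned ranges on both
local_align_aa <- function(query, subject) {
  pa <- pairwiseAlignment(AAString(query), AAString(subject),
                          type = "local",
                          substitutionMatrix = blosum62(),
                          gapOpening = 11, gapExtension = 1)
  list(score = score(pa),
       q_start = start(pattern(pa)), q_end = end(pattern(pa)),
       s_start = start(subject(pa)), s_end = end(subject(pa)))
}

# batched six-frame translation of a whole query set: returns a list of
# six (strand, frame, aa-character-vector) entries; too-short frames
# translate to ""
batch_query_frames <- function(qs, mode = "six") {
  strands <- if (mode == "forward0") "+" else c("+", "-")
  frames <- if (mode == "forward0") 0 else 0:2
  rc <- if ("-" %in% strands) reverseComplement(qs) else NULL
  lens <- width(qs)
  out <- list()
  for (strand in strands) {
    set <- if (strand == "+") qs else rc
    for (f in frames) {
      n_cod <- pmax(0L, (lens - f) %/% 3L)
      sub <- narrow(set, start = pmin(f + 1L, lens + 1L),
                    width = 3L * n_cod)
      af <- Biostrings::alphabetFrequency(sub, baseOnly = TRUE)
      aa <- if (sum(af[, "other"]) == 0) {
        as.character(translate(sub))
      } else {
        as.character(suppressWarnings(translate(sub,
                                                if.fuzzy.codon = "solve")))
      }
      out[[length(out) + 1]] <- list(strand = strand, frame = f, aa = aa)
    }
  }
  out
}

str_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

# hash from amino-acid k-mer -> integer vector of subject indices
build_kmer_index <- function(db_chr, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(db_chr)) {
    for (km in str_kmers(db_chr[si], k)) {
      env[[km]] <- c(env[[km]], si)
    }
  }
  env
}

seeded_candidates <- function(aa, index, k) {
  qk <- str_kmers(aa, k)
  if (length(qk) == 0) return(integer(0))
  hit <- qk[vapply(qk, function(km) !is.null(index[[km]]), TRUE)]
  if (length(hit) == 0) return(integer(0))
  sort(unique(unlist(lapply(hit, function(km) index[[km]]))))
}

#' Translated search of nucleotide queries against a protein database
#'
#' Each query is translated in six frames and locally aligned
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) against every
#' database protein; the best-scoring alignment per query is converted to
#' an E-value with [karlin_altschul_evalue()] (n = total database
#' residues) and reported if below `e_threshold`.
#'
#' @param queries named `DNAStringSet` (or named character vector)
#' @param db named `AAStringSet` (or named character vector) of proteins
#' @param e_threshold maximum E-value reported (default 1e-5)
#' @param prefilter_k if > 0, skip query-frame/subject pairs sharing no
#'   exact amino-acid k-mer of this size (a seeding heuristic; 0 = align
#'   all pairs as the contract states)
#' @param mode `"six"` (default) translates all six frames; `"forward0"`
#'   translates only frame 0 of the supplied strand, for queries that
#'   already are oriented reading frames (e.g. STOP-to-STOP ORFs)
#' @return data.frame, one row per query with a hit: `query`, `subject`,
#'   `score`, `evalue`, `strand`, `frame`, `q_aa_start`, `q_aa_end`,
#'   `s_start`, `s_end` (subject coordinates in residues)
#' @export
translated_search <- function(queries, db, e_threshold = 1e-5,
                              prefilter_k = 0, mode = "six") {
  if (!is(queries, "DNAStringSet")) queries <- DNAStringSet(queries)
  if (!is(db, "AAStringSet")) db <- AAStringSet(db)
  if (length(db) == 0) stop("database is empty")
  if (is.null(names(queries))) {
    names(queries) <- paste0("query_", seq_along(queries))
  }
  if (is.null(names(db))) names(db) <- paste0("protein_", seq_along(db))
  db_chr <- as.character(db)
  n_db <- sum(nchar(db_chr))
  index <- if (prefilter_k > 0) {
    build_kmer_index(db_chr, prefilter_k)
  }
  all_frames <- batch_query_frames(queries, mode)
  rows <- list()
  for (qi in seq_along(queries)) {
    if (width(queries)[qi] < 3) {
      warning("query ", names(queries)[qi], " shorter than one codon; skipped")
      next
    }
    frames <- Filter(function(fr) nzchar(fr$aa),
                     lapply(all_frames, function(fr) {
                       list(strand = fr$strand, frame = fr$frame,
                            aa = fr$aa[qi])
                     }))
    cand <- lapply(frames, function(fr) {
      if (prefilter_k > 0) {
        seeded_candidates(fr$aa, index, prefilter_k)
      } else {
        seq_along(db_chr)
      }
    })
    # score-only pass, batched over frames per subject; full traceback
    # only for the single best pair
    best_score <- -Inf; best_fi <- NA; best_si <- NA
    for (si in sort(unique(unlist(cand)))) {
      fis <- which(vapply(cand, function(x) si %in% x, TRUE))
      sc <- pairwiseAlignment(
        AAStringSet(vapply(frames[fis], `[[`, "", "aa")),
        AAString(db_chr[si]), type = "local",
        substitutionMatrix = blosum62(), gapOpening = 11,
        gapExtension = 1, scoreOnly = TRUE)
      if (max(sc) > best_score) {
        best_score <- max(sc)
        best_fi <- fis[which.max(sc)]
        best_si <- si
      }
    }
    if (!is.finite(best_score)) next
    fr <- frames[[best_fi]]
    al <- local_align_aa(fr$aa, db_chr[best_si])
    best <- c(al, list(subject = names(db)[best_si], strand = fr$strand,
                       frame = fr$frame, m = nchar(fr$aa)))
    ev <- karlin_altschul_evalue(best$score, best$m, n_db)
    if (ev < e_threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        query = names(queries)[qi], subject = best$subject,
        score = best$score, evalue = ev, strand = best$strand,
        frame = best$frame, q_aa_start = best$q_start,
        q_aa_end = best$q_end, s_start = best$s_start,
        s_end = best$s_end, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), evalue = numeric(0),
                      strand = character(0), frame = integer(0),
                      q_aa_start = integer(0), q_aa_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
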