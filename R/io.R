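# Readers/writers for the plain-text formats the pipeline exchanges:
# PAF, per-ORF score TSV, BED, GFF3 (minimal attribute support), dense
# contact-matrix TSV and flat key=value run configs.

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
              "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")

#' Read / write PAF alignment tables
#'
#' Only the 12 mandatory PAF columns are handled; coordinates keep PAF's
#' native 0-based half-open convention.
#'
#' @param path file path
#' @return data.frame with the 12 PAF columns
#' @export
read_paf <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("malformed PAF: fewer than 12 columns in ", path)
  df <- df[, 1:12]
  names(df) <- PAF_COLS
  df
}

#' @rdname read_paf
#' @param paf PAF-style data.frame
#' @export
write_paf <- function(paf, path) {
  write.table(paf[, PAF_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write per-ORF score tables
#'
#' TSV with header columns `contig`, `start`, `end`, `strand`,
#' `viral_bitscore`, `cellular_bitscore` (1-based inclusive coordinates).
#'
#' @param path file path
#' @export
read_orf_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "viral_bitscore",
            "cellular_bitscore")
  if (!all(need %in% names(df))) {
    stop("score TSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_orf_scores
#' @param scores score data.frame
#' @export
write_orf_scores <- function(scores, path) {
  keep <- intersect(c("contig", "start", "end", "strand",
                      "viral_bitscore", "cellular_bitscore"),
                    names(scores))
  write.table(scores[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an interval table as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param x interval table (optional `name` column becomes column 4)
#' @param path file path
#' @export
write_bed <- function(x, path) {
  name <- x$name %||% x$class %||% rep(".", nrow(x))
  df <- data.frame(x$contig, as.integer(x$start) - 1L, as.integer(x$end),
                   name, 0L, x$strand %||% rep(".", nrow(x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file as an interval table
#'
#' @param path file path
#' @return interval table; BED column 4, if present, is kept as `class`
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- intervals(df[[1]], df[[2]] + 1, df[[3]],
                   if (ncol(df) >= 6) df[[6]] else ".")
  if (ncol(df) >= 4) out$class <- as.character(df[[4]])
  out
}

#' Write gene/ORF annotations as GFF3
#'
#' @param x interval table; extra columns are serialized into the
#'   attribute field
#' @param path file path
#' @param source GFF3 source field
#' @param type GFF3 type field
#' @export
write_gff3 <- function(x, path, source = "gevescan", type = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  extra <- setdiff(names(x), c("contig", "start", "end", "strand"))
  for (i in seq_len(nrow(x))) {
    attrs <- paste0("ID=", if ("gene_id" %in% extra) {
      x$gene_id[i]
    } else {
      paste0("feat", i)
    })
    for (cl in setdiff(extra, "gene_id")) {
      v <- x[[cl]][i]
      if (!is.na(v) && v != "") attrs <- paste0(attrs, ";", cl, "=", v)
    }
    writeLines(paste(x$contig[i], source, type, x$start[i], x$end[i], ".",
                     x$strand[i], ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file as an interval table
#'
#' Minimal reader for the subset this package writes: standard 9 columns,
#' `key=value` attributes expanded into columns.
#'
#' @param path file path
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(intervals(character(0), numeric(0), numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad)) {
    stop("malformed GFF3 at line ", bad[1], " of ", path)
  }
  m <- do.call(rbind, parts)
  out <- intervals(m[, 1], as.numeric(m[, 4]), as.numeric(m[, 5]), m[, 7])
  out$type <- m[, 3]
  attrs <- strsplit(m[, 9], ";", fixed = TRUE)
  keys <- unique(unlist(lapply(attrs, function(a) {
    sub("=.*", "", a)
  })))
  for (k in keys) {
    out[[if (k == "ID") "gene_id" else k]] <- vapply(attrs, function(a) {
      hit <- a[startsWith(a, paste0(k, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, "")
  }
  out
}

#' Read / write a dense contact matrix
#'
#' TSV of a square symmetric matrix preceded by a header line
#' `# resolution=<bp> contig=<name>`.
#'
#' @param path file path
#' @return list `matrix`, `resolution`, `contig`
#' @export
read_contact_matrix <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*resolution=", first)) {
    stop("contact matrix must start with '# resolution=<bp>' header")
  }
  res <- as.numeric(sub(".*resolution=([0-9]+).*", "\\1", first))
  contig <- if (grepl("contig=", first)) {
    sub(".*contig=([^ ]+).*", "\\1", first)
  } else {
    "unknown"
  }
  m <- as.matrix(read.delim(path, header = FALSE, skip = 1))
  dimnames(m) <- NULL
  list(matrix = m, resolution = res, contig = contig)
}

#' @rdname read_contact_matrix
#' @param matrix square symmetric matrix
#' @param resolution bin size in bp
#' @param contig contig name
#' @export
write_contact_matrix <- function(matrix, resolution, path,
                                 contig = "genome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%d contig=%s", as.integer(resolution),
                     contig), con)
  write.table(matrix, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write flat key=value run configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept
#' as strings; [run_pipeline()] coerces them. Round-trips losslessly.
#'
#' @param path file path
#' @return named list of character values
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad)) stop("config parse error at entry ", bad[1])
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

#' @rdname read_run_config
#' @param config named list
#' @export
write_run_config <- function(config, path) {
  writeLines(paste(names(config), unlist(lapply(config, as.character)),
                   sep = " = "), path)
  invisible(path)
}
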