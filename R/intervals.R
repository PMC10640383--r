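#' Construct an interval table
#'
#' Intervals are the package's universal positional currency: a plain
#' data.frame with columns `contig`, `start`, `end`, `strand`, 1-based
#' inclusive. Strand is one of `"+"`, `"-"`, `"."`.
#'
#' @param contig contig identifier(s)
#' @param start,end 1-based inclusive coordinates, `start <= end`
#' @param strand strand character(s), default `"."`
#' @return data.frame with class `c("geve_intervals", "data.frame")`
#' @export
#' @examples
#' intervals("chr8", 1370742, 2921549)
intervals <- function(contig, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  contig <- rep(as.character(contig), length.out = length(start))
  strand <- rep(as.character(strand), length.out = length(start))
  if (any(start < 1) || any(end < start)) {
    stop("invalid interval: require 1 <= start <= end")
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  df <- data.frame(contig = contig, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("geve_intervals", "data.frame")
  df
}

#' @export
format.geve_intervals <- function(x, ...) format.data.frame(x, ...)

iv_width <- function(x) x$end - x$start + 1

# interval table -> IRanges (single contig assumed by callers)
as_ir <- function(x) {
  if (nrow(x) == 0) return(IRanges())
  IRanges(start = x$start, end = x$end)
}

# clip an IRanges to a single region interval (row of an interval table)
clip_to_region <- function(ir, region) {
  restrict(ir, start = region$start, end = region$end)
}

# union width of intervals inside a region
union_width_in <- function(x, region) {
  if (nrow(x) == 0) return(0)
  sum(width(reduce(clip_to_region(as_ir(x), region))))
}

check_one_region <- function(region) {
  if (!is.data.frame(region) || nrow(region) != 1) {
    stop("'region' must be a single-row interval table")
  }
  invisible(region)
}

# parse "chr:start-end" into an interval table
parse_region_string <- function(s) {
  m <- regmatches(s, regexec("^(.+):([0-9,]+)-([0-9,]+)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", s)
  intervals(m[2], as.numeric(gsub(",", "", m[3])),
            as.numeric(gsub(",", "", m[4])))
}

# coerce character/DNAString to DNAString
as_dna <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single sequence")
    return(x[[1]])
  }
  DNAString(as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# translate a codon-multiple DNAString; the fuzzy-codon path (which is
# expensive to set up) is only taken when ambiguity codes are present
translate_fast <- function(x) {
  f <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  if (f[["other"]] == 0) {
    as.character(translate(x))
  } else {
    as.character(suppressWarnings(translate(x, if.fuzzy.codon = "solve")))
  }
}
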