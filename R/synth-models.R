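#' Synthetic-world parameter models
#'
#' Constructors for the parameter objects consumed by the synthetic
#' endogenization generator. Defaults describe the scenario the package is
#' designed around: a low-GC (~28%) host chromosome carrying a single
#' contiguous higher-GC (~37%) viral insert of about 1.5 Mb with ~36%
#' coding density, decayed genes, sparse repeats inside the insert and
#' uniform long-read coverage across the junctions.
#'
#' @param length sequence length in bp
#' @param gc target GC fraction in `[0, 1]`
#' @param repeat_fraction fraction of the host covered by tandem repeat
#'   tracts, in `[0, 1)`; host chromosomes of the emulated fungus are
#'   42--65% repetitive, hence the 0.5 default
#' @param repeat_unit_length length of the tandem repeat unit in bp
#' @return a validated parameter list with class `geve_host_model`
#' @export
host_model <- function(length = 5e6, gc = 0.28, repeat_fraction = 0.5,
                       repeat_unit_length = 200) {
  if (length <= 0) stop("host length must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    stop("repeat_fraction must be in [0, 1)")
  }
  if (repeat_unit_length < 1) stop("repeat_unit_length must be >= 1")
  structure(list(length = as.integer(length), gc = gc,
                 repeat_fraction = repeat_fraction,
                 repeat_unit_length = as.integer(repeat_unit_length)),
            class = "geve_host_model")
}

#' @rdname host_model
#' @param n_genes number of genes placed in the insert; default derives
#'   from `coding_target * length / gene_length_mean`
#' @param gene_length_mean mean pre-decay gene length in bp (1,050 bp, a
#'   typical large-dsDNA-virus gene)
#' @param coding_target fraction of the insert covered by genes, in (0, 1]
#' @param marker_names giant-virus marker genes carried by the insert;
#'   must be a subset of the ten canonical nucleocytovirus markers
#' @export
insert_model <- function(length = 1.5e6, gc = 0.37, n_genes = NULL,
                         gene_length_mean = 1050, coding_target = 0.36,
                         marker_names = c("PolB", "RNAPL", "RNAPS",
                                          "mRNAc", "VLTF3")) {
  if (length <= 0) stop("insert length must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (coding_target <= 0 || coding_target > 1) {
    stop("coding_target must be in (0, 1]")
  }
  if (!all(marker_names %in% geve_marker_genes())) {
    stop("unknown marker name(s): ",
         paste(setdiff(marker_names, geve_marker_genes()), collapse = ", "))
  }
  if (is.null(n_genes)) {
    n_genes <- round(coding_target * length / gene_length_mean)
  }
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (n_genes < length(marker_names) && n_genes > 0) {
    stop("fewer genes than marker labels")
  }
  structure(list(length = as.integer(length), gc = gc,
                 n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean,
                 coding_target = coding_target,
                 marker_names = marker_names),
            class = "geve_insert_model")
}

#' @rdname host_model
#' @param stop_gain_rate per-codon probability of a nonsense substitution
#' @param frameshift_rate per-gene probability of a 1--2 bp indel
#' @param deletion_rate per-gene probability of an interior deletion
#' @param intron_rate per-gene probability of a spliceosomal (GT..AG)
#'   intron insertion
#' @param intron_length_range min/max intron length in bp (min >= 4 so the
#'   GT..AG dinucleotides fit)
#' @export
decay_model <- function(stop_gain_rate = 0.0015, frameshift_rate = 0.08,
                        deletion_rate = 0.04, intron_rate = 0.08,
                        intron_length_range = c(50, 400)) {
  rates <- c(stop_gain_rate, frameshift_rate, deletion_rate, intron_rate)
  if (any(rates < 0 | rates > 1)) stop("decay rates must be in [0, 1]")
  if (length(intron_length_range) != 2 || intron_length_range[1] < 4 ||
      intron_length_range[2] < intron_length_range[1]) {
    stop("intron_length_range must be c(min >= 4, max >= min)")
  }
  structure(list(stop_gain_rate = stop_gain_rate,
                 frameshift_rate = frameshift_rate,
                 deletion_rate = deletion_rate,
                 intron_rate = intron_rate,
                 intron_length_range = as.integer(intron_length_range)),
            class = "geve_decay_model")
}

#' @rdname host_model
#' @param depth target fold-coverage, defined as total read bases divided
#'   by genome size (113x is a typical long-read budget for a fungal
#'   chromosome-level assembly)
#' @param read_length_mean,read_length_sd read length distribution in bp
#' @param error_rate per-base substitution probability, in `[0, 0.3]`
#' @param seed RNG seed for the read simulator
#' @param both_strands sample reads from both strands? Forward-only by
#'   default; strand does not affect junction logic
#' @export
read_sim_model <- function(depth = 113, read_length_mean = 10000,
                           read_length_sd = 3000, error_rate = 0.05,
                           seed = 1, both_strands = FALSE) {
  if (depth <= 0) stop("depth must be positive")
  if (read_length_mean <= 0) stop("read_length_mean must be positive")
  if (error_rate < 0 || error_rate > 0.3) {
    stop("error_rate must be in [0, 0.3]")
  }
  structure(list(depth = depth, read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd, error_rate = error_rate,
                 seed = as.integer(seed), both_strands = both_strands),
            class = "geve_read_sim_model")
}

#' The ten canonical nucleocytovirus marker genes
#'
#' @return character vector of the ten marker gene labels
#' @export
geve_marker_genes <- function() {
  c("PolB", "RNAPL", "RNAPS", "mRNAc", "VLTF3",
    "MCP", "A32", "D5", "RNR", "SFII")
}
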