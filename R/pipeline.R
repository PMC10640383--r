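# Pipeline orchestration: simulate -> scan -> validate -> decay -> report
# with a single flat config; every stage reads/writes plain files so runs
# are resumable and every report number is recomputable from shipped
# intermediates.

#' Default run configuration
#'
#' All stage parameters with their package defaults. Values are plain
#' numbers/strings so the config round-trips through
#' [write_run_config()] / [read_run_config()] losslessly.
#'
#' @param out_dir output directory
#' @param seed master seed
#' @return named list
#' @export
default_run_config <- function(out_dir = "geve_run", seed = 1) {
  list(
    out_dir = out_dir, seed = seed, simulate = "yes",
    # synthetic world
    host_length = 5e6, host_gc = 0.28, repeat_fraction = 0.5,
    repeat_unit_length = 200,
    insert_length = 1.5e6, insert_gc = 0.37, gene_length_mean = 1050,
    coding_target = 0.36,
    stop_gain_rate = 0.0015, frameshift_rate = 0.08, deletion_rate = 0.04,
    intron_rate = 0.08, intron_min = 50, intron_max = 400,
    depth = 20, read_length_mean = 10000, read_length_sd = 3000,
    error_rate = 0.05, host_orfs = 2500,
    # scan
    w = 150, s = 0, gc_window = 50000,
    # validate
    bin = 1000, min_anchor = 1000,
    # decay
    min_aa = 50, min_len = 100, max_overlap_frac = 0.5,
    e_threshold = 1e-5, max_gap = 5000, prefilter_k = 5,
    # non-simulated inputs (paths, empty = not provided)
    fasta = "", scores = "", paf = "", repeats_bed = "", markers_tsv = "",
    proteins_faa = ""
  )
}

cfg_num <- function(config, key) as.numeric(config[[key]])

pipeline_log <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the full GEVE pipeline
#'
#' Executes simulate (optional), scan, validate, decay and report in
#' dependency order. Every intermediate is written as a standard plain
#' file under `out_dir`; a machine-readable region report (TSV) plus a
#' human-readable summary and a run log (parameter echo, input checksums,
#' seed) are emitted. Rerunning with the same config reproduces identical
#' outputs.
#'
#' @param config named list (see [default_run_config()]) or path to a
#'   flat key=value config file
#' @return invisibly, the region report data.frame
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  base <- default_run_config()
  for (k in names(config)) base[[k]] <- config[[k]]
  config <- base
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_num(config, "seed"))
  log_path <- file.path(out, "run.log")
  logc <- file(log_path, "w")
  on.exit(close(logc))
  pipeline_log(logc, "gevescan ",
               as.character(utils::packageVersion("gevescan")))
  pipeline_log(logc, "seed = ", seed)
  for (k in sort(names(config))) {
    pipeline_log(logc, "param ", k, " = ", as.character(config[[k]]))
  }

  run_stage <- function(name, expr) {
    pipeline_log(logc, "stage ", name, " start")
    res <- tryCatch(expr, error = function(e) {
      pipeline_log(logc, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(logc, "stage ", name, " done")
    res
  }

  # ---- simulate ---------------------------------------------------------
  truth <- NULL
  if (identical(tolower(as.character(config$simulate)), "yes")) {
    truth <- run_stage("simulate", {
      hm <- host_model(length = cfg_num(config, "host_length"),
                       gc = cfg_num(config, "host_gc"),
                       repeat_fraction = cfg_num(config, "repeat_fraction"),
                       repeat_unit_length = cfg_num(config,
                                                    "repeat_unit_length"))
      im <- insert_model(length = cfg_num(config, "insert_length"),
                         gc = cfg_num(config, "insert_gc"),
                         gene_length_mean = cfg_num(config,
                                                    "gene_length_mean"),
                         coding_target = cfg_num(config, "coding_target"))
      dm <- decay_model(stop_gain_rate = cfg_num(config, "stop_gain_rate"),
                        frameshift_rate = cfg_num(config, "frameshift_rate"),
                        deletion_rate = cfg_num(config, "deletion_rate"),
                        intron_rate = cfg_num(config, "intron_rate"),
                        intron_length_range = c(cfg_num(config, "intron_min"),
                                                cfg_num(config,
                                                        "intron_max")))
      rm_ <- read_sim_model(depth = cfg_num(config, "depth"),
                            read_length_mean = cfg_num(config,
                                                       "read_length_mean"),
                            read_length_sd = cfg_num(config,
                                                     "read_length_sd"),
                            error_rate = cfg_num(config, "error_rate"),
                            seed = seed)
      tr <- simulate_endogenization(hm, im, dm, reads = rm_,
                                    host_orfs = cfg_num(config,
                                                        "host_orfs"),
                                    seed = seed)
      gset <- DNAStringSet(tr$genome)
      names(gset) <- "genome"
      writeXStringSet(gset, file.path(out, "genome.fasta"))
      writeXStringSet(tr$reads, file.path(out, "reads.fasta"))
      write_paf(tr$alignments, file.path(out, "alignments.paf"))
      write_orf_scores(tr$orf_scores, file.path(out, "scores.tsv"))
      write_gff3(tr$gene_models, file.path(out, "truth.gff3"))
      ins_bed <- tr$insert_interval; ins_bed$name <- "insert"
      write_bed(ins_bed, file.path(out, "insert.bed"))
      write_bed(tr$repeats, file.path(out, "repeats.bed"))
      writeXStringSet(tr$proteins, file.path(out, "proteins.faa"))
      mk <- tr$gene_models[!is.na(tr$gene_models$marker), , drop = FALSE]
      write.table(mk[, c("contig", "start", "end", "strand", "marker")],
                  file.path(out, "markers.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tr
    })
  }

  fasta_path <- if (!is.null(truth)) {
    file.path(out, "genome.fasta")
  } else {
    config$fasta
  }
  if (!nzchar(fasta_path) || !file.exists(fasta_path)) {
    stop("pipeline stage 'scan' failed: no genome FASTA available",
         call. = FALSE)
  }
  scores_path <- if (!is.null(truth)) {
    file.path(out, "scores.tsv")
  } else {
    config$scores
  }
  pipeline_log(logc, "input genome md5 = ", unname(md5sum(fasta_path)))

  # ---- scan -------------------------------------------------------------
  scan_res <- run_stage("scan", {
    genome <- readDNAStringSet(fasta_path)
    scores <- read_orf_scores(scores_path)
    markers <- NULL
    mk_path <- if (!is.null(truth)) {
      file.path(out, "markers.tsv")
    } else {
      config$markers_tsv
    }
    if (nzchar(mk_path) && file.exists(mk_path)) {
      markers <- read.delim(mk_path, stringsAsFactors = FALSE)
    }
    res <- scan_chromosome(genome[[1]], scores,
                           w = cfg_num(config, "w"),
                           threshold = cfg_num(config, "s"),
                           gc_window = cfg_num(config, "gc_window"),
                           markers = markers)
    write.table(res$regions, file.path(out, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(res$regions) > 0) {
      rb <- res$regions; rb$name <- sprintf("region_%d",
                                            seq_len(nrow(rb)))
      write_bed(rb, file.path(out, "regions.bed"))
    }
    write.table(res$gc_profile, file.path(out, "gc_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  genome <- readDNAStringSet(fasta_path)[[1]]
  regions <- scan_res$regions

  # ---- validate ---------------------------------------------------------
  paf_path <- if (!is.null(truth)) {
    file.path(out, "alignments.paf")
  } else {
    config$paf
  }
  validation <- run_stage("validate", {
    if (!nzchar(paf_path) || !file.exists(paf_path) ||
        nrow(regions) == 0) {
      list(junctions = NULL, profile = NULL,
           per_region = data.frame(junction_reads = integer(0),
                                   coverage_ratio = numeric(0)))
    } else {
      paf <- read_paf(paf_path)
      prof <- coverage_profile(paf, length(genome),
                               bin = cfg_num(config, "bin"))
      write.table(prof$bins, file.path(out, "coverage.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jrows <- list()
      per_region <- data.frame(junction_reads = integer(nrow(regions)),
                               coverage_ratio = numeric(nrow(regions)))
      for (i in seq_len(nrow(regions))) {
        region <- regions[i, , drop = FALSE]
        jr <- detect_junction_reads(paf, region,
                                    min_anchor = cfg_num(config,
                                                         "min_anchor"))
        if (nrow(jr) > 0) {
          jr$region <- i
          jrows[[length(jrows) + 1]] <- jr
        }
        per_region$junction_reads[i] <- length(unique(jr$read_id))
        per_region$coverage_ratio[i] <-
          coverage_contrast(prof, region)$ratio
      }
      junctions <- if (length(jrows)) {
        do.call(rbind, jrows)
      } else {
        data.frame(read_id = character(0), boundary = character(0),
                   viral_bp = numeric(0), host_bp = numeric(0),
                   region = integer(0))
      }
      write.table(junctions, file.path(out, "junctions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(junctions = junctions, profile = prof,
           per_region = per_region)
    }
  })

  # ---- decay ------------------------------------------------------------
  prot_path <- if (!is.null(truth)) {
    file.path(out, "proteins.faa")
  } else {
    config$proteins_faa
  }
  rep_path <- if (!is.null(truth)) {
    file.path(out, "repeats.bed")
  } else {
    config$repeats_bed
  }
  decay_res <- run_stage("decay", {
    per_region <- data.frame(pseudogenes = integer(nrow(regions)),
                             intron_candidates = integer(nrow(regions)),
                             repeat_total = numeric(nrow(regions)),
                             repeat_te = numeric(nrow(regions)))
    all_sum <- list()
    have_db <- nzchar(prot_path) && file.exists(prot_path)
    reps <- if (nzchar(rep_path) && file.exists(rep_path) &&
                file.size(rep_path) > 0) {
      read_bed(rep_path)
    } else {
      intervals(character(0), numeric(0), numeric(0))
    }
    for (i in seq_len(nrow(regions))) {
      region <- regions[i, , drop = FALSE]
      region$contig <- "genome"
      if (have_db) {
        db <- readAAStringSet(prot_path)
        ann <- annotate_decay(genome, region, db,
                              min_aa = cfg_num(config, "min_aa"),
                              e_threshold = cfg_num(config, "e_threshold"),
                              max_gap = cfg_num(config, "max_gap"),
                              prefilter_k = cfg_num(config, "prefilter_k"))
        s <- ann$summary
        if (nrow(s) > 0) {
          s$region <- i
          all_sum[[length(all_sum) + 1]] <- s
        }
        per_region$pseudogenes[i] <-
          sum(s$classification == "pseudogene")
        per_region$intron_candidates[i] <-
          sum(s$classification == "intron_candidate")
        orf_mask <- ann$orfs
      } else {
        orf_mask <- intervals(character(0), numeric(0), numeric(0))
      }
      rd <- repeat_density(reps, region, orf_mask)
      per_region$repeat_total[i] <- rd$total
      per_region$repeat_te[i] <- rd$te
    }
    summary <- if (length(all_sum)) {
      do.call(rbind, all_sum)
    } else {
      NULL
    }
    if (!is.null(summary)) {
      write.table(summary, file.path(out, "decay.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(per_region = per_region, summary = summary)
  })

  # ---- report -----------------------------------------------------------
  report <- run_stage("report", {
    if (nrow(regions) == 0) {
      rep <- region_report_skeleton()
    } else {
      gc <- vapply(seq_len(nrow(regions)), function(i) {
        unlist(region_gc_contrast(genome, regions[i, , drop = FALSE]))
      }, c(region_gc = 0, complement_gc = 0))
      rep <- data.frame(
        contig = regions$contig, start = regions$start,
        end = regions$end, length_bp = iv_width(regions),
        length_kb = floor(iv_width(regions) / 1000),
        n_orfs = regions$n_orfs,
        mean_rolling_score = regions$mean_rolling_score,
        gc = regions$gc, complement_gc = gc["complement_gc", ],
        coding_density = regions$coding_density,
        markers = regions$markers %||% "",
        junction_reads = validation$per_region$junction_reads,
        coverage_ratio = validation$per_region$coverage_ratio,
        pseudogenes = decay_res$per_region$pseudogenes,
        intron_candidates = decay_res$per_region$intron_candidates,
        repeat_total = decay_res$per_region$repeat_total,
        repeat_te = decay_res$per_region$repeat_te,
        stringsAsFactors = FALSE)
    }
    write_report(rep, file.path(out, "report.tsv"),
                 summary_path = file.path(out, "summary.txt"))
    jsonlite::write_json(rep, file.path(out, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    rep
  })
  invisible(report)
}

region_report_skeleton <- function() {
  data.frame(contig = character(0), start = numeric(0), end = numeric(0),
             length_bp = numeric(0), length_kb = numeric(0),
             n_orfs = integer(0), mean_rolling_score = numeric(0),
             gc = numeric(0), complement_gc = numeric(0),
             coding_density = numeric(0), markers = character(0),
             junction_reads = integer(0), coverage_ratio = numeric(0),
             pseudogenes = integer(0), intron_candidates = integer(0),
             repeat_total = numeric(0), repeat_te = numeric(0),
             stringsAsFactors = FALSE)
}

#' Format a bp span the way region lengths are conventionally printed
#'
#' Floor of the inclusive span over 1000, with thousands separators and a
#' "kb" unit: 1,370,742--2,921,549 prints as "1,550 kb".
#'
#' @param bp span in bp
#' @return character
#' @export
format_kb <- function(bp) {
  paste0(format(floor(bp / 1000), big.mark = ",", scientific = FALSE,
                trim = TRUE), " kb")
}

#' Write the region report
#'
#' TSV with stable, documented columns plus a human-readable summary with
#' percentages printed to 1--2 decimals.
#'
#' @param report region report data.frame
#' @param path TSV output path
#' @param summary_path optional text-summary path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, summary_path = NULL) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    con <- file(summary_path, "w")
    on.exit(close(con))
    if (nrow(report) == 0) {
      writeLines("no viral regions called", con)
    }
    for (i in seq_len(nrow(report))) {
      writeLines(sprintf(
        "region %d: %s:%s-%s (%s), %d ORFs, GC %.2f%% vs %.2f%%, coding %.2f%%, %d junction reads, coverage ratio %.2f, %d pseudogenes, %d intron candidates, repeats %.2f%% (TE %.2f%%)",
        i, report$contig[i],
        format(report$start[i], big.mark = ",", scientific = FALSE,
               trim = TRUE),
        format(report$end[i], big.mark = ",", scientific = FALSE,
               trim = TRUE),
        format_kb(report$length_bp[i]), report$n_orfs[i],
        100 * report$gc[i], 100 * report$complement_gc[i],
        100 * report$coding_density[i], report$junction_reads[i],
        report$coverage_ratio[i], report$pseudogenes[i],
        report$intron_candidates[i], 100 * report$repeat_total[i],
        100 * report$repeat_te[i]), con)
    }
  }
  invisible(path)
}

#' Read back a region report written by [write_report()]
#'
#' @param path TSV path
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
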