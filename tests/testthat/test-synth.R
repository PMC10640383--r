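test_that("host sequence matches target composition and repeat coverage", {
  m <- host_model(length = 1e6, gc = 0.28, repeat_fraction = 0.5)
  h <- generate_host_sequence(m, seed = 1)
  expect_equal(length(h$sequence), 1e6)
  gc <- sum(letterFrequency(h$sequence, c("G", "C"))) / 1e6
  expect_gte(gc, 0.275)
  expect_lte(gc, 0.285)
  cover <- sum(h$repeats$end - h$repeats$start + 1) / 1e6
  expect_lt(abs(cover - 0.5), 0.02)
})

test_that("degenerate host compositions behave", {
  h <- generate_host_sequence(host_model(length = 100, gc = 1,
                                         repeat_fraction = 0), seed = 1)
  expect_true(all(strsplit(as.character(h$sequence), "")[[1]] %in%
                    c("G", "C")))
  expect_error(host_model(length = 0), "positive")
  expect_error(host_model(repeat_fraction = 1), "repeat_fraction")
})

test_that("host generation is deterministic per seed", {
  m <- host_model(length = 5e4, repeat_fraction = 0.4)
  a <- generate_host_sequence(m, seed = 42)
  b <- generate_host_sequence(m, seed = 42)
  expect_identical(as.character(a$sequence), as.character(b$sequence))
  expect_identical(a$repeats, b$repeats)
  c_ <- generate_host_sequence(m, seed = 43)
  expect_false(identical(as.character(a$sequence),
                         as.character(c_$sequence)))
})

test_that("no-decay limit leaves every gene intact", {
  v <- generate_viral_insert(
    insert_model(length = 5e4),
    decay_model(stop_gain_rate = 0, frameshift_rate = 0,
                deletion_rate = 0, intron_rate = 0), seed = 3)
  expect_true(all(v$gene_models$status == "intact"))
  expect_equal(nrow(v$decay_events), 0)
  expect_lt(abs(v$gc - 0.37), 0.01)
  # intact genes really are stop-free reading frames
  for (i in head(seq_len(nrow(v$gene_models)), 5)) {
    g <- v$gene_models[i, ]
    s <- subseq(v$sequence, g$start, g$end)
    if (g$strand == "-") s <- reverseComplement(s)
    aa <- as.character(translate(s))
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_identical(aa, as.character(v$proteins[[g$gene_id]]))
  }
})

test_that("pseudogene count follows the stop-gain binomial expectation", {
  im <- insert_model(length = 3e5, n_genes = 100)
  v <- generate_viral_insert(
    im, decay_model(stop_gain_rate = 0.002, frameshift_rate = 0,
                    deletion_rate = 0, intron_rate = 0), seed = 11)
  n_codons <- (v$gene_models$end - v$gene_models$start + 1) / 3
  p <- 1 - (1 - 0.002)^n_codons
  mu <- sum(p)
  sd_ <- sqrt(sum(p * (1 - p)))
  observed <- sum(v$gene_models$status == "pseudogene")
  expect_gte(observed, mu - 3 * sd_)
  expect_lte(observed, mu + 3 * sd_)
})

test_that("forced introns appear once per gene with GT..AG ends", {
  v <- generate_viral_insert(
    insert_model(length = 1e5),
    decay_model(stop_gain_rate = 0, frameshift_rate = 0,
                deletion_rate = 0, intron_rate = 1), seed = 5)
  expect_true(all(v$gene_models$status == "intron_bearing"))
  ev <- v$decay_events
  expect_true(all(ev$kind == "intron"))
  expect_equal(sort(ev$gene_id), sort(v$gene_models$gene_id))
  for (i in seq_len(nrow(v$gene_models))) {
    g <- v$gene_models[i, ]
    s <- subseq(v$sequence, g$start, g$end)
    if (g$strand == "-") s <- reverseComplement(s)
    coding <- as.character(s)
    pos <- ev$pos[ev$gene_id == g$gene_id]
    # recorded position is the first intron base on the coding strand
    expect_identical(substr(coding, pos, pos + 1), "GT")
  }
})

test_that("assembly coordinates are exact and invertible", {
  g <- assemble_genome("AAAA", "GG", 2)
  expect_identical(as.character(g$sequence), "AAGGAA")
  expect_equal(c(g$insert_interval$start, g$insert_interval$end), c(3, 4))
  g0 <- assemble_genome("AAAA", "GG", 0)
  expect_identical(as.character(g0$sequence), "GGAAAA")
  expect_equal(c(g0$insert_interval$start, g0$insert_interval$end),
               c(1, 2))
  expect_error(assemble_genome("AAAA", "GG", 5), "out of range")
  # inverse-operation oracle on random input
  set.seed(9)
  for (i in 1:20) {
    host <- random_dna(sample(50:200, 1))
    ins <- random_dna(sample(10:80, 1))
    p <- sample(0:nchar(host), 1)
    g <- assemble_genome(host, ins, p)
    iv <- g$insert_interval
    expect_equal(length(g$sequence), nchar(host) + nchar(ins))
    restored <- paste0(substr(as.character(g$sequence), 1, iv$start - 1),
                       substr(as.character(g$sequence), iv$end + 1,
                              length(g$sequence)))
    expect_identical(restored, host)
    expect_identical(substr(as.character(g$sequence), iv$start, iv$end),
                     ins)
  }
})

test_that("error-free reads are exact substrings at their PAF interval", {
  genome <- DNAString(random_dna(50000))
  rs <- simulate_long_reads(genome, read_sim_model(
    depth = 3, read_length_mean = 2000, read_length_sd = 500,
    error_rate = 0, seed = 2))
  gc_chr <- as.character(genome)
  for (i in seq_len(min(nrow(rs$paf), 20))) {
    expect_identical(as.character(rs$reads[[i]]),
                     substr(gc_chr, rs$paf$tstart[i] + 1, rs$paf$tend[i]))
  }
})

test_that("read simulation hits the depth target and is deterministic", {
  genome <- DNAString(random_dna(2e5))
  m <- read_sim_model(depth = 15, read_length_mean = 5000,
                      read_length_sd = 1000, error_rate = 0.05, seed = 7)
  rs <- simulate_long_reads(genome, m)
  total <- sum(rs$paf$alnlen)
  expect_lt(abs(total / length(genome) - 15) / 15, 0.10)
  rs2 <- simulate_long_reads(genome, m)
  expect_identical(as.character(rs$reads), as.character(rs2$reads))
  expect_identical(rs$paf, rs2$paf)
  # injected substitutions occur at roughly error_rate
  mm <- sum(rs$paf$alnlen - rs$paf$nmatch)
  expect_lt(abs(mm / total - 0.05), 0.01)
})

test_that("per-bin coverage recounted from the emitted PAF is near depth", {
  genome <- DNAString(random_dna(3e5))
  rs <- simulate_long_reads(genome, read_sim_model(
    depth = 20, read_length_mean = 5000, read_length_sd = 1000,
    error_rate = 0, seed = 4))
  depth <- oracle_coverage_bins(rs$paf, length(genome), 1000)
  interior <- depth[11:(length(depth) - 10)]
  expect_lt(abs(mean(interior) - 20) / 20, 0.15)
})

test_that("zero-noise score limit separates insert from host exactly", {
  tr <- small_truth(seed = 2, host_len = 1e5, insert_len = 3e4,
                    host_orfs = 50)
  sc <- simulate_orf_scores(tr, host_orfs = 50,
                            score_model = orf_score_model(
                              viral_mean = 80, cellular_mean = 80,
                              low_mean = 5, sd = 1e-9), seed = 1)
  raw <- orf_raw_score(sc$viral_bitscore, sc$cellular_bitscore)
  expect_true(all(abs(raw[sc$origin == "insert"] - 75) < 1e-6))
  expect_true(all(abs(raw[sc$origin == "host"] + 75) < 1e-6))
  expect_false(is.unsorted(sc$start))
})

test_that("truth gene models lie inside the insert interval", {
  tr <- small_truth(seed = 8, host_len = 1e5, insert_len = 4e4,
                    host_orfs = 40)
  expect_true(all(tr$gene_models$start >= tr$insert_interval$start))
  expect_true(all(tr$gene_models$end <= tr$insert_interval$end))
  expect_true(all(tr$decay_events$gene_id %in% tr$gene_models$gene_id))
  expect_equal(length(tr$genome),
               1e5 + (tr$insert_interval$end - tr$insert_interval$start + 1))
})
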