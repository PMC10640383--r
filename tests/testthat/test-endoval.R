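paf_row <- function(qname, tstart, tend, tlen = 100000, strand = "+") {
  data.frame(qname = qname, qlen = tend - tstart, qstart = 0,
             qend = tend - tstart, strand = strand, tname = "c",
             tlen = tlen, tstart = tstart, tend = tend,
             nmatch = tend - tstart, alnlen = tend - tstart, mapq = 60,
             stringsAsFactors = FALSE)
}

test_that("junction detection needs both anchors across a boundary", {
  region <- intervals("c", 20001, 60000)
  inside <- paf_row("r_in", 25000, 30000)
  expect_equal(nrow(detect_junction_reads(inside, region, 1000)), 0)
  # covers region.start - 2000 .. region.start + 1999 (1-based)
  sym <- paf_row("r_l", 18000, 22000)
  ev <- detect_junction_reads(sym, region, 1000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$boundary, "left")
  expect_equal(ev$host_bp, 2000)
  expect_equal(ev$viral_bp, 2000)
  # anchors below the minimum are rejected
  short <- paf_row("r_s", 19100, 22000) # host side 900
  expect_equal(nrow(detect_junction_reads(short, region, 1000)), 0)
  # one read may witness both boundaries
  span <- paf_row("r_b", 18000, 62000)
  ev2 <- detect_junction_reads(span, region, 1000)
  expect_equal(sort(ev2$boundary), c("left", "right"))
  expect_error(detect_junction_reads(sym, intervals("c", 1, 2e6), 1000),
               "outside contig")
})

test_that("junction detection is invariant to order and strand", {
  region <- intervals("c", 20001, 60000)
  aln <- rbind(paf_row("b", 58000, 63000, strand = "-"),
               paf_row("a", 18000, 22000),
               paf_row("c", 30000, 35000))
  ev <- detect_junction_reads(aln, region, 1000)
  ev_shuf <- detect_junction_reads(aln[c(3, 1, 2), ], region, 1000)
  expect_identical(ev, ev_shuf)
  expect_equal(ev$read_id, c("a", "b"))
})

test_that("synthetic junction reads equal the truth-derived set", {
  tr <- small_truth(seed = 3, depth = 10, host_len = 2e5,
                    insert_len = 6e4, host_orfs = 60)
  got <- detect_junction_reads(tr$alignments, tr$insert_interval, 1000)
  want <- oracle_junction_ids(tr$alignments, tr$insert_interval, 1000)
  expect_identical(sort(unique(got$read_id)), want)
  expect_gt(nrow(got), 0)
})

test_that("coverage profile handles unit and empty cases", {
  aln <- paf_row("r", 0, 10000, tlen = 10000)
  prof <- coverage_profile(aln, 10000, bin = 1000)
  expect_true(all(prof$bins$depth == 1))
  expect_equal(prof$global_mean, 1)
  empty <- coverage_profile(aln[0, ], 10000, bin = 1000)
  expect_true(all(empty$bins$depth == 0))
})

test_that("binned coverage matches the per-base pileup oracle", {
  set.seed(91)
  for (rep in 1:5) {
    L <- 20000
    n <- sample(20:80, 1)
    st <- sample(0:(L - 500), n, replace = TRUE)
    aln <- do.call(rbind, lapply(seq_len(n), function(i) {
      paf_row(paste0("r", i), st[i],
              min(L, st[i] + sample(200:2000, 1)), tlen = L)
    }))
    bin <- sample(c(250, 1000), 1)
    prof <- coverage_profile(aln, L, bin = bin)
    expect_equal(prof$bins$depth, oracle_coverage_bins(aln, L, bin))
    # conservation: sum(depth * bin bp) = total aligned bases
    expect_equal(sum(prof$bins$depth * (prof$bins$end - prof$bins$start + 1)),
                 sum(aln$tend - aln$tstart))
  }
})

test_that("coverage contrast reports region/complement ratio", {
  prof <- list(bins = data.frame(start = seq(1, 9001, 1000),
                                 end = seq(1000, 10000, 1000),
                                 depth = rep(10, 10)))
  region <- intervals("c", 3001, 6000)
  cc <- coverage_contrast(prof, region)
  expect_equal(cc$ratio, 1)
  prof$bins$depth[4:6] <- 20
  cc2 <- coverage_contrast(prof, region)
  expect_equal(cc2$ratio, 2)
  # region cutting through a bin weights by overlap
  region3 <- intervals("c", 3501, 6000)
  cc3 <- coverage_contrast(prof, region3)
  expect_equal(cc3$region_mean, 20)
})

test_that("synthetic endogenization has uniform coverage (single copy)", {
  # ratio sd scales as ~1/sqrt(reads in region); depth 40 with 4 kb
  # reads over a 100 kb insert puts 3 sd well inside the [0.9, 1.1] band
  tr <- simulate_endogenization(
    host = host_model(length = 3e5, repeat_fraction = 0.3),
    insert = insert_model(length = 1e5), decay = decay_model(),
    reads = read_sim_model(depth = 40, read_length_mean = 4000,
                           read_length_sd = 800, error_rate = 0.02,
                           seed = 105),
    host_orfs = 60, seed = 5)
  prof <- coverage_profile(tr$alignments, length(tr$genome), bin = 1000)
  cc <- coverage_contrast(prof, tr$insert_interval)
  expect_gt(cc$ratio, 0.9)
  expect_lt(cc$ratio, 1.1)
})

test_that("contact enrichment matches constructed and oracle values", {
  m <- matrix(1, 20, 20)
  region <- intervals("c", 125001, 375000) # bins 6..15 at 25 kb
  ce <- contact_enrichment(m, 25000, region)
  expect_equal(ce$ratio, 1)
  # block with doubled in-region pairs
  m2 <- m
  m2[6:15, 6:15] <- 2
  ce2 <- contact_enrichment(m2, 25000, region)
  expect_equal(ce2$ratio, 2)
  expect_equal(ce2$frac_above_threshold, 1)
  expect_error(contact_enrichment(m, 25000, intervals("c", 10, 100)),
               "resolution")
  # random symmetric matrix vs double-loop oracle
  set.seed(101)
  r <- matrix(runif(400), 20, 20)
  r <- (r + t(r)) / 2
  ce3 <- contact_enrichment(r, 25000, region)
  inside <- 6:15
  w <- c(); b <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    v <- r[i, j]
    if (i %in% inside && j %in% inside) w <- c(w, v)
    if (!(i %in% inside) && !(j %in% inside)) b <- c(b, v)
  }
  expect_equal(ce3$within_mean, mean(w))
  expect_equal(ce3$background_mean, mean(b))
  expect_equal(ce3$frac_above_threshold, mean(w > 1))
})

test_that("self-comparison matches everywhere; spliced insert is found", {
  set.seed(111)
  b <- random_dna(200000, gc = 0.4)
  cmp_self <- compare_strain_chromosomes(b, b, window = 5000)
  expect_true(all(cmp_self$windows$matched))
  expect_equal(nrow(cmp_self$insertions), 0)
  # splice a 100-kb foreign segment into A
  seg <- random_dna(100000, gc = 0.4)
  at <- 100000
  a <- paste0(substr(b, 1, at), seg, substr(b, at + 1, nchar(b)))
  cmp <- compare_strain_chromosomes(a, b, window = 5000)
  expect_equal(nrow(cmp$insertions), 1)
  ins <- cmp$insertions[1, ]
  true_ins <- c(at + 1, at + nchar(seg))
  inter <- max(0, min(ins$end, true_ins[2]) - max(ins$start, true_ins[1]) + 1)
  jacc <- inter / (max(ins$end, true_ins[2]) - min(ins$start, true_ins[1]) + 1)
  expect_gte(jacc, 0.8)
})

test_that("unrelated sequences share almost no windows", {
  set.seed(121)
  a <- random_dna(100000)
  b <- random_dna(100000)
  cmp <- compare_strain_chromosomes(a, b, window = 5000)
  expect_lte(mean(cmp$windows$matched), 0.02)
  expect_gt(nrow(cmp$insertions), 0)
})

test_that("growing B never increases unmatched intervals of A", {
  set.seed(131)
  a <- random_dna(60000)
  b_small <- substr(a, 1, 20000)
  b_big <- a
  cmp_small <- compare_strain_chromosomes(a, b_small, window = 5000,
                                          min_run = 2)
  cmp_big <- compare_strain_chromosomes(a, b_big, window = 5000,
                                        min_run = 2)
  expect_lte(sum(cmp_big$windows$matched == FALSE),
             sum(cmp_small$windows$matched == FALSE))
})
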