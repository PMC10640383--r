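# helpers to build hand-crafted clusters on a constructed sequence -------

codon_for <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1]
}

encode_protein <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]], codon_for, ""), collapse = "")
}

member_row <- function(start, end, subject, s_start, s_end,
                       q_aa_start = 1, q_aa_end = (end - start + 1) / 3,
                       frame = 0, strand = "+") {
  df <- intervals("c", start, end, strand)
  df$hit_strand <- strand
  df$hit_frame <- frame
  df$q_aa_start <- q_aa_start
  df$q_aa_end <- q_aa_end
  df$s_start <- s_start
  df$s_end <- s_end
  df$subject <- subject
  df
}

make_cluster <- function(...) {
  members <- do.call(rbind, list(...))
  structure(list(members = members, subject = members$subject[1],
                 strand = members$hit_strand[1], contig = "c"),
            class = "pseudogene_cluster")
}

test_that("canonical splice with contiguous coverage is an intron candidate", {
  set.seed(161)
  prot <- random_aa(200)
  exon1 <- encode_protein(substr(prot, 1, 100))
  exon2 <- encode_protein(substr(prot, 101, 200))
  intron <- paste0("GT", random_dna(76), "AG")
  seq <- paste0(random_dna(30), exon1, intron, exon2, random_dna(30))
  s1 <- 31
  s2 <- s1 + 300 + 80
  cl <- make_cluster(
    member_row(s1, s1 + 299, "P", 1, 100),
    member_row(s2, s2 + 299, "P", 101, 200))
  res <- classify_cluster(cl, seq)
  expect_equal(res$classification, "intron_candidate")
  expect_equal(nrow(res$disruptions), 0)
})

test_that("a frame break without splice motifs is a frameshift pseudogene", {
  set.seed(162)
  prot <- random_aa(200)
  exon1 <- encode_protein(substr(prot, 1, 100))
  exon2 <- encode_protein(substr(prot, 101, 200))
  seq <- paste0(random_dna(30), exon1, "C", exon2, random_dna(30))
  s1 <- 31
  s2 <- s1 + 300 + 1 # 1 bp gap -> phase change
  cl <- make_cluster(
    member_row(s1, s1 + 299, "P", 1, 100),
    member_row(s2, s2 + 299, "P", 101, 200))
  res <- classify_cluster(cl, seq)
  expect_equal(res$classification, "pseudogene")
  expect_equal(res$disruptions$kind, "frameshift")
})

test_that("an in-frame stop between collinear members is a stop gain", {
  set.seed(163)
  prot <- random_aa(200)
  exon1 <- encode_protein(substr(prot, 1, 100))
  exon2 <- encode_protein(substr(prot, 101, 200))
  seq <- paste0(random_dna(30), exon1, "TGA", exon2, random_dna(30))
  s1 <- 31
  s2 <- s1 + 300 + 3
  cl <- make_cluster(
    member_row(s1, s1 + 299, "P", 1, 100),
    member_row(s2, s2 + 299, "P", 101, 200))
  res <- classify_cluster(cl, seq)
  expect_equal(res$classification, "pseudogene")
  expect_equal(res$disruptions$kind, "stop_gain")
})

test_that("a large subject-coverage hole is a pseudogene gap", {
  set.seed(164)
  prot <- random_aa(300)
  exon1 <- encode_protein(substr(prot, 1, 100))
  # residues 101..200 deleted; stop-free in-phase spacer, no splice motif
  exon2 <- encode_protein(substr(prot, 201, 300))
  seq <- paste0(random_dna(30), exon1, strrep("GCA", 15), exon2,
                random_dna(30))
  s1 <- 31
  s2 <- s1 + 300 + 45
  cl <- make_cluster(
    member_row(s1, s1 + 299, "P", 1, 100),
    member_row(s2, s2 + 299, "P", 201, 300))
  res <- classify_cluster(cl, seq)
  expect_equal(res$classification, "pseudogene")
  expect_equal(res$disruptions$kind, "gap")
})

test_that("clustering requires shared subject, strand and collinearity", {
  a <- member_row(100, 399, "P", 1, 100)
  b <- member_row(500, 799, "P", 120, 200)
  both <- rbind(a, b)
  cl <- cluster_fragmented_orfs(both)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 2)
  # opposite orientation: no cluster
  b_rev <- b
  b_rev$hit_strand <- "-"
  expect_length(cluster_fragmented_orfs(rbind(a, b_rev)), 0)
  # different subject: no cluster
  b_other <- b
  b_other$subject <- "Q"
  expect_length(cluster_fragmented_orfs(rbind(a, b_other)), 0)
  # gap beyond max_gap splits
  b_far <- b
  b_far$start <- 20000
  b_far$end <- 20299
  expect_length(cluster_fragmented_orfs(rbind(a, b_far), max_gap = 5000), 0)
  # non-collinear coverage (nested / reversed) splits
  b_bad <- b
  b_bad$s_start <- 1
  b_bad$s_end <- 50
  expect_length(cluster_fragmented_orfs(rbind(a, b_bad)), 0)
})

test_that("minus-strand fragments cluster with reversed collinearity", {
  # genomic order: later protein part comes first on the chromosome
  a <- member_row(100, 399, "P", 101, 200, strand = "-")
  b <- member_row(500, 799, "P", 1, 100, strand = "-")
  cl <- cluster_fragmented_orfs(rbind(a, b))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$strand, "-")
})

test_that("clusters partition their member ORFs", {
  tr_ins <- generate_viral_insert(insert_model(length = 8e4),
                                  decay_model(), seed = 31)
  region <- intervals("insert", 1, length(tr_ins$sequence))
  ann <- annotate_decay(tr_ins$sequence, region, tr_ins$proteins)
  ids <- unlist(lapply(ann$clusters, function(cl) cl$members$orf_id))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("decay annotation recovers simulated decay states", {
  tr_ins <- generate_viral_insert(
    insert_model(length = 6e4),
    decay_model(stop_gain_rate = 0.004, frameshift_rate = 0,
                deletion_rate = 0, intron_rate = 0), seed = 33)
  region <- intervals("insert", 1, length(tr_ins$sequence))
  ann <- annotate_decay(tr_ins$sequence, region, tr_ins$proteins)
  decayed <- tr_ins$gene_models$gene_id[
    tr_ins$gene_models$status == "pseudogene"]
  found <- unique(ann$summary$subject)
  expect_gte(sum(decayed %in% found) / max(1, length(decayed)), 0.6)
  # recovered clusters for stop-gain decay classify as pseudogenes
  hit <- ann$summary[ann$summary$subject %in% decayed, ]
  if (nrow(hit) > 0) {
    expect_gte(mean(hit$classification == "pseudogene"), 0.8)
  }
})

test_that("repeat density decomposes conservatively", {
  region <- intervals("c", 1, 1000)
  reps <- intervals("c", 1, 500)
  reps$class <- "repeat"
  rd <- repeat_density(reps, region, intervals("c", 600, 800))
  expect_equal(rd$total, 0.5)
  expect_equal(rd$coding, 0)
  expect_equal(rd$noncoding, 0.5)
  expect_equal(rd$te, 0)
  # empty annotation
  rd0 <- repeat_density(intervals(character(0), numeric(0), numeric(0)),
                        region, intervals("c", 600, 800))
  expect_equal(unlist(rd0), c(total = 0, coding = 0, noncoding = 0,
                              te = 0))
  # random additivity
  set.seed(171)
  for (rep_i in 1:5) {
    n <- sample(5:30, 1)
    st <- sample(900, n)
    reps <- intervals("c", st, pmin(1000, st + sample(10:100, n, TRUE)))
    reps$class <- sample(c("repeat", "TE:gypsy"), n, TRUE)
    m <- sample(5:20, 1)
    ost <- sample(900, m)
    orfs <- intervals("c", ost, pmin(1000, ost + sample(20:150, m, TRUE)))
    rd <- repeat_density(reps, region, orfs)
    expect_equal(rd$coding + rd$noncoding, rd$total, tolerance = 1e-9)
    expect_lte(rd$te, rd$total + 1e-12)
  }
})

test_that("taxonomy breakdown counts the controlled vocabulary", {
  hits <- data.frame(
    taxon = c(rep("eukaryote", 108), rep("prokaryote", 10),
              rep("virus", 25)),
    lineage = c(rep("Fungi", 60), rep("Metazoa", 48), rep("Bacteria", 10),
                rep("Asfarviridae", 21), rep("Poxviridae", 4)),
    stringsAsFactors = FALSE)
  tb <- taxonomy_breakdown(hits)
  expect_equal(unname(tb$counts[c("eukaryote", "prokaryote", "virus")]),
               c(108L, 10L, 25L))
  expect_equal(sum(tb$fractions), 1)
  expect_equal(tb$lineage$n[tb$lineage$lineage == "Asfarviridae"], 21)
  # shuffled rows give identical output
  tb2 <- taxonomy_breakdown(hits[sample(nrow(hits)), ])
  expect_identical(tb$counts, tb2$counts)
  # empty and unknown labels
  tb0 <- taxonomy_breakdown(hits[0, ])
  expect_true(all(tb0$counts == 0))
  expect_warning(tbx <- taxonomy_breakdown(
    data.frame(taxon = c("virus", "archaeon"))), "unclassified")
  expect_equal(unname(tbx$counts["unclassified"]), 1L)
})

test_that("gene-trace summaries print 1-decimal percentages", {
  ids <- paste0("q", 1:1095)
  tr <- summarize_gene_traces(ids, ids[1:124], ids[500:721])
  expect_equal(tr$pct_db1, 11.3)
  expect_equal(tr$pct_db2, 20.3)
  expect_equal(tr$n_both, 0)
  tr2 <- summarize_gene_traces(ids, ids[1:100], ids[1:74])
  expect_equal(tr2$n_both, 74)
})
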