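small_cfg <- function(seed = 11, ...) {
  defaults <- list(seed = seed, contig_length = 20000L, n_genes = 6L,
                   alu_count = 6L, island_count = 2L, n_island_sites = 8L,
                   n_isolated_sites = 8L, n_snps = 20L, coverage = 15,
                   simple_repeat_count = 4L, homopolymer_count = 4L,
                   n_cell_lines = 2L, n_replicates = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("reference generation is deterministic and structurally sound", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(r1$bundle$repeats, r2$bundle$repeats)

  # requested Alu count materializes in the repeat track
  expect_equal(sum(r1$bundle$repeats$label == "Alu"), cfg$alu_count)

  # every internal exon boundary appears in the junction set
  ex <- r1$bundle$genes$exons
  j <- r1$bundle$junctions
  for (g in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == g, ]
    e <- e[order(e$start), ]
    n <- nrow(e)
    expect_true(all(e$end[-n] %in% j$pos[j$side == "donor"]))
    expect_true(all(e$start[-1] %in% j$pos[j$side == "acceptor"]))
  }

  # Alu copies really are (mutated) inverted repeats of one consensus:
  # neighbouring opposite-strand copies must be far more similar under
  # reverse complement than random sequence (~25% identity)
  alus <- r1$bundle$repeats[r1$bundle$repeats$label == "Alu", ]
  fwd <- alus[alus$strand == "+", ][1, ]
  rev <- alus[alus$strand == "-", ][1, ]
  s_f <- substring(r1$genome$seq[fwd$contig], fwd$start, fwd$end)
  s_r <- substring(r1$genome$seq[rev$contig], rev$start, rev$end)
  ident <- mean(strsplit(s_f, "")[[1]] ==
                  strsplit(edconsensus:::revcomp(s_r), "")[[1]])
  expect_gt(ident, 0.6)
})

test_that("planted truth respects its structural invariants", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  tr <- ds$truth

  # editing sites and SNPs are disjoint
  expect_length(intersect(site_key(tr$editing$contig, tr$editing$pos),
                          site_key(tr$snps$contig, tr$snps$pos)), 0)

  # island sites lie inside their island, islands inside Alu intervals
  isl_sites <- tr$editing[!is.na(tr$editing$island_id), ]
  for (i in seq_len(nrow(isl_sites))) {
    isl <- tr$islands[tr$islands$island_id == isl_sites$island_id[i], ]
    expect_true(isl_sites$pos[i] >= isl$start && isl_sites$pos[i] <= isl$end)
    expect_true(isl$start >= isl$alu_start && isl$end <= isl$alu_end)
  }
  alus <- ds$bundle$repeats[ds$bundle$repeats$label == "Alu", ]
  expect_true(all(edconsensus:::points_in_track(
    isl_sites$contig, isl_sites$pos, alus)))

  # editing sites sit at reference A (plus-strand genes / + Alus) or T
  ref_bases <- mapply(function(ct, p) base_at(ds$genome, ct, p),
                      tr$editing$contig, tr$editing$pos)
  expect_true(all(ref_bases == tr$editing$ref))
  expect_true(all(tr$editing$ref %in% c("A", "T")))
  expect_true(all(ifelse(tr$editing$ref == "A", tr$editing$alt == "G",
                         tr$editing$alt == "C")))

  # ADAR activity scales levels; activity 0 silences everything
  cfg0 <- small_cfg(adar_activity = c(1, 0))
  ds0 <- simulate_dataset(cfg0)
  expect_true(all(ds0$truth$levels[, 2] == 0))
  expect_true(all(ds0$truth$levels[, 1] >= cfg0$editing_level_min))
})

test_that("edited and DEG labels are independent when enrichment is 1", {
  # chi-square independence should hold across seeds at enrichment 1
  rejected <- 0L
  for (s in 1:10) {
    set.seed(s)
    lab <- sim_gene_labels(2000L, 0.3, 1, 0.3)
    p <- suppressWarnings(chisq.test(table(lab$deg, lab$edited))$p.value)
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 2L)

  # and the planted odds ratio is recovered at enrichment 4
  set.seed(99)
  lab <- sim_gene_labels(40000L, 0.3, 4, 0.15)
  odds <- mean(lab$edited[lab$deg]) / mean(lab$edited[!lab$deg])
  expect_gt(odds, 3.4)
  expect_lt(odds, 4.6)
})

test_that("read simulation reproduces planted allele frequencies", {
  # one contig, deep coverage, no errors: binomial checks at planted sites
  cfg <- small_cfg(seed = 5, contig_length = 3000L, n_genes = 1L,
                   alu_count = 2L, island_count = 1L, n_island_sites = 4L,
                   n_isolated_sites = 2L, n_snps = 4L, coverage = 1000,
                   error_rate = 0, dup_fraction = 0, low_qual_fraction = 0,
                   simple_repeat_count = 1L, homopolymer_count = 1L,
                   n_cell_lines = 1L, n_replicates = 1L, adar_activity = 1)
  ds <- simulate_dataset(cfg)
  pu <- build_pileup(ds$reads$line1[[1]], ds$genome, ds$bundle$junctions)
  st <- pu$sites

  het <- ds$truth$snps[ds$truth$snps$genotype == "het", ]
  for (i in seq_len(nrow(het))) {
    row <- st[st$contig == het$contig[i] & st$pos == het$pos[i], ]
    if (nrow(row) == 0 || row$cov < 200) next
    alt_n <- switch(het$alt[i], A = row$a_p + row$a_m, C = row$c_p + row$c_m,
                    G = row$g_p + row$g_m, T = row$t_p + row$t_m)
    # binomial 99% interval around 0.5 at this depth
    expect_gt(alt_n / row$cov, 0.5 - 2.58 * sqrt(0.25 / row$cov) - 0.01)
    expect_lt(alt_n / row$cov, 0.5 + 2.58 * sqrt(0.25 / row$cov) + 0.01)
  }

  ed <- ds$truth$editing
  lv <- ds$truth$levels[, 1]
  for (i in seq_len(nrow(ed))) {
    row <- st[st$contig == ed$contig[i] & st$pos == ed$pos[i], ]
    if (nrow(row) == 0 || row$cov < 200) next
    alt_n <- switch(ed$alt[i], G = row$g_p + row$g_m, C = row$c_p + row$c_m)
    p0 <- lv[[ed$site_id[i]]]
    half <- 2.58 * sqrt(p0 * (1 - p0) / row$cov) + 0.01
    expect_gt(alt_n / row$cov, p0 - half)
    expect_lt(alt_n / row$cov, p0 + half)
  }
})

test_that("error-free reads with silenced variation match the reference", {
  cfg <- small_cfg(seed = 6, contig_length = 3000L, n_genes = 1L,
                   alu_count = 2L, island_count = 1L, n_island_sites = 3L,
                   n_isolated_sites = 1L, n_snps = 0L, coverage = 5,
                   error_rate = 0, dup_fraction = 0, low_qual_fraction = 0,
                   adar_activity = 0, simple_repeat_count = 1L,
                   homopolymer_count = 1L, n_cell_lines = 1L,
                   n_replicates = 1L)
  ds <- simulate_dataset(cfg)
  reads <- ds$reads$line1[[1]]
  blocks <- edconsensus:::read_blocks(reads)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i]
    ref_piece <- substring(ds$genome$seq[[reads$contig[b$read_id]]],
                           b$pos, b$end)
    read_piece <- substring(reads$seq[b$read_id], b$qoff,
                            b$qoff + b$len - 1L)
    expect_identical(read_piece, ref_piece)
  }
})

test_that("simulated SAM output is byte-deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 12, contig_length = 5000L, n_genes = 2L,
                   alu_count = 3L, island_count = 1L, n_island_sites = 3L,
                   n_isolated_sites = 3L, n_snps = 6L, coverage = 8,
                   simple_repeat_count = 2L, homopolymer_count = 2L,
                   n_cell_lines = 1L, n_replicates = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genome.fa", "reads_line1_rep1.sam", "reads_line1_rep2.sam",
              "known_snps.vcf", "expression.tsv", "truth_editing.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # different replicates differ
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "reads_line1_rep1.sam"))),
    unname(tools::md5sum(file.path(d1, "reads_line1_rep2.sam")))))
})

test_that("expression generator honours means, noise and DEG fold change", {
  cfg <- small_cfg(seed = 13, expr_log_sd = 0)
  tr <- sim_expression_truth(cfg)
  expr <- generate_expression(tr, cfg)
  # zero noise: replicates identical within each line
  expect_equal(expr[, "line1_rep1"], expr[, "line1_rep2"])
  # DEG genes move by the fold change between lines, non-DEGs do not
  lfc <- log2(expr[, "line2_rep1"]) - log2(expr[, "line1_rep1"])
  expect_true(all(abs(abs(lfc[tr$genes$deg]) - log2(cfg$deg_fold_change))
                  < 1e-9))
  expect_true(all(abs(lfc[!tr$genes$deg]) < 1e-9))

  # with noise, non-DEG mean log-ratio stays near 0 (CLT bound)
  cfg2 <- small_cfg(seed = 14, n_replicates = 3L, expr_log_sd = 0.2)
  tr2 <- sim_expression_truth(cfg2)
  e2 <- generate_expression(tr2, cfg2)
  a <- rowMeans(log2(e2[, sprintf("line1_rep%d", 1:3)]))
  b <- rowMeans(log2(e2[, sprintf("line2_rep%d", 1:3)]))
  ratio <- (b - a)[!tr2$genes$deg]
  expect_lt(abs(mean(ratio)), 3 * 0.2 * sqrt(2 / 3) / sqrt(length(ratio)) + 0.05)
})
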