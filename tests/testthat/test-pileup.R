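test_that("dedupe keeps one read per locus and is idempotent", {
  r <- rbind(
    make_read("b", "fx", 10, strrep("A", 5)),
    make_read("a", "fx", 10, strrep("C", 5)),   # same locus, smaller name
    make_read("c", "fx", 10, strrep("A", 5), strand = "-"),
    make_read("d", "fx", 10, "AAAAA", cigar = "3M2N2M"),  # different CIGAR
    make_read("e", "fx", 50, strrep("G", 5))
  )
  expect_message(dd <- dedupe_reads(r), "removed 1 duplicate")
  expect_setequal(dd$qname, c("a", "c", "d", "e"))  # 'b' lost to 'a'
  expect_identical(dedupe_reads(dd), dd)
  expect_equal(nrow(dedupe_reads(r[0, ])), 0L)
})

test_that("pileup counts bases, skips N gaps and respects the quality floor", {
  g <- make_fixture_genome()
  bundle <- make_fixture_bundle(g)
  # 3 G reads over ref at pos 9 (background base A at pos 9)
  r <- rbind(
    make_read("g1", "fx", 9, "G"), make_read("g2", "fx", 9, "G"),
    make_read("g3", "fx", 9, "G", strand = "-"),
    # spliced read: M 10-12, N 13-112, M 113-115
    make_read("sp", "fx", 10, "ACGTAG", cigar = "3M100N3M"),
    # low-quality base excluded from counts
    make_read("lq", "fx", 9, "G", qual = "+")
  )
  pu <- build_pileup(r, g, bundle$junctions)
  st <- pu$sites
  at9 <- st[st$pos == 9]
  expect_equal(at9$g_p + at9$g_m, 3L)
  expect_equal(at9$cov, 3L)  # low-quality read not counted
  # N gap contributes nothing
  expect_equal(nrow(st[st$pos %in% 13:112 & st$contig == "fx"]), 0L)
  expect_setequal(st[st$pos > 9]$pos, c(10:12, 113:115))

  # junction distance: fixture junctions at 80 (donor) and 120 (acceptor)
  r2 <- make_read("j", "fx", 77, "AAAAAA")
  st2 <- build_pileup(r2, g, bundle$junctions)$sites
  expect_equal(st2[st2$pos == 77]$jdist, 3)
  expect_equal(st2[st2$pos == 80]$jdist, 0)
  expect_equal(st2[st2$pos == 82]$jdist, 2)

  # read overrunning the contig is an error naming the read
  expect_error(build_pileup(make_read("over", "fx", 398, "ACGTA"), g, NULL),
               "over")
})

test_that("candidate calling enforces coverage and alt-count thresholds", {
  g <- make_fixture_genome()
  reads <- rbind(
    site_reads("fx", 10, "C", "T", 1, 0, 2, 1),    # cov 4: rejected
    site_reads("fx", 30, "C", "T", 4, 4, 1, 1),    # alt 2: rejected
    site_reads("fx", 50, "C", "T", 4, 3, 2, 1)     # cov 10, alt 3: called
  )
  pu <- build_pileup(reads, g, NULL)
  cand <- call_candidates(pu)
  expect_equal(cand$pos, 50L)
  expect_equal(cand$alt_count, 3L)
  expect_equal(cand$vaf, 0.3)
  expect_equal(cand$alt, "T")
  expect_equal(cand$alt_plus, 2L)
  expect_equal(cand$alt_minus, 1L)

  # tri-allelic site keeps the majority alt; ties break alphabetically
  tri <- rbind(site_reads("fx", 70, "C", "T", 5, 5, 3, 0),
               site_reads("fx", 70, "C", "G", 0, 0, 3, 0, tag = "x2"))
  pu2 <- build_pileup(tri, g, NULL)
  cand2 <- call_candidates(pu2)
  expect_equal(cand2$alt, "G")  # 3 G vs 3 T: alphabetical
})

test_that("error-free candidates are exactly the detectable planted variants", {
  cfg <- sim_config(seed = 21, contig_length = 20000L, n_genes = 5L,
                    alu_count = 5L, island_count = 2L, n_island_sites = 8L,
                    n_isolated_sites = 6L, n_snps = 20L, coverage = 25,
                    error_rate = 0, low_qual_fraction = 0,
                    simple_repeat_count = 3L, homopolymer_count = 3L,
                    n_cell_lines = 1L, n_replicates = 1L, adar_activity = 1)
  ds <- simulate_dataset(cfg)
  dd <- suppressMessages(dedupe_reads(ds$reads$line1[[1]]))
  pu <- build_pileup(dd, ds$genome, ds$bundle$junctions)
  cand <- call_candidates(pu)
  got <- site_key(cand$contig, cand$pos)

  planted <- c(site_key(ds$truth$snps$contig, ds$truth$snps$pos),
               site_key(ds$truth$editing$contig, ds$truth$editing$pos))
  # every candidate is a planted variant (no errors -> no other source)
  expect_true(all(got %in% planted))
  # and every planted variant whose pileup meets the thresholds is called
  st <- pu$sites
  key_st <- site_key(st$contig, st$pos)
  planted_df <- rbind(ds$truth$snps[, c("contig", "pos", "alt")],
                      ds$truth$editing[, c("contig", "pos", "alt")])
  for (i in seq_len(nrow(planted_df))) {
    row <- st[key_st == site_key(planted_df$contig[i], planted_df$pos[i])]
    if (nrow(row) == 0) next
    alt_n <- switch(planted_df$alt[i],
                    A = row$a_p + row$a_m, C = row$c_p + row$c_m,
                    G = row$g_p + row$g_m, T = row$t_p + row$t_m)
    if (row$cov >= 5 && alt_n >= 3)
      expect_true(site_key(planted_df$contig[i], planted_df$pos[i]) %in% got)
  }
})
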