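test_that("homopolymer detection matches a window-scan oracle", {
  # CAAAAAC: 5-run of A at 2..6
  g <- genome_ref(c(h = "CAAAAACGTCAAAACGTACG"))
  expect_true(all(site_in_homopolymer(g, "h", 2:6)))   # inside the run
  expect_true(site_in_homopolymer(g, "h", 1))          # 1 bp left of run
  expect_true(site_in_homopolymer(g, "h", 7))          # 1 bp right of run
  expect_false(site_in_homopolymer(g, "h", 9))
  # run of 4 (positions 11..14) is below the threshold
  expect_false(any(site_in_homopolymer(g, "h", 10:15)))
  # but counts at L = 4
  expect_true(all(site_in_homopolymer(g, "h", 11:14, L = 4)))
  expect_error(site_in_homopolymer(g, "h", 99), "outside")
})

test_that("strand-bias Fisher p matches exact tail enumeration", {
  # enumeration oracle: P(alt+ = x) ~ Hypergeom; two-sided p sums all
  # tables at least as extreme (probability at most the observed one)
  enum_p <- function(ap, am, cp, cm) {
    alt <- ap + am
    xs <- max(0, alt - cm):min(alt, cp)
    probs <- dhyper(xs, cp, cm, alt)
    sum(probs[probs <= dhyper(ap, cp, cm, alt) * (1 + 1e-7)])
  }
  cases <- list(c(5, 5, 55, 55), c(10, 0, 35, 25), c(3, 7, 20, 30),
                c(0, 10, 50, 10), c(2, 2, 4, 4))
  for (cs in cases) {
    expect_equal(strand_bias_test(cs[1], cs[2], cs[3], cs[4]),
                 enum_p(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-9)
  }
  # balanced alt over balanced ref: no bias, p = 1
  expect_equal(strand_bias_test(5, 5, 55, 55), 1)
  # all alt on one strand against a balanced reference fails at 0.01
  expect_lt(strand_bias_test(10, 0, 35, 25), 0.01)
  expect_error(strand_bias_test(0, 0, 0, 0), "zero total")
  expect_error(strand_bias_test(6, 0, 5, 5), "exceeds")
})

test_that("mutual information matches the plug-in formula", {
  # perfectly linked 50/50 alleles: I = H(X) = 1 bit
  x <- rep(c(0, 1), each = 25)
  expect_equal(mi_score(x, x), 1)
  # independence: joint = product of marginals -> 0 bits
  xi <- rep(c(0, 0, 1, 1), 25); yi <- rep(c(0, 1, 0, 1), 25)
  expect_equal(mi_score(xi, yi), 0)
  # joint counts [[40,10],[10,40]]: frozen value from an independent
  # hand computation of sum p log2(p / (px py))
  xj <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  yj <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  expect_equal(mi_score(xj, yj), 0.278071905113, tolerance = 1e-9)
  expect_error(mi_score(1:3, 1:4), "length")
})

test_that("mutual information is symmetric, non-negative and entropy-bounded", {
  set.seed(31)
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- ifelse(runif(n) < 0.3, x, rbinom(n, 1, 0.5))
    expect_equal(mi_score(x, y), mi_score(y, x), tolerance = 1e-12)
    expect_gte(mi_score(x, y), 0)
    expect_lte(mi_score(x, y), min(H(x), H(y)) + 1e-12)
  }
})

test_that("hard-filter cascade removes each designed violation", {
  fx <- make_cascade_fixture()
  expect_equal(nrow(fx$candidates), 10L)
  expect_false(any(fx$sub_threshold_pos %in% fx$candidates$pos))

  hf <- hardfilter_call(fx$candidates, fx$bundle, replicate = 1L)
  expect_setequal(hf$calls$pos, fx$clean_pos)
  prov <- hf$provenance
  for (p in names(fx$expected_fail)) {
    expect_equal(prov$first_fail[prov$pos == as.integer(p)],
                 unname(fx$expected_fail[p]), label = paste("site", p))
  }
  expect_true(all(is.na(prov$first_fail[prov$pos %in% fx$clean_pos])))
})

test_that("the surviving set is invariant to filter order", {
  # each filter is a pure predicate; recompute them independently here and
  # check the conjunction (any order) equals the cascade's survivors
  fx <- make_cascade_fixture()
  cand <- fx$candidates
  bundle <- fx$bundle
  ok_known <- !site_key(cand$contig, cand$pos) %in%
    site_key(bundle$known_snps$contig, bundle$known_snps$pos)
  ok_simple <- !(cand$pos >= 200 & cand$pos <= 240)
  ok_homo <- !site_in_homopolymer(fx$genome, "fx", cand$pos)
  ok_sb <- vapply(seq_len(nrow(cand)), function(i)
    fisher.test(matrix(c(cand$alt_plus[i], cand$alt_minus[i],
                         cand$ref_plus[i], cand$ref_minus[i]), 2,
                       byrow = TRUE))$p.value >= 0.01, logical(1))
  ok_vaf <- cand$vaf >= 0.10 & cand$vaf <= 0.95
  ok_j <- cand$jdist > 4
  survivors <- cand$pos[ok_known & ok_simple & ok_homo & ok_sb & ok_vaf & ok_j]
  hf <- hardfilter_call(cand, bundle)
  expect_setequal(hf$calls$pos, survivors)
  # VAF bounds are inclusive at exactly 0.10 and 0.95
  edge <- rbind(make_cand(pos = 130, alt_count = 1L, cov = 10L, vaf = 0.10,
                          alt_plus = 1L, alt_minus = 0L, ref_plus = 5L,
                          ref_minus = 4L),
                make_cand(pos = 134, alt_count = 19L, cov = 20L, vaf = 0.95,
                          alt_plus = 10L, alt_minus = 9L, ref_plus = 1L,
                          ref_minus = 0L))
  hf2 <- hardfilter_call(edge, bundle)
  expect_true(all(hf2$provenance$vaf_band))
})

test_that("MI caller separates haplotype-linked SNPs from editing", {
  # dense phased SNPs so nearly every site has a pairable anchor
  cfg <- sim_config(seed = 41, contig_length = 20000L, n_genes = 4L,
                    alu_count = 5L, island_count = 2L, n_island_sites = 8L,
                    n_isolated_sites = 8L, n_snps = 250L, het_fraction = 1,
                    known_snp_fraction = 0.8, coverage = 50,
                    error_rate = 0, dup_fraction = 0, low_qual_fraction = 0,
                    simple_repeat_count = 2L, homopolymer_count = 2L,
                    n_cell_lines = 1L, n_replicates = 1L, adar_activity = 1)
  ds <- simulate_dataset(cfg)
  dd <- suppressMessages(dedupe_reads(ds$reads$line1[[1]]))
  pu <- build_pileup(dd, ds$genome, ds$bundle$junctions)
  cand <- call_candidates(pu)
  mi <- mi_call(cand, pu, ds$bundle$known_snps, replicate = 1L)
  info <- attr(mi, "target_info")
  info$key <- site_key(info$contig, info$pos)

  ed_keys <- site_key(ds$truth$editing$contig, ds$truth$editing$pos)
  unlisted <- ds$truth$snps[!ds$truth$snps$known, ]
  un_keys <- site_key(unlisted$contig, unlisted$pos)

  # among candidates scored through the MI route (>= 1 pairable anchor):
  ed_mi <- info[info$key %in% ed_keys & info$route == "mi", ]
  un_mi <- info[info$key %in% un_keys & info$route == "mi", ]
  expect_gte(nrow(ed_mi), 10)  # the design must actually exercise the route
  expect_gte(nrow(un_mi), 5)
  expect_gte(mean(ed_mi$called), 0.8)   # editing accepted
  expect_lte(mean(un_mi$called), 0.10)  # hidden SNPs rejected by linkage

  # editing sites' MI sits far below the SNP-SNP null quantile on average
  expect_lt(mean(ed_mi$mean_mi), attr(mi, "null_quantile"))

  # empty catalog: everything falls back to the VAF band, with a warning
  empty_cat <- ds$bundle$known_snps[0, ]
  expect_warning(mi0 <- mi_call(cand, pu, empty_cat, replicate = 1L),
                 "fallback")
  expect_true(all(attr(mi0, "target_info")$route == "vaf"))
})

test_that("island caller clusters dense sites and screens isolated ones", {
  bundle <- make_fixture_bundle()
  # three sites within gap 50: one island, all called
  c1 <- rbind(make_cand(pos = 100), make_cand(pos = 120),
              make_cand(pos = 140))
  r1 <- island_call(c1, bundle, replicate = 1L)
  expect_equal(nrow(r1$islands), 1L)
  expect_equal(r1$islands$n_sites, 3L)
  expect_equal(r1$islands$start, 100L)
  expect_equal(r1$islands$end, 140L)
  expect_setequal(r1$calls$calls$pos, c(100L, 120L, 140L))

  # two sites 100 bp apart: no island; isolated sites face the hard filter
  c2 <- rbind(make_cand(pos = 100), make_cand(pos = 200))
  r2 <- island_call(c2, bundle, replicate = 1L)
  expect_equal(nrow(r2$islands), 0L)
  # pos 100 passes the cascade; pos 200 is inside the simple repeat
  expect_equal(r2$calls$calls$pos, 100L)

  # known SNPs are excluded before clustering
  c3 <- rbind(make_cand(pos = 18), make_cand(pos = 20), make_cand(pos = 22))
  r3 <- island_call(c3, bundle, replicate = 1L)
  expect_equal(nrow(r3$islands), 0L)  # the SNP at 20 broke the cluster
})

test_that("hard filter is perfectly precise on clean simulation", {
  # no sequencing errors and a complete SNP catalog: every call must be a
  # planted editing site
  cfg <- sim_config(seed = 43, contig_length = 20000L, n_genes = 5L,
                    alu_count = 5L, island_count = 2L, n_island_sites = 8L,
                    n_isolated_sites = 6L, n_snps = 25L,
                    known_snp_fraction = 1, coverage = 25, error_rate = 0,
                    low_qual_fraction = 0, simple_repeat_count = 3L,
                    homopolymer_count = 3L, n_cell_lines = 1L,
                    n_replicates = 1L, adar_activity = 1)
  ds <- simulate_dataset(cfg)
  dd <- suppressMessages(dedupe_reads(ds$reads$line1[[1]]))
  pu <- build_pileup(dd, ds$genome, ds$bundle$junctions)
  cand <- call_candidates(pu)
  bundle <- ds$bundle; bundle$genome <- ds$genome
  hf <- hardfilter_call(cand, bundle)
  ed_keys <- site_key(ds$truth$editing$contig, ds$truth$editing$pos)
  expect_gt(nrow(hf$calls), 0L)
  expect_true(all(site_key(hf$calls$contig, hf$calls$pos) %in% ed_keys))
  # and all three callers emit subsets of the candidate list
  mi <- mi_call(cand, pu, bundle$known_snps)
  isl <- island_call(cand, bundle)
  ck <- site_key(cand$contig, cand$pos)
  expect_true(all(site_key(hf$calls$contig, hf$calls$pos) %in% ck))
  expect_true(all(site_key(mi$calls$contig, mi$calls$pos) %in% ck))
  expect_true(all(site_key(isl$calls$calls$contig, isl$calls$calls$pos)
                  %in% ck))
})
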