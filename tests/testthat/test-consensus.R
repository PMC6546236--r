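mk_set <- function(pos, caller = "hard", replicate = 1L, contig = "fx",
                   ref = "A", alt = "G", vaf = 0.4) {
  calls <- data.table::data.table(contig = contig, pos = as.integer(pos),
                                  ref = ref, alt = alt, vaf = vaf,
                                  alt_count = 4L, cov = 10L)
  edconsensus:::editing_call_set(caller, replicate, calls)
}

test_that("three-method intersection follows set semantics", {
  h <- mk_set(c(10, 20, 30), "hard")
  m <- mk_set(c(10, 20), "mi")
  i <- mk_set(c(10), "island")
  inter <- intersect_methods(h, m, i)
  expect_equal(inter$pos, 10L)
  # VAF comes from the hard-filter set
  h2 <- mk_set(c(10, 20), "hard", vaf = 0.7)
  inter2 <- intersect_methods(h2, mk_set(c(10, 20), "mi"),
                              mk_set(c(10, 20), "island"))
  expect_true(all(inter2$vaf == 0.7))
  # empty input -> empty output
  expect_equal(nrow(intersect_methods(h, mk_set(integer(0), "mi"), i)), 0L)
  # mixed replicates are refused
  expect_error(intersect_methods(h, mk_set(10, "mi", replicate = 2L), i),
               "different replicates")
  # commutative/associative on the site set
  perm <- intersect_methods(i, h, m)
  expect_setequal(site_key(perm$contig, perm$pos),
                  site_key(inter$contig, inter$pos))
  # |intersection| never exceeds any single caller's count
  expect_lte(nrow(inter), min(nrow(h$calls), nrow(m$calls), nrow(i$calls)))
})

test_that("replicate combination is a union with support bookkeeping", {
  r1 <- intersect_methods(mk_set(c(1, 2), replicate = "r1"),
                          mk_set(c(1, 2), "mi", "r1"),
                          mk_set(c(1, 2), "island", "r1"))
  r2 <- intersect_methods(mk_set(c(2, 3), replicate = "r2"),
                          mk_set(c(2, 3), "mi", "r2"),
                          mk_set(c(2, 3), "island", "r2"))
  r3 <- intersect_methods(mk_set(c(3, 4), replicate = "r3"),
                          mk_set(c(3, 4), "mi", "r3"),
                          mk_set(c(3, 4), "island", "r3"))
  cons <- combine_replicates(list(r1, r2, r3), "lineA")
  expect_setequal(cons$sites$pos, 1:4)
  expect_equal(cons$sites[cons$sites$pos == 2]$n_support, 2L)
  expect_equal(cons$sites[cons$sites$pos == 2]$replicates, "r1,r2")
  # union is at least as large as any single replicate
  expect_gte(nrow(cons$sites), max(nrow(r1), nrow(r2), nrow(r3)))
  # monotone: adding a replicate never shrinks the set
  cons2 <- combine_replicates(list(r1, r2), "lineA")
  expect_true(all(cons2$sites$pos %in% cons$sites$pos))
  # identical replicates: unchanged set, support everywhere 3
  consI <- combine_replicates(list(r1, r1, r1), "lineA")
  expect_setequal(consI$sites$pos, c(1, 2))
  expect_true(all(consI$sites$n_support == 1L))  # same replicate id
  # minimum-support option
  cons3 <- combine_replicates(list(r1, r2, r3), "lineA",
                              min_replicate_support = 2L)
  expect_setequal(cons3$sites$pos, c(2, 3))
})

test_that("A-to-I restriction resolves strand through gene models", {
  genes <- data.frame(gene_id = c("gp", "gm"), contig = "fx",
                      start = c(100L, 300L), end = c(200L, 400L),
                      strand = c("+", "-"))
  exons <- genes; exons$gene_id <- genes$gene_id
  models <- gene_models(genes, exons)
  sites <- data.table::data.table(
    contig = "fx",
    pos = c(150L, 160L, 350L, 360L, 500L, 510L, 520L),
    ref = c("A", "T", "T", "A", "A", "T", "C"),
    alt = c("G", "C", "C", "G", "G", "C", "T"),
    mean_level = 0.3, n_support = 1L, replicates = "r1")
  cons <- make_consensus(sites)
  res <- restrict_a_to_i(cons, models)
  # plus-strand gene: A>G kept, T>C dropped; minus-strand gene: T>C kept,
  # A>G dropped; intergenic: both A>G and T>C kept, C>T never
  expect_setequal(res$sites$pos, c(150L, 350L, 500L, 510L))
  expect_equal(res$sites[res$sites$pos == 150]$strand, "+")
  expect_equal(res$sites[res$sites$pos == 350]$strand, "-")
  expect_true(all(res$sites[res$sites$pos >= 500]$strand == "."))
  expect_true(all(res$sites$change == "A>G"))
})
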