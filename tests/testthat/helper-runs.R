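# Expensive pipeline runs shared across test files (computed once per
# session, on first use).

.run_cache <- new.env(parent = emptyenv())

# Reference-condition recovery run: one cell line at full ADAR activity
# (editing levels >= 0.2), 200 kb, depth 30, error 0.001, 3 replicates.
default_recovery_run <- function() {
  if (is.null(.run_cache$default)) {
    cfg <- sim_config(seed = 101, n_cell_lines = 1L, adar_activity = 1)
    .run_cache$default <- run_pipeline(cfg)
  }
  .run_cache$default
}

# Small three-line study exercising the multi-line set algebra and
# enrichment plumbing.
multiline_run <- function() {
  if (is.null(.run_cache$multi)) {
    cfg <- sim_config(seed = 202, contig_length = 50000L, n_genes = 12L,
                      alu_count = 12L, island_count = 5L,
                      n_island_sites = 20L, n_isolated_sites = 15L,
                      n_snps = 50L, simple_repeat_count = 8L,
                      homopolymer_count = 6L, coverage = 20,
                      n_cell_lines = 3L, n_replicates = 3L)
    .run_cache$multi <- run_pipeline(cfg)
  }
  .run_cache$multi
}

score_line <- function(res, line = "line1") {
  cands <- lapply(res$replicate_calls[[line]], function(x) x$candidates)
  isl <- do.call(rbind, lapply(res$replicate_calls[[line]],
                               function(x) x$islands))
  score_against_truth(res$consensus[[line]], res$dataset$truth, cands, isl)
}
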