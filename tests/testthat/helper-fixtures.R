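# Shared fixtures, built in code.

# Touch the heavy S4 machinery once at load time so per-test timings
# measure the operations, not method-table initialization.
invisible(GenomicRanges::findOverlaps(
  GenomicRanges::GRanges("w", IRanges::IRanges(1, 2)),
  GenomicRanges::GRanges("w", IRanges::IRanges(1, 2))))
invisible(stats::fisher.test(matrix(1:4, 2)))

# Periodic ACGT background genome (no homopolymer runs), with an AAAAA run
# planted at 301..305.  Length 400.
make_fixture_genome <- function() {
  b <- rep(c("A", "C", "G", "T"), length.out = 400)
  b[301:305] <- "A"
  genome_ref(c(fx = paste(b, collapse = "")))
}

# One read of arbitrary length (defaults: plus strand, all Q40).
make_read <- function(qname, contig, pos, seq,
                      cigar = paste0(nchar(seq), "M"),
                      strand = "+", qual = strrep("I", nchar(seq))) {
  data.table::data.table(
    qname = qname, flag = ifelse(strand == "-", 16L, 0L), contig = contig,
    pos = as.integer(pos), strand = strand, cigar = cigar, seq = seq,
    qual = qual, dup = FALSE)
}

# Stack of 1-bp reads producing an exact designed pileup at one site.
site_reads <- function(contig, pos, ref, alt, ref_p, ref_m, alt_p, alt_m,
                       tag = sprintf("s%d", pos)) {
  n <- ref_p + ref_m + alt_p + alt_m
  base <- rep(c(ref, ref, alt, alt), c(ref_p, ref_m, alt_p, alt_m))
  strand <- rep(c("+", "-", "+", "-"), c(ref_p, ref_m, alt_p, alt_m))
  data.table::data.table(
    qname = sprintf("%s_%03d", tag, seq_len(n)),
    flag = ifelse(strand == "-", 16L, 0L), contig = contig,
    pos = as.integer(pos), strand = strand, cigar = "1M", seq = base,
    qual = "I", dup = FALSE)
}

# Candidate row with full column set, defaults balanced and unremarkable.
make_cand <- function(contig = "fx", pos, ref = "A", alt = "G",
                      alt_count = 4L, cov = 10L, vaf = alt_count / cov,
                      alt_plus = 2L, alt_minus = 2L,
                      ref_plus = 3L, ref_minus = 3L, jdist = Inf) {
  data.table::data.table(contig = contig, pos = as.integer(pos), ref = ref,
                         alt = alt, alt_count = as.integer(alt_count),
                         cov = as.integer(cov), vaf = vaf,
                         alt_plus = as.integer(alt_plus),
                         alt_minus = as.integer(alt_minus),
                         ref_plus = as.integer(ref_plus),
                         ref_minus = as.integer(ref_minus), jdist = jdist)
}

# Minimal consensus_set from a site table.
make_consensus <- function(sites, cell_line = "lineA") {
  structure(list(cell_line = cell_line,
                 sites = data.table::as.data.table(sites)),
            class = "consensus_set")
}

# Crafted filter-cascade fixture: a toy pileup built from designed 1-bp
# reads, with one site violating each hard filter plus four clean sites.
# Sites (fixture genome, junctions at 80/120, Simple repeat 200..240,
# known SNP at 20, AAAAA homopolymer 301..305):
#   clean x4:       10, 30, 60, 170
#   known SNP:      20
#   simple repeat:  210
#   homopolymer:    303
#   strand bias:    90   (alt 10/0 vs ref 25/25)
#   VAF > 0.95:     250  (39 alt / 40)
#   junction <= 4:  78   (2 bp from the donor at 80)
#   below-coverage: 350  (cov 4)  -> never becomes a candidate
#   below-alt:      370  (alt 2)  -> never becomes a candidate
make_cascade_fixture <- function() {
  g <- make_fixture_genome()
  bundle <- make_fixture_bundle(g)
  ref_at <- function(p) unname(base_at(g, "fx", p))
  alt_for <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1]
  clean <- function(p) site_reads("fx", p, ref_at(p), alt_for(p),
                                  ref_p = 3, ref_m = 3, alt_p = 2, alt_m = 2)
  reads <- rbind(
    clean(10), clean(30), clean(60), clean(170),
    clean(20),                                   # at the known SNP
    clean(210),                                  # inside the simple repeat
    clean(303),                                  # inside the AAAAA run
    site_reads("fx", 90, ref_at(90), alt_for(90), 25, 25, 10, 0),
    site_reads("fx", 250, ref_at(250), alt_for(250), 1, 0, 20, 19),
    clean(78),                                   # 2 bp from junction at 80
    site_reads("fx", 350, ref_at(350), alt_for(350), 1, 0, 2, 1),
    site_reads("fx", 370, ref_at(370), alt_for(370), 4, 4, 1, 1)
  )
  pu <- build_pileup(reads, g, bundle$junctions)
  cand <- call_candidates(pu)
  list(genome = g, bundle = bundle, pileup = pu, candidates = cand,
       clean_pos = c(10L, 30L, 60L, 170L),
       expected_fail = c("20" = "known_snp", "210" = "simple_repeat",
                         "303" = "homopolymer", "90" = "strand_bias",
                         "250" = "vaf_band", "78" = "junction"),
       sub_threshold_pos = c(350L, 370L))
}

# Annotation bundle for the fixture genome: one two-exon gene (junctions at
# 80/120), a simple repeat at 200..240, a known SNP at position 20.
make_fixture_bundle <- function(genome = make_fixture_genome()) {
  genes <- data.frame(gene_id = "g1", contig = "fx", start = 50L, end = 150L,
                      strand = "+")
  exons <- data.frame(gene_id = c("g1", "g1"), contig = "fx",
                      start = c(50L, 120L), end = c(80L, 150L), strand = "+")
  models <- gene_models(genes, exons)
  repeats <- data.frame(contig = "fx", start = 200L, end = 240L,
                        strand = "+", label = "Simple")
  known <- data.frame(contig = "fx", pos = 20L,
                      ref = base_at(genome, "fx", 20L), alt = "G",
                      source = "test")
  list(genome = genome, genes = models, repeats = repeats,
       junctions = splice_junctions(models), known_snps = known)
}
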