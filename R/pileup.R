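# Per-site observations from aligned reads: duplicate removal, pileup
# construction with a base-quality floor, and raw candidate-variant calling.

#' Remove PCR duplicates
#'
#' Among reads sharing (contig, leftmost position, strand, CIGAR) — the
#' locus-based duplicate definition Picard uses — exactly one read is kept:
#' the lexicographically smallest read name, a deterministic tie-break.
#' Idempotent.
#'
#' @param reads Read table from [read_sam()] or [simulate_reads()].
#' @return Deduplicated read table; number removed reported via message.
#' @export
dedupe_reads <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  dt <- as.data.table(reads)
  setorder(dt, contig, pos, strand, cigar, qname)
  out <- dt[, .SD[1L], by = .(contig, pos, strand, cigar)]
  removed <- nrow(dt) - nrow(out)
  if (removed > 0L)
    msgf("dedupe_reads: removed %d duplicate read(s), %d retained",
         removed, nrow(out))
  setcolorder(out, names(reads))
  setorder(out, contig, pos, qname)
  out[]
}

#' Build a per-site pileup from aligned reads
#'
#' Expands CIGAR-aligned reads into per-position base observations.  Bases
#' with quality below `min_base_qual` are excluded; N (intron) gaps
#' contribute nothing; soft-clipped bases are skipped.  Each covered site
#' records strand-split base counts, total surviving coverage, the distance
#' to the nearest splice junction, and the per-read allele list needed by
#' the mutual-information caller.
#'
#' @param reads Deduplicated read table.
#' @param genome A `genome_ref`.
#' @param junctions Splice-junction table from [splice_junctions()] (or
#'   `NULL` for none).
#' @param min_base_qual Phred floor for counting a base (default 20).
#' @return A `pileup` object: list with `sites` (one row per covered
#'   position: `contig`, `pos`, `ref`, `a_p`..`t_p`, `a_m`..`t_m`, `cov`,
#'   `jdist`) and `read_bases` (long table `contig`, `pos`, `qname`, `base`,
#'   `strand`).
#' @export
build_pileup <- function(reads, genome, junctions = NULL, min_base_qual = 20L) {
  if (nrow(reads) == 0L) {
    sites <- data.table(contig = character(), pos = integer(),
                        ref = character(), a_p = integer(), c_p = integer(),
                        g_p = integer(), t_p = integer(), a_m = integer(),
                        c_m = integer(), g_m = integer(), t_m = integer(),
                        cov = integer(), jdist = numeric())
    return(structure(list(sites = sites,
                          read_bases = data.table(contig = character(),
                                                  pos = integer(),
                                                  qname = character(),
                                                  base = character(),
                                                  strand = character())),
                     class = "pileup"))
  }
  reads <- as.data.table(reads)
  span <- cigar_ref_span(reads$cigar)
  over <- reads$pos + span - 1L > genome$lengths[reads$contig]
  if (any(over))
    stopf("read %s overruns the end of contig %s",
          reads$qname[over][1], reads$contig[over][1])

  # long expansion of aligned (M/=/X) blocks
  blocks <- read_blocks(reads)
  n <- blocks$len
  idx <- rep(seq_len(nrow(blocks)), n)
  within <- sequence(n)
  long <- data.table(
    read_id = blocks$read_id[idx],
    pos = blocks$pos[idx] + within - 1L,
    qoff = blocks$qoff[idx] + within - 1L
  )
  # pull bases and quals through one concatenated raw vector
  seq_raw <- charToRaw(paste(reads$seq, collapse = ""))
  qual_raw <- charToRaw(paste(reads$qual, collapse = ""))
  offs <- cumsum(c(0L, nchar(reads$seq)))
  gpos <- offs[long$read_id] + long$qoff
  long[, base := rawToChar(seq_raw[gpos], multiple = TRUE)]
  long[, qual := as.integer(qual_raw[gpos]) - 33L]
  long[, contig := reads$contig[read_id]]
  long[, strand := reads$strand[read_id]]
  long <- long[qual >= min_base_qual & base %in% c("A", "C", "G", "T")]

  counts <- long[, .N, by = .(contig, pos, base, strand)]
  wide <- dcast(counts, contig + pos ~ base + strand, value.var = "N",
                fill = 0L)
  for (col in as.vector(outer(c("A", "C", "G", "T"), c("+", "-"), paste,
                              sep = "_")))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  setnames(wide,
           old = c("A_+", "C_+", "G_+", "T_+", "A_-", "C_-", "G_-", "T_-"),
           new = c("a_p", "c_p", "g_p", "t_p", "a_m", "c_m", "g_m", "t_m"))
  wide[, cov := a_p + c_p + g_p + t_p + a_m + c_m + g_m + t_m]
  wide[, ref := unname(base_at(genome, contig, pos))]
  if (!is.null(junctions) && nrow(junctions)) {
    wide[, jdist := min_dist_to(contig, pos, junctions$contig, junctions$pos)]
  } else {
    wide[, jdist := Inf]
  }
  setorder(wide, contig, pos)
  setcolorder(wide, c("contig", "pos", "ref", "a_p", "c_p", "g_p", "t_p",
                      "a_m", "c_m", "g_m", "t_m", "cov", "jdist"))

  rb <- long[, .(contig, pos, qname = reads$qname[read_id], base, strand)]
  structure(list(sites = wide, read_bases = rb), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d covered site(s), %d read-base record(s)\n",
              nrow(x$sites), nrow(x$read_bases)))
  invisible(x)
}

#' Call raw candidate variants from a pileup
#'
#' A site becomes a candidate when its coverage is at least `min_cov` and
#' the most frequent non-reference base is seen in at least `min_alt` reads.
#' One candidate per site: the majority alternate allele, ties broken
#' alphabetically.
#'
#' @param pileup A `pileup` object.
#' @param min_cov Minimum total coverage (default 5).
#' @param min_alt Minimum alt-supporting reads (default 3).
#' @return A `data.table` of candidates: `contig`, `pos`, `ref`, `alt`,
#'   `alt_count`, `cov`, `vaf`, strand-split alt and ref counts, `jdist`.
#' @export
call_candidates <- function(pileup, min_cov = 5L, min_alt = 3L) {
  s <- copy(pileup$sites)
  bases <- c("A", "C", "G", "T")
  tot <- as.matrix(s[, .(A = a_p + a_m, C = c_p + c_m,
                         G = g_p + g_m, T = t_p + t_m)])
  ref_idx <- match(s$ref, bases)
  ok <- !is.na(ref_idx)
  tot_alt <- tot
  tot_alt[cbind(seq_len(nrow(tot)), ref_idx)] <- -1L
  alt_idx <- max.col(tot_alt, ties.method = "first")  # alphabetical ties
  alt_count <- tot_alt[cbind(seq_len(nrow(tot)), alt_idx)]
  s[, alt := bases[alt_idx]]
  s[, alt_count := alt_count]
  cand <- s[ok & cov >= min_cov & alt_count >= min_alt]
  if (nrow(cand) == 0L) {
    return(data.table(contig = character(), pos = integer(), ref = character(),
                      alt = character(), alt_count = integer(),
                      cov = integer(), vaf = numeric(), alt_plus = integer(),
                      alt_minus = integer(), ref_plus = integer(),
                      ref_minus = integer(), jdist = numeric()))
  }
  pick <- function(base, suff) {
    m <- as.matrix(cand[, .(a = get(paste0("a_", suff)),
                            c = get(paste0("c_", suff)),
                            g = get(paste0("g_", suff)),
                            t = get(paste0("t_", suff)))])
    m[cbind(seq_len(nrow(m)), match(base, bases))]
  }
  cand[, `:=`(
    vaf = alt_count / cov,
    alt_plus = pick(alt, "p"), alt_minus = pick(alt, "m"),
    ref_plus = pick(ref, "p"), ref_minus = pick(ref, "m")
  )]
  cand[, .(contig, pos, ref, alt, alt_count, cov, vaf, alt_plus, alt_minus,
           ref_plus, ref_minus, jdist)]
}
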