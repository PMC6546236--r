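# Internal helpers shared across modules.
#
# Coordinate convention: every position and interval inside the package is
# 1-based with closed ends (the R/Bioconductor convention).  Converting from
# the 0-based formats (BED) or to/from 1-based ones (SAM, VCF, GFF) happens
# only inside readers and writers.

# Complement lookup used for minus-strand resolution.
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(.COMP[x])

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Deterministic sub-seed derivation; stays well below 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.numeric(seed) %% 1000003
  for (i in seq_along(offs)) {
    s <- (s * 1009 + as.numeric(offs[i]) * 97 + i) %% 1000003
  }
  as.integer(s + 1)
}

#' Canonical site key
#'
#' `"contig:pos"` string used for all set algebra on sites.
#'
#' @param contig Contig name(s).
#' @param pos 1-based position(s).
#' @return Character vector of keys.
#' @export
site_key <- function(contig, pos) paste0(contig, ":", pos)

# GRanges from a data.frame of 1-based closed intervals.
as_gr <- function(df, strand_col = NULL) {
  strand <- if (!is.null(strand_col) && strand_col %in% names(df)) {
    s <- df[[strand_col]]
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand
  )
}

points_gr <- function(contig, pos) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
}

# Which points overlap any interval in `track` (data.frame contig/start/end)?
points_in_track <- function(contig, pos, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, length(pos)))
  hits <- GenomicRanges::findOverlaps(points_gr(contig, pos), as_gr(track))
  out <- rep(FALSE, length(pos))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# Minimum distance (bp) from each position to a set of per-contig positions.
# Returns Inf where the contig has no reference positions.
min_dist_to <- function(contig, pos, ref_contig, ref_pos) {
  out <- rep(Inf, length(pos))
  if (length(ref_pos) == 0L) return(out)
  for (ct in unique(contig)) {
    rp <- sort(ref_pos[ref_contig == ct])
    if (length(rp) == 0L) next
    idx <- which(contig == ct)
    i <- findInterval(pos[idx], rp)
    lo <- ifelse(i >= 1L, abs(pos[idx] - rp[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(rp), abs(rp[pmin(i + 1L, length(rp))] - pos[idx]), Inf)
    out[idx] <- pmin(lo, hi)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))
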