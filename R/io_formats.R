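# Readers and writers for the standard formats the pipeline touches.
# Everything downstream works in 1-based closed coordinates; BED input is
# converted here and nowhere else.

#' Read a reference genome from FASTA
#'
#' Loads all records of a FASTA file into an in-memory genome object.
#' Sequences are uppercased; multi-line record bodies are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_ref` object: a list with `seq` (named character vector of
#'   uppercase sequences) and `lengths` (named integer vector).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  seqs <- toupper(as.character(ss))
  # keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_ref(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of nucleotide sequences (A/C/G/T/N).
#' @return A `genome_ref` object.
#' @export
genome_ref <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("genome sequences must have unique names")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("sequence %s contains non-ACGTN characters", names(seqs)[bad][1])
  structure(
    list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %d contig(s), %s bp total\n",
              length(x$seq), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Write a genome object to FASTA
#'
#' @param genome A `genome_ref`.
#' @param path Output path.
#' @param width Line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reference base(s) at genomic positions
#'
#' @param genome A `genome_ref`.
#' @param contig Contig name(s).
#' @param pos 1-based position(s).
#' @return Character vector of reference bases.
#' @export
base_at <- function(genome, contig, pos) {
  if (length(contig) == 1L && length(pos) > 1L) contig <- rep(contig, length(pos))
  bad <- !contig %in% names(genome$seq)
  if (any(bad)) stopf("unknown contig: %s", contig[bad][1])
  if (any(pos < 1L | pos > genome$lengths[contig]))
    stopf("position outside contig bounds")
  substring(genome$seq[contig], pos, pos)
}

## ---- SAM ----

# CIGAR ops the pipeline understands.  M/=/X consume reference and query,
# N consumes reference only, S query only.
.CIGAR_OK <- c("M", "N", "S", "=", "X")

# Parse CIGAR strings into a long data.table (read_id, op, len).
cigar_ops <- function(cigars) {
  m <- gregexpr("\\d+[A-Z=]", cigars)
  toks <- regmatches(cigars, m)
  n <- lengths(toks)
  toks <- unlist(toks, use.names = FALSE)
  data.table(
    read_id = rep(seq_along(cigars), n),
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

#' Reference span consumed by CIGAR strings
#'
#' Sums the reference-consuming operations (M, N, =, X) of each CIGAR.
#'
#' @param cigars Character vector of CIGAR strings.
#' @return Integer vector of reference footprints in bp.
#' @export
cigar_ref_span <- function(cigars) {
  ops <- cigar_ops(cigars)
  ops[, sum(len[op %in% c("M", "N", "=", "X")]), by = read_id][
    match(seq_along(cigars), read_id), ifelse(is.na(V1), 0L, V1)]
}

#' Read aligned reads from a SAM file
#'
#' Parses the single-end SAM dialect the pipeline uses: `@SQ` headers are
#' required, CIGAR operations are restricted to M, N, S, `=`, X.  Unmapped
#' (FLAG 0x4) and secondary/supplementary (0x100/0x800) records are skipped;
#' the PCR-duplicate flag (0x400) is propagated.  Records with unsupported
#' CIGAR operations are dropped with a warning.
#'
#' @param path Path to a SAM file.
#' @param genome Optional `genome_ref`; when given, alignment contigs must
#'   exist in it.
#' @return A `data.table` with columns `qname`, `flag`, `contig`, `pos`
#'   (1-based leftmost), `strand`, `cigar`, `seq`, `qual`, `dup`.
#' @export
read_sam <- function(path, genome = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stopf("SAM file %s has no @SQ header lines", path)
  sq_names <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  if (!is.null(genome)) {
    missing <- setdiff(sq_names, names(genome$seq))
    if (length(missing))
      stopf("SAM header contig(s) absent from genome: %s",
            paste(missing, collapse = ", "))
  }
  if (length(body) == 0L) {
    return(data.table(qname = character(), flag = integer(),
                      contig = character(), pos = integer(),
                      strand = character(), cigar = character(),
                      seq = character(), qual = character(), dup = logical()))
  }
  f <- tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  dt <- data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), contig = f[[3]],
    pos = as.integer(f[[4]]), cigar = f[[6]], seq = f[[10]], qual = f[[11]]
  )
  dt <- dt[bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
             bitwAnd(flag, 0x800L) == 0L]
  unknown <- !dt$contig %in% sq_names
  if (any(unknown))
    stopf("alignment on contig %s missing from @SQ header", dt$contig[unknown][1])
  bad_cig <- vapply(seq_len(nrow(dt)), function(i) {
    any(!cigar_ops(dt$cigar[i])$op %in% .CIGAR_OK)
  }, logical(1))
  if (any(bad_cig)) {
    warning(sprintf("%d record(s) with unsupported CIGAR operations dropped",
                    sum(bad_cig)), call. = FALSE)
    dt <- dt[!bad_cig]
  }
  dt[, strand := ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+")]
  dt[, dup := bitwAnd(flag, 0x400L) > 0L]
  setcolorder(dt, c("qname", "flag", "contig", "pos", "strand", "cigar",
                    "seq", "qual", "dup"))
  dt[]
}

#' Write aligned reads to a SAM file
#'
#' @param reads A read table as returned by [read_sam()] or
#'   [simulate_reads()].
#' @param genome A `genome_ref` supplying the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq),
                   unname(genome$lengths)))
  flag <- reads$flag %||% (ifelse(reads$strand == "-", 16L, 0L) +
                             ifelse(isTRUE(reads$dup), 1024L, 0L))
  body <- if (nrow(reads)) {
    paste(reads$qname, flag, reads$contig, reads$pos, 60L, reads$cigar,
          "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- intervals: BED and GFF-lite ----

#' Read genomic intervals or gene models
#'
#' BED (3-6 columns, 0-based half-open) is converted to the internal 1-based
#' closed convention.  The GFF-lite dialect is tab-separated with columns
#' contig, source, type (gene|exon), start (1-based), end (inclusive), score,
#' strand, frame, attributes (`gene_id=<id>`); gene and exon lines are
#' assembled into gene models keyed by `gene_id`.
#'
#' @param path Path to the file.
#' @param format `"bed"` or `"gff"`.
#' @return For BED, a `data.frame` with columns `contig`, `start`, `end`,
#'   `label`, `strand`.  For GFF, a `gene_models` object.
#' @export
read_intervals <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  tb <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  if (format == "bed") {
    if (ncol(tb) < 3L) stopf("BED file %s needs at least 3 columns", path)
    df <- data.frame(
      contig = tb[[1]],
      start = as.integer(tb[[2]]) + 1L,   # 0-based -> 1-based
      end = as.integer(tb[[3]]),          # half-open end == closed end
      label = if (ncol(tb) >= 4L) tb[[4]] else ".",
      strand = if (ncol(tb) >= 6L) tb[[6]] else ".",
      stringsAsFactors = FALSE
    )
    if (any(df$start > df$end)) stopf("empty/negative BED interval in %s", path)
    return(df)
  }
  if (ncol(tb) < 9L) stopf("GFF-lite file %s needs 9 columns", path)
  gid <- sub("^.*gene_id=([^;]+).*$", "\\1", tb[[9]])
  df <- data.frame(
    contig = tb[[1]], type = tb[[3]],
    start = as.integer(tb[[4]]), end = as.integer(tb[[5]]),
    strand = tb[[7]], gene_id = gid, stringsAsFactors = FALSE
  )
  genes <- df[df$type == "gene", c("gene_id", "contig", "start", "end", "strand")]
  exons <- df[df$type == "exon", c("gene_id", "contig", "start", "end", "strand")]
  gene_models(genes, exons)
}

#' Construct gene models from gene and exon tables
#'
#' @param genes `data.frame` with `gene_id`, `contig`, `start`, `end`,
#'   `strand` (one row per gene).
#' @param exons `data.frame` with the same columns (one row per exon).
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene_id in gene table")
  exons <- exons[order(exons$gene_id, exons$start), ]
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, ]
    gi <- genes[genes$gene_id == g, ]
    if (nrow(gi) == 0L) stopf("exon references unknown gene_id %s", g)
    if (any(ex$start < gi$start | ex$end > gi$end))
      stopf("exon outside gene span for gene_id %s", g)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stopf("overlapping exons in gene_id %s", g)
    if (any(ex$strand != gi$strand))
      stopf("exon strand differs from gene strand in gene_id %s", g)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Splice-junction positions of a set of gene models
#'
#' Internal exon boundaries only: the last base of each non-terminal exon
#' (donor side) and the first base of each non-initial exon (acceptor side),
#' in 1-based coordinates.
#'
#' @param models A `gene_models` object.
#' @return `data.frame` with columns `contig`, `pos`, `side`.
#' @export
splice_junctions <- function(models) {
  out <- list()
  for (g in unique(models$exons$gene_id)) {
    ex <- models$exons[models$exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    n <- nrow(ex)
    if (n < 2L) next
    out[[g]] <- data.frame(
      contig = ex$contig[1],
      pos = c(ex$end[-n], ex$start[-1L]),
      side = rep(c("donor", "acceptor"), each = n - 1L),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(), pos = integer(),
                      side = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  unique(res)
}

#' Write gene models as GFF-lite
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  g <- models$genes
  e <- models$exons
  lines <- c(
    sprintf("%s\tedconsensus\tgene\t%d\t%d\t.\t%s\t.\tgene_id=%s",
            g$contig, g$start, g$end, g$strand, g$gene_id),
    sprintf("%s\tedconsensus\texon\t%d\t%d\t.\t%s\t.\tgene_id=%s",
            e$contig, e$start, e$end, e$strand, e$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df Interval `data.frame` (`contig`, `start`, `end`, `label`,
#'   `strand`), 1-based closed; converted to BED's 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   df$contig, df$start - 1L, df$end,
                   df$label %||% ".", df$strand %||% ".")
  writeLines(lines, path)
  invisible(path)
}

## ---- VCF ----

#' Read an SNV catalog from VCF
#'
#' Used both for known-SNP catalogs (dbSNP-like) and DNA-seq variant calls.
#' Positions are kept 1-based; multi-allelic records are split into one entry
#' per alternate allele; records that are not single-nucleotide substitutions
#' are skipped (count reported via message).
#'
#' @param path Path to a VCF 4.x file.
#' @param genome Optional `genome_ref` for reference-allele validation.
#' @param source Tag recorded in the `source` column.
#' @return `data.frame` with columns `contig`, `pos`, `ref`, `alt`, `source`.
#' @export
read_variant_catalog <- function(path, genome = NULL, source = basename(path)) {
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), source = character(),
                      stringsAsFactors = FALSE)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) {
      # header-only VCFs are legal (empty call set)
      lines <- readLines(path)
      if (all(startsWith(lines[nzchar(lines)], "#"))) return(NULL)
      stopf("failed to parse VCF %s: %s", path, conditionMessage(e))
    }
  )
  if (is.null(v)) return(empty)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCF
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  df <- data.frame(
    contig = rep(fix$CHROM, n),
    pos = rep(as.integer(fix$POS), n),
    ref = rep(fix$REF, n),
    alt = unlist(alts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  if (any(!snv))
    msgf("read_variant_catalog: skipped %d non-SNV record(s)", sum(!snv))
  df <- df[snv, , drop = FALSE]
  if (!is.null(genome) && nrow(df)) {
    obs <- base_at(genome, df$contig, df$pos)
    bad <- obs != df$ref
    if (any(bad))
      stopf("VCF REF mismatch vs genome at: %s",
            paste(site_key(df$contig[bad], df$pos[bad]), collapse = ", "))
  }
  df$source <- source
  rownames(df) <- NULL
  df
}

#' Write an SNV table as VCF 4.2
#'
#' @param df `data.frame` with `contig`, `pos` (1-based), `ref`, `alt` and
#'   optionally `info` (preformatted INFO strings).
#' @param path Output path.
#' @param genome Optional `genome_ref` for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(df, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=edconsensus")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$seq), unname(genome$lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(df)) {
    o <- order(df$contig, df$pos)
    d <- df[o, , drop = FALSE]
    paste(d$contig, d$pos, ".", d$ref, d$alt, ".", "PASS",
          d$info %||% ".", sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a consensus editing call set as VCF 4.2
#'
#' INFO fields: `EDLEV` (mean editing level), `DP` (coverage), `AD` (alt
#' reads), `METHODS` (comma list of supporting callers).  Calls are sorted by
#' position before writing; a message is emitted if input order changed.
#'
#' @param calls `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `level` and optionally `dp`, `ad`, `methods`.
#' @param path Output path.
#' @param genome Optional `genome_ref` for header contig lines.
#' @return `path`, invisibly.
#' @export
write_editing_vcf <- function(calls, path, genome = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=edconsensus",
    "##INFO=<ID=EDLEV,Number=1,Type=Float,Description=\"Mean editing level\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read coverage\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
    "##INFO=<ID=METHODS,Number=.,Type=String,Description=\"Supporting callers\">"
  )
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$seq), unname(genome$lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character()
  if (nrow(calls)) {
    o <- order(calls$contig, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      msgf("write_editing_vcf: calls were unsorted; sorted before writing")
    d <- calls[o, , drop = FALSE]
    info <- sprintf("EDLEV=%.4g;DP=%d;AD=%d;METHODS=%s",
                    d$level %||% rep(NA_real_, nrow(d)),
                    as.integer(d$dp %||% rep(0L, nrow(d))),
                    as.integer(d$ad %||% rep(0L, nrow(d))),
                    d$methods %||% rep("consensus", nrow(d)))
    body <- paste(d$contig, d$pos, ".", d$ref, d$alt, ".", "PASS", info,
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
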