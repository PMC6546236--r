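# Region classification, edited-gene assignment, cell-line-specific
# partitions, and per-gene genomic-SNV counting.

#' Classify consensus sites by Alu and gene-body context
#'
#' A site is `Alu` iff it overlaps an Alu-labelled repeat interval and
#' `genebody` iff it lies within any gene span (either strand); otherwise
#' `intergenic`.  Total over all sites.
#'
#' @param sites `data.frame` with `contig`, `pos` (e.g. a
#'   `consensus_set$sites`).
#' @param repeat_track Repeat intervals with a `label` column.
#' @param gene_models A `gene_models` object.
#' @return `data.frame` `sites` with added columns `alu_flag`
#'   (`"Alu"`/`"nonAlu"`) and `locus_flag` (`"genebody"`/`"intergenic"`).
#' @export
classify_region <- function(sites, repeat_track, gene_models) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0L) {
    sites$alu_flag <- character(0)
    sites$locus_flag <- character(0)
    return(sites)
  }
  alu <- repeat_track[repeat_track$label == "Alu", , drop = FALSE]
  in_alu <- points_in_track(sites$contig, sites$pos, alu)
  genes <- gene_models$genes
  in_gene <- points_in_track(sites$contig, sites$pos,
                             data.frame(contig = genes$contig,
                                        start = genes$start,
                                        end = genes$end))
  sites$alu_flag <- ifelse(in_alu, "Alu", "nonAlu")
  sites$locus_flag <- ifelse(in_gene, "genebody", "intergenic")
  sites
}

#' Assign consensus editing sites to genes
#'
#' A gene is "edited" iff at least one consensus site overlaps its span;
#' a site overlapping several genes counts for each of them (bedops-style
#' interval join).
#'
#' @param consensus A `consensus_set` (or its `sites` table).
#' @param gene_models A `gene_models` object.
#' @return `data.frame` with one row per edited gene: `gene_id`,
#'   `n_sites`, `sites` (comma-joined site keys).
#' @export
assign_genes <- function(consensus, gene_models) {
  sites <- if (inherits(consensus, "consensus_set")) consensus$sites else consensus
  sites <- as.data.frame(sites)
  empty <- data.frame(gene_id = character(), n_sites = integer(),
                      sites = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  genes <- gene_models$genes
  hits <- GenomicRanges::findOverlaps(
    points_gr(sites$contig, sites$pos),
    as_gr(data.frame(contig = genes$contig, start = genes$start,
                     end = genes$end)))
  if (length(hits) == 0L) return(empty)
  df <- data.table(gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                   key_ = site_key(sites$contig, sites$pos)[
                     S4Vectors::queryHits(hits)])
  out <- df[, .(n_sites = uniqueN(key_),
                sites = paste(sort(unique(key_)), collapse = ",")),
            by = gene_id]
  setorder(out, gene_id)
  as.data.frame(out)
}

#' Cell-line-specific site and gene partitions
#'
#' For each cell line: the consensus sites present in that line and absent
#' from every other line, the full Venn-region counts (which sum exactly to
#' the size of the union), and per-line edited genes flagged by whether they
#' contain a line-specific site.
#'
#' @param consensus_sets Named list of >= 2 `consensus_set`s.
#' @param gene_models A `gene_models` object for the per-gene flags.
#' @return List with `specific_sites` (per-line character vectors of site
#'   keys), `venn` (`data.frame` `region`, `count`), `gene_tables` (per-line
#'   [assign_genes()] output with `has_specific` flag), and `pct_specific`
#'   (per-line percentage of edited genes containing a line-specific site).
#' @export
specific_sites <- function(consensus_sets, gene_models = NULL) {
  if (length(consensus_sets) < 2L)
    stopf("specific_sites: need at least two cell lines")
  nm <- names(consensus_sets) %||% sprintf("line%d", seq_along(consensus_sets))
  if (is.null(names(consensus_sets))) names(consensus_sets) <- nm
  keys <- lapply(consensus_sets, function(cs) {
    s <- cs$sites
    if (nrow(s)) site_key(s$contig, s$pos) else character()
  })
  universe <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  region <- apply(member, 1L, function(r) paste(nm[r], collapse = "&"))
  venn_counts <- table(factor(region))
  all_regions <- unlist(lapply(seq_along(nm), function(k)
    combn(nm, k, paste, collapse = "&", simplify = TRUE)))
  venn <- data.frame(region = all_regions,
                     count = as.integer(venn_counts[all_regions]),
                     stringsAsFactors = FALSE)
  venn$count[is.na(venn$count)] <- 0L

  spec <- lapply(nm, function(l) universe[member[, l] & rowSums(member) == 1L])
  names(spec) <- nm

  gene_tables <- NULL
  pct <- NULL
  if (!is.null(gene_models)) {
    gene_tables <- lapply(nm, function(l) {
      gt <- assign_genes(consensus_sets[[l]], gene_models)
      if (nrow(gt)) {
        gt$has_specific <- vapply(strsplit(gt$sites, ",", fixed = TRUE),
                                  function(ss) any(ss %in% spec[[l]]),
                                  logical(1))
      } else gt$has_specific <- logical(0)
      gt
    })
    names(gene_tables) <- nm
    pct <- vapply(gene_tables, function(gt)
      if (nrow(gt)) 100 * mean(gt$has_specific) else NA_real_, numeric(1))
  }
  list(specific_sites = spec, venn = venn, gene_tables = gene_tables,
       pct_specific = pct)
}

#' Count genomic SNVs over a gene and its exons
#'
#' @param snv_catalog DNA-seq SNV table (from [read_variant_catalog()]).
#' @param gene_models A `gene_models` object.
#' @param gene_id Gene to count for.
#' @param known_catalog Optional known-SNP table; span SNVs absent from it
#'   are counted as novel.
#' @return List with `span_count`, `exon_count`, `novel_count`.
#' @export
count_snvs_per_gene <- function(snv_catalog, gene_models, gene_id,
                                known_catalog = NULL) {
  g <- gene_models$genes[gene_models$genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) stopf("gene_id '%s' not found in gene models", gene_id)
  ex <- gene_models$exons[gene_models$exons$gene_id == gene_id, ]
  sv <- as.data.frame(snv_catalog)
  in_span <- sv$contig == g$contig & sv$pos >= g$start & sv$pos <= g$end
  span_sv <- sv[in_span, , drop = FALSE]
  in_exon <- points_in_track(span_sv$contig, span_sv$pos,
                             data.frame(contig = ex$contig, start = ex$start,
                                        end = ex$end))
  novel <- if (!is.null(known_catalog)) {
    !site_key(span_sv$contig, span_sv$pos) %in%
      site_key(known_catalog$contig, known_catalog$pos)
  } else rep(NA, nrow(span_sv))
  list(span_count = nrow(span_sv),
       exon_count = sum(in_exon),
       novel_count = if (all(is.na(novel))) NA_integer_ else sum(novel))
}
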