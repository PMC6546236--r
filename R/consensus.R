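# Consensus set algebra: intersect the three callers within a replicate,
# union replicates within a cell line, and restrict to A-to-I changes after
# strand resolution.

#' Intersect the three callers' call sets for one replicate
#'
#' Site-key intersection of the hard-filter, MI and island call sets from
#' the same replicate.  Per-site VAF, ref and alt are taken from the
#' hard-filter caller (the canonical source, since it alone guarantees the
#' count thresholds).
#'
#' @param set_hard,set_mi,set_island `editing_call_set`s from one replicate
#'   (the island caller's `$calls` element).
#' @return A `data.table` of intersected calls with the replicate id
#'   attached as attribute `replicate`.
#' @export
intersect_methods <- function(set_hard, set_mi, set_island) {
  sets <- list(set_hard, set_mi, set_island)
  reps <- vapply(sets, function(s) as.character(s$replicate), character(1))
  if (length(unique(reps)) != 1L)
    stopf("intersect_methods: call sets come from different replicates (%s)",
          paste(reps, collapse = ", "))
  keys <- lapply(sets, function(s)
    if (nrow(s$calls)) site_key(s$calls$contig, s$calls$pos) else character())
  common <- Reduce(intersect, keys)
  calls <- set_hard$calls[site_key(contig, pos) %in% common]
  out <- calls[, .(contig, pos, ref, alt, vaf)]
  setattr(out, "replicate", set_hard$replicate)
  out
}

#' Union replicate call sets into a per-cell-line consensus
#'
#' Union of site keys across replicates; each site records the supporting
#' replicates and the mean editing level (VAF) over them.  Optionally
#' requires support in at least `min_replicate_support` replicates.
#'
#' @param per_replicate_sets List of tables from [intersect_methods()].
#' @param cell_line Cell-line identifier.
#' @param min_replicate_support Minimum number of supporting replicates for
#'   a site to be kept (default 1, i.e. plain union).
#' @return A `consensus_set`: list with `cell_line` and `sites`
#'   (`contig`, `pos`, `ref`, `alt`, `mean_level`, `n_support`,
#'   `replicates`).
#' @export
combine_replicates <- function(per_replicate_sets, cell_line = "line1",
                               min_replicate_support = 1L) {
  if (length(per_replicate_sets) == 0L)
    stopf("combine_replicates: need at least one replicate set")
  tagged <- rbindlist(lapply(per_replicate_sets, function(s) {
    dt <- as.data.table(s)
    dt[, replicate := as.character(attr(s, "replicate") %||% NA_character_)]
    dt
  }), fill = TRUE)
  if (nrow(tagged) == 0L) {
    sites <- data.table(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        mean_level = numeric(), n_support = integer(),
                        replicates = character())
  } else {
    sites <- tagged[, .(ref = ref[1L], alt = alt[1L],
                        mean_level = mean(vaf),
                        n_support = uniqueN(replicate),
                        replicates = paste(sort(unique(replicate)),
                                           collapse = ",")),
                    by = .(contig, pos)]
    sites <- sites[n_support >= min_replicate_support]
    setorder(sites, contig, pos)
  }
  structure(list(cell_line = cell_line, sites = sites[]),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> cell line '%s': %d site(s)\n",
              x$cell_line, nrow(x$sites)))
  invisible(x)
}

#' Restrict a consensus set to A-to-I changes
#'
#' The editing strand is resolved from overlapping gene models: a site in a
#' plus-strand gene is A-to-I iff the plus-strand observation is A>G; in a
#' minus-strand gene iff it is T>C (the reverse complement).  Intergenic
#' sites keep whichever of A>G / T>C the plus-strand mismatch already is,
#' reported with strand ".".  All other mismatch types are removed.
#'
#' @param consensus A `consensus_set`.
#' @param gene_models A `gene_models` object.
#' @return The filtered `consensus_set` with added columns `strand` and
#'   `change` (always `"A>G"` on the resolved strand).
#' @export
restrict_a_to_i <- function(consensus, gene_models) {
  s <- copy(consensus$sites)
  if (nrow(s) == 0L) {
    s[, `:=`(strand = character(), change = character())]
    consensus$sites <- s
    return(consensus)
  }
  genes <- gene_models$genes
  hits <- GenomicRanges::findOverlaps(
    points_gr(s$contig, s$pos),
    as_gr(data.frame(contig = genes$contig, start = genes$start,
                     end = genes$end)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  has_plus <- has_minus <- logical(nrow(s))
  has_plus[unique(qh[genes$strand[sh] == "+"])] <- TRUE
  has_minus[unique(qh[genes$strand[sh] == "-"])] <- TRUE

  is_ag <- s$ref == "A" & s$alt == "G"
  is_tc <- s$ref == "T" & s$alt == "C"
  genic <- has_plus | has_minus
  keep <- (has_plus & is_ag) | (has_minus & is_tc) | (!genic & (is_ag | is_tc))
  stv <- rep(".", nrow(s))
  stv[has_plus & is_ag] <- "+"
  stv[has_minus & is_tc] <- "-"
  s[, strand := stv]
  s[, change := "A>G"]
  consensus$sites <- s[keep]
  consensus
}
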