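# Three independent editing-calling strategies over a shared candidate list:
#   * hardfilter_call — a strict cascade of annotation/statistics filters;
#   * mi_call         — mutual-information allelic linkage against known SNPs
#                       (an empirical-quantile rule standing in for the
#                       trained classifier of the original MI method);
#   * island_call     — single-linkage clustering into editing islands.

#' Filter parameters
#'
#' Thresholds of the hard-filter cascade and the other callers: minimum
#' coverage 5 and 3 alt reads, homopolymer run length 5 nt, strand-bias
#' Fisher alpha 0.01, variant-allele-frequency band \[0.10, 0.95\]
#' (inclusive at both bounds; only strictly more extreme frequencies are
#' removed), junction distance 4 nt, island gap 50 bp with at least 3 member
#' sites, and the MI caller's minimum shared-read count and null quantile.
#'
#' @param min_cov,min_alt Candidate count thresholds.
#' @param homopolymer_len Minimal run length counted as homopolymer.
#' @param vaf_low,vaf_high Inclusive VAF acceptance band.
#' @param junction_dist Sites at most this many nt from a splice junction
#'   are removed.
#' @param strand_bias_alpha Fisher exact alpha for strand bias.
#' @param island_gap,island_min_sites Island clustering parameters.
#' @param mi_min_shared Minimum reads shared by a site pair for MI.
#' @param mi_null_quantile Quantile of the SNP-SNP MI null below which a
#'   candidate's mean MI indicates editing.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_cov = 5L, min_alt = 3L, homopolymer_len = 5L,
                          vaf_low = 0.10, vaf_high = 0.95,
                          junction_dist = 4L, strand_bias_alpha = 0.01,
                          island_gap = 50L, island_min_sites = 3L,
                          mi_min_shared = 5L, mi_null_quantile = 0.05) {
  p <- as.list(environment())
  if (!(p$vaf_low >= 0 && p$vaf_low < p$vaf_high && p$vaf_high <= 1))
    stopf("filter_params: need 0 <= vaf_low < vaf_high <= 1")
  if (p$homopolymer_len < 2L) stopf("filter_params: homopolymer_len >= 2")
  if (p$junction_dist < 0L) stopf("filter_params: junction_dist >= 0")
  structure(p, class = "filter_params")
}

#' Is a site inside (or adjacent to) a homopolymer run?
#'
#' TRUE when the position lies within, or immediately adjacent to (+/- 1 bp),
#' a maximal run of at least `L` identical reference bases.
#'
#' @param genome A `genome_ref`.
#' @param contig Contig name (scalar).
#' @param pos 1-based position(s).
#' @param L Minimal run length (default 5).
#' @return Logical vector.
#' @export
site_in_homopolymer <- function(genome, contig, pos, L = 5L) {
  if (any(pos < 1L | pos > genome$lengths[[contig]]))
    stopf("position outside contig %s", contig)
  mask <- homopolymer_mask(genome$seq[[contig]], L)
  mask[pos]
}

#' Fisher exact test for strand bias
#'
#' Two-sided Fisher exact p-value on the 2x2 table
#' `[[alt+, alt-], [ref+, ref-]]` where ref counts are coverage minus alt on
#' each strand.  Vectorized over candidates.
#'
#' @param alt_plus,alt_minus Alt-supporting reads per strand.
#' @param cov_plus,cov_minus Total (ref+alt) informative reads per strand.
#' @return Numeric vector of p-values.
#' @export
strand_bias_test <- function(alt_plus, alt_minus, cov_plus, cov_minus) {
  n <- length(alt_plus)
  if (any(alt_plus > cov_plus | alt_minus > cov_minus))
    stopf("strand_bias_test: alt exceeds coverage")
  if (any(cov_plus + cov_minus == 0L))
    stopf("strand_bias_test: zero total coverage")
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(alt_plus[i], alt_minus[i],
                    cov_plus[i] - alt_plus[i], cov_minus[i] - alt_minus[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

# Shared constructor for a caller's result.
editing_call_set <- function(caller, replicate, calls, provenance = NULL) {
  structure(list(caller = caller, replicate = replicate,
                 calls = as.data.table(calls), provenance = provenance),
            class = "editing_call_set")
}

#' @export
print.editing_call_set <- function(x, ...) {
  cat(sprintf("<editing_call_set> caller '%s', replicate %s: %d call(s)\n",
              x$caller, as.character(x$replicate), nrow(x$calls)))
  invisible(x)
}

#' Strict hard-filter editing caller
#'
#' Applies, in order, recording each verdict: (0) coverage and alt-read
#' count; (1) known-SNP removal; (2) simple-repeat regions; (3) homopolymer
#' runs (>= `homopolymer_len` nt, +/- 1 bp); (4) strand bias (Fisher exact
#' p < alpha); (5) extreme variant allele frequency (strictly > `vaf_high`
#' or < `vaf_low`); (6) proximity to a known splice junction
#' (<= `junction_dist` nt).  Survivors become calls.  The surviving set is
#' invariant to filter order (each filter is a pure predicate); order
#' affects provenance only.
#'
#' @param candidates Candidate table from [call_candidates()].
#' @param bundle Annotation bundle: list with `genome` or precomputed
#'   homopolymer info, `repeats` (with `label` column), `known_snps`,
#'   `junctions`; typically `simulate_dataset()$bundle` plus `genome`.
#' @param params A [filter_params()].
#' @param replicate Replicate identifier carried into the call set.
#' @param genome A `genome_ref` (used for the homopolymer scan when not in
#'   `bundle`).
#' @return An `editing_call_set`; `$provenance` holds one row per candidate
#'   with per-filter verdicts and `first_fail`.
#' @export
hardfilter_call <- function(candidates, bundle, params = filter_params(),
                            replicate = 1L, genome = bundle$genome) {
  if (is.null(bundle$repeats)) stopf("annotation bundle lacks repeat track")
  if (is.null(bundle$known_snps)) stopf("annotation bundle lacks known-SNP catalog")
  if (is.null(genome)) stopf("hardfilter_call needs a genome")
  cand <- as.data.table(candidates)
  n <- nrow(cand)
  if (n == 0L) {
    return(editing_call_set("hardfilter", replicate,
                            data.table(contig = character(), pos = integer(),
                                       ref = character(), alt = character(),
                                       vaf = numeric())))
  }
  verdicts <- data.table(contig = cand$contig, pos = cand$pos)

  verdicts[, min_cov := cand$cov >= params$min_cov]
  verdicts[, min_alt := cand$alt_count >= params$min_alt]

  ks <- bundle$known_snps
  verdicts[, known_snp := !site_key(cand$contig, cand$pos) %in%
             site_key(ks$contig, ks$pos)]

  simple <- bundle$repeats[bundle$repeats$label != "Alu", , drop = FALSE]
  verdicts[, simple_repeat := !points_in_track(cand$contig, cand$pos, simple)]

  hp <- logical(n)
  for (ct in unique(cand$contig)) {
    i <- cand$contig == ct
    hp[i] <- site_in_homopolymer(genome, ct, cand$pos[i],
                                 params$homopolymer_len)
  }
  verdicts[, homopolymer := !hp]

  sb_p <- strand_bias_test(cand$alt_plus, cand$alt_minus,
                           cand$alt_plus + cand$ref_plus,
                           cand$alt_minus + cand$ref_minus)
  verdicts[, strand_bias := sb_p >= params$strand_bias_alpha]

  verdicts[, vaf_band := cand$vaf >= params$vaf_low &
             cand$vaf <= params$vaf_high]

  verdicts[, junction := cand$jdist > params$junction_dist]

  filter_cols <- c("min_cov", "min_alt", "known_snp", "simple_repeat",
                   "homopolymer", "strand_bias", "vaf_band", "junction")
  vm <- as.matrix(verdicts[, ..filter_cols])
  pass <- rowSums(!vm) == 0L
  first_fail <- apply(vm, 1L, function(r) {
    f <- which(!r)
    if (length(f)) filter_cols[f[1L]] else NA_character_
  })
  verdicts[, first_fail := first_fail]
  verdicts[, pass := pass]

  calls <- cand[pass, .(contig, pos, ref, alt, vaf, alt_count, cov)]
  editing_call_set("hardfilter", replicate, calls, provenance = verdicts[])
}

#' Plug-in mutual information between two allele vectors
#'
#' `I(X; Y) = sum p(x, y) log2[ p(x, y) / (p(x) p(y)) ]` over the reads
#' shared by two sites, with `0 log 0 = 0`.  Symmetric, non-negative, and
#' bounded by `min(H(X), H(Y))`.
#'
#' @param x,y Equal-length vectors of per-read alleles at the two sites
#'   (any discrete coding, e.g. `"ref"`/`"alt"`).
#' @return Mutual information in bits.
#' @export
mi_score <- function(x, y) {
  if (length(x) != length(y)) stopf("mi_score: allele vectors differ in length")
  if (length(x) == 0L) stopf("mi_score: no shared reads")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Mutual-information (allelic linkage) editing caller
#'
#' Alleles of a genomic SNP co-segregate with the read's haplotype, so the
#' mutual information between a true SNP and a nearby known het SNP is high;
#' editing happens independently per transcript, so an editing site's MI
#' with SNPs stays near zero.  For each candidate not itself in the known
#' catalog, the caller computes the mean MI against catalog sites sharing at
#' least `mi_min_shared` reads; the null distribution is built from
#' catalog-catalog pairs, and the candidate is called editing when its mean
#' MI falls below the `mi_null_quantile` quantile of that null.  Candidates
#' with no pairable SNP fall back to the hard-filter VAF band; an empty
#' catalog routes everything to the fallback with a warning.
#'
#' @param candidates Candidate table from [call_candidates()].
#' @param pileup The `pileup` the candidates came from (supplies per-read
#'   alleles).
#' @param catalog Known-SNP catalog (`data.frame` with `contig`, `pos`).
#' @param params A [filter_params()].
#' @param replicate Replicate identifier.
#' @return An `editing_call_set` (caller `"mi"`); per-call columns include
#'   `mean_mi`, `n_partners`, `route` (`"mi"` or `"vaf"`).
#' @export
mi_call <- function(candidates, pileup, catalog, params = filter_params(),
                    replicate = 1L) {
  cand <- as.data.table(candidates)
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(), vaf = numeric(),
                      mean_mi = numeric(), n_partners = integer(),
                      route = character())
  if (nrow(cand) == 0L)
    return(editing_call_set("mi", replicate, empty))

  ckey <- site_key(cand$contig, cand$pos)
  kkey <- if (nrow(catalog)) site_key(catalog$contig, catalog$pos) else character()
  is_snp <- ckey %in% kkey
  if (length(kkey) == 0L)
    warning("mi_call: empty known-SNP catalog; all candidates use the VAF fallback",
            call. = FALSE)

  # per-read binarized alleles at candidate sites (anchors = known SNPs)
  rb <- pileup$read_bases[site_key(contig, pos) %in% ckey]
  site_info <- cand[, .(contig, pos, ref, alt)]
  rb <- merge(rb, site_info, by = c("contig", "pos"))
  rb <- rb[base == ref | base == alt]
  rb[, allele := as.integer(base == alt)]

  anchors <- cand[is_snp]
  targets <- cand[!is_snp]
  if (nrow(targets) == 0L)
    return(editing_call_set("mi", replicate, empty))

  allele_list <- split(rb[, .(qname, allele)],
                       site_key(rb$contig, rb$pos))
  pair_mi <- function(k1, k2) {
    a <- allele_list[[k1]]; b <- allele_list[[k2]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    m <- merge(a, b, by = "qname")
    if (nrow(m) < params$mi_min_shared) return(NA_real_)
    # partner must be informative (both alleles seen among shared reads)
    if (length(unique(m$allele.y)) < 2L) return(NA_real_)
    mi_score(m$allele.x, m$allele.y)
  }

  reach <- 2000L  # only nearby sites can share reads; cheap prefilter
  akey <- site_key(anchors$contig, anchors$pos)

  # null: anchor-anchor MI
  null_mi <- numeric(0)
  if (nrow(anchors) >= 2L) {
    for (i in seq_len(nrow(anchors) - 1L)) {
      near <- which(anchors$contig == anchors$contig[i] &
                      abs(anchors$pos - anchors$pos[i]) <= reach)
      near <- near[near > i]
      for (j in near) {
        v <- pair_mi(akey[i], akey[j])
        if (!is.na(v)) null_mi <- c(null_mi, v)
      }
    }
  }
  thresh <- if (length(null_mi))
    as.numeric(quantile(null_mi, params$mi_null_quantile, type = 1)) else NA_real_

  tkey <- site_key(targets$contig, targets$pos)
  mean_mi <- rep(NA_real_, nrow(targets))
  n_part <- integer(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    near <- which(anchors$contig == targets$contig[i] &
                    abs(anchors$pos - targets$pos[i]) <= reach)
    if (!length(near)) next
    vals <- vapply(near, function(j) pair_mi(tkey[i], akey[j]), numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      mean_mi[i] <- mean(vals)
      n_part[i] <- length(vals)
    }
  }

  route <- ifelse(n_part > 0L & !is.na(thresh), "mi", "vaf")
  called_mi <- route == "mi" & !is.na(mean_mi) & mean_mi < thresh
  called_vaf <- route == "vaf" & targets$vaf >= params$vaf_low &
    targets$vaf <= params$vaf_high
  keep_i <- which(called_mi | called_vaf)
  calls <- targets[keep_i, .(contig, pos, ref, alt, vaf)]
  mm <- mean_mi[keep_i]; np <- n_part[keep_i]; rt <- route[keep_i]
  calls[, `:=`(mean_mi = mm, n_partners = np, route = rt)]
  res <- editing_call_set("mi", replicate, calls)
  # per-target diagnostics (also for candidates not called)
  diag <- targets[, .(contig, pos, vaf)]
  diag[, `:=`(mean_mi = mean_mi, n_partners = n_part, route = route,
              called = called_mi | called_vaf)]
  attr(res, "target_info") <- diag[]
  attr(res, "null_quantile") <- thresh
  res
}

#' Editing-island caller
#'
#' Single-linkage clustering of candidate sites (known SNPs excluded) with
#' inter-site gap at most `island_gap` bp; clusters with at least
#' `island_min_sites` members become editing islands and all members are
#' called.  Isolated candidates are called only if they pass the full
#' hard-filter cascade.
#'
#' @param candidates Candidate table from [call_candidates()].
#' @param bundle Annotation bundle (see [hardfilter_call()]).
#' @param params A [filter_params()].
#' @param replicate Replicate identifier.
#' @param genome A `genome_ref` for the hard-filter fallback on isolated
#'   sites.
#' @return List with `calls` (an `editing_call_set`, caller `"island"`) and
#'   `islands` (`data.frame`: `island_id`, `contig`, `start`, `end`,
#'   `n_sites`).
#' @export
island_call <- function(candidates, bundle, params = filter_params(),
                        replicate = 1L, genome = bundle$genome) {
  cand <- as.data.table(candidates)
  ks <- bundle$known_snps
  if (!is.null(ks) && nrow(cand))
    cand <- cand[!site_key(contig, pos) %in% site_key(ks$contig, ks$pos)]
  if (nrow(cand) == 0L) {
    return(list(calls = editing_call_set("island", replicate,
                                         data.table(contig = character(),
                                                    pos = integer(),
                                                    ref = character(),
                                                    alt = character(),
                                                    vaf = numeric())),
                islands = data.frame(island_id = character(),
                                     contig = character(), start = integer(),
                                     end = integer(), n_sites = integer())))
  }
  setorder(cand, contig, pos)
  cand[, gap := c(Inf, diff(pos)), by = contig]
  cand[, cluster := cumsum(gap > params$island_gap)]
  cand[, cluster := paste(contig, cluster, sep = "_")]
  sizes <- cand[, .N, by = cluster]
  island_clusters <- sizes[N >= params$island_min_sites, cluster]
  in_island <- cand$cluster %in% island_clusters

  if (any(in_island)) {
    islands <- cand[in_island, .(contig = contig[1L], start = min(pos),
                                 end = max(pos), n_sites = .N), by = cluster]
    islands[, island_id := sprintf("island%03d", seq_len(.N))]
  } else {
    islands <- data.table(cluster = character(), contig = character(),
                          start = integer(), end = integer(),
                          n_sites = integer(), island_id = character())
  }
  member_calls <- cand[in_island, .(contig, pos, ref, alt, vaf)]

  isolated <- cand[!in_island]
  iso_calls <- NULL
  if (nrow(isolated)) {
    hf <- hardfilter_call(isolated, bundle, params, replicate, genome)
    iso_calls <- hf$calls[, .(contig, pos, ref, alt, vaf)]
  }
  calls <- rbind(member_calls, iso_calls)
  setorder(calls, contig, pos)
  list(calls = editing_call_set("island", replicate, calls),
       islands = as.data.frame(islands[, .(island_id, contig, start, end,
                                           n_sites)]))
}
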