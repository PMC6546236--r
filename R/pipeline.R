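# End-to-end orchestration: simulate -> call -> consensus -> annotate ->
# enrich, with a manifest of per-stage counts, plus the evaluation harness
# that scores a consensus set against planted truth.

#' Run the three callers and their intersection on one replicate
#'
#' Dedupe, pileup, candidate calling, the three callers, and the
#' three-method intersection for a single replicate's reads.
#'
#' @param reads Read table (one replicate).
#' @param genome A `genome_ref`.
#' @param bundle Annotation bundle with `genes`, `repeats`, `junctions`,
#'   `known_snps`.
#' @param params A [filter_params()].
#' @param replicate Replicate identifier.
#' @return List with `candidates`, `hard`, `mi`, `island`, `islands`,
#'   `intersection`.
#' @export
call_replicate <- function(reads, genome, bundle, params = filter_params(),
                           replicate = 1L) {
  bundle$genome <- genome
  dd <- suppressMessages(dedupe_reads(reads))
  pu <- build_pileup(dd, genome, bundle$junctions)
  cand <- call_candidates(pu, params$min_cov, params$min_alt)
  hard <- hardfilter_call(cand, bundle, params, replicate, genome)
  mi <- mi_call(cand, pu, bundle$known_snps, params, replicate)
  isl <- island_call(cand, bundle, params, replicate, genome)
  inter <- intersect_methods(hard, mi, isl$calls)
  list(candidates = cand, hard = hard, mi = mi, island = isl$calls,
       islands = isl$islands, intersection = inter)
}

#' Run the full consensus pipeline on a simulated dataset
#'
#' Simulates the configured study (or accepts a pre-built dataset), runs
#' per-replicate calling and the consensus set algebra for every cell line,
#' annotates consensus sites (Alu / gene-body), assigns edited genes,
#' computes cell-line-specific partitions and Venn counts, counts genomic
#' SNVs per gene from each line's DNA call set, calls DEGs between the
#' parental line and each transformed line, and tests hypergeometric
#' enrichment of DEGs among that line's edited genes.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; when given, all tables, VCFs
#'   and a JSON manifest are written there.
#' @param params A [filter_params()].
#' @param min_replicate_support Minimum supporting replicates per site.
#' @param dataset Optional pre-built [simulate_dataset()] result (skips
#'   simulation).
#' @return A `pipeline_result` list: `dataset`, `replicate_calls`,
#'   `consensus` (per line), `region_class`, `edited_genes`, `specific`,
#'   `snv_counts`, `deg`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         params = filter_params(),
                         min_replicate_support = 1L, dataset = NULL) {
  if (is.null(dataset))
    dataset <- simulate_dataset(config, if (!is.null(out_dir))
      file.path(out_dir, "sim") else NULL)
  genome <- dataset$genome
  bundle <- dataset$bundle
  bundle$genome <- genome
  if (is.null(bundle$known_snps)) stopf("pipeline: missing known-SNP track")
  nl <- config$n_cell_lines; nr <- config$n_replicates
  lines <- sprintf("line%d", seq_len(nl))

  rep_calls <- list()
  consensus <- list()
  manifest_counts <- list()
  for (l in seq_len(nl)) {
    ln <- lines[l]
    per_rep <- list()
    inters <- list()
    for (r in seq_len(nr)) {
      rid <- sprintf("%s_rep%d", ln, r)
      cr <- call_replicate(dataset$reads[[ln]][[r]], genome, bundle, params,
                           replicate = rid)
      per_rep[[r]] <- cr
      inters[[r]] <- cr$intersection
      manifest_counts[[rid]] <- list(
        candidates = nrow(cr$candidates),
        hardfilter = nrow(cr$hard$calls),
        mi = nrow(cr$mi$calls),
        island = nrow(cr$island$calls),
        all_methods = nrow(cr$intersection)
      )
    }
    rep_calls[[ln]] <- per_rep
    cons <- combine_replicates(inters, cell_line = ln,
                               min_replicate_support = min_replicate_support)
    cons <- restrict_a_to_i(cons, bundle$genes)
    consensus[[ln]] <- cons
    manifest_counts[[ln]] <- list(rna_editing = nrow(cons$sites))
  }

  region_class <- lapply(consensus, function(cs)
    classify_region(cs$sites, bundle$repeats, bundle$genes))
  edited_genes <- lapply(consensus, function(cs)
    assign_genes(cs, bundle$genes))
  specific <- if (nl >= 2L) specific_sites(consensus, bundle$genes) else NULL

  # per-gene genomic SNV counts from each line's DNA-seq call set
  snv_counts <- list()
  known <- bundle$known_snps
  for (l in seq_len(nl)) {
    ln <- lines[l]
    dna <- dataset$truth$snps[, c("contig", "pos", "ref", "alt")]
    nv <- dataset$truth$novel_snvs[[ln]]
    if (!is.null(nv)) dna <- rbind(dna, nv[, c("contig", "pos", "ref", "alt")])
    tab <- do.call(rbind, lapply(bundle$genes$genes$gene_id, function(g) {
      cnt <- count_snvs_per_gene(dna, bundle$genes, g, known)
      data.frame(line = ln, gene_id = g, span_count = cnt$span_count,
                 exon_count = cnt$exon_count, novel_count = cnt$novel_count,
                 stringsAsFactors = FALSE)
    }))
    snv_counts[[ln]] <- tab
  }

  # DEG calling and enrichment: parental line vs each transformed line
  deg <- list(); enrichment <- list()
  if (nl >= 2L && nr >= 2L) {
    expr <- dataset$expression
    universe <- rownames(expr)[rowMeans(expr) > 0]
    for (l in 2:nl) {
      ln <- lines[l]
      d <- simple_deg(expr, lines[1], ln)
      deg[[ln]] <- d
      ed <- intersect(edited_genes[[ln]]$gene_id, universe)
      enrichment[[ln]] <- if (length(ed))
        hypergeom_enrichment(universe, intersect(attr(d, "deg_set"), universe),
                             ed) else NULL
    }
  }

  manifest <- list(
    package = "edconsensus",
    version = as.character(utils::packageVersion("edconsensus")),
    seed = config$seed,
    counts = manifest_counts,
    params = unclass(params),
    config_hash = config_hash(config)
  )

  result <- structure(list(
    dataset = dataset, replicate_calls = rep_calls, consensus = consensus,
    region_class = region_class, edited_genes = edited_genes,
    specific = specific, snv_counts = snv_counts, deg = deg,
    enrichment = enrichment, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, genome)
  result
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `sim` (fields of [sim_config()]), `params` (fields of
#' [filter_params()]), `min_replicate_support`, `seed`, `out_dir`.  Unknown
#' keys at any level are rejected.
#'
#' @param path Path to a YAML file.
#' @return List with `sim` (a `sim_config`), `params` (a `filter_params`),
#'   `min_replicate_support`, `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known_top <- c("sim", "params", "min_replicate_support", "seed", "out_dir")
  bad <- setdiff(names(y), known_top)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  sim_args <- y$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) stopf("unknown sim config key(s): %s",
                         paste(bad, collapse = ", "))
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  par_args <- y$params %||% list()
  bad <- setdiff(names(par_args), names(formals(filter_params)))
  if (length(bad)) stopf("unknown filter params key(s): %s",
                         paste(bad, collapse = ", "))
  list(sim = do.call(sim_config, sim_args),
       params = do.call(filter_params, par_args),
       min_replicate_support = y$min_replicate_support %||% 1L,
       out_dir = y$out_dir)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, out_dir, genome) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (ln in names(result$consensus)) {
    cs <- result$consensus[[ln]]
    s <- cs$sites
    vcf_df <- data.frame(contig = s$contig, pos = s$pos, ref = s$ref,
                         alt = s$alt, level = s$mean_level,
                         dp = 0L, ad = 0L, methods = "hard,mi,island")
    write_editing_vcf(vcf_df, file.path(out_dir,
                                        sprintf("consensus_%s.vcf", ln)),
                      genome)
    wt(s, sprintf("consensus_%s.tsv", ln))
    wt(result$region_class[[ln]], sprintf("region_class_%s.tsv", ln))
    wt(result$edited_genes[[ln]], sprintf("edited_genes_%s.tsv", ln))
    wt(result$snv_counts[[ln]], sprintf("snv_counts_%s.tsv", ln))
    reps <- result$replicate_calls[[ln]]
    for (r in seq_along(reps)) {
      cr <- reps[[r]]
      prov <- cr$hard$provenance
      wt(prov, sprintf("hardfilter_%s_rep%d.tsv", ln, r))
      wt(cr$intersection, sprintf("all_methods_%s_rep%d.tsv", ln, r))
    }
  }
  if (!is.null(result$specific)) wt(result$specific$venn, "venn_counts.tsv")
  if (length(result$enrichment)) {
    en <- do.call(rbind, lapply(names(result$enrichment), function(ln) {
      e <- result$enrichment[[ln]]
      if (is.null(e)) return(NULL)
      data.frame(line = ln, N = e$N, K = e$K, n = e$n, k = e$k,
                 p_value = e$p_value, fold_enrichment = e$fold_enrichment)
    }))
    if (!is.null(en)) wt(en, "enrichment.tsv")
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (ln in names(x$consensus))
    cat(sprintf("  %s: %d consensus A-to-I site(s), %d edited gene(s)\n",
                ln, nrow(x$consensus[[ln]]$sites),
                nrow(x$edited_genes[[ln]])))
  invisible(x)
}

#' Score a consensus call set against planted truth
#'
#' Sensitivity is computed over the planted editing sites that were
#' detectable in the data — i.e. that met the coverage and alt-read
#' thresholds (appeared as a candidate) in at least one replicate;
#' precision over all called sites.  False positives are attributed to
#' planted SNPs or to other causes (errors, shifted alleles).
#'
#' @param consensus A `consensus_set`.
#' @param truth A `sim_truth`.
#' @param candidates_by_rep Optional list of per-replicate candidate tables
#'   used to restrict the sensitivity denominator to detectable sites;
#'   when omitted, all planted sites count.
#' @param islands Optional `data.frame` of recovered islands (union over
#'   replicates) to compute island-site recovery.
#' @return List with `sensitivity`, `precision`, `n_called`, `n_truth`,
#'   `n_detectable`, `fp_breakdown`, and `island_recovery` when islands are
#'   given.
#' @export
score_against_truth <- function(consensus, truth, candidates_by_rep = NULL,
                                islands = NULL) {
  called <- if (nrow(consensus$sites))
    site_key(consensus$sites$contig, consensus$sites$pos) else character()
  planted <- site_key(truth$editing$contig, truth$editing$pos)
  if (length(called) &&
      !any(consensus$sites$contig %in% truth$editing$contig) &&
      nrow(truth$editing))
    stopf("score_against_truth: contig mismatch between calls and truth")
  detectable <- planted
  if (!is.null(candidates_by_rep)) {
    seen <- unique(unlist(lapply(candidates_by_rep, function(cd)
      if (nrow(cd)) site_key(cd$contig, cd$pos) else character())))
    detectable <- intersect(planted, seen)
  }
  tp <- intersect(called, planted)
  sens <- if (length(detectable)) length(intersect(called, detectable)) /
    length(detectable) else NA_real_
  prec <- if (length(called)) length(tp) / length(called) else NA_real_
  fp <- setdiff(called, planted)
  snp_keys <- site_key(truth$snps$contig, truth$snps$pos)
  fp_breakdown <- c(snp = sum(fp %in% snp_keys),
                    other = sum(!fp %in% snp_keys))
  out <- list(sensitivity = sens, precision = prec,
              n_called = length(called), n_truth = length(planted),
              n_detectable = length(detectable),
              fp_breakdown = fp_breakdown)
  if (!is.null(islands)) {
    isl_sites <- truth$editing[!is.na(truth$editing$island_id), ]
    if (nrow(isl_sites)) {
      inside <- points_in_track(isl_sites$contig, isl_sites$pos,
                                islands)
      out$island_recovery <- mean(inside)
    } else out$island_recovery <- NA_real_
  }
  out
}
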