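# Synthetic-data generator.
#
# Emulates the study design the pipeline was built for: several clonal cell
# lines from one parental genome, three RNA-seq replicates each, A-to-I
# editing concentrated in inverted Alu-like repeats plus isolated sites,
# phased heterozygous SNPs as confounders, a per-line ADAR-activity scalar
# multiplying editing levels, and a two-condition expression matrix in which
# DEG status is enriched among edited genes by a configurable odds ratio.

#' Simulation configuration
#'
#' Defaults define the reference study conditions: one 200 kb contig, 40
#' multi-exon genes, 30 inverted Alu-like repeats, mean depth 30, per-base
#' error 0.001, 3 replicates per cell line, editing levels drawn as
#' `0.2 + 0.8 * Beta(2, 5)` and scaled by each line's ADAR activity.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_contigs,contig_length Genome shape.
#' @param n_genes,exons_per_gene Gene models planted per contig set.
#' @param alu_count,alu_length Alu-like repeat copies (alternating
#'   orientation around a shared consensus, 5-15 percent mutated).
#' @param simple_repeat_count,simple_repeat_length,homopolymer_count,homopolymer_length
#'   Low-complexity decoy features.
#' @param n_snps Planted genomic SNPs; `het_fraction` of them heterozygous
#'   (phased onto one of two haplotypes), the rest homozygous-alt.
#' @param known_snp_fraction Fraction of planted SNPs present in the
#'   known-SNP catalog (models dbSNP incompleteness).
#' @param n_island_sites,island_count,n_isolated_sites Editing-site layout:
#'   island sites grouped inside `island_count` Alu copies, isolated sites
#'   in genes and intergenic space.
#' @param editing_beta Beta shape parameters of the base editing level.
#' @param editing_level_min Lower bound of base editing levels.
#' @param adar_activity Per-cell-line multiplier on editing levels, in
#'   \[0, 1\]; recycled or truncated to `n_cell_lines`.
#' @param coverage,read_length,error_rate,dup_fraction,low_qual_fraction
#'   Read-simulation parameters.
#' @param n_replicates,n_cell_lines Study layout.
#' @param deg_fraction Fraction of genes differentially expressed between
#'   the first (parental) line and the others.
#' @param deg_edited_enrichment Odds multiplier for a DEG being edited,
#'   i.e. P(edited | DEG) / P(edited | not DEG).
#' @param edited_gene_rate P(edited | not DEG).
#' @param deg_fold_change,expr_log_sd Expression effect size and log2
#'   replicate noise.
#' @param n_novel_snvs Line-specific genomic SNVs added to each
#'   non-parental line's DNA-seq call set.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 1L,
                       contig_length = 200000L,
                       n_genes = 40L,
                       exons_per_gene = 3L,
                       alu_count = 30L,
                       alu_length = 300L,
                       simple_repeat_count = 20L,
                       simple_repeat_length = 60L,
                       homopolymer_count = 15L,
                       homopolymer_length = 8L,
                       n_snps = 150L,
                       het_fraction = 0.7,
                       known_snp_fraction = 0.8,
                       n_island_sites = 60L,
                       island_count = 12L,
                       n_isolated_sites = 40L,
                       editing_beta = c(2, 5),
                       editing_level_min = 0.2,
                       adar_activity = c(1, 0.7, 0.5),
                       coverage = 30,
                       read_length = 100L,
                       error_rate = 0.001,
                       dup_fraction = 0.02,
                       low_qual_fraction = 0.01,
                       n_replicates = 3L,
                       n_cell_lines = 3L,
                       deg_fraction = 0.15,
                       deg_edited_enrichment = 4,
                       edited_gene_rate = 0.15,
                       deg_fold_change = 4,
                       expr_log_sd = 0.1,
                       n_novel_snvs = 25L) {
  cfg <- as.list(environment())
  counts <- c("n_contigs", "contig_length", "n_genes", "exons_per_gene",
              "alu_count", "alu_length", "n_snps", "n_island_sites",
              "island_count", "n_isolated_sites", "n_replicates",
              "n_cell_lines", "read_length", "n_novel_snvs")
  for (k in counts) if (cfg[[k]] < 0) stopf("sim_config: %s must be >= 0", k)
  probs <- c("het_fraction", "known_snp_fraction", "editing_level_min",
             "error_rate", "dup_fraction", "low_qual_fraction",
             "deg_fraction", "edited_gene_rate")
  for (k in probs) if (cfg[[k]] < 0 || cfg[[k]] > 1)
    stopf("sim_config: %s must be in [0, 1]", k)
  if (cfg$read_length > cfg$contig_length)
    stopf("sim_config: read_length exceeds contig_length")
  if (any(cfg$adar_activity < 0 | cfg$adar_activity > 1))
    stopf("sim_config: adar_activity must be in [0, 1]")
  if (length(cfg$adar_activity) < cfg$n_cell_lines)
    cfg$adar_activity <- rep_len(cfg$adar_activity, cfg$n_cell_lines)
  cfg$adar_activity <- cfg$adar_activity[seq_len(cfg$n_cell_lines)]
  if (cfg$island_count > 0 && cfg$n_island_sites < 3L * cfg$island_count)
    stopf("sim_config: need >= 3 island sites per island")
  if (cfg$island_count > cfg$alu_count)
    stopf("sim_config: more islands than Alu copies")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> seed %d: %d x %s bp contig(s), %d genes, %d Alu copies\n",
    "  %d SNPs (%.0f%% het, %.0f%% known), %d island + %d isolated editing sites\n",
    "  depth %g, error %g, %d line(s) x %d replicate(s), ADAR activity %s\n"),
    x$seed, x$n_contigs, format(x$contig_length, big.mark = ","), x$n_genes,
    x$alu_count, x$n_snps, 100 * x$het_fraction, 100 * x$known_snp_fraction,
    x$n_island_sites, x$n_isolated_sites, x$coverage, x$error_rate,
    x$n_cell_lines, x$n_replicates,
    paste(x$adar_activity, collapse = "/")))
  invisible(x)
}

## ---- reference generation ----

# Random sequence with no homopolymer run longer than max_run.
random_seq <- function(n, max_run = 3L) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  r <- rle(b)
  while (any(r$lengths > max_run)) {
    ends <- cumsum(r$lengths)
    for (i in which(r$lengths > max_run)) {
      run_pos <- (ends[i] - r$lengths[i] + 1L):ends[i]
      fix <- run_pos[seq(max_run + 1L, length(run_pos), by = max_run + 1L)]
      for (p in fix) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    }
    r <- rle(b)
  }
  paste(b, collapse = "")
}

mutate_seq <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- max(1L, round(length(b) * rate))
  idx <- sample(length(b), k)
  for (p in idx) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

# Rejection-sample non-overlapping placements; errors if capacity exceeded.
place_features <- function(lengths, contig_length, occupied, margin = 10L) {
  out <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    placed <- FALSE
    for (try in 1:500) {
      s <- sample.int(contig_length - L + 1L, 1L)
      e <- s + L - 1L
      if (nrow(occupied) == 0L ||
          all(e + margin < occupied$start | s - margin > occupied$end)) {
        occupied <- rbind(occupied, data.frame(start = s, end = e))
        out[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("requested features exceed contig capacity (%d bp)", contig_length)
  }
  list(starts = out, occupied = occupied)
}

#' Generate a toy reference genome with annotation
#'
#' Plants, per contig: multi-exon gene models, Alu-like repeats (alternating
#' inverted copies of one consensus, each mutated 5-15 percent), simple dinucleotide
#' repeats and homopolymer runs.  All features are intergenic except genes;
#' splice junctions are derived from exon boundaries.  Deterministic under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `genome_ref`) and `bundle` (annotation:
#'   `genes`, `repeats`, `junctions`, plus an empty `known_snps` slot).
#' @export
generate_reference <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  contigs <- sprintf("chrS%d", seq_len(config$n_contigs))
  seqs <- character(0)
  genes_l <- list(); exons_l <- list(); reps_l <- list()
  alu_consensus <- random_seq(config$alu_length)
  gene_idx <- 0L
  for (ci in seq_along(contigs)) {
    ct <- contigs[ci]
    chars <- strsplit(random_seq(config$contig_length), "", fixed = TRUE)[[1]]
    occupied <- data.frame(start = integer(), end = integer())

    # gene structures
    n_ex <- config$exons_per_gene
    gene_plans <- lapply(seq_len(config$n_genes), function(i) {
      ex_len <- sample(150:250, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(300:800, n_ex - 1L, replace = TRUE) else integer()
      list(ex_len = ex_len, in_len = in_len, span = sum(ex_len) + sum(in_len))
    })
    pl <- place_features(vapply(gene_plans, `[[`, numeric(1), "span"),
                         config$contig_length, occupied)
    occupied <- pl$occupied
    for (i in seq_along(gene_plans)) {
      gene_idx <- gene_idx + 1L
      gp <- gene_plans[[i]]
      s <- pl$starts[i]
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("g%03d", gene_idx)
      ex_starts <- s + cumsum(c(0L, head(gp$ex_len, -1L) + gp$in_len))
      genes_l[[gid]] <- data.frame(
        gene_id = gid, contig = ct, start = s, end = s + gp$span - 1L,
        strand = strand, stringsAsFactors = FALSE)
      exons_l[[gid]] <- data.frame(
        gene_id = gid, contig = ct, start = ex_starts,
        end = ex_starts + gp$ex_len - 1L, strand = strand,
        stringsAsFactors = FALSE)
    }

    # Alu copies: alternate orientation, mutate 5-15%
    if (config$alu_count > 0L) {
      pl <- place_features(rep(config$alu_length, config$alu_count),
                           config$contig_length, occupied)
      occupied <- pl$occupied
      for (i in seq_len(config$alu_count)) {
        fwd <- i %% 2L == 1L
        body <- if (fwd) alu_consensus else revcomp(alu_consensus)
        body <- mutate_seq(body, runif(1, 0.05, 0.15))
        s <- pl$starts[i]
        e <- s + config$alu_length - 1L
        chars[s:e] <- strsplit(body, "", fixed = TRUE)[[1]]
        reps_l[[length(reps_l) + 1L]] <- data.frame(
          contig = ct, start = s, end = e, strand = if (fwd) "+" else "-",
          label = "Alu", stringsAsFactors = FALSE)
      }
    }

    # simple dinucleotide repeats
    if (config$simple_repeat_count > 0L) {
      pl <- place_features(rep(config$simple_repeat_length,
                               config$simple_repeat_count),
                           config$contig_length, occupied)
      occupied <- pl$occupied
      for (i in seq_len(config$simple_repeat_count)) {
        unit <- sample(c("AC", "AG", "CT", "GT", "AT"), 1L)
        body <- strrep(unit, ceiling(config$simple_repeat_length / 2))
        body <- substr(body, 1L, config$simple_repeat_length)
        s <- pl$starts[i]
        e <- s + config$simple_repeat_length - 1L
        chars[s:e] <- strsplit(body, "", fixed = TRUE)[[1]]
        reps_l[[length(reps_l) + 1L]] <- data.frame(
          contig = ct, start = s, end = e, strand = "+", label = "Simple",
          stringsAsFactors = FALSE)
      }
    }

    # homopolymer runs
    if (config$homopolymer_count > 0L) {
      pl <- place_features(rep(config$homopolymer_length,
                               config$homopolymer_count),
                           config$contig_length, occupied)
      occupied <- pl$occupied
      for (i in seq_len(config$homopolymer_count)) {
        s <- pl$starts[i]
        e <- s + config$homopolymer_length - 1L
        chars[s:e] <- sample(c("A", "C", "G", "T"), 1L)
      }
    }

    seqs[ct] <- paste(chars, collapse = "")
  }
  genome <- genome_ref(seqs)
  models <- gene_models(do.call(rbind, genes_l), do.call(rbind, exons_l))
  repeats <- if (length(reps_l)) do.call(rbind, reps_l) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), label = character())
  rownames(repeats) <- NULL
  bundle <- list(genes = models, repeats = repeats,
                 junctions = splice_junctions(models), known_snps = NULL)
  list(genome = genome, bundle = bundle)
}

## ---- variant planting ----

# Logical mask of positions inside (or +/-1 adjacent to) homopolymer runs
# of length >= L.
homopolymer_mask <- function(seq, L = 5L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- logical(length(b))
  for (i in which(r$lengths >= L)) {
    s <- max(1L, starts[i] - 1L)
    e <- min(length(b), ends[i] + 1L)
    mask[s:e] <- TRUE
  }
  mask
}

#' Draw per-gene DEG and edited labels with a fixed enrichment odds
#'
#' `P(edited | DEG) = min(1, enrichment * edited_rate)`,
#' `P(edited | not DEG) = edited_rate`; with `enrichment = 1` the two labels
#' are independent.  Uses the current RNG state.
#'
#' @param n_genes Number of genes.
#' @param deg_fraction P(DEG).
#' @param enrichment Odds multiplier for edited given DEG.
#' @param edited_rate P(edited | not DEG).
#' @return `data.frame` with logical columns `deg`, `edited`.
#' @export
sim_gene_labels <- function(n_genes, deg_fraction, enrichment, edited_rate) {
  deg <- runif(n_genes) < deg_fraction
  p <- ifelse(deg, pmin(1, enrichment * edited_rate), edited_rate)
  data.frame(deg = deg, edited = runif(n_genes) < p)
}

# Sample positions inside [lo, hi] whose plus-strand base equals `want`,
# excluding masked positions.  Returns integer(0) if none.
editable_positions <- function(chars, lo, hi, want, excluded) {
  idx <- lo:hi
  idx <- idx[chars[idx] == want & !excluded[idx]]
  idx
}

#' Plant SNPs, editing sites and expression truth
#'
#' SNPs are placed uniformly (het with the configured fraction, phased onto
#' one of two haplotypes; otherwise hom-alt).  Editing sites are placed only
#' at adenosines of the annotated strand (reference A for `+` features,
#' reference T for `-`), at positions the annotation-based filters would not
#' exclude a priori.  Island sites are grouped (successive gaps kept under
#' the island-calling gap) inside chosen Alu copies; isolated sites go to
#' edited-labelled genes and to intergenic non-Alu space.  Per-site editing
#' levels are `editing_level_min + (1 - editing_level_min) * Beta(a, b)`,
#' multiplied per cell line by its ADAR activity.
#'
#' @param genome,bundle Output of [generate_reference()].
#' @param config The same [sim_config()].
#' @return A `sim_truth` object.
#' @export
plant_variants <- function(genome, bundle, config) {
  set.seed(derive_seed(config$seed, 2L))
  contigs <- names(genome$seq)
  chars_by_ct <- lapply(genome$seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  lens <- genome$lengths

  # exclusion mask per contig: homopolymers (+/-1), simple repeats,
  # within 5 bp of a splice junction
  excl <- lapply(contigs, function(ct) {
    m <- homopolymer_mask(genome$seq[[ct]], 5L)
    sr <- bundle$repeats[bundle$repeats$label != "Alu" &
                           bundle$repeats$contig == ct, ]
    if (nrow(sr)) for (i in seq_len(nrow(sr))) m[sr$start[i]:sr$end[i]] <- TRUE
    jp <- bundle$junctions$pos[bundle$junctions$contig == ct]
    for (p in jp) m[max(1L, p - 5L):min(lens[[ct]], p + 5L)] <- TRUE
    m
  })
  names(excl) <- contigs

  # ---- SNPs: uniform over the genome ----
  n_per <- as.vector(stats::rmultinom(1L, config$n_snps,
                                      lens / sum(lens)))
  snps <- do.call(rbind, lapply(seq_along(contigs), function(ci) {
    ct <- contigs[ci]
    if (n_per[ci] == 0L) return(NULL)
    pos <- sort(sample.int(lens[[ct]], n_per[ci]))
    data.frame(contig = ct, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(snps)) snps <- data.frame(contig = character(), pos = integer())
  if (nrow(snps)) {
    snps$ref <- mapply(function(ct, p) chars_by_ct[[ct]][p],
                       snps$contig, snps$pos, USE.NAMES = FALSE)
    snps$alt <- vapply(snps$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
      USE.NAMES = FALSE)
    snps$genotype <- ifelse(runif(nrow(snps)) < config$het_fraction,
                            "het", "hom")
    snps$hap <- sample(1:2, nrow(snps), replace = TRUE)
    snps$known <- runif(nrow(snps)) < config$known_snp_fraction
  } else {
    snps$ref <- snps$alt <- snps$genotype <- character()
    snps$hap <- integer(); snps$known <- logical()
  }
  snp_taken <- lapply(contigs, function(ct) {
    m <- logical(lens[[ct]]); m[snps$pos[snps$contig == ct]] <- TRUE; m
  })
  names(snp_taken) <- contigs

  genes <- bundle$genes$genes
  labels <- sim_gene_labels(nrow(genes), config$deg_fraction,
                            config$deg_edited_enrichment,
                            config$edited_gene_rate)
  gene_tab <- cbind(genes, labels)

  taken <- lapply(contigs, function(ct) logical(lens[[ct]]))
  names(taken) <- contigs
  ed_l <- list()
  add_site <- function(ct, p, strand, island_id, gene_id) {
    ref <- chars_by_ct[[ct]][p]
    alt <- ifelse(ref == "A", "G", "C")   # T>C is A>G on the minus strand
    data.frame(contig = ct, pos = p, ref = ref, alt = alt, strand = strand,
               island_id = island_id, gene_id = gene_id,
               stringsAsFactors = FALSE)
  }

  # ---- island sites inside chosen Alu copies ----
  islands_l <- list()
  alus <- bundle$repeats[bundle$repeats$label == "Alu", ]
  if (config$island_count > 0L) {
    if (nrow(alus) < config$island_count)
      stopf("not enough Alu intervals for %d islands", config$island_count)
    host <- alus[sample.int(nrow(alus), config$island_count), ]
    per <- rep(config$n_island_sites %/% config$island_count,
               config$island_count)
    extra <- config$n_island_sites %% config$island_count
    if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    for (i in seq_len(config$island_count)) {
      ct <- host$contig[i]
      want <- if (host$strand[i] == "+") "A" else "T"
      avail <- editable_positions(chars_by_ct[[ct]], host$start[i],
                                  host$end[i], want,
                                  excl[[ct]] | snp_taken[[ct]] | taken[[ct]])
      if (length(avail) < per[i])
        stopf("insufficient %s positions in Alu interval for island %d",
              want, i)
      # walk left to right with bounded gaps so the island stays dense
      avail <- sort(avail)
      picked <- integer(0)
      start_i <- sample.int(max(1L, length(avail) - 3L * per[i]), 1L)
      cur <- avail[start_i]
      picked <- cur
      while (length(picked) < per[i]) {
        nxt <- avail[avail > cur + sample(5:25, 1L) & avail <= cur + 45L]
        if (length(nxt) == 0L) nxt <- avail[avail > cur & avail <= cur + 45L]
        if (length(nxt) == 0L) {
          # restart from scratch with the remaining positions
          rest <- setdiff(avail, picked)
          if (!length(rest)) stopf("island %d cannot be placed densely", i)
          cur <- rest[1L]; picked <- c(picked, cur); next
        }
        cur <- nxt[1L]
        picked <- c(picked, cur)
      }
      picked <- sort(picked[seq_len(per[i])])
      for (p in picked) taken[[ct]][p] <- TRUE
      iid <- sprintf("isl%02d", i)
      islands_l[[iid]] <- data.frame(
        island_id = iid, contig = ct, start = min(picked), end = max(picked),
        alu_start = host$start[i], alu_end = host$end[i],
        stringsAsFactors = FALSE)
      ed_l[[length(ed_l) + 1L]] <- add_site(ct, picked, host$strand[i],
                                            iid, NA_character_)
    }
  }

  # ---- isolated sites: first in edited-labelled genes ----
  n_isolated_left <- config$n_isolated_sites
  ed_gene_ids <- gene_tab$gene_id[gene_tab$edited]
  if (length(ed_gene_ids) > n_isolated_left && n_isolated_left > 0L)
    ed_gene_ids <- ed_gene_ids[seq_len(n_isolated_left)]
  gene_tab$edited <- gene_tab$gene_id %in% ed_gene_ids
  for (gid in ed_gene_ids) {
    g <- gene_tab[gene_tab$gene_id == gid, ]
    ct <- g$contig
    want <- if (g$strand == "+") "A" else "T"
    avail <- editable_positions(chars_by_ct[[ct]], g$start, g$end, want,
                                excl[[ct]] | snp_taken[[ct]] | taken[[ct]])
    if (length(avail) == 0L)
      stopf("insufficient editable positions in gene %s", gid)
    k <- min(sample(1:3, 1L), length(avail), n_isolated_left)
    k <- max(k, 1L)
    picked <- sort(avail[sample.int(length(avail), k)])
    for (p in picked) taken[[ct]][p] <- TRUE
    ed_l[[length(ed_l) + 1L]] <- add_site(ct, picked, g$strand, NA_character_, gid)
    n_isolated_left <- n_isolated_left - k
    if (n_isolated_left <= 0L) break
  }

  # ---- remaining isolated sites: intergenic, non-Alu ----
  if (n_isolated_left > 0L) {
    gene_gr <- as_gr(data.frame(contig = genes$contig, start = genes$start,
                                end = genes$end))
    alu_gr <- if (nrow(alus)) as_gr(alus) else NULL
    for (ci in seq_along(contigs)) {
      ct <- contigs[ci]
      if (n_isolated_left <= 0L) break
      blocked <- excl[[ct]] | snp_taken[[ct]] | taken[[ct]]
      gsub_df <- genes[genes$contig == ct, ]
      if (nrow(gsub_df)) for (i in seq_len(nrow(gsub_df)))
        blocked[gsub_df$start[i]:gsub_df$end[i]] <- TRUE
      asub <- alus[alus$contig == ct, ]
      if (nrow(asub)) for (i in seq_len(nrow(asub)))
        blocked[asub$start[i]:asub$end[i]] <- TRUE
      avail <- which((chars_by_ct[[ct]] == "A" | chars_by_ct[[ct]] == "T") &
                       !blocked)
      k <- min(n_isolated_left, length(avail))
      if (k == 0L) next
      picked <- sort(avail[sample.int(length(avail), k)])
      for (p in picked) taken[[ct]][p] <- TRUE
      for (j in seq_len(k))
        ed_l[[length(ed_l) + 1L]] <- add_site(ct, picked[j], ".",
                                              NA_character_, NA_character_)
      n_isolated_left <- n_isolated_left - k
    }
    if (n_isolated_left > 0L)
      stopf("could not place %d isolated editing sites", n_isolated_left)
  }

  editing <- do.call(rbind, ed_l)
  rownames(editing) <- NULL
  editing$site_id <- sprintf("ed%04d", seq_len(nrow(editing)))
  editing$base_level <- config$editing_level_min +
    (1 - config$editing_level_min) *
    rbeta(nrow(editing), config$editing_beta[1], config$editing_beta[2])
  levels <- outer(editing$base_level, config$adar_activity)
  colnames(levels) <- sprintf("line%d", seq_len(config$n_cell_lines))
  rownames(levels) <- editing$site_id

  islands <- if (length(islands_l)) do.call(rbind, islands_l) else
    data.frame(island_id = character(), contig = character(),
               start = integer(), end = integer(),
               alu_start = integer(), alu_end = integer())
  rownames(islands) <- NULL

  # expression means: baseline per gene; DEGs shifted in lines > 1
  base_log2 <- runif(nrow(gene_tab), 3, 9)
  direction <- sample(c(-1, 1), nrow(gene_tab), replace = TRUE)
  mean_log2 <- matrix(base_log2, nrow(gene_tab), config$n_cell_lines)
  if (config$n_cell_lines > 1L) {
    shift <- direction * log2(config$deg_fold_change) * gene_tab$deg
    for (l in 2:config$n_cell_lines) mean_log2[, l] <- base_log2 + shift
  }
  colnames(mean_log2) <- sprintf("line%d", seq_len(config$n_cell_lines))
  rownames(mean_log2) <- gene_tab$gene_id

  # line-specific novel DNA SNVs (modelled at the DNA level only)
  novel <- list()
  if (config$n_cell_lines > 1L && config$n_novel_snvs > 0L) {
    for (l in 2:config$n_cell_lines) {
      picks <- list()
      for (ci in seq_along(contigs)) {
        ct <- contigs[ci]
        k <- round(config$n_novel_snvs * lens[[ct]] / sum(lens))
        if (k == 0L) next
        blocked <- snp_taken[[ct]] | taken[[ct]]
        free <- which(!blocked)
        pos <- free[sample.int(length(free), k)]
        ref <- chars_by_ct[[ct]][pos]
        alt <- vapply(ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
          USE.NAMES = FALSE)
        picks[[ct]] <- data.frame(contig = ct, pos = sort(pos),
                                  ref = ref[order(pos)], alt = alt[order(pos)],
                                  stringsAsFactors = FALSE)
      }
      novel[[sprintf("line%d", l)]] <- do.call(rbind, picks)
    }
  }

  out <- structure(list(
    snps = snps, editing = editing, levels = levels, islands = islands,
    genes = gene_tab, mean_log2 = mean_log2, novel_snvs = novel,
    config = config
  ), class = "sim_truth")
  attr(out, "exons") <- bundle$genes$exons
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_truth> %d SNPs (%d known), %d editing sites (%d in %d islands),\n",
    "  %d genes (%d DEG, %d edited)\n"),
    nrow(x$snps), sum(x$snps$known), nrow(x$editing),
    sum(!is.na(x$editing$island_id)), nrow(x$islands),
    nrow(x$genes), sum(x$genes$deg), sum(x$genes$edited)))
  invisible(x)
}

## ---- read simulation ----

#' Simulate pre-aligned RNA-seq reads for one replicate
#'
#' Single-end reads of fixed length are drawn uniformly over the genome at
#' the configured mean depth.  Reads starting inside an exon follow the
#' transcript across introns (N CIGAR operations); reads starting in introns
#' or intergenic space are contiguous.  Each read is assigned one of two
#' haplotypes: heterozygous SNP alleles follow the read's haplotype, editing
#' sites convert A to G (plus-strand representation) independently per read
#' with probability equal to the site's per-line editing level, and
#' independent per-base errors are added.  A configurable fraction of reads
#' is duplicated (PCR duplicates, not flag-marked).  Deterministic given
#' (config seed, cell line, replicate).
#'
#' @param genome A `genome_ref` from [generate_reference()].
#' @param truth A `sim_truth` from [plant_variants()].
#' @param config The [sim_config()].
#' @param cell_line Cell-line index (1-based).
#' @param replicate Replicate index (1-based).
#' @return A read `data.table` compatible with [write_sam()] / [read_sam()].
#' @export
simulate_reads <- function(genome, truth, config, cell_line = 1L,
                           replicate = 1L) {
  set.seed(derive_seed(config$seed, 3L, cell_line, replicate))
  rl <- config$read_length
  out <- list()
  lev <- truth$levels[, min(cell_line, ncol(truth$levels))]
  for (ct in names(genome$seq)) {
    len <- genome$lengths[[ct]]
    n_reads <- round(len * config$coverage / rl)
    if (n_reads == 0L) next
    start <- sample.int(len - rl + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    hap <- sample(1:2, n_reads, replace = TRUE)
    sq <- substring(genome$seq[[ct]], start, start + rl - 1L)
    cigar <- rep(sprintf("%dM", rl), n_reads)
    rend <- start + rl - 1L

    # spliced reads: start inside a non-terminal region of an exon and the
    # contiguous read would cross that exon's end
    ex <- truth_exons(truth)[truth_exons(truth)$contig == ct, ]
    if (nrow(ex)) {
      ex <- ex[order(ex$gene_id, ex$start), ]
      hits <- GenomicRanges::findOverlaps(
        points_gr(rep(ct, n_reads), start), as_gr(ex))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      cross <- rend[qh] > ex$end[sh]
      # not the gene's last exon
      last_of_gene <- !duplicated(ex$gene_id, fromLast = TRUE)
      cross <- cross & !last_of_gene[sh]
      for (k in which(cross)) {
        ri <- qh[k]; ei <- sh[k]
        gid <- ex$gene_id[ei]
        gx <- ex[ex$gene_id == gid, ]
        j <- which(gx$start == ex$start[ei])
        pos0 <- start[ri]
        remaining <- rl
        pieces <- character(0); cig <- character(0)
        cur_start <- pos0
        repeat {
          take <- min(remaining, gx$end[j] - cur_start + 1L)
          pieces <- c(pieces, substring(genome$seq[[ct]], cur_start,
                                        cur_start + take - 1L))
          cig <- c(cig, sprintf("%dM", take))
          remaining <- remaining - take
          if (remaining <= 0L) break
          if (j == nrow(gx)) break
          gap <- gx$start[j + 1L] - gx$end[j] - 1L
          cig <- c(cig, sprintf("%dN", gap))
          j <- j + 1L
          cur_start <- gx$start[j]
        }
        if (sum(nchar(pieces)) < 30L) next  # too short, keep contiguous
        sq[ri] <- paste(pieces, collapse = "")
        cigar[ri] <- paste(cig, collapse = "")
      }
    }

    qname <- sprintf("l%dr%d_%s_%07d", cell_line, replicate, ct,
                     seq_len(n_reads))

    # map of reference position -> read offset, for variant application
    blocks <- read_blocks(data.table(pos = start, cigar = cigar))

    # apply SNPs (haplotype-coherent) and editing (independent per read)
    sn <- truth$snps[truth$snps$contig == ct, , drop = FALSE]
    if (nrow(sn)) for (i in seq_len(nrow(sn))) {
      hit <- blocks[pos <= sn$pos[i] & sn$pos[i] <= end]
      if (!nrow(hit)) next
      off <- hit$qoff + (sn$pos[i] - hit$pos)
      sel <- if (sn$genotype[i] == "het")
        hap[hit$read_id] == sn$hap[i] else rep(TRUE, nrow(hit))
      if (any(sel)) {
        ids <- hit$read_id[sel]
        substring(sq[ids], off[sel], off[sel]) <- sn$alt[i]
      }
    }
    edt <- truth$editing[truth$editing$contig == ct, , drop = FALSE]
    if (nrow(edt)) for (i in seq_len(nrow(edt))) {
      lv <- lev[[edt$site_id[i]]]
      if (lv <= 0) next
      hit <- blocks[pos <= edt$pos[i] & edt$pos[i] <= end]
      if (!nrow(hit)) next
      off <- hit$qoff + (edt$pos[i] - hit$pos)
      sel <- runif(nrow(hit)) < lv
      if (any(sel)) {
        ids <- hit$read_id[sel]
        substring(sq[ids], off[sel], off[sel]) <- edt$alt[i]
      }
    }

    # sequencing errors
    nch <- nchar(sq)
    n_err <- rbinom(1L, sum(nch), config$error_rate)
    if (n_err > 0L) {
      er <- sample.int(n_reads, n_err, replace = TRUE)
      eo <- 1L + floor(runif(n_err) * nch[er])
      for (k in seq_len(n_err)) {
        cur <- substring(sq[er[k]], eo[k], eo[k])
        substring(sq[er[k]], eo[k], eo[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }

    # base qualities: Q40 background with a sprinkling of Q10 bases
    qual <- strrep("I", nch)
    n_lq <- rbinom(1L, sum(nch), config$low_qual_fraction)
    if (n_lq > 0L) {
      lr <- sample.int(n_reads, n_lq, replace = TRUE)
      lo <- 1L + floor(runif(n_lq) * nch[lr])
      for (k in seq_len(n_lq))
        substring(qual[lr[k]], lo[k], lo[k]) <- "+"
    }

    reads <- data.table(qname = qname, contig = ct, pos = start,
                        strand = strand, cigar = cigar, seq = sq, qual = qual)

    # PCR duplicates: exact copies under new (later-sorting) names
    n_dup <- round(config$dup_fraction * nrow(reads))
    if (n_dup > 0L) {
      di <- sample.int(nrow(reads), n_dup)
      dups <- copy(reads[di])
      dups[, qname := paste0(qname, "d")]
      reads <- rbind(reads, dups)
    }
    out[[ct]] <- reads
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table(qname = character(), contig = character(),
                      pos = integer(), strand = character(),
                      cigar = character(), seq = character(),
                      qual = character())
  }
  res[, flag := ifelse(strand == "-", 16L, 0L)]
  res[, dup := FALSE]
  setorder(res, contig, pos, qname)
  setcolorder(res, c("qname", "flag", "contig", "pos", "strand", "cigar",
                     "seq", "qual", "dup"))
  res[]
}

# Aligned blocks (M segments) of each read: read_id, pos, end, qoff.
read_blocks <- function(reads) {
  ops <- cigar_ops(reads$cigar)
  ops[, ref_consume := ifelse(op %in% c("M", "N", "=", "X"), len, 0L)]
  ops[, q_consume := ifelse(op %in% c("M", "S", "=", "X"), len, 0L)]
  ops[, roff := cumsum(shift(ref_consume, fill = 0L)), by = read_id]
  ops[, qoff := cumsum(shift(q_consume, fill = 0L)), by = read_id]
  m <- ops[op %in% c("M", "=", "X")]
  m[, pos := reads$pos[read_id] + roff]
  m[, end := pos + len - 1L]
  m[, qoff := qoff + 1L]
  m[, .(read_id, pos, end, len, qoff)]
}

# The exon table travels with the truth object so read simulation can splice.
truth_exons <- function(truth) {
  ex <- attr(truth, "exons")
  if (is.null(ex)) stopf("sim_truth lacks exon annotation; use simulate_dataset")
  ex
}

## ---- expression ----

#' Generate a replicate expression matrix from planted truth
#'
#' Log-normal noise (`expr_log_sd`, log2 scale) around each gene's
#' per-cell-line mean; DEG genes differ between the parental line and the
#' others by the configured fold change.
#'
#' @param truth A `sim_truth`.
#' @param config The [sim_config()].
#' @return Numeric matrix genes x (cell line x replicate); column names
#'   `line<i>_rep<j>`.
#' @export
generate_expression <- function(truth, config) {
  set.seed(derive_seed(config$seed, 4L))
  nl <- config$n_cell_lines; nr <- config$n_replicates
  ng <- nrow(truth$genes)
  cols <- as.vector(outer(seq_len(nr), seq_len(nl),
                          function(r, l) sprintf("line%d_rep%d", l, r)))
  m <- matrix(NA_real_, ng, nl * nr, dimnames = list(truth$genes$gene_id, cols))
  for (l in seq_len(nl)) for (r in seq_len(nr)) {
    mu <- truth$mean_log2[, l]
    m[, sprintf("line%d_rep%d", l, r)] <-
      2^(mu + rnorm(ng, 0, config$expr_log_sd))
  }
  m
}

#' Expression-only truth for enrichment studies
#'
#' Draws per-gene DEG/edited labels with [sim_gene_labels()] and
#' per-cell-line expression means, without generating a genome or reads.
#' Useful for studying the DEG-enrichment behaviour at gene counts larger
#' than a toy genome carries.  The result feeds [generate_expression()].
#'
#' @param config A [sim_config()] (only the gene/expression fields are
#'   used).
#' @return List with `genes` (`gene_id`, `deg`, `edited`) and `mean_log2`
#'   (genes x cell lines).
#' @export
sim_expression_truth <- function(config) {
  set.seed(derive_seed(config$seed, 5L))
  labels <- sim_gene_labels(config$n_genes, config$deg_fraction,
                            config$deg_edited_enrichment,
                            config$edited_gene_rate)
  genes <- cbind(data.frame(gene_id = sprintf("g%04d",
                                              seq_len(config$n_genes))),
                 labels)
  base_log2 <- runif(nrow(genes), 3, 9)
  direction <- sample(c(-1, 1), nrow(genes), replace = TRUE)
  mean_log2 <- matrix(base_log2, nrow(genes), config$n_cell_lines)
  if (config$n_cell_lines > 1L) {
    shift <- direction * log2(config$deg_fold_change) * genes$deg
    for (l in 2:config$n_cell_lines) mean_log2[, l] <- base_log2 + shift
  }
  colnames(mean_log2) <- sprintf("line%d", seq_len(config$n_cell_lines))
  rownames(mean_log2) <- genes$gene_id
  list(genes = genes, mean_log2 = mean_log2)
}

## ---- one-call dataset ----

#' Generate a complete synthetic dataset
#'
#' Runs [generate_reference()], [plant_variants()], [simulate_reads()] for
#' every cell line and replicate, and [generate_expression()]; optionally
#' writes every artifact (FASTA, GFF-lite, BED, VCFs, SAMs, TSVs) to a
#' directory.  All outputs are byte-deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `genome`, `bundle` (annotation incl. the known-SNP
#'   catalog), `truth`, `reads` (nested list `[[line]][[replicate]]`),
#'   `expression`, and `paths` (named files when `out_dir` given).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  ref <- generate_reference(config)
  truth <- plant_variants(ref$genome, ref$bundle, config)
  attr(truth, "exons") <- ref$bundle$genes$exons
  known <- truth$snps[truth$snps$known, c("contig", "pos", "ref", "alt"),
                      drop = FALSE]
  known$source <- rep("known_snps", nrow(known))
  ref$bundle$known_snps <- known
  reads <- lapply(seq_len(config$n_cell_lines), function(l) {
    lapply(seq_len(config$n_replicates), function(r) {
      simulate_reads(ref$genome, truth, config, l, r)
    })
  })
  names(reads) <- sprintf("line%d", seq_len(config$n_cell_lines))
  expr <- generate_expression(truth, config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      genes = file.path(out_dir, "genes.gff"),
      repeats = file.path(out_dir, "repeats.bed"),
      known_snps = file.path(out_dir, "known_snps.vcf"),
      expression = file.path(out_dir, "expression.tsv")
    )
    write_fasta(ref$genome, paths$genome)
    write_gff(ref$bundle$genes, paths$genes)
    write_bed(ref$bundle$repeats, paths$repeats)
    write_snv_vcf(known, paths$known_snps, ref$genome)
    em <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    write.table(em, paths$expression, sep = "\t", quote = FALSE,
                row.names = FALSE)
    # per-line DNA-seq call sets: shared SNPs plus line-specific novels
    for (l in seq_len(config$n_cell_lines)) {
      ln <- sprintf("line%d", l)
      dna <- truth$snps[, c("contig", "pos", "ref", "alt")]
      if (!is.null(truth$novel_snvs[[ln]]))
        dna <- rbind(dna, truth$novel_snvs[[ln]][, c("contig", "pos", "ref", "alt")])
      p <- file.path(out_dir, sprintf("dna_%s.vcf", ln))
      write_snv_vcf(dna[order(dna$contig, dna$pos), ], p, ref$genome)
      paths[[sprintf("dna_%s", ln)]] <- p
      for (r in seq_len(config$n_replicates)) {
        sp <- file.path(out_dir, sprintf("reads_%s_rep%d.sam", ln, r))
        write_sam(reads[[ln]][[r]], ref$genome, sp)
        paths[[sprintf("reads_%s_rep%d", ln, r)]] <- sp
      }
    }
    # truth tables
    tt <- function(df, name) {
      p <- file.path(out_dir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths$truth_snps <- tt(truth$snps, "truth_snps.tsv")
    paths$truth_editing <- tt(
      cbind(truth$editing, truth$levels), "truth_editing.tsv")
    paths$truth_genes <- tt(truth$genes, "truth_genes.tsv")
    paths$truth_islands <- tt(truth$islands, "truth_islands.tsv")
  }
  list(genome = ref$genome, bundle = ref$bundle, truth = truth,
       reads = reads, expression = expr, paths = paths)
}
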