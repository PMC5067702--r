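#' Configuration for the synthetic two-tissue time-course simulator
#'
#' Defines the study design the generator emulates: a two-tissue
#' (sciatic nerve, dorsal root ganglion), five-timepoint (days 0, 1, 4,
#' 7, 14), three-replicate intensity matrix with planted differential
#' effects, plus an annotation with planted lincRNA-neighbor,
#' antisense-overlap and pseudogene-parent relationships and cDNA
#' sequences in which each pseudogene is a mutated copy of its parent.
#'
#' @param n_chromosomes number of simulated chromosomes.
#' @param chrom_length chromosome length in bp; must exceed twice the
#'   largest planted neighbor offset.
#' @param n_coding,n_lincrna,n_antisense,n_pseudogene feature counts.
#'   \code{n_coding} must cover the planted neighbor targets, antisense
#'   hosts and pseudogene parents.
#' @param planted_neighbor_offsets data.frame with columns
#'   \code{distance} (bp, > 0) and \code{side} ("left"/"right"); row i is
#'   the planted target of lincRNA i (extra lincRNAs get no target).
#' @param antisense_overlap_fraction fraction (0,1] of the shorter member
#'   each antisense pair overlaps by.
#' @param pseudogene_mutation_rate,pseudogene_indel_rate per-site
#'   substitution / indel probabilities in [0,1) applied to the parent
#'   cDNA copy.
#' @param tissues,timepoints,replicates the sample design; day 0 is the
#'   baseline and \code{replicates >= 2}.
#' @param de_effect_log2 planted log2 effect size (sign alternates across
#'   planted pairs).
#' @param noise_sd_log2 per-measurement log2 noise SD.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-feature
#'   baseline log2 intensities.
#' @param probes_per_feature probes emitted per feature (probe collapse
#'   is exercised when > 1).
#' @param gene_length_range,cdna_length_range bp ranges for gene loci and
#'   cDNA sequences.
#' @param isolation_bp guard distance: coding genes destined to be
#'   differentially expressed are placed at least this far from every
#'   lincRNA other than their own planted partner, so planted
#'   neighborhoods are identifiable (defaults to the 3 Mb analysis
#'   window).
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical outputs.
#' @return validated list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_chromosomes = 4,
                              chrom_length = 30e6,
                              n_coding = 30,
                              n_lincrna = 5,
                              n_antisense = 3,
                              n_pseudogene = 5,
                              planted_neighbor_offsets = data.frame(
                                distance = c(274577L, 50000L, 1500000L, 2500000L, 800000L),
                                side = c("right", "left", "right", "left", "right"),
                                stringsAsFactors = FALSE),
                              antisense_overlap_fraction = 0.5,
                              pseudogene_mutation_rate = 0.05,
                              pseudogene_indel_rate = 0.005,
                              tissues = c("SN", "DRG"),
                              timepoints = c(0, 1, 4, 7, 14),
                              replicates = 3,
                              de_effect_log2 = 2,
                              noise_sd_log2 = 0.25,
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 1.5,
                              probes_per_feature = 1,
                              gene_length_range = c(5000, 20000),
                              cdna_length_range = c(400, 1200),
                              isolation_bp = 3e6,
                              seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_coding = as.integer(n_coding),
              n_lincrna = as.integer(n_lincrna),
              n_antisense = as.integer(n_antisense),
              n_pseudogene = as.integer(n_pseudogene),
              planted_neighbor_offsets = planted_neighbor_offsets,
              antisense_overlap_fraction = antisense_overlap_fraction,
              pseudogene_mutation_rate = pseudogene_mutation_rate,
              pseudogene_indel_rate = pseudogene_indel_rate,
              tissues = as.character(tissues),
              timepoints = as.numeric(timepoints),
              replicates = as.integer(replicates),
              de_effect_log2 = de_effect_log2,
              noise_sd_log2 = noise_sd_log2,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              probes_per_feature = as.integer(probes_per_feature),
              gene_length_range = as.integer(gene_length_range),
              cdna_length_range = as.integer(cdna_length_range),
              isolation_bp = as.numeric(isolation_bp),
              seed = as.integer(seed))
  counts <- c(cfg$n_chromosomes, cfg$n_coding, cfg$n_lincrna,
              cfg$n_antisense, cfg$n_pseudogene)
  if (any(counts < 0)) stop("feature counts must be >= 0")
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  rates <- c(cfg$pseudogene_mutation_rate, cfg$pseudogene_indel_rate)
  if (any(rates < 0 | rates >= 1)) stop("mutation/indel rates must lie in [0, 1)")
  if (cfg$antisense_overlap_fraction <= 0 || cfg$antisense_overlap_fraction > 1) {
    stop("antisense_overlap_fraction must lie in (0, 1]")
  }
  offs <- cfg$planted_neighbor_offsets
  if (nrow(offs) > 0) {
    if (!all(c("distance", "side") %in% names(offs))) {
      stop("planted_neighbor_offsets needs columns distance, side")
    }
    if (any(offs$distance <= 0)) stop("planted neighbor distances must be > 0")
    if (!all(offs$side %in% c("left", "right"))) {
      stop("planted neighbor side must be 'left' or 'right'")
    }
    if (cfg$chrom_length <= 2 * max(offs$distance)) {
      stop("chrom_length must exceed twice the largest planted offset")
    }
  }
  if (cfg$replicates < 2) stop("replicates must be >= 2")
  if (!0 %in% cfg$timepoints) stop("timepoints must include the day-0 baseline")
  n_planted <- min(nrow(offs), cfg$n_lincrna)
  needed <- n_planted + cfg$n_antisense + cfg$n_pseudogene
  if (cfg$n_coding < needed) {
    stop("n_coding (", cfg$n_coding, ") must cover planted targets, ",
         "antisense hosts and pseudogene parents (", needed, ")")
  }
  structure(cfg, class = "SimulationConfig")
}

# Rejection-sampling placement. `blocks` is the running data.frame of
# placed features; `spans` is a data.frame of intervals (offsets relative
# to a unit origin) to be placed together. Predicates enforce
# non-overlap (except explicitly allowed within the unit) and the
# cis-isolation guard between lincRNAs and DE-destined coding genes.
place_unit <- function(blocks, spans, cfg, max_attempts = 1000L) {
  span_len <- max(spans$off_end)
  for (attempt in seq_len(max_attempts)) {
    chrom <- paste0("chr", sample.int(cfg$n_chromosomes, 1))
    origin <- sample.int(as.integer(cfg$chrom_length - span_len), 1)
    cand <- spans
    cand$chrom <- chrom
    cand$start <- origin + spans$off_start
    cand$end <- origin + spans$off_end
    ok <- TRUE
    prior <- blocks[blocks$chrom == chrom, , drop = FALSE]
    if (nrow(prior) > 0) {
      for (i in seq_len(nrow(cand))) {
        gaps <- boundary_gap(prior$start, prior$end, cand$start[i], cand$end[i])
        if (any(gaps == 0)) { ok <- FALSE; break }
        if (cand$is_linc[i] && any(prior$de_coding & gaps <= cfg$isolation_bp)) {
          ok <- FALSE; break
        }
        if (cand$de_coding[i] && any(prior$is_linc & gaps <= cfg$isolation_bp)) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) return(cand)
  }
  stop("placement infeasible: could not place unit [",
       paste(spans$gene_id, collapse = ", "),
       "] after ", max_attempts, " attempts; ",
       "increase chrom_length/n_chromosomes or reduce feature counts")
}

blank_blocks <- function() {
  data.frame(gene_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             raw_biotype = character(), is_linc = logical(),
             de_coding = logical(), stringsAsFactors = FALSE)
}

span_row <- function(gene_id, off_start, off_end, strand, raw_biotype,
                     is_linc = FALSE, de_coding = FALSE) {
  data.frame(gene_id = gene_id, off_start = off_start, off_end = off_end,
             strand = strand, raw_biotype = raw_biotype,
             is_linc = is_linc, de_coding = de_coding,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic annotation with planted relationships
#'
#' Places non-overlapping gene loci on simulated chromosomes (rejection
#' sampling, deterministic given the seed): lincRNAs with a planted
#' protein-coding neighbor at exactly the requested gap and side,
#' antisense RNAs overlapping a host coding gene on the opposite strand
#' by the requested fraction of the shorter member, pseudogene loci with
#' an assigned parent coding gene, and unrelated coding genes. Coding
#' genes destined to carry differential effects are kept outside the
#' isolation window of unrelated lincRNAs so the planted neighborhoods
#' are exactly recoverable.
#'
#' @param cfg \code{\link{simulation_config}}.
#' @return list with elements \code{annotation} (an
#'   \code{\link{annotation_set}}, source \code{"synthetic"}) and
#'   \code{truth} (a \code{TruthManifest}: \code{planted_de},
#'   \code{planted_neighbors}, \code{planted_antisense},
#'   \code{planted_parents}).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  offs <- cfg$planted_neighbor_offsets
  n_planted <- min(nrow(offs), cfg$n_lincrna)
  n_parent <- cfg$n_pseudogene
  n_host <- cfg$n_antisense
  n_plain <- cfg$n_coding - n_planted - n_host - n_parent

  coding_ids <- make_ids("PCG", cfg$n_coding)
  target_ids <- coding_ids[seq_len(n_planted)]
  host_ids <- coding_ids[n_planted + seq_len(n_host)]
  parent_ids <- coding_ids[n_planted + n_host + seq_len(n_parent)]
  plain_ids <- coding_ids[n_planted + n_host + n_parent + seq_len(max(0, n_plain))]
  linc_ids <- make_ids("LINC", cfg$n_lincrna)
  as_ids <- make_ids("ASR", cfg$n_antisense)
  psg_ids <- make_ids("PSG", cfg$n_pseudogene)

  rand_len <- function() sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1)
  rand_strand <- function() sample(c("+", "-"), 1)

  blocks <- blank_blocks()
  neighbors <- antisense <- NULL

  # lincRNA + planted neighbor target units
  for (i in seq_len(n_planted)) {
    L1 <- rand_len(); L2 <- rand_len()
    d <- offs$distance[i]; side <- offs$side[i]
    if (side == "right") {
      linc_span <- c(0L, L1 - 1L)
      tgt_span <- c(L1 - 1L + d, L1 - 1L + d + L2 - 1L)
    } else {
      tgt_span <- c(0L, L2 - 1L)
      linc_span <- c(L2 - 1L + d, L2 - 1L + d + L1 - 1L)
    }
    spans <- rbind(
      span_row(linc_ids[i], linc_span[1], linc_span[2], rand_strand(),
               "lincRNA", is_linc = TRUE),
      span_row(target_ids[i], tgt_span[1], tgt_span[2], rand_strand(),
               "protein_coding", de_coding = TRUE))
    placed <- place_unit(blocks, spans, cfg)
    blocks <- rbind(blocks, placed[, names(blocks)])
    neighbors <- rbind(neighbors, data.frame(
      lincrna_id = linc_ids[i], target_id = target_ids[i],
      distance = d, side = side, stringsAsFactors = FALSE))
  }

  # antisense RNA overlapping an opposite-strand host coding gene
  for (j in seq_len(n_host)) {
    Lh <- rand_len(); La <- rand_len()
    ov <- max(1L, as.integer(round(cfg$antisense_overlap_fraction * min(Lh, La))))
    host_strand <- rand_strand()
    as_strand <- setdiff(c("+", "-"), host_strand)
    # asRNA ends `ov` bp into the host; unit origin = asRNA start
    as_span <- c(0L, La - 1L)
    host_span <- c(La - ov, La - ov + Lh - 1L)
    spans <- rbind(
      span_row(as_ids[j], as_span[1], as_span[2], as_strand, "antisense"),
      span_row(host_ids[j], host_span[1], host_span[2], host_strand,
               "protein_coding", de_coding = TRUE))
    # overlap within the unit is intended: place against prior blocks only
    placed <- place_unit(blocks, spans, cfg)
    blocks <- rbind(blocks, placed[, names(blocks)])
    antisense <- rbind(antisense, data.frame(
      asrna_id = as_ids[j], target_id = host_ids[j],
      overlap_bp = ov, stringsAsFactors = FALSE))
  }

  # remaining lincRNAs (no planted target), parents, plain coding, pseudogenes
  singles <- list()
  for (i in setdiff(seq_len(cfg$n_lincrna), seq_len(n_planted))) {
    singles[[length(singles) + 1]] <- list(linc_ids[i], "lincRNA", TRUE, FALSE)
  }
  for (id in parent_ids) {
    singles[[length(singles) + 1]] <- list(id, "protein_coding", FALSE, TRUE)
  }
  for (id in plain_ids) {
    singles[[length(singles) + 1]] <- list(id, "protein_coding", FALSE, FALSE)
  }
  for (id in psg_ids) {
    singles[[length(singles) + 1]] <- list(id, "processed_pseudogene", FALSE, FALSE)
  }
  for (s in singles) {
    L <- rand_len()
    spans <- span_row(s[[1]], 0L, L - 1L, rand_strand(), s[[2]],
                      is_linc = s[[3]], de_coding = s[[4]])
    placed <- place_unit(blocks, spans, cfg)
    blocks <- rbind(blocks, placed[, names(blocks)])
  }

  parents <- if (cfg$n_pseudogene > 0) {
    data.frame(pseudogene_id = psg_ids, parent_id = parent_ids,
               stringsAsFactors = FALSE)
  } else {
    data.frame(pseudogene_id = character(), parent_id = character(),
               stringsAsFactors = FALSE)
  }

  # planted differential effects: each related pair is assigned one
  # (tissue, interval) contrast round-robin; effect sign alternates.
  labs <- interval_labels(cfg$timepoints)
  contrasts <- expand.grid(interval = unname(labs), tissue = cfg$tissues,
                           stringsAsFactors = FALSE)[, c("tissue", "interval")]
  pair_members <- c(
    lapply(seq_len(n_planted), function(i) c(linc_ids[i], target_ids[i])),
    lapply(seq_len(n_host), function(j) c(as_ids[j], host_ids[j])),
    lapply(seq_len(cfg$n_pseudogene), function(k) c(psg_ids[k], parent_ids[k])))
  planted_de <- NULL
  for (p in seq_along(pair_members)) {
    ct <- contrasts[(p - 1) %% nrow(contrasts) + 1, ]
    eff <- cfg$de_effect_log2 * if (p %% 2 == 1) 1 else -1
    planted_de <- rbind(planted_de, data.frame(
      feature_id = pair_members[[p]], tissue = ct$tissue,
      interval = ct$interval, effect_log2 = eff, stringsAsFactors = FALSE))
  }
  if (is.null(planted_de)) {
    planted_de <- data.frame(feature_id = character(), tissue = character(),
                             interval = character(), effect_log2 = numeric(),
                             stringsAsFactors = FALSE)
  }
  if (is.null(neighbors)) {
    neighbors <- data.frame(lincrna_id = character(), target_id = character(),
                            distance = integer(), side = character(),
                            stringsAsFactors = FALSE)
  }
  if (is.null(antisense)) {
    antisense <- data.frame(asrna_id = character(), target_id = character(),
                            overlap_bp = integer(), stringsAsFactors = FALSE)
  }

  feats <- blocks
  feats$gene_name <- tolower(feats$gene_id)
  feats$biotype <- classify_biotype(feats$raw_biotype)
  feats$source <- "synthetic"
  feats <- feats[order(feats$chrom, feats$start, feats$gene_id),
                 c("gene_id", "gene_name", "chrom", "start", "end", "strand",
                   "biotype", "raw_biotype", "source")]
  ann <- annotation_set(feats)
  truth <- structure(list(planted_de = planted_de,
                          planted_neighbors = neighbors,
                          planted_antisense = antisense,
                          planted_parents = parents),
                     class = "TruthManifest")
  list(annotation = ann, truth = truth)
}

# Apply i.i.d. substitutions then indels to a base vector.
mutate_bases <- function(bases, sub_rate, indel_rate) {
  alphabet <- c("A", "C", "G", "T")
  n <- length(bases)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (i in hit) {
      bases[i] <- sample(setdiff(alphabet, bases[i]), 1)
    }
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(bases)) < indel_rate)
    if (length(hit) > 0) {
      pieces <- as.list(bases)
      for (i in hit) {
        if (stats::runif(1) < 0.5) {
          pieces[[i]] <- character(0)                      # deletion
        } else {
          pieces[[i]] <- c(bases[i], sample(alphabet, 1)) # insertion after
        }
      }
      bases <- unlist(pieces)
    }
  }
  bases
}

#' Generate cDNA sequences for coding genes and pseudogenes
#'
#' Coding genes receive independent uniform-random sequences (expected
#' pairwise identity about 0.25); each pseudogene sequence is a copy of
#' its planted parent with i.i.d. substitutions at
#' \code{pseudogene_mutation_rate} and indels at
#' \code{pseudogene_indel_rate} per site.
#'
#' @param ann annotation from \code{\link{generate_annotation}}.
#' @param truth matching \code{TruthManifest}.
#' @param cfg \code{\link{simulation_config}}.
#' @return \code{Biostrings::DNAStringSet} named by gene id (coding genes
#'   first, then pseudogenes).
#' @export
generate_sequences <- function(ann, truth, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)
  f <- ann_features(ann)
  coding <- f$gene_id[f$biotype == "protein_coding"]
  alphabet <- c("A", "C", "G", "T")
  seqs <- lapply(coding, function(id) {
    len <- sample(cfg$cdna_length_range[1]:cfg$cdna_length_range[2], 1)
    sample(alphabet, len, replace = TRUE)
  })
  names(seqs) <- coding
  pg <- truth$planted_parents
  for (k in seq_len(nrow(pg))) {
    parent <- pg$parent_id[k]
    if (!parent %in% names(seqs)) {
      stop("pseudogene ", pg$pseudogene_id[k],
           " has parent ", parent, " without a sequence")
    }
    seqs[[pg$pseudogene_id[k]]] <- mutate_bases(
      seqs[[parent]], cfg$pseudogene_mutation_rate, cfg$pseudogene_indel_rate)
  }
  Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
}

#' Generate a linear-scale intensity matrix with planted effects
#'
#' Per-probe log2 intensity = per-feature baseline
#' (Normal(\code{baseline_log2_mean}, \code{baseline_log2_sd})) + the
#' planted signed log2 effect for samples in that feature's planted
#' (tissue, interval) + Normal(0, \code{noise_sd_log2}) noise; the
#' returned matrix is \code{2^log2}, hence strictly positive.
#'
#' @param ann annotation from \code{\link{generate_annotation}}.
#' @param truth matching \code{TruthManifest}.
#' @param cfg \code{\link{simulation_config}}.
#' @return list of class \code{ncx_expression}: \code{intensities}
#'   (probes x samples, linear scale), \code{design} (sample, tissue,
#'   day, replicate), \code{probe_map} (probe_id, gene_id).
#' @export
generate_expression <- function(ann, truth, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!0 %in% cfg$timepoints) stop("design has no day-0 baseline group")
  set.seed(cfg$seed + 2L)
  f <- ann_features(ann)
  k <- cfg$probes_per_feature
  probe_map <- data.frame(
    probe_id = paste0(rep(f$gene_id, each = k), "_p", rep(seq_len(k), nrow(f))),
    gene_id = rep(f$gene_id, each = k), stringsAsFactors = FALSE)

  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        day = cfg$timepoints, tissue = cfg$tissues,
                        stringsAsFactors = FALSE)[, c("tissue", "day", "replicate")]
  design$sample <- sprintf("%s_d%g_r%d", design$tissue, design$day, design$replicate)
  design <- design[, c("sample", "tissue", "day", "replicate")]

  labs <- interval_labels(cfg$timepoints)
  baseline <- stats::rnorm(nrow(f), cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  names(baseline) <- f$gene_id

  log2mat <- matrix(rep(baseline[probe_map$gene_id], nrow(design)),
                    nrow = nrow(probe_map), ncol = nrow(design))
  rownames(log2mat) <- probe_map$probe_id
  colnames(log2mat) <- design$sample

  de <- truth$planted_de
  for (i in seq_len(nrow(de))) {
    probes <- probe_map$probe_id[probe_map$gene_id == de$feature_id[i]]
    day <- as.numeric(names(labs)[labs == de$interval[i]])
    cols <- design$sample[design$tissue == de$tissue[i] & design$day == day]
    log2mat[probes, cols] <- log2mat[probes, cols] + de$effect_log2[i]
  }
  if (cfg$noise_sd_log2 > 0) {
    log2mat <- log2mat + matrix(
      stats::rnorm(length(log2mat), 0, cfg$noise_sd_log2),
      nrow = nrow(log2mat))
  }
  structure(list(intensities = 2^log2mat, design = design,
                 probe_map = probe_map),
            class = "ncx_expression")
}

#' Run the full generator
#'
#' @param cfg \code{\link{simulation_config}}.
#' @return list of class \code{ncx_simulation} with \code{annotation},
#'   \code{truth}, \code{sequences}, \code{expression}, \code{config}.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  at <- generate_annotation(cfg)
  seqs <- generate_sequences(at$annotation, at$truth, cfg)
  expr <- generate_expression(at$annotation, at$truth, cfg)
  structure(list(annotation = at$annotation, truth = at$truth,
                 sequences = seqs, expression = expr, config = cfg),
            class = "ncx_simulation")
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits annotation.gtf, cdna.fa, expression.tsv (first column probe id),
#' samples.tsv, probe_map.tsv, and truth.json into \code{dir}.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture_set <- function(sim, dir) {
  stopifnot(inherits(sim, "ncx_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             fasta = file.path(dir, "cdna.fa"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             truth = file.path(dir, "truth.json"))
  write_gtf(sim$annotation, paths["gtf"])
  Biostrings::writeXStringSet(sim$sequences, paths["fasta"])
  mat <- sim$expression$intensities
  expr_df <- data.frame(probe = rownames(mat), mat, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$design, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$probe_map, paths["probe_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), paths["truth"], digits = NA)
  invisible(paths)
}
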