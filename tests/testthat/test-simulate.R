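test_that("simulation_config enforces its invariants", {
  expect_s3_class(simulation_config(), "SimulationConfig")
  expect_error(simulation_config(replicates = 1), "replicates")
  expect_error(simulation_config(pseudogene_mutation_rate = 1), "rates")
  expect_error(simulation_config(antisense_overlap_fraction = 0), "overlap_fraction")
  expect_error(simulation_config(chrom_length = 4e6,
    planted_neighbor_offsets = data.frame(distance = 2.5e6, side = "right")),
    "twice the largest")
  expect_error(simulation_config(timepoints = c(1, 4)), "baseline")
  expect_error(simulation_config(n_coding = 2), "must cover")
})

test_that("planted neighbor pairs sit at exactly the requested gap and side", {
  cfg <- simulation_config(
    n_lincrna = 1, n_antisense = 0, n_pseudogene = 0, n_coding = 1,
    planted_neighbor_offsets = data.frame(distance = 274577L, side = "right"),
    seed = 3)
  at <- generate_annotation(cfg)
  tr <- at$truth$planted_neighbors
  expect_equal(nrow(tr), 1)
  expect_equal(tr$distance, 274577L)
  expect_equal(tr$side, "right")
  f <- ann_features(at$annotation)
  l <- f[f$gene_id == tr$lincrna_id, ]
  t <- f[f$gene_id == tr$target_id, ]
  expect_equal(t$chrom, l$chrom)
  expect_equal(t$start - l$end, 274577L)
})

test_that("absent feature classes leave their manifest sections empty", {
  cfg <- simulation_config(n_antisense = 0, n_pseudogene = 0, seed = 5)
  at <- generate_annotation(cfg)
  expect_equal(nrow(at$truth$planted_antisense), 0)
  expect_equal(nrow(at$truth$planted_parents), 0)
  f <- ann_features(at$annotation)
  expect_false(any(f$biotype %in% c("antisense", "pseudogene")))
})

test_that("identical config and seed give byte-identical GTF output", {
  cfg <- simulation_config(seed = 19)
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(generate_annotation(cfg)$annotation, p1)
  write_gtf(generate_annotation(simulation_config(seed = 19))$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("manifest ids all exist in the annotation and placements do not collide", {
  cfg <- simulation_config(seed = 23)
  at <- generate_annotation(cfg)
  f <- ann_features(at$annotation)
  tr <- at$truth
  ids <- c(tr$planted_de$feature_id, tr$planted_neighbors$lincrna_id,
           tr$planted_neighbors$target_id, tr$planted_antisense$asrna_id,
           tr$planted_antisense$target_id, tr$planted_parents$pseudogene_id,
           tr$planted_parents$parent_id)
  expect_true(all(ids %in% f$gene_id))
  # only planted antisense pairs may overlap
  allowed <- paste(pmin(tr$planted_antisense$asrna_id, tr$planted_antisense$target_id),
                   pmax(tr$planted_antisense$asrna_id, tr$planted_antisense$target_id))
  for (chrom in unique(f$chrom)) {
    g <- f[f$chrom == chrom, ]
    if (nrow(g) < 2) next
    for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      ov <- min(g$end[i], g$end[j]) - max(g$start[i], g$start[j]) + 1
      if (ov > 0) {
        expect_true(paste(min(g$gene_id[i], g$gene_id[j]),
                          max(g$gene_id[i], g$gene_id[j])) %in% allowed)
      }
    }
  }
})

test_that("infeasible placement raises an explicit error", {
  cfg <- simulation_config(n_chromosomes = 1, chrom_length = 6e4,
                           n_coding = 30, n_lincrna = 0, n_antisense = 0,
                           n_pseudogene = 0,
                           planted_neighbor_offsets = data.frame(
                             distance = integer(), side = character()),
                           gene_length_range = c(5000, 5000), seed = 1)
  expect_error(generate_annotation(cfg), "placement infeasible")
})

test_that("pseudogene sequences derive from their parents at the planted rates", {
  base <- simulation_config(n_lincrna = 0, n_antisense = 0, n_pseudogene = 3,
                            n_coding = 6,
                            planted_neighbor_offsets = data.frame(
                              distance = integer(), side = character()),
                            cdna_length_range = c(2000, 2000), seed = 31)

  # zero rates: identical copy
  cfg0 <- base; cfg0$pseudogene_mutation_rate <- 0; cfg0$pseudogene_indel_rate <- 0
  at <- generate_annotation(cfg0)
  seqs <- generate_sequences(at$annotation, at$truth, cfg0)
  pp <- at$truth$planted_parents
  expect_identical(as.character(seqs[[pp$pseudogene_id[1]]]),
                   as.character(seqs[[pp$parent_id[1]]]))

  # substitution-only: Hamming fraction within binomial 99% bounds of 0.05
  cfg1 <- base; cfg1$pseudogene_mutation_rate <- 0.05; cfg1$pseudogene_indel_rate <- 0
  seqs1 <- generate_sequences(at$annotation, at$truth, cfg1)
  for (k in seq_len(nrow(pp))) {
    p <- strsplit(as.character(seqs1[[pp$parent_id[k]]]), "")[[1]]
    g <- strsplit(as.character(seqs1[[pp$pseudogene_id[k]]]), "")[[1]]
    expect_equal(length(g), length(p))
    mism <- sum(p != g)
    bounds <- qbinom(c(0.005, 0.995), length(p), 0.05)
    expect_gte(mism, bounds[1])
    expect_lte(mism, bounds[2])
  }

  # no pseudogenes: only coding sequences emitted
  cfg2 <- simulation_config(n_lincrna = 0, n_antisense = 0, n_pseudogene = 0,
                            n_coding = 4,
                            planted_neighbor_offsets = data.frame(
                              distance = integer(), side = character()),
                            seed = 33)
  at2 <- generate_annotation(cfg2)
  seqs2 <- generate_sequences(at2$annotation, at2$truth, cfg2)
  f2 <- ann_features(at2$annotation)
  expect_setequal(names(seqs2), f2$gene_id[f2$biotype == "protein_coding"])
})

test_that("expression matrix realises baseline, planted effect, and noise model", {
  # zero noise, no effects: constant per feature
  cfg <- simulation_config(noise_sd_log2 = 0, de_effect_log2 = 0, seed = 41)
  sim <- simulate_dataset(cfg)
  expect_true(all(apply(sim$expression$intensities, 1,
                        function(x) diff(range(x))) == 0))
  expect_true(all(sim$expression$intensities > 0))

  # zero noise with a +2 log2 effect: linear FC exactly 4 in that contrast
  cfg2 <- simulation_config(noise_sd_log2 = 0, seed = 43)
  sim2 <- simulate_dataset(cfg2)
  de <- sim2$truth$planted_de
  up <- de[de$effect_log2 == 2, ][1, ]
  deg <- run_de(sim2$expression$intensities, sim2$expression$design)
  row <- deg[deg$feature == paste0(up$feature_id, "_p1") &
               deg$tissue == up$tissue & deg$interval == up$interval, ]
  expect_equal(row$fc, 4)

  # noisy: per-gene sample SD within chi-square 99% bounds almost always
  cfg3 <- simulation_config(de_effect_log2 = 0, seed = 47)
  sim3 <- simulate_dataset(cfg3)
  log2m <- log2(sim3$expression$intensities)
  sn_cols <- sim3$expression$design$sample[sim3$expression$design$tissue == "SN"]
  sds <- apply(log2m[, sn_cols], 1, sd)
  n <- length(sn_cols)
  bounds <- sqrt(qchisq(c(0.005, 0.995), n - 1) / (n - 1)) * cfg3$noise_sd_log2
  frac_out <- mean(sds < bounds[1] | sds > bounds[2])
  expect_lt(frac_out, 0.05)
})

test_that("fixture files are written as plain text and round-trip key content", {
  cfg <- simulation_config(seed = 53)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  paths <- write_fixture_set(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_gtf(paths["gtf"], source = "synthetic")
  expect_equal(length(back), length(sim$annotation))
  expr <- read.delim(paths["expression"], check.names = FALSE)
  expect_equal(nrow(expr), nrow(sim$expression$intensities))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$planted_parents$pseudogene_id),
               sort(sim$truth$planted_parents$pseudogene_id))
})
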