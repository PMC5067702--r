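ann_from <- function(df) {
  df$gene_name <- tolower(df$gene_id)
  df$source <- "synthetic"
  annotation_set(df)
}

test_that("neighbor search honours distance, side, bin, and the inclusive window", {
  ann <- ann_from(data.frame(
    gene_id = c("L1", "T1", "T2", "T3", "T4"),
    chrom = "chr1",
    start = c(1000000, 1284577, 1005000, 4010001, 4010000),
    end = c(1010000, 1290000, 1006000, 4020000, 4019999),
    strand = "+",
    biotype = c("lincRNA", rep("protein_coding", 4)),
    stringsAsFactors = FALSE))
  # T3 gap = 3,000,001 (excluded), T4 gap = 3,000,000 (included)
  nb <- find_lincrna_neighbors(ann, "L1", c("T1", "T2", "T3", "T4"), window = 3e6)
  expect_setequal(nb$target, c("T1", "T2", "T4"))
  t1 <- nb[nb$target == "T1", ]
  expect_equal(t1$distance, 274577)
  expect_equal(t1$side, "right")
  expect_equal(t1$bin, "<=1MB")
  t2 <- nb[nb$target == "T2", ]
  expect_equal(t2$distance, 0)
  expect_equal(t2$side, "overlap")
  expect_equal(nb$target[1], "T2")  # closest first
  expect_equal(nb$distance[nb$target == "T4"], 3e6)
  expect_error(find_lincrna_neighbors(ann, "L1", "T1", window = 0), "window")
  expect_error(find_lincrna_neighbors(ann, "nope", "T1"), "unknown gene id")
})

test_that("neighbor search equals the all-pairs scan on random annotations", {
  set.seed(99)
  for (rep in 1:100) {
    feats <- random_features(30, n_chrom = 2, chrom_len = 5e6)
    ann <- ann_from(feats[, c("gene_id", "chrom", "start", "end", "strand", "biotype")])
    lincs <- feats$gene_id[feats$biotype == "lincRNA"]
    coding <- feats$gene_id[feats$biotype == "protein_coding"]
    if (length(lincs) == 0 || length(coding) == 0) next
    window <- sample(c(1e5, 5e5, 2e6), 1)
    got <- find_lincrna_neighbors(ann, lincs, coding, window)
    want <- oracle_neighbors(feats, lincs, coding, window)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$ncrna, got$target), c("ncrna", "target", "distance", "side")]
      want <- want[order(want$ncrna, want$target), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("antisense detection requires same chromosome, opposite strand, overlap", {
  ann <- ann_from(data.frame(
    gene_id = c("AS1", "G1", "G2", "G3"),
    chrom = c("chr2", "chr2", "chr2", "chr3"),
    start = c(100, 300, 600, 300),
    end = c(500, 900, 901, 900),
    strand = c("-", "+", "-", "+"),
    biotype = c("antisense", rep("protein_coding", 3)),
    stringsAsFactors = FALSE))
  hits <- find_antisense_targets(ann, "AS1", c("G1", "G2", "G3"))
  expect_equal(hits$target, "G1")
  expect_equal(hits$overlap, 201)   # [300,500] inclusive
  # G2 same strand as AS1 -> excluded; G3 other chromosome -> excluded
  expect_false(any(c("G2", "G3") %in% hits$target))
})

test_that("antisense detection equals brute-force interval intersection", {
  set.seed(123)
  for (rep in 1:100) {
    feats <- random_features(25, n_chrom = 2, chrom_len = 2e5,
                             biotypes = c("protein_coding", "antisense"))
    ann <- ann_from(feats[, c("gene_id", "chrom", "start", "end", "strand", "biotype")])
    as_ids <- feats$gene_id[feats$biotype == "antisense"]
    coding <- feats$gene_id[feats$biotype == "protein_coding"]
    if (length(as_ids) == 0 || length(coding) == 0) next
    got <- find_antisense_targets(ann, as_ids, coding)
    want <- oracle_antisense(feats, as_ids, coding)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$ncrna, got$target), c("ncrna", "target", "overlap")]
      want <- want[order(want$ncrna, want$target), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("antisense detection is invariant under chromosome-wide translation", {
  feats <- random_features(20, n_chrom = 1, chrom_len = 1e5,
                           biotypes = c("protein_coding", "antisense"))
  ann1 <- ann_from(feats[, c("gene_id", "chrom", "start", "end", "strand", "biotype")])
  shifted <- feats
  shifted$start <- shifted$start + 12345
  shifted$end <- shifted$end + 12345
  ann2 <- ann_from(shifted[, c("gene_id", "chrom", "start", "end", "strand", "biotype")])
  as_ids <- feats$gene_id[feats$biotype == "antisense"]
  coding <- feats$gene_id[feats$biotype == "protein_coding"]
  expect_equal(find_antisense_targets(ann2, as_ids, coding),
               find_antisense_targets(ann1, as_ids, coding))
})

test_that("local alignment reproduces hand-computed scores", {
  expect_equal(local_align("ACGT", "ACGT")[, c("score", "identity", "length")],
               data.frame(score = 8, identity = 1.0, length = 4L))
  expect_equal(local_align("ACGT", "ACGA")$score, 6)  # best block "ACG"
  none <- local_align("AAAA", "TTTT")
  expect_equal(none$score, 0)
  expect_equal(none$length, 0L)
  expect_error(local_align("ACGX", "ACGT"), "non-ACGTN")
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local alignment equals a hand-rolled Smith-Waterman on random pairs", {
  set.seed(17)
  for (i in 1:100) {
    q <- random_dna(sample(4:14, 1))
    s <- random_dna(sample(4:14, 1))
    expect_equal(local_align(q, s)$score, oracle_sw_score(q, s),
                 info = paste(q, s))
  }
})

test_that("local alignment score is symmetric and maximal on self", {
  set.seed(19)
  for (i in 1:20) {
    q <- random_dna(sample(5:30, 1))
    s <- random_dna(sample(5:30, 1))
    expect_equal(local_align(q, s)$score, local_align(s, q)$score)
    expect_equal(local_align(q, q)$score, 2 * nchar(q))
  }
})

test_that("BLAST tabular parsing converts identity and validates columns", {
  path <- tempfile()
  writeLines(paste(c("PSG1", "PCG1", "95.00", "480", "20", "2",
                     "1", "480", "5", "490", "1e-100", "350.5"),
                   collapse = "\t"), path)
  hits <- read_blast_tab(path)
  expect_equal(hits$identity, 0.95)
  expect_equal(hits$length, 480L)
  expect_equal(hits$score, 350.5)

  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_blast_tab(empty)), 0)

  bad <- tempfile()
  writeLines(paste(rep("x", 11), collapse = "\t"), bad)
  expect_error(read_blast_tab(bad), "line 1")
})

test_that("parental assignment keeps only the unique best hit", {
  set.seed(21)
  parent <- random_dna(600)
  # a 95%-identity copy of parent A among 9 unrelated coding sequences
  pb <- strsplit(parent, "")[[1]]
  mut <- sample(600, 30)
  for (i in mut) pb[i] <- sample(setdiff(c("A", "C", "G", "T"), pb[i]), 1)
  pseudo <- paste(pb, collapse = "")
  coding <- c(A = parent,
              setNames(vapply(1:9, function(i) random_dna(600), character(1)),
                       paste0("U", 1:9)))
  got <- assign_parental_genes(
    pseudo_seqs = c(PSG1 = pseudo), coding_seqs = coding)
  expect_equal(got$target, "A")
  expect_equal(got$relation, "parental")
  expect_gt(got$identity, 0.9)
  # cross-check: A maximises the exhaustive per-candidate alignment score
  scores <- vapply(coding, function(s) local_align(pseudo, s)$score, numeric(1))
  expect_equal(names(which.max(scores)), "A")

  # two identical candidate parents force a tie -> ambiguous, excluded
  twins <- c(A = parent, B = parent)
  amb <- assign_parental_genes(pseudo_seqs = c(PSG1 = pseudo), coding_seqs = twins)
  expect_equal(nrow(amb), 0)
  expect_equal(unique(attr(amb, "ambiguous")$query), "PSG1")
  # ... unless the tie policy keeps the lexicographically first subject
  first <- assign_parental_genes(pseudo_seqs = c(PSG1 = pseudo),
                                 coding_seqs = twins, ambiguous = "first")
  expect_equal(first$target, "A")

  # a random pseudogene stays unassigned under the default thresholds
  rnd <- assign_parental_genes(pseudo_seqs = c(PSGR = random_dna(600)),
                               coding_seqs = coding["A"])
  expect_equal(nrow(rnd), 0)
  expect_equal(attr(rnd, "unassigned"), "PSGR")
})

test_that("parental recovery stays above 95% at mutation rate 0.10", {
  cfg <- simulation_config(
    n_lincrna = 0, n_antisense = 0, n_pseudogene = 20, n_coding = 40,
    planted_neighbor_offsets = data.frame(distance = integer(),
                                          side = character()),
    pseudogene_mutation_rate = 0.10, pseudogene_indel_rate = 0.01,
    cdna_length_range = c(400, 800), seed = 101)
  at <- generate_annotation(cfg)
  seqs <- generate_sequences(at$annotation, at$truth, cfg)
  f <- ann_features(at$annotation)
  psg <- f$gene_id[f$biotype == "pseudogene"]
  coding <- f$gene_id[f$biotype == "protein_coding"]  # 20 parents + 20 distractors
  got <- assign_parental_genes(pseudo_seqs = seqs[psg],
                               coding_seqs = seqs[coding])
  truth <- at$truth$planted_parents
  correct <- merge(got, truth, by.x = "ncrna", by.y = "pseudogene_id")
  n_right <- sum(correct$target == correct$parent_id)
  expect_gte(n_right / nrow(truth), 0.95)
})

test_that("DE filtering annotates targets with their contrast evidence", {
  assocs <- data.frame(ncrna = c("L1", "L2"), target = c("G1", "G2"),
                       relation = "neighbor", distance = c(100, 200),
                       side = "right", bin = "<=1MB", stringsAsFactors = FALSE)
  deg <- data.frame(feature = c("G1", "G1", "G2"),
                    tissue = c("SN", "SN", "DRG"),
                    interval = c("I2", "I3", "I1"),
                    fc = 2, p = 0.01, q = 0.01,
                    de = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  out <- filter_de_targets(assocs, deg)
  expect_equal(out$target_de, c(TRUE, FALSE))
  expect_equal(out$evidence[1], "SN:I2;SN:I3")
  only <- filter_de_targets(assocs, deg, only_de = TRUE)
  expect_equal(only$target, "G1")
  empty <- filter_de_targets(assocs[0, ], deg)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("target_de", "evidence") %in% names(empty)))
})
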