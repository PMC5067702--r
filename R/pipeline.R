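#' Run the full context-annotation pipeline on a simulated dataset
#'
#' Chains every stage on a generated dataset: differential expression
#' per (tissue, interval) contrast, probe-to-gene collapse, selection of
#' DE ncRNAs per biotype group, the three contextual target procedures
#' (lincRNA neighborhood, antisense opposite-strand overlap, pseudogene
#' parental assignment by local alignment), DE filtering of targets, and
#' the summary tables.
#'
#' @param sim an \code{ncx_simulation} from \code{\link{simulate_dataset}}
#'   or a \code{\link{simulation_config}} (simulated on the fly).
#' @param thr \code{\link{thresholds}}.
#' @return list with \code{deg_probe}, \code{deg_gene},
#'   \code{de_ncrnas} (ids per biotype), \code{neighbors},
#'   \code{antisense}, \code{parental} (all annotated with target DE
#'   status), \code{evidence}, \code{biotype_counts},
#'   \code{unique_counts}, plus the input \code{annotation},
#'   \code{truth} and \code{config}.
#' @export
run_pipeline <- function(sim, thr = thresholds()) {
  if (inherits(sim, "SimulationConfig")) sim <- simulate_dataset(sim)
  stopifnot(inherits(sim, "ncx_simulation"))
  ann <- sim$annotation
  f <- ann_features(ann)

  deg_probe <- run_de(sim$expression$intensities, sim$expression$design, thr)
  deg_gene <- collapse_probes(deg_probe, sim$expression$probe_map)

  de_ids <- unique(deg_gene$feature[deg_gene$de])
  de_by_bio <- lapply(
    stats::setNames(nm = c("lincRNA", "antisense", "pseudogene", "protein_coding")),
    function(b) intersect(de_ids, f$gene_id[f$biotype == b]))

  neighbors <- find_lincrna_neighbors(ann, de_by_bio$lincRNA,
                                      de_by_bio$protein_coding,
                                      window = thr$neighbor_window)
  antisense <- find_antisense_targets(ann, de_by_bio$antisense,
                                      f$gene_id[f$biotype == "protein_coding"])
  de_psg <- intersect(de_by_bio$pseudogene, names(sim$sequences))
  coding_seqs <- sim$sequences[intersect(names(sim$sequences),
                                         f$gene_id[f$biotype == "protein_coding"])]
  parental <- if (length(de_psg) > 0 && length(coding_seqs) > 0) {
    assign_parental_genes(pseudo_seqs = sim$sequences[de_psg],
                          coding_seqs = coding_seqs)
  } else {
    assign_parental_genes(hits = data.frame(
      query = character(), subject = character(), identity = numeric(),
      length = integer(), score = numeric(), stringsAsFactors = FALSE))
  }

  neighbors <- filter_de_targets(neighbors, deg_gene)
  antisense <- filter_de_targets(antisense, deg_gene)
  parental <- filter_de_targets(parental, deg_gene)

  list(annotation = ann, truth = sim$truth, config = sim$config,
       deg_probe = deg_probe, deg_gene = deg_gene,
       de_ncrnas = de_by_bio[c("lincRNA", "antisense", "pseudogene")],
       neighbors = neighbors, antisense = antisense, parental = parental,
       evidence = build_evidence_table(neighbors),
       biotype_counts = biotype_count_table(deg_gene, ann),
       unique_counts = unique_de_counts(deg_gene, ann))
}
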