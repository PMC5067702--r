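#' Published lincRNA-target pairs used as a worked reference fixture
#'
#' The 30 lincRNA / protein-coding target pairs (26 sciatic-nerve, 4
#' dorsal-root-ganglion) reported in the source study's lincRNA
#' neighborhood analysis, with the printed boundary distance in bp and
#' the side of the target relative to the lincRNA locus.
#'
#' @return data.frame with columns \code{tissue}, \code{lincrna},
#'   \code{target}, \code{distance}, \code{side}.
#' @export
published_pairs <- function() {
  sn <- rbind(
    c("RGD1562521", "Rgs22", 274577, "right"),
    c("Rn50_X_0667.2", "Rgs18", 217956, "left"),
    c("Gm26825", "Stim2", 487168, "left"),
    c("Fam9b", "Vps13b", 274577, "left"),
    c("Rn50_X_0711.1", "Creb1", 116889, "right"),
    c("Ct55", "Edem3", 84281, "left"),
    c("Rn50_14_0846.1", "Suco", 242915, "right"),
    c("Rn50_13_0828.1", "Zfyve28", 18891, "left"),
    c("Fam178b", "Ptchd1", 253992, "right"),
    c("Rn50_13_0839.5", "Pof1b", 145307, "right"),
    c("Rn50_7_1163.2", "Gpd1", 699513, "right"),
    c("Ino80dos", "Rb1cc1", 609632, "right"),
    c("RP23-61N4.3", "Gng11", 602367, "right"),
    c("Gm26673", "Thsd7a", 862550, "right"),
    c("Gm26827", "Peg3", 413420, "right"),
    c("Gm20204", "Arhgef7", 493494, "right"),
    c("Gm28933", "Rdh14", 28368, "right"),
    c("Gm26723", "Rdh14", 130201, "right"),
    c("Gm26819", "Klf6", 1620120, "right"),
    c("Yam1", "Tfb1m", 965615, "right"),
    c("Gm26823", "Cul2", 303188, "right"),
    c("Gm4221", "Zeb1", 416081, "right"),
    c("4731419I09Rik", "Hey1", 771424, "right"),
    c("A530017D24Rik", "Ccm2", 139918, "right"),
    c("1700086L19Rik", "Klhl29", 2852122, "right"),
    c("C130071C03Rik", "Wdr37", 85451, "right"))
  drg <- rbind(
    c("1700020I14Rik", "Itga8", 354118, "right"),
    c("Rn50_X_0744.2", "Edem3", 39848, "left"),
    c("Rn50_13_0853.1", "Chm", 974768, "right"),
    c("Rn50_7_1164.1", "Lhfpl1", 678582, "left"))
  all <- rbind(cbind("SN", sn), cbind("DRG", drg))
  data.frame(tissue = all[, 1], lincrna = all[, 2], target = all[, 3],
             distance = as.integer(all[, 4]), side = all[, 5],
             stringsAsFactors = FALSE)
}

#' Build the reference annotation fixture for the published pairs
#'
#' Encodes every row of \code{\link{published_pairs}} on its own
#' chromosome: a 10 kb lincRNA locus with its protein-coding target
#' placed at exactly the printed boundary gap on the printed side, plus
#' one distractor protein-coding gene per chromosome at a gap beyond the
#' neighborhood window. Target gene ids are suffixed with the row number
#' so repeated target names stay distinct loci.
#'
#' @param distractor_gap boundary gap of each distractor gene in bp
#'   (default 3.2 Mb, outside the 3 Mb window).
#' @return list with \code{annotation} (an
#'   \code{\link{annotation_set}}), \code{pairs} (the reference table
#'   plus fixture ids \code{lincrna_id}, \code{target_id}), and
#'   \code{deg_table} (gene-level table marking every target and
#'   distractor DE in its row's tissue at interval I1).
#' @export
build_published_fixture <- function(distractor_gap = 3.2e6) {
  pairs <- published_pairs()
  n <- nrow(pairs)
  gene_len <- 10000L
  linc_anchor <- 4000000L   # lincRNA start; leaves room for left placements
  rows <- list()
  for (i in seq_len(n)) {
    chrom <- paste0("chr", i)
    l_start <- linc_anchor; l_end <- linc_anchor + gene_len - 1L
    d <- pairs$distance[i]
    if (pairs$side[i] == "right") {
      t_start <- l_end + d; t_end <- t_start + gene_len - 1L
    } else {
      t_end <- l_start - d; t_start <- t_end - gene_len + 1L
    }
    dist_start <- l_end + as.integer(distractor_gap)
    rows[[i]] <- data.frame(
      gene_id = c(pairs$lincrna[i],
                  paste0(pairs$target[i], "_", i),
                  paste0("DISTR_", i)),
      gene_name = c(pairs$lincrna[i], pairs$target[i], paste0("Distr", i)),
      chrom = chrom,
      start = c(l_start, t_start, dist_start),
      end = c(l_end, t_end, dist_start + gene_len - 1L),
      strand = "+",
      biotype = c("lincRNA", "protein_coding", "protein_coding"),
      raw_biotype = c("lincRNA", "protein_coding", "protein_coding"),
      source = "synthetic", stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, rows)
  ann <- annotation_set(feats)
  pairs$lincrna_id <- pairs$lincrna
  pairs$target_id <- paste0(pairs$target, "_", seq_len(n))
  deg <- data.frame(
    feature = c(pairs$target_id, paste0("DISTR_", seq_len(n))),
    tissue = c(pairs$tissue, pairs$tissue),
    interval = "I1", fc = 2, p = 0.01, q = 0.01, de = TRUE,
    stringsAsFactors = FALSE)
  list(annotation = ann, pairs = pairs, deg_table = deg)
}

#' Assemble the evidence table of lincRNA targets
#'
#' One row per retained (ncRNA, target) association with its tissue
#' evidence, distance, side and megabase bin, sorted so each ncRNA's
#' closest target ranks first. Per-tissue distinct-target counts are
#' attached as the \code{"tissue_counts"} attribute.
#'
#' @param assocs neighbor associations annotated by
#'   \code{\link{filter_de_targets}} (columns \code{ncrna},
#'   \code{target}, \code{distance}, \code{side}, \code{bin},
#'   \code{target_de}, \code{evidence}).
#' @param only_de keep only associations whose target is DE (default
#'   TRUE).
#' @return data.frame with columns \code{tissue}, \code{ncrna},
#'   \code{target}, \code{distance}, \code{side}, \code{bin},
#'   \code{relation}.
#' @export
build_evidence_table <- function(assocs, only_de = TRUE) {
  if (!"target_de" %in% names(assocs)) {
    stop("associations must be annotated with filter_de_targets() first")
  }
  a <- if (only_de) assocs[assocs$target_de, , drop = FALSE] else assocs
  if (nrow(a) == 0) {
    out <- data.frame(tissue = character(), ncrna = character(),
                      target = character(), distance = numeric(),
                      side = character(), bin = character(),
                      relation = character(), stringsAsFactors = FALSE)
    attr(out, "tissue_counts") <- integer(0)
    return(out)
  }
  tissues <- lapply(strsplit(a$evidence, ";", fixed = TRUE),
                    function(e) unique(sub(":.*$", "", e[nzchar(e)])))
  idx <- rep(seq_len(nrow(a)), lengths(tissues))
  out <- a[idx, , drop = FALSE]
  out$tissue <- unlist(tissues)
  keep <- c("tissue", "ncrna", "target",
            intersect(c("distance", "side", "bin", "overlap"), names(out)),
            "relation")
  out <- out[, keep, drop = FALSE]
  ord <- if ("distance" %in% names(out)) {
    order(out$tissue, out$ncrna, out$distance, out$target)
  } else {
    order(out$tissue, out$ncrna, out$target)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  counts <- vapply(split(out$target, out$tissue),
                   function(x) length(unique(x)), integer(1))
  attr(out, "tissue_counts") <- counts
  out
}

#' Signed fold-change matrix for ncRNA/target pairs across intervals
#'
#' Rows interleave each ncRNA with its target; columns are the
#' (tissue, interval) contrasts present in the gene-level table. Missing
#' contrasts are filled with NA and flagged in the \code{"missing"}
#' attribute.
#'
#' @param pairs data.frame with columns \code{ncrna}, \code{target}.
#' @param deg_table gene-level contrast table (\code{feature},
#'   \code{tissue}, \code{interval}, \code{fc}).
#' @param tissue optional tissue filter; default uses all tissues in the
#'   table (columns labelled tissue_interval).
#' @return numeric matrix, rows = interleaved ncRNA/target ids.
#' @export
fc_heatmap_matrix <- function(pairs, deg_table, tissue = NULL) {
  genes <- unique(c(pairs$ncrna, pairs$target))
  unknown <- setdiff(genes, deg_table$feature)
  if (length(unknown) > 0) {
    stop("gene(s) absent from the contrast table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  d <- deg_table
  if (!is.null(tissue)) d <- d[d$tissue %in% tissue, , drop = FALSE]
  contrasts <- unique(d[, c("tissue", "interval")])
  contrasts <- contrasts[order(contrasts$tissue, contrasts$interval), ]
  cols <- paste(contrasts$tissue, contrasts$interval, sep = "_")
  row_ids <- as.vector(rbind(pairs$ncrna, pairs$target))
  mat <- matrix(NA_real_, nrow = length(row_ids), ncol = length(cols),
                dimnames = list(row_ids, cols))
  key <- paste(d$feature, d$tissue, d$interval, sep = "\r")
  for (i in seq_along(row_ids)) {
    for (j in seq_len(nrow(contrasts))) {
      hit <- match(paste(row_ids[i], contrasts$tissue[j],
                         contrasts$interval[j], sep = "\r"), key)
      if (!is.na(hit)) mat[i, j] <- d$fc[hit]
    }
  }
  attr(mat, "missing") <- which(is.na(mat), arr.ind = TRUE)
  mat
}

#' Count differentially expressed features per biotype, contrast, source
#'
#' Tabulates DE features per (biotype, tissue, interval, source) over
#' the four canonical biotype groups, with zero cells present. Counts
#' from a secondary annotation source are separate rows, mirroring
#' reports where secondary-reference-only detections are shown in
#' parentheses.
#'
#' @param deg_table gene-level contrast table with a \code{de} flag.
#' @param ann \code{\link{annotation_set}} supplying biotype and source
#'   per feature.
#' @return data.frame with columns \code{biotype}, \code{tissue},
#'   \code{interval}, \code{source}, \code{n}.
#' @export
biotype_count_table <- function(deg_table, ann) {
  f <- ann_features(ann)
  de <- deg_table[deg_table$de, , drop = FALSE]
  de$biotype <- f$biotype[match(de$feature, f$gene_id)]
  de$source <- f$source[match(de$feature, f$gene_id)]
  sources <- attr(ann, "source_order")
  if (is.null(sources)) sources <- unique(f$source)
  grid <- expand.grid(biotype = CANONICAL_BIOTYPES,
                      tissue = unique(deg_table$tissue),
                      interval = sort(unique(deg_table$interval)),
                      source = sources,
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(b, t, i, s) {
    sum(de$biotype == b & de$tissue == t & de$interval == i & de$source == s,
        na.rm = TRUE)
  }, grid$biotype, grid$tissue, grid$interval, grid$source)
  grid[order(grid$biotype, grid$tissue, grid$interval, grid$source), ]
}

#' Count unique DE features per biotype and tissue across intervals
#'
#' Deduplicates DE features by id across intervals within each tissue
#' (e.g. "unique lincRNAs in SN").
#'
#' @param deg_table gene-level contrast table with a \code{de} flag.
#' @param ann \code{\link{annotation_set}}.
#' @return data.frame with columns \code{biotype}, \code{tissue},
#'   \code{n_unique}.
#' @export
unique_de_counts <- function(deg_table, ann) {
  f <- ann_features(ann)
  de <- deg_table[deg_table$de, , drop = FALSE]
  de$biotype <- f$biotype[match(de$feature, f$gene_id)]
  grid <- expand.grid(biotype = CANONICAL_BIOTYPES,
                      tissue = unique(deg_table$tissue),
                      stringsAsFactors = FALSE)
  grid$n_unique <- mapply(function(b, t) {
    length(unique(de$feature[de$biotype == b & de$tissue == t &
                               !is.na(de$biotype)]))
  }, grid$biotype, grid$tissue)
  grid
}
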