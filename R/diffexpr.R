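#' Analysis thresholds
#'
#' The significance and context thresholds used throughout the pipeline.
#' A feature is flagged differentially expressed in a contrast when
#' |FC| > \code{fc_min} (strict), t-test p < \code{p_max} (strict) and
#' BH q < \code{q_max} (strict). The neighborhood window and the network
#' confidence threshold are inclusive at their boundary.
#'
#' @param fc_min minimum linear fold change (exclusive; default 1.5).
#' @param p_max,q_max p-value / BH q-value ceilings (exclusive; default 0.05).
#' @param neighbor_window lincRNA neighborhood half-width in bp
#'   (inclusive; default 3,000,000).
#' @param network_confidence_min minimum interaction-edge confidence
#'   (inclusive; default 0.7).
#' @param var_floor variance floor on the log2 scale for degenerate
#'   zero-variance groups in the t-test (default 1e-8).
#' @return list of class \code{ncx_thresholds}.
#' @export
thresholds <- function(fc_min = 1.5, p_max = 0.05, q_max = 0.05,
                       neighbor_window = 3e6, network_confidence_min = 0.7,
                       var_floor = 1e-8) {
  if (fc_min <= 1) stop("fc_min must be > 1")
  if (p_max <= 0 || p_max >= 1) stop("p_max must lie in (0, 1)")
  if (q_max <= 0 || q_max >= 1) stop("q_max must lie in (0, 1)")
  if (neighbor_window <= 0) stop("neighbor_window must be > 0")
  if (network_confidence_min < 0 || network_confidence_min > 1) {
    stop("network_confidence_min must lie in [0, 1]")
  }
  structure(list(fc_min = fc_min, p_max = p_max, q_max = q_max,
                 neighbor_window = neighbor_window,
                 network_confidence_min = network_confidence_min,
                 var_floor = var_floor),
            class = "ncx_thresholds")
}

#' Log2-transform a strictly positive intensity matrix
#'
#' @param matrix numeric matrix of linear-scale intensities.
#' @param median_center if TRUE, subtract the per-sample (column) median
#'   after the transform so each sample has log2 median 0.
#' @return log2-scale matrix.
#' @export
normalize_log2 <- function(matrix, median_center = FALSE) {
  bad <- which(!(matrix > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(matrix); cn <- colnames(matrix)
    stop("non-positive intensity at [",
         if (is.null(rn)) bad[1, 1] else rn[bad[1, 1]], ", ",
         if (is.null(cn)) bad[1, 2] else cn[bad[1, 2]], "]: ",
         matrix[bad[1, 1], bad[1, 2]])
  }
  out <- log2(matrix)
  if (median_center) {
    out <- sweep(out, 2, apply(out, 2, stats::median))
  }
  out
}

#' Signed linear fold change between two sample groups
#'
#' Computes the ratio of linear-scale group means r =
#' mean(interval)/mean(baseline) and encodes direction in the sign:
#' r when r >= 1, otherwise -1/r, so |FC| >= 1 always.
#'
#' @param group_baseline,group_interval numeric vectors of linear-scale
#'   intensities (non-empty).
#' @return signed linear fold change.
#' @export
signed_fold_change <- function(group_baseline, group_interval) {
  if (length(group_baseline) == 0 || length(group_interval) == 0) {
    stop("both groups must be non-empty")
  }
  mb <- mean(group_baseline)
  if (mb == 0) stop("zero baseline mean")
  r <- mean(group_interval) / mb
  if (r >= 1) r else -1 / r
}

#' Two-sided Welch t-test p-value with a variance floor
#'
#' Unequal-variance t-test on log2 values; each group variance is
#' floored at \code{var_floor} so zero-variance groups (exact ties) give
#' a finite statistic instead of a division by zero. Degrees of freedom
#' follow Welch-Satterthwaite on the floored variances.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @param var_floor variance floor (default 1e-8).
#' @return two-sided p-value.
#' @export
welch_t_pvalue <- function(group_a, group_b, var_floor = 1e-8) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- max(stats::var(group_a), var_floor)
  vb <- max(stats::var(group_b), var_floor)
  sa <- va / na; sb <- vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q-values); order-preserving with respect to
#' the input positions and capped at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Vectorized per-row group means and variances for a column subset.
row_group_stats <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  n <- ncol(sub)
  m <- rowMeans(sub)
  v <- rowSums((sub - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}

#' Time-course differential expression against the day-0 baseline
#'
#' For each tissue, every post-baseline day is contrasted against that
#' tissue's day-0 group: signed fold change on linear-scale group means,
#' two-sided Welch t-test on log2 values (variance floored), and
#' Benjamini-Hochberg adjustment applied across all features within each
#' (tissue, interval) contrast. Days are labelled I1, I2, ... in
#' ascending order.
#'
#' @param matrix strictly positive linear-scale intensity matrix
#'   (features x samples, named columns).
#' @param design data.frame with columns \code{sample}, \code{tissue},
#'   \code{day}, \code{replicate} covering all matrix columns; each
#'   tissue needs a day-0 group.
#' @param thr \code{\link{thresholds}}.
#' @return data.frame with one row per (feature, tissue, interval):
#'   columns \code{feature}, \code{tissue}, \code{interval}, \code{fc},
#'   \code{p}, \code{q}, \code{de}.
#' @export
run_de <- function(matrix, design, thr = thresholds()) {
  stopifnot(inherits(thr, "ncx_thresholds"))
  if (is.null(colnames(matrix))) stop("matrix needs sample column names")
  missing_cols <- setdiff(colnames(matrix), design$sample)
  if (length(missing_cols) > 0) {
    stop("design does not cover matrix column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  design <- design[match(colnames(matrix), design$sample), ]
  log2mat <- normalize_log2(matrix)
  labs <- interval_labels(design$day)
  out <- list()
  for (tis in unique(design$tissue)) {
    base_cols <- design$sample[design$tissue == tis & design$day == 0]
    if (length(base_cols) == 0) {
      stop("tissue ", tis, " has no day-0 baseline group")
    }
    base_lin <- row_group_stats(matrix, base_cols)
    base_log <- row_group_stats(log2mat, base_cols)
    for (day in sort(unique(design$day[design$tissue == tis & design$day != 0]))) {
      int_cols <- design$sample[design$tissue == tis & design$day == day]
      if (length(int_cols) < 2 || length(base_cols) < 2) {
        stop("contrast groups need >= 2 replicates (tissue ", tis,
             ", day ", day, ")")
      }
      int_lin <- row_group_stats(matrix, int_cols)
      int_log <- row_group_stats(log2mat, int_cols)
      if (any(base_lin$mean == 0)) stop("zero baseline mean encountered")
      r <- int_lin$mean / base_lin$mean
      fc <- ifelse(r >= 1, r, -1 / r)
      va <- pmax(int_log$var, thr$var_floor) / int_log$n
      vb <- pmax(base_log$var, thr$var_floor) / base_log$n
      tstat <- (int_log$mean - base_log$mean) / sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (int_log$n - 1) + vb^2 / (base_log$n - 1))
      p <- 2 * stats::pt(-abs(tstat), df)
      q <- bh_adjust(p)
      out[[length(out) + 1]] <- data.frame(
        feature = rownames(matrix), tissue = tis,
        interval = unname(labs[as.character(day)]),
        fc = fc, p = p, q = q,
        de = abs(fc) > thr$fc_min & p < thr$p_max & q < thr$q_max,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Collapse probe-level contrast results to gene level
#'
#' Per (gene, tissue, interval) the probe with the smallest q-value is
#' kept (ties broken by largest |FC|, then lexicographic probe id); the
#' gene inherits that probe's statistics and DE flag. Probes absent from
#' the map are excluded with a warning and reported in the
#' \code{"excluded_probes"} attribute; probes mapping to several genes
#' contribute to each of them and are reported in the
#' \code{"multi_mapped"} attribute.
#'
#' @param results probe-level table from \code{\link{run_de}}.
#' @param probe_map data.frame with columns \code{probe_id},
#'   \code{gene_id} (a probe may appear on several rows).
#' @return gene-level data.frame with columns \code{feature} (gene id),
#'   \code{probe}, \code{tissue}, \code{interval}, \code{fc}, \code{p},
#'   \code{q}, \code{de}.
#' @export
collapse_probes <- function(results, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  unmapped <- setdiff(results$feature, probe_map$probe_id)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " probe(s) missing from probe_map excluded: ",
            paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ..." else "")
  }
  multi <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  merged <- merge(results, probe_map, by.x = "feature", by.y = "probe_id")
  if (nrow(merged) == 0) {
    out <- data.frame(feature = character(), probe = character(),
                      tissue = character(), interval = character(),
                      fc = numeric(), p = numeric(), q = numeric(),
                      de = logical(), stringsAsFactors = FALSE)
    attr(out, "excluded_probes") <- unmapped
    attr(out, "multi_mapped") <- multi
    return(out)
  }
  merged <- merged[order(merged$gene_id, merged$tissue, merged$interval,
                         merged$q, -abs(merged$fc), merged$feature), ]
  key <- paste(merged$gene_id, merged$tissue, merged$interval, sep = "\r")
  best <- merged[!duplicated(key), ]
  out <- data.frame(feature = best$gene_id, probe = best$feature,
                    tissue = best$tissue, interval = best$interval,
                    fc = best$fc, p = best$p, q = best$q, de = best$de,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$feature, out$tissue, out$interval), ]
  rownames(out) <- NULL
  attr(out, "excluded_probes") <- unmapped
  attr(out, "multi_mapped") <- multi
  out
}
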