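# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain loops and closed-form sums only.

# Smith-Waterman local alignment score with affine gaps (Gotoh).
# A gap of length k costs open + k * extend.
oracle_sw_score <- function(q, s, match = 2, mismatch = -3,
                            open = 5, extend = 2) {
  qb <- strsplit(q, "")[[1]]
  sb <- strsplit(s, "")[[1]]
  n <- length(qb); m <- length(sb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      sub <- if (qb[i - 1] == sb[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Boundary gap between two 1-based inclusive intervals (0 = overlap).
oracle_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) s2 - e1 else if (e2 < s1) s1 - e2 else 0
}

# All-pairs lincRNA neighbor scan.
oracle_neighbors <- function(features, lincrna_ids, coding_deg_ids, window) {
  out <- NULL
  for (li in lincrna_ids) {
    l <- features[features$gene_id == li, ]
    for (ti in coding_deg_ids) {
      t <- features[features$gene_id == ti, ]
      if (t$biotype != "protein_coding" || t$chrom != l$chrom || ti == li) next
      gap <- oracle_gap(l$start, l$end, t$start, t$end)
      if (gap > window) next
      side <- if (t$end < l$start) "left" else if (t$start > l$end) "right" else "overlap"
      out <- rbind(out, data.frame(ncrna = li, target = ti, distance = gap,
                                   side = side, stringsAsFactors = FALSE))
    }
  }
  out
}

# Pairwise antisense overlap scan.
oracle_antisense <- function(features, asrna_ids, coding_ids, min_overlap = 1) {
  out <- NULL
  for (ai in asrna_ids) {
    a <- features[features$gene_id == ai, ]
    for (ci in coding_ids) {
      g <- features[features$gene_id == ci, ]
      if (g$biotype != "protein_coding" || ci == ai) next
      if (a$chrom != g$chrom || a$strand == g$strand) next
      ov <- min(a$end, g$end) - max(a$start, g$start) + 1
      if (ov >= min_overlap) {
        out <- rbind(out, data.frame(ncrna = ai, target = ci, overlap = ov,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Step-up BH adjustment applied literally from the definition:
# q_(i) = min_{j >= i} p_(j) * n / j over sorted p, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# Exact upper-tail hypergeometric P(X >= k) by direct summation.
oracle_hyper_upper <- function(k, set_size, query_size, background) {
  xs <- k:min(set_size, query_size)
  if (k <= 0) return(1)
  sum(choose(set_size, xs) * choose(background - set_size, query_size - xs)) /
    choose(background, query_size)
}

# Connected components by breadth-first search over an edge list.
oracle_components <- function(nodes, edges_u, edges_v) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_u)) {
    adj[[edges_u[i]]] <- c(adj[[edges_u[i]]], edges_v[i])
    adj[[edges_v[i]]] <- c(adj[[edges_v[i]]], edges_u[i])
  }
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(-lengths(comps), vapply(comps, `[`, character(1), 1))]
}

# Random gene-level feature table for property tests.
random_features <- function(n, n_chrom = 3, chrom_len = 1e7,
                            biotypes = c("protein_coding", "lincRNA")) {
  start <- sample.int(chrom_len - 5e4, n)
  data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_name = sprintf("g%03d", seq_len(n)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(5e4, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(biotypes, n, replace = TRUE),
    source = "synthetic", stringsAsFactors = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
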