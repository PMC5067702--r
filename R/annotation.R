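#' Canonical biotype groups
#'
#' The four biotype groups the pipeline operates on, in display order,
#' plus the catch-all \code{"other"}.
#' @keywords internal
CANONICAL_BIOTYPES <- c("protein_coding", "lincRNA", "antisense", "pseudogene")

#' Collapse a raw annotation biotype into its canonical group
#'
#' Ensembl GTFs carry many fine-grained biotypes. For contextual target
#' analysis these are consolidated into four groups: every
#' \code{*pseudogene*} variant (processed, unprocessed, transcribed, ...)
#' becomes \code{pseudogene}; intergenic lncRNA labels become
#' \code{lincRNA}; antisense labels become \code{antisense};
#' \code{protein_coding} is kept; everything else maps to \code{other}.
#'
#' @param raw_biotype character vector of raw biotype strings (NA allowed).
#' @return character vector of the same length with values in
#'   \code{protein_coding, lincRNA, antisense, pseudogene, other}.
#' @examples
#' classify_biotype(c("processed_pseudogene", "lincRNA", "miRNA"))
#' @export
classify_biotype <- function(raw_biotype) {
  raw <- as.character(raw_biotype)
  lower <- tolower(raw)
  out <- rep("other", length(raw))
  out[!is.na(lower) & lower == "protein_coding"] <- "protein_coding"
  out[!is.na(lower) & lower %in% c("lincrna", "lncrna, intergenic", "lncrna_intergenic")] <- "lincRNA"
  out[!is.na(lower) & lower %in% c("antisense", "antisense_rna")] <- "antisense"
  out[!is.na(lower) & grepl("pseudogene", lower, fixed = TRUE)] <- "pseudogene"
  out
}

#' Construct an annotation set of gene-level genomic features
#'
#' An \code{AnnotationSet} holds one row per gene locus (id, name,
#' chromosome, 1-based inclusive start/end, strand, canonical biotype,
#' source species) together with a \code{GRanges} interval index used by
#' the overlap queries.
#'
#' @param features data.frame with columns \code{gene_id}, \code{gene_name},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{biotype},
#'   \code{source}. An optional \code{raw_biotype} column is preserved.
#' @return object of class \code{AnnotationSet}.
#' @export
annotation_set <- function(features) {
  required <- c("gene_id", "gene_name", "chrom", "start", "end",
                "strand", "biotype", "source")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("annotation features missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1L)) stop("feature start must be >= 1")
  if (any(features$end < features$start)) stop("feature end must be >= start")
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every feature")
  }
  key <- paste(features$source, features$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- features$gene_id[duplicated(key)]
    stop("duplicate (source, gene_id): ", paste(unique(dup), collapse = ", "))
  }
  rownames(features) <- NULL
  index <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  structure(list(features = features, index = index), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet with", nrow(x$features), "gene-level features\n")
  tab <- table(x$features$source, x$features$biotype)
  print(tab)
  invisible(x)
}

#' Number of features in an annotation set
#' @param x AnnotationSet
#' @export
length.AnnotationSet <- function(x) nrow(x$features)

#' Extract the feature table of an annotation set
#' @param ann AnnotationSet
#' @return data.frame of gene-level features
#' @export
ann_features <- function(ann) {
  stopifnot(inherits(ann, "AnnotationSet"))
  ann$features
}

#' Overlap query against the interval index
#'
#' Returns the features whose interval intersects \code{[start, end]} on
#' \code{chrom} (1-based inclusive, strand-blind).
#'
#' @param ann AnnotationSet
#' @param chrom chromosome label (exact string match)
#' @param start,end query interval, 1-based inclusive
#' @return data.frame subset of the feature table
#' @export
query_overlaps <- function(ann, chrom, start, end) {
  stopifnot(inherits(ann, "AnnotationSet"))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, ann$index, ignore.strand = TRUE)
  ann$features[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# Parse the 9th GTF column into a named character vector.
parse_gtf_attributes <- function(attr_string) {
  parts <- strsplit(attr_string, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
  keys <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  vals <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
                 character(1))
  ok <- !is.na(keys)
  stats::setNames(vals[ok], keys[ok])
}

#' Read a GTF file into a gene-level annotation set
#'
#' Parses a tab-separated GTF (1-based inclusive coordinates). One feature
#' is produced per \code{gene_id}: the explicit \code{gene} record where
#' present, otherwise the min-start/max-end span over that gene's
#' transcript/exon records. The attribute keys \code{gene_id},
#' \code{gene_name} and \code{gene_biotype} (or the newer
#' \code{gene_type}) are honoured; raw biotypes are consolidated with
#' \code{\link{classify_biotype}} and kept in \code{raw_biotype}.
#'
#' @param path GTF file path.
#' @param source source label recorded on every feature
#'   (e.g. \code{"rat"}, \code{"mouse"}, \code{"synthetic"}).
#' @param normalize_chrom if TRUE, strip a leading \code{"chr"} from
#'   chromosome labels; Ensembl GTFs are unprefixed, so the default is
#'   FALSE and labels are compared as exact strings.
#' @return \code{\link{annotation_set}}.
#' @export
read_gtf <- function(path, source = "rat", normalize_chrom = FALSE) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warning("empty GTF: ", path)
    return(annotation_set(data.frame(
      gene_id = character(), gene_name = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      biotype = character(), raw_biotype = character(),
      source = character(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(nf < 9)[1]
    stop("malformed GTF record at line ", line_no[bad],
         ": expected 9 tab-separated fields, got ", nf[bad])
  }
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed GTF record at line ", line_no[i],
           ": non-integer coordinates")
    }
    at <- parse_gtf_attributes(f[9])
    if (!"gene_id" %in% names(at) || !nzchar(at[["gene_id"]])) {
      stop("missing gene_id at line ", line_no[i])
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) {
      stop("malformed GTF record at line ", line_no[i],
           ": strand must be '+' or '-'")
    }
    bio <- if ("gene_biotype" %in% names(at)) at[["gene_biotype"]]
           else if ("gene_type" %in% names(at)) at[["gene_type"]]
           else NA_character_
    list(gene_id = at[["gene_id"]],
         gene_name = if ("gene_name" %in% names(at)) at[["gene_name"]] else at[["gene_id"]],
         chrom = f[1], feature = f[3],
         start = start, end = end, strand = strand, raw_biotype = bio)
  })
  df <- data.frame(
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    gene_name = vapply(recs, `[[`, character(1), "gene_name"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    feature = vapply(recs, `[[`, character(1), "feature"),
    start = vapply(recs, `[[`, integer(1), "start"),
    end = vapply(recs, `[[`, integer(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    raw_biotype = vapply(recs, `[[`, character(1), "raw_biotype"),
    stringsAsFactors = FALSE
  )
  if (normalize_chrom) df$chrom <- sub("^chr", "", df$chrom)
  per_gene <- lapply(split(df, df$gene_id), function(g) {
    gene_row <- g[g$feature == "gene", , drop = FALSE]
    anchor <- if (nrow(gene_row) > 0) gene_row[1, ] else g[1, ]
    bio <- anchor$raw_biotype
    if (is.na(bio)) {
      known <- g$raw_biotype[!is.na(g$raw_biotype)]
      bio <- if (length(known) > 0) known[1] else NA_character_
    }
    data.frame(gene_id = anchor$gene_id, gene_name = anchor$gene_name,
               chrom = anchor$chrom,
               start = min(g$start), end = max(g$end),
               strand = anchor$strand, raw_biotype = bio,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, per_gene)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  genes$biotype <- classify_biotype(genes$raw_biotype)
  genes$source <- source
  annotation_set(genes[, c("gene_id", "gene_name", "chrom", "start", "end",
                           "strand", "biotype", "raw_biotype", "source")])
}

#' Merge two annotation sources with provenance
#'
#' Features are unioned keyed by (source, gene_id), so the same gene name
#' arriving from both a primary (e.g. rat) and a secondary (e.g. mouse)
#' reference stays as two distinct features. Per-biotype counts are kept
#' separately per source, so detections unique to the secondary reference
#' remain countable.
#'
#' @param primary,secondary AnnotationSet objects with distinct source tags.
#' @return merged AnnotationSet; per-source biotype counts via
#'   \code{\link{biotype_source_counts}}.
#' @export
merge_sources <- function(primary, secondary) {
  stopifnot(inherits(primary, "AnnotationSet"), inherits(secondary, "AnnotationSet"))
  cols <- union(names(primary$features), names(secondary$features))
  pf <- primary$features
  sf <- secondary$features
  for (cl in setdiff(cols, names(pf))) pf[[cl]] <- NA_character_
  for (cl in setdiff(cols, names(sf))) sf[[cl]] <- NA_character_
  combined <- rbind(pf[, cols], sf[, cols])
  merged <- annotation_set(combined)   # duplicate (source, id) -> error here
  attr(merged, "source_order") <- c(unique(pf$source), unique(sf$source))
  merged
}

#' Per-source, per-biotype feature counts of an annotation set
#' @param ann AnnotationSet
#' @return data.frame with columns source, biotype, n
#' @export
biotype_source_counts <- function(ann) {
  f <- ann_features(ann)
  src <- attr(ann, "source_order")
  if (is.null(src)) src <- unique(f$source)
  grid <- expand.grid(source = src,
                      biotype = c(CANONICAL_BIOTYPES, "other"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(s, b) sum(f$source == s & f$biotype == b),
                   grid$source, grid$biotype)
  grid
}

#' Write gene-level features as a GTF file
#'
#' Emits one \code{gene} record per feature with \code{gene_id},
#' \code{gene_name} and \code{gene_biotype} attributes (the raw biotype
#' where available, so fine-grained labels like
#' \code{processed_pseudogene} round-trip through the reader's
#' consolidation).
#'
#' @param ann AnnotationSet
#' @param path output file
#' @export
write_gtf <- function(ann, path) {
  f <- ann_features(ann)
  bio <- if ("raw_biotype" %in% names(f)) {
    ifelse(is.na(f$raw_biotype), f$biotype, f$raw_biotype)
  } else f$biotype
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   f$gene_id, f$gene_name, bio)
  lines <- paste(f$chrom, "ncontext", "gene", f$start, f$end, ".",
                 f$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
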