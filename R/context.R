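#' Find protein-coding neighbors of lincRNA loci within a genomic window
#'
#' For each lincRNA, every differentially expressed protein-coding gene
#' on the same chromosome whose boundary gap to the lincRNA is at most
#' \code{window} bp (inclusive) is reported as a putative cis target.
#' The gap is measured between closest feature boundaries
#' (downstream.start - upstream.end; 0 when the intervals overlap,
#' 1 when adjacent). The side is \code{left} when the target lies
#' entirely before the lincRNA start, \code{right} when entirely after
#' its end, \code{overlap} otherwise, and each association carries a
#' megabase bin label (\code{<=1MB}, \code{<=2MB}, \code{<=3MB} computed
#' against thirds of the window). Results are sorted by (lincRNA,
#' distance), so the closest target ranks first.
#'
#' @param ann \code{\link{annotation_set}}.
#' @param lincrna_ids lincRNA gene ids present in \code{ann}.
#' @param coding_deg_ids differentially expressed protein-coding gene ids
#'   (the candidate targets).
#' @param window half-width of the neighborhood in bp (> 0; default 3 Mb).
#' @return data.frame with columns \code{ncrna}, \code{target},
#'   \code{relation} (= "neighbor"), \code{distance}, \code{side},
#'   \code{bin}.
#' @export
find_lincrna_neighbors <- function(ann, lincrna_ids, coding_deg_ids,
                                   window = 3e6) {
  if (window <= 0) stop("window must be > 0")
  f <- ann_features(ann)
  missing_ids <- setdiff(c(lincrna_ids, coding_deg_ids), f$gene_id)
  if (length(missing_ids) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  linc <- f[f$gene_id %in% lincrna_ids, , drop = FALSE]
  cand <- f[f$gene_id %in% coding_deg_ids & f$biotype == "protein_coding", ,
            drop = FALSE]
  empty <- data.frame(ncrna = character(), target = character(),
                      relation = character(), distance = numeric(),
                      side = character(), bin = character(),
                      stringsAsFactors = FALSE)
  if (nrow(linc) == 0 || nrow(cand) == 0) return(empty)
  # indexed route: widen each lincRNA by the window and intersect
  lg <- GenomicRanges::GRanges(
    linc$chrom,
    IRanges::IRanges(pmax(1, linc$start - window), linc$end + window))
  cg <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start, cand$end))
  hits <- GenomicRanges::findOverlaps(lg, cg, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  li <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  gap <- boundary_gap(linc$start[li], linc$end[li],
                      cand$start[ci], cand$end[ci])
  # widening by `window` admits gaps up to window + 1 at the edge
  keep <- gap <= window & linc$gene_id[li] != cand$gene_id[ci]
  li <- li[keep]; ci <- ci[keep]; gap <- gap[keep]
  if (length(li) == 0) return(empty)
  side <- ifelse(cand$end[ci] < linc$start[li], "left",
                 ifelse(cand$start[ci] > linc$end[li], "right", "overlap"))
  third <- window / 3
  bin <- ifelse(gap <= third, "<=1MB", ifelse(gap <= 2 * third, "<=2MB", "<=3MB"))
  out <- data.frame(ncrna = linc$gene_id[li], target = cand$gene_id[ci],
                    relation = "neighbor", distance = as.numeric(gap),
                    side = side, bin = bin, stringsAsFactors = FALSE)
  out <- out[order(out$ncrna, out$distance, out$target), ]
  rownames(out) <- NULL
  out
}

#' Find opposite-strand overlapping protein-coding targets of antisense RNAs
#'
#' An association (asRNA, coding gene) is emitted iff both lie on the
#' same chromosome, on opposite strands, and their intervals overlap by
#' at least \code{min_overlap} bp (1-based inclusive overlap length
#' recorded).
#'
#' @param ann \code{\link{annotation_set}}.
#' @param asrna_ids antisense RNA gene ids.
#' @param coding_ids candidate protein-coding gene ids.
#' @param min_overlap minimum genomic overlap in bp (default 1).
#' @return data.frame with columns \code{ncrna}, \code{target},
#'   \code{relation} (= "antisense"), \code{overlap}.
#' @export
find_antisense_targets <- function(ann, asrna_ids, coding_ids,
                                   min_overlap = 1) {
  f <- ann_features(ann)
  missing_ids <- setdiff(c(asrna_ids, coding_ids), f$gene_id)
  if (length(missing_ids) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  a <- f[f$gene_id %in% asrna_ids, , drop = FALSE]
  cand <- f[f$gene_id %in% coding_ids & f$biotype == "protein_coding", ,
            drop = FALSE]
  empty <- data.frame(ncrna = character(), target = character(),
                      relation = character(), overlap = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(cand) == 0) return(empty)
  ag <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  cg <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$start, cand$end))
  hits <- GenomicRanges::findOverlaps(ag, cg, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  ai <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  keep <- a$strand[ai] != cand$strand[ci] & a$gene_id[ai] != cand$gene_id[ci]
  ai <- ai[keep]; ci <- ci[keep]
  if (length(ai) == 0) return(empty)
  ov <- pmin(a$end[ai], cand$end[ci]) - pmax(a$start[ai], cand$start[ci]) + 1
  out <- data.frame(ncrna = a$gene_id[ai], target = cand$gene_id[ci],
                    relation = "antisense", overlap = as.numeric(ov),
                    stringsAsFactors = FALSE)
  out <- out[out$overlap >= min_overlap, ]
  out <- out[order(out$ncrna, -out$overlap, out$target), ]
  rownames(out) <- NULL
  out
}

# BLASTN-like scoring scheme shared by local_align / assign_parental_genes.
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
}

validate_dna <- function(x, label) {
  x <- toupper(as.character(x))
  if (nchar(x) == 0) stop(label, " sequence is empty")
  if (grepl("[^ACGTN]", x)) {
    stop(label, " sequence contains non-ACGTN symbol(s)")
  }
  x
}

ncx_substitution_matrix <- function(scoring) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- scoring$match
  # N never rewards a match
  m["N", ] <- scoring$mismatch; m[, "N"] <- scoring$mismatch
  m
}

#' Local (Smith-Waterman) alignment of two nucleotide sequences
#'
#' Affine-gap local alignment with BLASTN-like defaults: match +2,
#' mismatch -3, gap open 5, gap extend 2 (a gap of length k costs
#' open + k * extend). Returns the best local score (0 when no positive-
#' scoring block exists), the identity fraction over aligned columns and
#' the alignment length.
#'
#' @param query,subject nucleotide sequences (character or
#'   \code{DNAString}); ACGTN alphabet.
#' @param scoring list with elements \code{match}, \code{mismatch},
#'   \code{gap_open}, \code{gap_extend}.
#' @return one-row data.frame: \code{score}, \code{identity} (NA when
#'   there is no positive-scoring hit), \code{length}.
#' @export
local_align <- function(query, subject, scoring = default_scoring()) {
  q <- validate_dna(query, "query")
  s <- validate_dna(subject, "subject")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = ncx_substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  score <- BiocGenerics::score(al)
  if (score <= 0) {
    return(data.frame(score = 0, identity = NA_real_, length = 0L,
                      stringsAsFactors = FALSE))
  }
  len <- Biostrings::nchar(al)
  data.frame(score = score,
             identity = Biostrings::nmatch(al) / len,
             length = len, stringsAsFactors = FALSE)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore); percent identity is converted to a fraction and the
#' bitscore is used as the hit score.
#'
#' @param path file path.
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{identity}, \code{length}, \code{score}.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), length = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("malformed BLAST tabular line ", bad, ": expected 12 columns, got ",
         nf[bad])
  }
  pident <- as.numeric(vapply(fields, `[`, character(1), 3))
  len <- as.integer(vapply(fields, `[`, character(1), 4))
  bits <- as.numeric(vapply(fields, `[`, character(1), 12))
  if (any(is.na(pident)) || any(is.na(len)) || any(is.na(bits))) {
    bad <- which(is.na(pident) | is.na(len) | is.na(bits))[1]
    stop("malformed BLAST tabular line ", bad, ": non-numeric field")
  }
  data.frame(query = vapply(fields, `[`, character(1), 1),
             subject = vapply(fields, `[`, character(1), 2),
             identity = pident / 100, length = len, score = bits,
             stringsAsFactors = FALSE)
}

#' Assign parental genes to pseudogenes by best unique alignment hit
#'
#' Each pseudogene is aligned against every candidate coding sequence
#' (or pre-computed hits are used); candidates below \code{min_score} or
#' \code{min_identity} are discarded, the remainder are ranked by score
#' (ties: identity, then lexicographic subject id) and only the top hit
#' is kept — at most one parent per pseudogene. When the top two hits
#' across different subjects tie on both score and identity, the
#' pseudogene is marked ambiguous and excluded from the unique list
#' (reported in the \code{"ambiguous"} attribute) unless
#' \code{ambiguous = "first"}, which keeps the lexicographically first
#' subject. Pseudogenes with no retained hit are reported in the
#' \code{"unassigned"} attribute.
#'
#' @param pseudo_seqs named \code{DNAStringSet} (or named character) of
#'   pseudogene sequences; ignored when \code{hits} is supplied.
#' @param coding_seqs named \code{DNAStringSet} of candidate parents.
#' @param hits optional pre-computed hit table
#'   (\code{\link{read_blast_tab}} layout).
#' @param min_score minimum alignment score (default 50).
#' @param min_identity minimum identity fraction (default 0.7).
#' @param ambiguous \code{"exclude"} (default) or \code{"first"}.
#' @param scoring scoring scheme for the built-in alignment.
#' @return data.frame with columns \code{ncrna}, \code{target},
#'   \code{relation} (= "parental"), \code{score}, \code{identity},
#'   \code{length}; attributes \code{"ambiguous"} (data.frame) and
#'   \code{"unassigned"} (character).
#' @export
assign_parental_genes <- function(pseudo_seqs = NULL, coding_seqs = NULL,
                                  hits = NULL, min_score = 50,
                                  min_identity = 0.7,
                                  ambiguous = c("exclude", "first"),
                                  scoring = default_scoring()) {
  ambiguous <- match.arg(ambiguous)
  if (is.null(hits)) {
    if (is.null(pseudo_seqs) || is.null(coding_seqs)) {
      stop("either hits or both pseudo_seqs and coding_seqs are required")
    }
    pseudo_seqs <- Biostrings::DNAStringSet(pseudo_seqs)
    coding_seqs <- Biostrings::DNAStringSet(coding_seqs)
    if (is.null(names(pseudo_seqs)) || is.null(names(coding_seqs))) {
      stop("sequences must be named")
    }
    submat <- ncx_substitution_matrix(scoring)
    rows <- list()
    for (sj in names(coding_seqs)) {
      als <- Biostrings::pairwiseAlignment(
        pseudo_seqs, coding_seqs[[sj]], type = "local",
        substitutionMatrix = submat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      len <- Biostrings::nchar(als)
      rows[[sj]] <- data.frame(
        query = names(pseudo_seqs), subject = sj,
        identity = Biostrings::nmatch(als) / pmax(len, 1L),
        length = len, score = BiocGenerics::score(als),
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    queries <- names(pseudo_seqs)
  } else {
    queries <- unique(hits$query)
  }
  hits <- hits[hits$score >= min_score & hits$identity >= min_identity &
                 hits$score > 0, , drop = FALSE]
  assigned <- list(); amb <- list()
  for (qy in queries) {
    h <- hits[hits$query == qy, , drop = FALSE]
    if (nrow(h) == 0) next
    h <- h[order(-h$score, -h$identity, h$subject), , drop = FALSE]
    if (nrow(h) >= 2 && h$score[1] == h$score[2] &&
        h$identity[1] == h$identity[2] && h$subject[1] != h$subject[2]) {
      if (ambiguous == "exclude") {
        amb[[qy]] <- h[1:2, ]
        next
      }
    }
    assigned[[qy]] <- h[1, ]
  }
  to_assoc <- function(h) {
    data.frame(ncrna = h$query, target = h$subject, relation = "parental",
               score = h$score, identity = h$identity, length = h$length,
               stringsAsFactors = FALSE)
  }
  out <- if (length(assigned) > 0) {
    do.call(rbind, lapply(assigned, to_assoc))
  } else {
    data.frame(ncrna = character(), target = character(),
               relation = character(), score = numeric(),
               identity = numeric(), length = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "ambiguous") <- if (length(amb) > 0) do.call(rbind, amb) else NULL
  attr(out, "unassigned") <- setdiff(queries, c(names(assigned), names(amb)))
  out
}

#' Intersect target associations with gene-level differential expression
#'
#' Annotates each association with whether its target is differentially
#' expressed in any (tissue, interval) contrast and with the evidence
#' list of those contrasts (collapsed as "tissue:interval" strings).
#'
#' @param assocs association data.frame (column \code{target}).
#' @param gene_deg_table gene-level table from
#'   \code{\link{collapse_probes}} or \code{\link{run_de}}.
#' @param only_de if TRUE, return only associations whose target is DE.
#' @return input data.frame plus columns \code{target_de} (logical) and
#'   \code{evidence} (character, ";"-separated contrasts).
#' @export
filter_de_targets <- function(assocs, gene_deg_table, only_de = FALSE) {
  if (nrow(assocs) == 0) {
    assocs$target_de <- logical(0)
    assocs$evidence <- character(0)
    return(assocs)
  }
  de_rows <- gene_deg_table[gene_deg_table$de, , drop = FALSE]
  ev_by_gene <- split(paste(de_rows$tissue, de_rows$interval, sep = ":"),
                      de_rows$feature)
  ev <- lapply(assocs$target, function(g) {
    e <- ev_by_gene[[g]]
    if (is.null(e)) character(0) else sort(unique(e))
  })
  assocs$target_de <- lengths(ev) > 0
  assocs$evidence <- vapply(ev, paste, character(1), collapse = ";")
  if (only_de) assocs <- assocs[assocs$target_de, , drop = FALSE]
  rownames(assocs) <- NULL
  assocs
}
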