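# Shared low-level helpers.

# Gap between the closest boundaries of two 1-based inclusive intervals
# on the same chromosome: 0 when they overlap, 1 when adjacent
# (end1 + 1 == start2), i.e. downstream.start - upstream.end.
boundary_gap <- function(start1, end1, start2, end2) {
  ifelse(end1 < start2, start2 - end1,
         ifelse(end2 < start1, start1 - end2, 0L))
}

# Interval label for a post-baseline day: days sorted ascending map to
# I1, I2, ... within a design.
interval_labels <- function(days) {
  nz <- sort(unique(days[days != 0]))
  stats::setNames(paste0("I", seq_along(nz)), as.character(nz))
}

# Deterministic sprintf-style id maker: prefix + zero-padded index.
make_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%s%04d", prefix, seq_len(n))
}
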