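# Shared toy models and the independent geometric oracle used to verify the
# event-taxonomy classifier.

# a deterministic plus-strand toy gene with explicit exon layout
toy_gene <- function(n_exons = 3L, exon_len = 120L, intron_len = 300L,
                     strand = "+", offset = 1000L, with_seq = FALSE,
                     seed = 99L) {
  if (with_seq) {
    return(make_gene_model(exon_lengths = rep(exon_len, n_exons),
                           intron_lengths = rep(intron_len, n_exons - 1L),
                           seed = seed, strand = strand, offset = offset,
                           gene = "TOY"))
  }
  starts <- offset + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  ex <- tibble::tibble(start = starts, end = starts + exon_len)
  if (strand == "-") ex <- ex[rev(seq_len(n_exons)), ]
  gene_model("TOY", "chrT", strand, ex)
}

# make a junction tibble in SJ coordinates
jt <- function(model, starts, ends, reads = 50L, sample_id = "s1") {
  tibble::tibble(chrom = model$chrom, intron_start = as.integer(starts),
                 intron_end = as.integer(ends), strand = model$strand,
                 unique_reads = as.integer(rep_len(reads, length(starts))),
                 sample_id = sample_id)
}

# ---- independent oracle -----------------------------------------------------
# Classifies a junction set by pure interval arithmetic against the canonical
# transcript: compute the removed genomic region(s), derive which exonic
# sequence is excluded and which intronic sequence stays included, and apply
# the taxonomy definitions directly. Shares no code with the classifier's
# end-context case analysis.
oracle_classify <- function(model, starts, ends, max_cryptic_exon = 1000L) {
  stopifnot(model$strand == "+")  # oracle runs on plus-strand toys
  ex <- model$exons[order(model$exons$start), ]
  n <- nrow(ex)
  ex1 <- tibble::tibble(lo = ex$start + 1L, hi = ex$end)      # 1-based
  introns <- tibble::tibble(lo = ex$end[-n] + 1L, hi = ex$start[-1L])
  R <- tibble::tibble(lo = as.integer(starts), hi = as.integer(ends))
  span <- c(min(ex1$lo), max(ex1$hi))
  if (any(R$lo < span[1] | R$hi > span[2])) return("OUTSIDE")

  ov_len <- function(alo, ahi, blo, bhi) pmax(0L, pmin(ahi, bhi) - pmax(alo, blo) + 1L)
  # exon exclusion
  exc <- vapply(seq_len(n), function(k) {
    sum(ov_len(ex1$lo[k], ex1$hi[k], R$lo, R$hi))
  }, integer(1L))
  full_skip <- exc == (ex1$hi - ex1$lo + 1L)
  part_skip <- exc > 0L & !full_skip
  # intronic inclusion: kept segments of introns overlapped by R
  kept_segments <- list()
  for (k in seq_len(n - 1L)) {
    o <- sum(ov_len(introns$lo[k], introns$hi[k], R$lo, R$hi))
    if (o == 0L) next
    pos <- introns$lo[k]:introns$hi[k]
    removed <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(R))) {
      removed[pos >= R$lo[r] & pos <= R$hi[r]] <- TRUE
    }
    if (any(!removed)) {
      runs <- rle(removed)
      idx_end <- cumsum(runs$lengths)
      idx_start <- idx_end - runs$lengths + 1L
      for (j in which(!runs$values)) {
        kept_segments[[length(kept_segments) + 1L]] <- list(
          intron = k,
          lo = pos[idx_start[j]], hi = pos[idx_end[j]],
          at_left = idx_start[j] == 1L, at_right = idx_end[j] == length(pos))
      }
    }
  }
  n_inc <- length(kept_segments)
  if (n_inc > 0L) {
    if (any(full_skip) || any(part_skip) || n_inc > 1L) return("UNCLASSIFIED")
    seg <- kept_segments[[1L]]
    if (seg$at_left != seg$at_right && nrow(R) == 1L) return("IP")
    if (!seg$at_left && !seg$at_right && nrow(R) == 2L &&
        (seg$hi - seg$lo + 1L) <= max_cryptic_exon) return("IC")
    return("UNCLASSIFIED")
  }
  if (any(full_skip) && any(part_skip)) return("ES")
  if (any(full_skip)) return("ESF")
  if (any(part_skip)) return("ESP")
  "CANONICAL"
}

# enumerate representative junction-end placements on a toy gene:
# canonical donors/acceptors, exon-internal and intron-internal positions
enumerate_junction_ends <- function(model) {
  ex <- model$exons[order(model$exons$start), ]
  n <- nrow(ex)
  donors <- c(ex$end[-n] + 1L,                    # canonical donor per intron
              ex$start + 40L,                     # exon-internal
              ex$end[-n] + 15L, ex$end[-n] + 60L) # intron-internal
  acceptors <- c(ex$start[-1L],                   # canonical acceptor
                 ex$end - 40L,                    # exon-internal
                 ex$start[-1L] - 15L, ex$start[-1L] - 60L)
  list(donors = sort(unique(donors)), acceptors = sort(unique(acceptors)))
}
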