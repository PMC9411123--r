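#' Construct a gene model for one canonical isoform
#'
#' A `gene_model` holds the exon/intron structure of a single canonical
#' isoform of one panel gene, plus (optionally) the genomic sequence of its
#' span in transcript orientation. All genomic intervals are stored 0-based,
#' half-open; exons are kept in transcription order (genomically descending
#' for minus-strand genes).
#'
#' @param gene Gene symbol, e.g. `"APC"`.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (0-based half-open
#'   genomic intervals) in transcription order. Exons must not overlap and
#'   every intron must be at least 1 nt long.
#' @param cds_start,cds_end Genomic 0-based coordinates of the first and last
#'   coding base *in transcription order*. Default: the whole transcript is
#'   coding.
#' @param isoform_id Canonical isoform identifier (RefSeq-style label).
#' @param seq Optional [Biostrings::DNAString] (or character) covering the
#'   gene span in transcript orientation, starting at the first base of the
#'   first exon.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, exons,
                       cds_start = NULL, cds_end = NULL,
                       isoform_id = paste0(gene, ".canonical"), seq = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  strand <- match.arg(strand, c("+", "-"))
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) stop("gene model needs at least one exon")
  if (any(exons$end <= exons$start)) stop("exons must have positive length")
  if (nrow(exons) > 1L) {
    if (strand == "+") {
      gaps <- exons$start[-1L] - exons$end[-nrow(exons)]
    } else {
      gaps <- exons$start[-nrow(exons)] - exons$end[-1L]
    }
    if (any(gaps < 1L)) {
      stop("exons must be non-overlapping, in transcription order, with introns >= 1 nt")
    }
  }
  if (is.null(cds_start)) {
    cds_start <- if (strand == "+") exons$start[1L] else exons$end[1L] - 1L
  }
  if (is.null(cds_end)) {
    n <- nrow(exons)
    cds_end <- if (strand == "+") exons$end[n] - 1L else exons$start[n]
  }
  if (!is.null(seq)) seq <- Biostrings::DNAString(as.character(seq))
  m <- structure(
    list(gene = gene, chrom = chrom, strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         isoform_id = isoform_id, seq = seq),
    class = "gene_model"
  )
  nm <- norm_model(m)
  ex0 <- pos_norm1(m, c(m$cds_start, m$cds_end) + 1L)
  if (!all(vapply(ex0, function(p) any(p > nm$exons$start & p <= nm$exons$end), TRUE))) {
    stop("cds_start/cds_end must fall within exonic sequence")
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s strand, %d exon(s), span %s:%d-%d\n",
              x$gene, x$isoform_id, x$strand, nrow(x$exons), x$chrom,
              min(x$exons$start) + 1L, max(x$exons$end)))
  cat(sprintf("  transcript %d nt, coding %d nt%s\n",
              sum(x$exons$end - x$exons$start), coding_length(x),
              if (is.null(x$seq)) "" else sprintf(", sequence attached (%d nt)", length(x$seq))))
  invisible(x)
}

#' @export
n_exons <- function(model) nrow(model$exons)

#' Exon and intron lengths of a gene model
#' @param model A [gene_model()].
#' @return Integer vector of lengths in transcription order.
#' @export
exon_lengths <- function(model) as.integer(model$exons$end - model$exons$start)

#' @rdname exon_lengths
#' @export
intron_lengths <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(integer(0))
  if (model$strand == "+") as.integer(ex$start[-1L] - ex$end[-n])
  else as.integer(ex$start[-n] - ex$end[-1L])
}

coding_length <- function(model) {
  nm <- norm_model(model)
  as.integer(nm$cds_tx_end - nm$cds_tx_start + 1L)
}

# ---- normalized (transcript-oriented, plus-strand) frame --------------------
#
# All event / PSI / mechanism logic runs in a reflected coordinate frame in
# which the transcript reads left to right. For plus-strand genes this is the
# identity; for minus-strand genes positions are reflected within the gene
# span so exon order and sequence orientation match transcription.

norm_model <- function(model) {
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  ex <- model$exons
  if (model$strand == "-") {
    ex <- tibble::tibble(start = span_lo + span_hi - model$exons$end,
                         end   = span_lo + span_hi - model$exons$start)
  }
  n <- nrow(ex)
  len <- ex$end - ex$start
  tx_start <- cumsum(c(0L, len[-n])) + 1L
  cds1 <- if (model$strand == "+") model$cds_start + 1L else span_lo + span_hi - model$cds_start
  cds2 <- if (model$strand == "+") model$cds_end + 1L else span_lo + span_hi - model$cds_end
  nm <- list(exons = ex, tx_start = as.integer(tx_start), exon_len = as.integer(len),
             span_lo = span_lo, span_hi = span_hi, n = n, seq = model$seq,
             chrom = model$chrom, gene = model$gene)
  nm$cds_tx_start <- tx_of_norm(nm, cds1)
  nm$cds_tx_end <- tx_of_norm(nm, cds2)
  nm
}

# reflect original 1-based genomic positions into the normalized frame (and
# back -- the reflection is an involution)
pos_norm1 <- function(model, pos1) {
  if (model$strand == "+") return(as.integer(pos1))
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  as.integer(span_lo + 1L + span_hi - pos1)
}

# normalized 1-based inclusive interval from original [a, b]
interval_norm1 <- function(model, a, b) {
  if (model$strand == "+") return(list(a = as.integer(a), b = as.integer(b)))
  list(a = pos_norm1(model, b), b = pos_norm1(model, a))
}

# transcript coordinate (1..tx_len) of an exonic normalized position; NA if
# intronic or outside
tx_of_norm <- function(nm, p) {
  out <- rep(NA_integer_, length(p))
  for (i in seq_len(nm$n)) {
    hit <- !is.na(p) & p > nm$exons$start[i] & p <= nm$exons$end[i]
    out[hit] <- nm$tx_start[i] + (p[hit] - nm$exons$start[i]) - 1L
  }
  out
}

norm_of_tx <- function(nm, t) {
  out <- rep(NA_integer_, length(t))
  for (i in seq_len(nm$n)) {
    hit <- !is.na(t) & t >= nm$tx_start[i] & t < nm$tx_start[i] + nm$exon_len[i]
    out[hit] <- nm$exons$start[i] + (t[hit] - nm$tx_start[i]) + 1L
  }
  as.integer(out)
}

# exon index (transcription order) containing a normalized position, NA if not
# exonic
exon_index_norm <- function(nm, p) {
  out <- rep(NA_integer_, length(p))
  for (i in seq_len(nm$n)) {
    hit <- !is.na(p) & p > nm$exons$start[i] & p <= nm$exons$end[i]
    out[hit] <- i
  }
  out
}

# intron index i (between transcription exons i and i+1) containing a
# normalized position, NA otherwise
intron_index_norm <- function(nm, p) {
  out <- rep(NA_integer_, length(p))
  if (nm$n < 2L) return(out)
  for (i in seq_len(nm$n - 1L)) {
    lo <- nm$exons$end[i]        # first intronic base is lo + 1 (1-based)
    hi <- nm$exons$start[i + 1L] # last intronic base (1-based)
    hit <- !is.na(p) & p > lo & p <= hi
    out[hit] <- i
  }
  out
}
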