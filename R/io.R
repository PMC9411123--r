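#' Read a splice-junction table
#'
#' Accepts either the 5-column dialect (`chrom`, `intron_start`,
#' `intron_end`, `strand`, `unique_reads`; 1-based inclusive intron
#' coordinates) or a full 9-column STAR `SJ.out.tab` file, from which columns
#' 1-4 and 7 are taken (STAR strand codes 0/1/2 become `*`/`+`/`-`).
#'
#' @param path Path to a TSV file (no header).
#' @param sample_id Sample label attached to every row.
#' @return A junction tibble.
#' @export
read_junction_table <- function(path, sample_id) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) >= 9L) {
    out <- tibble::tibble(
      chrom = as.character(x[[1L]]),
      intron_start = as.integer(x[[2L]]),
      intron_end = as.integer(x[[3L]]),
      strand = c("*", "+", "-")[as.integer(x[[4L]]) + 1L],
      unique_reads = as.integer(x[[7L]])
    )
  } else if (ncol(x) == 5L) {
    out <- tibble::tibble(
      chrom = as.character(x[[1L]]),
      intron_start = as.integer(x[[2L]]),
      intron_end = as.integer(x[[3L]]),
      strand = as.character(x[[4L]]),
      unique_reads = as.integer(x[[5L]])
    )
  } else {
    stop("junction table must have 5 or >=9 columns: ", path)
  }
  if (any(out$intron_start > out$intron_end)) {
    stop("malformed junction record (start > end) in ", path)
  }
  out$sample_id <- sample_id
  out
}

#' @rdname read_junction_table
#' @param junctions Junction tibble to write (5-column dialect).
#' @export
write_junction_table <- function(junctions, path) {
  readr::write_tsv(
    junctions[, c("chrom", "intron_start", "intron_end", "strand", "unique_reads")],
    path, col_names = FALSE)
  invisible(path)
}

#' Read and write sample manifests
#'
#' A manifest maps `sample_id` to a junction-table file path (TSV, with
#' header).
#'
#' @param path Manifest path.
#' @return A tibble with `sample_id` and `file`.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' @rdname read_manifest
#' @param manifest Tibble with `sample_id`, `file`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("sample_id", "file")], path)
  invisible(path)
}

#' Load all junction tables named by a manifest
#'
#' @param manifest Manifest tibble ([read_manifest()]).
#' @param base_dir Directory that relative file paths are resolved against.
#' @return One stacked junction tibble with `sample_id`.
#' @export
read_junctions_from_manifest <- function(manifest, base_dir = ".") {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    f <- manifest$file[i]
    if (!file.exists(f)) f <- file.path(base_dir, manifest$file[i])
    if (!file.exists(f)) stop("junction table not found: ", manifest$file[i])
    read_junction_table(f, manifest$sample_id[i])
  })
}

#' Write the gene span sequence as FASTA
#'
#' The record covers the gene span in transcript orientation; the header
#' carries the gene, span and strand.
#'
#' @param model A [gene_model()] with sequence attached.
#' @param path Output path.
#' @export
write_gene_fasta <- function(model, path) {
  if (is.null(model$seq)) stop("gene model carries no sequence")
  s <- Biostrings::DNAStringSet(model$seq)
  names(s) <- sprintf("%s|%s:%d-%d|%s", model$gene, model$chrom,
                      min(model$exons$start) + 1L, max(model$exons$end),
                      model$strand)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read / write gene models as BED12
#'
#' BED12 blocks are the exons; thickStart/thickEnd delimit the CDS. One
#' canonical isoform per gene is enforced on read.
#'
#' @param path BED12 file path.
#' @return A list of [gene_model()] objects, named by gene.
#' @export
read_gene_model_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (anyDuplicated(gr$name)) stop("one canonical isoform per gene is enforced")
  out <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    strand <- as.character(BiocGenerics::strand(g))
    if (!strand %in% c("+", "-")) stop("BED12 records must be stranded")
    bl <- g$blocks[[1L]]
    starts <- GenomicRanges::start(g) - 1L + BiocGenerics::start(bl) - 1L
    ends <- GenomicRanges::start(g) - 1L + BiocGenerics::end(bl)
    ex <- tibble::tibble(start = starts, end = ends)
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    thick <- g$thick
    cds_lo <- BiocGenerics::start(thick) - 1L
    cds_hi <- BiocGenerics::end(thick) - 1L
    gene_model(
      gene = sub("\\|.*$", "", g$name), chrom = as.character(GenomicRanges::seqnames(g)),
      strand = strand, exons = ex,
      cds_start = if (strand == "+") cds_lo else cds_hi,
      cds_end = if (strand == "+") cds_hi else cds_lo,
      isoform_id = sub("^.*\\|", "", g$name)
    )
  })
  names(out) <- vapply(out, function(m) m$gene, character(1L))
  out
}

#' @rdname read_gene_model_bed12
#' @param models A list of (or a single) [gene_model()].
#' @export
write_gene_model_bed12 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  grl <- lapply(models, function(m) {
    ex <- m$exons[order(m$exons$start), ]
    span_lo <- min(ex$start)
    cds <- sort(c(m$cds_start, m$cds_end))
    gr <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(start = span_lo + 1L, end = max(ex$end)),
      strand = m$strand)
    gr$name <- paste0(m$gene, "|", m$isoform_id)
    gr$score <- 0L
    gr$thick <- IRanges::IRanges(start = cds[1L] + 1L, end = cds[2L] + 1L)
    gr$blocks <- IRanges::IRangesList(
      IRanges::IRanges(start = ex$start - span_lo + 1L, end = ex$end - span_lo))
    gr
  })
  rtracklayer::export(do.call(c, unname(grl)), path, format = "bed")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Assembles one canonical isoform per gene from `exon` and `CDS` features
#' (grouped by `transcript_id`).
#'
#' @param path GTF file path.
#' @return A list of [gene_model()] objects, named by gene.
#' @export
read_gene_model_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  txs <- unique(ex$transcript_id)
  genes <- vapply(txs, function(tx) unique(ex$gene_id[ex$transcript_id == tx])[1L],
                  character(1L))
  if (anyDuplicated(genes)) stop("one canonical isoform per gene is enforced")
  out <- lapply(txs, function(tx) {
    e <- ex[ex$transcript_id == tx]
    strand <- as.character(BiocGenerics::strand(e))[1L]
    tab <- tibble::tibble(start = GenomicRanges::start(e) - 1L,
                          end = GenomicRanges::end(e))
    tab <- tab[order(tab$start, decreasing = strand == "-"), ]
    k <- cds[cds$transcript_id == tx]
    cds_lo <- if (length(k)) min(GenomicRanges::start(k)) - 1L else NULL
    cds_hi <- if (length(k)) max(GenomicRanges::end(k)) - 1L else NULL
    gene_model(
      gene = unique(e$gene_id)[1L],
      chrom = as.character(GenomicRanges::seqnames(e))[1L],
      strand = strand, exons = tab,
      cds_start = if (is.null(cds_lo)) NULL else if (strand == "+") cds_lo else cds_hi,
      cds_end = if (is.null(cds_hi)) NULL else if (strand == "+") cds_hi else cds_lo,
      isoform_id = tx)
  })
  names(out) <- vapply(out, function(m) m$gene, character(1L))
  out
}
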