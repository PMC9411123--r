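#' Parse HGVS-style cDNA positions with intronic offsets
#'
#' Parses strings of the form `c.<pos>`, `c.<pos>+<k>`, `c.<pos>-<k>` with an
#' optional second position (`_` ranges, as printed for multi-nucleotide
#' deletions) and an optional allele suffix (`C>T`, `del2827`, `dup`, `insACGT`).
#' Only the coding-coordinate dialect used for splicing variants is supported;
#' protein notation, inversions and complex alleles are out of scope.
#'
#' @param x Character vector of cDNA position strings.
#' @return A tibble with one row per input: `input`, `coding_pos`,
#'   `intron_offset`, `coding_pos2`, `intron_offset2` (NA unless a range),
#'   `suffix` (allele part, `""` if absent) and `is_range`.
#' @examples
#' parse_cdna(c("c.423-3958C>T", "c.100G>A", "c.1565+672_1566-23del2827"))
#' @export
parse_cdna <- function(x) {
  stopifnot(is.character(x))
  pat <- "^c\\.(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?(.*)$"
  ok <- stringr::str_detect(x, pat)
  if (any(!ok)) {
    stop("malformed cDNA position string: '", x[!ok][1L], "'")
  }
  m <- stringr::str_match(x, pat)
  suffix <- m[, 6L]
  bad_sfx <- !stringr::str_detect(
    suffix, "^([ACGTN]+>[ACGTN]+|del[0-9]*|del[ACGTN]*|dup[0-9]*|ins[ACGTN]+)?$")
  if (any(bad_sfx)) {
    stop("unrecognised allele suffix in cDNA string: '", suffix[bad_sfx][1L], "'")
  }
  off <- function(s) ifelse(is.na(s), NA_integer_, suppressWarnings(as.integer(s)))
  tibble::tibble(
    input = x,
    coding_pos = as.integer(m[, 2L]),
    intron_offset = dplyr::coalesce(off(m[, 3L]), 0L),
    coding_pos2 = off(m[, 4L]),
    intron_offset2 = dplyr::if_else(is.na(m[, 4L]), NA_integer_,
                                    dplyr::coalesce(off(m[, 5L]), 0L)),
    suffix = suffix,
    is_range = !is.na(m[, 4L])
  )
}

#' Format a cDNA position back to HGVS-like text
#'
#' Inverse of [parse_cdna()]: `format_cdna(parse_cdna(x))` reproduces `x`.
#'
#' @param pos A tibble as returned by [parse_cdna()], or a coding position
#'   vector when `intron_offset` is given.
#' @param intron_offset Signed intronic offsets (0 = exonic).
#' @param suffix Optional allele suffix.
#' @return Character vector.
#' @export
format_cdna <- function(pos, intron_offset = NULL, suffix = "") {
  if (is.data.frame(pos)) {
    p <- pos
    fmt1 <- function(cp, io) {
      paste0(cp, ifelse(io == 0L, "", sprintf("%+d", io)))
    }
    out <- paste0("c.", fmt1(p$coding_pos, p$intron_offset))
    rng <- p$is_range
    out[rng] <- paste0(out[rng], "_", fmt1(p$coding_pos2[rng], p$intron_offset2[rng]))
    return(paste0(out, p$suffix))
  }
  io <- if (is.null(intron_offset)) 0L else intron_offset
  paste0("c.", pos, ifelse(io == 0L, "", sprintf("%+d", io)), suffix)
}

#' Map cDNA coordinates to genomic coordinates
#'
#' Strand-aware mapping from coding position + intronic offset to a 1-based
#' genomic coordinate, and back. [genomic_to_cdna()] inverts
#' [cdna_to_genomic()] exactly for every position within the gene span.
#'
#' @param model A [gene_model()].
#' @param coding_pos Coding (c.) positions, 1-based within the CDS.
#' @param intron_offset Signed intronic offsets (0 for exonic positions).
#' @return `cdna_to_genomic`: integer vector of 1-based genomic positions.
#' @export
cdna_to_genomic <- function(model, coding_pos, intron_offset = 0L) {
  nm <- norm_model(model)
  if (length(coding_pos) == 0L) return(integer(0))
  n <- max(length(coding_pos), length(intron_offset))
  coding_pos <- rep_len(as.integer(coding_pos), n)
  intron_offset <- rep_len(as.integer(intron_offset), n)
  tx <- coding_pos + nm$cds_tx_start - 1L
  if (any(tx < 1L | tx > sum(nm$exon_len))) {
    stop("coding position outside the transcript")
  }
  anchor <- norm_of_tx(nm, tx)
  gnorm <- anchor + intron_offset
  # offsets must stay inside the adjacent intron
  chk <- intron_offset != 0L
  if (any(chk)) {
    ii <- intron_index_norm(nm, gnorm[chk])
    if (any(is.na(ii))) stop("intronic offset falls outside the adjacent intron")
  }
  if (any(gnorm <= nm$span_lo | gnorm > nm$span_hi)) {
    stop("position outside the gene span")
  }
  pos_norm1(model, gnorm)
}

#' @rdname cdna_to_genomic
#' @param genomic_pos 1-based genomic positions within the gene span.
#' @return `genomic_to_cdna`: a tibble with `coding_pos`, `intron_offset`,
#'   `anchor_exon` (transcription-order index of the anchoring exon) and
#'   `region` (`"exonic"` or `"intronic"`).
#' @export
genomic_to_cdna <- function(model, genomic_pos) {
  nm <- norm_model(model)
  p <- pos_norm1(model, as.integer(genomic_pos))
  if (any(p <= nm$span_lo | p > nm$span_hi)) stop("position outside the gene span")
  ei <- exon_index_norm(nm, p)
  ii <- intron_index_norm(nm, p)
  out <- tibble::tibble(coding_pos = NA_integer_, intron_offset = 0L,
                        anchor_exon = NA_integer_,
                        region = ifelse(is.na(ei), "intronic", "exonic"),
                        .rows = length(p))
  ex <- !is.na(ei)
  out$coding_pos[ex] <- tx_of_norm(nm, p[ex]) - nm$cds_tx_start + 1L
  out$anchor_exon[ex] <- ei[ex]
  if (any(!ex)) {
    i <- ii[!ex]
    lo <- nm$exons$end[i]          # last exonic base (1-based) of upstream exon
    hi <- nm$exons$start[i + 1L]   # last intronic base (1-based)
    d <- p[!ex] - lo               # distance into intron from donor side
    a <- hi - p[!ex] + 1L          # distance from acceptor side
    donor_side <- d <= a
    anchor_tx <- ifelse(donor_side,
                        nm$tx_start[i] + nm$exon_len[i] - 1L,  # last nt of exon i
                        nm$tx_start[i + 1L])                   # first nt of exon i+1
    out$coding_pos[!ex] <- as.integer(anchor_tx - nm$cds_tx_start + 1L)
    out$intron_offset[!ex] <- as.integer(ifelse(donor_side, d, -a))
    out$anchor_exon[!ex] <- as.integer(ifelse(donor_side, i, i + 1L))
  }
  out
}

#' Bin a variant position relative to the exon structure
#'
#' Classifies each position into one of seven bins used throughout clinical
#' splicing-variant reporting: exonic (internal vs the last nucleotide of an
#' exon, which carries the donor signal), the canonical +-1/2 splice sites,
#' and intronic shells at 3-5, 6-10, 11-20 and >20 nt from the exon.
#' The bins partition all positions: every nucleotide of a gene maps to
#' exactly one bin.
#'
#' @param coding_pos,intron_offset Parsed cDNA coordinates (see [parse_cdna()]).
#' @param model A [gene_model()]; needed to decide whether an exonic position
#'   is the last nucleotide of a (non-terminal) exon.
#' @return A factor with levels `EXONIC_INTERNAL`, `EXONIC_LAST_NT`,
#'   `CANONICAL_1_2`, `INTRONIC_3_5`, `INTRONIC_6_10`, `INTRONIC_11_20`,
#'   `DEEP_INTRONIC_GT20`.
#' @export
position_bin <- function(coding_pos, intron_offset, model) {
  n <- max(length(coding_pos), length(intron_offset))
  coding_pos <- rep_len(as.integer(coding_pos), n)
  intron_offset <- rep_len(as.integer(intron_offset), n)
  a <- abs(intron_offset)
  out <- dplyr::case_when(
    a == 0L ~ NA_character_,  # filled below
    a <= 2L ~ "CANONICAL_1_2",
    a <= 5L ~ "INTRONIC_3_5",
    a <= 10L ~ "INTRONIC_6_10",
    a <= 20L ~ "INTRONIC_11_20",
    TRUE ~ "DEEP_INTRONIC_GT20"
  )
  exonic <- a == 0L
  if (any(exonic)) {
    nm <- norm_model(model)
    # transcript coordinates of the last nt of each non-terminal exon
    if (nm$n > 1L) {
      last_nt_tx <- nm$tx_start[-nm$n] + nm$exon_len[-nm$n] - 1L
      last_nt_c <- last_nt_tx - nm$cds_tx_start + 1L
    } else {
      last_nt_c <- integer(0)
    }
    out[exonic] <- ifelse(coding_pos[exonic] %in% last_nt_c,
                          "EXONIC_LAST_NT", "EXONIC_INTERNAL")
  }
  factor(out, levels = position_bin_levels())
}

#' @rdname position_bin
#' @export
position_bin_levels <- function() {
  c("EXONIC_INTERNAL", "EXONIC_LAST_NT", "CANONICAL_1_2", "INTRONIC_3_5",
    "INTRONIC_6_10", "INTRONIC_11_20", "DEEP_INTRONIC_GT20")
}
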