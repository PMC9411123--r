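variant_classifications <- function() c("P", "LP", "VUS", "LB", "B", "unclassified")

variant_types <- function() {
  c("missense", "nonsense", "frameshift", "splicing", "gross_del_dup",
    "synonymous", "other")
}

#' Read panel variants from a VCF file
#'
#' Expects VCF 4.2 with INFO keys `GENE`, `HGVSC`, `CLASS`, `TYPE`,
#' `INSILICO` and per-sample FORMAT fields `GT`, `AF`, `DP`, `GQ` (one record
#' per variant; carriers are the samples with a non-reference genotype).
#'
#' @param path Path to a `.vcf` file.
#' @return A tibble with one row per variant: identity, quality metrics,
#'   prior classification, and a `carrier_ids` list-column.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    ifelse(is.na(x), NA_character_, x)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  af <- suppressWarnings(apply(vcfR::extract.gt(v, element = "AF"), c(1, 2), as.numeric))
  dp <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DP"), c(1, 2), as.numeric))
  carriers <- lapply(seq_len(nrow(gt)), function(i) {
    colnames(gt)[!is.na(gt[i, ]) & !gt[i, ] %in% c("0/0", "0|0", ".")]
  })
  pick <- function(mat, i, ids) {
    if (length(ids) == 0L) return(NA_real_)
    mean(mat[i, ids], na.rm = TRUE)
  }
  tibble::tibble(
    variant_id = paste0(fix$CHROM, ":", fix$POS, fix$REF, ">", fix$ALT),
    gene = info("GENE"),
    hgvs_c = info("HGVSC"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    q_score = suppressWarnings(as.numeric(fix$QUAL)),
    variant_type = info("TYPE"),
    classification = info("CLASS"),
    insilico_deleterious = info("INSILICO") %in% c("1", "TRUE", "deleterious"),
    allele_fraction = vapply(seq_along(carriers), function(i) pick(af, i, carriers[[i]]), 1),
    depth = vapply(seq_along(carriers), function(i) pick(dp, i, carriers[[i]]), 1),
    carrier_ids = carriers
  )
}

#' Write panel variants to a VCF 4.2 file
#'
#' Emits the dialect consumed by [read_variant_vcf()]: INFO keys `GENE`,
#' `HGVSC`, `CLASS`, `TYPE`, `INSILICO`; FORMAT `GT:AF:DP:GQ` for every
#' sample named in `samples` (carriers genotyped `0/1`).
#'
#' @param variants Variant tibble (see [read_variant_vcf()] for columns).
#' @param path Output path.
#' @param samples Character vector of all sample names to emit as columns
#'   (default: union of all carriers).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, samples = NULL) {
  v <- tibble::as_tibble(variants)
  if (is.null(samples)) samples <- sort(unique(unlist(v$carrier_ids)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=splicedx",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"cDNA (c.) notation\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Prior classification\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=INSILICO,Number=1,Type=Integer,Description=\"In silico splice-deleterious flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- vapply(seq_len(nrow(v)), function(i) {
    info <- sprintf("GENE=%s;HGVSC=%s;CLASS=%s;TYPE=%s;INSILICO=%d",
                    v$gene[i], v$hgvs_c[i], v$classification[i],
                    v$variant_type[i], as.integer(isTRUE(v$insilico_deleterious[i])))
    gt <- vapply(samples, function(s) {
      if (s %in% v$carrier_ids[[i]]) {
        sprintf("0/1:%.3f:%d:%d", v$allele_fraction[i], as.integer(v$depth[i]), 99L)
      } else {
        sprintf("0/0:0.000:%d:%d", as.integer(v$depth[i]), 99L)
      }
    }, character(1L))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
            format(v$q_score[i]), "PASS", info, "GT:AF:DP:GQ", gt),
          collapse = "\t")
  }, character(1L))
  readr::write_lines(c(hdr, recs), path)
  invisible(path)
}

#' DNA variant quality filter
#'
#' Drops variants with a Q score of at most 30 *and* an allele fraction below
#' 10 percent (the printed conjunction). A disjunctive mode (either condition
#' drops) is available since the clinical intent of the printed rule is
#' ambiguous.
#'
#' @param variants Variant tibble with `q_score` and `allele_fraction`.
#' @param mode `"conjunction"` (default) or `"disjunction"`.
#' @return `variants` with `keep` (logical) and `filter_reason` columns.
#'   Variants with missing quality fields are kept with an `"unfiltered"`
#'   reason.
#' @export
dna_variant_filter <- function(variants, mode = c("conjunction", "disjunction")) {
  mode <- match.arg(mode)
  v <- tibble::as_tibble(variants)
  low_q <- v$q_score <= 30
  low_af <- v$allele_fraction < 0.10
  drop <- if (mode == "conjunction") low_q & low_af else low_q | low_af
  unfiltered <- is.na(low_q) | is.na(low_af)
  v$keep <- ifelse(unfiltered, TRUE, !drop)
  v$filter_reason <- dplyr::case_when(
    unfiltered ~ "unfiltered: missing quality fields",
    drop ~ "low quality: Q<=30 / AF<10%",
    TRUE ~ ""
  )
  v
}

#' Sanger confirmation requirement
#'
#' SNVs and small indels (at most 3 nt) with allele fraction above 35 percent
#' and at least 100x coverage are exempt from Sanger confirmation. Calls in
#' regions flagged as having below-20x NGS coverage, or flagged for pseudogene
#' interference, are always confirmed.
#'
#' @param variants Variant tibble with `ref`, `alt`, `allele_fraction`,
#'   `depth`, and optional logical columns `low_coverage_region` and
#'   `pseudogene_flag`.
#' @return `variants` with `sanger_required` and `sanger_reason` columns.
#' @export
sanger_confirmation_required <- function(variants) {
  v <- tibble::as_tibble(variants)
  if (!"low_coverage_region" %in% names(v)) v$low_coverage_region <- FALSE
  if (!"pseudogene_flag" %in% names(v)) v$pseudogene_flag <- FALSE
  indel_size <- abs(nchar(v$ref) - nchar(v$alt))
  small <- pmax(nchar(v$ref), nchar(v$alt)) == 1L | indel_size <= 3L
  exempt <- small & v$allele_fraction > 0.35 & v$depth >= 100
  forced <- v$low_coverage_region | v$pseudogene_flag
  v$sanger_required <- forced | !exempt
  v$sanger_reason <- dplyr::case_when(
    v$low_coverage_region ~ "region <20x on NGS",
    v$pseudogene_flag ~ "pseudogene interference",
    !small ~ "indel >3 nt",
    v$allele_fraction <= 0.35 ~ "allele fraction <=35%",
    v$depth < 100 ~ "coverage <100x",
    TRUE ~ ""
  )
  v
}

#' Apply the analytical reporting-range mask
#'
#' The reporting range covers coding exons plus 5 intronic nucleotides on each
#' side. Variants beyond it (|intronic offset| > 5) are only reportable when
#' an abnormal RNA transcript was detected for them; otherwise they are
#' masked and must never appear in a report.
#'
#' @param variants Variant tibble with an `intron_offset` column.
#' @param has_abnormal_rna Logical vector (recycled): abnormal RNA detected
#'   for this variant.
#' @param masking_offset Reporting-range half-width in intronic nucleotides
#'   (default 5).
#' @return `variants` with a `reportable` logical column.
#' @export
reporting_range_mask <- function(variants, has_abnormal_rna,
                                 masking_offset = 5L) {
  v <- tibble::as_tibble(variants)
  has_abnormal_rna <- rep_len(has_abnormal_rna, nrow(v))
  v$reportable <- abs(v$intron_offset) <= masking_offset | has_abnormal_rna
  v
}

#' Splicing-candidate definition
#'
#' A variant is a splicing candidate when in silico modeling predicts a
#' deleterious splicing impact, or it is intronic within five nucleotides of
#' the exon, or an abnormal RNA transcript was detected.
#'
#' @param variants Variant tibble with `intron_offset` and
#'   `insilico_deleterious` columns.
#' @param has_abnormal_rna Logical vector (recycled).
#' @return Logical vector.
#' @export
is_splicing_candidate <- function(variants, has_abnormal_rna = FALSE) {
  v <- tibble::as_tibble(variants)
  has_abnormal_rna <- rep_len(has_abnormal_rna, nrow(v))
  v$insilico_deleterious |
    (v$intron_offset != 0L & abs(v$intron_offset) <= 5L) |
    has_abnormal_rna
}
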