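# Packaged deep-intronic fixture scenarios.
#
# Four engineered cases exercising the deep-intronic arm of the pipeline end
# to end: three cryptic-exon (IC) events created or strengthened by a single
# intronic substitution, and one double partial-intron-retention (IP) case
# caused by a multi-kilobase intronic deletion removing the native acceptor's
# branch point. Gene structures are toy-scale but the intronic offsets of the
# variants are kept at realistic deep-intronic magnitudes so position binning
# and reporting-range masking are exercised at those values. All sequences
# are synthetic.

# replace bases of a model's transcript-oriented sequence at normalized
# 1-based genomic positions
edit_model_seq <- function(model, at, bases) {
  nm <- norm_model(model)
  s <- strsplit(as.character(model$seq), "")[[1L]]
  s[at - nm$span_lo] <- bases
  model$seq <- Biostrings::DNAString(paste(s, collapse = ""))
  model
}

acceptor_tail12 <- function() c("T","C","T","T","T","C","T","T","A","C","A","G")

# carrier junction table: canonical junctions at `depth`, novel junctions at
# fixed counts, host-intron canonical reduced by the event reads (for a
# grouped cryptic-exon pair, by the rounded mean of the flanking counts)
fixture_junctions <- function(model, novel, novel_reads, depth, sample_id,
                              grouped = FALSE) {
  cj <- canonical_junctions(model)
  reads <- rep(as.integer(depth), nrow(cj))
  if (grouped) {
    hit <- vapply(seq_len(nrow(cj)), function(k) {
      any(novel$intron_start <= cj$intron_end[k] &
            novel$intron_end >= cj$intron_start[k])
    }, logical(1L))
    reads[hit] <- reads[hit] - as.integer(round_half_up(mean(novel_reads)))
  } else {
    for (i in seq_len(nrow(novel))) {
      hit <- novel$intron_start[i] <= cj$intron_end &
        novel$intron_end[i] >= cj$intron_start
      reads[hit] <- reads[hit] - novel_reads[i]
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = cj$chrom, intron_start = cj$intron_start,
                   intron_end = cj$intron_end, strand = cj$strand,
                   unique_reads = pmax(reads, 0L)),
    dplyr::mutate(novel, unique_reads = as.integer(novel_reads)))
  out$sample_id <- sample_id
  out
}

fixture_variant <- function(model, hgvs, variant_type = "splicing",
                            ref = "N", alt = "N", sample_id) {
  p <- parse_cdna(hgvs)
  gpos <- cdna_to_genomic(model, p$coding_pos, p$intron_offset)
  tibble::tibble(
    variant_id = paste0(model$gene, ":", hgvs),
    gene = model$gene, hgvs_c = hgvs, chrom = model$chrom, pos = gpos,
    ref = ref, alt = alt,
    coding_pos = p$coding_pos, intron_offset = p$intron_offset,
    coding_pos2 = p$coding_pos2, intron_offset2 = p$intron_offset2,
    variant_type = variant_type, classification = "VUS",
    q_score = 60, allele_fraction = 0.48, depth = 250L,
    insilico_deleterious = TRUE,
    carrier_ids = list(sample_id),
    position_bin = position_bin(p$coding_pos, p$intron_offset, model)
  )
}

#' Packaged deep-intronic fixture cases
#'
#' Four synthetic scenarios, each a toy gene with engineered sequence, a
#' heterozygous carrier junction table, the DNA variant record and the
#' expected outcome:
#'
#' * `APC_like`: `c.423-3958C>T` converts the +6 position of a weak
#'   deep-intronic cryptic donor to the consensus T, strengthening the site
#'   and splicing in a 100-nt cryptic exon (IC, novel-site creation).
#' * `ATM_like`: `c.497-2661A>G` creates the -1 G of a new acceptor,
#'   splicing in an 88-nt cryptic exon (IC, novel-site creation).
#' * `BRCA2_like`: `c.832-3384A>T` creates the +2 T of a new donor,
#'   splicing in a 95-nt cryptic exon (IC, novel-site creation).
#' * `CDH1_like`: `c.1565+672_1566-23del2827` removes the branch point of
#'   the native acceptor; two preexisting deep-intronic cryptic acceptors
#'   take over, causing two partial intron-retention events (IP,
#'   branch-point deletion).
#'
#' All four variants are deep intronic (outside the DNA reporting range),
#' carry a prior VUS classification, and are expected to be upgraded on RNA
#' evidence.
#'
#' @param depth Carrier junction depth (default 1000).
#' @return A named list of fixtures; each has `name`, `model`, `variant`,
#'   `carrier_junctions`, `sample_id`, and `expected` (list with
#'   `event_type`, `mechanism`, `n_events`).
#' @export
fixture_cases <- function(depth = 1000L) {
  out <- list()

  # ---- APC-like: +6 strengthens a cryptic donor -> cryptic exon ----------
  m <- make_gene_model(gene = "APC", chrom = "chrA", seed = 11L,
                       exon_lengths = c(210L, 212L, 180L, 160L),
                       intron_lengths = c(800L, 4300L, 700L))
  nm <- norm_model(m)
  f3 <- nm$exons$start[3L] + 1L                # first base of exon 3 (c.423)
  var <- f3 - 3958L
  cend <- var - 6L                             # last nt of the cryptic exon
  cstart <- cend - 99L                         # 100-nt cryptic exon
  m <- edit_model_seq(m, c((cstart - 12L):(cstart - 1L),          # cryptic acceptor
                           (cend - 2L):cend, (cend + 1L):(cend + 6L)),
                      c(acceptor_tail12(), "C","A","G", "G","T","A","A","G","C"))
  stopifnot(substr(as.character(m$seq), var - nm$span_lo, var - nm$span_lo) == "C")
  novel <- tibble::tibble(
    chrom = m$chrom,
    intron_start = pos_norm1(m, c(nm$exons$end[2L] + 1L, cend + 1L)),
    intron_end = pos_norm1(m, c(cstart - 1L, f3 - 1L)),
    strand = "+")
  nr <- round(0.40 * depth)
  out$APC_like <- list(
    name = "APC_like", model = m,
    variant = fixture_variant(m, "c.423-3958C>T", ref = "C", alt = "T",
                              sample_id = "apc_carrier"),
    carrier_junctions = fixture_junctions(m, novel, c(nr, nr), depth, "apc_carrier", grouped = TRUE),
    sample_id = "apc_carrier",
    expected = list(event_type = "IC", mechanism = "NOVEL_SITE_CREATION",
                    n_events = 1L))

  # ---- ATM-like: -1 A>G creates a new acceptor -> cryptic exon -----------
  m <- make_gene_model(gene = "ATM", chrom = "chrB", seed = 12L,
                       exon_lengths = c(250L, 246L, 190L, 170L),
                       intron_lengths = c(900L, 3000L, 800L))
  nm <- norm_model(m)
  f3 <- nm$exons$start[3L] + 1L                # c.497
  var <- f3 - 2661L
  cstart <- var + 1L
  cend <- cstart + 87L                         # 88-nt cryptic exon
  m <- edit_model_seq(m, c((var - 11L):(var - 2L), var - 1L, var,
                           (cend - 2L):cend, (cend + 1L):(cend + 6L)),
                      c(rep(c("T", "C"), 5L), "A", "A",
                        "C","A","G", "G","T","A","A","G","T"))
  novel <- tibble::tibble(
    chrom = m$chrom,
    intron_start = pos_norm1(m, c(nm$exons$end[2L] + 1L, cend + 1L)),
    intron_end = pos_norm1(m, c(var, f3 - 1L)),
    strand = "+")
  nr <- round(0.35 * depth)
  out$ATM_like <- list(
    name = "ATM_like", model = m,
    variant = fixture_variant(m, "c.497-2661A>G", ref = "A", alt = "G",
                              sample_id = "atm_carrier"),
    carrier_junctions = fixture_junctions(m, novel, c(nr, nr), depth, "atm_carrier", grouped = TRUE),
    sample_id = "atm_carrier",
    expected = list(event_type = "IC", mechanism = "NOVEL_SITE_CREATION",
                    n_events = 1L))

  # ---- BRCA2-like: +2 A>T creates a new donor -> cryptic exon ------------
  m <- make_gene_model(gene = "BRCA2", chrom = "chrC", seed = 13L,
                       exon_lengths = c(420L, 411L, 200L, 150L),
                       intron_lengths = c(1000L, 3700L, 900L))
  nm <- norm_model(m)
  f3 <- nm$exons$start[3L] + 1L                # c.832
  var <- f3 - 3384L
  cend <- var - 2L                             # variant is donor +2
  cstart <- cend - 94L                         # 95-nt cryptic exon
  m <- edit_model_seq(m, c((cstart - 12L):(cstart - 1L),
                           (cend - 2L):cend, cend + 1L, var, (var + 1L):(var + 4L)),
                      c(acceptor_tail12(), "C","A","G", "G", "A", "A","A","G","T"))
  novel <- tibble::tibble(
    chrom = m$chrom,
    intron_start = pos_norm1(m, c(nm$exons$end[2L] + 1L, cend + 1L)),
    intron_end = pos_norm1(m, c(cstart - 1L, f3 - 1L)),
    strand = "+")
  nr <- round(0.30 * depth)
  out$BRCA2_like <- list(
    name = "BRCA2_like", model = m,
    variant = fixture_variant(m, "c.832-3384A>T", ref = "A", alt = "T",
                              sample_id = "brca2_carrier"),
    carrier_junctions = fixture_junctions(m, novel, c(nr, nr), depth, "brca2_carrier", grouped = TRUE),
    sample_id = "brca2_carrier",
    expected = list(event_type = "IC", mechanism = "NOVEL_SITE_CREATION",
                    n_events = 1L))

  # ---- CDH1-like: branch-point deletion -> two partial intron retentions -
  m <- make_gene_model(gene = "CDH1", chrom = "chrD", seed = 14L,
                       exon_lengths = c(520L, 523L, 522L, 300L),
                       intron_lengths = c(1100L, 1200L, 3520L))
  nm <- norm_model(m)
  e3 <- nm$exons$end[3L]                       # last base of exon 3 (c.1565)
  f4 <- nm$exons$start[4L] + 1L                # first base of exon 4 (c.1566)
  p1 <- e3 + 300L                              # preexisting cryptic acceptors
  p2 <- e3 + 500L
  m <- edit_model_seq(m, c((p1 - 11L):p1, p1 + 1L, (p2 - 11L):p2, p2 + 1L),
                      rep(c(acceptor_tail12(), "G"), 2L))
  novel <- tibble::tibble(
    chrom = m$chrom,
    intron_start = pos_norm1(m, c(e3 + 1L, e3 + 1L)),
    intron_end = pos_norm1(m, c(p1, p2)),
    strand = "+")
  out$CDH1_like <- list(
    name = "CDH1_like", model = m,
    variant = fixture_variant(m, "c.1565+672_1566-23del2827",
                              sample_id = "cdh1_carrier"),
    carrier_junctions = fixture_junctions(m, novel, c(round(0.25 * depth),
                                                      round(0.20 * depth)),
                                          depth, "cdh1_carrier"),
    sample_id = "cdh1_carrier",
    expected = list(event_type = "IP", mechanism = "BRANCH_POINT_DELETION",
                    n_events = 2L))
  out
}
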