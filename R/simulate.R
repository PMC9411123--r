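# Synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes: a control pool
# with low-baseline alternative splicing (per-control event PSI drawn from a
# Beta(0.5, 99.5), mean 0.005), heterozygous carriers whose variant-induced
# events are sampled binomially around a true PSI, and engineered fixture
# genes. All generation is seeded and deterministic.

#' Generate a random gene model with consensus splice sites
#'
#' Builds a toy panel gene: exon/intron lengths drawn uniformly from the
#' given ranges, random background sequence, and canonical donor
#' (`CAG|GTAAGT`) and acceptor (pyrimidine tract + `CAG|G`) consensus
#' embedded at every exon/intron boundary. Deterministic given `seed`.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_len_range,intron_len_range Length ranges (nt).
#' @param seed Integer seed.
#' @param gene,chrom,strand,offset Identity and placement of the gene
#'   (`offset` = 0-based genomic start of the first exon in transcription
#'   order for `+`; for `-` the span is reflected).
#' @param exon_lengths,intron_lengths Optional fixed length vectors
#'   overriding the ranges (used by the packaged fixture genes).
#' @return A [gene_model()] with attached sequence (transcript orientation).
#' @export
make_gene_model <- function(n_exons = 5L, exon_len_range = c(90L, 210L),
                            intron_len_range = c(300L, 3000L), seed = 1L,
                            gene = "GENE1", chrom = "chrS", strand = "+",
                            offset = 1000L, exon_lengths = NULL,
                            intron_lengths = NULL) {
  if (!is.null(exon_lengths)) n_exons <- length(exon_lengths)
  stopifnot(n_exons >= 2L)
  if (exon_len_range[1L] < 30L || intron_len_range[1L] < 60L) {
    stop("exons must be >= 30 nt and introns >= 60 nt to hold splice signals")
  }
  withr::local_seed(seed)
  ex_len <- if (is.null(exon_lengths)) {
    sample(exon_len_range[1L]:exon_len_range[2L], n_exons, replace = TRUE)
  } else as.integer(exon_lengths)
  in_len <- if (is.null(intron_lengths)) {
    sample(intron_len_range[1L]:intron_len_range[2L], n_exons - 1L,
           replace = TRUE)
  } else as.integer(intron_lengths)
  stopifnot(length(in_len) == n_exons - 1L, all(ex_len >= 30L), all(in_len >= 60L))
  total <- sum(ex_len) + sum(in_len)
  seq <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                prob = c(0.28, 0.22, 0.22, 0.28))

  # exon boundaries on the transcript-oriented axis (1-based within seq)
  starts <- cumsum(c(1L, head(ex_len, -1L) + in_len))
  ends <- starts + ex_len - 1L
  for (k in seq_len(n_exons - 1L)) {
    e <- ends[k]
    seq[(e - 2L):e] <- c("C", "A", "G")                      # donor exonic -3..-1
    seq[(e + 1L):(e + 6L)] <- c("G", "T", "A", "A", "G", "T") # donor +1..+6
    f <- starts[k + 1L]
    tail12 <- c("T", "C", "T", "T", "T", "C", "T", "T", "A", "C", "A", "G")
    seq[(f - 12L):(f - 1L)] <- tail12                        # acceptor -12..-1
    seq[f] <- "G"                                            # acceptor +1
  }
  # normalized exon coordinates (0-based half-open), anchored at `offset`
  ex_norm <- tibble::tibble(start = offset + starts - 1L, end = offset + ends)
  if (strand == "-") {
    span_lo <- min(ex_norm$start); span_hi <- max(ex_norm$end)
    ex <- tibble::tibble(start = span_lo + span_hi - ex_norm$end,
                         end = span_lo + span_hi - ex_norm$start)
  } else {
    ex <- ex_norm
  }
  gene_model(gene = gene, chrom = chrom, strand = strand, exons = ex,
             isoform_id = paste0(gene, ".1"),
             seq = paste(seq, collapse = ""))
}

#' Build the novel-junction layout of a blueprint splicing event
#'
#' Describes the aberrant transcript structure that a simulated variant
#' induces, as the novel junction coordinates the aligner would report.
#'
#' @param model A [gene_model()].
#' @param type `"ESF"` (skip exon `exon`), `"ESP"` (truncate the 5' end of
#'   `exon` by `trim` nt), `"IP"` (retain the first `extend` nt of intron
#'   `intron`), or `"IC"` (a cryptic exon of length `cryptic_len` starting
#'   `cryptic_at` nt into intron `intron`).
#' @param exon,intron Target exon / intron (transcription order).
#' @param trim,extend,cryptic_at,cryptic_len Geometry parameters (nt).
#' @return A list: `type`, `junctions` (genomic SJ tibble), `event_key`.
#' @export
event_blueprint <- function(model, type = c("ESF", "ESP", "IP", "IC"),
                            exon = 2L, intron = 1L, trim = 30L, extend = 25L,
                            cryptic_at = 200L, cryptic_len = 100L) {
  type <- match.arg(type)
  nm <- norm_model(model)
  mkj <- function(a, b) {
    # normalized removed interval [a, b] -> original SJ coordinates
    iv <- sort(pos_norm1(model, c(a, b)))
    tibble::tibble(chrom = model$chrom, intron_start = iv[1L],
                   intron_end = iv[2L], strand = model$strand)
  }
  j <- switch(type,
    ESF = {
      stopifnot(exon > 1L, exon < nm$n)
      mkj(nm$exons$end[exon - 1L] + 1L, nm$exons$start[exon + 1L])
    },
    ESP = {
      stopifnot(exon > 1L, trim < nm$exon_len[exon])
      mkj(nm$exons$end[exon - 1L] + 1L, nm$exons$start[exon] + trim)
    },
    IP = {
      stopifnot(intron < nm$n,
                extend < nm$exons$start[intron + 1L] - nm$exons$end[intron])
      mkj(nm$exons$end[intron] + 1L + extend, nm$exons$start[intron + 1L])
    },
    IC = {
      ilen <- nm$exons$start[intron + 1L] - nm$exons$end[intron]
      stopifnot(intron < nm$n, cryptic_at + cryptic_len + 20L < ilen)
      cstart <- nm$exons$end[intron] + 1L + cryptic_at
      dplyr::bind_rows(
        mkj(nm$exons$end[intron] + 1L, cstart - 1L),
        mkj(cstart + cryptic_len, nm$exons$start[intron + 1L]))
    })
  list(type = type,
       junctions = j,
       event_key = event_key_of(model$chrom, j$intron_start, j$intron_end))
}

#' Simulate one sample's junction table
#'
#' Every canonical junction region gets `depth` reads; for each blueprint
#' event with true PSI p, novel-junction reads are drawn Binomial(depth, p)
#' (independently per flanking junction for a cryptic exon) and the
#' overlapped canonical junctions keep the complement. Regions without events
#' emit `depth` canonical reads.
#'
#' @param model A [gene_model()].
#' @param events List of blueprints from [event_blueprint()] (possibly
#'   empty); `true_psi` gives each blueprint's PSI (recycled).
#' @param true_psi Numeric vector of per-event true PSI values in `[0, 1]`.
#' @param depth Junction read depth per region (default 1000).
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return A junction tibble.
#' @export
simulate_sample <- function(model, events = list(), true_psi = numeric(0),
                            depth = 1000L, sample_id = "sample", seed = 1L) {
  withr::local_seed(seed)
  stopifnot(all(true_psi >= 0 & true_psi <= 1))
  true_psi <- rep_len(true_psi, length(events))
  cj <- canonical_junctions(model)
  canon_reads <- rep(as.integer(depth), nrow(cj))
  novel <- list()
  for (i in seq_along(events)) {
    bp <- events[[i]]
    nj <- bp$junctions
    reads <- stats::rbinom(nrow(nj), depth, true_psi[i])
    eff <- if (nrow(nj) == 2L) round_half_up(mean(reads)) else sum(reads)
    hit <- vapply(seq_len(nrow(cj)), function(k) {
      any(nj$intron_start <= cj$intron_end[k] & nj$intron_end >= cj$intron_start[k])
    }, logical(1L))
    canon_reads[hit] <- pmax(0L, as.integer(depth - eff))
    keep <- reads > 0L
    if (any(keep)) {
      novel[[length(novel) + 1L]] <-
        dplyr::mutate(nj[keep, ], unique_reads = as.integer(reads[keep]))
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = cj$chrom, intron_start = cj$intron_start,
                   intron_end = cj$intron_end, strand = cj$strand,
                   unique_reads = canon_reads),
    dplyr::bind_rows(novel))
  out$sample_id <- sample_id
  out[out$unique_reads > 0L, ]
}

#' Simulation configuration
#'
#' Bundles the study-level generation parameters: a 345-donor control pool
#' with Beta(0.5, 99.5) baseline event PSI (mean 0.005), junction depth 1000,
#' deleterious heterozygous carriers with true PSI drawn from 0.30-0.50
#' (two carriers per deleterious variant, so reproducibility is observable),
#' benign carrier variants with true PSI 0, and no NMD attenuation unless
#' requested.
#'
#' @param seed Integer master seed; all draws derive from it.
#' @param n_controls Control pool size (default 345).
#' @param junction_depth Reads per junction region (default 1000).
#' @param baseline_shape Beta shape parameters for control baseline PSI.
#' @param n_deleterious Number of deleterious (event-inducing) variants.
#' @param carriers_per_deleterious Carriers per deleterious variant.
#' @param n_benign Number of benign carrier variants (no event, 1 carrier).
#' @param true_psi_range Range of deleterious true PSI.
#' @param nmd_attenuation Multiplier in `[0, 1]` applied to carrier PSI to
#'   emulate decay of the aberrant transcript.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_controls = 345L,
                              junction_depth = 1000L,
                              baseline_shape = c(0.5, 99.5),
                              n_deleterious = 15L,
                              carriers_per_deleterious = 2L,
                              n_benign = 20L,
                              true_psi_range = c(0.30, 0.50),
                              nmd_attenuation = 1.0) {
  stopifnot(junction_depth > 0, nmd_attenuation >= 0, nmd_attenuation <= 1,
            all(true_psi_range >= 0 & true_psi_range <= 1))
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 junction_depth = as.integer(junction_depth),
                 baseline_shape = baseline_shape,
                 n_deleterious = as.integer(n_deleterious),
                 carriers_per_deleterious = as.integer(carriers_per_deleterious),
                 n_benign = as.integer(n_benign),
                 true_psi_range = true_psi_range,
                 nmd_attenuation = nmd_attenuation),
            class = "simulation_config")
}

#' Simulate a paired DNA-RNA cohort
#'
#' Generates a control pool, carrier samples, their DNA variants and a truth
#' table, all derived deterministically from the config seed. Deleterious
#' variants are placed at splice-relevant positions matching their blueprint
#' event (canonical dinucleotide for full skips, +3/+5 intronic for partial
#' events, deep intronic at the cryptic donor for cryptic exons); benign
#' variants are exonic missense changes with no event.
#'
#' @param config A [simulation_config()].
#' @param model Optional [gene_model()]; a default 8-exon gene is generated
#'   from the config seed when omitted.
#' @return A list: `model`, `controls` and `carriers` (stacked junction
#'   tibbles), `variants` (variant tibble with `carrier_ids`), `truth`
#'   (per-variant generation record), `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), model = NULL) {
  cfg <- config
  if (is.null(model)) {
    model <- make_gene_model(n_exons = 8L, intron_len_range = c(400L, 2500L),
                             seed = cfg$seed + 101L, gene = "PANEL1")
  }
  nm <- norm_model(model)
  withr::local_seed(cfg$seed)

  # --- deleterious variant specs ---------------------------------------
  types <- rep(c("ESF", "ESP", "IP", "IC"), length.out = cfg$n_deleterious)
  if (cfg$n_deleterious > 4L * (nm$n - 2L)) {
    stop("too many deleterious variants for distinct type/target combinations")
  }
  specs <- purrr::map(seq_len(cfg$n_deleterious), function(d) {
    ty <- types[d]
    exon <- 2L + ((d - 1L) %/% 4L) %% (nm$n - 2L)   # target exon 2..n-1
    intron <- 1L + ((d - 1L) %/% 4L) %% (nm$n - 2L)
    bp <- switch(ty,
      ESF = event_blueprint(model, "ESF", exon = exon),
      ESP = event_blueprint(model, "ESP", exon = exon, trim = 21L + 3L * d),
      IP = event_blueprint(model, "IP", intron = intron, extend = 20L + d),
      IC = event_blueprint(model, "IC", intron = intron, cryptic_at = 120L + 5L * d,
                           cryptic_len = 100L))
    # variant position tied to the event geometry
    pos_g <- switch(ty,
      ESF = cdna_to_genomic(model, coding_of_exon_start(nm, exon), -1L),
      ESP = cdna_to_genomic(model, coding_of_exon_start(nm, exon), -3L - (d %% 3L)),
      IP = cdna_to_genomic(model, coding_of_exon_end(nm, intron), +3L + 2L * (d %% 2L)),
      IC = {
        cstart <- nm$exons$end[intron] + 1L + 120L + 5L * d
        pos_norm1(model, cstart + 100L)  # +1 intronic base of the cryptic donor
      })
    list(type = ty, blueprint = bp, pos = pos_g)
  })
  tp <- stats::runif(cfg$n_deleterious, cfg$true_psi_range[1L], cfg$true_psi_range[2L]) *
    cfg$nmd_attenuation

  # --- samples -----------------------------------------------------------
  ctl_ids <- sprintf("control_%03d", seq_len(cfg$n_controls))
  controls <- purrr::map_dfr(seq_len(cfg$n_controls), function(i) {
    base <- stats::rbeta(length(specs), cfg$baseline_shape[1L], cfg$baseline_shape[2L])
    simulate_sample(model, purrr::map(specs, "blueprint"), base,
                    depth = cfg$junction_depth, sample_id = ctl_ids[i],
                    seed = cfg$seed + 1000L + i)
  })

  car_rows <- tidyr::expand_grid(d = seq_len(cfg$n_deleterious),
                                 rep = seq_len(cfg$carriers_per_deleterious))
  car_rows$sample_id <- sprintf("carrier_%03d", seq_len(nrow(car_rows)))
  carriers_del <- purrr::map_dfr(seq_len(nrow(car_rows)), function(i) {
    d <- car_rows$d[i]
    simulate_sample(model, list(specs[[d]]$blueprint), tp[d],
                    depth = cfg$junction_depth, sample_id = car_rows$sample_id[i],
                    seed = cfg$seed + 5000L + i)
  })
  ben_ids <- sprintf("carrier_%03d", nrow(car_rows) + seq_len(cfg$n_benign))
  carriers_ben <- purrr::map_dfr(seq_len(cfg$n_benign), function(i) {
    simulate_sample(model, list(), numeric(0), depth = cfg$junction_depth,
                    sample_id = ben_ids[i], seed = cfg$seed + 9000L + i)
  })

  # --- DNA variants ------------------------------------------------------
  del_cd <- purrr::map_dfr(specs, function(s) genomic_to_cdna(model, s$pos))
  ben_cp <- sort(sample(seq_len(coding_length(model)), cfg$n_benign))
  ben_pos <- cdna_to_genomic(model, ben_cp, 0L)
  ref_at <- function(pos) {
    if (is.null(model$seq)) return("N")
    substr(as.character(model$seq), pos_norm1(model, pos) - nm$span_lo,
           pos_norm1(model, pos) - nm$span_lo)
  }
  other_base <- function(b) c(A = "G", C = "T", G = "A", T = "C", N = "A")[[b]]
  mk_var <- function(pos, cd, type) {
    rb <- vapply(pos, ref_at, character(1L))
    tibble::tibble(
      gene = model$gene, chrom = model$chrom, pos = pos, ref = rb,
      alt = vapply(rb, other_base, character(1L)),
      coding_pos = cd$coding_pos, intron_offset = cd$intron_offset,
      hgvs_c = format_cdna(cd$coding_pos, cd$intron_offset),
      variant_type = type, classification = "VUS",
      q_score = round(stats::runif(length(pos), 45, 95), 1),
      allele_fraction = round(stats::runif(length(pos), 0.40, 0.55), 3),
      depth = as.integer(round(stats::runif(length(pos), 150, 400))),
      insilico_deleterious = FALSE
    )
  }
  v_del <- mk_var(vapply(specs, `[[`, 1L, "pos"), del_cd, "splicing")
  v_ben <- mk_var(ben_pos, tibble::tibble(coding_pos = ben_cp, intron_offset = 0L),
                  "missense")
  v_del$carrier_ids <- purrr::map(seq_len(cfg$n_deleterious), function(d) {
    car_rows$sample_id[car_rows$d == d]
  })
  v_ben$carrier_ids <- purrr::map(ben_ids, identity)
  variants <- dplyr::bind_rows(v_del, v_ben)
  variants$variant_id <- paste0(variants$gene, ":", variants$hgvs_c)
  variants$position_bin <- position_bin(variants$coding_pos,
                                        variants$intron_offset, model)

  truth <- tibble::tibble(
    variant_id = variants$variant_id,
    deleterious = c(rep(TRUE, cfg$n_deleterious), rep(FALSE, cfg$n_benign)),
    event_key = c(vapply(specs, function(s) s$blueprint$event_key, character(1L)),
                  rep(NA_character_, cfg$n_benign)),
    event_type = c(types, rep(NA_character_, cfg$n_benign)),
    true_psi = c(tp, rep(0, cfg$n_benign)),
    expected_impact = c(rep("upgrade", cfg$n_deleterious), rep("none", cfg$n_benign))
  )

  list(model = model, controls = controls,
       carriers = dplyr::bind_rows(carriers_del, carriers_ben),
       variants = variants, truth = truth, config = cfg)
}

# coding position of the first / last base of an exon (normalized model)
coding_of_exon_start <- function(nm, exon) {
  as.integer(nm$tx_start[exon] - nm$cds_tx_start + 1L)
}
coding_of_exon_end <- function(nm, exon) {
  as.integer(nm$tx_start[exon] + nm$exon_len[exon] - 1L - nm$cds_tx_start + 1L)
}

#' Simulate a standalone variant table for cohort summaries
#'
#' Draws variant types with the landscape weights (69.2% missense, 6.2%
#' splicing, 2.8% gross deletion/duplication, remainder other) and positions
#' across the position bins, with bin-conditional classification
#' probabilities (canonical sites overwhelmingly P/LP, exonic mostly VUS).
#'
#' @param n Number of variants.
#' @param model A [gene_model()].
#' @param seed Integer seed.
#' @return A variant tibble with positions, bins, classes and quality fields.
#' @export
simulate_variant_table <- function(n, model, seed = 1L) {
  withr::local_seed(seed)
  nm <- norm_model(model)
  type_w <- c(missense = 0.692, splicing = 0.062, gross_del_dup = 0.028,
              other = 0.218)
  vtype <- sample(names(type_w), n, replace = TRUE, prob = type_w)
  # positions: splicing variants intronic (mixed shells), others exonic
  io <- integer(n)
  intr <- vtype == "splicing"
  shells <- sample(c(1L, 2L, 3L, 5L, 8L, 15L, 30L, 300L), sum(intr), replace = TRUE)
  io[intr] <- shells * sample(c(-1L, 1L), sum(intr), replace = TRUE)
  max_intron <- min(intron_lengths(model)) - 1L
  io <- pmax(pmin(io, max_intron), -max_intron)
  cp <- integer(n)
  cp[!intr] <- sample(seq_len(coding_length(model)), sum(!intr), replace = TRUE)
  # intronic anchors: exon boundaries compatible with the offset sign
  don_c <- vapply(seq_len(nm$n - 1L), function(k) coding_of_exon_end(nm, k), 1L)
  acc_c <- vapply(2L:nm$n, function(k) coding_of_exon_start(nm, k), 1L)
  cp[intr] <- ifelse(io[intr] > 0,
                     sample(don_c, sum(intr), replace = TRUE),
                     sample(acc_c, sum(intr), replace = TRUE))
  bin <- position_bin(cp, io, model)
  class_probs <- list(
    EXONIC_INTERNAL = c(P = 0.12, LP = 0.10, VUS = 0.78),
    EXONIC_LAST_NT = c(P = 0.40, LP = 0.23, VUS = 0.37),
    CANONICAL_1_2 = c(P = 0.80, LP = 0.156, VUS = 0.044),
    INTRONIC_3_5 = c(P = 0.30, LP = 0.25, VUS = 0.45),
    INTRONIC_6_10 = c(P = 0.10, LP = 0.15, VUS = 0.75),
    INTRONIC_11_20 = c(P = 0.08, LP = 0.12, VUS = 0.80),
    DEEP_INTRONIC_GT20 = c(P = 0.05, LP = 0.15, VUS = 0.80)
  )
  cls <- vapply(as.character(bin), function(b) {
    p <- class_probs[[b]]
    sample(names(p), 1L, prob = p)
  }, character(1L))
  to_g <- purrr::possibly(function(c1, o1) cdna_to_genomic(model, c1, o1),
                          otherwise = NA_integer_)
  pos <- purrr::map2_int(cp, io, to_g)
  tibble::tibble(
    gene = model$gene, chrom = model$chrom, pos = pos,
    coding_pos = cp, intron_offset = io,
    hgvs_c = format_cdna(cp, io),
    variant_id = paste0(model$gene, ":", format_cdna(cp, io), ":", seq_len(n)),
    variant_type = vtype, classification = cls,
    position_bin = bin,
    q_score = round(stats::runif(n, 20, 95), 1),
    allele_fraction = round(stats::runif(n, 0.05, 0.55), 3),
    depth = as.integer(round(stats::runif(n, 60, 400))),
    insilico_deleterious = stats::runif(n) < ifelse(intr & abs(io) <= 5, 0.5, 0.02),
    ref = "N", alt = "N"
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the formats the pipeline consumes: per-sample junction TSVs with
#' control and carrier manifests, a multi-sample VCF 4.2, the gene model as
#' BED12, the gene-span FASTA and the truth table TSV.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump_group <- function(jt, sub) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
    ids <- unique(jt$sample_id)
    files <- vapply(ids, function(s) {
      f <- file.path(sub, paste0(s, ".sj.tsv"))
      write_junction_table(jt[jt$sample_id == s, ], file.path(dir, f))
      f
    }, character(1L))
    write_manifest(tibble::tibble(sample_id = ids, file = files),
                   file.path(dir, paste0(sub, "_manifest.tsv")))
  }
  dump_group(cohort$controls, "controls")
  dump_group(cohort$carriers, "carriers")
  write_variant_vcf(cohort$variants, file.path(dir, "variants.vcf"),
                    samples = sort(unique(cohort$carriers$sample_id)))
  write_gene_model_bed12(cohort$model, file.path(dir, "panel.bed"))
  write_gene_fasta(cohort$model, file.path(dir, "panel.fa"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
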