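# Splice-site strength scoring.
#
# A consensus log-odds position-weight-matrix scorer over fixed windows:
#   donor:    9 nt, exonic -3..-1 + intronic +1..+6  (consensus CAG|GTAAGT)
#   acceptor: 23 nt, intronic -20..-1 + exonic +1..+3 (polypyrimidine..CAG|G..)
# Frequencies are bundled as plain CSV under inst/extdata (versioned with the
# package) in the style of classical mammalian splice-site consensus tables.
# Scores are sums of log2(f_base / 0.25); 'N' bases contribute 0.

.pwm_cache <- new.env(parent = emptyenv())

load_pwm <- function(site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (!is.null(.pwm_cache[[site_type]])) return(.pwm_cache[[site_type]])
  path <- system.file("extdata", paste0(site_type, "_pwm.csv"), package = "splicedx")
  tab <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(tab[, c("A", "C", "G", "T")])
  rownames(mat) <- tab$position
  .pwm_cache[[site_type]] <- mat
  mat
}

#' Window sizes of the bundled splice-site PWMs
#' @return Named integer vector: `donor = 9`, `acceptor = 23`.
#' @export
pwm_window_size <- function() c(donor = 9L, acceptor = 23L)

#' Score splice-site strength with the bundled consensus PWM
#'
#' Computes a log-odds score (base 2, uniform background) of a candidate
#' splice-site window against the bundled donor or acceptor position-weight
#' matrix. Donor windows are 9 nt spanning the last 3 exonic and first 6
#' intronic bases; acceptor windows are 23 nt spanning the last 20 intronic
#' and first 3 exonic bases. Higher scores mean stronger sites; the consensus
#' sequence attains the maximum and `N` bases contribute zero.
#'
#' @param seq Character vector of window sequences (or anything coercible via
#'   `as.character`, e.g. a [Biostrings::DNAStringSet]).
#' @param site_type `"donor"` or `"acceptor"`.
#' @return Numeric vector of log-odds scores.
#' @examples
#' splice_site_strength("CAGGTAAGT", "donor")
#' @export
splice_site_strength <- function(seq, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  seq <- toupper(as.character(seq))
  w <- pwm_window_size()[[site_type]]
  if (any(nchar(seq) != w)) {
    stop(sprintf("%s windows must be exactly %d nt (got %d)",
                 site_type, w, nchar(seq)[nchar(seq) != w][1L]))
  }
  pwm <- load_pwm(site_type)
  lo <- log2(pwm / 0.25)
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    idx <- match(b, c("A", "C", "G", "T"))
    sum(lo[cbind(seq_len(w), idx)], na.rm = TRUE)  # N (and gaps) contribute 0
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @rdname splice_site_strength
#' @details `pwm_consensus()` returns the maximum-scoring window sequence.
#' @export
pwm_consensus <- function(site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  pwm <- load_pwm(site_type)
  paste0(c("A", "C", "G", "T")[apply(pwm, 1L, which.max)], collapse = "")
}

# ---- window extraction on a normalized model --------------------------------

# 1-based normalized window [from, to] for a donor whose last exonic base is
# at normalized position e, or an acceptor whose first exonic base is at f
donor_window_at <- function(e) c(from = e - 2L, to = e + 6L)
acceptor_window_at <- function(f) c(from = f - 20L, to = f + 2L)

# extract a window from the transcript-oriented sequence of a normalized model
norm_seq_window <- function(nm, from, to) {
  if (is.null(nm$seq)) stop("gene model carries no sequence")
  i <- from - nm$span_lo
  j <- to - nm$span_lo
  if (i < 1L || j > length(nm$seq)) stop("window outside the gene sequence")
  as.character(Biostrings::subseq(nm$seq, i, j))
}
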