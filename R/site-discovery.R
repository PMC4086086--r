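## Candidate enumeration: CRISPR 23 bp sites (20 bp protospacer + NGG PAM)
## on both strands, TALEN monomers (5'-T anchored windows) and their pairing
## across a bounded spacer, plus RVD assembly strings.

CRISPR_SITE_LEN <- 23L
PROTOSPACER_LEN <- 20L

## logical vector: does the length-w window starting at each position 1..n-w+1
## contain any N?
window_has_n <- function(ch, w) {
  n_pos <- cumsum(ch == "N")
  n <- length(ch)
  if (n < w) return(logical(0))
  starts <- seq_len(n - w + 1L)
  (n_pos[starts + w - 1L] - c(0, n_pos)[starts]) > 0L
}

#' Scan a region for CRISPR/Cas9 candidate sites
#'
#' Enumerates every 23 bp window on both strands whose last three bases (in
#' site orientation, 5'->3') match the NGG PAM, whose sequence is N-free,
#' and whose protospacer 5' end satisfies the polymerase synthesis
#' constraint if one is requested (`"GG"`: the first two protospacer bases
#' are GG, for T7; `"GN_or_NG"`: a G in the first or second position, for
#' U6). Overlapping sites are all reported. Genomic starts are plus-strand
#' 0-based coordinates of the 23 bp site regardless of strand.
#'
#' @param region a `TargetRegion`.
#' @param five_prime_constraint `"none"`, `"GG"` or `"GN_or_NG"`.
#' @return data frame with one row per candidate: `chrom`, `start`,
#'   `strand`, `protospacer`, `pam`, `gc_percent`, `g20`.
#' @export
scan_crispr <- function(region,
                        five_prime_constraint = c("none", "GG", "GN_or_NG")) {
  five_prime_constraint <- match.arg(five_prime_constraint)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), protospacer = character(0),
                      pam = character(0), gc_percent = numeric(0),
                      g20 = logical(0), stringsAsFactors = FALSE)
  n <- nchar(region$sequence)
  if (n < CRISPR_SITE_LEN) {
    warning("region shorter than ", CRISPR_SITE_LEN, " bp; no CRISPR sites")
    return(empty)
  }
  ch <- seq_chars(region$sequence)
  starts <- seq_len(n - CRISPR_SITE_LEN + 1L)     # 1-based local
  has_n <- window_has_n(ch, CRISPR_SITE_LEN)

  ## plus strand: PAM = positions 22,23 of the window
  plus <- !has_n & ch[starts + 21L] == "G" & ch[starts + 22L] == "G"
  ## minus strand: site read 5'->3' on minus; PAM GG maps to CC at window
  ## positions 1,2 on the plus strand
  minus <- !has_n & ch[starts] == "C" & ch[starts + 1L] == "C"

  rows <- list()
  if (any(plus)) {
    st <- starts[plus]
    proto <- substring(region$sequence, st, st + PROTOSPACER_LEN - 1L)
    pam <- substring(region$sequence, st + 20L, st + 22L)
    rows$plus <- data.frame(chrom = region$chrom,
                            start = region$start + st - 1L, strand = "+",
                            protospacer = proto, pam = pam,
                            stringsAsFactors = FALSE)
  }
  if (any(minus)) {
    st <- starts[minus]
    site <- revcomp(substring(region$sequence, st, st + CRISPR_SITE_LEN - 1L))
    rows$minus <- data.frame(chrom = region$chrom,
                             start = region$start + st - 1L, strand = "-",
                             protospacer = substr(site, 1, 20),
                             pam = substr(site, 21, 23),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) empty else do.call(rbind, rows)
  if (nrow(out) == 0) return(empty)
  p1 <- substr(out$protospacer, 1, 1); p2 <- substr(out$protospacer, 2, 2)
  keep <- switch(five_prime_constraint,
                 none = rep(TRUE, nrow(out)),
                 GG = p1 == "G" & p2 == "G",
                 GN_or_NG = p1 == "G" | p2 == "G")
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$gc_percent <- 100 * count_gc(out$protospacer) / PROTOSPACER_LEN
  out$g20 <- substr(out$protospacer, 20, 20) == "G"
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a region for TALEN monomer sites
#'
#' Enumerates every N-free window of the given length, on either strand,
#' whose 5' base (in site orientation) is T — the anchoring requirement of
#' the TALE N-terminal domain. Starts are plus-strand 0-based coordinates of
#' the window footprint.
#'
#' @param region a `TargetRegion`.
#' @param length monomer target-site length in bp (10-30).
#' @return data frame: `chrom`, `start`, `strand`, `length`, `sequence`
#'   (5'->3' on its strand).
#' @export
scan_talen_monomers <- function(region, length = 15L) {
  length <- as.integer(length)
  stopifnot(length >= 10L, length <= 30L)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  n <- nchar(region$sequence)
  if (n < length) return(empty)
  ch <- seq_chars(region$sequence)
  starts <- seq_len(n - length + 1L)
  has_n <- window_has_n(ch, length)
  ## plus: window begins with T; minus: 5' base of the minus-strand read is
  ## the complement of the window's last plus-strand base, i.e. that base is A
  plus <- !has_n & ch[starts] == "T"
  minus <- !has_n & ch[starts + length - 1L] == "A"
  rows <- list()
  if (any(plus)) {
    st <- starts[plus]
    rows$plus <- data.frame(chrom = region$chrom,
                            start = region$start + st - 1L, strand = "+",
                            length = length,
                            sequence = substring(region$sequence, st,
                                                 st + length - 1L),
                            stringsAsFactors = FALSE)
  }
  if (any(minus)) {
    st <- starts[minus]
    rows$minus <- data.frame(chrom = region$chrom,
                             start = region$start + st - 1L, strand = "-",
                             length = length,
                             sequence = revcomp(
                               substring(region$sequence, st,
                                         st + length - 1L)),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair TALEN monomers across a spacer
#'
#' Combines plus-strand (left) and minus-strand (right) monomers whose
#' footprints face each other with a gap — the FokI dimerisation spacer —
#' of length within `[spacer_min, spacer_max]` (defaults 14-20 bp).
#'
#' @param monomers data frame from [scan_talen_monomers()].
#' @param region the `TargetRegion` the monomers came from (for the spacer
#'   sequence).
#' @param spacer_min,spacer_max inclusive spacer length bounds in bp.
#' @return data frame with one row per pair: left/right starts and
#'   sequences, spacer interval, length and plus-strand sequence.
#' @export
pair_talens <- function(monomers, region, spacer_min = 14L, spacer_max = 20L) {
  stopifnot(spacer_min <= spacer_max)
  empty <- data.frame(chrom = character(0), left_start = integer(0),
                      right_start = integer(0), length = integer(0),
                      left_seq = character(0), right_seq = character(0),
                      spacer_start = integer(0), spacer_end = integer(0),
                      spacer_len = integer(0), spacer_seq = character(0),
                      stringsAsFactors = FALSE)
  left <- monomers[monomers$strand == "+", , drop = FALSE]
  right <- monomers[monomers$strand == "-", , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  combos <- expand.grid(l = seq_len(nrow(left)), r = seq_len(nrow(right)))
  gap_start <- left$start[combos$l] + left$length[combos$l]
  gap_end <- right$start[combos$r]
  gap <- gap_end - gap_start
  keep <- gap >= spacer_min & gap <= spacer_max
  if (!any(keep)) return(empty)
  combos <- combos[keep, , drop = FALSE]
  gs <- gap_start[keep]; ge <- gap_end[keep]
  out <- data.frame(
    chrom = left$chrom[combos$l],
    left_start = left$start[combos$l],
    right_start = right$start[combos$r],
    length = left$length[combos$l],
    left_seq = left$sequence[combos$l],
    right_seq = right$sequence[combos$r],
    spacer_start = gs, spacer_end = ge, spacer_len = ge - gs,
    spacer_seq = substring(region$sequence, gs - region$start + 1L,
                           ge - region$start),
    stringsAsFactors = FALSE)
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster equivalent TALEN pairs
#'
#' Pairs whose combined footprints (left monomer start through right monomer
#' end) reciprocally overlap by at least `min_overlap` are grouped into one
#' cluster — these are essentially the same design differing only in spacer
#' size or a small shift — and the highest-ranked member represents the
#' cluster in summary output. Input must already be in ranking order (best
#' first); clustering is greedy from the top.
#'
#' @param pairs ranked data frame of TALEN pairs (best first).
#' @param min_overlap reciprocal overlap fraction (default 0.8).
#' @return `pairs` with added `cluster` (integer id) and `representative`
#'   (logical) columns, in the input order.
#' @export
cluster_talen_pairs <- function(pairs, min_overlap = 0.8) {
  n <- nrow(pairs)
  pairs$cluster <- integer(n)
  pairs$representative <- logical(n)
  if (n == 0) return(pairs)
  fs <- pairs$left_start
  fe <- pairs$right_start + pairs$length
  reps_s <- numeric(0); reps_e <- numeric(0); reps_chrom <- character(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (length(reps_s) > 0) {
      ov <- pmin(fe[i], reps_e) - pmax(fs[i], reps_s)
      frac_i <- ov / (fe[i] - fs[i])
      frac_r <- ov / (reps_e - reps_s)
      hit <- which(reps_chrom == pairs$chrom[i] & ov > 0 &
                     frac_i >= min_overlap & frac_r >= min_overlap)
      if (length(hit) > 0) {
        pairs$cluster[i] <- hit[1]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      reps_s <- c(reps_s, fs[i]); reps_e <- c(reps_e, fe[i])
      reps_chrom <- c(reps_chrom, pairs$chrom[i])
      pairs$cluster[i] <- length(reps_s)
      pairs$representative[i] <- TRUE
    }
  }
  pairs
}

RVD_CODE <- c(A = "NI", C = "HD", T = "NG")

#' RVD assembly string for a TALEN monomer
#'
#' Translates a monomer target sequence into the repeat-variable di-residue
#' (RVD) string to synthesize: NI binds A, HD binds C, NG binds T, and
#' guanine is bound by either NN or the more specific NH depending on the
#' assembly kit. The invariant 5' T is recognised by the TALE N-terminal
#' domain, not by a repeat, so RVDs encode positions 2..L of the site.
#'
#' @param sequence monomer target sequence (must start with T, ACGT only).
#' @param g_code `"NN"` or `"NH"` — the RVD used for guanine.
#' @return character vector of RVD codes of length `nchar(sequence) - 1`.
#' @export
rvd_string <- function(sequence, g_code = c("NN", "NH")) {
  g_code <- match.arg(g_code)
  sequence <- toupper(sequence)
  if (substr(sequence, 1, 1) != "T")
    stop("TALEN monomer must start with T")
  if (grepl("[^ACGT]", sequence))
    stop("monomer sequence contains non-ACGT base")
  code <- c(RVD_CODE, G = g_code)
  unname(code[seq_chars(sequence)[-1]])
}
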