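## Genotyping aids anchored to the predicted cut site: exhaustively
## enumerated, specificity-ranked PCR primer pairs and restriction-site
## maps (including sites confined to a TALEN spacer).

# ---------------------------------------------------------------------------
# Melting temperature: unified nearest-neighbor thermodynamics
# (SantaLucia 1998), entropic salt correction 0.368 * (N-1) * ln[Na+],
# Tm = dH / (dS + R ln(CT/x)) with x = 4 for non-self-complementary
# duplexes. Default conditions are 50 mM monovalent salt, 50 nM oligo.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
GAS_CONSTANT <- 1.987    # cal / (mol K)

#' Primer melting temperature (nearest-neighbor)
#'
#' Duplex melting temperature from the unified nearest-neighbor parameter
#' set with an entropic salt correction. Self-complementary sequences get
#' the symmetry entropy term and the undiluted strand concentration.
#'
#' @param seq DNA string, 10-40 bp, ACGT only.
#' @param na_mM monovalent cation concentration (mM, default 50).
#' @param oligo_nM total oligo concentration (nM, default 50).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 50) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 10 || L > 40) stop("primer length must be 10-40 bp (got ", L, ")")
  if (grepl("[^ACGT]", seq)) stop("primer must be ACGT only")
  ch <- seq_chars(seq)
  nn <- paste0(ch[-L], ch[-1])
  dh <- sum(NN_DH[nn])
  ds <- sum(NN_DS[nn])
  for (term in ch[c(1, L)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(seq, revcomp1(seq))
  x <- 4
  if (selfcomp) { ds <- ds - 1.4; x <- 1 }
  ds <- ds + 0.368 * (L - 1) * log(na_mM / 1000)
  1000 * dh / (ds + GAS_CONSTANT * log(oligo_nM * 1e-9 / x)) - 273.15
}

#' Default primer design options
#'
#' Defaults mirror common genotyping practice: primers 18-25 bp
#' (optimum 22), product 150-290 bp, Tm 57-63 degrees C (optimum 60), and at
#' least 50 bp between each primer and the cut site so small indels stay
#' inside the amplicon. `max_pairs` caps how many pairs are emitted, best
#' penalty first.
#'
#' @param primer_min,primer_max,primer_opt primer length bounds/optimum (bp).
#' @param product_min,product_max product size bounds (bp).
#' @param tm_min,tm_max,tm_opt melting temperature bounds/optimum (C).
#' @param min_dist minimum primer to cut-site distance (bp).
#' @param max_pairs maximum pairs returned.
#' @return list of options for [design_primer_pairs()].
#' @export
primer_options <- function(primer_min = 18L, primer_max = 25L,
                           primer_opt = 22L, product_min = 150L,
                           product_max = 290L, tm_min = 57, tm_max = 63,
                           tm_opt = 60, min_dist = 50L, max_pairs = 10L) {
  stopifnot(primer_min <= primer_opt, primer_opt <= primer_max,
            product_min <= product_max, tm_min <= tm_max)
  list(primer_min = as.integer(primer_min),
       primer_max = as.integer(primer_max),
       primer_opt = as.integer(primer_opt),
       product_min = as.integer(product_min),
       product_max = as.integer(product_max),
       tm_min = tm_min, tm_max = tm_max, tm_opt = tm_opt,
       min_dist = as.integer(min_dist), max_pairs = as.integer(max_pairs))
}

## enumerate candidate primers on one side of the exclusion zone;
## returns df(start, end, len, seq, tm) with seq 5'->3' on the priming strand
enumerate_primers <- function(region, lo, hi, opts, side) {
  out <- data.frame(start = integer(0), end = integer(0), len = integer(0),
                    seq = character(0), tm = numeric(0),
                    stringsAsFactors = FALSE)
  if (hi - lo < opts$primer_min) return(out)
  combos <- expand.grid(start = lo:(hi - opts$primer_min),
                        len = opts$primer_min:opts$primer_max)
  combos <- combos[combos$start + combos$len <= hi, , drop = FALSE]
  if (nrow(combos) == 0) return(out)
  seqs <- substring(region$sequence, combos$start - region$start + 1L,
                    combos$start + combos$len - region$start)
  keep <- !grepl("N", seqs, fixed = TRUE)
  combos <- combos[keep, , drop = FALSE]; seqs <- seqs[keep]
  if (side == "right") seqs <- revcomp(seqs)
  if (nrow(combos) == 0) return(out)
  tm <- vapply(seqs, melting_temperature, numeric(1), USE.NAMES = FALSE)
  keep <- tm >= opts$tm_min & tm <= opts$tm_max
  data.frame(start = combos$start[keep],
             end = combos$start[keep] + combos$len[keep],
             len = combos$len[keep], seq = seqs[keep], tm = tm[keep],
             stringsAsFactors = FALSE)
}

#' Design PCR primer pairs around a cut site
#'
#' Exhaustively enumerates every primer placement (start x length) outside
#' an exclusion zone of `min_dist` bp on each side of the cut site, filters
#' on length, Tm and product-size constraints, and returns the best
#' `max_pairs` pairs by the penalty
#' `|Tm_l - Tm_opt| + |Tm_r - Tm_opt| + 0.2 (|len_l - len_opt| + |len_r - len_opt|)`.
#' The amplicon always spans the cut site, so loss of the product (or a
#' size shift) reports a successful edit.
#'
#' @param region a `TargetRegion` providing genomic context; should extend
#'   at least `product_max` beyond the cut site on both sides (clipped at
#'   the region edges with a warning otherwise).
#' @param cut_site 0-based genomic coordinate of the predicted cut.
#' @param opts options from [primer_options()].
#' @return data frame of pairs: sequences, genomic coordinates, Tm values,
#'   `product_size` and `penalty`, sorted by ascending penalty. Empty (with
#'   a diagnostic message) when the geometry is infeasible.
#' @export
design_primer_pairs <- function(region, cut_site, opts = primer_options()) {
  empty <- data.frame(left_seq = character(0), right_seq = character(0),
                      left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      tm_left = numeric(0), tm_right = numeric(0),
                      product_size = integer(0), penalty = numeric(0),
                      stringsAsFactors = FALSE)
  if (cut_site < region$start || cut_site >= region$end)
    stop("cut site outside the region")
  if (cut_site - region$start < opts$product_max ||
      region$end - cut_site < opts$product_max)
    warning("context shorter than the maximum product size on one side; ",
            "primer placements clipped at the region edge")
  left_lo <- max(region$start, cut_site - opts$product_max)
  left_hi <- cut_site - opts$min_dist
  right_lo <- cut_site + opts$min_dist
  right_hi <- min(region$end, cut_site + opts$product_max)
  left <- enumerate_primers(region, left_lo, left_hi, opts, "left")
  right <- enumerate_primers(region, right_lo, right_hi, opts, "right")
  if (nrow(left) == 0 || nrow(right) == 0) {
    side <- c(if (nrow(left) == 0) "left", if (nrow(right) == 0) "right")
    message("no feasible primer pair: no acceptable ",
            paste(side, collapse = " or "),
            " primer under the length/Tm/distance constraints")
    return(empty)
  }
  combos <- expand.grid(l = seq_len(nrow(left)), r = seq_len(nrow(right)))
  product <- right$end[combos$r] - left$start[combos$l]
  keep <- product >= opts$product_min & product <= opts$product_max
  if (!any(keep)) {
    message("no feasible primer pair: product-size window ",
            opts$product_min, "-", opts$product_max,
            " bp cannot be met by any in-bounds primer placement")
    return(empty)
  }
  combos <- combos[keep, , drop = FALSE]
  product <- product[keep]
  penalty <- abs(left$tm[combos$l] - opts$tm_opt) +
    abs(right$tm[combos$r] - opts$tm_opt) +
    0.2 * (abs(left$len[combos$l] - opts$primer_opt) +
             abs(right$len[combos$r] - opts$primer_opt))
  out <- data.frame(left_seq = left$seq[combos$l],
                    right_seq = right$seq[combos$r],
                    left_start = left$start[combos$l],
                    left_end = left$end[combos$l],
                    right_start = right$start[combos$r],
                    right_end = right$end[combos$r],
                    tm_left = left$tm[combos$l],
                    tm_right = right$tm[combos$r],
                    product_size = product, penalty = penalty,
                    stringsAsFactors = FALSE)
  out <- out[order(out$penalty, out$left_start, out$right_start), ,
             drop = FALSE]
  out <- head(out, opts$max_pairs)
  rownames(out) <- NULL
  out
}

#' Map a primer to the genome
#'
#' Exact occurrences of a primer on both strands, enumerated through the
#' seed index and stopped at `cap` hits (the specificity screen does not
#' need more than "many").
#'
#' @param primer ACGT string.
#' @param genome a `Genome`.
#' @param index a `SeedIndex`.
#' @param cap maximum hits to enumerate (default 10).
#' @return data frame `chrom`, `start` (0-based footprint start), `strand`,
#'   with attribute `capped` (logical).
#' @export
map_primer <- function(primer, genome, index, cap = 10L) {
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer)) stop("primer must be ACGT only")
  L <- nchar(primer)
  k <- index$k
  stopifnot(L >= k)
  seed <- substr(primer, 1, k)
  p <- index_lookup(index, seed)
  hits <- data.frame(chrom = character(0), start = integer(0),
                     strand = character(0), stringsAsFactors = FALSE)
  if (nrow(p) > 0) {
    start <- ifelse(p$strand == "+", p$pos, p$pos + k - L)
    ok <- start >= 0
    for (i in which(ok)) {
      n <- genome$lengths[[p$chrom[i]]]
      if (start[i] + L > n) next
      w <- substr(genome$seq[[p$chrom[i]]], start[i] + 1L, start[i] + L)
      if (p$strand[i] == "-") w <- revcomp1(w)
      if (w == primer)
        hits <- rbind(hits, data.frame(chrom = p$chrom[i],
                                       start = as.integer(start[i]),
                                       strand = p$strand[i],
                                       stringsAsFactors = FALSE))
    }
  }
  hits <- unique(hits)
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  capped <- nrow(hits) > cap
  hits <- head(hits, cap)
  attr(hits, "capped") <- capped
  hits
}

#' Specificity-rank primer pairs
#'
#' Maps both primers of each pair against the genome and counts unintended
#' amplicons: loci other than the target where a left-primer hit and a
#' right-primer hit lie in convergent orientation within
#' `product_factor` times the maximum product size. Pairs are ordered by
#' ascending off-product count, then total primer hit count, then design
#' penalty.
#'
#' @param pairs data frame from [design_primer_pairs()].
#' @param genome a `Genome`.
#' @param index a `SeedIndex`.
#' @param opts the [primer_options()] used at design time.
#' @param product_factor off-product size cutoff as a multiple of
#'   `product_max` (default 1.5).
#' @param cap per-primer hit cap (see [map_primer()]).
#' @return `pairs` with `left_hits`, `right_hits`, `off_products` and
#'   `specificity_rank` columns, sorted by specificity.
#' @export
rank_primer_pairs <- function(pairs, genome, index, opts = primer_options(),
                              product_factor = 1.5, cap = 10L) {
  n <- nrow(pairs)
  pairs$left_hits <- integer(n); pairs$right_hits <- integer(n)
  pairs$off_products <- integer(n)
  if (n == 0) { pairs$specificity_rank <- integer(0); return(pairs) }
  max_amp <- product_factor * opts$product_max
  for (i in seq_len(n)) {
    Ll <- nchar(pairs$left_seq[i]); Lr <- nchar(pairs$right_seq[i])
    lh <- map_primer(pairs$left_seq[i], genome, index, cap)
    rh <- map_primer(pairs$right_seq[i], genome, index, cap)
    pairs$left_hits[i] <- nrow(lh); pairs$right_hits[i] <- nrow(rh)
    pairs$off_products[i] <- count_off_products(
      lh, Ll, rh, Lr,
      target = c(pairs$left_start[i], pairs$right_start[i]),
      max_amp = max_amp)
  }
  o <- order(pairs$off_products, pairs$left_hits + pairs$right_hits,
             pairs$penalty, pairs$left_start, pairs$right_start)
  pairs <- pairs[o, , drop = FALSE]
  pairs$specificity_rank <- seq_len(n)
  rownames(pairs) <- NULL
  pairs
}

## convergent (amplifiable) combinations of one left-primer hit and one
## right-primer hit, excluding the intended target amplicon
count_off_products <- function(lh, Ll, rh, Lr, target, max_amp) {
  count <- 0L
  if (nrow(lh) == 0 || nrow(rh) == 0) return(count)
  for (a in seq_len(nrow(lh))) for (b in seq_len(nrow(rh))) {
    if (lh$chrom[a] != rh$chrom[b]) next
    if (lh$strand[a] == "+" && rh$strand[b] == "-") {
      amp <- (rh$start[b] + Lr) - lh$start[a]
      is_target <- lh$start[a] == target[1] && rh$start[b] == target[2]
    } else if (lh$strand[a] == "-" && rh$strand[b] == "+") {
      amp <- (lh$start[a] + Ll) - rh$start[b]
      is_target <- FALSE
    } else next
    if (!is_target && amp > 0 && amp <= max_amp) count <- count + 1L
  }
  count
}

# ---------------------------------------------------------------------------
# Restriction sites

#' Built-in restriction enzyme table
#'
#' A compact set of widely used enzymes with IUPAC recognition sequences
#' and supplier tags for filtering. Users can substitute their own table
#' via [load_enzyme_table()].
#'
#' @param suppliers optional character vector; keep only enzymes carrying
#'   at least one of these supplier tags.
#' @return data frame: `name`, `recognition`, `site_length`, `suppliers`
#'   (comma-separated tags).
#' @export
default_enzymes <- function(suppliers = NULL) {
  e <- read.table(text = "
EcoRI GAATTC NEB,Thermo,Promega
BamHI GGATCC NEB,Thermo,Promega
HindIII AAGCTT NEB,Thermo,Promega
NotI GCGGCCGC NEB,Thermo
XhoI CTCGAG NEB,Thermo,Promega
SalI GTCGAC NEB,Thermo
PstI CTGCAG NEB,Thermo,Promega
SmaI CCCGGG NEB,Thermo
KpnI GGTACC NEB,Thermo,Promega
SacI GAGCTC NEB,Thermo,Promega
XbaI TCTAGA NEB,Thermo,Promega
SpeI ACTAGT NEB,Thermo
NcoI CCATGG NEB,Thermo
NdeI CATATG NEB,Thermo
BglII AGATCT NEB,Thermo
EcoRV GATATC NEB,Thermo,Promega
AatII GACGTC NEB,Thermo
NheI GCTAGC NEB,Thermo
MfeI CAATTG NEB
ApaI GGGCCC NEB,Thermo,Promega
ScaI AGTACT NEB,Thermo
StuI AGGCCT NEB,Thermo
AluI AGCT NEB,Thermo
HaeIII GGCC NEB,Thermo,Promega
RsaI GTAC NEB,Thermo,Promega
TaqI TCGA NEB,Thermo
Sau3AI GATC NEB
MspI CCGG NEB,Thermo
HinfI GANTC NEB,Thermo,Promega
DdeI CTNAG NEB,Thermo
AvaI CYCGRG NEB,Thermo
StyI CCWWGG NEB,Thermo
HincII GTYRAC NEB,Thermo,Promega
BstXI CCANNNNNNTGG NEB,Thermo
DraI TTTAAA NEB,Thermo,Promega
", header = FALSE, col.names = c("name", "recognition", "suppliers"),
    stringsAsFactors = FALSE)
  e$site_length <- nchar(e$recognition)
  e <- e[, c("name", "recognition", "site_length", "suppliers")]
  if (!is.null(suppliers)) {
    tags <- strsplit(e$suppliers, ",", fixed = TRUE)
    e <- e[vapply(tags, function(t) any(t %in% suppliers), logical(1)), ,
           drop = FALSE]
    rownames(e) <- NULL
  }
  e
}

#' Load a user enzyme table
#'
#' TSV with columns name, recognition (IUPAC) and optional comma-separated
#' supplier tags.
#'
#' @param path TSV file path.
#' @return enzyme data frame as in [default_enzymes()].
#' @export
load_enzyme_table <- function(path) {
  e <- read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                  stringsAsFactors = FALSE)
  if (ncol(e) < 2) stop("enzyme table needs at least name + recognition")
  names(e)[1:2] <- c("name", "recognition")
  e$suppliers <- if (ncol(e) >= 3) as.character(e[[3]]) else ""
  e$recognition <- toupper(e$recognition)
  bad <- grepl(paste0("[^", paste(names(IUPAC_CLASS), collapse = ""), "]"),
               e$recognition)
  if (any(bad))
    stop("invalid IUPAC recognition sequence for enzyme(s): ",
         paste(e$name[bad], collapse = ", "))
  e$site_length <- nchar(e$recognition)
  e[, c("name", "recognition", "site_length", "suppliers")]
}

empty_sites <- function() {
  data.frame(enzyme = character(0), start = integer(0), strand = character(0),
             recognition = character(0), unique_in_region = logical(0),
             stringsAsFactors = FALSE)
}

#' Scan a region for restriction sites
#'
#' Matches each enzyme's IUPAC recognition sequence (expanded degeneracy)
#' against both strands of the region. Palindromic recognition sequences
#' are reported once per locus on the plus strand. Enzymes whose site is
#' shorter than `min_site_len` are excluded up front (short sites cut too
#' often to be useful for genotyping).
#'
#' @param region a `TargetRegion`.
#' @param enzymes enzyme data frame (see [default_enzymes()]).
#' @param min_site_len minimum recognition-site length to keep (bp).
#' @return data frame: `enzyme`, `start` (0-based genomic), `strand`,
#'   `recognition`, `unique_in_region` (NA until
#'   [classify_uniqueness()]).
#' @export
scan_restriction_sites <- function(region, enzymes = default_enzymes(),
                                   min_site_len = 4L) {
  enzymes <- enzymes[enzymes$site_length >= min_site_len, , drop = FALSE]
  out <- list()
  subject <- Biostrings::DNAString(region$sequence)
  for (i in seq_len(nrow(enzymes))) {
    rec <- toupper(enzymes$recognition[i])
    bad <- setdiff(seq_chars(rec), names(IUPAC_CLASS))
    if (length(bad) > 0)
      stop("enzyme ", enzymes$name[i], ": invalid IUPAC letter(s) ",
           paste(unique(bad), collapse = ", "))
    rc <- revcomp(rec)
    pats <- if (rc == rec) list(c("+", rec)) else list(c("+", rec),
                                                       c("-", rc))
    for (p in pats) {
      m <- Biostrings::matchPattern(p[2], subject, fixed = "subject")
      if (length(m) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        enzyme = enzymes$name[i],
        start = region$start + Biostrings::start(m) - 1L,
        strand = p[1], recognition = rec,
        unique_in_region = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_sites())
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$start, sites$enzyme, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Flag restriction sites unique within the region
#'
#' An enzyme with exactly one site in the displayed region is the most
#' informative for a digestion assay; its site is flagged unique.
#'
#' @param sites data frame from [scan_restriction_sites()] (one region).
#' @return `sites` with `unique_in_region` filled in.
#' @export
classify_uniqueness <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  counts <- table(sites$enzyme)
  sites$unique_in_region <- counts[sites$enzyme] == 1L
  sites
}

#' Restriction sites inside a TALEN spacer
#'
#' Sites fully contained in the spacer between the two monomer footprints;
#' a cut there is destroyed by repair indels, making these enzymes direct
#' genotyping probes. Sites straddling a spacer/monomer boundary are not
#' reported.
#'
#' @param pair one-row data frame from [pair_talens()].
#' @param enzymes enzyme data frame.
#' @param min_site_len minimum site length (default 1: report everything
#'   that fits in the spacer).
#' @return restriction-site data frame with genomic coordinates.
#' @export
spacer_restriction_sites <- function(pair, enzymes = default_enzymes(),
                                     min_site_len = 1L) {
  spacer <- new_target_region(pair$chrom[[1]], pair$spacer_start[[1]],
                              pair$spacer_end[[1]], pair$spacer_seq[[1]],
                              "coordinates")
  scan_restriction_sites(spacer, enzymes, min_site_len)
}
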