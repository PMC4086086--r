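## Candidate ordering. The criteria and their priority: off-target severity
## (perfect hits worst, then 1- and 2-mismatch hits), then for sgRNAs the
## GC window and the PAM-proximal guanine, then position within the gene
## (5'-most first). Implemented as a strict lexicographic sort; the listed
## priority supplies the order, no weights.

#' GC content of a protospacer
#'
#' @param protospacer 20 bp ACGT string (vectorised).
#' @return percent G+C over the 20-mer.
#' @export
gc_percent <- function(protospacer) {
  if (any(nchar(protospacer) != PROTOSPACER_LEN))
    stop("protospacer must be exactly ", PROTOSPACER_LEN, " bp")
  if (any(grepl("[^ACGTacgt]", protospacer)))
    stop("protospacer must be ACGT only")
  100 * count_gc(toupper(protospacer)) / PROTOSPACER_LEN
}

#' Is a GC content inside the effective window?
#'
#' sgRNAs are most effective with GC content between 45 and 80 percent;
#' bounds are inclusive.
#'
#' @param gc percent (0-100), vectorised.
#' @param low,high window bounds in percent.
#' @return logical.
#' @export
gc_in_window <- function(gc, low = 45, high = 80) {
  stopifnot(all(gc >= 0 & gc <= 100))
  gc >= low & gc <= high
}

#' Tally off-target hits by mismatch count
#'
#' @param hits hit data frame (self hits are excluded).
#' @return named integer vector `n0`, `n1`, `n2`.
#' @export
tally_offtargets <- function(hits) {
  h <- hits[!hits$is_self, , drop = FALSE]
  c(n0 = sum(h$mismatches == 0L), n1 = sum(h$mismatches == 1L),
    n2 = sum(h$mismatches == 2L))
}

## distance of a site from the transcript 5' end (or region start when no
## model): strand-aware when a model is supplied
transcript_offset <- function(start, end, region, model = NULL) {
  if (is.null(model)) return(start - region$start)
  span <- tx_span(model)
  if (model$strand == "+") start - span[1] else span[2] - end
}

#' Rank CRISPR candidates
#'
#' Orders candidates by the lexicographic key: ascending perfect
#' off-targets (n0), then 1-mismatch (n1), then 2-mismatch (n2) counts;
#' then candidates whose GC content lies in the 45-80 percent window; then
#' a guanine at protospacer position 20 (PAM-adjacent); then proximity to
#' the transcript 5' end. Remaining ties break on plus-strand coordinate,
#' then strand (+ before -), so the order is total and deterministic.
#'
#' @param candidates data frame from [scan_crispr()] with tally columns
#'   `n0`, `n1`, `n2` added.
#' @param region the `TargetRegion` searched.
#' @param model optional `GeneModel` for strand-aware 5' offsets.
#' @return the data frame sorted into rank order with `transcript_offset`
#'   and `rank` (1..N) columns.
#' @export
rank_crispr <- function(candidates, region, model = NULL) {
  df <- candidates
  if (nrow(df) == 0) { df$transcript_offset <- integer(0); df$rank <- integer(0); return(df) }
  df$transcript_offset <- transcript_offset(df$start, df$start + CRISPR_SITE_LEN,
                                            region, model)
  o <- order(df$n0, df$n1, df$n2,
             -as.integer(gc_in_window(df$gc_percent)),
             -as.integer(df$g20),
             df$transcript_offset,
             df$start,
             match(df$strand, c("+", "-")))
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Rank TALEN pairs
#'
#' Orders pairs by ascending paired off-target count (loci where both
#' monomers could co-bind at cutting distance — the dominant risk), then by
#' the summed monomer tallies (n0, n1, n2), then by transcript 5'
#' proximity, with coordinate tie-breaks.
#'
#' @param pairs data frame from [pair_talens()] with columns
#'   `paired_offtargets`, `n0`, `n1`, `n2` (summed over both monomers).
#' @param region the `TargetRegion` searched.
#' @param model optional `GeneModel`.
#' @return the data frame sorted into rank order with `transcript_offset`
#'   and `rank` columns.
#' @export
rank_talen <- function(pairs, region, model = NULL) {
  df <- pairs
  if (nrow(df) == 0) { df$transcript_offset <- integer(0); df$rank <- integer(0); return(df) }
  df$transcript_offset <- transcript_offset(
    df$left_start, df$right_start + df$length, region, model)
  o <- order(df$paired_offtargets, df$n0, df$n1, df$n2,
             df$transcript_offset, df$left_start, df$right_start)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

## quartile colour bins for reports (display plumbing)
rank_color <- function(rank, n) {
  q <- ceiling(4 * rank / max(n, 1))
  c("green", "yellow", "orange", "red")[pmin(pmax(q, 1), 4)]
}
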