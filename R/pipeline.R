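## End-to-end design pipelines: discovery -> off-target search -> tallies ->
## ranking, plus per-mode report columns. These are what the CLI drives and
## what scripted analyses call directly.

## seed length giving max_mm+1 disjoint seeds within a query of length L
pick_seed_k <- function(L, max_mm) {
  min(16L, max(4L, L %/% (max_mm + 1L)))
}

candidate_id <- function(chrom, start, strand) {
  sprintf("%s:%d:%s", chrom, start + 1L, strand)
}

## 1-based transcript-order exon index containing a position, 0 if intronic
## or outside, NA if no model
exon_of <- function(pos, model) {
  if (is.null(model)) return(NA_integer_)
  ex <- model$exons
  g <- which(pos >= ex[, 1] & pos < ex[, 2])
  if (length(g) == 0) return(0L)
  if (model$strand == "+") g[1] else nrow(ex) + 1L - g[1]
}

#' Run the full CRISPR design pipeline on a region
#'
#' Scans the region for candidate sites, searches the whole genome for
#' off-targets of each candidate under the requested mismatch model,
#' tallies non-self hits by mismatch count and ranks the candidates.
#'
#' @param genome a `Genome`.
#' @param region a `TargetRegion` within the genome (or a raw-sequence
#'   region, which is then also searched against the genome).
#' @param model optional `GeneModel` for 5'-position tie-breaks and exon
#'   annotation.
#' @param offtarget_mode `"all_upstream"`, `"seed_exact"` or
#'   `"perfect_only"`.
#' @param max_mm maximum off-target mismatches (default 2).
#' @param five_prime_constraint protospacer 5' synthesis constraint.
#' @param index optional pre-built `SeedIndex`; built automatically with a
#'   pigeonhole-sound seed length otherwise.
#' @return list: `ranked` (ranked candidate data frame with tallies and
#'   `exon` column), `offtargets` (named list of per-candidate hit data
#'   frames keyed by candidate id), `index`.
#' @export
crispr_pipeline <- function(genome, region, model = NULL,
                            offtarget_mode = "all_upstream", max_mm = 2L,
                            five_prime_constraint = "none", index = NULL) {
  cands <- scan_crispr(region, five_prime_constraint)
  if (is.null(index))
    index <- build_index(genome, pick_seed_k(PROTOSPACER_LEN, max_mm))
  offtargets <- list()
  n <- nrow(cands)
  cands$n0 <- integer(n); cands$n1 <- integer(n); cands$n2 <- integer(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      hits <- find_crispr_offtargets(cands[i, ], genome, index,
                                     mode = offtarget_mode, max_mm = max_mm)
      tly <- tally_offtargets(hits)
      cands$n0[i] <- tly[["n0"]]; cands$n1[i] <- tly[["n1"]]
      cands$n2[i] <- tly[["n2"]]
      offtargets[[candidate_id(cands$chrom[i], cands$start[i],
                               cands$strand[i])]] <- hits
    }
  }
  ranked <- rank_crispr(cands, region, model)
  ranked$exon <- vapply(ranked$start, exon_of, integer(1), model = model)
  list(ranked = ranked, offtargets = offtargets, index = index)
}

#' Run the full TALEN design pipeline on a region
#'
#' Enumerates 5'-T monomers, pairs them across the spacer range, searches
#' the genome for monomer and paired off-targets of every pair (monomer
#' searches are memoised by sequence), ranks the pairs, clusters
#' near-identical designs and attaches RVD strings and spacer restriction
#' enzymes.
#'
#' @param genome,region,model,index as in [crispr_pipeline()].
#' @param monomer_length TALEN monomer target-site length (bp).
#' @param spacer_min,spacer_max spacer length bounds (bp).
#' @param max_mm per-monomer off-target mismatches (0-2, default 2).
#' @param g_code RVD used for guanine (`"NN"` or `"NH"`).
#' @param enzymes enzyme table for spacer restriction sites.
#' @return list: `ranked` (ranked, clustered pair data frame),
#'   `offtargets` (per-pair list with `monomer_hits` and `paired`),
#'   `index`.
#' @export
talen_pipeline <- function(genome, region, model = NULL,
                           monomer_length = 15L, spacer_min = 14L,
                           spacer_max = 20L, max_mm = 2L, g_code = "NN",
                           enzymes = default_enzymes(), index = NULL) {
  monomers <- scan_talen_monomers(region, monomer_length)
  pairs <- pair_talens(monomers, region, spacer_min, spacer_max)
  if (is.null(index))
    index <- build_index(genome, pick_seed_k(monomer_length, max_mm))
  n <- nrow(pairs)
  pairs$paired_offtargets <- integer(n)
  pairs$n0 <- integer(n); pairs$n1 <- integer(n); pairs$n2 <- integer(n)
  offtargets <- list()
  cache <- new.env(parent = emptyenv())
  cached_hits <- function(seq) {
    if (!exists(seq, envir = cache, inherits = FALSE))
      assign(seq, find_monomer_hits(seq, genome, index, max_mm),
             envir = cache)
    get(seq, envir = cache)
  }
  if (n > 0) {
    for (i in seq_len(n)) {
      pr <- pairs[i, ]
      left <- cached_hits(pr$left_seq)
      right <- cached_hits(pr$right_seq)
      ot <- assemble_talen_offtargets(pr, left, right, spacer_min,
                                      spacer_max)
      tly <- tally_offtargets(ot$monomer_hits)
      pairs$n0[i] <- tly[["n0"]]; pairs$n1[i] <- tly[["n1"]]
      pairs$n2[i] <- tly[["n2"]]
      pairs$paired_offtargets[i] <- nrow(ot$paired)
      offtargets[[candidate_id(pr$chrom, pr$left_start, "+")]] <- ot
    }
  }
  ranked <- rank_talen(pairs, region, model)
  ranked <- cluster_talen_pairs(ranked)
  ranked$rvds_left <- vapply(ranked$left_seq, function(s)
    paste(rvd_string(s, g_code), collapse = "-"), character(1),
    USE.NAMES = FALSE)
  ranked$rvds_right <- vapply(ranked$right_seq, function(s)
    paste(rvd_string(s, g_code), collapse = "-"), character(1),
    USE.NAMES = FALSE)
  ## one scan of the whole region; a spacer's sites are the region sites
  ## fully contained in [spacer_start, spacer_end)
  region_sites <- scan_restriction_sites(region, enzymes, min_site_len = 1L)
  site_end <- region_sites$start + nchar(region_sites$recognition)
  ranked$spacer_enzymes <- vapply(seq_len(nrow(ranked)), function(i) {
    inside <- region_sites$start >= ranked$spacer_start[i] &
      site_end <= ranked$spacer_end[i]
    paste(sort(unique(region_sites$enzyme[inside])), collapse = ",")
  }, character(1))
  list(ranked = ranked, offtargets = offtargets, index = index)
}

## pair pre-computed monomer hit sets into paired off-targets (shared by
## find_talen_offtargets and the memoised pipeline path)
assemble_talen_offtargets <- function(pair, left, right, spacer_min,
                                      spacer_max) {
  L <- pair$length[[1]]
  left$monomer <- rep("left", nrow(left))
  right$monomer <- rep("right", nrow(right))
  hits <- rbind(left, right)
  if (nrow(hits) > 0) {
    hits$is_self <- (hits$monomer == "left" & hits$chrom == pair$chrom[[1]] &
                       hits$start == pair$left_start[[1]] &
                       hits$strand == "+") |
      (hits$monomer == "right" & hits$chrom == pair$chrom[[1]] &
         hits$start == pair$right_start[[1]] & hits$strand == "-")
  }
  fwd <- hits[hits$strand == "+", , drop = FALSE]
  rev <- hits[hits$strand == "-", , drop = FALSE]
  paired <- data.frame(chrom = character(0), left_start = integer(0),
                       right_start = integer(0), left_mismatches = integer(0),
                       right_mismatches = integer(0), gap_len = integer(0),
                       stringsAsFactors = FALSE)
  if (nrow(fwd) > 0 && nrow(rev) > 0) {
    combos <- expand.grid(a = seq_len(nrow(fwd)), b = seq_len(nrow(rev)))
    same <- fwd$chrom[combos$a] == rev$chrom[combos$b]
    gap <- rev$start[combos$b] - (fwd$start[combos$a] + L)
    keep <- same & gap >= spacer_min & gap <= spacer_max &
      !(fwd$is_self[combos$a] & rev$is_self[combos$b])
    if (any(keep)) {
      combos <- combos[keep, , drop = FALSE]
      paired <- data.frame(
        chrom = fwd$chrom[combos$a],
        left_start = fwd$start[combos$a],
        right_start = rev$start[combos$b],
        left_mismatches = fwd$mismatches[combos$a],
        right_mismatches = rev$mismatches[combos$b],
        gap_len = gap[keep], stringsAsFactors = FALSE)
      paired <- paired[order(paired$chrom, paired$left_start,
                             paired$right_start), , drop = FALSE]
      rownames(paired) <- NULL
    }
  }
  list(monomer_hits = hits, paired = paired)
}

#' Predicted nuclease cut site of a ranked target
#'
#' Cas9 cuts ~3 bp 5' of the PAM (between protospacer positions 17 and
#' 18); a TALEN pair cuts in the middle of its spacer.
#'
#' @param target one-row ranked data frame.
#' @param mode `"crispr"` or `"talen"`.
#' @return 0-based genomic coordinate of the predicted cut.
#' @export
cut_site <- function(target, mode = c("crispr", "talen")) {
  mode <- match.arg(mode)
  if (mode == "crispr") {
    if (target$strand[[1]] == "+") target$start[[1]] + 17L
    else target$start[[1]] + 6L
  } else {
    target$spacer_start[[1]] + target$spacer_len[[1]] %/% 2L
  }
}
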