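## Genome-wide off-target search. The indexed path seeds candidate loci from
## exact k-mer matches (pigeonhole: max_mm mismatches cannot hit all of
## max_mm+1 disjoint k-seeds) and verifies each locus against the mode
## predicate. brute_force_offtargets() is an independent, fully vectorised
## window sweep used as the test oracle.

## Mismatch models for CRISPR:
##   all_upstream  - <= max_mm mismatches anywhere in the 20-mer (default)
##   seed_exact    - the 11 PAM-proximal protospacer positions (10-20) must
##                   match exactly; mismatches only in positions 1-9
##   perfect_only  - exact protospacer match
## In every mode the PAM must match NGG (first base free, never N).
CRISPR_MODES <- c("all_upstream", "seed_exact", "perfect_only")
SEED_REGION <- 10:20   # PAM-proximal protospacer positions (1-based, 5'->3')

empty_hits <- function() {
  data.frame(chrom = character(0), start = integer(0), strand = character(0),
             mismatches = integer(0), positions = character(0),
             is_self = logical(0), stringsAsFactors = FALSE)
}

hit_row <- function(chrom, start, strand, mm_pos) {
  data.frame(chrom = chrom, start = as.integer(start), strand = strand,
             mismatches = length(mm_pos),
             positions = paste(mm_pos, collapse = ","),
             is_self = FALSE, stringsAsFactors = FALSE)
}

finish_hits <- function(rows, self_chrom = NULL, self_start = NULL,
                        self_strand = NULL) {
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(self_chrom))
    out$is_self <- out$chrom == self_chrom & out$start == self_start &
      out$strand == self_strand
  out
}

# ---------------------------------------------------------------------------
# Seed index

#' Build a k-mer seed index of a genome
#'
#' Records the genomic position of every N-free k-mer on both strands.
#' Minus-strand k-mers are stored as read 5'->3' on the minus strand,
#' keyed by their plus-strand footprint start. The index drives
#' seed-and-extend off-target search; for a query of length L searched with
#' up to `max_mm` mismatches, soundness requires `(max_mm + 1) * k <= L`
#' (disjoint-seed pigeonhole), e.g. k = 6 for 20 bp protospacers at 2
#' mismatches and k = 5 for 15 bp TALEN monomers.
#'
#' @param genome a `Genome`.
#' @param k seed length (4-16).
#' @return a `SeedIndex` object.
#' @export
build_index <- function(genome, k) {
  k <- as.integer(k)
  stopifnot(k >= 4L, k <= 16L)
  if (length(genome$seq) == 0 || sum(as.numeric(genome$lengths)) == 0)
    stop("cannot index an empty genome")
  km <- character(0); chrom <- character(0); pos <- integer(0)
  strand <- character(0)
  for (nm in names(genome$seq)) {
    s <- genome$seq[[nm]]; n <- nchar(s)
    if (n < k) next
    ch <- seq_chars(s)
    starts <- seq_len(n - k + 1L)
    ok <- !window_has_n(ch, k)
    if (!any(ok)) next
    st <- starts[ok]
    kp <- substring(s, st, st + k - 1L)
    km <- c(km, kp, revcomp(kp))
    chrom <- c(chrom, rep(nm, 2L * length(st)))
    pos <- c(pos, st - 1L, st - 1L)
    strand <- c(strand, rep("+", length(st)), rep("-", length(st)))
  }
  postings <- new.env(hash = TRUE, parent = emptyenv())
  if (length(km) > 0) {
    grp <- split(seq_along(km), km)
    for (key in names(grp)) {
      i <- grp[[key]]
      assign(key, data.frame(chrom = chrom[i], pos = pos[i],
                             strand = strand[i], stringsAsFactors = FALSE),
             envir = postings)
    }
  }
  structure(list(k = k, postings = postings, n_kmers = length(km)),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex: k =", x$k, "-", x$n_kmers, "postings\n")
  invisible(x)
}

index_lookup <- function(index, kmer) {
  if (exists(kmer, envir = index$postings, inherits = FALSE))
    get(kmer, envir = index$postings)
  else data.frame(chrom = character(0), pos = integer(0),
                  strand = character(0), stringsAsFactors = FALSE)
}

## candidate loci from disjoint seeds of a query; returns df(chrom,start,strand)
## where start is the 0-based plus-strand footprint start of the full query
seed_candidates <- function(query, index, n_seeds) {
  k <- index$k
  L <- nchar(query)
  if (n_seeds * k > L)
    stop("index k = ", k, " too large: need ", n_seeds,
         " disjoint seeds within a ", L, " bp query; rebuild with k <= ",
         L %/% n_seeds)
  offs <- (seq_len(n_seeds) - 1L) * k
  out <- list()
  for (off in offs) {
    seed <- substr(query, off + 1L, off + k)
    p <- index_lookup(index, seed)
    if (nrow(p) == 0) next
    plus <- p$strand == "+"
    ## plus hit: query footprint starts off bases left of the seed footprint.
    ## minus hit: seed's 5' base (query position off+1) sits at plus
    ## coordinate pos+k-1, so the query footprint start is pos+k+off-L.
    out[[length(out) + 1L]] <- data.frame(
      chrom = p$chrom,
      start = ifelse(plus, p$pos - off, p$pos + k + off - L),
      strand = p$strand, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  cand <- do.call(rbind, out)
  unique(cand[cand$start >= 0, , drop = FALSE])
}

## verify one CRISPR locus: site = 23 bp whose plus-strand start is at
## `start` (candidate start refers to the protospacer footprint; the full
## 23 bp site starts at the protospacer on +, 3 bp earlier on -)
verify_crispr_locus <- function(genome, chrom, proto_start, strand, qch,
                                mode, max_mm) {
  n <- genome$lengths[[chrom]]
  site_start <- if (strand == "+") proto_start else proto_start - 3L
  if (site_start < 0 || site_start + CRISPR_SITE_LEN > n) return(NULL)
  w <- substr(genome$seq[[chrom]], site_start + 1L,
              site_start + CRISPR_SITE_LEN)
  if (grepl("N", w, fixed = TRUE)) return(NULL)
  if (strand == "-") w <- revcomp1(w)
  wch <- seq_chars(w)
  if (wch[22] != "G" || wch[23] != "G") return(NULL)
  mm <- which(wch[seq_len(PROTOSPACER_LEN)] != qch)
  ok <- switch(mode,
               perfect_only = length(mm) == 0,
               all_upstream = length(mm) <= max_mm,
               seed_exact = length(mm) <= max_mm &&
                 !any(mm %in% SEED_REGION))
  if (!ok) return(NULL)
  list(site_start = site_start, mm = mm)
}

#' Find CRISPR off-targets with the seed index
#'
#' Genome-wide search for occurrences of a candidate's protospacer adjacent
#' to an NGG PAM, under one of three mismatch models (see Details). The
#' candidate's own locus is returned flagged `is_self` so downstream
#' tallies can exclude it.
#'
#' @details `all_upstream` tolerates up to `max_mm` mismatches at any
#'   protospacer position (PAM always NGG); `seed_exact` additionally
#'   requires the 11 PAM-proximal positions (10-20) to match exactly,
#'   reflecting that a single mismatch there abolishes cleavage;
#'   `perfect_only` reports exact matches only.
#'
#' @param candidate one-row data frame (or list) with `chrom`, `start`,
#'   `strand`, `protospacer` as produced by [scan_crispr()].
#' @param genome a `Genome`.
#' @param index a `SeedIndex` with `(max_mm + 1) * k <= 20`.
#' @param mode one of `"all_upstream"`, `"seed_exact"`, `"perfect_only"`.
#' @param max_mm maximum mismatches (0-3; default 2).
#' @return data frame of hits: `chrom`, `start` (0-based plus-strand start
#'   of the 23 bp site), `strand`, `mismatches`, `positions` (1-based
#'   protospacer positions from the 5' end, comma-separated), `is_self`.
#' @export
find_crispr_offtargets <- function(candidate, genome, index,
                                   mode = CRISPR_MODES, max_mm = 2L) {
  mode <- match.arg(mode)
  max_mm <- as.integer(max_mm)
  stopifnot(max_mm >= 0L, max_mm <= 3L)
  q <- toupper(candidate$protospacer[[1]])
  stopifnot(nchar(q) == PROTOSPACER_LEN)
  qch <- seq_chars(q)
  n_seeds <- if (mode == "perfect_only") 1L else max_mm + 1L
  cand <- seed_candidates(q, index, n_seeds)
  rows <- list()
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      v <- verify_crispr_locus(genome, cand$chrom[i], cand$start[i],
                               cand$strand[i], qch, mode, max_mm)
      if (!is.null(v))
        rows[[length(rows) + 1L]] <- hit_row(cand$chrom[i], v$site_start,
                                             cand$strand[i], v$mm)
    }
  }
  finish_hits(rows, candidate$chrom[[1]], candidate$start[[1]],
              candidate$strand[[1]])
}

verify_talen_locus <- function(genome, chrom, start, strand, qch, max_mm) {
  L <- length(qch)
  n <- genome$lengths[[chrom]]
  if (start < 0 || start + L > n) return(NULL)
  w <- substr(genome$seq[[chrom]], start + 1L, start + L)
  if (grepl("N", w, fixed = TRUE)) return(NULL)
  if (strand == "-") w <- revcomp1(w)
  wch <- seq_chars(w)
  if (wch[1] != "T") return(NULL)   # 5' T binding requirement at every locus
  mm <- which(wch != qch)
  if (length(mm) > max_mm) return(NULL)
  mm
}

## indexed search for one TALEN monomer sequence
find_monomer_hits <- function(sequence, genome, index, max_mm) {
  q <- toupper(sequence)
  qch <- seq_chars(q)
  cand <- seed_candidates(q, index, max_mm + 1L)
  rows <- list()
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      mm <- verify_talen_locus(genome, cand$chrom[i], cand$start[i],
                               cand$strand[i], qch, max_mm)
      if (!is.null(mm))
        rows[[length(rows) + 1L]] <- hit_row(cand$chrom[i], cand$start[i],
                                             cand$strand[i], mm)
    }
  }
  finish_hits(rows)
}

#' Find TALEN off-targets (monomer and paired)
#'
#' Searches the genome independently for occurrences of both monomers of a
#' TALEN pair with up to `max_mm` mismatches (default 2); every reported
#' locus must carry the 5' T on its strand. Opposite-strand hit
#' combinations whose gap falls in the spacer range are reported as paired
#' off-targets — the loci where FokI could dimerise and cut — excluding the
#' on-target pair itself.
#'
#' @param pair one-row data frame from [pair_talens()].
#' @param genome a `Genome`.
#' @param index a `SeedIndex` with `(max_mm + 1) * k <=` monomer length.
#' @param max_mm 0, 1 or 2 mismatches per monomer (default 2).
#' @param spacer_min,spacer_max paired off-target gap bounds (bp).
#' @return list with `monomer_hits` (hit data frame plus a `monomer`
#'   column, `"left"`/`"right"`, with `is_self` set at the on-target loci)
#'   and `paired` (data frame: chrom, left/right starts, mismatch counts,
#'   `gap_len`).
#' @export
find_talen_offtargets <- function(pair, genome, index, max_mm = 2L,
                                  spacer_min = 14L, spacer_max = 20L) {
  max_mm <- as.integer(max_mm)
  stopifnot(max_mm >= 0L, max_mm <= 2L)
  left <- find_monomer_hits(pair$left_seq[[1]], genome, index, max_mm)
  right <- find_monomer_hits(pair$right_seq[[1]], genome, index, max_mm)
  assemble_talen_offtargets(pair, left, right, spacer_min, spacer_max)
}

# ---------------------------------------------------------------------------
# Brute-force oracle (independent vectorised sweep; used in tests and as a
# reference path for small genomes)

## mismatch profile of query characters qch against every window of ch;
## returns integer vector over 1-based window starts
mismatch_profile <- function(ch, qch, starts) {
  m <- integer(length(starts))
  for (j in seq_along(qch)) m <- m + (ch[starts + j - 1L] != qch[j])
  m
}

#' Exhaustive off-target sweep (oracle)
#'
#' Scans every window of every sequence on both strands and applies the
#' same matching predicate as the indexed search, with no index and no
#' seeding. Quadratic and intended for verification on small genomes; the
#' indexed search must return exactly this hit set.
#'
#' @param query protospacer (kind `"crispr"`, 20 bp), monomer sequence
#'   (kind `"talen"`), or any sequence up to 40 bp (kind `"exact"`).
#' @param genome a `Genome`.
#' @param kind matching rule family: `"crispr"` (NGG PAM + mode),
#'   `"talen"` (5' T + mismatches), `"exact"` (exact occurrences, both
#'   strands — the primer-mapping predicate).
#' @param mode CRISPR mismatch model (see [find_crispr_offtargets()]).
#' @param max_mm maximum mismatches.
#' @return hit data frame in the same shape as [find_crispr_offtargets()].
#' @export
brute_force_offtargets <- function(query, genome,
                                   kind = c("crispr", "talen", "exact"),
                                   mode = CRISPR_MODES, max_mm = 2L) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  q <- toupper(query)
  stopifnot(nchar(q) <= 40)
  rows <- list()
  for (nm in names(genome$seq)) {
    rows[[nm]] <- switch(kind,
      crispr = bf_crispr_chrom(q, nm, genome$seq[[nm]], mode, max_mm),
      talen = bf_talen_chrom(q, nm, genome$seq[[nm]], max_mm),
      exact = bf_exact_chrom(q, nm, genome$seq[[nm]]))
  }
  finish_hits(unlist(rows, recursive = FALSE))
}

bf_crispr_chrom <- function(q, chrom, s, mode, max_mm) {
  n <- nchar(s)
  if (n < CRISPR_SITE_LEN) return(list())
  ch <- seq_chars(s)
  qch <- seq_chars(q)
  starts <- seq_len(n - CRISPR_SITE_LEN + 1L)     # 1-based site starts
  has_n <- window_has_n(ch, CRISPR_SITE_LEN)
  rows <- list()

  ## plus strand: protospacer at site start, PAM GG at offsets 21,22
  ok <- !has_n & ch[starts + 21L] == "G" & ch[starts + 22L] == "G"
  if (any(ok)) {
    st <- starts[ok]
    m_tot <- mismatch_profile(ch, qch, st)
    m_seed <- mismatch_profile(ch, qch[SEED_REGION], st + 9L)
    pass <- switch(mode,
                   all_upstream = m_tot <= max_mm,
                   seed_exact = m_tot <= max_mm & m_seed == 0L,
                   perfect_only = m_tot == 0L)
    for (i in which(pass)) {
      w <- st[i]
      mm <- which(ch[w:(w + 19L)] != qch)
      rows[[length(rows) + 1L]] <- hit_row(chrom, w - 1L, "+", mm)
    }
  }
  ## minus strand: plus bases CC at site start (revcomp of PAM GG);
  ## protospacer footprint = site offsets 3..22, compared to revcomp(q)
  qrc <- seq_chars(revcomp(q))
  ok <- !has_n & ch[starts] == "C" & ch[starts + 1L] == "C"
  if (any(ok)) {
    st <- starts[ok]
    m_tot <- mismatch_profile(ch, qrc, st + 3L)
    ## protospacer position p maps to plus offset 21-p within the footprint;
    ## seed positions 10..20 are footprint offsets 1..11
    m_seed <- mismatch_profile(ch, qrc[seq_len(11L)], st + 3L)
    pass <- switch(mode,
                   all_upstream = m_tot <= max_mm,
                   seed_exact = m_tot <= max_mm & m_seed == 0L,
                   perfect_only = m_tot == 0L)
    for (i in which(pass)) {
      w <- st[i]
      j <- which(ch[(w + 3L):(w + 22L)] != qrc)   # plus offsets 1..20
      rows[[length(rows) + 1L]] <- hit_row(chrom, w - 1L, "-",
                                           sort(21L - j))
    }
  }
  rows
}

bf_talen_chrom <- function(q, chrom, s, max_mm) {
  L <- nchar(q)
  n <- nchar(s)
  if (n < L) return(list())
  ch <- seq_chars(s)
  qch <- seq_chars(q)
  starts <- seq_len(n - L + 1L)
  has_n <- window_has_n(ch, L)
  rows <- list()
  ok <- !has_n & ch[starts] == "T"
  if (any(ok)) {
    st <- starts[ok]
    m <- mismatch_profile(ch, qch, st)
    for (i in which(m <= max_mm)) {
      w <- st[i]
      mm <- which(ch[w:(w + L - 1L)] != qch)
      rows[[length(rows) + 1L]] <- hit_row(chrom, w - 1L, "+", mm)
    }
  }
  qrc <- seq_chars(revcomp(q))
  ok <- !has_n & ch[starts + L - 1L] == "A"   # minus-strand 5' T
  if (any(ok)) {
    st <- starts[ok]
    m <- mismatch_profile(ch, qrc, st)
    for (i in which(m <= max_mm)) {
      w <- st[i]
      j <- which(ch[w:(w + L - 1L)] != qrc)
      rows[[length(rows) + 1L]] <- hit_row(chrom, w - 1L, "-",
                                           sort(L + 1L - j))
    }
  }
  rows
}

bf_exact_chrom <- function(q, chrom, s) {
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") q else revcomp(q)
    hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (hits[1] != -1L)
      for (h in as.integer(hits))
        rows[[length(rows) + 1L]] <- hit_row(chrom, h - 1L, strand,
                                             integer(0))
  }
  rows
}
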