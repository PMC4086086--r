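## Seeded synthetic genomes with planted on-/off-target structures and a
## machine-readable truth table, so discovery, off-target search, ranking
## and genotyping are all testable without any external downloads. The
## background is rejection-sampled so that no accidental near-match (<= 2
## mismatches, with the required context) of any planted query exists —
## the truth table is therefore exact.

#' Plant descriptors for [synth_genome()]
#'
#' Helpers building the individual plants of a [plant_spec()]:
#' `plant_crispr_site` places a 23 bp protospacer+PAM site;
#' `plant_crispr_decoy` places a mismatched copy of a planted site (edits
#' are `(protospacer position, base)` pairs, 1-based from the 5' end) with
#' an intact NGG PAM; `plant_talen_pair` places two 5'-T monomers around a
#' spacer; `plant_talen_decoy` places a mismatched copy of one monomer;
#' `plant_seq` places a verbatim sequence (amplicon duplicates, enzyme
#' sites, ...).
#'
#' @param position 0-based plus-strand start of the planted footprint.
#' @param strand strand of the planted element (`+`/`-`).
#' @param protospacer optional 20-mer; random (ACGT) when NULL.
#' @param pam optional PAM (default random base + GG).
#' @param id plant identifier; auto-assigned when NULL.
#' @param of id of the referenced site/pair plant for decoys.
#' @param edits list of `c(position, base)` pairs (positions 1-based,
#'   5'->3' in site orientation).
#' @param length TALEN monomer length.
#' @param spacer_len TALEN spacer length.
#' @param left_seq,right_seq optional monomer sequences (must start with T).
#' @param which which monomer of the referenced pair a TALEN decoy copies.
#' @param sequence verbatim plus-strand sequence for `plant_seq`.
#' @return a plant descriptor (list) for [plant_spec()].
#' @name plants
NULL

#' @rdname plants
#' @export
plant_crispr_site <- function(position, strand = "+", protospacer = NULL,
                              pam = NULL, id = NULL) {
  list(kind = "crispr_site", position = as.integer(position),
       strand = strand, protospacer = protospacer, pam = pam, id = id)
}

#' @rdname plants
#' @export
plant_crispr_decoy <- function(of, position, strand = "+", edits = list(),
                               pam = NULL, id = NULL) {
  list(kind = "crispr_decoy", of = of, position = as.integer(position),
       strand = strand, edits = edits, pam = pam, id = id)
}

#' @rdname plants
#' @export
plant_talen_pair <- function(position, length = 15L, spacer_len = 16L,
                             left_seq = NULL, right_seq = NULL, id = NULL) {
  list(kind = "talen_pair", position = as.integer(position),
       length = as.integer(length), spacer_len = as.integer(spacer_len),
       left_seq = left_seq, right_seq = right_seq, id = id)
}

#' @rdname plants
#' @export
plant_talen_decoy <- function(of, which = c("left", "right"), position,
                              strand = "+", edits = list(), id = NULL) {
  list(kind = "talen_decoy", of = of, which = match.arg(which),
       position = as.integer(position), strand = strand, edits = edits,
       id = id)
}

#' @rdname plants
#' @export
plant_seq <- function(position, sequence, id = NULL) {
  list(kind = "seq", position = as.integer(position),
       sequence = toupper(sequence), id = id)
}

#' Specification of a synthetic genome
#'
#' @param genome_length background length in bp.
#' @param seed RNG seed; the same spec always yields the same genome.
#' @param plants list of plant descriptors (see [plants]).
#' @param gc background GC fraction (default 0.5, uniform bases).
#' @param chrom name of the single synthetic sequence.
#' @return a `PlantSpec` list for [synth_genome()].
#' @export
plant_spec <- function(genome_length, seed, plants = list(), gc = 0.5,
                       chrom = "chrS") {
  structure(list(genome_length = as.integer(genome_length),
                 seed = as.integer(seed), plants = plants, gc = gc,
                 chrom = chrom),
            class = "PlantSpec")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

apply_edits <- function(seq, edits) {
  for (e in edits) {
    pos <- as.integer(e[[1]]); base <- toupper(e[[2]])
    stopifnot(pos >= 1, pos <= nchar(seq), base %in% DNA_BASES)
    if (substr(seq, pos, pos) == base)
      stop("edit at position ", pos, " does not change the base")
    substr(seq, pos, pos) <- base
  }
  seq
}

## resolve one plant into concrete plus-strand insertions + truth rows
materialize_plant <- function(p, resolved, gc) {
  id <- p$id %||% paste0("p", length(resolved$truth) + 1L)
  ins <- list(); truth <- list()
  if (p$kind == "crispr_site") {
    proto <- toupper(p$protospacer %||% random_dna(PROTOSPACER_LEN, gc))
    pam <- toupper(p$pam %||% paste0(sample(DNA_BASES, 1), "GG"))
    site <- paste0(proto, pam)
    plus <- if (p$strand == "+") site else revcomp(site)
    ins[[1]] <- list(pos = p$position, seq = plus)
    truth[[1]] <- data.frame(id = id, kind = p$kind, of = "",
                             start = p$position,
                             end = p$position + CRISPR_SITE_LEN,
                             strand = p$strand, sequence = site,
                             n_edits = 0L, edit_positions = "",
                             stringsAsFactors = FALSE)
  } else if (p$kind == "crispr_decoy") {
    ref <- resolved$by_id[[p$of]]
    if (is.null(ref)) stop("decoy references unknown plant: ", p$of)
    proto <- apply_edits(substr(ref$sequence, 1, PROTOSPACER_LEN), p$edits)
    pam <- toupper(p$pam %||% paste0(sample(DNA_BASES, 1), "GG"))
    site <- paste0(proto, pam)
    plus <- if (p$strand == "+") site else revcomp(site)
    ins[[1]] <- list(pos = p$position, seq = plus)
    ep <- vapply(p$edits, function(e) as.integer(e[[1]]), integer(1))
    truth[[1]] <- data.frame(id = id, kind = p$kind, of = p$of,
                             start = p$position,
                             end = p$position + CRISPR_SITE_LEN,
                             strand = p$strand, sequence = site,
                             n_edits = length(p$edits),
                             edit_positions = paste(sort(ep), collapse = ","),
                             stringsAsFactors = FALSE)
  } else if (p$kind == "talen_pair") {
    L <- p$length
    left <- toupper(p$left_seq %||%
                      paste0("T", random_dna(L - 1L, gc)))
    right <- toupper(p$right_seq %||%
                       paste0("T", random_dna(L - 1L, gc)))
    if (substr(left, 1, 1) != "T" || substr(right, 1, 1) != "T")
      stop("TALEN monomer sequences must start with T")
    spacer <- random_dna(p$spacer_len, gc)
    plus <- paste0(left, spacer, revcomp(right))
    ins[[1]] <- list(pos = p$position, seq = plus)
    truth[[1]] <- data.frame(id = id, kind = p$kind, of = "",
                             start = p$position,
                             end = p$position + nchar(plus),
                             strand = "+",
                             sequence = paste(left, right, sep = "|"),
                             n_edits = 0L,
                             edit_positions = as.character(p$spacer_len),
                             stringsAsFactors = FALSE)
  } else if (p$kind == "talen_decoy") {
    ref <- resolved$by_id[[p$of]]
    if (is.null(ref)) stop("decoy references unknown plant: ", p$of)
    mono <- strsplit(ref$sequence, "|", fixed = TRUE)[[1]]
    seq <- apply_edits(mono[if (p$which == "left") 1 else 2], p$edits)
    plus <- if (p$strand == "+") seq else revcomp(seq)
    ins[[1]] <- list(pos = p$position, seq = plus)
    ep <- vapply(p$edits, function(e) as.integer(e[[1]]), integer(1))
    truth[[1]] <- data.frame(id = id, kind = p$kind, of = p$of,
                             start = p$position,
                             end = p$position + nchar(seq),
                             strand = p$strand, sequence = seq,
                             n_edits = length(p$edits),
                             edit_positions = paste(sort(ep), collapse = ","),
                             stringsAsFactors = FALSE)
  } else if (p$kind == "seq") {
    ins[[1]] <- list(pos = p$position, seq = p$sequence)
    truth[[1]] <- data.frame(id = id, kind = "seq", of = "",
                             start = p$position,
                             end = p$position + nchar(p$sequence),
                             strand = "+", sequence = p$sequence,
                             n_edits = 0L, edit_positions = "",
                             stringsAsFactors = FALSE)
  } else stop("unknown plant kind: ", p$kind)
  list(id = id, insertions = ins, truth = truth[[1]])
}

#' Generate a synthetic genome with planted structures
#'
#' Draws a seeded random background, writes each plant at its position, and
#' verifies by brute force that the background contains no accidental
#' near-match (within 2 mismatches, with the required PAM / 5'-T context)
#' of any planted protospacer or monomer; if it does, the background is
#' resampled (plants kept fixed). Overlapping plants are an error.
#'
#' @param spec a [plant_spec()].
#' @param max_attempts background resampling attempts before giving up.
#' @return list with `genome` (a `Genome`), `truth` (data frame, one row
#'   per plant: id, kind, reference, interval, strand, planted sequence in
#'   site orientation, edit count and positions).
#' @export
synth_genome <- function(spec, max_attempts = 50L) {
  stopifnot(inherits(spec, "PlantSpec"))
  with_seed(spec$seed, {
    ## materialize plants once (their random parts are seed-determined)
    resolved <- list(by_id = list(), truth = list())
    all_ins <- list()
    for (p in spec$plants) {
      m <- materialize_plant(p, resolved, spec$gc)
      resolved$by_id[[m$id]] <- m$truth
      resolved$truth[[m$id]] <- m$truth
      all_ins <- c(all_ins, m$insertions)
    }
    truth <- if (length(resolved$truth) > 0)
      do.call(rbind, unname(resolved$truth))
    else data.frame(id = character(0), kind = character(0), of = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), sequence = character(0),
                    n_edits = integer(0), edit_positions = character(0),
                    stringsAsFactors = FALSE)
    ## overlap check
    if (length(all_ins) > 1) {
      iv <- t(vapply(all_ins, function(i)
        c(i$pos, i$pos + nchar(i$seq)), numeric(2)))
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping plants in spec")
    }
    for (i in all_ins)
      if (i$pos < 0 || i$pos + nchar(i$seq) > spec$genome_length)
        stop("plant outside genome bounds")

    for (attempt in seq_len(max_attempts)) {
      bg <- random_dna(spec$genome_length, spec$gc)
      for (i in all_ins)
        substr(bg, i$pos + 1L, i$pos + nchar(i$seq)) <- i$seq
      genome <- new_genome(setNames(bg, spec$chrom))
      if (background_clean(genome, truth)) {
        return(list(genome = genome, truth = truth))
      }
    }
    stop("could not sample a clean background in ", max_attempts,
         " attempts; genome too small for the planted queries?")
  })
}

## no off-target hit of any planted query outside the planted footprints
background_clean <- function(genome, truth) {
  queries <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$kind %in% c("crispr_site")) {
      queries[[length(queries) + 1L]] <-
        list(kind = "crispr", q = substr(row$sequence, 1, PROTOSPACER_LEN))
    } else if (row$kind == "talen_pair") {
      mono <- strsplit(row$sequence, "|", fixed = TRUE)[[1]]
      queries[[length(queries) + 1L]] <- list(kind = "talen", q = mono[1])
      queries[[length(queries) + 1L]] <- list(kind = "talen", q = mono[2])
    }
  }
  if (length(queries) == 0) return(TRUE)
  planted <- truth[, c("start", "end")]
  for (qu in queries) {
    hits <- brute_force_offtargets(qu$q, genome, kind = qu$kind,
                                   mode = "all_upstream", max_mm = 2L)
    if (nrow(hits) == 0) next
    w <- if (qu$kind == "crispr") CRISPR_SITE_LEN else nchar(qu$q)
    ok <- vapply(seq_len(nrow(hits)), function(j)
      any(hits$start[j] < planted$end & hits$start[j] + w > planted$start),
      logical(1))
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

#' Generate synthetic gene models
#'
#' Places `n_genes` non-overlapping multi-exon transcripts (2-4 exons,
#' alternating strands, CDS inside the exon span) across the genome's first
#' sequence.
#'
#' @param genome a `Genome`.
#' @param n_genes number of models.
#' @param seed RNG seed.
#' @return list of `GeneModel`s.
#' @export
synth_gene_table <- function(genome, n_genes, seed = 1L) {
  if (n_genes == 0) return(list())
  chrom <- names(genome$seq)[1]
  n <- genome$lengths[[chrom]]
  slot <- n %/% n_genes
  if (slot < 1200)
    stop("genome too small for ", n_genes, " genes (need >= 1200 bp each)")
  with_seed(seed, {
    models <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      base <- (g - 1L) * slot
      n_ex <- sample(2:4, 1)
      pos <- base + sample(50:150, 1)
      exons <- matrix(0L, n_ex, 2)
      for (e in seq_len(n_ex)) {
        len <- sample(80:200, 1)
        exons[e, ] <- c(pos, pos + len)
        pos <- pos + len + sample(60:150, 1)   # intron
      }
      exons[n_ex, 2] <- min(exons[n_ex, 2], base + slot - 50L)
      strand <- if (g %% 2 == 1) "+" else "-"
      cds_start <- exons[1, 1] + sample(10:40, 1)
      cds_end <- exons[n_ex, 2] - sample(10:40, 1)
      models[[g]] <- new_gene_model(
        gene_name = paste0("gene", g),
        transcript_id = paste0("gene", g, ".t1"),
        chrom = chrom, strand = strand, exons = exons,
        cds_start = cds_start, cds_end = cds_end)
    }
    models
  })
}

#' Write fixture files
#'
#' Writes a genome (FASTA), gene models (refFlat TSV) and truth table (TSV)
#' into a directory, for tests that exercise the file-based interfaces.
#'
#' @param genome a `Genome`.
#' @param models list of `GeneModel`s (may be empty).
#' @param truth truth data frame from [synth_genome()] (may be NULL).
#' @param dir output directory (created if needed).
#' @return named list of the file paths written.
#' @export
write_fixture <- function(genome, models = list(), truth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), fasta)
  paths <- list(fasta = fasta)
  if (length(models) > 0) {
    rf <- file.path(dir, "genes.refflat")
    writeLines(vapply(models, refflat_line, character(1)), rf)
    paths$gene_table <- rf
  }
  if (!is.null(truth)) {
    tt <- file.path(dir, "truth.tsv")
    write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth <- tt
  }
  paths
}

refflat_line <- function(m) {
  span <- tx_span(m)
  cds <- if (is.na(m$cds_start)) c(span[2], span[2]) else
    c(m$cds_start, m$cds_end)
  paste(m$gene_name, m$transcript_id, m$chrom, m$strand, span[1], span[2],
        cds[1], cds[2], nrow(m$exons),
        paste0(paste(m$exons[, 1], collapse = ","), ","),
        paste0(paste(m$exons[, 2], collapse = ","), ","),
        sep = "\t")
}
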