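## Genome and gene-model input, query resolution, sub-region extraction.
## All internal coordinates are 0-based half-open; user-facing strings
## ("chrom:start-end") are 1-based inclusive.

#' Load a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a `Genome` object: a set of named
#' uppercase DNA sequences over the alphabet A/C/G/T/N. Lowercase input is
#' uppercased; IUPAC degeneracy codes other than N are mapped to N with a
#' warning (degenerate bases cannot be targeted and are treated as
#' unmatchable).
#'
#' @param path path to a FASTA file.
#' @return a `Genome` object (named sequences plus their lengths).
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ## readDNAStringSet keeps the full header line; sequence name = first token
  nms <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  if (anyNA(nms) || any(nms == ""))
    stop("malformed FASTA header (empty sequence name)")
  if (anyDuplicated(nms))
    stop("duplicate sequence name in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  degen <- grepl("[^ACGTN]", seqs)
  if (any(degen)) {
    warning("non-ACGTN IUPAC bases in sequence(s) ",
            paste(nms[degen], collapse = ", "), " mapped to N")
    seqs[degen] <- gsub("[^ACGTN]", "N", seqs[degen])
  }
  new_genome(seqs)
}

#' Construct a Genome from named character sequences
#'
#' @param seqs named character vector of uppercase DNA strings (A/C/G/T/N).
#' @return a `Genome` object.
#' @export
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("Genome sequences must be over {A,C,G,T,N}")
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$seq), "sequence(s),",
      sum(as.numeric(x$lengths)), "bp total\n")
  for (nm in head(names(x$seq), 10))
    cat("  ", nm, ": ", x$lengths[[nm]], " bp\n", sep = "")
  invisible(x)
}

## extract genome slice, 0-based half-open
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) stop("unknown sequence: ", chrom)
  n <- genome$lengths[[chrom]]
  if (start < 0 || end > n || end <= start)
    stop(sprintf("coordinates %d-%d out of bounds for %s (length %d)",
                 start, end, chrom, n))
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Load gene models from a refFlat or BED12 table
#'
#' Parses transcript models into a list of `GeneModel` records with 0-based
#' half-open exon intervals. refFlat is the UCSC 11-column dialect
#' (geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds); BED12 uses blockSizes/blockStarts
#' relative to chromStart, with thickStart/thickEnd as the CDS. Rows whose
#' exon list cannot be ordered into non-overlapping ascending intervals are
#' skipped with a warning.
#'
#' @param path path to the table (TSV, no header; `#` comment lines ignored).
#' @param format `"refFlat"` or `"bed12"`.
#' @return list of `GeneModel` objects.
#' @export
load_gene_table <- function(path, format = c("refFlat", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  models <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    m <- tryCatch(
      if (format == "refFlat") parse_refflat_row(f) else parse_bed12_row(f),
      error = function(e) {
        warning("skipping gene-table row ", i, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  models
}

int_list_field <- function(x) {
  as.integer(strsplit(sub(",$", "", x), ",")[[1]])
}

validate_exons <- function(starts, ends) {
  if (length(starts) != length(ends) || length(starts) == 0)
    stop("exon start/end count mismatch")
  starts <- as.integer(starts); ends <- as.integer(ends)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(ends <= starts)) stop("empty or inverted exon")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("overlapping exons")
  cbind(start = starts, end = ends)
}

parse_refflat_row <- function(f) {
  if (length(f) < 11) stop("refFlat row needs 11 fields")
  exons <- validate_exons(int_list_field(f[10]), int_list_field(f[11]))
  cds_start <- as.integer(f[7]); cds_end <- as.integer(f[8])
  if (cds_start >= cds_end) { cds_start <- NA_integer_; cds_end <- NA_integer_ }
  new_gene_model(gene_name = f[1], transcript_id = f[2], chrom = f[3],
                 strand = f[4], exons = exons,
                 cds_start = cds_start, cds_end = cds_end)
}

parse_bed12_row <- function(f) {
  if (length(f) < 12) stop("BED12 row needs 12 fields")
  chrom_start <- as.integer(f[2])
  sizes <- int_list_field(f[11]); offsets <- int_list_field(f[12])
  if (length(sizes) != as.integer(f[10])) stop("blockCount mismatch")
  starts <- chrom_start + offsets
  exons <- validate_exons(starts, starts + sizes)
  cds_start <- as.integer(f[7]); cds_end <- as.integer(f[8])
  if (cds_start >= cds_end) { cds_start <- NA_integer_; cds_end <- NA_integer_ }
  new_gene_model(gene_name = f[4], transcript_id = f[4], chrom = f[1],
                 strand = f[6], exons = exons,
                 cds_start = cds_start, cds_end = cds_end)
}

#' Construct a GeneModel
#'
#' @param gene_name,transcript_id identifiers.
#' @param chrom,strand location (`+` or `-`).
#' @param exons two-column integer matrix of 0-based half-open exon
#'   intervals, sorted ascending and non-overlapping.
#' @param cds_start,cds_end CDS bounds (0-based half-open) or NA for
#'   non-coding transcripts.
#' @return a `GeneModel` object.
#' @export
new_gene_model <- function(gene_name, transcript_id, chrom, strand, exons,
                           cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- validate_exons(exons[, 1], exons[, 2])
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (!is.na(cds_start) &&
      (cds_start < exons[1, 1] || cds_end > exons[nrow(exons), 2]))
    stop("CDS outside exon span")
  structure(list(gene_name = gene_name, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "GeneModel")
}

tx_span <- function(model) c(model$exons[1, 1], model$exons[nrow(model$exons), 2])

exonic_length <- function(model) sum(model$exons[, 2] - model$exons[, 1])

#' Construct a TargetRegion
#'
#' @param chrom sequence name (`"query"` for pasted sequence).
#' @param start,end 0-based half-open bounds.
#' @param sequence the region's DNA.
#' @param source one of `"gene"`, `"coordinates"`, `"raw"`.
#' @return a `TargetRegion` object.
#' @export
new_target_region <- function(chrom, start, end, sequence,
                              source = c("coordinates", "gene", "raw")) {
  source <- match.arg(source)
  stopifnot(end > start, nchar(sequence) == end - start)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), sequence = toupper(sequence),
                 source = source),
            class = "TargetRegion")
}

#' @export
print.TargetRegion <- function(x, ...) {
  cat("TargetRegion ", format_region(x$chrom, x$start, x$end),
      " (", x$end - x$start, " bp, source=", x$source, ")\n", sep = "")
  invisible(x)
}

#' Resolve a query to a target region
#'
#' Accepts the three query forms users write: a gene name (resolved through
#' the gene models, using the longest transcript by exonic length when
#' several share the name), a `"chrom:start-end"` coordinate string (1-based
#' inclusive), or a pasted raw DNA sequence of at least 23 bp (returned as a
#' synthetic region named `"query"`).
#'
#' @param query query string.
#' @param genome a `Genome` (may be NULL for raw-sequence queries).
#' @param models list of `GeneModel`s (for gene-name queries).
#' @param sub_region optional sub-region filter passed to
#'   [extract_subregion()]; the resolved region is narrowed to the span of
#'   the filtered intervals.
#' @return a `TargetRegion`.
#' @export
resolve_query <- function(query, genome = NULL, models = list(),
                          sub_region = NULL) {
  query <- trimws(query)
  coord <- regmatches(query,
                      regexec("^([^:]+):([0-9]+)-([0-9]+)$", query))[[1]]
  if (length(coord) == 4) {
    if (is.null(genome)) stop("coordinate query requires a genome")
    chrom <- coord[2]
    start <- as.integer(coord[3]) - 1L   # 1-based inclusive -> 0-based
    end <- as.integer(coord[4])
    seq <- genome_slice(genome, chrom, start, end)
    return(new_target_region(chrom, start, end, seq, "coordinates"))
  }
  if (grepl("^[ACGTNacgtn]+$", query) && nchar(query) >= 23 &&
      !query_is_gene(query, models)) {
    return(new_target_region("query", 0L, nchar(query), toupper(query), "raw"))
  }
  if (grepl("^[A-Za-z]+$", query) && grepl("^[ACGTNacgtn]+$", query) &&
      !query_is_gene(query, models)) {
    stop("raw sequence query must be at least 23 bp (got ", nchar(query), ")")
  }
  model <- lookup_gene(query, models)
  if (is.null(genome)) stop("gene query requires a genome")
  span <- tx_span(model)
  if (!is.null(sub_region)) {
    ivs <- extract_subregion(model, sub_region)
    if (nrow(ivs) == 0)
      stop("sub-region filter yields no intervals for ", query)
    span <- c(min(ivs[, 1]), max(ivs[, 2]))
  }
  seq <- genome_slice(genome, model$chrom, span[1], span[2])
  new_target_region(model$chrom, span[1], span[2], seq, "gene")
}

query_is_gene <- function(query, models) {
  any(vapply(models, function(m)
    identical(toupper(m$gene_name), toupper(query)) ||
    identical(toupper(m$transcript_id), toupper(query)), logical(1)))
}

lookup_gene <- function(name, models) {
  hits <- Filter(function(m)
    identical(toupper(m$gene_name), toupper(name)) ||
    identical(toupper(m$transcript_id), toupper(name)), models)
  if (length(hits) == 0) {
    all_names <- unique(unlist(lapply(models, function(m)
      c(m$gene_name, m$transcript_id))))
    near <- all_names[agrepl(name, all_names, ignore.case = TRUE,
                             max.distance = 0.3)]
    stop("unknown gene '", name, "'",
         if (length(near) > 0)
           paste0("; did you mean: ", paste(head(near, 5), collapse = ", "))
         else "")
  }
  if (length(hits) > 1) {
    lens <- vapply(hits, exonic_length, numeric(1))
    pick <- which.max(lens)
    message("gene '", name, "' has ", length(hits),
            " transcripts; using longest by exonic length: ",
            hits[[pick]]$transcript_id)
    hits[[pick]]
  } else hits[[1]]
}

#' Extract gene sub-regions
#'
#' Returns the genomic intervals selected by a sub-region filter on a
#' transcript model. Supported filters: `"five_prime_utr"`,
#' `"three_prime_utr"`, `"cds"`, `"exons"` (full exons including UTRs),
#' `"splice_sites"` (windows of `splice_halfwidth` bp on each side of every
#' intron/exon boundary), or a list `list(exon_subset = indices)` with
#' 1-based exon indices in transcript orientation (exon 1 is the 5'-most
#' exon of the transcript, i.e. the last genomic exon on the minus strand).
#'
#' @param model a `GeneModel`.
#' @param filter filter name or `list(exon_subset = indices)`.
#' @param splice_halfwidth half-width of each splice-site window (bp).
#' @return two-column matrix of 0-based half-open intervals (possibly empty),
#'   sorted and non-overlapping.
#' @export
extract_subregion <- function(model, filter, splice_halfwidth = 20L) {
  ex <- model$exons
  n_ex <- nrow(ex)
  empty <- cbind(start = integer(0), end = integer(0))
  if (is.list(filter) && !is.null(filter$exon_subset)) {
    idx <- as.integer(filter$exon_subset)
    if (any(idx < 1 | idx > n_ex))
      stop("exon index out of range (transcript has ", n_ex, " exons)")
    genomic_idx <- if (model$strand == "+") idx else n_ex + 1L - idx
    ivs <- ex[sort(unique(genomic_idx)), , drop = FALSE]
    return(ivs)
  }
  filter <- match.arg(filter, c("five_prime_utr", "three_prime_utr",
                                "splice_sites", "exons", "cds"))
  if (filter == "exons") return(ex)
  if (filter == "splice_sites") {
    if (n_ex < 2) return(empty)
    span <- tx_span(model)
    bounds <- c(ex[-n_ex, 2], ex[-1, 1])   # exon ends + exon starts at introns
    ivs <- cbind(start = pmax(bounds - splice_halfwidth, span[1]),
                 end = pmin(bounds + splice_halfwidth, span[2]))
    return(merge_intervals(ivs))
  }
  if (is.na(model$cds_start)) {
    warning("transcript ", model$transcript_id, " is non-coding; ", filter,
            " filter yields no intervals")
    return(empty)
  }
  if (filter == "cds")
    return(intersect_intervals(ex, model$cds_start, model$cds_end))
  ## UTRs: genomic-left of CDS is 5' UTR on plus strand, 3' UTR on minus
  left <- intersect_intervals(ex, tx_span(model)[1], model$cds_start)
  right <- intersect_intervals(ex, model$cds_end, tx_span(model)[2])
  if ((filter == "five_prime_utr") == (model$strand == "+")) left else right
}

intersect_intervals <- function(ivs, lo, hi) {
  s <- pmax(ivs[, 1], lo); e <- pmin(ivs[, 2], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

merge_intervals <- function(ivs) {
  if (nrow(ivs) <= 1) return(ivs)
  o <- order(ivs[, 1])
  ivs <- ivs[o, , drop = FALSE]
  out <- ivs[1, , drop = FALSE]
  for (i in 2:nrow(ivs)) {
    if (ivs[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], ivs[i, 2])
    else out <- rbind(out, ivs[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
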