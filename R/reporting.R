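## Report writers (TSV + GenBank) and the command-line entry point.
## All printed coordinates are 1-based inclusive; all outputs are
## byte-deterministic for a given configuration and input.

CRISPR_REPORT_COLS <- c("rank", "target_seq", "chrom", "start_1based",
                        "strand", "exon", "gc_percent", "mm0", "mm1", "mm2")
TALEN_REPORT_COLS <- c("rank", "left_seq", "right_seq", "spacer_len",
                       "rvds_left", "rvds_right", "spacer_enzymes",
                       "paired_offtargets", "mm0", "mm1", "mm2")

#' Write the ranked results table
#'
#' TSV report mirroring the on-screen results table. CRISPR rows carry the
#' full 23 bp site (protospacer + PAM), location, exon, GC content and the
#' 0/1/2-mismatch off-target tallies; TALEN rows carry both monomer
#' sequences, the spacer length, RVD strings, enzymes cutting in the
#' spacer, and paired/monomer off-target counts.
#'
#' @param ranked ranked data frame from [crispr_pipeline()] or
#'   [talen_pipeline()] (may be empty: a header-only file is written).
#' @param path output file.
#' @param mode `"crispr"` or `"talen"`.
#' @return the path, invisibly.
#' @export
write_results_table <- function(ranked, path, mode = c("crispr", "talen")) {
  mode <- match.arg(mode)
  if (mode == "crispr") {
    df <- data.frame(rank = ranked$rank,
                     target_seq = paste0(ranked$protospacer, ranked$pam),
                     chrom = ranked$chrom, start_1based = ranked$start + 1L,
                     strand = ranked$strand,
                     exon = ranked$exon %||% NA_integer_,
                     gc_percent = ranked$gc_percent,
                     mm0 = ranked$n0, mm1 = ranked$n1, mm2 = ranked$n2,
                     stringsAsFactors = FALSE)
    if (nrow(ranked) == 0) df <- df[0, CRISPR_REPORT_COLS]
  } else {
    df <- data.frame(rank = ranked$rank, left_seq = ranked$left_seq,
                     right_seq = ranked$right_seq,
                     spacer_len = ranked$spacer_len,
                     rvds_left = ranked$rvds_left,
                     rvds_right = ranked$rvds_right,
                     spacer_enzymes = ranked$spacer_enzymes,
                     paired_offtargets = ranked$paired_offtargets,
                     mm0 = ranked$n0, mm1 = ranked$n1, mm2 = ranked$n2,
                     stringsAsFactors = FALSE)
    if (nrow(ranked) == 0) df <- df[0, TALEN_REPORT_COLS]
  }
  write_tsv(df, path)
}

#' Write the per-candidate off-target detail table
#'
#' One row per off-target hit: which candidate it belongs to, genomic
#' location (1-based), strand, mismatch count and the 1-based positions of
#' the mismatches within the protospacer/monomer, and whether the row is
#' the candidate's own locus.
#'
#' @param offtargets named list of hit data frames (CRISPR) or of
#'   `monomer_hits`/`paired` lists (TALEN), as returned by the pipelines.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_offtarget_table <- function(offtargets, path) {
  rows <- list()
  for (id in names(offtargets)) {
    h <- offtargets[[id]]
    if (is.list(h) && !is.data.frame(h)) h <- h$monomer_hits
    if (nrow(h) == 0) next
    rows[[id]] <- data.frame(candidate = id, chrom = h$chrom,
                             start_1based = h$start + 1L, strand = h$strand,
                             mismatches = h$mismatches,
                             positions = h$positions, is_self = h$is_self,
                             stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(candidate = character(0), chrom = character(0),
               start_1based = integer(0), strand = character(0),
               mismatches = integer(0), positions = character(0),
               is_self = logical(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")   # binary: byte-identical across platforms
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenBank writer

gb_location <- function(start1, end1, strand) {
  loc <- sprintf("%d..%d", start1, end1)
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

gb_feature <- function(key, start1, end1, strand, qualifiers) {
  lines <- sprintf("     %-16s%s", key, gb_location(start1, end1, strand))
  for (q in names(qualifiers))
    lines <- c(lines, sprintf("                     /%s=\"%s\"", q,
                              qualifiers[[q]]))
  lines
}

gb_origin <- function(seq) {
  n <- nchar(seq)
  lines <- character(0)
  for (off in seq(1, n, by = 60)) {
    chunk <- substr(seq, off, min(off + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off,
                              paste(tolower(groups), collapse = " ")))
  }
  lines
}

#' Write an annotated GenBank flat file
#'
#' Writes the region sequence with `misc_feature` records for candidate
#' target sites (labelled by rank) and restriction sites, and
#' `primer_bind` records for primers. Coordinates are 1-based inclusive
#' and minus-strand features use `complement()`. With
#' `include_introns = FALSE` the exons of `model` are spliced together and
#' features are remapped onto the spliced sequence; features not fully
#' inside one exon are dropped with a warning.
#'
#' @param region a `TargetRegion`.
#' @param annotations list with any of `targets`, `primers`, `sites`: data
#'   frames with columns `start`, `end` (0-based half-open genomic),
#'   `strand`, `label`.
#' @param path output file.
#' @param include_introns keep the full genomic sequence (default) or
#'   splice to exons of `model`.
#' @param model `GeneModel` required when `include_introns = FALSE`.
#' @param name LOCUS name.
#' @return the path, invisibly.
#' @export
write_genbank <- function(region, annotations = list(), path,
                          include_introns = TRUE, model = NULL,
                          name = region$chrom) {
  seq <- region$sequence
  ## feature coordinates local to the written sequence, 0-based half-open
  remap <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), label = character(0),
                        stringsAsFactors = FALSE))
    if (any(df$start < region$start | df$end > region$end))
      stop("annotation outside the region bounds")
    df$start <- df$start - region$start
    df$end <- df$end - region$start
    df
  }
  feats <- lapply(annotations, remap)
  if (!include_introns) {
    if (is.null(model)) stop("include_introns = FALSE requires a gene model")
    ex <- model$exons
    ex[, 1] <- pmax(ex[, 1], region$start); ex[, 2] <- pmin(ex[, 2], region$end)
    ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
    local_ex <- ex - region$start
    seq <- paste(substring(region$sequence, local_ex[, 1] + 1L,
                           local_ex[, 2]), collapse = "")
    offsets <- cumsum(c(0L, local_ex[, 2] - local_ex[, 1]))
    remap_spliced <- function(df) {
      keep <- logical(nrow(df))
      for (i in seq_len(nrow(df))) {
        e <- which(df$start[i] >= local_ex[, 1] & df$end[i] <= local_ex[, 2])
        if (length(e) > 0) {
          keep[i] <- TRUE
          shift <- offsets[e[1]] - local_ex[e[1], 1]
          df$start[i] <- df$start[i] + shift
          df$end[i] <- df$end[i] + shift
        }
      }
      if (any(!keep))
        warning(sum(!keep), " feature(s) not fully within one exon dropped",
                " from spliced GenBank output")
      df[keep, , drop = FALSE]
    }
    feats <- lapply(feats, remap_spliced)
  }
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN 01-JAN-1980",
            substr(name, 1, 16), n),
    sprintf("DEFINITION  target region %s.",
            format_region(region$chrom, region$start, region$end)),
    sprintf("ACCESSION   %s", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", n)))
  emit <- function(df, key, note) {
    out <- character(0)
    if (nrow(df) == 0) return(out)
    for (i in seq_len(nrow(df)))
      out <- c(out, gb_feature(key, df$start[i] + 1L, df$end[i],
                               df$strand[i],
                               list(label = df$label[i], note = note)))
    out
  }
  lines <- c(lines,
             emit(feats$targets %||% remap(NULL), "misc_feature",
                  "candidate target site"),
             emit(feats$primers %||% remap(NULL), "primer_bind",
                  "genotyping primer"),
             emit(feats$sites %||% remap(NULL), "misc_feature",
                  "restriction site"),
             "ORIGIN", gb_origin(seq), "//")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Command-line entry point

usage_error <- function(msg) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
data_error <- function(msg) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

cli_defaults <- function() {
  list(query = NULL, genome = NULL, gene_table = NULL,
       gene_table_format = "refFlat", mode = "crispr",
       offtarget_mode = "all", max_mm = 2L, five_prime = "none",
       spacer_min = 14L, spacer_max = 20L, monomer_length = 15L,
       g_rvd = "NN", sub_region = NULL,
       primer_size_min = 18L, primer_size_max = 25L, primer_size_opt = 22L,
       product_min = 150L, product_max = 290L,
       tm_min = 57, tm_max = 63, tm_opt = 60, primer_min_dist = 50L,
       enzymes = "default", min_site_len = 4L, out = NULL, verbose = 0L)
}

parse_cli_args <- function(args) {
  cfg <- cli_defaults()
  int_opts <- c("max_mm", "spacer_min", "spacer_max", "monomer_length",
                "primer_size_min", "primer_size_max", "primer_size_opt",
                "product_min", "product_max", "primer_min_dist",
                "min_site_len", "verbose")
  num_opts <- c("tm_min", "tm_max", "tm_opt")
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!grepl("^--", a)) usage_error(paste("unexpected argument:", a))
    key <- gsub("-", "_", sub("^--", "", a))
    if (key == "config") {
      if (i == length(args)) usage_error("--config needs a value")
      cfg <- modifyList(cfg, read_config(args[i + 1L]))
      i <- i + 2L
      next
    }
    if (!key %in% names(cfg)) usage_error(paste("unknown option:", a))
    if (i == length(args)) usage_error(paste(a, "needs a value"))
    val <- args[i + 1L]
    if (key %in% int_opts) val <- as.integer(val)
    else if (key %in% num_opts) val <- as.numeric(val)
    if (length(val) != 1 || is.na(val))
      usage_error(paste("bad value for", a))
    cfg[[key]] <- val
    i <- i + 2L
  }
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$genome)) usage_error("--genome FASTA is required")
  if (is.null(cfg$query)) usage_error("--query is required")
  if (is.null(cfg$out)) usage_error("--out DIR is required")
  if (!cfg$mode %in% c("crispr", "talen"))
    usage_error("--mode must be crispr or talen")
  if (!cfg$offtarget_mode %in% c("all", "seed", "perfect"))
    usage_error("--offtarget-mode must be all, seed or perfect")
  if (!cfg$five_prime %in% c("none", "GG", "GN"))
    usage_error("--five-prime must be none, GG or GN")
  if (!cfg$g_rvd %in% c("NN", "NH"))
    usage_error("--g-rvd must be NN or NH")
  if (cfg$spacer_min > cfg$spacer_max)
    usage_error("--spacer-min must not exceed --spacer-max")
  if (cfg$max_mm < 0 || cfg$max_mm > 3)
    usage_error("--max-mm must be in 0..3")
  if (cfg$mode == "talen" && cfg$max_mm > 2)
    usage_error("--max-mm must be in 0..2 for TALEN mode")
  if (cfg$monomer_length < 10 || cfg$monomer_length > 30)
    usage_error("--monomer-length must be in 10..30")
  invisible(cfg)
}

#' Write a key=value configuration file
#'
#' @param cfg configuration list.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  keys <- sort(names(cfg))
  vals <- vapply(keys, function(k)
    if (is.null(cfg[[k]])) "" else as.character(cfg[[k]]), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(keys, "=", vals), con)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' @param path file written by [write_config()] (or by hand).
#' @return named list of options (types coerced by [run_cli()]'s parser
#'   rules).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) usage_error(paste("config file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    if (val == "") next
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      if (num == round(num)) as.integer(num) else num
    } else val
  }
  out
}

#' Command-line entry point
#'
#' Runs a full design query against local files and writes all reports
#' into the output directory: `results.tsv` (ranked targets),
#' `offtargets.tsv` (per-candidate hit detail), `region.gb` (annotated
#' GenBank), `restriction_sites.tsv`, `primers.tsv` (specificity-ranked
#' pairs for the top target) and `config.txt` (the effective
#' configuration). Identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param args character vector of command-line arguments (`--query`,
#'   `--genome`, `--gene-table`, `--mode crispr|talen`,
#'   `--offtarget-mode all|seed|perfect`, `--max-mm`, `--five-prime
#'   none|GG|GN`, `--spacer-min`, `--spacer-max`, `--monomer-length`,
#'   `--g-rvd NN|NH`, `--sub-region`, primer options, `--enzymes`,
#'   `--min-site-len`, `--out`, `--config`, `--verbose`).
#' @return exit code, invisibly: 0 success, 1 data error, 2 usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    cfg <- parse_cli_args(args)
    validate_config(cfg)
    run_query(cfg)
    0L
  },
  usage_error = function(e) { message("usage error: ", e$message); 2L },
  data_error = function(e) { message("error: ", e$message); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}

log_msg <- function(cfg, ...) if (cfg$verbose > 0) message(...)

run_query <- function(cfg) {
  genome <- tryCatch(load_fasta(cfg$genome),
                     error = function(e) data_error(conditionMessage(e)))
  models <- if (!is.null(cfg$gene_table))
    tryCatch(load_gene_table(cfg$gene_table,
                             if (tolower(cfg$gene_table_format) == "bed12")
                               "bed12" else "refFlat"),
             error = function(e) data_error(conditionMessage(e)))
  else list()
  sub_region <- if (!is.null(cfg$sub_region)) {
    if (grepl("^exon_subset:", cfg$sub_region))
      list(exon_subset = as.integer(strsplit(
        sub("^exon_subset:", "", cfg$sub_region), ",")[[1]]))
    else cfg$sub_region
  }
  region <- tryCatch(resolve_query(cfg$query, genome, models, sub_region),
                     error = function(e) data_error(conditionMessage(e)))
  if (region$source == "raw") {
    ## a pasted sequence becomes part of the search universe
    genome <- new_genome(c(genome$seq, query = region$sequence))
  }
  model <- if (region$source == "gene")
    tryCatch(lookup_gene(cfg$query, models), error = function(e) NULL)
  else NULL
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  enzymes <- if (identical(cfg$enzymes, "default")) default_enzymes()
  else tryCatch(load_enzyme_table(cfg$enzymes),
                error = function(e) data_error(conditionMessage(e)))
  popts <- primer_options(primer_min = cfg$primer_size_min,
                          primer_max = cfg$primer_size_max,
                          primer_opt = cfg$primer_size_opt,
                          product_min = cfg$product_min,
                          product_max = cfg$product_max,
                          tm_min = cfg$tm_min, tm_max = cfg$tm_max,
                          tm_opt = cfg$tm_opt,
                          min_dist = cfg$primer_min_dist)
  ot_mode <- c(all = "all_upstream", seed = "seed_exact",
               perfect = "perfect_only")[[cfg$offtarget_mode]]
  fp <- c(none = "none", GG = "GG", GN = "GN_or_NG")[[cfg$five_prime]]

  if (cfg$mode == "crispr") {
    log_msg(cfg, "scanning for CRISPR sites (constraint ", fp, ")")
    res <- crispr_pipeline(genome, region, model, offtarget_mode = ot_mode,
                           max_mm = cfg$max_mm, five_prime_constraint = fp)
    ranked <- res$ranked
    write_results_table(ranked, file.path(cfg$out, "results.tsv"), "crispr")
    targets_ann <- data.frame(
      start = ranked$start, end = ranked$start + CRISPR_SITE_LEN,
      strand = ranked$strand, label = paste0("rank_", ranked$rank),
      stringsAsFactors = FALSE)[seq_len(nrow(ranked)), , drop = FALSE]
  } else {
    log_msg(cfg, "scanning for TALEN pairs")
    res <- talen_pipeline(genome, region, model,
                          monomer_length = cfg$monomer_length,
                          spacer_min = cfg$spacer_min,
                          spacer_max = cfg$spacer_max, max_mm = cfg$max_mm,
                          g_code = cfg$g_rvd, enzymes = enzymes)
    ranked <- res$ranked[res$ranked$representative, , drop = FALSE]
    write_results_table(ranked, file.path(cfg$out, "results.tsv"), "talen")
    targets_ann <- if (nrow(ranked) > 0) data.frame(
      start = ranked$left_start, end = ranked$right_start + ranked$length,
      strand = "+", label = paste0("rank_", ranked$rank),
      stringsAsFactors = FALSE)
    else data.frame(start = integer(0), end = integer(0),
                    strand = character(0), label = character(0))
  }
  write_offtarget_table(res$offtargets, file.path(cfg$out, "offtargets.tsv"))

  sites <- classify_uniqueness(
    scan_restriction_sites(region, enzymes, cfg$min_site_len))
  write_tsv(data.frame(enzyme = sites$enzyme,
                       start_1based = sites$start + 1L,
                       strand = sites$strand,
                       recognition = sites$recognition,
                       unique_in_region = sites$unique_in_region,
                       stringsAsFactors = FALSE),
            file.path(cfg$out, "restriction_sites.tsv"))

  primers <- data.frame()
  if (nrow(ranked) > 0) {
    cut <- cut_site(ranked[1, ], cfg$mode)
    ## primer context extends beyond the query region: a genotyping
    ## amplicon may reach past the gene/sub-region boundary
    ctx_chrom <- if (cfg$mode == "crispr") ranked$chrom[1] else region$chrom
    ctx_lo <- max(0L, cut - popts$product_max - 10L)
    ctx_hi <- min(genome$lengths[[ctx_chrom]],
                  cut + popts$product_max + 10L)
    context <- new_target_region(ctx_chrom, ctx_lo, ctx_hi,
                                 genome_slice(genome, ctx_chrom, ctx_lo,
                                              ctx_hi), "coordinates")
    primers <- tryCatch({
      pp <- suppressWarnings(design_primer_pairs(context, cut, popts))
      if (nrow(pp) > 0) rank_primer_pairs(pp, genome, res$index, popts)
      else pp
    }, error = function(e) { log_msg(cfg, "primer design: ",
                                     conditionMessage(e)); data.frame() })
  }
  primer_cols <- data.frame(rank = integer(0), left_seq = character(0),
                            right_seq = character(0), tm_left = numeric(0),
                            tm_right = numeric(0), product_size = integer(0),
                            off_products = integer(0))
  if (nrow(primers) > 0)
    primer_cols <- data.frame(rank = primers$specificity_rank,
                              left_seq = primers$left_seq,
                              right_seq = primers$right_seq,
                              tm_left = round(primers$tm_left, 2),
                              tm_right = round(primers$tm_right, 2),
                              product_size = primers$product_size,
                              off_products = primers$off_products,
                              stringsAsFactors = FALSE)
  write_tsv(primer_cols, file.path(cfg$out, "primers.tsv"))

  site_ann <- if (nrow(sites) > 0)
    data.frame(start = sites$start,
               end = sites$start + nchar(sites$recognition),
               strand = sites$strand, label = sites$enzyme,
               stringsAsFactors = FALSE)
  else data.frame(start = integer(0), end = integer(0),
                  strand = character(0), label = character(0))
  primer_ann <- if (nrow(primers) > 0) {
    p1 <- primers[1, ]
    data.frame(start = c(p1$left_start, p1$right_start),
               end = c(p1$left_end, p1$right_end),
               strand = c("+", "-"),
               label = c("primer_left", "primer_right"),
               stringsAsFactors = FALSE)
  } else data.frame(start = integer(0), end = integer(0),
                    strand = character(0), label = character(0))
  ## primers may bind outside the displayed region; only in-region features
  ## can be annotated on it
  primer_ann <- primer_ann[primer_ann$start >= region$start &
                             primer_ann$end <= region$end, , drop = FALSE]
  write_genbank(region,
                list(targets = targets_ann, primers = primer_ann,
                     sites = site_ann),
                file.path(cfg$out, "region.gb"), model = model)
  write_config(cfg, file.path(cfg$out, "config.txt"))
  log_msg(cfg, "wrote reports to ", cfg$out)
  invisible(cfg$out)
}
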