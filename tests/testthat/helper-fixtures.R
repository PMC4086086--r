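## shared test helpers: tiny constructors and independent oracles

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mk_region <- function(seq, chrom = "chr1", start = 0L,
                      source = "coordinates") {
  new_target_region(chrom, start, start + nchar(seq), seq, source)
}

mk_genome <- function(...) new_genome(c(...))

rc <- function(x) cutdesign::revcomp(x)

write_fasta_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

## overlapping occurrences of an IUPAC pattern via regex lookahead —
## independent oracle for the Biostrings-backed scanner
iupac_regex_starts <- function(pattern, seq) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rx <- paste0("(?=", paste(cls[strsplit(toupper(pattern), "")[[1]]],
                            collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## minimal GenBank reader for round-trip checks: returns a data frame of
## features (key, start1, end1, strand) and the ORIGIN sequence
read_genbank_tiny <- function(path) {
  lines <- readLines(path)
  feats <- data.frame(key = character(0), start1 = integer(0),
                      end1 = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  in_feat <- FALSE
  for (ln in lines) {
    if (grepl("^FEATURES", ln)) { in_feat <- TRUE; next }
    if (grepl("^ORIGIN", ln)) break
    if (in_feat && grepl("^     \\S", ln)) {
      key <- trimws(substr(ln, 1, 21))
      loc <- trimws(substr(ln, 22, nchar(ln)))
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      feats <- rbind(feats, data.frame(key = key, start1 = nums[1],
                                       end1 = nums[2], strand = strand,
                                       stringsAsFactors = FALSE))
    }
  }
  ori <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(ori) == 1) {
    body <- lines[(ori + 1):(length(lines))]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[ 0-9]", "", paste(body, collapse = "")))
  }
  list(features = feats, sequence = seq)
}

## a small clean genome plus one planted CRISPR site, reused across tests
planted_crispr_fixture <- function(seed = 101, genome_length = 12000,
                                   extra_plants = list()) {
  plants <- c(list(plant_crispr_site(1000L, "+", id = "site")), extra_plants)
  synth_genome(plant_spec(genome_length, seed = seed, plants = plants))
}

site_candidate <- function(fix, id = "site") {
  row <- fix$truth[fix$truth$id == id, ]
  data.frame(chrom = names(fix$genome$seq)[1], start = row$start,
             strand = row$strand,
             protospacer = substr(row$sequence, 1, 20),
             stringsAsFactors = FALSE)
}
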