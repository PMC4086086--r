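ranked_crispr_fixture <- function() {
  set.seed(51)
  g <- mk_genome(c1 = rand_seq(8000))
  region <- new_target_region("c1", 1000L, 2000L,
                              substr(g$seq[["c1"]], 1001, 2000),
                              "coordinates")
  res <- crispr_pipeline(g, region)
  list(genome = g, region = region, res = res)
}

test_that("results tables round-trip through TSV", {
  fx <- ranked_crispr_fixture()
  ranked <- head(fx$res$ranked, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(ranked, path, "crispr")
  lines <- readLines(path)
  expect_length(lines, 4)   # header + 3 rows
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back$rank, ranked$rank)
  expect_identical(back$target_seq, paste0(ranked$protospacer, ranked$pam))
  expect_identical(back$start_1based, ranked$start + 1L)
  expect_identical(back$strand, ranked$strand)
  expect_equal(back$gc_percent, ranked$gc_percent)
  expect_identical(back$mm0, ranked$n0)
  ## empty result: header only
  write_results_table(ranked[0, ], path, "crispr")
  expect_length(readLines(path), 1)
})

test_that("off-target detail tables carry per-hit mismatch locations", {
  fx <- ranked_crispr_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_offtarget_table(fx$res$offtargets, path)
  back <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(positions = "character"))
  expect_true(all(c("candidate", "chrom", "start_1based", "strand",
                    "mismatches", "positions", "is_self") %in% names(back)))
  ## every candidate contributes its self hit
  expect_identical(sum(back$is_self), length(fx$res$offtargets))
})

test_that("GenBank output round-trips coordinates and strand", {
  set.seed(52)
  seq <- rand_seq(1000)
  region <- mk_region(seq, chrom = "locus1", start = 5000L)
  targets <- data.frame(start = 5100L, end = 5123L, strand = "+",
                        label = "rank_1", stringsAsFactors = FALSE)
  primers <- data.frame(start = c(5050L, 5400L), end = c(5070L, 5420L),
                        strand = c("+", "-"),
                        label = c("primer_left", "primer_right"),
                        stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(region, list(targets = targets, primers = primers), path)
  gb <- read_genbank_tiny(path)
  expect_identical(gb$sequence, seq)
  mf <- gb$features[gb$features$key == "misc_feature", ]
  expect_identical(mf$start1, 101L)       # 5100 genomic -> local 1-based 101
  expect_identical(mf$end1, 123L)
  pb <- gb$features[gb$features$key == "primer_bind", ]
  expect_identical(pb$strand, c("+", "-"))

  ## minus-strand target uses complement()
  targets$strand <- "-"
  write_genbank(region, list(targets = targets), path)
  expect_true(any(grepl("complement\\(101\\.\\.123\\)", readLines(path))))

  ## out-of-bounds annotation errors
  expect_error(write_genbank(region, list(targets = data.frame(
    start = 4000L, end = 4023L, strand = "+", label = "x")), path),
    "outside")
})

test_that("intronless GenBank splices exons and remaps features", {
  set.seed(53)
  seq <- rand_seq(600)
  region <- mk_region(seq, chrom = "c", start = 0L)
  model <- new_gene_model("g", "g.t", "c", "+",
                          cbind(c(50L, 400L), c(150L, 550L)))
  ## one target inside exon 1, one inside the intron
  targets <- data.frame(start = c(60L, 200L), end = c(83L, 223L),
                        strand = "+", label = c("in_exon", "in_intron"),
                        stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  expect_warning(
    write_genbank(region, list(targets = targets), path,
                  include_introns = FALSE, model = model),
    "dropped")
  gb <- read_genbank_tiny(path)
  expect_identical(nchar(gb$sequence), 250L)   # 100 + 150 exon bp
  expect_identical(gb$sequence,
                   paste0(substr(seq, 51, 150), substr(seq, 401, 550)))
  mf <- gb$features[gb$features$key == "misc_feature", ]
  expect_identical(nrow(mf), 1L)
  expect_identical(mf$start1, 11L)   # genomic 60 -> spliced offset 10
})

test_that("config files round-trip and drive the parser", {
  cfg <- list(mode = "talen", max_mm = 1L, tm_opt = 59.5, query = "geneA")
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  back <- read_config(path)
  expect_identical(back$mode, "talen")
  expect_identical(back$max_mm, 1L)
  expect_equal(back$tm_opt, 59.5)
  expect_identical(back$query, "geneA")
})

cli_fixture <- function(envir = parent.frame()) {
  fix <- synth_genome(plant_spec(15000, seed = 61, plants = list(
    plant_crispr_site(5100L, "+", id = "site"))))
  models <- synth_gene_table(fix$genome, 2, seed = 62)
  dir <- withr::local_tempdir(.local_envir = envir)
  paths <- write_fixture(fix$genome, models, fix$truth, dir)
  list(paths = paths, dir = dir)
}

test_that("the CLI runs a full query and enforces its exit codes", {
  fx <- cli_fixture()
  out <- file.path(fx$dir, "out")
  code <- run_cli(c("--query", "gene1", "--genome", fx$paths$fasta,
                    "--gene-table", fx$paths$gene_table,
                    "--mode", "crispr", "--out", out))
  expect_identical(code, 0L)
  expect_true(all(file.exists(file.path(out,
    c("results.tsv", "offtargets.tsv", "region.gb",
      "restriction_sites.tsv", "primers.tsv", "config.txt")))))
  results <- read.delim(file.path(out, "results.tsv"))
  expect_gt(nrow(results), 0)
  ## every printed site maps back to the genome slice
  g <- load_fasta(fx$paths$fasta)
  for (i in seq_len(min(5, nrow(results)))) {
    slice <- substr(g$seq[[results$chrom[i]]], results$start_1based[i],
                    results$start_1based[i] + 22L)
    expect_identical(results$target_seq[i],
                     if (results$strand[i] == "+") slice else rc(slice))
  }

  ## usage errors exit 2 without touching the filesystem
  expect_identical(suppressMessages(
    run_cli(c("--query", "x", "--genome", "g.fa", "--out", "o",
              "--mode", "talen", "--spacer-min", "21",
              "--spacer-max", "20"))), 2L)
  expect_identical(suppressMessages(run_cli(c("--bogus", "1"))), 2L)
  expect_identical(suppressMessages(run_cli(character(0))), 2L)

  ## data errors exit 1
  expect_identical(suppressMessages(
    run_cli(c("--query", "nosuchgene", "--genome", fx$paths$fasta,
              "--gene-table", fx$paths$gene_table, "--out",
              file.path(fx$dir, "o2")))), 1L)
  expect_identical(suppressMessages(
    run_cli(c("--query", "gene1", "--genome",
              file.path(fx$dir, "missing.fa"), "--out",
              file.path(fx$dir, "o3")))), 1L)
})

test_that("identical configuration and inputs give byte-identical outputs", {
  fx <- cli_fixture()
  out <- file.path(fx$dir, "det")
  args <- c("--query", "gene2", "--genome", fx$paths$fasta,
            "--gene-table", fx$paths$gene_table, "--mode", "talen",
            "--out", out)
  expect_identical(run_cli(args), 0L)
  snap <- lapply(setNames(nm = list.files(out)), function(f)
    readBin(file.path(out, f), "raw", file.size(file.path(out, f))))
  expect_identical(run_cli(args), 0L)
  for (f in names(snap))
    expect_identical(readBin(file.path(out, f), "raw",
                             file.size(file.path(out, f))), snap[[f]],
                     label = paste("bytes of", f))
})

test_that("raw sequence queries search the pasted sequence plus genome", {
  fx <- cli_fixture()
  g <- load_fasta(fx$paths$fasta)
  raw <- substr(g$seq[[1]], 5001, 5400)   # includes the planted site
  out <- file.path(fx$dir, "raw_out")
  code <- run_cli(c("--query", raw, "--genome", fx$paths$fasta,
                    "--mode", "crispr", "--out", out))
  expect_identical(code, 0L)
  results <- read.delim(file.path(out, "results.tsv"))
  expect_gt(nrow(results), 0)
  expect_true(all(results$chrom == "query"))
  ## the planted site's genomic copy makes every candidate in the pasted
  ## window a perfect off-target of itself in the genome
  expect_true(all(results$mm0 >= 1))
})
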