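test_that("nearest-neighbor Tm matches an independent implementation", {
  ## reference values computed with a second implementation of the unified
  ## nearest-neighbor parameters (identical table, entropic salt
  ## correction, 50 mM Na+, 50 nM oligo)
  ref <- c(AGCGGATAACAATTTCACACAGGA = 54.8388,
           ACGTACGTACGTACGTACGT = 53.9935,   # self-complementary
           GGGGCCCCGGGGCCCCGGGG = 72.6691,
           GTAAAACGACGGCCAGT = 49.1681,
           CAGGAAACAGCTATGAC = 43.6040)
  for (s in names(ref))
    expect_equal(melting_temperature(s), ref[[s]], tolerance = 0.5 / 50)
  ## self-complementary duplex: symmetry term + undiluted concentration
  expect_equal(melting_temperature("ATATATATATATATATATAT"), 25.1015,
               tolerance = 0.5 / 25)
})

test_that("Tm is duplex-symmetric and increases with GC at fixed length", {
  set.seed(41)
  for (i in 1:10) {
    s <- rand_seq(22)
    expect_equal(melting_temperature(s), melting_temperature(rc(s)),
                 tolerance = 1e-10)
  }
  low <- "ATATTAATTATAATATTATTAT"
  mid <- "ACGTGATCTAGCTAGATCGTAC"
  high <- "GCGGCCGCACGTGCGCGGCCGC"
  expect_lt(melting_temperature(low), melting_temperature(mid))
  expect_lt(melting_temperature(mid), melting_temperature(high))
  expect_error(melting_temperature("ACGT"), "length")
  expect_error(melting_temperature("ACGTNACGTNACGT"), "ACGT only")
})

test_that("designed primer pairs respect every active constraint", {
  set.seed(42)
  region <- mk_region(rand_seq(1000), chrom = "c")
  opts <- primer_options(max_pairs = 50L)
  pairs <- design_primer_pairs(region, 500L, opts)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$product_size >= 150 & pairs$product_size <= 290))
  expect_true(all(nchar(pairs$left_seq) >= 18 & nchar(pairs$left_seq) <= 25))
  expect_true(all(nchar(pairs$right_seq) >= 18 &
                    nchar(pairs$right_seq) <= 25))
  expect_true(all(pairs$tm_left >= 57 & pairs$tm_left <= 63))
  expect_true(all(pairs$tm_right >= 57 & pairs$tm_right <= 63))
  ## exclusion zone: primers keep >= 50 bp from the cut site, product spans it
  expect_true(all(pairs$left_end <= 450))
  expect_true(all(pairs$right_start >= 550))
  expect_true(all(pairs$left_start < 500 & pairs$right_end > 500))
  ## sequences are the genomic slice (right primer reverse-complemented)
  for (i in seq_len(min(5, nrow(pairs)))) {
    expect_identical(pairs$left_seq[i],
                     substr(region$sequence, pairs$left_start[i] + 1,
                            pairs$left_end[i]))
    expect_identical(pairs$right_seq[i],
                     rc(substr(region$sequence, pairs$right_start[i] + 1,
                               pairs$right_end[i])))
  }
  ## penalties sorted ascending
  expect_true(!is.unsorted(pairs$penalty))
})

test_that("infeasible geometry yields an empty list with a diagnostic", {
  set.seed(43)
  region <- mk_region(rand_seq(1000), chrom = "c")
  expect_message(
    pairs <- suppressWarnings(design_primer_pairs(region, 30L)),
    "no feasible")
  expect_identical(nrow(pairs), 0L)
})

test_that("tightening the product window never grows the pair set", {
  set.seed(44)
  region <- mk_region(rand_seq(1000), chrom = "c")
  uncapped <- 100000000L   # no pair-count cap: compare full feasible sets
  wide <- design_primer_pairs(region, 500L,
                              primer_options(max_pairs = uncapped))
  narrow <- suppressMessages(design_primer_pairs(
    region, 500L, primer_options(product_min = 200L, product_max = 210L,
                                 max_pairs = uncapped)))
  key <- function(p) paste(p$left_start, p$left_end, p$right_start,
                           p$right_end)
  expect_lte(nrow(narrow), nrow(wide))
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("map_primer counts exact occurrences on both strands, capped", {
  primer <- "GACTGGTCACGATCGAGT"
  set.seed(45)
  bg <- rand_seq(3000)
  ## plant 3 copies: two forward, one reverse-complement
  substr(bg, 201, 218) <- primer
  substr(bg, 1001, 1018) <- primer
  substr(bg, 2001, 2018) <- rc(primer)
  g <- mk_genome(c1 = bg)
  idx <- build_index(g, 8)
  hits <- map_primer(primer, g, idx)
  oracle <- brute_force_offtargets(primer, g, "exact")
  expect_identical(hits$start, oracle$start)
  expect_identical(hits$strand, oracle$strand)
  expect_identical(nrow(hits), 3L)
  expect_false(attr(hits, "capped"))
  ## absent primer
  none <- map_primer("TTTTTTTTTTGGGGGGGGGG", mk_genome(c1 = strrep("AC", 500)),
                     build_index(mk_genome(c1 = strrep("AC", 500)), 8))
  expect_identical(nrow(none), 0L)
  ## cap semantics: 25 planted copies report 10 with the capped flag
  many <- mk_genome(c1 = paste(rep(c(primer, "CCCCCC"), 25), collapse = ""))
  hits <- map_primer(primer, many, build_index(many, 8), cap = 10L)
  expect_identical(nrow(hits), 10L)
  expect_true(attr(hits, "capped"))
})

test_that("off-product counting matches a convergent-hit oracle", {
  set.seed(46)
  region_seq <- rand_seq(1000)
  ## genome = locus + an exact duplicate of an internal amplicon elsewhere
  dup <- substr(region_seq, 301, 700)
  g <- mk_genome(c1 = paste0(region_seq, rand_seq(500), dup, rand_seq(300)))
  region <- mk_region(substr(g$seq[["c1"]], 1, 1000), chrom = "c1")
  idx <- build_index(g, 8)
  opts <- primer_options(max_pairs = 20L)
  pairs <- design_primer_pairs(region, 500L, opts)
  ranked <- rank_primer_pairs(pairs, g, idx, opts)
  ## pairs fully inside the duplicated 300-700 window amplify twice
  inside <- ranked$left_start >= 300 & ranked$right_end <= 700
  expect_true(all(ranked$off_products[inside] >= 1L))
  expect_true(all(ranked$off_products[!inside] == 0L))
  ## specificity order: every 0-off-product pair precedes every other
  if (any(inside) && any(!inside))
    expect_lt(max(ranked$specificity_rank[!inside]),
              min(ranked$specificity_rank[inside]))
  ## oracle recount from raw hit lists
  for (i in seq_len(nrow(ranked))) {
    lh <- brute_force_offtargets(ranked$left_seq[i], g, "exact")
    rh <- brute_force_offtargets(ranked$right_seq[i], g, "exact")
    Ll <- nchar(ranked$left_seq[i]); Lr <- nchar(ranked$right_seq[i])
    cnt <- 0L
    for (a in seq_len(nrow(lh))) for (b in seq_len(nrow(rh))) {
      if (lh$strand[a] == "+" && rh$strand[b] == "-") {
        amp <- rh$start[b] + Lr - lh$start[a]
        tgt <- lh$start[a] == ranked$left_start[i] &&
          rh$start[b] == ranked$right_start[i]
        if (!tgt && amp > 0 && amp <= 1.5 * 290) cnt <- cnt + 1L
      } else if (lh$strand[a] == "-" && rh$strand[b] == "+") {
        amp <- lh$start[a] + Ll - rh$start[b]
        if (amp > 0 && amp <= 1.5 * 290) cnt <- cnt + 1L
      }
    }
    expect_identical(ranked$off_products[i], cnt)
  }
})

test_that("restriction scanning equals the IUPAC-regex oracle", {
  ## direct palindrome: one site, plus strand only
  sites <- scan_restriction_sites(mk_region("AAGAATTCAA", chrom = "c"),
                                  default_enzymes()["EcoRI" ==
                                                       default_enzymes()$name, ])
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 2L)
  expect_identical(sites$strand, "+")

  ## length filter removes short-site enzymes entirely
  enz <- data.frame(name = "KpnI", recognition = "GGTACC", site_length = 6L,
                    suppliers = "", stringsAsFactors = FALSE)
  sites <- scan_restriction_sites(mk_region("AAGGTACCAA"), enz,
                                  min_site_len = 8L)
  expect_identical(nrow(sites), 0L)

  ## degenerate recognition: all four GRCGYC expansions planted
  enz <- data.frame(name = "AcyI", recognition = "GRCGYC", site_length = 6L,
                    suppliers = "", stringsAsFactors = FALSE)
  seq <- paste0("TTT", "GACGCC", "TTT", "GACGTC", "TTT", "GGCGCC", "TTT",
                "GGCGTC", "TTT")
  sites <- scan_restriction_sites(mk_region(seq), enz)
  plus <- sites[sites$strand == "+", ]
  expect_identical(plus$start, c(3L, 12L, 21L, 30L))

  ## random sequence, whole built-in table vs regex oracle
  set.seed(47)
  seq <- rand_seq(4000, gc = 0.55)
  region <- mk_region(seq, chrom = "c")
  sites <- scan_restriction_sites(region, default_enzymes(), min_site_len = 4)
  for (enzname in unique(default_enzymes()$name)) {
    rec <- default_enzymes()$recognition[default_enzymes()$name == enzname]
    got <- sites[sites$enzyme == enzname, ]
    exp_plus <- iupac_regex_starts(rec, seq) - 1L
    if (rc(rec) == rec) {
      expect_setequal(got$start, exp_plus)
      expect_true(all(got$strand == "+"))
    } else {
      exp_minus <- iupac_regex_starts(rc(rec), seq) - 1L
      expect_setequal(got$start[got$strand == "+"], exp_plus)
      expect_setequal(got$start[got$strand == "-"], exp_minus)
    }
  }
  ## invalid IUPAC letter names the enzyme
  bad <- data.frame(name = "BadZyme", recognition = "GAXTC", site_length = 5L,
                    suppliers = "", stringsAsFactors = FALSE)
  expect_error(scan_restriction_sites(region, bad), "BadZyme")
})

test_that("uniqueness classification is per enzyme within the region", {
  seq <- paste0("AA", "GAATTC", "AAA", "GGATCC", "AAA", "GGATCC", "AA")
  region <- mk_region(seq)
  sites <- classify_uniqueness(scan_restriction_sites(region,
                                                      default_enzymes()))
  eco <- sites[sites$enzyme == "EcoRI", ]
  bam <- sites[sites$enzyme == "BamHI", ]
  expect_true(all(eco$unique_in_region))
  expect_identical(nrow(bam), 2L)
  expect_false(any(bam$unique_in_region))
})

test_that("spacer restriction sites require full containment", {
  ## spacer contains an EcoRI site
  pair <- data.frame(chrom = "c", left_start = 0L, right_start = 31L,
                     length = 15L, left_seq = "x", right_seq = "y",
                     spacer_start = 15L, spacer_end = 31L,
                     spacer_seq = "TGAATTCAGGCCTAGT", stringsAsFactors = FALSE)
  sites <- spacer_restriction_sites(pair)
  expect_true("EcoRI" %in% sites$enzyme)
  expect_true(all(sites$start >= 15L &
                    sites$start + nchar(sites$recognition) <= 31L))
  ## a site straddling the spacer boundary is not reported: GAATTC split
  ## so only GAATT lies in the spacer
  pair$spacer_seq <- "AAAAAAAAAAAGAATT"
  expect_false("EcoRI" %in% spacer_restriction_sites(pair)$enzyme)
  ## empty enzyme table
  expect_identical(nrow(spacer_restriction_sites(pair,
                                                 default_enzymes()[0, ])), 0L)
})
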