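index_lookup_ <- function(idx, kmer) cutdesign:::index_lookup(idx, kmer)

test_that("seed index postings record every N-free k-mer on both strands", {
  idx <- build_index(mk_genome(a = "ACGTACGT"), 8)
  p <- index_lookup_(idx, "ACGTACGT")
  expect_true(any(p$chrom == "a" & p$pos == 0 & p$strand == "+"))
  ## palindromic 8-mer: the minus-strand read is identical
  expect_true(any(p$strand == "-"))

  idx <- build_index(mk_genome(a = strrep("N", 50)), 8)
  expect_identical(idx$n_kmers, 0L)
  expect_error(build_index(mk_genome(a = "ACGT")[0], 8))

  ## positions agree with a direct overlapping-substring enumeration
  set.seed(21)
  g <- mk_genome(c1 = rand_seq(2000))
  k <- 8
  idx <- build_index(g, k)
  for (i in 1:20) {
    s <- sample.int(2000 - k, 1)
    kmer <- substr(g$seq[["c1"]], s, s + k - 1)
    p <- index_lookup_(idx, kmer)
    plus_expected <- iupac_regex_starts(kmer, g$seq[["c1"]]) - 1L
    expect_setequal(p$pos[p$strand == "+"], plus_expected)
    minus_expected <- iupac_regex_starts(rc(kmer), g$seq[["c1"]]) - 1L
    expect_setequal(p$pos[p$strand == "-"], minus_expected)
  }
})

test_that("planted duplicates and decoys are found per mismatch model", {
  fix <- planted_crispr_fixture(seed = 101, extra_plants = list(
    plant_crispr_decoy("site", 3000L, "+", edits = list(), id = "dup"),
    plant_crispr_decoy("site", 5000L, "-", edits = list(), id = "dup_rc")))
  cand <- site_candidate(fix)
  g <- fix$genome
  idx <- build_index(g, 6)
  for (mode in c("all_upstream", "seed_exact", "perfect_only")) {
    hits <- find_crispr_offtargets(cand, g, idx, mode, 2)
    non_self <- hits[!hits$is_self, ]
    expect_identical(nrow(non_self), 2L)
    expect_true(all(non_self$mismatches == 0L))
    expect_setequal(non_self$start, c(3000L, 5000L))
    expect_identical(sum(hits$is_self), 1L)
  }
})

test_that("a 20-mer match without an NGG PAM is never an off-target", {
  fix <- planted_crispr_fixture(seed = 102, extra_plants = list(
    plant_crispr_decoy("site", 4000L, "+", edits = list(), pam = "ACG",
                       id = "badpam")))
  cand <- site_candidate(fix)
  idx <- build_index(fix$genome, 6)
  for (mode in c("all_upstream", "seed_exact", "perfect_only")) {
    hits <- find_crispr_offtargets(cand, fix$genome, idx, mode, 2)
    expect_false(any(hits$start == 4000L))
  }
})

test_that("single-mismatch decoys resolve to their edited positions", {
  ## one decoy per protospacer position, alternating strands
  plants <- lapply(1:20, function(p) {
    plant_crispr_decoy("site", 1500L + 300L * p,
                       strand = if (p %% 2 == 0) "-" else "+",
                       edits = list(c(p, "PLACEHOLDER")),
                       id = paste0("d", p))
  })
  ## pick an edit base different from the site's base at each position:
  ## materialization needs concrete bases, so build the site first
  base_fix <- planted_crispr_fixture(seed = 103)
  proto <- substr(base_fix$truth$sequence[1], 1, 20)
  plants <- lapply(1:20, function(p) {
    cur <- substr(proto, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), cur)[1]
    plant_crispr_decoy("site", 1500L + 300L * p,
                       strand = if (p %% 2 == 0) "-" else "+",
                       edits = list(c(p, alt)), id = paste0("d", p))
  })
  fix <- synth_genome(plant_spec(12000, seed = 103, plants = c(
    list(plant_crispr_site(1000L, "+",
                           protospacer = proto, pam = "TGG", id = "site")),
    plants)))
  cand <- site_candidate(fix)
  idx <- build_index(fix$genome, 6)

  all_hits <- find_crispr_offtargets(cand, fix$genome, idx, "all_upstream", 2)
  non_self <- all_hits[!all_hits$is_self, ]
  expect_identical(nrow(non_self), 20L)
  expect_true(all(non_self$mismatches == 1L))
  expect_setequal(as.integer(non_self$positions), 1:20)

  seed_hits <- find_crispr_offtargets(cand, fix$genome, idx, "seed_exact", 2)
  pos <- as.integer(seed_hits$positions[!seed_hits$is_self])
  expect_setequal(pos, 1:9)

  perfect <- find_crispr_offtargets(cand, fix$genome, idx, "perfect_only", 2)
  expect_identical(nrow(perfect[!perfect$is_self, ]), 0L)
})

test_that("TALEN monomer and paired off-targets follow the 5' T rule", {
  left <- "TGACGTCAGGTCACG"; right <- "TCGGATCCTGACGTG"
  fix <- synth_genome(plant_spec(15000, seed = 104, plants = list(
    plant_talen_pair(1000L, left_seq = left, right_seq = right,
                     spacer_len = 16L, id = "tp"),
    ## extra copy of only the left monomer
    plant_talen_decoy("tp", "left", 4000L, "+", edits = list(), id = "lc"),
    ## both monomers re-planted at a valid 16 bp gap elsewhere
    plant_talen_pair(8000L, left_seq = left, right_seq = right,
                     spacer_len = 16L, id = "tp2"),
    ## left copy whose 5' base is no longer T
    plant_talen_decoy("tp", "left", 11000L, "+", edits = list(c(1, "C")),
                      id = "noT"))))
  pair <- data.frame(chrom = "chrS", left_start = 1000L,
                     right_start = 1000L + 15L + 16L, length = 15L,
                     left_seq = left, right_seq = right,
                     spacer_start = 1015L, spacer_end = 1031L,
                     spacer_len = 16L, spacer_seq = "x",
                     stringsAsFactors = FALSE)
  idx <- build_index(fix$genome, 5)
  ot <- find_talen_offtargets(pair, fix$genome, idx, max_mm = 2)
  hits <- ot$monomer_hits
  expect_false(any(hits$start == 11000L))          # lost 5' T
  expect_true(any(hits$start == 4000L & hits$monomer == "left"))
  expect_identical(sum(hits$is_self), 2L)          # both on-target monomers
  ## exactly one paired off-target: the re-planted pair at 8000
  expect_identical(nrow(ot$paired), 1L)
  expect_identical(ot$paired$left_start, 8000L)
  expect_identical(ot$paired$gap_len, 16L)
})

test_that("indexed search equals brute force across modes (random genomes)", {
  set.seed(22)
  g <- mk_genome(c1 = rand_seq(20000), c2 = rand_seq(10000))
  region <- new_target_region("c1", 500L, 2500L,
                              substr(g$seq[["c1"]], 501, 2500),
                              "coordinates")
  cands <- scan_crispr(region)
  cands <- cands[sample.int(nrow(cands), 20), ]
  idx <- build_index(g, 6)
  for (i in seq_len(nrow(cands))) {
    for (mode in c("all_upstream", "seed_exact", "perfect_only")) {
      a <- find_crispr_offtargets(cands[i, ], g, idx, mode, 2)
      b <- brute_force_offtargets(cands$protospacer[i], g, "crispr", mode, 2)
      expect_identical(a[, c("chrom", "start", "strand", "mismatches",
                             "positions")],
                       b[, c("chrom", "start", "strand", "mismatches",
                             "positions")])
    }
  }
  ## TALEN monomers likewise
  idx5 <- build_index(g, 5)
  mono <- scan_talen_monomers(region, 15)
  mono <- mono[sample.int(nrow(mono), 10), ]
  for (i in seq_len(nrow(mono))) {
    a <- cutdesign:::find_monomer_hits(mono$sequence[i], g, idx5, 2)
    b <- brute_force_offtargets(mono$sequence[i], g, "talen", max_mm = 2)
    expect_identical(a, b)
  }
})

test_that("mismatch modes nest: perfect within seed within all-upstream", {
  set.seed(23)
  g <- mk_genome(c1 = rand_seq(15000))
  region <- new_target_region("c1", 0L, 1500L, substr(g$seq[["c1"]], 1, 1500),
                              "coordinates")
  cands <- scan_crispr(region)
  idx <- build_index(g, 6)
  key <- function(h) paste(h$chrom, h$start, h$strand)
  for (i in sample.int(nrow(cands), 10)) {
    all_h <- find_crispr_offtargets(cands[i, ], g, idx, "all_upstream", 2)
    seed_h <- find_crispr_offtargets(cands[i, ], g, idx, "seed_exact", 2)
    perf_h <- find_crispr_offtargets(cands[i, ], g, idx, "perfect_only", 2)
    expect_true(all(key(perf_h) %in% key(seed_h)))
    expect_true(all(key(seed_h) %in% key(all_h)))
    ## every scanned candidate is its own unique perfect hit
    expect_identical(sum(perf_h$is_self), 1L)
    expect_identical(perf_h$mismatches[perf_h$is_self], 0L)
  }
})

test_that("off-target hit sets mirror under genome reverse complement", {
  set.seed(24)
  seq <- rand_seq(8000)
  g <- mk_genome(c1 = seq)
  g_rc <- mk_genome(c1 = rc(seq))
  region <- new_target_region("c1", 0L, 1000L, substr(seq, 1, 1000),
                              "coordinates")
  cands <- scan_crispr(region)
  idx <- build_index(g, 6); idx_rc <- build_index(g_rc, 6)
  n <- 8000L
  for (i in sample.int(nrow(cands), 5)) {
    a <- find_crispr_offtargets(cands[i, ], g, idx, "all_upstream", 2)
    b <- find_crispr_offtargets(cands[i, ], g_rc, idx_rc, "all_upstream", 2)
    mirrored <- data.frame(start = n - b$start - 23L,
                           strand = ifelse(b$strand == "+", "-", "+"),
                           mismatches = b$mismatches,
                           stringsAsFactors = FALSE)
    o1 <- order(a$start, a$strand)
    o2 <- order(mirrored$start, mirrored$strand)
    expect_identical(a$start[o1], mirrored$start[o2])
    expect_identical(a$strand[o1], mirrored$strand[o2])
    expect_identical(a$mismatches[o1], mirrored$mismatches[o2])
  }
})

test_that("brute force handles degenerate inputs", {
  g <- mk_genome(tiny = "ACGTACGTAA")
  expect_identical(nrow(brute_force_offtargets(strrep("T", 20), g, "talen",
                                               max_mm = 2)), 0L)
  hits <- brute_force_offtargets("ACGTACGT", g, "exact")
  expect_true(any(hits$start == 0 & hits$strand == "+"))
})
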