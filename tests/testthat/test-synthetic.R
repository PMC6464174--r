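test_that("hairpin construction validates its inputs", {
  expect_error(build_hairpin("UGAGGUAGUAGGUUGUAUA"), "20-24")   # 19 nt
  expect_error(build_hairpin("UGAGGXAGUAGGUUGUAUAGUU"), "mature")
  expect_error(build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 2), "loop_len")
  expect_error(build_hairpin("UGAGGUAGUAGGUUGUAUAGUU",
                             star_mismatches = 23), "exceeds")
})

test_that("the shortest legal hairpin folds with its designed 3-nt loop", {
  hp <- build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", "5p", loop_len = 3,
                      star_mismatches = 0, seed = 1)
  f <- fold_mfe(hp$seq)
  unpaired <- which(is.na(f$partner))
  expect_equal(length(unpaired), 3)
  expect_equal(unpaired, (hp$mature_end + 1):(hp$mature_end + 3))
  expect_equal(sum(is.na(f$partner[hp$mature_start:hp$mature_end])), 0)
})

test_that("hairpin construction is deterministic in the seed", {
  a <- build_hairpin("UUGGACUGAAGGGAGCUCCCU", "5p", 8, 3, seed = 5,
                     stem_ext = 30)
  b <- build_hairpin("UUGGACUGAAGGGAGCUCCCU", "5p", 8, 3, seed = 5,
                     stem_ext = 30)
  d <- build_hairpin("UUGGACUGAAGGGAGCUCCCU", "5p", 8, 3, seed = 6,
                     stem_ext = 30)
  expect_identical(a, b)
  expect_false(identical(a$seq, d$seq))
})

test_that("fixture generation is reproducible bit-for-bit", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- default_fixture_config()
  cfg$precursors <- cfg$precursors[1:2]
  cfg$ssrs <- cfg$ssrs[1:2]
  cfg$background$n <- 1L
  generate_fixture(cfg, seed = 9, out_dir = dir1)
  generate_fixture(cfg, seed = 9, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "transcripts.fa")),
                   readLines(file.path(dir2, "transcripts.fa")))
  expect_identical(readLines(file.path(dir1, "truth.tsv")),
                   readLines(file.path(dir2, "truth.tsv")))
  # FASTA wrapped at 70 columns
  fa <- readLines(file.path(dir1, "transcripts.fa"))
  expect_true(all(nchar(fa[!startsWith(fa, ">")]) <= 70))
})

test_that("the standard fixture has the declared composition and truth rows", {
  fx <- std_fixture(seed = 42)
  expect_equal(length(fx$transcripts), 17)  # 8 precursor + 5 SSR + 4 background
  expect_equal(nrow(fx$truth), 13)
  expect_equal(sum(fx$truth$feature_type == "precursor"), 3)
  expect_equal(sum(fx$truth$feature_type == "decoy"), 5)
  expect_equal(sum(fx$truth$feature_type == "ssr"), 5)
  # planted coordinates lie inside their hosts
  for (r in seq_len(nrow(fx$truth))) {
    n <- nchar(fx$transcripts[[fx$truth$transcript_id[r]]])
    expect_gte(fx$truth$start[r], 1)
    expect_lte(fx$truth$end[r], n)
  }
  # background composition near the requested GC
  bg_ids <- setdiff(names(fx$transcripts), fx$truth$transcript_id)
  for (id in bg_ids) {
    expect_lt(abs(gc_percent(fx$transcripts[[id]]) - 42), 2)
  }
})

test_that("every true precursor passes and each decoy fails only its criterion", {
  fx <- std_fixture(seed = 42)
  matures <- read_mature_fasta(default_mature_fasta())
  pre_rows <- fx$truth[fx$truth$feature_type %in% c("precursor", "decoy"), ]
  for (r in seq_len(nrow(pre_rows))) {
    id <- pre_rows$transcript_id[r]
    payload <- jsonlite::fromJSON(pre_rows$payload[r])
    host <- fx$transcripts[[id]]
    hits <- find_homology_hits(stats::setNames(host, id), matures)
    expect_equal(nrow(hits), 1)
    cand <- extract_precursor_window(hits[1, ], host)
    coding <- flag_coding(cand, host)
    ev <- evaluate_candidate(cand, fold_mfe(cand$seq))
    if (pre_rows$feature_type[r] == "precursor") {
      expect_false(coding)
      expect_true(ev$verdict, label = paste("true precursor", payload$mature_id))
    } else if (payload$violates == "coding") {
      expect_true(coding)
      expect_true(ev$verdict)  # structurally sound, removed by the ORF filter
    } else {
      expect_false(coding)
      fails <- names(ev$passes)[!ev$passes]
      expect_equal(fails, payload$violates,
                   label = paste("decoy", payload$mature_id))
    }
  }
})

test_that("a zero-feature configuration yields pure background and no candidates", {
  cfg <- default_fixture_config()
  cfg$precursors <- list()
  cfg$ssrs <- list()
  cfg$background <- list(n = 3L, length = 600L, gc = 0.42)
  fx <- generate_fixture(cfg, seed = 15)
  expect_equal(nrow(fx$truth), 0)
  run <- run_mirna_pipeline(fx$transcripts)
  expect_equal(nrow(run$candidates), 0)
  expect_equal(run$mfei_summary$n, 0)
  srun <- run_ssr_pipeline(fx$transcripts)
  expect_equal(nrow(srun$loci), 0)
})
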