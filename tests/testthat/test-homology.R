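make_refs <- function(...) {
  seqs <- c(...)
  data.frame(id = names(seqs), family = tolower(names(seqs)),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

test_that("reference deduplication removes identical and contained sequences", {
  refs <- make_refs(b = "UGAGGUAGUAGGUUGUAUAGUU",
                    a = "UGAGGUAGUAGGUUGUAUAGUU",
                    c = "GAGGUAGUAGGUUGUAUAGU")
  kept <- deduplicate_matures(refs)
  expect_equal(kept$id, "a")  # identical: smallest id; substring: dropped

  # one substitution apart: both retained (100% identity clustering)
  refs2 <- make_refs(x = "UGAGGUAGUAGGUUGUAUAGUU",
                     y = "UGAGGUAGUAGCUUGUAUAGUU")
  expect_equal(nrow(deduplicate_matures(refs2)), 2)

  # idempotent, and verified against a brute-force containment scan
  withr::with_seed(42, {
    seqs <- replicate(12, rand_rna(sample(18:24, 1)))
    seqs <- c(seqs, substr(seqs[1], 2, nchar(seqs[1])), seqs[2])
    refs3 <- data.frame(id = sprintf("m%02d", seq_along(seqs)), seq = seqs,
                        stringsAsFactors = FALSE)
    once <- deduplicate_matures(refs3)
    expect_identical(deduplicate_matures(once), once)
    for (r in seq_len(nrow(once))) {
      others <- setdiff(seq_len(nrow(once)), r)
      expect_false(any(vapply(others, function(k) {
        grepl(once$seq[r], once$seq[k], fixed = TRUE)
      }, logical(1))))
    }
  })
  expect_error(deduplicate_matures(data.frame()), "empty")
})

test_that("exact hits match planted coordinates and reject substitutions", {
  withr::with_seed(3, {
    bg <- rand_seq(1000)
    mat <- "UGAGGUAGUAGGUUGUAUAGUU"
    tx <- paste0(substr(bg, 1, 250), chartr("U", "T", mat), substr(bg, 273, 1000))
    refs <- make_refs(let7 = mat)
    hits <- find_homology_hits(c(t1 = tx), refs)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$t_start, 251)
    expect_equal(hits$t_end, 272)
    expect_equal(hits$match_len, 22)

    mutated <- paste0(substr(tx, 1, 255), "A", substr(tx, 257, nchar(tx)))
    if (substr(tx, 256, 256) == "A") {
      mutated <- paste0(substr(tx, 1, 255), "C", substr(tx, 257, nchar(tx)))
    }
    expect_equal(nrow(find_homology_hits(c(t1 = mutated), refs)), 0)
  })
})

test_that("hit finder agrees with the naive quadratic scan on random fixtures", {
  withr::with_seed(77, {
    refs <- make_refs(m1 = rand_rna(20), m2 = rand_rna(21), m3 = rand_rna(24),
                      short = rand_rna(19))
    # ~60 kb total, with planted single and double occurrences
    txs <- character(0)
    for (i in 1:6) {
      s <- rand_seq(10000)
      ins <- chartr("U", "T", refs$seq[(i %% 3) + 1])
      p1 <- sample(100:4000, 1)
      s <- paste0(substr(s, 1, p1 - 1), ins, substr(s, p1 + nchar(ins), 10000))
      if (i <= 2) {  # plant the same mature twice
        p2 <- sample(6000:9000, 1)
        s <- paste0(substr(s, 1, p2 - 1), ins, substr(s, p2 + nchar(ins), nchar(s)))
      }
      txs[sprintf("t%d", i)] <- s
    }
    got <- find_homology_hits(txs, refs)
    want <- naive_hits(txs, refs)
    expect_equal(got[, c("transcript_id", "mature_id", "t_start", "t_end")],
                 want, ignore_attr = TRUE)
    expect_true(all(got$match_len >= 20))
  })
})

test_that("precursor windows are cut, clipped and flagged correctly", {
  tx <- strrep("A", 1000)
  hit <- data.frame(transcript_id = "t", mature_id = "m",
                    t_start = 251, t_end = 271)
  w <- extract_precursor_window(hit, tx)
  expect_equal(c(w$window_start, w$window_end), c(51, 471))
  expect_equal(nchar(w$seq), 421)
  expect_equal(w$mature_start, 201)
  expect_false(w$truncated)

  hit2 <- data.frame(transcript_id = "t", mature_id = "m",
                     t_start = 6, t_end = 26)
  w2 <- extract_precursor_window(hit2, tx)
  expect_equal(c(w2$window_start, w2$window_end), c(1, 226))
  expect_equal(w2$mature_start, 6)
  expect_true(w2$truncated)

  hit3 <- data.frame(transcript_id = "t", mature_id = "m",
                     t_start = 986, t_end = 1006)
  expect_error(extract_precursor_window(hit3, tx), "outside")

  # window length bound: <= 2*flank + match_len, equality iff unclipped
  withr::with_seed(12, {
    for (k in 1:20) {
      st <- sample(1:950, 1)
      hit <- data.frame(transcript_id = "t", mature_id = "m",
                        t_start = st, t_end = min(1000, st + 20))
      w <- extract_precursor_window(hit, tx)
      len <- w$window_end - w$window_start + 1
      bound <- 2 * 200 + (hit$t_end - hit$t_start + 1)
      expect_lte(len, bound)
      expect_equal(len == bound, !w$truncated)
    }
  })
})

test_that("ORF heuristic flags coding windows in all six frames", {
  withr::with_seed(9, {
    # ORF on the forward strand
    orf <- paste0("ATG", paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), 149, replace = TRUE), collapse = ""), "TAA")
    tx <- paste0(rand_seq(100), orf, rand_seq(300))
    orfs <- find_orfs(tx, min_aa = 100)
    expect_true(any(orfs$n_aa >= 150 & orfs$strand == "+"))
    cand <- list(window_start = 150, window_end = 500)
    expect_true(flag_coding(cand, tx))
    # reverse strand is detected too
    expect_true(flag_coding(cand, chartr("ACGT", "TGCA",
                                         paste(rev(strsplit(tx, "")[[1]]),
                                               collapse = ""))))

    # stop-saturated background has no long ORFs: the 4-periodic TAAC
    # repeat puts a stop in every frame of both strands every 12 nt
    stopsat <- strrep("TAAC", 225)
    expect_equal(nrow(find_orfs(stopsat, min_aa = 100)), 0)
    expect_false(flag_coding(list(window_start = 1, window_end = 900), stopsat))

    # degenerate threshold: a single in-frame ATG..TAA
    tiny <- paste0("CCCCC", "ATGTAA", "CCCCC")
    expect_true(flag_coding(list(window_start = 1, window_end = 16), tiny,
                            min_orf_aa = 1))
  })
})
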