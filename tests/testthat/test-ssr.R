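test_that("threshold boundaries are respected", {
  withr::with_seed(1, {
    bg1 <- rand_seq(100)
    bg2 <- rand_seq(100)
    # guard flanks so the planted run cannot extend by chance
    tx6 <- c(s = paste0(bg1, "C", strrep("AG", 6), "C", bg2))
    loci <- scan_ssrs(tx6)
    loci <- loci[loci$motif == "AG", , drop = FALSE]
    expect_equal(nrow(loci), 1)
    expect_equal(loci$repeats, 6)
    expect_equal(loci$start, 102)

    tx5 <- c(s = paste0(bg1, "C", strrep("AG", 5), "C", bg2))
    loci5 <- scan_ssrs(tx5)
    expect_false(any(loci5$motif == "AG"))
  })
})

test_that("runs are credited to the primitive unit with complete repeats", {
  tx <- c(s = paste0("CCCGGG", strrep("AT", 12), "GGGCCC"))
  loci <- scan_ssrs(tx)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$motif, "AT")   # never (ATAT)6
  expect_equal(loci$repeats, 12)
  expect_equal(loci$start, 7)
  # a trailing partial unit does not extend the reported span
  tx2 <- c(s = paste0("CCCTTT", strrep("ACG", 5), "AC", "TTTCCC"))
  l2 <- scan_ssrs(tx2)
  expect_equal(l2$motif, "ACG")
  expect_equal(l2$end - l2$start + 1L, 15L)
})

test_that("scanner agrees with the regex oracle on random sequences", {
  withr::with_seed(1234, {
    for (k in 1:25) {
      s <- rand_seq(10000, gc = runif(1, 0.3, 0.6))
      # spike in planted repeats so loci are not vanishingly rare
      for (m in c("AG", "TTA", "ACCA", "T")) {
        reps <- sample(5:12, 1)
        p <- sample(1000:8000, 1)
        run <- strrep(m, reps)
        s <- paste0(substr(s, 1, p - 1), run, substr(s, p + nchar(run), nchar(s)))
      }
      got <- scan_ssrs(c(x = s))
      want <- regex_ssr_oracle(s)
      expect_equal(got[, c("motif", "unit_len", "repeats", "start", "end")],
                   want, ignore_attr = TRUE)
    }
  })
})

test_that("motif classes are invariant under rotation and reverse complement", {
  expect_equal(canonical_motif_class("CT")$representative, "AG")
  expect_equal(canonical_motif_class("CTT")$representative, "AAG")
  expect_equal(canonical_motif_class("A")$representative, "A")
  expect_equal(canonical_motif_class("GGT")$representative, "ACC")
  expect_error(canonical_motif_class("ATAT"), "primitive")

  rot1 <- function(m) paste0(substr(m, 2, nchar(m)), substr(m, 1, 1))
  withr::with_seed(2, {
    for (k in 1:40) {
      u <- sample(1:6, 1)
      m <- rand_seq(u)
      if (!mirssr:::is_primitive_motif(m)) next
      rep0 <- canonical_motif_class(m)$representative
      expect_equal(canonical_motif_class(rot1(m))$representative, rep0)
      expect_equal(canonical_motif_class(revcomp_dna(m))$representative, rep0)
    }
  })
})

test_that("compound grouping follows the interruption limit", {
  loci <- data.frame(
    transcript_id = "t", motif = c("AG", "CTT"), unit_len = c(2L, 3L),
    repeats = c(6L, 5L), start = c(10L, 27L), end = c(21L, 41L),
    motif_class = c("AG", "AAG"), stringsAsFactors = FALSE)
  merged <- merge_compound(loci)  # gap of 5 nt
  expect_equal(merged$compound_id, c("c1", "c1"))

  loci$start[2] <- 123L  # gap of 101 nt
  loci$end[2] <- 137L
  merged2 <- merge_compound(loci)
  expect_true(all(is.na(merged2$compound_id)))

  single <- merge_compound(loci[1, ])
  expect_true(is.na(single$compound_id))
})

test_that("summary excludes mononucleotides and sums to 100%", {
  loci <- data.frame(
    transcript_id = "t",
    motif = c("AG", "GA", "CT", "CTT", "A"),
    unit_len = c(2L, 2L, 2L, 3L, 1L),
    repeats = c(6L, 6L, 7L, 5L, 12L),
    start = c(1, 50, 100, 150, 300), end = c(12, 61, 113, 164, 311),
    motif_class = c("AG", "AG", "AG", "AAG", "A"),
    stringsAsFactors = FALSE)
  s <- ssr_summary(loci)
  ul <- s[s$level == "unit_length", ]
  expect_false("mono" %in% ul$key)
  expect_equal(ul$pct[ul$key == "di"], 75)
  expect_equal(ul$pct[ul$key == "tri"], 25)
  expect_equal(sum(ul$pct), 100)
  mc <- s[s$level == "motif_class", ]
  expect_equal(mc$n[mc$key == "AG"], 3L)

  withmono <- ssr_summary(loci, exclude_mono = FALSE)
  expect_true("mono" %in% withmono$key)
  expect_equal(nrow(ssr_summary(loci[0, ])), 0)
})

test_that("fixture SSRs round-trip through the scanner exactly", {
  fx <- std_fixture(seed = 42)
  truth <- fx$truth[fx$truth$feature_type == "ssr", ]
  for (r in seq_len(nrow(truth))) {
    id <- truth$transcript_id[r]
    loci <- scan_ssrs(fx$transcripts[id])
    expect_equal(nrow(loci), 1)
    expect_equal(loci$start, truth$start[r])
    expect_equal(loci$end, truth$end[r])
    payload <- jsonlite::fromJSON(truth$payload[r])
    expect_equal(loci$motif, payload$motif)
    expect_equal(loci$repeats, payload$repeats)
  }
})
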