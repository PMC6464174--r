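# Criterion logic exercised on constructed hairpins whose pairing
# pattern is known by construction.

fold_planted <- function(hp) {
  f <- fold_mfe(hp$seq)
  list(fold = f, span = c(hp$mature_start, hp$mature_end))
}

test_that("arm assignment recognizes clean 5p and 3p precursors", {
  hp5 <- build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", "5p", loop_len = 6,
                       star_mismatches = 0, seed = 1, stem_ext = 20)
  p5 <- fold_planted(hp5)
  expect_equal(assign_arm(p5$fold, p5$span), "5p")
  expect_equal(count_star_mismatches(p5$fold, p5$span), 0)
  expect_true(check_loop_break(p5$fold, p5$span))

  hp3 <- build_hairpin("UUGGACUGAAGGGAGCUCCCU", "3p", loop_len = 8,
                       star_mismatches = 0, seed = 2, stem_ext = 20)
  p3 <- fold_planted(hp3)
  expect_equal(assign_arm(p3$fold, p3$span), "3p")
})

test_that("a mature straddling the terminal loop is assigned no arm", {
  hp <- build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", "5p", loop_len = 6,
                      star_mismatches = 0, seed = 3, stem_ext = 20)
  f <- fold_mfe(hp$seq)
  # shift the queried span so it covers the loop
  span <- c(hp$mature_end - 4, hp$mature_end + 8)
  expect_equal(assign_arm(f, span), "none")
  expect_false(check_loop_break(f, span))
  expect_error(count_star_mismatches(f, span), "one arm")
})

test_that("a mature pairing into two stems is assigned no arm", {
  split <- mirssr:::build_split_hairpin("UUUGGUUUGAAGGGAGCUCUA", seed = 4)
  f <- fold_mfe(split$seq)
  span <- c(split$mature_start, split$mature_end)
  expect_equal(assign_arm(f, span), "none")
  # but its duplex is intact: no terminal-loop overlap, no unpaired run
  expect_true(check_loop_break(f, span))
  expect_equal(sum(is.na(f$partner[span[1]:span[2]])), 0)
})

test_that("star-mismatch counts equal the planted substitution counts", {
  for (sm in c(0, 2, 3, 7)) {
    hp <- build_hairpin("ACUCUCCCUCAAGGGCUUCAG", "5p", loop_len = 8,
                        star_mismatches = sm, seed = 10 + sm, stem_ext = 40)
    p <- fold_planted(hp)
    expect_equal(assign_arm(p$fold, p$span), "5p")
    expect_equal(count_star_mismatches(p$fold, p$span), sm)
  }
})

test_that("internal bulges beyond the gap limit fail the loop/break check", {
  hp <- build_hairpin("ACGCAGGAGAGAUGAUGCUGGA", "5p", loop_len = 8,
                      star_mismatches = 4, seed = 5, stem_ext = 40,
                      mismatch_mode = "contiguous")
  p <- fold_planted(hp)
  expect_false(check_loop_break(p$fold, p$span, max_internal_gap = 3))
  expect_true(check_loop_break(p$fold, p$span, max_internal_gap = 4))
  # spread mismatches of the same count pass
  hp2 <- build_hairpin("ACGCAGGAGAGAUGAUGCUGGA", "5p", loop_len = 8,
                       star_mismatches = 4, seed = 6, stem_ext = 40)
  p2 <- fold_planted(hp2)
  expect_true(check_loop_break(p2$fold, p2$span))
})

test_that("AMFE and MFEI follow their defining identities", {
  expect_equal(compute_mfei(50, 100, 50), list(amfe = 50, mfei = 1))
  expect_equal(compute_mfei(0, 421, 40)$mfei, 0)
  expect_equal(compute_mfei(84.2, 421, 40), list(amfe = 20, mfei = 0.5))
  expect_error(compute_mfei(50, 100, 0), "gc_pct")
  # scale consistency: doubling dG and length changes nothing
  a <- compute_mfei(37.3, 421, 43.2)
  b <- compute_mfei(74.6, 842, 43.2)
  expect_equal(a, b)
})

test_that("the verdict is the conjunction of the four criteria", {
  hp <- build_hairpin("UGAAGCUGCCAGCAUGAUCUGG", "5p", loop_len = 8,
                      star_mismatches = 2, seed = 7, stem_ext = 50)
  cand <- list(seq = hp$seq, mature_start = hp$mature_start,
               mature_end = hp$mature_end)
  f <- fold_mfe(hp$seq)
  ev <- evaluate_candidate(cand, f)
  expect_true(ev$verdict)
  expect_equal(unname(ev$passes), rep(TRUE, 4))
  expect_equal(ev$amfe, ev$delta_g_mag / nchar(hp$seq) * 100)
  expect_equal(ev$mfei, ev$amfe / ev$gc_pct)

  # raising the MFEI threshold can only shrink the accepted set
  stricter <- evaluate_candidate(cand, f,
                                 thresholds = list(mfei_threshold = 1.50,
                                                   max_star_mismatches = 6,
                                                   max_internal_gap = 3))
  expect_true(ev$passes["mfei"] >= stricter$passes["mfei"])
  expect_true(all(!stricter$verdict | ev$verdict))

  # tightening the mismatch cap likewise
  tight <- evaluate_candidate(cand, f,
                              thresholds = list(mfei_threshold = 0.70,
                                                max_star_mismatches = 1,
                                                max_internal_gap = 3))
  expect_false(tight$passes[["star_mismatch"]])
  expect_false(tight$verdict)
})

test_that("MFEI summaries use round-half-up at two decimals", {
  s <- summarize_mfei(c(0.70, 0.80))
  expect_equal(s$mean, 0.75)
  expect_equal(summarize_mfei(0.5), list(n = 1L, mean = 0.5, min = 0.5,
                                         max = 0.5))
  e <- summarize_mfei(numeric(0))
  expect_equal(e$n, 0L)
})
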