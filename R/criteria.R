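## The four precursor criteria applied to folded windows, plus the
## AMFE/MFEI statistics:
##   1. the mature sits entirely within one arm of the hairpin;
##   2. the window folds strongly: MFEI at or above a threshold;
##   3. at most `max_star_mismatches` mature bases are unpaired against
##      the star arm;
##   4. the mature neither touches the terminal loop nor contains an
##      unpaired run longer than `max_internal_gap`.

## Locate the terminal loop of a fold: take the longest helix (maximal
## run of stacked pairs; ties -> smallest 5' index), then walk inward
## from its innermost pair through single-branch loops until a hairpin
## loop is reached. If a multiloop blocks the walk, the unpaired bases
## directly enclosed by the last pair are used. Returns NULL when the
## structure has no pairs.
terminal_loop <- function(fold) {
  pairs <- fold$pairs
  if (!NROW(pairs)) return(NULL)
  partner <- fold$partner
  ## helices: consecutive stacked pairs
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  key <- paste(pairs[, 1], pairs[, 2])
  stacked_prev <- paste(pairs[, 1] - 1L, pairs[, 2] + 1L) %in% key
  helix_id <- cumsum(!stacked_prev)
  lens <- tabulate(helix_id)
  best <- which.max(lens)  # ties -> first = smallest i
  inner_row <- max(which(helix_id == best))
  a <- pairs[inner_row, 1]
  b <- pairs[inner_row, 2]
  repeat {
    inside <- (a + 1L):(b - 1L)
    kids_i <- inside[!is.na(partner[inside]) & partner[inside] > inside]
    kids_i <- kids_i[partner[kids_i] <= b - 1L]
    ## keep only top-level children of (a,b)
    if (length(kids_i) > 1) {
      keep <- logical(length(kids_i))
      cursor <- a
      for (q in seq_along(kids_i)) {
        if (kids_i[q] > cursor) {
          keep[q] <- TRUE
          cursor <- partner[kids_i[q]]
        }
      }
      kids_i <- kids_i[keep]
    }
    if (length(kids_i) == 0) {
      return(list(positions = inside, closing = c(a, b)))
    } else if (length(kids_i) == 1) {
      a <- kids_i
      b <- partner[kids_i]
    } else {
      un <- inside[is.na(partner[inside])]
      return(list(positions = un, closing = c(a, b)))
    }
  }
}

#' Assign the hairpin arm hosting the mature miRNA
#'
#' Returns `"5p"` or `"3p"` when the mature span avoids the terminal loop
#' and every paired mature base pairs across the loop to the opposite
#' arm; `"none"` otherwise (including structures without pairs, and
#' matures whose bases pair into a second stem).
#'
#' @param fold a [fold_mfe()] result for the precursor window.
#' @param mature_span integer vector `c(start, end)`, 1-based inclusive
#'   positions of the mature within the folded sequence; at least 20 nt.
#' @return `"5p"`, `"3p"` or `"none"`.
#' @export
assign_arm <- function(fold, mature_span) {
  stopifnot(inherits(fold, "fold_result"), length(mature_span) == 2)
  span <- mature_span[1]:mature_span[2]
  stopifnot(span[1] >= 1, span[length(span)] <= nchar(fold$seq))
  tl <- terminal_loop(fold)
  if (is.null(tl)) return("none")
  if (length(tl$positions) && any(span %in% tl$positions)) return("none")
  ls <- tl$closing[1]  # loop is strictly inside (ls, le)
  le <- tl$closing[2]
  side <- if (all(span <= ls)) "5p" else if (all(span >= le)) "3p" else return("none")
  partner <- fold$partner[span]
  paired <- partner[!is.na(partner)]
  opposite <- if (side == "5p") all(paired >= le) else all(paired <= ls)
  if (opposite) side else "none"
}

#' Count mature bases unpaired against the star arm
#'
#' The structural reading of "mismatches with the opposite miRNA": the
#' number of mature positions left unpaired in the MFE structure (bulged
#' bases count).
#'
#' @inheritParams assign_arm
#' @return an integer count.
#' @export
count_star_mismatches <- function(fold, mature_span) {
  if (assign_arm(fold, mature_span) == "none") {
    stop("count_star_mismatches requires the mature to lie in one arm",
         call. = FALSE)
  }
  unpaired_in_span(fold, mature_span)
}

unpaired_in_span <- function(fold, mature_span) {
  span <- mature_span[1]:mature_span[2]
  sum(is.na(fold$partner[span]))
}

#' Check duplex integrity of the mature ("no loop or break")
#'
#' TRUE iff the mature does not intersect the terminal loop and contains
#' no run of more than `max_internal_gap` consecutive unpaired bases.
#'
#' @inheritParams assign_arm
#' @param max_internal_gap longest tolerated unpaired run inside the
#'   mature, in nt.
#' @return logical.
#' @export
check_loop_break <- function(fold, mature_span, max_internal_gap = 3) {
  span <- mature_span[1]:mature_span[2]
  tl <- terminal_loop(fold)
  if (is.null(tl)) return(FALSE)
  if (length(tl$positions) && any(span %in% tl$positions)) return(FALSE)
  unp <- is.na(fold$partner[span])
  if (!any(unp)) return(TRUE)
  runs <- rle(unp)
  max(runs$lengths[runs$values]) <= max_internal_gap
}

#' Adjusted MFE and the minimal folding free energy index
#'
#' `amfe = delta_g_mag / length * 100` (kcal/mol per 100 nt);
#' `mfei = amfe / gc_pct`. High MFEI separates miRNA precursors from
#' typical mRNA, tRNA and rRNA.
#'
#' @param delta_g_mag magnitude of the negative folding free energy
#'   (kcal/mol).
#' @param length precursor window length, nt.
#' @param gc_pct GC percentage on (0, 100].
#' @return a list with `amfe` and `mfei`.
#' @examples
#' compute_mfei(50, 100, 50)  # amfe 50, mfei 1
#' @export
compute_mfei <- function(delta_g_mag, length, gc_pct) {
  stopifnot(length > 0)
  if (gc_pct <= 0 || gc_pct > 100) {
    stop("gc_pct must lie in (0, 100]", call. = FALSE)
  }
  amfe <- delta_g_mag / length * 100
  list(amfe = amfe, mfei = amfe / gc_pct)
}

#' Evaluate a precursor candidate against the four criteria
#'
#' @param candidate a precursor candidate from
#'   [extract_precursor_window()].
#' @param fold the [fold_mfe()] result for `candidate$seq`.
#' @param thresholds list with `mfei_threshold` (default 0.70),
#'   `max_star_mismatches` (6) and `max_internal_gap` (3).
#' @return a list of class `hairpin_evaluation` carrying the arm call,
#'   star-mismatch count, GC%, AMFE, MFEI, per-criterion flags and the
#'   conjunction verdict.
#' @export
evaluate_candidate <- function(candidate, fold,
                               thresholds = list(mfei_threshold = 0.70,
                                                 max_star_mismatches = 6,
                                                 max_internal_gap = 3)) {
  stopifnot(inherits(fold, "fold_result"))
  if (!identical(as_rna(candidate$seq), fold$seq)) {
    stop("fold does not correspond to the candidate sequence", call. = FALSE)
  }
  span <- c(candidate$mature_start, candidate$mature_end)
  arm <- assign_arm(fold, span)
  star_mm <- unpaired_in_span(fold, span)
  loop_ok <- check_loop_break(fold, span, thresholds$max_internal_gap)
  gc <- gc_percent(candidate$seq)
  if (gc > 0) {
    stats <- compute_mfei(fold$delta_g_mag, nchar(candidate$seq), gc)
    amfe <- stats$amfe
    mfei <- stats$mfei
    mfei_ok <- mfei >= thresholds$mfei_threshold
  } else {
    amfe <- fold$delta_g_mag / nchar(candidate$seq) * 100
    mfei <- NA_real_
    mfei_ok <- FALSE  # undefined MFEI can never pass criterion 2
  }
  passes <- c(
    arm = arm != "none",
    mfei = mfei_ok,
    star_mismatch = star_mm <= thresholds$max_star_mismatches,
    loop_break = loop_ok
  )
  structure(list(
    candidate = candidate,
    fold = fold,
    arm = arm,
    star_mismatches = star_mm,
    loop_break_ok = loop_ok,
    gc_pct = gc,
    amfe = amfe,
    mfei = mfei,
    delta_g_mag = fold$delta_g_mag,
    passes = passes,
    verdict = all(passes)
  ), class = "hairpin_evaluation")
}

#' Summarize MFEI values of accepted candidates
#'
#' @param evals a numeric vector of MFEI values, or a list of
#'   `hairpin_evaluation` objects.
#' @return a list with `n`, `mean` (2 decimals, round-half-up), `min`
#'   and `max`; `n = 0` yields an empty summary.
#' @examples
#' summarize_mfei(c(0.70, 0.80))$mean  # 0.75
#' @export
summarize_mfei <- function(evals) {
  vals <- if (is.numeric(evals)) {
    evals
  } else {
    vapply(evals, function(e) e$mfei, numeric(1))
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    return(list(n = 0L, mean = NA_real_, min = NA_real_, max = NA_real_))
  }
  list(n = length(vals),
       mean = round_half_up(mean(vals), 2),
       min = min(vals),
       max = max(vals))
}
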