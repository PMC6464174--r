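## MISA-style microsatellite detection. Default minimum repeat numbers
## per unit size 1-6 are {10, 6, 5, 5, 5, 5}. A run is attributed to its
## primitive unit only, spans complete repeats, and is reported in
## 1-based inclusive coordinates.

#' Default SSR repeat thresholds
#'
#' Minimum repeat numbers for unit sizes 1-6.
#' @return a named integer vector.
#' @export
default_ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0) {
      unit <- substr(motif, 1, d)
      if (paste(rep(unit, u / d), collapse = "") == motif) return(FALSE)
    }
  }
  TRUE
}

#' Scan a transcript for microsatellites
#'
#' Reports every maximal tandem run whose primitive unit (1-6 nt) meets
#' its repeat threshold. Runs of a non-primitive unit are credited to
#' the primitive divisor only (no `(ATAT)n` when `(AT)2n` applies), runs
#' cover complete repeats, and a locus wholly contained in a locus of a
#' different unit size is suppressed. Motifs containing `N` are ignored.
#'
#' @param transcript a single sequence string, or a length-1 named
#'   character vector (the name becomes `transcript_id`).
#' @param thresholds named vector of minimum repeat numbers for unit
#'   sizes 1-6 ([default_ssr_thresholds()]).
#' @return a data.frame of loci: `transcript_id`, `motif` (as read),
#'   `unit_len`, `repeats`, `start`, `end` (1-based inclusive),
#'   `motif_class` (canonical representative), sorted by start.
#' @examples
#' scan_ssrs(c(tx = paste0(strrep("AG", 6), "CCCTTTGGGAAA")))
#' @export
scan_ssrs <- function(transcript, thresholds = default_ssr_thresholds()) {
  id <- if (!is.null(names(transcript))) names(transcript)[1] else "seq1"
  s <- toupper(as_dna(transcript[[1]]))
  check_alphabet(s, "ACGTN", "transcript")
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  loci <- list()
  for (u in 1:6) {
    min_rep <- thresholds[[as.character(u)]]
    if (n < u * min_rep) next
    eq <- ch[seq_len(n - u)] == ch[seq_len(n - u) + u]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      run_start <- starts[q]               # first position of the run
      run_len <- r$lengths[q] + u          # char length incl. the u seed
      repeats <- run_len %/% u
      if (repeats < min_rep) next
      motif <- substr(s, run_start, run_start + u - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next
      loci[[length(loci) + 1L]] <- data.frame(
        transcript_id = id, motif = motif, unit_len = u,
        repeats = repeats, start = run_start,
        end = run_start + repeats * u - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(loci)) return(empty_ssr_frame())
  df <- do.call(rbind, loci)
  ## suppress loci wholly contained in a locus of another unit size
  if (nrow(df) > 1) {
    drop <- logical(nrow(df))
    for (a in seq_len(nrow(df))) {
      for (b in seq_len(nrow(df))) {
        if (a == b || df$unit_len[a] == df$unit_len[b]) next
        if (df$start[a] >= df$start[b] && df$end[a] <= df$end[b]) {
          drop[a] <- TRUE
          break
        }
      }
    }
    df <- df[!drop, , drop = FALSE]
  }
  df$motif_class <- vapply(df$motif,
                           function(m) canonical_motif_class(m)$representative,
                           character(1), USE.NAMES = FALSE)
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_ssr_frame <- function() {
  data.frame(transcript_id = character(0), motif = character(0),
             unit_len = integer(0), repeats = integer(0),
             start = integer(0), end = integer(0),
             motif_class = character(0), stringsAsFactors = FALSE)
}

#' Canonical motif class of a microsatellite unit
#'
#' The class notation conventional for EST-SSR surveys (AG/CT, AAG/CTT,
#' ...): a motif, all its cyclic rotations, and all rotations of its
#' reverse complement form one class represented by the
#' lexicographically smallest member.
#'
#' @param motif a primitive repeat unit, 1-6 nt (DNA).
#' @return a list with `representative` and the sorted `members`.
#' @examples
#' canonical_motif_class("CT")$representative   # "AG"
#' canonical_motif_class("CTT")$representative  # "AAG"
#' @export
canonical_motif_class <- function(motif) {
  motif <- toupper(as_dna(motif))
  u <- nchar(motif)
  if (u < 1 || u > 6) stop("motif must be 1-6 nt", call. = FALSE)
  check_alphabet(motif, "ACGT", "motif")
  if (!is_primitive_motif(motif)) {
    stop("motif is not primitive: ", motif, call. = FALSE)
  }
  rot <- function(m) {
    k <- nchar(m)
    vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1))
    }, character(1))
  }
  members <- sort(unique(c(rot(motif), rot(revcomp_dna(motif)))))
  list(representative = members[1], members = members)
}

#' Group nearby loci into compound microsatellites
#'
#' Loci on one transcript separated by at most `max_interruption`
#' intervening bases share a `compound_id`; isolated loci get `NA`.
#'
#' @param loci a [scan_ssrs()] data.frame for a single transcript,
#'   sorted by start.
#' @param max_interruption largest interruption in nt (default 100).
#' @return `loci` with a `compound_id` column.
#' @export
merge_compound <- function(loci, max_interruption = 100) {
  if (!NROW(loci)) {
    loci$compound_id <- character(0)
    return(loci)
  }
  stopifnot(!is.unsorted(loci$start))
  gap <- loci$start[-1] - loci$end[-nrow(loci)] - 1L
  grp <- cumsum(c(1L, as.integer(gap > max_interruption)))
  sizes <- table(grp)
  in_group <- as.vector(sizes[as.character(grp)]) > 1
  loci$compound_id <- ifelse(in_group, paste0("c", grp), NA_character_)
  loci
}

#' Distribution of microsatellites by unit size and motif class
#'
#' Mononucleotide runs are excluded by default: in transcriptome
#' assemblies they are confounded with sequencing and assembly error.
#'
#' @param loci a [scan_ssrs()]-style data.frame (any number of
#'   transcripts).
#' @param exclude_mono drop unit-length-1 loci first (default TRUE).
#' @return a data.frame with `level` (`unit_length` or `motif_class`),
#'   `key`, `n` and `pct`; percentages within each level sum to 100 up
#'   to rounding.
#' @export
ssr_summary <- function(loci, exclude_mono = TRUE) {
  if (exclude_mono && NROW(loci)) {
    loci <- loci[loci$unit_len > 1, , drop = FALSE]
  }
  if (!NROW(loci)) {
    return(data.frame(level = character(0), key = character(0),
                      n = integer(0), pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  one <- function(level, keys) {
    tab <- sort(table(keys), decreasing = TRUE)
    data.frame(level = level, key = names(tab), n = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / sum(tab), 2),
               stringsAsFactors = FALSE)
  }
  unit_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  rbind(one("unit_length", unit_names[loci$unit_len]),
        one("motif_class", loci$motif_class))
}
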