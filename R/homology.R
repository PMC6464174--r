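## Homology screen: reference deduplication, exact full-length matching
## of mature miRNAs in transcripts, and precursor-window extraction.
## Exact substring semantics replace a heuristic aligner here: requiring
## zero mismatches, zero gaps and full mature length makes every hit an
## exact substring, so no e-value machinery is needed and the accepted
## set is unchanged.

#' Read a mature-miRNA reference FASTA
#'
#' Accepts miRBase-style headers (`ath-miR319a ...`); the family label is
#' parsed from the id (`miR319a` -> `mir319`). U-containing sequences are
#' accepted and stored as RNA.
#'
#' @param path FASTA file of mature sequences.
#' @return a data.frame with `id`, `family`, `seq` (RNA).
#' @export
read_mature_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as_rna(as.character(set))
  check_alphabet(seqs, "ACGU", "mature reference")
  len <- nchar(seqs)
  if (any(len < 18 | len > 26)) {
    stop("mature references must be 18-26 nt", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate mature ids", call. = FALSE)
  data.frame(id = ids, family = mirna_family(ids), seq = seqs,
             stringsAsFactors = FALSE)
}

mirna_family <- function(id) {
  m <- regmatches(id, regexpr("(?i)mir[0-9]+", id, perl = TRUE))
  fam <- rep(NA_character_, length(id))
  fam[regexpr("(?i)mir[0-9]+", id, perl = TRUE) > 0] <- tolower(m)
  ifelse(is.na(fam), tolower(id), fam)
}

#' Read a transcript FASTA
#'
#' @param path FASTA file of assembled transcripts (DNA, `N` allowed).
#' @return a named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty transcript record", call. = FALSE)
  check_alphabet(seqs, "ACGTN", "transcript")
  names(seqs) <- ids
  seqs
}

#' Remove redundant mature references
#'
#' 100%-identity clustering: a retained sequence is never identical to,
#' nor a full-length substring of, another retained sequence. On a
#' containment tie the longer sequence is kept; among identical
#' sequences the lexicographically smallest id wins. Idempotent.
#'
#' @param refs data.frame with `id` and `seq` columns (RNA or DNA).
#' @return the retained subset, original row order preserved.
#' @export
deduplicate_matures <- function(refs) {
  if (!NROW(refs)) stop("empty mature reference set", call. = FALSE)
  seqs <- as_rna(refs$seq)
  ord <- order(-nchar(seqs), refs$id)
  keep_idx <- integer(0)
  for (r in ord) {
    contained <- FALSE
    for (k in keep_idx) {
      if (grepl(seqs[r], seqs[k], fixed = TRUE)) {
        contained <- TRUE
        break
      }
    }
    if (!contained) keep_idx <- c(keep_idx, r)
  }
  refs[sort(keep_idx), , drop = FALSE]
}

#' Find exact full-length mature matches in transcripts
#'
#' Reports every occurrence of each mature reference (T/U equivalent,
#' zero mismatches, zero gaps) in the forward strand of every transcript;
#' matures shorter than `min_len` cannot produce hits. With
#' `both_strands = TRUE` the reverse complement is searched too and
#' hits are reported in forward coordinates with `strand = "-"`.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param matures data.frame with `id`, `seq` (see [read_mature_fasta()]).
#' @param min_len minimum mature length for a reportable hit (nt).
#' @param both_strands also search the reverse complement (default off:
#'   assembled transcripts are oriented mRNA surrogates).
#' @return a data.frame of hits: `transcript_id`, `mature_id`, `t_start`,
#'   `t_end` (1-based inclusive), `match_len`, `strand`, sorted by
#'   (transcript_id, t_start).
#' @export
find_homology_hits <- function(transcripts, matures, min_len = 20,
                               both_strands = FALSE) {
  stopifnot(min_len >= 1)
  usable <- matures[nchar(matures$seq) >= min_len, , drop = FALSE]
  out <- list()
  subj <- Biostrings::DNAStringSet(unname(transcripts))
  names(subj) <- names(transcripts)
  strands <- if (both_strands) c("+", "-") else "+"
  for (r in seq_len(NROW(usable))) {
    pat_fwd <- as_dna(usable$seq[r])
    for (strand in strands) {
      pat <- if (strand == "+") pat_fwd else revcomp_dna(pat_fwd)
      mt <- Biostrings::vmatchPattern(pat, subj, fixed = TRUE)
      for (tix in seq_along(mt)) {
        rg <- mt[[tix]]
        if (!length(rg)) next
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = names(subj)[tix],
          mature_id = usable$id[r],
          t_start = IRanges::start(rg),
          t_end = IRanges::end(rg),
          match_len = IRanges::width(rg),
          strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), mature_id = character(0),
                      t_start = integer(0), t_end = integer(0),
                      match_len = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$transcript_id, hits$t_start, hits$mature_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Cut the precursor window around a homology hit
#'
#' The window runs from `flank` nt upstream of the mature start to
#' `flank` nt downstream of its end ("about 400 nt" at the default 200-nt
#' flank), clipped at the transcript ends; clipped windows carry
#' `truncated = TRUE` and proceed through the cascade.
#'
#' @param hit one row of [find_homology_hits()] output.
#' @param transcript the host transcript sequence (single string).
#' @param flank flank size in nt (default 200).
#' @return a list of class `precursor_candidate`: window coordinates on
#'   the transcript (1-based inclusive), the window sequence as RNA,
#'   the mature span inside the window, and a `truncated` flag.
#' @export
extract_precursor_window <- function(hit, transcript, flank = 200) {
  n <- nchar(transcript)
  if (hit$t_start < 1 || hit$t_end > n || hit$t_start > hit$t_end) {
    stop("hit coordinates outside transcript", call. = FALSE)
  }
  ws <- max(1L, hit$t_start - as.integer(flank))
  we <- min(n, hit$t_end + as.integer(flank))
  structure(list(
    transcript_id = hit$transcript_id,
    mature_id = hit$mature_id,
    window_start = ws,
    window_end = we,
    seq = as_rna(substr(transcript, ws, we)),
    mature_start = hit$t_start - ws + 1L,
    mature_end = hit$t_end - ws + 1L,
    truncated = (ws > hit$t_start - flank) || (we < hit$t_end + flank),
    coding_flag = NA
  ), class = "precursor_candidate")
}
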