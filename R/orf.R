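## Six-frame open-reading-frame heuristic used to drop protein-coding
## precursor windows before folding. An ORF is a run of sense codons in
## any of the six frames: complete (ATG .. stop), 3'-partial (ATG to the
## transcript edge, no stop reached) or 5'-partial (frame start to the
## first stop, no ATG required) -- the TransDecoder-like reading of
## "open at the transcript boundaries". Lengths are counted in codons,
## excluding the stop.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' @param seq a transcript sequence (DNA).
#' @param min_aa minimum ORF length in codons (amino acids).
#' @return a data.frame with `start`, `end` (1-based inclusive, forward
#'   transcript coordinates of the codon span), `strand`, `frame` (0-2),
#'   `n_aa`, `partial` (`"none"`, `"5p"`, `"3p"`, `"both"`).
#' @export
find_orfs <- function(seq, min_aa = 100) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_dna(seq)
    for (frame in 0:2) {
      n_cod <- (n - frame) %/% 3
      if (n_cod < 1) next
      starts <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      ## segment the frame at stop codons; each segment is a candidate
      seg_id <- cumsum(c(TRUE, is_stop[-n_cod]))
      for (sid in unique(seg_id)) {
        idx <- which(seg_id == sid)
        ## drop the stop codon that opened the segment
        idx <- idx[!is_stop[idx]]
        if (!length(idx)) next
        has_stop_after <- (max(idx) < n_cod) && is_stop[max(idx) + 1L]
        open5 <- min(idx) == 1L  # segment touches the frame start
        atg_in <- which(is_atg[idx])
        ## candidate starts: first ATG (complete/3'-partial), or the
        ## segment start when the segment is 5'-open
        cand <- integer(0)
        if (length(atg_in)) cand <- idx[atg_in[1]]
        if (open5 && (!length(cand) || cand > idx[1])) cand <- c(idx[1], cand)
        for (c0 in unique(cand)) {
          aa <- max(idx) - c0 + 1L
          if (aa < min_aa) next
          p5 <- (c0 == idx[1]) && open5 && !is_atg[c0]
          p3 <- !has_stop_after
          cs <- frame + 1L + 3L * (c0 - 1L)
          ce <- frame + 3L * max(idx)
          if (strand == "-") {
            tmp <- cs
            cs <- n - ce + 1L
            ce <- n - tmp + 1L
          }
          out[[length(out) + 1L]] <- data.frame(
            start = cs, end = ce, strand = strand, frame = frame,
            n_aa = aa,
            partial = if (p5 && p3) "both" else if (p5) "5p"
                      else if (p3) "3p" else "none",
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_aa = integer(0), partial = character(0),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, out)
  orfs[order(orfs$start, orfs$end), , drop = FALSE]
}

#' Flag precursor windows that overlap a long ORF
#'
#' The in-package substitute for a protein-database search: a candidate
#' is flagged as protein-coding iff its window overlaps an ORF of at
#' least `min_orf_aa` codons in any of the six frames of the host
#' transcript. Flagged candidates are removed before folding.
#'
#' @param candidate a [extract_precursor_window()] result.
#' @param transcript the host transcript sequence.
#' @param min_orf_aa ORF length threshold in codons (default 100).
#' @return logical.
#' @export
flag_coding <- function(candidate, transcript, min_orf_aa = 100) {
  orfs <- find_orfs(transcript, min_aa = min_orf_aa)
  if (!NROW(orfs)) return(FALSE)
  any(orfs$start <= candidate$window_end & orfs$end >= candidate$window_start)
}
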