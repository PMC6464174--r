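## Nearest-neighbor duplex melting temperatures (SantaLucia 1998 unified
## parameter set) and exhaustive flanking primer-pair search under the
## marker-development constraints: product 100-300 bp, primer 18-25 nt,
## Tm 55-62 C with 57 C optimal.

## Unified NN parameters: dH kcal/mol, dS cal/(mol K), 37 C, 1 M NaCl.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature of an oligonucleotide
#'
#' Two-state NN thermodynamics with the unified parameter table
#' (SantaLucia 1998): dimer stacking terms, terminal A/T and G/C
#' initiation corrections, the self-complementarity symmetry term, and
#' the entropic salt correction `dS + 0.368 (N-1) ln[Na+]`. `Tm(K) =
#' 1000 dH / (dS + R ln(Ct/x))` with `x = 4` for non-self-complementary
#' oligos.
#'
#' @param oligo primer sequence, 10-40 nt, A/C/G/T only.
#' @param monovalent_mM monovalent cation concentration (default 50 mM).
#' @param oligo_nM total strand concentration (default 50 nM).
#' @return melting temperature in degrees Celsius.
#' @examples
#' melt_tm("ATGCATGCATGCATGCATGC")
#' @export
melt_tm <- function(oligo, monovalent_mM = 50, oligo_nM = 50) {
  stopifnot(is.character(oligo), length(oligo) == 1L)
  s <- toupper(as_dna(oligo))
  check_alphabet(s, "ACGT", "oligo")
  n <- nchar(s)
  if (n < 10 || n > 40) stop("oligo must be 10-40 nt", call. = FALSE)
  dimers <- substring(s, seq_len(n - 1), seq_len(n - 1) + 1)
  dh <- sum(NN_DH[dimers])
  ds <- sum(NN_DS[dimers])
  for (term in c(substr(s, 1, 1), substr(s, n, n))) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1
      ds <- ds - 2.8
    } else {
      dh <- dh + 2.3
      ds <- ds + 4.1
    }
  }
  selfcomp <- identical(s, revcomp_dna(s))
  x <- 4
  if (selfcomp) {
    ds <- ds - 1.4
    x <- 1
  }
  ds <- ds + 0.368 * (n - 1) * log(monovalent_mM / 1000)
  ct <- oligo_nM * 1e-9
  1000 * dh / (ds + 1.9872 * log(ct / x)) - 273.15
}

#' Default primer-design constraints
#' @return a list: product size range (bp), primer length range (nt),
#'   Tm range and optimum (C), plus the Tm assay conditions.
#' @export
default_primer_constraints <- function() {
  list(product = c(100, 300), length = c(18, 25),
       tm = c(55, 62), tm_opt = 57,
       monovalent_mM = 50, oligo_nM = 50)
}

#' Design flanking primer pairs for a microsatellite locus
#'
#' Exhaustively enumerates forward and reverse primers in the flanks
#' (never overlapping the repeat run), keeps those meeting the length
#' and Tm constraints, pairs them under the product-size constraint and
#' ranks pairs by `|mean Tm - tm_opt|`, then `|Tm_fwd - Tm_rev|`. For
#' each 3' position only the candidate closest to the optimum Tm is
#' kept, which bounds the search without losing good designs.
#'
#' @param transcript the host sequence (single string or length-1 named
#'   vector).
#' @param locus one row of [scan_ssrs()] output (list or data.frame row).
#' @param constraints see [default_primer_constraints()].
#' @param max_pairs maximum number of ranked pairs returned.
#' @return a data.frame of pairs: `forward_seq`, `fwd_start`, `fwd_tm`,
#'   `reverse_seq`, `rev_end`, `rev_tm`, `product_size`. Empty (with a
#'   `reason` attribute) when no design satisfies the constraints.
#' @export
design_primer_pairs <- function(transcript, locus,
                                constraints = default_primer_constraints(),
                                max_pairs = 5) {
  s <- toupper(as_dna(transcript[[1]]))
  n <- nchar(s)
  cs <- constraints
  empty <- function(reason) {
    out <- data.frame(forward_seq = character(0), fwd_start = integer(0),
                      fwd_tm = numeric(0), reverse_seq = character(0),
                      rev_end = integer(0), rev_tm = numeric(0),
                      product_size = integer(0), stringsAsFactors = FALSE)
    attr(out, "reason") <- reason
    out
  }
  left <- locus$start - 1L
  right <- n - locus$end
  if (left < cs$length[1] || right < cs$length[1]) {
    return(empty("flank shorter than the minimum primer length"))
  }

  candidates <- function(region_start, region_end, strand) {
    ## enumerate primers lying fully within [region_start, region_end]
    cand <- list()
    for (len in cs$length[1]:cs$length[2]) {
      if (region_end - len + 1L < region_start) next
      starts <- seq.int(region_start, region_end - len + 1L)
      for (st in starts) {
        sub <- substr(s, st, st + len - 1L)
        if (grepl("N", sub, fixed = TRUE)) next
        seqp <- if (strand == "+") sub else revcomp_dna(sub)
        tm <- melt_tm(seqp, cs$monovalent_mM, cs$oligo_nM)
        if (tm < cs$tm[1] || tm > cs$tm[2]) next
        cand[[length(cand) + 1L]] <- data.frame(
          seq = seqp, start = st, end = st + len - 1L, tm = tm,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) return(NULL)
    df <- do.call(rbind, cand)
    ## one candidate per 3' position: the one closest to the optimum
    anchor <- if (strand == "+") df$end else df$start
    ord <- order(anchor, abs(df$tm - cs$tm_opt))
    df <- df[ord, , drop = FALSE]
    df[!duplicated(anchor[ord]), , drop = FALSE]
  }

  fwd <- candidates(1L, locus$start - 1L, "+")
  if (is.null(fwd)) return(empty("no forward primer satisfies the constraints"))
  rvs <- candidates(locus$end + 1L, n, "-")
  if (is.null(rvs)) return(empty("no reverse primer satisfies the constraints"))

  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rvs)))
  ps <- rvs$end[grid$r] - fwd$start[grid$f] + 1L
  ok <- ps >= cs$product[1] & ps <= cs$product[2]
  if (!any(ok)) return(empty("no pair satisfies the product-size constraint"))
  grid <- grid[ok, , drop = FALSE]
  ps <- ps[ok]
  mean_dev <- abs((fwd$tm[grid$f] + rvs$tm[grid$r]) / 2 - cs$tm_opt)
  tm_diff <- abs(fwd$tm[grid$f] - rvs$tm[grid$r])
  ord <- order(mean_dev, tm_diff, ps)
  grid <- grid[ord, , drop = FALSE]
  ps <- ps[ord]
  keep <- seq_len(min(max_pairs, nrow(grid)))
  data.frame(
    forward_seq = fwd$seq[grid$f[keep]],
    fwd_start = fwd$start[grid$f[keep]],
    fwd_tm = fwd$tm[grid$f[keep]],
    reverse_seq = rvs$seq[grid$r[keep]],
    rev_end = rvs$end[grid$r[keep]],
    rev_tm = rvs$tm[grid$r[keep]],
    product_size = ps[keep],
    stringsAsFactors = FALSE
  )
}
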