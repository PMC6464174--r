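# Independent oracles used by the property and acceptance tests. Each is
# a brute-force reimplementation that deliberately shares no code with
# the package internals it checks.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T"), gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# quadratic exact-substring scan (homology oracle)
naive_hits <- function(transcripts, matures, min_len = 20) {
  out <- list()
  for (tid in names(transcripts)) {
    tx <- chartr("U", "T", toupper(transcripts[[tid]]))
    for (r in seq_len(nrow(matures))) {
      pat <- chartr("U", "T", toupper(matures$seq[r]))
      m <- nchar(pat)
      if (m < min_len) next
      n <- nchar(tx)
      if (n < m) next
      for (i in seq_len(n - m + 1)) {
        if (substr(tx, i, i + m - 1) == pat) {
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = tid, mature_id = matures$id[r],
            t_start = i, t_end = i + m - 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), mature_id = character(0),
                      t_start = integer(0), t_end = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$transcript_id, df$t_start, df$mature_id), , drop = FALSE]
}

# regex back-reference microsatellite scan (SSR oracle)
oracle_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 &&
        paste(rep(substr(motif, 1, d), u / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

regex_ssr_oracle <- function(seq, thresholds = c(10, 6, 5, 5, 5, 5)) {
  s <- toupper(seq)
  out <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thresholds[u] - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      start <- m[k]
      motif <- substr(s, start, start + u - 1L)
      if (!oracle_primitive(motif)) next
      repeats <- lens[k] %/% u
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = u, repeats = repeats,
        start = start, end = start + repeats * u - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), unit_len = integer(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0)))
  }
  df <- do.call(rbind, out)
  # same containment rule as the scanner: a locus inside a locus of a
  # different unit size is suppressed
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
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independently coded nearest-neighbor Tm from the same published table:
# dimer parameters derived on the fly from the 10 unique duplex steps via
# the complement rule, accumulated in an explicit character loop
oracle_tm <- function(seq, na_mM = 50, ct_nM = 50) {
  uniq <- list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lookup <- function(d) {
    if (!is.null(uniq[[d]])) return(uniq[[d]])
    rc <- paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
    uniq[[rc]]
  }
  s <- strsplit(toupper(seq), "")[[1]]
  dh <- 0
  ds <- 0
  for (i in seq_len(length(s) - 1)) {
    v <- lookup(paste0(s[i], s[i + 1]))
    dh <- dh + v[1]
    ds <- ds + v[2]
  }
  for (b in c(s[1], s[length(s)])) {
    if (b == "G" || b == "C") {
      dh <- dh + 0.1
      ds <- ds - 2.8
    } else {
      dh <- dh + 2.3
      ds <- ds + 4.1
    }
  }
  rc_full <- paste(rev(comp[s]), collapse = "")
  x <- 4
  if (identical(paste(s, collapse = ""), rc_full)) {
    ds <- ds - 1.4
    x <- 1
  }
  ds <- ds + 0.368 * (length(s) - 1) * log(na_mM / 1000)
  1000 * dh / (ds + 1.9872 * log(ct_nM * 1e-9 / x)) - 273.15
}
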