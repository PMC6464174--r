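## Synthetic-transcriptome generator: plants hairpin precursors (true
## ones and decoys that each violate exactly one acceptance criterion),
## microsatellite loci and i.i.d. background, and emits a truth table so
## every downstream stage can be scored against known coordinates.
##
## Construction guarantees do the heavy lifting -- star arms are reverse
## complements with non-pairing substitutions at the declared mismatch
## positions, so the intended duplex is locked in by the nesting
## constraint -- and a verify-and-redraw loop folds and scans every
## planted transcript, re-drawing its background until the feature shows
## exactly its intended criterion profile. Fixtures are therefore valid
## under any seed, not just a blessed one.

## bases that can pair with neither b (Watson-Crick nor GU wobble)
non_partners <- function(b) {
  switch(b,
         A = c("A", "C", "G"),
         C = c("A", "C", "U"),
         G = c("A", "G"),
         U = c("C", "U"),
         stop("invalid base ", b, call. = FALSE))
}

#' Construct a hairpin precursor around a mature miRNA
#'
#' Builds `5' ext + mature + loop + star + rc(ext) 3'` (or the mirrored
#' layout for a 3p mature), where the star arm is the reverse complement
#' of the mature with `star_mismatches` positions substituted to bases
#' that can pair with neither the mature base (mismatch positions are
#' interior, so the duplex stays anchored at both ends). Mismatches are
#' spread (isolated, criterion-3 style) or contiguous (one internal
#' bulge, criterion-4 style).
#'
#' @param mature_seq mature miRNA, 20-24 nt RNA (DNA accepted).
#' @param arm `"5p"` or `"3p"`: which arm carries the mature.
#' @param loop_len terminal loop size, >= 3 nt.
#' @param star_mismatches number of mature positions left unpaired.
#' @param seed integer seed; the construction is deterministic given it.
#' @param stem_ext extra perfectly paired stem on each side, nt.
#' @param mismatch_mode `"spread"` or `"contiguous"`.
#' @param gc GC fraction of the random stem extension.
#' @return a list of class `hairpin`: `seq` (RNA), `mature_start`,
#'   `mature_end` (1-based within the precursor), `arm`,
#'   `mismatch_positions` (mature-relative).
#' @examples
#' hp <- build_hairpin("UGAGGUAGUAGGUUGUAUAGUU", "5p", loop_len = 6,
#'                     star_mismatches = 0, seed = 1)
#' nchar(hp$seq)
#' @export
build_hairpin <- function(mature_seq, arm = c("5p", "3p"), loop_len = 8,
                          star_mismatches = 0, seed = 1, stem_ext = 0,
                          mismatch_mode = c("spread", "contiguous"),
                          gc = 0.42) {
  arm <- match.arg(arm)
  mismatch_mode <- match.arg(mismatch_mode)
  m <- as_rna(mature_seq)
  check_alphabet(m, "ACGU", "mature sequence")
  len <- nchar(m)
  if (len < 20 || len > 24) stop("mature must be 20-24 nt", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  if (star_mismatches > len) {
    stop("star_mismatches exceeds mature length", call. = FALSE)
  }
  withr::with_seed(seed, {
    mb <- strsplit(m, "", fixed = TRUE)[[1]]
    layout <- mismatch_layout(mb, star_mismatches, mismatch_mode)
    pos <- layout$pos
    subs <- layout$subs
    star_b <- strsplit(revcomp_rna(m), "", fixed = TRUE)[[1]]
    star_b[len - pos + 1L] <- subs
    star <- paste(star_b, collapse = "")
    ## A/C loops cannot pair internally (no A-C, A-A or C-C pairs) and,
    ## being random, do not plant accidental homopolymer microsatellites
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                  collapse = "")
    ext5 <- if (stem_ext > 0) as_rna(random_seq(stem_ext, gc)) else ""
    ext3 <- if (stem_ext > 0) revcomp_rna(ext5) else ""
    if (arm == "5p") {
      seqs <- paste0(ext5, m, loop, star, ext3)
      mstart <- nchar(ext5) + 1L
    } else {
      seqs <- paste0(ext5, star, loop, m, ext3)
      mstart <- nchar(ext5) + len + loop_len + 1L
    }
    structure(list(seq = seqs, mature_start = mstart,
                   mature_end = mstart + len - 1L, arm = arm,
                   mismatch_positions = pos, loop_len = loop_len),
              class = "hairpin")
  })
}

## Choose mature positions to leave unpaired and the star-side
## substitutes that enforce it. Mismatch runs are kept short and the
## helices between them at least 3 bp, so the designed duplex register
## is also the thermodynamically optimal one and the realized unpaired
## count equals the requested one:
##   spread     - isolated positions, >= 3 paired bases between them;
##   grouped    - runs of up to 3 with >= 3 paired bases between runs
##                (for counts too large to place in isolation);
##   contiguous - one run (a single internal bulge of that size).
## Every run needs a base that pairs with none of its mature bases; run
## starts shift forward until such a substitute exists.
mismatch_layout <- function(mb, n_mm, mode) {
  len <- length(mb)
  if (n_mm == 0) return(list(pos = integer(0), subs = character(0)))
  run_lens <- switch(mode,
    spread = rep(1L, n_mm),
    contiguous = n_mm,
    grouped = {
      r <- c(rep(3L, n_mm %/% 3L), if (n_mm %% 3L) n_mm %% 3L)
      as.integer(r)
    })
  if (mode == "spread" && n_mm > 5) {
    ## not enough isolated slots on a <= 24-nt mature; fall back to runs
    run_lens <- c(rep(3L, n_mm %/% 3L), if (n_mm %% 3L) n_mm %% 3L)
    run_lens <- as.integer(run_lens)
  }
  pos <- integer(0)
  subs <- character(0)
  ## keep >= 3 paired anchor bases at both duplex ends: shorter anchor
  ## helices are not worth their loop penalties and open up in the fold
  start <- 4L
  for (rl in run_lens) {
    placed <- FALSE
    while (start + rl - 1L <= len - 3L) {
      window <- mb[start:(start + rl - 1L)]
      shared <- Reduce(intersect, lapply(window, non_partners))
      if (length(shared)) {
        ## prefer A/C substitutes: they have the fewest pairing partners
        ## (no wobble), so they cannot seed a shifted register
        pref <- intersect(shared, c("A", "C"))
        pool <- if (length(pref)) pref else shared
        pos <- c(pos, start:(start + rl - 1L))
        subs <- c(subs, rep(pool[sample.int(length(pool), 1)], rl))
        start <- start + rl + 3L
        placed <- TRUE
        break
      }
      start <- start + 1L
    }
    if (!placed) {
      stop("cannot place ", n_mm, " star mismatches (mode '", mode,
           "') on this mature sequence", call. = FALSE)
    }
  }
  list(pos = pos, subs = subs)
}

## Arm-violating construction: the mature straddles two adjacent
## hairpins, each half pairing into its own stem. All mature bases pair
## (criteria 3 and 4 hold), both stems are long (criterion 2 holds), but
## no single arm hosts the mature, so criterion 1 fails.
build_split_hairpin <- function(mature_seq, loop_len = 8, ext1 = 60,
                                ext2 = 45, seed = 1, gc = 0.42) {
  m <- as_rna(mature_seq)
  len <- nchar(m)
  h <- ceiling(len / 2)
  m1 <- substr(m, 1, h)
  m2 <- substr(m, h + 1, len)
  withr::with_seed(seed, {
    e1 <- as_rna(random_seq(ext1, gc))
    e2 <- as_rna(random_seq(ext2, gc))
    a <- paste0(revcomp_rna(m1), e1)
    b <- paste0(m2, e2)
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                  collapse = "")
    seqs <- paste0(a, loop, revcomp_rna(a), b, loop, revcomp_rna(b))
    mstart <- nchar(a) + loop_len + nchar(e1) + 1L
    structure(list(seq = seqs, mature_start = mstart,
                   mature_end = mstart + len - 1L, arm = "none",
                   mismatch_positions = integer(0), loop_len = loop_len),
              class = "hairpin")
  })
}

#' Default synthetic-fixture configuration
#'
#' The standard study-scale fixture: three true precursors (5p and 3p
#' arms, 0/2/4 star mismatches, 65-nt stem extensions — dominant hairpins
#' of realistic precursor size), five decoys each violating exactly one
#' criterion (arm, MFEI, star-mismatch count, loop/break, protein-coding
#' overlap), five SSR loci spanning unit sizes 1-3 at and above the MISA
#' thresholds, and i.i.d. background at 42% GC (a typical plant
#' transcriptome composition). Mature sequences come from the packaged
#' reference set of conserved plant miRNA families.
#'
#' @return a nested list understood by [generate_fixture()].
#' @export
default_fixture_config <- function() {
  list(
    background = list(n = 4L, length = 800L, gc = 0.42),
    precursors = list(
      list(kind = "true", mature_id = "ath-miR319a", arm = "5p",
           loop_len = 8, star_mismatches = 0, stem_ext = 65,
           host_length = 1000L, host_gc = 0.42),
      list(kind = "true", mature_id = "cca-miR396c", arm = "3p",
           loop_len = 12, star_mismatches = 2, stem_ext = 65,
           host_length = 1000L, host_gc = 0.42),
      list(kind = "true", mature_id = "ath-miR167d", arm = "5p",
           loop_len = 8, star_mismatches = 4, stem_ext = 65,
           host_length = 1000L, host_gc = 0.42),
      list(kind = "decoy_arm", mature_id = "pde-miR159",
           host_length = 1000L, host_gc = 0.42),
      list(kind = "decoy_star_mismatch", mature_id = "mes-miR477h",
           arm = "5p", loop_len = 8, star_mismatches = 7, stem_ext = 65,
           host_length = 1000L, host_gc = 0.42),
      list(kind = "decoy_loop_break", mature_id = "sly-miR4376",
           arm = "5p", loop_len = 8, star_mismatches = 4, stem_ext = 65,
           mismatch_mode = "contiguous", host_length = 1000L,
           host_gc = 0.42),
      list(kind = "decoy_mfei", mature_id = "gma-miR169d", arm = "5p",
           loop_len = 8, star_mismatches = 0, stem_ext = 0,
           host_length = 1000L, host_gc = 0.60),
      list(kind = "decoy_coding", mature_id = "ctr-miR171", arm = "5p",
           loop_len = 8, star_mismatches = 0, stem_ext = 65,
           host_length = 1200L, host_gc = 0.42)
    ),
    ssrs = list(
      list(motif = "AG", repeats = 8L, host_length = 600L, host_gc = 0.42),
      list(motif = "AAG", repeats = 6L, host_length = 600L, host_gc = 0.42),
      list(motif = "TCA", repeats = 5L, host_length = 600L, host_gc = 0.42),
      list(motif = "AT", repeats = 7L, host_length = 600L, host_gc = 0.42),
      list(motif = "C", repeats = 12L, host_length = 600L, host_gc = 0.42)
    ),
    max_tries = 30L
  )
}

#' Path to the packaged mature-miRNA reference FASTA
#' @return a file path.
#' @export
default_mature_fasta <- function() {
  system.file("extdata", "mature_refs.fa", package = "mirssr",
              mustWork = TRUE)
}

splice_seq <- function(host, pos, insert) {
  paste0(substr(host, 1, pos - 1L), insert,
         substr(host, pos + nchar(insert), nchar(host)))
}

## guard the bases flanking a planted SSR run so the run cannot extend
guard_ssr_flanks <- function(host, start, end, motif) {
  u <- nchar(motif)
  ch <- strsplit(host, "", fixed = TRUE)[[1]]
  if (start > 1) {
    bad <- substr(motif, u, u)
    if (ch[start - 1] == bad) {
      ch[start - 1] <- sample(setdiff(c("A", "C", "G", "T"), bad), 1)
    }
  }
  if (end < length(ch)) {
    bad <- substr(motif, 1, 1)
    if (ch[end + 1] == bad) {
      ch[end + 1] <- sample(setdiff(c("A", "C", "G", "T"), bad), 1)
    }
  }
  paste(ch, collapse = "")
}

## a stop-free random ORF of n_codons (incl. ATG, excl. the TAA added)
random_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Generate a synthetic transcriptome fixture with a truth table
#'
#' Draws background transcripts and plants the configured precursors,
#' decoys and SSR loci (see [default_fixture_config()]). Each planted
#' transcript is validated by running the package's own screen on it
#' (fold + criteria for precursors, [scan_ssrs()] + primer design for
#' SSR hosts) and re-drawn with fresh background until it exhibits
#' exactly the intended profile. Output is byte-identical for identical
#' `(config, seed)`.
#'
#' @param config a fixture configuration list.
#' @param seed integer seed controlling every random draw.
#' @param out_dir if non-NULL, write `transcripts.fa` (70-column FASTA)
#'   and `truth.tsv` there.
#' @return a list of class `fixture`: `transcripts` (named character),
#'   `truth` (data.frame: feature_type, transcript_id, start, end,
#'   payload JSON string), `seed`.
#' @export
generate_fixture <- function(config = default_fixture_config(), seed = 42,
                             out_dir = NULL) {
  matures <- read_mature_fasta(default_mature_fasta())
  thresholds <- list(mfei_threshold = 0.70, max_star_mismatches = 6,
                     max_internal_gap = 3)
  max_tries <- config$max_tries %||% 30L
  transcripts <- character(0)
  truth <- list()
  withr::with_seed(seed, {
    tx_i <- 0L
    next_id <- function() {
      tx_i <<- tx_i + 1L
      sprintf("tx%04d", tx_i)
    }

    for (spec in config$precursors) {
      id <- next_id()
      ref <- matures[matures$id == spec$mature_id, , drop = FALSE]
      if (!nrow(ref)) stop("unknown mature id: ", spec$mature_id, call. = FALSE)
      built <- NULL
      for (try in seq_len(max_tries)) {
        built <- build_precursor_host(spec, ref, matures, thresholds)
        if (!is.null(built)) break
      }
      if (is.null(built)) {
        stop("could not realize planted feature in ", spec$mature_id,
             " host after ", max_tries, " draws", call. = FALSE)
      }
      transcripts[id] <- built$host
      payload <- jsonlite::toJSON(c(list(
        family = ref$family, mature_id = ref$id, kind = spec$kind),
        built$meta), auto_unbox = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        feature_type = if (spec$kind == "true") "precursor" else "decoy",
        transcript_id = id, start = built$start, end = built$end,
        payload = as.character(payload), stringsAsFactors = FALSE)
    }

    for (spec in config$ssrs) {
      id <- next_id()
      built <- NULL
      for (try in seq_len(max_tries)) {
        built <- build_ssr_host(spec, matures)
        if (!is.null(built)) break
      }
      if (is.null(built)) {
        stop("could not realize planted SSR (", spec$motif, ")",
             call. = FALSE)
      }
      transcripts[id] <- built$host
      payload <- jsonlite::toJSON(list(motif = spec$motif,
                                       repeats = spec$repeats),
                                  auto_unbox = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        feature_type = "ssr", transcript_id = id,
        start = built$start, end = built$end,
        payload = as.character(payload), stringsAsFactors = FALSE)
    }

    bg <- config$background
    if (!is.null(bg) && bg$n > 0) {
      for (k in seq_len(bg$n)) {
        id <- next_id()
        for (try in seq_len(max_tries)) {
          host <- random_seq(bg$length, bg$gc)
          clean <- !NROW(scan_ssrs(stats::setNames(host, id))) &&
            !NROW(find_homology_hits(stats::setNames(host, id), matures))
          if (clean) break
        }
        transcripts[id] <- host
      }
    }
  })
  truth_df <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(feature_type = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0),
               payload = character(0), stringsAsFactors = FALSE)
  }
  out <- structure(list(transcripts = transcripts, truth = truth_df,
                        seed = seed, config = config),
                   class = "fixture")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    set <- Biostrings::DNAStringSet(transcripts)
    Biostrings::writeXStringSet(set, file.path(out_dir, "transcripts.fa"),
                                width = 70L)
    write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- c(transcripts = file.path(out_dir, "transcripts.fa"),
                   truth = file.path(out_dir, "truth.tsv"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## one attempt at a precursor/decoy host; NULL if the draw fails its
## intended criterion profile
build_precursor_host <- function(spec, ref, matures, thresholds) {
  kind <- spec$kind
  hp_seed <- sample.int(.Machine$integer.max, 1)
  hp <- if (kind == "decoy_arm") {
    build_split_hairpin(ref$seq, seed = hp_seed, gc = spec$host_gc)
  } else {
    build_hairpin(ref$seq, arm = spec$arm, loop_len = spec$loop_len,
                  star_mismatches = spec$star_mismatches, seed = hp_seed,
                  stem_ext = spec$stem_ext,
                  mismatch_mode = spec$mismatch_mode %||% "spread",
                  gc = spec$host_gc)
  }
  pre_dna <- as_dna(hp$seq)
  pre_len <- nchar(pre_dna)
  n <- spec$host_length
  if (pre_len + 40 > n) return(NULL)
  host <- random_seq(n, spec$host_gc)

  orf_span <- NULL
  if (kind == "decoy_coding") {
    ## ORF upstream; the precursor sits just downstream so its window
    ## reaches back into the ORF
    orf <- random_orf(178L)
    orf_pos <- 101L
    host <- splice_seq(host, orf_pos, orf)
    orf_span <- c(orf_pos, orf_pos + nchar(orf) - 1L)
    pos <- orf_span[2] + 41L
    if (pos + pre_len - 1L > n) return(NULL)
  } else {
    ## keep the window unclipped: 200 nt of host on both sides of the mature
    lo <- max(1L, 201L - hp$mature_start + 1L)
    hi <- n - pre_len + 1L
    hi <- min(hi, n - (hp$mature_end + 200L) + 1L)
    if (hi < lo) return(NULL)
    pos <- if (hi > lo) sample(lo:hi, 1) else lo
  }
  host <- splice_seq(host, pos, pre_dna)

  ## run the package's own screen on the host
  id <- "candidate"
  tx <- stats::setNames(host, id)
  hits <- find_homology_hits(tx, matures)
  if (nrow(hits) != 1 || hits$mature_id != ref$id) return(NULL)
  cand <- extract_precursor_window(hits[1, ], host)
  coding <- flag_coding(cand, host)
  ev <- evaluate_candidate(cand, fold_mfe(cand$seq), thresholds)
  profile_ok <- switch(kind,
    true = !coding && ev$verdict,
    decoy_arm = !coding && !ev$passes["arm"] && ev$passes["mfei"] &&
      ev$passes["star_mismatch"] && ev$passes["loop_break"],
    decoy_star_mismatch = !coding && !ev$passes["star_mismatch"] &&
      ev$passes["arm"] && ev$passes["mfei"] && ev$passes["loop_break"],
    decoy_loop_break = !coding && !ev$passes["loop_break"] &&
      ev$passes["arm"] && ev$passes["mfei"] &&
      ev$passes["star_mismatch"],
    decoy_mfei = !coding && !ev$passes["mfei"] && ev$passes["arm"] &&
      ev$passes["star_mismatch"] && ev$passes["loop_break"],
    decoy_coding = coding && ev$verdict,
    stop("unknown precursor kind: ", kind, call. = FALSE))
  if (!isTRUE(unname(profile_ok))) return(NULL)
  if (NROW(scan_ssrs(tx))) return(NULL)  # no accidental microsatellites
  meta <- list(arm = hp$arm, loop_len = hp$loop_len,
               star_mismatches = length(hp$mismatch_positions),
               mature_start = pos + hp$mature_start - 1L,
               mature_end = pos + hp$mature_end - 1L)
  if (kind != "true") {
    meta$violates <- sub("^decoy_", "", kind)
  }
  if (!is.null(orf_span)) meta$orf <- orf_span
  list(host = host, start = pos, end = pos + pre_len - 1L, meta = meta)
}

build_ssr_host <- function(spec, matures) {
  run <- strrep(spec$motif, spec$repeats)
  n <- spec$host_length
  if (nchar(run) + 80 > n) return(NULL)
  host <- random_seq(n, spec$host_gc)
  pos <- (n - nchar(run)) %/% 2L + 1L
  host <- splice_seq(host, pos, run)
  end <- pos + nchar(run) - 1L
  host <- guard_ssr_flanks(host, pos, end, spec$motif)
  id <- "ssr_host"
  loci <- scan_ssrs(stats::setNames(host, id))
  ok <- nrow(loci) == 1 && loci$start == pos && loci$end == end &&
    loci$motif == spec$motif && loci$repeats == spec$repeats
  if (!ok) return(NULL)
  if (NROW(find_homology_hits(stats::setNames(host, id), matures))) {
    return(NULL)
  }
  if (nchar(spec$motif) > 1) {
    pairs <- design_primer_pairs(host, loci[1, ])
    if (!nrow(pairs)) return(NULL)
  }
  list(host = host, start = pos, end = end)
}
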