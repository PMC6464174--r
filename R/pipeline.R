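## The two end-to-end pipelines (miRNA discovery; SSR marker design),
## flat key-value configuration, run manifests and the standard-format
## writers. Coordinates are 1-based inclusive in every emitted table and
## GFF3 record.

#' Default pipeline configuration
#'
#' Every default matches the screening protocol: 200-nt flanks, 20-nt
#' minimum exact match, MFEI threshold 0.70, at most 6 star mismatches,
#' at most a 3-nt unpaired run inside the mature, 100-aa ORF filter,
#' MISA repeat thresholds 10/6/5/5/5/5, and primer constraints
#' 100-300 bp product, 18-25 nt, 55-62 C with 57 C optimal.
#'
#' @return a named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    flank = 200L,
    min_match = 20L,
    mfei_threshold = 0.70,
    max_star_mismatches = 6L,
    max_internal_gap = 3L,
    min_orf_aa = 100L,
    ssr_thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                       `5` = 5L, `6` = 5L),
    max_compound_interruption = 100L,
    exclude_mono = TRUE,
    product_size = c(100L, 300L),
    primer_length = c(18L, 25L),
    tm_range = c(55, 62),
    tm_opt = 57,
    monovalent_mM = 50,
    oligo_nM = 50,
    both_strands = FALSE,
    dedupe_transcripts = FALSE,
    seed = 1L
  ), class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' YAML-formatted flat document; recognized keys override the defaults
#' and any unrecognized key is a hard error (typos must not silently
#' fall back to defaults).
#'
#' @param path configuration file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unrecognized configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    v <- user[[k]]
    if (k == "ssr_thresholds") v <- stats::setNames(as.integer(v), as.character(1:6))
    cfg[[k]] <- v
  }
  cfg
}

primer_constraints_from_config <- function(config) {
  list(product = config$product_size, length = config$primer_length,
       tm = config$tm_range, tm_opt = config$tm_opt,
       monovalent_mM = config$monovalent_mM, oligo_nM = config$oligo_nM)
}

resolve_transcripts <- function(transcripts) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    list(seqs = read_transcript_fasta(transcripts), path = transcripts)
  } else {
    stopifnot(is.character(transcripts), !is.null(names(transcripts)))
    list(seqs = toupper(transcripts), path = NA_character_)
  }
}

resolve_matures <- function(matures) {
  if (is.character(matures) && length(matures) == 1L && file.exists(matures)) {
    list(refs = read_mature_fasta(matures), path = matures)
  } else {
    stopifnot(is.data.frame(matures), all(c("id", "seq") %in% names(matures)))
    if (is.null(matures$family)) matures$family <- mirna_family(matures$id)
    list(refs = matures, path = NA_character_)
  }
}

run_manifest <- function(stage_counts, config, input_paths) {
  checks <- vapply(input_paths, function(p) {
    if (is.na(p)) NA_character_ else unname(tools::md5sum(p))
  }, character(1))
  list(tool = "mirssr",
       version = as.character(utils::packageVersion("mirssr")),
       config = config,
       input_md5 = as.list(checks),
       counts = stage_counts)
}

#' Run the miRNA discovery pipeline
#'
#' Stage order: deduplicate references -> exact homology hits ->
#' precursor windows -> ORF coding filter -> MFE folding -> four-criterion
#' evaluation -> window-level deduplication (best MFEI per window) ->
#' MFEI summary. Each filter's input/output counts are logged in the run
#' manifest so the cascade is auditable.
#'
#' @param transcripts transcript FASTA path, or a named character vector.
#' @param matures mature-reference FASTA path, or a data.frame with
#'   `id`, `seq`.
#' @param config a [default_config()]-style list.
#' @param out_dir if non-NULL, write `candidates.tsv`, `accepted.gff3`
#'   and `manifest.json` there.
#' @return a list of class `mirna_run`: `candidates` (evaluation table),
#'   `accepted` (verdict-true subset), `evaluations` (the underlying
#'   `hairpin_evaluation` objects of the deduplicated candidates),
#'   `mfei_summary`, `manifest`.
#' @export
run_mirna_pipeline <- function(transcripts, matures = default_mature_fasta(),
                               config = default_config(), out_dir = NULL) {
  tx <- resolve_transcripts(transcripts)
  mr <- resolve_matures(matures)

  refs <- deduplicate_matures(mr$refs)
  seqs <- tx$seqs
  if (isTRUE(config$dedupe_transcripts)) {
    tdf <- data.frame(id = names(seqs), seq = unname(seqs),
                      stringsAsFactors = FALSE)
    tdf <- deduplicate_matures(tdf)
    seqs <- stats::setNames(tdf$seq, tdf$id)
  }
  hits <- find_homology_hits(seqs, refs, min_len = config$min_match,
                             both_strands = isTRUE(config$both_strands))

  thresholds <- list(mfei_threshold = config$mfei_threshold,
                     max_star_mismatches = config$max_star_mismatches,
                     max_internal_gap = config$max_internal_gap)
  evals <- list()
  n_coding <- 0L
  for (r in seq_len(nrow(hits))) {
    cand <- extract_precursor_window(hits[r, ], seqs[[hits$transcript_id[r]]],
                                     flank = config$flank)
    cand$coding_flag <- flag_coding(cand, seqs[[hits$transcript_id[r]]],
                                    min_orf_aa = config$min_orf_aa)
    if (cand$coding_flag) {
      n_coding <- n_coding + 1L
      next
    }
    fold <- fold_mfe(cand$seq, energy_model("stacking"))
    evals[[length(evals) + 1L]] <- evaluate_candidate(cand, fold, thresholds)
  }

  cand_df <- evaluations_to_frame(evals, refs)
  ## one evaluation per window: keep the best MFEI
  if (nrow(cand_df) > 1) {
    key <- paste(cand_df$transcript_id, cand_df$window_start,
                 cand_df$window_end)
    ord <- order(key, -ifelse(is.na(cand_df$mfei), -Inf, cand_df$mfei),
                 cand_df$mature_id)
    cand_df <- cand_df[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    cand_df <- cand_df[keep, , drop = FALSE]
    cand_df <- cand_df[order(cand_df$transcript_id, cand_df$window_start), ,
                       drop = FALSE]
  }
  evals <- evals[cand_df$.eval_idx]
  cand_df$.eval_idx <- NULL
  rownames(cand_df) <- NULL
  accepted <- cand_df[cand_df$verdict, , drop = FALSE]
  summary <- summarize_mfei(accepted$mfei)

  counts <- list(matures_in = nrow(mr$refs), matures_unique = nrow(refs),
                 hits = nrow(hits), coding_removed = n_coding,
                 folded = length(evals), candidates = nrow(cand_df),
                 accepted = nrow(accepted))
  manifest <- run_manifest(counts, config,
                           c(transcripts = tx$path, matures = mr$path))
  out <- structure(list(candidates = cand_df, accepted = accepted,
                        evaluations = evals, mfei_summary = summary,
                        manifest = manifest),
                   class = "mirna_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(format_candidates_tsv(cand_df),
                file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_accepted_gff3(accepted, file.path(out_dir, "accepted.gff3"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    out$paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
                   accepted = file.path(out_dir, "accepted.gff3"),
                   manifest = file.path(out_dir, "manifest.json"))
  }
  out
}

evaluations_to_frame <- function(evals, refs) {
  if (!length(evals)) {
    return(data.frame(transcript_id = character(0), mature_id = character(0),
                      family = character(0), window_start = integer(0),
                      window_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), truncated = logical(0),
                      arm = character(0), star_mismatches = integer(0),
                      delta_g_mag = numeric(0), gc_pct = numeric(0),
                      amfe = numeric(0), mfei = numeric(0),
                      pass_arm = logical(0), pass_mfei = logical(0),
                      pass_star_mismatch = logical(0),
                      pass_loop_break = logical(0), verdict = logical(0),
                      .eval_idx = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(evals), function(i) {
    e <- evals[[i]]
    cd <- e$candidate
    fam <- refs$family[match(cd$mature_id, refs$id)]
    data.frame(
      transcript_id = cd$transcript_id, mature_id = cd$mature_id,
      family = if (is.na(fam)) mirna_family(cd$mature_id) else fam,
      window_start = cd$window_start, window_end = cd$window_end,
      mature_start = cd$mature_start + cd$window_start - 1L,
      mature_end = cd$mature_end + cd$window_start - 1L,
      truncated = cd$truncated,
      arm = e$arm, star_mismatches = e$star_mismatches,
      delta_g_mag = e$delta_g_mag, gc_pct = e$gc_pct,
      amfe = e$amfe, mfei = e$mfei,
      pass_arm = unname(e$passes["arm"]),
      pass_mfei = unname(e$passes["mfei"]),
      pass_star_mismatch = unname(e$passes["star_mismatch"]),
      pass_loop_break = unname(e$passes["loop_break"]),
      verdict = e$verdict, .eval_idx = i,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

format_candidates_tsv <- function(df) {
  num <- c("delta_g_mag", "gc_pct", "amfe", "mfei")
  for (k in num) df[[k]] <- round_half_up(df[[k]], 2)
  df
}

write_accepted_gff3 <- function(accepted, path) {
  if (!nrow(accepted)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  pre <- GenomicRanges::GRanges(
    seqnames = accepted$transcript_id,
    ranges = IRanges::IRanges(accepted$window_start, accepted$window_end),
    strand = "+")
  S4Vectors::mcols(pre) <- S4Vectors::DataFrame(
    source = "mirssr", type = "miRNA_primary_transcript",
    ID = sprintf("pre-%s-%d", accepted$family, seq_len(nrow(accepted))),
    Name = accepted$family,
    mature_id = accepted$mature_id,
    mfei = round_half_up(accepted$mfei, 2))
  mat <- GenomicRanges::GRanges(
    seqnames = accepted$transcript_id,
    ranges = IRanges::IRanges(accepted$mature_start, accepted$mature_end),
    strand = "+")
  S4Vectors::mcols(mat) <- S4Vectors::DataFrame(
    source = "mirssr", type = "miRNA",
    ID = sprintf("mir-%s-%d", accepted$family, seq_len(nrow(accepted))),
    Name = accepted$mature_id,
    Parent = sprintf("pre-%s-%d", accepted$family, seq_len(nrow(accepted))))
  rtracklayer::export(c(pre, mat), path, format = "gff3")
  invisible(path)
}

#' Run the EST-SSR marker pipeline
#'
#' Scans every transcript for microsatellites, groups compound loci,
#' summarizes the distribution (mononucleotides excluded by default) and
#' designs flanking primer pairs for every non-mononucleotide locus with
#' adequate flanks.
#'
#' @inheritParams run_mirna_pipeline
#' @return a list of class `ssr_run`: `loci`, `summary`, `primers`
#'   (best pair per locus, marker-table layout), `primer_pairs` (all
#'   ranked pairs), `manifest`.
#' @export
run_ssr_pipeline <- function(transcripts, config = default_config(),
                             out_dir = NULL) {
  tx <- resolve_transcripts(transcripts)
  seqs <- tx$seqs
  loci_list <- lapply(names(seqs), function(id) {
    loci <- scan_ssrs(stats::setNames(seqs[[id]], id),
                      thresholds = config$ssr_thresholds)
    merge_compound(loci, config$max_compound_interruption)
  })
  loci <- do.call(rbind, c(loci_list, list(empty_ssr_frame_compound())))
  rownames(loci) <- NULL
  summary <- ssr_summary(loci, exclude_mono = isTRUE(config$exclude_mono))

  constraints <- primer_constraints_from_config(config)
  primer_pairs <- list()
  best_rows <- list()
  for (r in seq_len(nrow(loci))) {
    if (loci$unit_len[r] == 1) next
    pairs <- design_primer_pairs(seqs[[loci$transcript_id[r]]], loci[r, ],
                                 constraints = constraints)
    if (!nrow(pairs)) next
    pairs$transcript_id <- loci$transcript_id[r]
    pairs$ssr <- sprintf("(%s)%d", loci$motif[r], loci$repeats[r])
    primer_pairs[[length(primer_pairs) + 1L]] <- pairs
    best_rows[[length(best_rows) + 1L]] <- data.frame(
      ID = loci$transcript_id[r],
      SSR = sprintf("(%s)%d", loci$motif[r], loci$repeats[r]),
      `Forward Primer (5'-3')` = pairs$forward_seq[1],
      `Tm F (C)` = round_half_up(pairs$fwd_tm[1], 3),
      `size F` = nchar(pairs$forward_seq[1]),
      `Reverse Primer (5'-3')` = pairs$reverse_seq[1],
      `Tm R (C)` = round_half_up(pairs$rev_tm[1], 3),
      `size R` = nchar(pairs$reverse_seq[1]),
      `PS (bp)` = pairs$product_size[1],
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  primers <- if (length(best_rows)) do.call(rbind, best_rows) else NULL
  all_pairs <- if (length(primer_pairs)) do.call(rbind, primer_pairs) else NULL

  counts <- list(transcripts = length(seqs), ssr_loci = nrow(loci),
                 compound_groups = length(unique(stats::na.omit(loci$compound_id))),
                 loci_with_primers = length(best_rows),
                 primer_pairs = if (is.null(all_pairs)) 0L else nrow(all_pairs))
  manifest <- run_manifest(counts, config, c(transcripts = tx$path))
  out <- structure(list(loci = loci, summary = summary, primers = primers,
                        primer_pairs = all_pairs, manifest = manifest),
                   class = "ssr_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(format_ssr_tsv(loci), file.path(out_dir, "ssr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(primers)) {
      write.table(primers, file.path(out_dir, "primers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(summary, file.path(out_dir, "ssr_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    out$paths <- c(ssr = file.path(out_dir, "ssr.tsv"),
                   summary = file.path(out_dir, "ssr_summary.tsv"),
                   manifest = file.path(out_dir, "manifest.json"))
  }
  out
}

empty_ssr_frame_compound <- function() {
  df <- empty_ssr_frame()
  df$compound_id <- character(0)
  df
}

format_ssr_tsv <- function(loci) {
  if (!nrow(loci)) {
    return(data.frame(ID = character(0), `SSR nr.` = integer(0),
                      `SSR type` = character(0), SSR = character(0),
                      size = integer(0), start = integer(0),
                      end = integer(0), check.names = FALSE))
  }
  data.frame(
    ID = loci$transcript_id,
    `SSR nr.` = stats::ave(seq_len(nrow(loci)), loci$transcript_id,
                           FUN = seq_along),
    `SSR type` = ifelse(!is.na(loci$compound_id), "c",
                        paste0("p", loci$unit_len)),
    SSR = sprintf("(%s)%d", loci$motif, loci$repeats),
    size = loci$end - loci$start + 1L,
    start = loci$start,
    end = loci$end,
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.mirna_run <- function(x, ...) {
  c0 <- x$manifest$counts
  cat(sprintf(paste0("miRNA discovery run: %d hits -> %d candidates ",
                     "(%d coding removed) -> %d accepted\n"),
              c0$hits, c0$candidates, c0$coding_removed, c0$accepted))
  if (x$mfei_summary$n > 0) {
    cat(sprintf("accepted MFEI: mean %.2f, range %.2f-%.2f (n = %d)\n",
                x$mfei_summary$mean, x$mfei_summary$min,
                x$mfei_summary$max, x$mfei_summary$n))
  }
  invisible(x)
}

#' @export
print.ssr_run <- function(x, ...) {
  c0 <- x$manifest$counts
  cat(sprintf("SSR run: %d transcripts, %d loci, %d loci with primers\n",
              c0$transcripts, c0$ssr_loci, c0$loci_with_primers))
  invisible(x)
}
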