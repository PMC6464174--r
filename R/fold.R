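## RNA secondary-structure prediction: model definitions, the MFE folder
## (Rcpp DP), an exhaustive enumeration oracle, and dot-bracket utilities.

FOLD_PAIR_LEVELS <- c("AU", "CG", "GC", "UA", "GU", "UG")

## Nearest-neighbor stack free energies (kcal/mol, 37 C), indexed
## [outer pair, inner pair] for a stack 5'-(i)(i+1)...(j-1)(j)-3' with
## (i,j) outer and (i+1,j-1) inner. Watson-Crick values follow the
## Xia et al. 1998 unified set; GU wobble values follow the Mathews et
## al. 1999 extension (approximate where the published motif tables are
## non-additive). The table is symmetric under strand reversal:
## stack[P, Q] == stack[rev(Q), rev(P)].
stack_table <- function() {
  m <- matrix(NA_real_, 6, 6, dimnames = list(FOLD_PAIR_LEVELS, FOLD_PAIR_LEVELS))
  set <- function(outer, inner, val) {
    m[outer, inner] <<- val
    rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    m[rev2(inner), rev2(outer)] <<- val
  }
  set("AU", "AU", -0.93); set("AU", "CG", -2.24); set("AU", "GC", -2.08)
  set("AU", "UA", -1.10); set("AU", "GU", -0.55); set("AU", "UG", -1.36)
  set("CG", "AU", -2.11); set("CG", "CG", -3.26); set("CG", "GC", -2.36)
  set("CG", "UA", -2.08); set("CG", "GU", -1.41); set("CG", "UG", -2.11)
  set("GC", "AU", -2.35); set("GC", "CG", -3.42); set("GC", "GC", -3.26)
  set("GC", "UA", -2.24); set("GC", "GU", -1.53); set("GC", "UG", -2.51)
  set("UA", "AU", -1.33); set("UA", "CG", -2.35); set("UA", "GC", -2.11)
  set("UA", "UA", -0.93); set("UA", "GU", -1.00); set("UA", "UG", -1.27)
  set("GU", "GU", -0.50); set("GU", "UG", +0.50); set("UG", "GU", -0.60)
  set("UG", "UG", -0.50)
  stopifnot(!anyNA(m))
  m
}

#' Folding energy models
#'
#' Two scoring models for pseudoknot-free single-strand folding:
#'
#' * `"stacking"` — nearest-neighbor stack free energies (kcal/mol) with
#'   logarithmic hairpin/bulge/interior loop penalties and an affine
#'   multiloop cost. No dangling ends or coaxial stacking: the smallest
#'   model that yields kcal/mol-scaled minimum free energies, so AMFE and
#'   MFEI land on the scale conventional for plant precursor screening.
#' * `"pair_count"` — every pair scores -1 and all loops are free, i.e.
#'   classic base-pair maximization. Retained because its optimum is
#'   cheaply verifiable by exhaustive enumeration, which makes it the
#'   reference model for oracle tests.
#'
#' Allowed pairs are AU/UA, CG/GC and the GU/UG wobble; hairpin loops
#' need at least `min_loop` (3) unpaired bases; interior/bulge loops are
#' capped at `max_interior` (30) unpaired bases in total.
#'
#' @param name `"stacking"` or `"pair_count"`.
#' @return a list of class `energy_model` with the stack table and loop
#'   penalty constants.
#' @examples
#' energy_model("pair_count")$pair_bonus
#' @export
energy_model <- function(name = c("stacking", "pair_count")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    pair_rules = FOLD_PAIR_LEVELS,
    min_loop = 3L,
    max_interior = 30L
  )
  if (name == "stacking") {
    base <- c(base, list(
      stack = stack_table(),
      pair_bonus = 0,
      hp_a = 5.4, hp_b = 1.078,          # hairpin(n) = hp_a + hp_b*log(n/3)
      bulge1 = 3.8, bl_a = 2.8, bl_b = 1.078,
      il_a = 1.7, il_b = 1.078, il_asym = 0.6, il_asym_max = 3.0,
      ml_a = 3.4, ml_b = 0.4
    ))
  } else {
    base <- c(base, list(
      stack = matrix(0, 6, 6, dimnames = list(FOLD_PAIR_LEVELS, FOLD_PAIR_LEVELS)),
      pair_bonus = -1,
      hp_a = 0, hp_b = 0,
      bulge1 = 0, bl_a = 0, bl_b = 0,
      il_a = 0, il_b = 0, il_asym = 0, il_asym_max = 0,
      ml_a = 0, ml_b = 0
    ))
  }
  structure(base, class = "energy_model")
}

encode_rna <- function(seq) {
  s <- as_rna(seq)
  check_alphabet(s, "ACGUN", "fold input")
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U", "N")) - 1L
}

#' Fold a sequence to its minimum-free-energy structure
#'
#' Dynamic-programming MFE folding with deterministic traceback (ties are
#' broken toward the pairing with the smallest 5' index, then the smallest
#' 3' index). `N` bases are accepted and treated as unpairable.
#'
#' @param seq a single sequence, 10–2000 nt (DNA input is converted to RNA).
#' @param model an [energy_model()].
#' @return a list of class `fold_result`: `seq` (RNA), `dotbracket`,
#'   `pairs` (two-column matrix of 1-based indices, i < j), `energy`
#'   (model score; kcal/mol for the stacking model, -pairs for
#'   pair_count), and `delta_g_mag`, the magnitude of the negative folding
#'   free energy that feeds AMFE/MFEI.
#' @examples
#' fold_mfe("GGGAAACCC", energy_model("pair_count"))$dotbracket
#' @export
fold_mfe <- function(seq, model = energy_model("stacking")) {
  stopifnot(inherits(model, "energy_model"), is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 5 || n > 2000) {
    stop("fold_mfe expects sequences of 5-2000 nt, got ", n, call. = FALSE)
  }
  codes <- encode_rna(seq)
  res <- .fold_mfe_cpp(codes, unclass(model))
  partner <- res$partner
  pairs <- cbind(i = which(!is.na(partner) & seq_len(n) < partner),
                 j = partner[!is.na(partner) & seq_len(n) < partner])
  structure(list(
    seq = as_rna(seq),
    dotbracket = pairs_to_dotbracket(pairs, n),
    pairs = pairs,
    partner = partner,
    energy = res$energy,
    delta_g_mag = max(0, -res$energy),
    model = model$name
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("MFE fold (%s model): %d nt, %d pairs, dG = %.2f\n",
              x$model, nchar(x$seq), nrow(x$pairs), x$energy))
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Dot-bracket conversions
#'
#' Lossless round-trip between a two-column pair matrix (1-based, i < j)
#' and dot-bracket notation for nested structures.
#'
#' @param pairs a two-column integer matrix of paired positions.
#' @param n sequence length.
#' @param db a dot-bracket string over `(`, `)`, `.`.
#' @examples
#' dotbracket_to_pairs("((...))")
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (NROW(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket string", call. = FALSE)
  open <- integer(0)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
      out <- rbind(out, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
  out[order(out[, 1]), , drop = FALSE]
}

## Score an explicit structure under a model by loop decomposition.
## Independent of the DP: used by the enumeration oracle and in tests.
## Returns +Inf for structures the model forbids (interior loops above
## the cap; sub-min_loop hairpins and disallowed pairs are rejected too).
#' Score an explicit secondary structure
#'
#' Loop-decomposition scoring of a given set of pairs under an
#' [energy_model()]. This is the scoring arm of the exhaustive oracle and
#' is deliberately independent of the folding DP.
#'
#' @inheritParams fold_mfe
#' @param pairs two-column matrix of 1-based pair indices (i < j), nested.
#' @return the model energy (kcal/mol or -pairs), or `Inf` if the
#'   structure violates the model's hard constraints.
#' @export
score_structure <- function(seq, pairs, model = energy_model("stacking")) {
  codes <- encode_rna(seq)
  n <- length(codes)
  if (!NROW(pairs)) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ptype <- function(i, j) {
    pt <- c("01" = NA, "03" = 1L, "12" = 2L, "21" = 3L, "30" = 4L, "23" = 5L, "32" = 6L)
    unname(pt[paste0(codes[i], codes[j])])
  }
  partner <- rep(NA_integer_, n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pt <- ptype(i, j)
    if (is.na(pt)) return(Inf)
    if (j - i - 1 < model$min_loop) return(Inf)
    total <- total + model$pair_bonus
    ## children = pairs directly enclosed by (i,j)
    kids <- list()
    k <- i + 1
    while (k < j) {
      if (!is.na(partner[k])) {
        if (partner[k] < k || partner[k] > j) return(Inf)  # crossing
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1
      } else {
        k <- k + 1
      }
    }
    nk <- length(kids)
    if (nk == 0) {
      total <- total + model$hp_a + model$hp_b * log((j - i - 1) / 3)
    } else if (nk == 1) {
      k1 <- kids[[1]][1]; l1 <- kids[[1]][2]
      n1 <- k1 - i - 1; n2 <- j - l1 - 1
      if (n1 + n2 > model$max_interior) return(Inf)
      if (n1 == 0 && n2 == 0) {
        pt2 <- ptype(k1, l1)
        if (is.na(pt2)) return(Inf)
        total <- total + model$stack[pt, pt2]
      } else if (n1 == 0 || n2 == 0) {
        nn <- n1 + n2
        total <- total +
          if (nn == 1) model$bulge1 else model$bl_a + model$bl_b * log(nn)
      } else {
        total <- total + model$il_a + model$il_b * log((n1 + n2) / 2) +
          min(model$il_asym * abs(n1 - n2), model$il_asym_max)
      }
    } else {
      total <- total + model$ml_a + model$ml_b * (nk + 1)
    }
  }
  unname(total)
}

#' Exhaustively enumerate nested structures (testing oracle)
#'
#' Enumerates every nested, constraint-respecting pairing of a short
#' sequence, scores each with [score_structure()], and returns the best
#' score. The search is brute force and intentionally shares no code with
#' the folding DP; it refuses sequences longer than 14 nt.
#'
#' @inheritParams fold_mfe
#' @return a list with `energy` (the optimal score) and `n_structures`
#'   (number of structures enumerated).
#' @examples
#' enumerate_structures("GGGAAACCC", energy_model("pair_count"))$energy  # -3
#' @export
enumerate_structures <- function(seq, model = energy_model("stacking")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  n <- nchar(seq)
  if (n > 14) stop("enumeration oracle refuses sequences > 14 nt", call. = FALSE)
  codes <- encode_rna(seq)
  can_pair <- function(i, j) {
    a <- codes[i]; b <- codes[j]
    (a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1) ||
      (a == 2 && b == 3) || (a == 3 && b == 2)
  }
  ## all pairings of positions i..j as lists of rbind-able pairs
  enum <- function(i, j) {
    if (i >= j) return(list(NULL))
    out <- enum(i + 1, j)  # i unpaired
    kmin <- i + model$min_loop + 1
    ks <- if (kmin > j) integer(0) else kmin:j
    for (k in ks) {
      if (!can_pair(i, k)) next
      inner <- enum(i + 1, k - 1)
      outer <- enum(k + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    out
  }
  structs <- enum(1L, n)
  best <- Inf
  for (s in structs) {
    e <- if (is.null(s)) 0 else {
      colnames(s) <- c("i", "j")
      score_structure(seq, s, model)
    }
    if (e < best) best <- e
  }
  list(energy = best, n_structures = length(structs))
}

#' Write a connectivity-table (CT) file for a fold
#'
#' Minimal CT writer for viewing structures in external tools.
#'
#' @param fold a `fold_result`.
#' @param path output file.
#' @param title optional record title.
#' @return `path`, invisibly.
#' @export
write_ct <- function(fold, path, title = "mirssr fold") {
  stopifnot(inherits(fold, "fold_result"))
  n <- nchar(fold$seq)
  bases <- strsplit(fold$seq, "", fixed = TRUE)[[1]]
  partner <- fold$partner
  partner[is.na(partner)] <- 0L
  lines <- c(
    sprintf("%d  dG = %.2f  %s", n, fold$energy, title),
    sprintf("%d %s %d %d %d %d", seq_len(n), bases, seq_len(n) - 1L,
            c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n))
  )
  writeLines(lines, path)
  invisible(path)
}
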