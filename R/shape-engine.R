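#' Reverse-complement DNA sequences
#'
#' Vectorised Watson-Crick reverse complement over the alphabet
#' `{A, C, G, T, N}`; `N` maps to `N`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("CACGTG", "AAAAA", "ACGTN"))
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) abort("`seq` must be a character vector.")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf(
      "non-nucleotide character in sequence(s): %s",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Canonicalize a pentamer by reverse complementation
#'
#' A pentamer and its reverse complement share one structural record; the
#' canonical representative is the lexicographically smaller of the two.
#' No odd-length DNA string equals its own reverse complement, so the 1024
#' pentamers collapse to exactly 512 canonical classes.
#'
#' @param p Character vector of 5-mers over `{A, C, G, T}`.
#' @return A tibble with columns `pentamer` (input), `canonical` and
#'   `reversed` (`TRUE` when the canonical form is the reverse complement
#'   of the input).
#' @examples
#' canonical_pentamer(c("TTTTT", "AAAAA"))
#' @export
canonical_pentamer <- function(p) {
  if (!is.character(p)) abort("`p` must be a character vector.")
  if (any(nchar(p) != 5L)) abort("pentamers must have length 5.")
  if (any(grepl("[^ACGT]", p))) abort("pentamers must be over {A, C, G, T}.")
  rc <- reverse_complement(p)
  canonical <- ifelse(p <= rc, p, rc)
  tibble::tibble(pentamer = p, canonical = canonical, reversed = canonical != p)
}

all_pentamers <- function() {
  g <- expand.grid(p5 = DNA_BASES, p4 = DNA_BASES, p3 = DNA_BASES,
                   p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

#' All 512 canonical pentamers
#'
#' @return Sorted character vector of the 512 canonical 5-mers (each the
#'   lexicographic minimum of itself and its reverse complement).
#' @export
canonical_pentamers <- function() {
  p <- all_pentamers()
  sort(unique(canonical_pentamer(p)$canonical))
}

PENTAMER_TABLE_COLS <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2",
                         "HelT1", "HelT2")

new_pentamer_table <- function(tbl, source = "unspecified") {
  tbl <- tibble::as_tibble(tbl)[PENTAMER_TABLE_COLS]
  tbl <- tbl[order(tbl$pentamer), ]
  structure(tbl,
            source = source,
            class = c("pentamer_table", class(tibble::tibble())))
}

validate_pentamer_table <- function(tbl) {
  if (!all(PENTAMER_TABLE_COLS %in% names(tbl))) {
    abort(sprintf("pentamer table must have columns: %s",
                  paste(PENTAMER_TABLE_COLS, collapse = ", ")))
  }
  num <- PENTAMER_TABLE_COLS[-1]
  for (cl in num) {
    if (!is.numeric(tbl[[cl]]) || anyNA(tbl[[cl]])) {
      abort(sprintf("column `%s` must be numeric with no missing values.", cl))
    }
  }
  if (any(grepl("[^ACGT]", tbl$pentamer))) {
    abort("pentamer keys must be over {A, C, G, T}.")
  }
  canon <- canonical_pentamer(tbl$pentamer)
  if (any(canon$reversed)) {
    abort(sprintf(
      "non-canonical pentamer key(s): %s",
      paste(head(tbl$pentamer[canon$reversed], 5L), collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$pentamer)) abort("duplicated pentamer keys.")
  if (nrow(tbl) != 512L) {
    abort(sprintf("incomplete pentamer table: %d of 512 canonical pentamers.",
                  nrow(tbl)))
  }
  if (any(tbl$MGW <= 0)) abort("all MGW values must be positive.")
  invisible(tbl)
}

#' Read a pentamer structural query table
#'
#' The table is a TSV with header
#' `pentamer  MGW  ProT  Roll1  Roll2  HelT1  HelT2`, one row per canonical
#' pentamer (512 rows).  MGW and ProT are the values at the centre base pair
#' of the 5-mer; Roll1/Roll2 and HelT1/HelT2 are the values at its two
#' central base-pair steps (left, right).
#'
#' @param path Path to the TSV file.
#' @param source Provenance label stored on the returned table; defaults to
#'   the file path.
#' @return A `pentamer_table` (tibble with 512 rows).
#' @seealso [simulate_pentamer_table()], [write_pentamer_table()]
#' @export
load_pentamer_table <- function(path, source = path) {
  tbl <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    pentamer = readr::col_character(),
    .default = readr::col_double()
  )))
  readr::stop_for_problems(tbl)
  validate_pentamer_table(tbl)
  new_pentamer_table(tbl, source = source)
}

#' Write a pentamer table to TSV
#'
#' @param table A `pentamer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pentamer_table <- function(table, path) {
  validate_pentamer_table(table)
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

# Expand the 512-row canonical table to a 1024-entry lookup keyed by every
# pentamer.  For a reverse-complement lookup the two step values are swapped:
# the pentamer read on the other strand traverses the same two physical steps
# in the opposite order (MGW/ProT are strand-invariant).
pentamer_lookup <- function(table) {
  validate_pentamer_table(table)
  p <- table$pentamer
  rc <- reverse_complement(p)
  keys <- c(p, rc)
  lk <- list(
    mgw   = setNames(c(table$MGW,   table$MGW),   keys),
    prot  = setNames(c(table$ProT,  table$ProT),  keys),
    roll1 = setNames(c(table$Roll1, table$Roll2), keys),
    roll2 = setNames(c(table$Roll2, table$Roll1), keys),
    helt1 = setNames(c(table$HelT1, table$HelT2), keys),
    helt2 = setNames(c(table$HelT2, table$HelT1), keys)
  )
  # palindrome-free: duplicated keys cannot occur for odd-length k-mers,
  # but revcomp(p) may coincide with another canonical p only if p == rc
  lapply(lk, function(v) v[!duplicated(names(v))])
}

as_sequence_tbl <- function(sequences) {
  if (is.data.frame(sequences)) {
    if (!all(c("seq_id", "sequence") %in% names(sequences))) {
      abort("data-frame input must have columns `seq_id` and `sequence`.")
    }
    tbl <- tibble::tibble(seq_id = as.character(sequences$seq_id),
                          sequence = toupper(sequences$sequence))
  } else {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    tbl <- tibble::tibble(seq_id = unname(ids),
                          sequence = toupper(unname(as.character(sequences))))
  }
  if (anyDuplicated(tbl$seq_id)) abort("duplicated `seq_id`.")
  tbl
}

#' Predict DNA shape profiles by sliding-pentamer lookup
#'
#' Slides a 5-bp window along each sequence; each window's canonical pentamer
#' is looked up in the structural query table.  The window centred at
#' (0-based) position `i` supplies MGW and ProT at `i` and contributes its
#' two central-step Roll/HelT values to the steps `(i-1, i)` and `(i, i+1)`;
#' a step covered by two windows stores the mean of the two contributions.
#' Positions or steps not covered by any full window are missing (`NA`): for
#' an unflanked sequence these are the first and last two base pairs and the
#' terminal steps.
#'
#' @param sequences Character vector (optionally named by sequence id) or a
#'   data frame with columns `seq_id`, `sequence`.  Bases must be
#'   `{A, C, G, T}`; `N` handling is controlled by `na_action`.
#' @param table A `pentamer_table`.
#' @param origin Integer offset of the first base relative to the coordinate
#'   origin (e.g. `-2` when the sequence carries 2-bp flanks ahead of the
#'   core start, so that core positions start at 0).
#' @param na_action `"error"` (default) rejects sequences containing `N`;
#'   `"mask"` marks every position/step touched by an `N`-containing window
#'   as missing.
#' @return A long tibble of class `shape_tbl` with columns `seq_id`,
#'   `feature` (`MGW`, `ProT`, `Roll`, `HelT`), `position` and `value`.
#'   Base-pair features occupy integer positions; step features occupy the
#'   step midpoints (`j + 0.5`).  Tracks are complete: a sequence of length
#'   `L` yields `L` rows per bp feature and `L - 1` rows per step feature,
#'   with `NA` values where prediction is impossible.
#' @examples
#' tab <- simulate_pentamer_table(seed = 1)
#' predict_shape(c(site1 = "aaCACGTGtt"), tab, origin = -2)
#' @export
predict_shape <- function(sequences, table, origin = 0L,
                          na_action = c("error", "mask")) {
  na_action <- match.arg(na_action)
  tbl <- as_sequence_tbl(sequences)
  if (any(grepl("[^ACGTN]", tbl$sequence))) {
    abort("sequences must be over {A, C, G, T, N}.")
  }
  has_n <- grepl("N", tbl$sequence, fixed = TRUE)
  if (na_action == "error" && any(has_n)) {
    abort(sprintf("ambiguous base N in sequence(s): %s (use na_action = \"mask\").",
                  paste(head(tbl$seq_id[has_n], 5L), collapse = ", ")))
  }
  L <- nchar(tbl$sequence)
  if (any(L < 5L)) {
    abort(sprintf("sequence(s) shorter than 5 bp: %s",
                  paste(head(tbl$seq_id[L < 5L], 5L), collapse = ", ")))
  }
  lk <- pentamer_lookup(table)

  # one row per full window: sequence index s, 0-based centre c
  n_win <- L - 4L
  s <- rep.int(seq_len(nrow(tbl)), n_win)
  c0 <- unlist(lapply(n_win, function(k) seq.int(2L, length.out = k)),
               use.names = FALSE)
  win <- substr(rep.int(tbl$sequence, n_win), c0 - 1L, c0 + 3L)
  keep <- !grepl("N", win, fixed = TRUE)
  s <- s[keep]; c0 <- c0[keep]; win <- win[keep]

  mgw <- unname(lk$mgw[win])
  prot <- unname(lk$prot[win])

  # flat per-track storage: bp track k occupies slots bp_start[k] + 0..L[k]-1,
  # step track k occupies st_start[k] + 0..L[k]-2
  n_seq <- nrow(tbl)
  bp_start <- c(0L, cumsum(L))[seq_len(n_seq)]
  st_start <- c(0L, cumsum(L - 1L))[seq_len(n_seq)]
  mgw_full <- prot_full <- rep(NA_real_, sum(L))
  idx_bp <- bp_start[s] + c0 + 1L
  mgw_full[idx_bp] <- mgw
  prot_full[idx_bp] <- prot

  # step contributions: window at centre c -> roll1/helt1 at step c-1,
  # roll2/helt2 at step c; overlapping contributions are averaged
  roll_full <- helt_full <- rep(NA_real_, sum(L - 1L))
  idx_st <- c(st_start[s] + c0, st_start[s] + c0 + 1L)
  roll_v <- c(unname(lk$roll1[win]), unname(lk$roll2[win]))
  helt_v <- c(unname(lk$helt1[win]), unname(lk$helt2[win]))
  cnt <- rowsum(rep(1, length(idx_st)), idx_st)
  slots <- as.integer(rownames(cnt))
  roll_full[slots] <- rowsum(roll_v, idx_st)[, 1] / cnt[, 1]
  helt_full[slots] <- rowsum(helt_v, idx_st)[, 1] / cnt[, 1]

  bp_seq <- rep.int(seq_len(n_seq), L)
  st_seq <- rep.int(seq_len(n_seq), L - 1L)
  bp_pos <- sequence(L) - 1L
  st_pos <- sequence(L - 1L) - 1L + 0.5
  seq_out <- c(bp_seq, bp_seq, st_seq, st_seq)
  feat_out <- rep.int(1:4, c(sum(L), sum(L), sum(L - 1L), sum(L - 1L)))
  pos_out <- c(bp_pos, bp_pos, st_pos, st_pos)
  val_out <- c(mgw_full, prot_full, roll_full, helt_full)
  ord <- order(seq_out, feat_out, pos_out)
  res <- tibble::tibble(
    seq_id = tbl$seq_id[seq_out[ord]],
    feature = factor(SHAPE_FEATURES[feat_out[ord]], levels = SHAPE_FEATURES),
    position = origin + pos_out[ord],
    value = val_out[ord]
  )
  class(res) <- c("shape_tbl", class(res))
  res
}

#' Symmetrize shape profiles about a centre position
#'
#' Averages each track element-wise with its mirror image about `centre`
#' (the strand-reversed counterpart of the profile).  Used for palindromic
#' core motifs such as the E-box, where the two strands are equivalent
#' descriptions of the same site.  Missing values propagate as the mean of
#' the available values; the operation is idempotent.
#'
#' @param profiles A `shape_tbl` (see [predict_shape()]).
#' @param centre Centre position in profile coordinates; may be half-integer
#'   (e.g. `2.5` for a 6-bp core at positions 0..5).
#' @return A `shape_tbl` of the same shape.
#' @export
symmetrize_profile <- function(profiles, centre) {
  stopifnot(is.data.frame(profiles))
  if (length(centre) != 1L || !is.finite(centre)) {
    abort("`centre` must be a single finite position.")
  }
  if (abs(2 * centre - round(2 * centre)) > 1e-9) {
    abort("`centre` must be a multiple of 0.5 so that mirrored positions land on the track grid.")
  }
  rng <- range(profiles$position)
  if (centre < rng[1] || centre > rng[2]) {
    abort(sprintf("`centre` = %s lies outside the profile positions [%s, %s].",
                  centre, rng[1], rng[2]))
  }
  key <- paste(profiles$seq_id, profiles$feature, profiles$position)
  mirror_key <- paste(profiles$seq_id, profiles$feature,
                      2 * centre - profiles$position)
  mirror_value <- profiles$value[match(mirror_key, key)]
  both <- cbind(profiles$value, mirror_value)
  m <- rowMeans(both, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  out <- profiles
  out$value <- m
  out
}
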