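new_tfbs_dataset <- function(tbl, core_length, flank_width, provenance = list()) {
  tbl <- tibble::as_tibble(tbl)[c("seq_id", "sequence")]
  stopifnot(all(nchar(tbl$sequence) == core_length + 2L * flank_width))
  structure(tbl,
            core_length = core_length,
            flank_width = flank_width,
            provenance = provenance,
            class = c("tfbs_dataset", class(tibble::tibble())))
}

#' Core length, flank width and provenance of a TFBS dataset
#'
#' @param dataset A `tfbs_dataset`.
#' @return `core_length()`/`flank_width()` return integers; `provenance()`
#'   returns the list of assembly settings and stage-by-stage record counts.
#' @export
core_length <- function(dataset) attr(dataset, "core_length")

#' @rdname core_length
#' @export
flank_width <- function(dataset) attr(dataset, "flank_width")

#' @rdname core_length
#' @export
provenance <- function(dataset) attr(dataset, "provenance")

#' @export
print.tfbs_dataset <- function(x, ...) {
  cat(sprintf("<tfbs_dataset> %d sequences, core %d bp, flanks %d bp\n",
              nrow(x), core_length(x), flank_width(x)))
  NextMethod()
}

#' Parse a case-annotated FASTA file of binding sites
#'
#' In the JASPAR dialect the core binding site is written in upper case and
#' the flanking sequence in lower case.  Each record must contain exactly
#' one contiguous upper-case run; records violating this (no upper-case
#' base, several upper-case runs, or non-ACGT characters) are dropped with
#' per-record diagnostics rather than failing the whole file.  A record with
#' no lower-case letters at all is a core-only site with zero flanks.
#'
#' @param path Path to the FASTA file.
#' @return Tibble of class `case_annotated_tbl` with columns `seq_id`,
#'   `sequence` (as given), `core_start` (0-based), `core_length`,
#'   `left_flank`, `right_flank`.  Rejected records are attached as the
#'   `rejected` attribute (tibble of `seq_id`, `reason`) and reported via a
#'   warning.
#' @export
parse_jaspar_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort("empty FASTA file.")
  ids <- sub("\\s.*$", "", names(seqs))
  raw <- unname(as.character(seqs))
  reasons <- character(length(raw))
  core_start <- integer(length(raw))
  core_len <- integer(length(raw))
  for (k in seq_along(raw)) {
    s <- raw[k]
    if (grepl("[^ACGTacgt]", s)) {
      reasons[k] <- "non-ACGT character"
      next
    }
    m <- gregexpr("[ACGT]+", s)[[1]]
    if (m[1] == -1L) {
      reasons[k] <- "no upper-case core"
    } else if (length(m) > 1L) {
      reasons[k] <- sprintf("%d upper-case runs (expected 1)", length(m))
    } else {
      core_start[k] <- m[1] - 1L
      core_len[k] <- attr(m, "match.length")[1]
    }
  }
  ok <- !nzchar(reasons)
  if (any(!ok)) {
    warn(sprintf("rejected %d record(s): %s", sum(!ok),
                 paste(sprintf("%s (%s)", ids[!ok], reasons[!ok])[seq_len(min(5L, sum(!ok)))],
                       collapse = "; ")))
  }
  if (!any(ok)) abort("no valid case-annotated records in file.")
  out <- tibble::tibble(
    seq_id = ids[ok],
    sequence = raw[ok],
    core_start = core_start[ok],
    core_length = core_len[ok],
    left_flank = core_start[ok],
    right_flank = nchar(raw[ok]) - core_start[ok] - core_len[ok]
  )
  attr(out, "rejected") <- tibble::tibble(seq_id = ids[!ok], reason = reasons[!ok])
  class(out) <- c("case_annotated_tbl", class(out))
  out
}

#' Assemble a dataset from case-annotated records via the flank-retention rule
#'
#' Computes the fraction `q` of records carrying at least `required_flank`
#' bp of flank on *both* sides of the core.  When `q` exceeds `majority`
#' (strictly), records without full flanks are removed and the rest are
#' trimmed to exactly `required_flank` bp per side (the `nnNNN...NNNnn`
#' layout).  Otherwise (`q <= majority`) all records are kept and flanks are
#' stripped entirely (`NNN...NNN`), in which case shape features cannot be
#' predicted for the two terminal core positions at either end.
#'
#' @param records Output of [parse_jaspar_fasta()] (or a data frame with the
#'   same columns).  All cores must have equal length; unequal cores signal
#'   an error instructing pre-alignment.
#' @param required_flank Flank width required per side (default 2 bp, the
#'   width needed to predict shape for the entire core).
#' @param majority Retention threshold on `q` (default 0.5).
#' @return A `tfbs_dataset` (case-encoded sequences: core upper, flanks
#'   lower) with provenance counts.
#' @export
apply_flank_rule <- function(records, required_flank = 2L, majority = 0.5) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  clen <- unique(records$core_length)
  if (length(clen) != 1L) {
    abort(sprintf(
      "core lengths differ (%s); records must be pre-aligned to a common core before assembly.",
      paste(sort(clen), collapse = ", ")))
  }
  flanked <- records$left_flank >= required_flank &
    records$right_flank >= required_flank
  q <- mean(flanked)
  if (q > majority) {
    kept <- records[flanked, , drop = FALSE]
    seq <- substr(kept$sequence,
                  kept$core_start - required_flank + 1L,
                  kept$core_start + kept$core_length + required_flank)
    seq <- paste0(
      tolower(substr(seq, 1L, required_flank)),
      toupper(substr(seq, required_flank + 1L, required_flank + clen)),
      tolower(substr(seq, required_flank + clen + 1L, nchar(seq)))
    )
    out <- tibble::tibble(seq_id = kept$seq_id, sequence = seq)
    fw <- as.integer(required_flank)
  } else {
    seq <- toupper(substr(records$sequence, records$core_start + 1L,
                          records$core_start + records$core_length))
    out <- tibble::tibble(seq_id = records$seq_id, sequence = seq)
    fw <- 0L
  }
  new_tfbs_dataset(out, core_length = clen, flank_width = fw,
                   provenance = list(
                     source = "case_annotated_fasta",
                     n_input = nrow(records),
                     n_flanked = sum(flanked),
                     flanked_fraction = q,
                     branch = if (q > majority) "trim_to_flanks" else "strip_flanks",
                     required_flank = as.integer(required_flank),
                     majority = majority,
                     n_output = nrow(out)))
}

#' Assemble a dataset from PBM probes via motif scanning
#'
#' Pipeline: (1) scan all probes for motif occurrences at `p_threshold`;
#' (2) optionally remove probes containing two or more occurrences;
#' (3) optionally keep only the `top_fraction` of the remaining
#' motif-containing probes with the highest signal intensities (ties at the
#' cutoff are kept); (4) extract every surviving occurrence together with
#' 2-bp flanks, reverse-complementing minus-strand occurrences into motif
#' orientation; occurrences without 2 bp of probe sequence on both sides are
#' dropped; (5) emit the aligned dataset (`flank_width = 2`) with
#' stage-by-stage provenance counts.
#'
#' @param probes Data frame with `probe_id`, `sequence`, `intensity`.
#' @param model A `motif_model`.
#' @param p_threshold Occurrence-calling threshold (default `1e-3`).
#' @param drop_multi_site Remove probes with multiple occurrences
#'   (default `TRUE`).
#' @param top_fraction Fraction of highest-intensity probes to keep after
#'   the multi-site filter, or `NULL` for all (the ranked-probe selection
#'   used for PBM data is 0.25).
#' @param required_flank Flank width extracted around each occurrence
#'   (default 2 bp).
#' @return A `tfbs_dataset` whose sequence ids are
#'   `<probe_id>:<offset><strand>`, sorted by (probe_id, offset, strand).
#' @export
assemble_from_probes <- function(probes, model, p_threshold = 1e-3,
                                 drop_multi_site = TRUE, top_fraction = NULL,
                                 required_flank = 2L) {
  tbl <- as_probe_tbl(probes)
  occ <- scan_probes(tbl, model, p_threshold = p_threshold)
  counts <- list(n_probes = nrow(tbl))
  n_occ <- table(factor(occ$probe_id, levels = tbl$probe_id))
  with_sites <- tbl$probe_id[n_occ >= 1L]
  counts$n_probes_with_sites <- length(with_sites)
  keep_ids <- with_sites
  if (isTRUE(drop_multi_site)) {
    keep_ids <- tbl$probe_id[n_occ == 1L]
  }
  counts$n_after_multisite_filter <- length(keep_ids)
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) {
      abort("`top_fraction` must be in (0, 1].")
    }
    if (!"intensity" %in% names(tbl)) {
      abort("`top_fraction` requires an `intensity` column.")
    }
    sub <- tbl[tbl$probe_id %in% keep_ids, , drop = FALSE]
    n_keep <- ceiling(top_fraction * nrow(sub))
    if (n_keep > 0L) {
      cutoff <- sort(sub$intensity, decreasing = TRUE)[n_keep]
      keep_ids <- sub$probe_id[sub$intensity >= cutoff]  # ties at cutoff kept
    } else {
      keep_ids <- character(0)
    }
  }
  counts$n_after_intensity_filter <- length(keep_ids)
  occ <- occ[occ$probe_id %in% keep_ids, , drop = FALSE]
  counts$n_occurrences <- nrow(occ)

  W <- model$width
  probe_seq <- setNames(tbl$sequence, tbl$probe_id)
  L <- nchar(probe_seq[occ$probe_id])
  has_flanks <- occ$offset >= required_flank &
    occ$offset + W + required_flank <= L
  occ <- occ[has_flanks, , drop = FALSE]
  counts$n_sites_with_flanks <- nrow(occ)
  if (nrow(occ) == 0L) {
    abort(paste0(
      "no binding sites survived assembly; stage counts: ",
      paste(sprintf("%s=%d", names(counts), unlist(counts)), collapse = ", ")))
  }
  frag <- substr(probe_seq[occ$probe_id],
                 occ$offset - required_flank + 1L,
                 occ$offset + W + required_flank)
  minus <- occ$strand == "-"
  frag[minus] <- reverse_complement(frag[minus])
  frag <- paste0(tolower(substr(frag, 1L, required_flank)),
                 toupper(substr(frag, required_flank + 1L, required_flank + W)),
                 tolower(substr(frag, required_flank + W + 1L, nchar(frag))))
  out <- tibble::tibble(
    seq_id = sprintf("%s:%d%s", occ$probe_id, occ$offset, occ$strand),
    sequence = unname(frag)
  )
  ord <- order(occ$probe_id, occ$offset, occ$strand)
  out <- out[ord, , drop = FALSE]
  new_tfbs_dataset(out, core_length = W,
                   flank_width = as.integer(required_flank),
                   provenance = c(list(source = "pbm_probes",
                                       p_threshold = p_threshold,
                                       drop_multi_site = drop_multi_site,
                                       top_fraction = top_fraction),
                                  counts))
}

#' Build a dataset directly from pre-aligned sequences
#'
#' For user-supplied aligned sites (all the same length).  Case annotation,
#' when present, defines the core; an all-upper-case input is treated as an
#' unflanked core.
#'
#' @param sequences Character vector (optionally named) or data frame with
#'   `seq_id`, `sequence`.
#' @param flank_width Flank width on each side (0 or 2); inferred from case
#'   annotation when `NULL`.
#' @return A `tfbs_dataset`.
#' @export
as_tfbs_dataset <- function(sequences, flank_width = NULL) {
  tbl <- if (is.data.frame(sequences)) {
    tibble::tibble(seq_id = as.character(sequences$seq_id),
                   sequence = sequences$sequence)
  } else {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    tibble::tibble(seq_id = ids, sequence = unname(sequences))
  }
  if (any(grepl("[^ACGTacgt]", tbl$sequence))) {
    abort("sequences must be over {A, C, G, T} (case-annotated).")
  }
  len <- unique(nchar(tbl$sequence))
  if (length(len) != 1L) abort("aligned sequences must all have the same length.")
  if (is.null(flank_width)) {
    lo <- regexpr("[ACGT]", tbl$sequence)
    fw <- unique(lo - 1L)
    if (length(fw) != 1L || fw < 0L) {
      abort("cannot infer a common flank width from case annotation; pass `flank_width`.")
    }
    flank_width <- fw
  }
  flank_width <- as.integer(flank_width)
  core <- len - 2L * flank_width
  if (core < 1L) abort("`flank_width` too large for the sequence length.")
  seq <- paste0(tolower(substr(tbl$sequence, 1L, flank_width)),
                toupper(substr(tbl$sequence, flank_width + 1L, flank_width + core)),
                tolower(substr(tbl$sequence, flank_width + core + 1L, len)))
  new_tfbs_dataset(tibble::tibble(seq_id = tbl$seq_id, sequence = seq),
                   core_length = core, flank_width = flank_width,
                   provenance = list(source = "prealigned",
                                     n_input = nrow(tbl),
                                     n_output = nrow(tbl)))
}

#' Position frequency matrix and information content of a dataset
#'
#' Tallies base counts at every position of the assembled sites (flanks
#' included) and computes the per-position information content
#' `2 - H(frequencies)` in bits against a uniform background (no
#' small-sample correction) — the numeric data behind a motif logo.
#' Positions are numbered in core coordinates (core start = 0, flanks
#' negative), matching the shape heat maps.
#'
#' @param dataset A `tfbs_dataset`.
#' @return Tibble with columns `position`, `A`, `C`, `G`, `T`,
#'   `info_bits`.
#' @export
compute_pfm <- function(dataset) {
  stopifnot(inherits(dataset, "tfbs_dataset"), nrow(dataset) > 0L)
  seqs <- toupper(dataset$sequence)
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
                byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(factor(mat[, j], levels = DNA_BASES), nbins = 4L)
  }, integer(4))
  freq <- sweep(counts, 2L, colSums(counts), "/")
  h <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  tibble::tibble(
    position = seq_len(L) - 1L - flank_width(dataset),
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    info_bits = 2 - h
  )
}

#' Write a dataset as case-annotated FASTA
#'
#' @param dataset A `tfbs_dataset`.
#' @param path Output FASTA path.
#' @param provenance_path Optional path for a JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset_fasta <- function(dataset, path, provenance_path = NULL) {
  stopifnot(inherits(dataset, "tfbs_dataset"))
  x <- Biostrings::BStringSet(setNames(dataset$sequence, dataset$seq_id))
  Biostrings::writeXStringSet(x, path)
  if (!is.null(provenance_path)) {
    jsonlite::write_json(
      c(provenance(dataset),
        list(core_length = core_length(dataset),
             flank_width = flank_width(dataset))),
      provenance_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(path)
}
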