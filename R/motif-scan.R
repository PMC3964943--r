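#' Build a log-odds position weight matrix from a frequency matrix
#'
#' Columns of the PFM (counts or probabilities; auto-normalised) are
#' converted to frequencies, a pseudocount proportional to the background is
#' added, and the result is expressed as base-2 log-odds against the
#' background, so scores are in bits.
#'
#' @param pfm 4 x W non-negative matrix with rows A, C, G, T (rownames
#'   optional, assumed in that order when absent).
#' @param pseudocount Total pseudocount added per column, distributed
#'   proportionally to the background (default 0.01).
#' @param background Base probabilities (A, C, G, T); must be positive and
#'   sum to 1.
#' @return A `motif_model`: list with elements `pfm`, `probs`
#'   (pseudocounted frequencies), `pwm` (bits), `width`, `pseudocount`,
#'   `background`.
#' @examples
#' pfm <- matrix(c(8, 0, 0, 0, 0, 8, 0, 0, 0, 0, 8, 0), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' build_pwm(pfm)
#' @export
build_pwm <- function(pfm, pseudocount = 0.01,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) abort("`pfm` must have 4 rows (A, C, G, T).")
  if (ncol(pfm) < 1L) abort("`pfm` must have at least one column.")
  if (any(pfm < 0) || anyNA(pfm)) abort("`pfm` must be non-negative and complete.")
  if (is.null(rownames(pfm))) rownames(pfm) <- DNA_BASES
  pfm <- pfm[DNA_BASES, , drop = FALSE]
  background <- unname(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-12) {
    abort("`background` must be 4 positive probabilities summing to 1.")
  }
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  csum <- colSums(pfm)
  if (any(csum == 0)) {
    abort(sprintf("degenerate matrix: all-zero column(s) %s",
                  paste(which(csum == 0), collapse = ", ")))
  }
  f <- sweep(pfm, 2L, csum, "/")
  probs <- sweep(f + pseudocount * background, 2L, 1 + pseudocount, "/")
  pwm <- log2(probs / background)
  structure(
    list(pfm = pfm, probs = probs, pwm = pwm, width = ncol(pfm),
         pseudocount = pseudocount,
         background = setNames(background, DNA_BASES)),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, pseudocount %g\n", x$width,
              x$pseudocount))
  cat("consensus:", paste(DNA_BASES[apply(x$pwm, 2L, which.max)],
                          collapse = ""), "\n")
  print(round(x$pwm, 3))
  invisible(x)
}

#' Exact score-to-p-value map for a PWM
#'
#' Discretizes the PWM onto a fixed score grid and computes, by positional
#' convolution over the background base distribution, the exact distribution
#' of the discretized score of a random W-mer.  The returned map gives
#' `p(s) = P(score >= s)` — a survival function, monotone non-increasing,
#' with `p(minimum achievable score) = 1`.  Observed scores must be rounded
#' to the same grid before lookup; [scan_probes()] does this internally.
#'
#' @param model A `motif_model`.
#' @param bins_per_bit Grid resolution: number of score bins per bit
#'   (default 1000, i.e. scores rounded to 0.001 bit).
#' @return A `score_dist`: list with the grid `step`, integer score range
#'   `kmin`/`kmax`, the survival vector `surv`, the discretized PWM `ipwm`,
#'   and `pvalue(score_bits)`, a vectorised lookup function.
#' @export
score_pvalue_map <- function(model, bins_per_bit = 1000) {
  stopifnot(inherits(model, "motif_model"))
  ipwm <- round(model$pwm * bins_per_bit)
  kmin_j <- apply(ipwm, 2L, min)
  kmax_j <- apply(ipwm, 2L, max)
  kmin <- sum(kmin_j)
  kmax <- sum(kmax_j)
  if (kmax - kmin < 100L) {
    abort("score grid too coarse: fewer than 100 bins over the PWM score range; increase `bins_per_bit`.")
  }
  bg <- unname(model$background)
  # dense DP over integer scores, offset so index 1 <=> current minimum
  probv <- 1
  off <- 0L
  for (j in seq_len(model$width)) {
    kj <- ipwm[, j] - kmin_j[j]
    width_j <- max(kj)
    newv <- numeric(length(probv) + width_j)
    for (b in 1:4) {
      idx <- seq_along(probv) + kj[b]
      newv[idx] <- newv[idx] + probv * bg[b]
    }
    probv <- newv
    off <- off + kmin_j[j]
  }
  # probv[i] = P(score == kmin + i - 1)
  surv <- rev(cumsum(rev(probv)))
  step <- 1 / bins_per_bit
  pvalue <- function(score_bits) {
    k <- round(score_bits / step)
    i <- pmin(pmax(k - kmin + 1, 1L), length(surv))
    p <- surv[i]
    p[k < kmin] <- 1
    p[k > kmax] <- surv[length(surv)]
    p
  }
  structure(list(step = step, kmin = kmin, kmax = kmax, surv = surv,
                 ipwm = ipwm, bins_per_bit = bins_per_bit, pvalue = pvalue),
            class = "score_dist")
}

encode_dna <- function(seq) {
  x <- utf8ToInt(seq)
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[x]
}

score_windows <- function(codes, ipwm) {
  W <- ncol(ipwm)
  nw <- length(codes) - W + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(W)) {
    sc <- sc + ipwm[codes[j:(j + nw - 1L)], j]
  }
  sc
}

as_probe_tbl <- function(probes) {
  if (!is.data.frame(probes) ||
      !all(c("probe_id", "sequence") %in% names(probes))) {
    abort("`probes` must be a data frame with columns `probe_id` and `sequence`.")
  }
  tbl <- tibble::as_tibble(probes)
  tbl$probe_id <- as.character(tbl$probe_id)
  tbl$sequence <- toupper(tbl$sequence)
  if (anyDuplicated(tbl$probe_id)) abort("duplicated `probe_id`.")
  if (any(grepl("[^ACGT]", tbl$sequence))) {
    abort("probe sequences must be over {A, C, G, T}.")
  }
  tbl
}

#' Scan probe sequences for motif occurrences with exact p-values
#'
#' Scores every window on both strands of every probe with the discretized
#' log-odds PWM and reports windows whose exact p-value (probability of an
#' equal or better score under the background model) is at or below
#' `p_threshold`.  Overlapping occurrences are all reported.
#'
#' @param probes Data frame with columns `probe_id`, `sequence` (and
#'   optionally `intensity`).
#' @param model A `motif_model`.
#' @param p_threshold Occurrence-calling threshold (default `1e-3`).
#' @param bins_per_bit Score grid passed to [score_pvalue_map()].
#' @return Tibble with columns `probe_id`, `offset` (0-based start on the
#'   forward strand), `strand` (`"+"`/`"-"`), `score_bits`, `p_value`,
#'   sorted by `(probe_id, offset, strand)`.  Probes shorter than the motif
#'   are skipped with a warning.
#' @export
scan_probes <- function(probes, model, p_threshold = 1e-3,
                        bins_per_bit = 1000) {
  stopifnot(inherits(model, "motif_model"))
  if (p_threshold <= 0 || p_threshold > 1) {
    abort("`p_threshold` must be in (0, 1].")
  }
  tbl <- as_probe_tbl(probes)
  if (nrow(tbl) == 0L) abort("`probes` must be non-empty.")
  W <- model$width
  short <- nchar(tbl$sequence) < W
  if (any(short)) {
    warn(sprintf("skipping %d probe(s) shorter than the motif width (%d).",
                 sum(short), W))
    tbl <- tbl[!short, , drop = FALSE]
  }
  sd_map <- score_pvalue_map(model, bins_per_bit = bins_per_bit)
  ipwm <- sd_map$ipwm
  res <- vector("list", nrow(tbl))
  for (k in seq_len(nrow(tbl))) {
    seqk <- tbl$sequence[k]
    Lk <- nchar(seqk)
    fc <- encode_dna(seqk)
    rc <- encode_dna(reverse_complement(seqk))
    fwd <- score_windows(fc, ipwm)
    rev_sc <- score_windows(rc, ipwm)
    nw <- Lk - W + 1L
    k_all <- c(fwd, rev_sc)
    off_all <- c(0:(nw - 1L), (nw - 1L):0)  # reverse window i starts at L-W-i
    strand_all <- rep(c("+", "-"), each = nw)
    p <- sd_map$pvalue(k_all * sd_map$step)
    hit <- p <= p_threshold
    if (!any(hit)) next
    res[[k]] <- tibble::tibble(
      probe_id = tbl$probe_id[k],
      offset = off_all[hit],
      strand = strand_all[hit],
      score_bits = k_all[hit] * sd_map$step,
      p_value = p[hit]
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(probe_id = character(), offset = integer(),
                          strand = character(), score_bits = double(),
                          p_value = double())
  }
  dplyr::arrange(out, .data$probe_id, .data$offset, .data$strand)
}

#' Barcode probes by motif occurrence count
#'
#' Orders probes by descending signal intensity (the barcode's left-to-right
#' order; ties broken by `probe_id`) and assigns each a category: `white`
#' for no motif occurrence, `yellow` for exactly one, `brown` for two or
#' more.
#'
#' @param probes Data frame with columns `probe_id`, `sequence`,
#'   `intensity`.
#' @param occurrences Occurrence table from [scan_probes()]; its
#'   `probe_id`s must be a subset of the probes'.
#' @return A tibble of class `barcode_tbl` with columns `rank`, `probe_id`,
#'   `intensity`, `n_sites`, `category` (factor white/yellow/brown).
#' @export
barcode_probes <- function(probes, occurrences) {
  tbl <- as_probe_tbl(probes)
  if (!"intensity" %in% names(tbl)) abort("`probes` must have an `intensity` column.")
  if (any(!is.finite(tbl$intensity))) abort("probe intensities must be finite.")
  extra <- setdiff(unique(occurrences$probe_id), tbl$probe_id)
  if (length(extra) > 0L) {
    abort(sprintf("occurrences refer to unknown probe_id(s): %s",
                  paste(head(extra, 5L), collapse = ", ")))
  }
  counts <- table(factor(occurrences$probe_id, levels = tbl$probe_id))
  tbl$n_sites <- as.integer(counts[tbl$probe_id])
  tbl$category <- factor(
    ifelse(tbl$n_sites == 0L, "white",
           ifelse(tbl$n_sites == 1L, "yellow", "brown")),
    levels = c("white", "yellow", "brown")
  )
  out <- dplyr::arrange(tbl, dplyr::desc(.data$intensity), .data$probe_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  out <- dplyr::select(out, "rank", "probe_id", "intensity", "n_sites",
                       "category")
  class(out) <- c("barcode_tbl", class(out))
  out
}

#' Read a position frequency matrix
#'
#' Understands the JASPAR matrix dialect (`>` header optional; four rows,
#' either bare numbers or `A [ 1 2 3 ]`) and UniPROBE-style rows
#' (`A: 0.1 0.2 ...`).  Counts versus probabilities are auto-detected from
#' the column sums; both are accepted by [build_pwm()].
#'
#' @param path Path to the matrix file.
#' @return 4 x W numeric matrix with rows A, C, G, T.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  if (length(lines) < 4L) abort("PFM file must contain 4 matrix rows (A, C, G, T).")
  lines <- lines[seq_len(4L)]
  rows <- lapply(lines, function(ln) {
    ln <- sub("^[ACGTacgt][:]?\\s*", "", ln)
    ln <- gsub("[][]", " ", ln)
    suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  })
  w <- lengths(rows)
  if (length(unique(w)) != 1L) abort("PFM rows have unequal lengths.")
  m <- do.call(rbind, rows)
  if (anyNA(m)) abort("non-numeric cell in PFM file.")
  rownames(m) <- DNA_BASES
  m
}

#' Read a probe file
#'
#' TSV with columns `probe_id`, `sequence`, `intensity`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of probe records.
#' @export
read_probes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    sequence = readr::col_character(),
    intensity = readr::col_double()
  ))
  as_probe_tbl(tbl)
}
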