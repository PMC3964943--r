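#' Simulate a pentamer structural query table
#'
#' Draws one value per feature (two per step feature) for each of the 512
#' canonical pentamers, uniformly within physically plausible ranges:
#' MGW 2.8-6.2 Angstrom, ProT -18-0 degrees, Roll -8-10 degrees,
#' HelT 30-40 degrees.  Deterministic per seed.  A real query table derived
#' from molecular simulations can be used instead via
#' [load_pentamer_table()]; this synthetic table preserves the method's
#' structure (canonical keys, value ranges, strand conventions), not its
#' measured values.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(min, max)` per feature.
#' @return A `pentamer_table` with `source = "synthetic"`.
#' @export
simulate_pentamer_table <- function(seed = 1L,
                                    ranges = list(MGW = c(2.8, 6.2),
                                                  ProT = c(-18, 0),
                                                  Roll = c(-8, 10),
                                                  HelT = c(30, 40))) {
  stopifnot(all(c("MGW", "ProT", "Roll", "HelT") %in% names(ranges)))
  p <- canonical_pentamers()
  set.seed(seed)
  u <- function(rg) runif(length(p), rg[1], rg[2])
  tbl <- tibble::tibble(
    pentamer = p,
    MGW = u(ranges$MGW), ProT = u(ranges$ProT),
    Roll1 = u(ranges$Roll), Roll2 = u(ranges$Roll),
    HelT1 = u(ranges$HelT), HelT2 = u(ranges$HelT)
  )
  new_pentamer_table(tbl, source = "synthetic")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate case-annotated binding-site records
#'
#' Emulates motif-database FASTA input with variable flank availability: a
#' fraction `flank_fraction` of records carries lower-case flanks of at
#' least 2 bp on both sides; the remainder carries 0-1 bp per side, so the
#' flank-retention rule later keeps exactly `ceiling(flank_fraction * n)`
#' records when the fraction exceeds the majority threshold.  Cores are the
#' consensus with independent per-position mutations.
#'
#' @param n Number of records.
#' @param consensus Core consensus sequence (default the E-box `CACGTG`).
#' @param mutation_rate Per-position core mutation probability.
#' @param flank_fraction Fraction of records with full (>= 2 bp) flanks.
#' @param flank_range Flank widths (per side) for fully-flanked records,
#'   `c(min, max)` with `min >= 2`.
#' @param seed Integer seed.
#' @return Tibble with columns `seq_id`, `sequence` (case-encoded),
#'   `core_start`, `core_length`, `left_flank`, `right_flank`, `flanked`
#'   (ground truth), directly consumable by [apply_flank_rule()] or
#'   writable via [write_sites_fasta()].
#' @export
simulate_jaspar_sites <- function(n = 50L, consensus = "CACGTG",
                                  mutation_rate = 0.1, flank_fraction = 0.6,
                                  flank_range = c(2L, 4L), seed = 1L) {
  stopifnot(flank_fraction >= 0, flank_fraction <= 1, flank_range[1] >= 2L)
  set.seed(seed)
  cl <- nchar(consensus)
  n_flanked <- ceiling(flank_fraction * n)
  flanked <- seq_len(n) <= n_flanked
  cores <- mutate_sequence(rep(consensus, n), mutation_rate)
  lf <- rf <- integer(n)
  lf[flanked] <- sample(seq.int(flank_range[1], flank_range[2]),
                        n_flanked, replace = TRUE)
  rf[flanked] <- sample(seq.int(flank_range[1], flank_range[2]),
                        n_flanked, replace = TRUE)
  lf[!flanked] <- sample(0:1, n - n_flanked, replace = TRUE)
  rf[!flanked] <- sample(0:1, n - n_flanked, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(tolower(if (lf[i] > 0) random_dna(1L, lf[i]) else ""),
           toupper(cores[i]),
           tolower(if (rf[i] > 0) random_dna(1L, rf[i]) else ""))
  }, character(1))
  out <- tibble::tibble(
    seq_id = sprintf("site%03d", seq_len(n)),
    sequence = seqs,
    core_start = lf,
    core_length = cl,
    left_flank = lf,
    right_flank = rf,
    flanked = flanked
  )
  class(out) <- c("case_annotated_tbl", class(out))
  out
}

#' Write case-annotated records as FASTA
#'
#' @param records Data frame with `seq_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(setNames(records$sequence, records$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

consensus_pfm <- function(consensus, n_sites = 100L, dominant = 0.85) {
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  W <- length(ch)
  m <- matrix(round(n_sites * (1 - dominant) / 3), 4L, W,
              dimnames = list(DNA_BASES, NULL))
  m[cbind(match(ch, DNA_BASES), seq_len(W))] <- round(n_sites * dominant)
  m
}

#' Simulate a protein binding microarray experiment
#'
#' Generates random probes, plants motif occurrences (consensus with
#' optional mutations) in a configured fraction of them (one site, or two
#' non-overlapping sites) at uniform random offsets and strands, always
#' leaving at least 2 bp of probe sequence on both sides of the site, and
#' assigns fluorescence intensities by a log-normal model:
#' `intensity = exp(seq_weight * best planted-site PWM score +
#' shape_weight * (planted-site mean MGW - table mean MGW) + noise)`;
#' motif-free probes draw `exp(noise)` around the baseline.  Returns the
#' probe table, a consensus-derived PFM, the motif model and a manifest of
#' every planted site.
#'
#' @param n_probes Number of probes.
#' @param probe_length Probe length in bp (default 36).
#' @param consensus Planted motif consensus (default `"CACGTTAC"`,
#'   non-palindromic).
#' @param site_fraction Fraction of probes with exactly one planted site.
#' @param two_site_fraction Fraction with two planted sites.
#' @param site_mutation_rate Per-position mutation rate of planted sites.
#' @param seq_weight,shape_weight,noise_sd Intensity-model coefficients.
#' @param table `pentamer_table` used for the shape term (default: a
#'   synthetic table from the same seed).
#' @param dominant Consensus-base probability encoded in the PFM.
#' @param seed Integer seed.
#' @return List with `probes` (tibble `probe_id`, `sequence`,
#'   `intensity`), `pfm` (4 x W counts), `model` (`motif_model`),
#'   `manifest` (tibble `probe_id`, `offset`, `strand`, `site`), `table`.
#' @export
simulate_pbm_experiment <- function(n_probes = 500L, probe_length = 36L,
                                    consensus = "CACGTTAC",
                                    site_fraction = 0.5,
                                    two_site_fraction = 0.1,
                                    site_mutation_rate = 0,
                                    seq_weight = 0.25, shape_weight = 0.2,
                                    noise_sd = 0.3, table = NULL,
                                    dominant = 0.85, seed = 1L) {
  W <- nchar(consensus)
  if (probe_length < W + 4L) abort("`probe_length` must be at least motif width + 4.")
  stopifnot(site_fraction + two_site_fraction <= 1)
  if (is.null(table)) table <- simulate_pentamer_table(seed = seed)
  pfm <- consensus_pfm(consensus, dominant = dominant)
  model <- build_pwm(pfm)
  set.seed(seed)
  seqs <- random_dna(n_probes, probe_length)
  n_two <- round(two_site_fraction * n_probes)
  n_one <- round(site_fraction * n_probes)
  n_sites_per_probe <- c(rep(2L, n_two), rep(1L, n_one),
                         rep(0L, n_probes - n_two - n_one))
  ids <- sprintf("probe%04d", seq_len(n_probes))
  manifest <- list()
  offsets_ok <- 2L:(probe_length - W - 2L)
  for (i in seq_len(n_probes)) {
    k <- n_sites_per_probe[i]
    if (k == 0L) next
    repeat {
      offs <- sort(sample(offsets_ok, k))
      if (k == 1L || diff(offs) >= W) break
    }
    for (o in offs) {
      site <- mutate_sequence(consensus, site_mutation_rate)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") site else reverse_complement(site)
      substr(seqs[i], o + 1L, o + W) <- planted
      manifest[[length(manifest) + 1L]] <-
        tibble::tibble(probe_id = ids[i], offset = o, strand = strand,
                       site = site)
    }
  }
  manifest <- if (length(manifest) > 0L) dplyr::bind_rows(manifest) else
    tibble::tibble(probe_id = character(), offset = integer(),
                   strand = character(), site = character())

  # intensity model: best planted site drives the signal
  mgw_mean_table <- mean(table$MGW)
  log_int <- rnorm(n_probes, 0, noise_sd)
  sd_map <- score_pvalue_map(model)
  if (nrow(manifest) > 0L) {
    site_score <- vapply(manifest$site, function(s) {
      sum(sd_map$ipwm[cbind(encode_dna(s), seq_len(W))]) * sd_map$step
    }, numeric(1), USE.NAMES = FALSE)
    site_mgw <- vapply(manifest$site, function(s) {
      prof <- predict_shape(c(x = s), table)
      mean(prof$value[prof$feature == "MGW"], na.rm = TRUE)
    }, numeric(1), USE.NAMES = FALSE)
    contrib <- seq_weight * site_score + shape_weight * (site_mgw - mgw_mean_table)
    best <- tapply(contrib, manifest$probe_id, max)
    idx <- match(names(best), ids)
    log_int[idx] <- log_int[idx] + as.numeric(best)
  }
  probes <- tibble::tibble(probe_id = ids, sequence = seqs,
                           intensity = exp(log_int))
  list(probes = probes, pfm = pfm, model = model, manifest = manifest,
       table = table)
}

#' Simulate an aligned site set with a planted shape effect on intensity
#'
#' Generates `n_sites` aligned binding sites (consensus core with
#' per-position mutations, fully random 2-bp flanks) and log-normal
#' intensities composed of a sequence term (random coefficients on the
#' mononucleotide identity of every position), a shape term (random
#' coefficients on the standardized per-position MGW and Roll tracks) and
#' Gaussian noise.  The sequence and shape terms are each scaled to unit
#' standard deviation and multiplied by their weights, so the weights set
#' the relative variance contributions directly.  Because shape is a
#' nonlinear (pentamer-level) function of sequence that also crosses the
#' core-flank boundary, mononucleotide features recover only part of the
#' shape term — the planted margin that a shape-augmented model should
#' close.
#'
#' @param n_sites Number of sites (default 2000).
#' @param consensus Core consensus (default `CACGTG`).
#' @param mutation_rate Per-position core mutation probability
#'   (default 0.15).
#' @param seq_weight,shape_weight Standard deviations of the sequence and
#'   shape terms (defaults 1 and 1).
#' @param noise_sd Residual noise standard deviation (default 0.5).
#' @param table `pentamer_table` (default: synthetic from the same seed).
#' @param seed Integer seed.
#' @return List with `dataset` (a `tfbs_dataset`, flank width 2),
#'   `intensities` (tibble `seq_id`, `intensity`), `profiles`
#'   (`shape_tbl`), `table`, and `truth` (the planted coefficients and
#'   weights).
#' @export
simulate_specificity_dataset <- function(n_sites = 2000L,
                                         consensus = "CACGTG",
                                         mutation_rate = 0.15,
                                         seq_weight = 1, shape_weight = 1,
                                         noise_sd = 0.5, table = NULL,
                                         seed = 1L) {
  if (is.null(table)) table <- simulate_pentamer_table(seed = seed)
  set.seed(seed)
  cl <- nchar(consensus)
  cores <- mutate_sequence(rep(consensus, n_sites), mutation_rate)
  seqs <- paste0(tolower(random_dna(n_sites, 2L)), toupper(cores),
                 tolower(random_dna(n_sites, 2L)))
  dataset <- new_tfbs_dataset(
    tibble::tibble(seq_id = sprintf("site%05d", seq_len(n_sites)),
                   sequence = seqs),
    core_length = cl, flank_width = 2L,
    provenance = list(source = "simulated", n_input = n_sites,
                      n_output = n_sites, seed = seed))
  profiles <- dataset_profiles(dataset, table)

  L <- cl + 4L
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  seq_coef <- matrix(rnorm(4L * L), 4L, L)
  seq_part <- rowSums(vapply(seq_len(L), function(j) {
    seq_coef[match(chars[, j], DNA_BASES), j]
  }, numeric(n_sites)))

  mgw <- profile_matrix(profiles, "MGW")
  roll <- profile_matrix(profiles, "Roll")
  shp <- cbind(mgw, roll)
  shp <- scale(shp)
  shape_coef <- rnorm(ncol(shp))
  shape_part <- as.numeric(shp %*% shape_coef)

  unit <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x
  log_int <- seq_weight * unit(seq_part) + shape_weight * unit(shape_part) +
    rnorm(n_sites, 0, noise_sd)
  list(dataset = dataset,
       intensities = tibble::tibble(seq_id = dataset$seq_id,
                                    intensity = exp(log_int)),
       profiles = profiles, table = table,
       truth = list(seq_coef = seq_coef, shape_coef = shape_coef,
                    seq_weight = seq_weight, shape_weight = shape_weight,
                    noise_sd = noise_sd, seed = seed))
}
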