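write_fasta_lines <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

test_that("case-annotated FASTA parsing locates the single upper-case core", {
  path <- write_fasta_lines(list(s1 = "aaCACGTGtt", s2 = "CACGTG",
                                 s3 = "aaCAcgTGtt"))
  expect_warning(rec <- parse_jaspar_fasta(path), "rejected 1")
  expect_identical(rec$seq_id, c("s1", "s2"))
  expect_equal(rec$core_start[1], 2L)
  expect_equal(rec$core_length[1], 6L)
  expect_equal(c(rec$left_flank[1], rec$right_flank[1]), c(2L, 2L))
  expect_equal(c(rec$left_flank[2], rec$right_flank[2]), c(0L, 0L))
  expect_identical(attr(rec, "rejected")$seq_id, "s3")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(parse_jaspar_fasta(empty))
  allbad <- write_fasta_lines(list(x = "acgtacgt"))
  expect_warning(expect_error(parse_jaspar_fasta(allbad), "no valid"))
})

test_that("flank-retention rule branches on the majority threshold", {
  rec <- function(id, l, r) {
    tibble::tibble(seq_id = id,
                   sequence = paste0(strrep("a", l), "CACGTG", strrep("t", r)),
                   core_start = l, core_length = 6L,
                   left_flank = l, right_flank = r)
  }
  # 3 of 5 flanked (q = 0.6 > 0.5): keep the 3, trim to 2-bp flanks
  recs <- dplyr::bind_rows(rec("a", 2, 2), rec("b", 3, 4), rec("c", 2, 3),
                           rec("d", 0, 1), rec("e", 1, 0))
  ds <- apply_flank_rule(recs)
  expect_equal(nrow(ds), 3L)
  expect_equal(flank_width(ds), 2L)
  expect_true(all(nchar(ds$sequence) == 10L))
  expect_identical(ds$sequence[2], "aaCACGTGtt")  # over-long flanks trimmed

  # 2 of 5 flanked (q = 0.4): keep all, strip flanks
  recs2 <- dplyr::bind_rows(rec("a", 2, 2), rec("b", 3, 4), rec("c", 1, 3),
                            rec("d", 0, 1), rec("e", 1, 0))
  ds2 <- apply_flank_rule(recs2)
  expect_equal(nrow(ds2), 5L)
  expect_equal(flank_width(ds2), 0L)
  expect_true(all(ds2$sequence == "CACGTG"))

  # exactly 50% flanked falls in the strip-flanks branch
  recs3 <- dplyr::bind_rows(rec("a", 2, 2), rec("b", 2, 2),
                            rec("c", 0, 0), rec("d", 1, 1))
  ds3 <- apply_flank_rule(recs3)
  expect_equal(nrow(ds3), 4L)
  expect_equal(flank_width(ds3), 0L)

  # unequal core lengths are an alignment error
  bad <- dplyr::bind_rows(rec("a", 2, 2),
                          tibble::tibble(seq_id = "z", sequence = "aaCACGTGGtt",
                                         core_start = 2L, core_length = 7L,
                                         left_flank = 2L, right_flank = 2L))
  expect_error(apply_flank_rule(bad), "pre-aligned")
})

test_that("flank rule output size matches the rule over randomized sets", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:40, 1)
    f <- runif(1)
    sites <- simulate_jaspar_sites(n = n, flank_fraction = f, seed = seed)
    q <- mean(sites$left_flank >= 2 & sites$right_flank >= 2)
    ds <- apply_flank_rule(sites)
    if (q > 0.5) {
      expect_equal(nrow(ds), sum(sites$left_flank >= 2 & sites$right_flank >= 2))
      expect_equal(flank_width(ds), 2L)
    } else {
      expect_equal(nrow(ds), n)
      expect_equal(flank_width(ds), 0L)
    }
    pv <- provenance(ds)
    expect_equal(pv$n_output, nrow(ds))       # counts telescope
    expect_equal(pv$n_input, n)
  }
})

# deterministic probe fixture: AT-only background cannot score against a
# C/G-anchored consensus, so scan results equal the plant design exactly
probe_fixture <- function() {
  W <- 6L
  cons <- "CACGTA"
  bg <- function() strrep("AT", 15)   # 30 bp
  plant <- function(seq, offset, site) {
    substr(seq, offset + 1L, offset + nchar(site)) <- site
    seq
  }
  seqs <- character(10)
  # probes 1..8: one site each (probe 3 on the minus strand)
  offs <- c(4L, 6L, 8L, 10L, 12L, 14L, 16L, 18L)
  for (i in 1:8) {
    site <- if (i == 3) reverse_complement(cons) else cons
    seqs[i] <- plant(bg(), offs[i], site)
  }
  # probes 9, 10: two sites each
  seqs[9] <- plant(plant(bg(), 2L, cons), 20L, cons)
  seqs[10] <- plant(plant(bg(), 4L, cons), 16L, cons)
  pfm <- matrix(1, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  pfm[cbind(idx, 1:W)] <- 85
  list(probes = tibble::tibble(probe_id = sprintf("pr%02d", 1:10),
                               sequence = seqs,
                               intensity = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)),
       model = build_pwm(pfm), offsets = offs, consensus = cons)
}

test_that("probe assembly drops multi-site probes and extracts flanked sites", {
  fx <- probe_fixture()
  ds <- assemble_from_probes(fx$probes, fx$model, drop_multi_site = TRUE)
  expect_equal(nrow(ds), 8L)
  expect_equal(core_length(ds), 6L)
  expect_equal(flank_width(ds), 2L)
  expect_true(all(nchar(ds$sequence) == 10L))
  # minus-strand occurrence extracted in motif orientation
  expect_identical(toupper(substr(ds$sequence[3], 3, 8)), fx$consensus)
  pv <- provenance(ds)
  expect_equal(pv$n_probes, 10L)
  expect_equal(pv$n_probes_with_sites, 10L)
  expect_equal(pv$n_after_multisite_filter, 8L)
  expect_equal(pv$n_occurrences, 8L)
  expect_equal(pv$n_sites_with_flanks, 8L)

  # keeping multi-site probes yields all 12 occurrences
  ds_all <- assemble_from_probes(fx$probes, fx$model, drop_multi_site = FALSE)
  expect_equal(nrow(ds_all), 12L)

  # top fraction: half of the 8 single-site probes by intensity
  ds_top <- assemble_from_probes(fx$probes, fx$model, drop_multi_site = TRUE,
                                 top_fraction = 0.5)
  expect_equal(nrow(ds_top), 4L)
  expect_setequal(unique(sub(":.*$", "", ds_top$seq_id)),
                  c("pr01", "pr02", "pr03", "pr04"))
})

test_that("sites without room for 2-bp flanks are dropped", {
  fx <- probe_fixture()
  # plant a site flush at offset 0: no left flank available
  probes <- tibble::tibble(
    probe_id = c("edge", "mid"),
    sequence = c(paste0(fx$consensus, strrep("AT", 12)),
                 paste0("ATAT", fx$consensus, strrep("AT", 10))),
    intensity = c(1, 2))
  ds <- assemble_from_probes(probes, fx$model)
  expect_equal(nrow(ds), 1L)
  expect_equal(sub(":.*$", "", ds$seq_id), "mid")
  expect_equal(provenance(ds)$n_occurrences, 2L)
  expect_equal(provenance(ds)$n_sites_with_flanks, 1L)

  # nothing survives -> stage-by-stage error
  lone <- tibble::tibble(probe_id = "edge",
                         sequence = paste0(fx$consensus, strrep("AT", 12)),
                         intensity = 1)
  expect_error(assemble_from_probes(lone, fx$model), "stage counts")
})

test_that("probe assembly is invariant to input order", {
  fx <- probe_fixture()
  ds1 <- assemble_from_probes(fx$probes, fx$model)
  set.seed(2)
  shuffled <- fx$probes[sample(nrow(fx$probes)), ]
  ds2 <- assemble_from_probes(shuffled, fx$model)
  expect_identical(ds1$seq_id, ds2$seq_id)
  expect_identical(ds1$sequence, ds2$sequence)
})

test_that("PFM counts and information content", {
  ds <- as_tfbs_dataset(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                        flank_width = 0)
  pfm <- compute_pfm(ds)
  expect_equal(pfm$info_bits, rep(2, 4))          # identical sequences
  expect_equal(pfm$position, 0:3)

  ds2 <- as_tfbs_dataset(c(a = "AA", b = "CA", c = "GA", d = "TA"),
                         flank_width = 0)
  pfm2 <- compute_pfm(ds2)
  expect_equal(pfm2$info_bits[1], 0)              # equal base counts
  expect_equal(pfm2$info_bits[2], 2)

  # hand tally on a 4-sequence dataset with flanks
  ds3 <- as_tfbs_dataset(c(a = "atACGTcc", b = "ggACGTtt",
                           c = "taAGGTac", d = "ccACTTga"))
  expect_equal(flank_width(ds3), 2L)
  pfm3 <- compute_pfm(ds3)
  expect_equal(pfm3$position, -2:5)
  expect_equal(pfm3$A[pfm3$position == 0], 4L)
  expect_equal(pfm3$C[pfm3$position == 1], 3L)
  expect_equal(pfm3$G[pfm3$position == 1], 1L)
  expect_equal(pfm3$G[pfm3$position == 2], 3L)
  expect_equal(pfm3$T[pfm3$position == 3], 4L)
})

test_that("dataset FASTA round-trips with provenance sidecar", {
  sites <- simulate_jaspar_sites(n = 12, flank_fraction = 0.8, seed = 3)
  ds <- apply_flank_rule(sites)
  fa <- tempfile(fileext = ".fasta")
  js <- tempfile(fileext = ".json")
  write_dataset_fasta(ds, fa, provenance_path = js)
  rec <- parse_jaspar_fasta(fa)
  ds2 <- apply_flank_rule(rec)
  expect_identical(ds2$sequence, ds$sequence)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$core_length, core_length(ds))
  expect_equal(meta$n_output, nrow(ds))
})
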