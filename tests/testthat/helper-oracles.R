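# Independent oracles and small fixture builders.  These deliberately avoid
# the package's own lookup/canonicalization/DP code paths.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# a pentamer table in which every feature is constant
const_pentamer_table <- function(mgw = 5, prot = -5, roll = 2, helt = 34) {
  p <- canonical_pentamers()
  tbl <- tibble::tibble(pentamer = p, MGW = mgw, ProT = prot,
                        Roll1 = roll, Roll2 = roll,
                        HelT1 = helt, HelT2 = helt)
  # reuse the loader contract via the TSV round trip to exercise validation
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  load_pentamer_table(path, source = "constant")
}

# brute-force shape prediction: expands the canonical table to 1024 rows
# (step values swapped on the reverse-complement key) and slides windows
# with plain loops
brute_force_shape <- function(seq, table) {
  tab <- tibble::as_tibble(table)
  rc <- vapply(tab$pentamer, oracle_revcomp, character(1))
  keys <- c(tab$pentamer, rc)
  mgw_t <- c(tab$MGW, tab$MGW)
  prot_t <- c(tab$ProT, tab$ProT)
  r1_t <- c(tab$Roll1, tab$Roll2)
  r2_t <- c(tab$Roll2, tab$Roll1)
  h1_t <- c(tab$HelT1, tab$HelT2)
  h2_t <- c(tab$HelT2, tab$HelT1)
  L <- nchar(seq)
  mgw <- prot <- rep(NA_real_, L)
  roll_acc <- helt_acc <- replicate(L - 1L, numeric(0), simplify = FALSE)
  for (c0 in 2:(L - 3)) {                    # 0-based window centre
    w <- substr(seq, c0 - 1L, c0 + 3L)
    i <- match(w, keys)
    mgw[c0 + 1L] <- mgw_t[i]
    prot[c0 + 1L] <- prot_t[i]
    roll_acc[[c0]] <- c(roll_acc[[c0]], r1_t[i])          # step c0-1
    roll_acc[[c0 + 1L]] <- c(roll_acc[[c0 + 1L]], r2_t[i]) # step c0
    helt_acc[[c0]] <- c(helt_acc[[c0]], h1_t[i])
    helt_acc[[c0 + 1L]] <- c(helt_acc[[c0 + 1L]], h2_t[i])
  }
  list(
    mgw = mgw, prot = prot,
    roll = vapply(roll_acc, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    helt = vapply(helt_acc, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  )
}

shape_values <- function(profiles, id, feature) {
  profiles$value[profiles$seq_id == id & profiles$feature == feature]
}

enumerate_kmers <- function(W) {
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), W),
                              stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(W)), drop = FALSE], 1L, paste, collapse = "")
}

# exact p-values by enumerating all 4^W W-mers on the discretization grid
brute_force_pvalues <- function(model, bins_per_bit = 1000) {
  W <- model$width
  kmers <- enumerate_kmers(W)
  ipwm <- round(model$pwm * bins_per_bit)
  bg <- unname(model$background)
  code <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]],
                            c("A", "C", "G", "T"))
  score_k <- vapply(kmers, function(s) {
    sum(ipwm[cbind(code(s), seq_len(W))])
  }, numeric(1))
  prob <- vapply(kmers, function(s) prod(bg[code(s)]), numeric(1))
  function(k) vapply(k, function(kk) sum(prob[score_k >= kk]), numeric(1))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive agglomeration: returns the cophenetic distance matrix implied by
# merging the closest pair of clusters at each step
brute_cophenetic <- function(dm, method = "average") {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  cd <- matrix(0, n, n)
  link <- function(a, b) {
    v <- dm[clusters[[a]], clusters[[b]], drop = FALSE]
    switch(method, average = mean(v), single = min(v), complete = max(v))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        d <- link(a, b)
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    cd[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    cd[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  cd
}

# long shape table from a plain matrix (rows = sequences)
shape_tbl_from_matrix <- function(m, feature = "MGW") {
  ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  pos <- as.numeric(colnames(m) %||% (seq_len(ncol(m)) - 1L))
  out <- tibble::tibble(
    seq_id = rep(ids, each = ncol(m)),
    feature = factor(feature, levels = c("MGW", "ProT", "Roll", "HelT")),
    position = rep(pos, nrow(m)),
    value = as.vector(t(m))
  )
  class(out) <- c("shape_tbl", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
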