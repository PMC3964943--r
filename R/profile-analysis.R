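#' Shape profiles for an assembled TFBS dataset
#'
#' Predicts the four structural features for every sequence and restricts
#' the tracks to the core coordinate frame: base-pair features at positions
#' `0 .. core_length - 1`, step features at the midpoints between core
#' bases.  With 2-bp flanks every core cell is defined; without flanks the
#' first and last two base-pair positions (and the terminal steps) are
#' missing, which renders as white space at the heat-map margins.
#'
#' @param dataset A `tfbs_dataset`.
#' @param table A `pentamer_table`.
#' @param symmetrize_centre Optional centre position (core coordinates) for
#'   [symmetrize_profile()]; use the motif midpoint for palindromic cores.
#' @return A `shape_tbl` (long tibble: `seq_id`, `feature`, `position`,
#'   `value`) covering all sequences; rows in dataset order.
#' @export
dataset_profiles <- function(dataset, table, symmetrize_centre = NULL) {
  stopifnot(inherits(dataset, "tfbs_dataset"), nrow(dataset) > 0L)
  fw <- flank_width(dataset)
  cl <- core_length(dataset)
  prof <- predict_shape(
    tibble::tibble(seq_id = dataset$seq_id,
                   sequence = toupper(dataset$sequence)),
    table, origin = -fw)
  prof <- prof[prof$position >= 0 & prof$position <= cl - 1, , drop = FALSE]
  if (!is.null(symmetrize_centre)) {
    prof <- symmetrize_profile(prof, symmetrize_centre)
  }
  prof$seq_id <- factor(prof$seq_id, levels = dataset$seq_id)
  prof <- dplyr::arrange(prof, .data$seq_id, .data$feature, .data$position)
  prof$seq_id <- as.character(prof$seq_id)
  class(prof) <- unique(c("shape_tbl", class(prof)))
  prof
}

#' Extract one feature of a shape table as a sequence-by-position matrix
#'
#' @param profiles A `shape_tbl`.
#' @param feature One of `"MGW"`, `"ProT"`, `"Roll"`, `"HelT"`.
#' @return Numeric matrix, rows = sequences (in first-appearance order),
#'   columns = positions (ascending), `NA` for missing cells.
#' @export
profile_matrix <- function(profiles, feature = "MGW") {
  feature <- match.arg(feature, SHAPE_FEATURES)
  sub <- profiles[profiles$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("no rows for feature %s.", feature))
  ids <- unique(sub$seq_id)
  pos <- sort(unique(sub$position))
  m <- matrix(NA_real_, length(ids), length(pos),
              dimnames = list(ids, format(pos, trim = TRUE)))
  m[cbind(match(sub$seq_id, ids), match(sub$position, pos))] <- sub$value
  m
}

#' Average shape profile
#'
#' Column means over the non-missing cells of each feature track; a
#' position with no defined values stays missing.
#'
#' @param profiles A `shape_tbl`.
#' @return Tibble with columns `feature`, `position`, `mean`, `n` (number
#'   of sequences contributing).
#' @export
average_profile <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
  out <- dplyr::summarise(
    dplyr::group_by(profiles, .data$feature, .data$position),
    mean = if (all(is.na(.data$value))) NA_real_ else
      mean(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop")
  dplyr::arrange(out, .data$feature, .data$position)
}

# Pairwise-complete squared Euclidean distances between matrix rows,
# rescaled to the full row length: d_ij = sqrt(ncol * ss_ij / n_ij).
pairwise_complete_ed <- function(m) {
  M <- !is.na(m)
  X0 <- m
  X0[!M] <- 0
  A <- X0 * X0
  storage.mode(M) <- "double"
  n_shared <- M %*% t(M)
  d2 <- A %*% t(M) + M %*% t(A) - 2 * X0 %*% t(X0)
  d2[d2 < 0] <- 0
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    abort("some row pairs share no defined positions; cannot compute distances.")
  }
  sqrt(ncol(m) * d2 / n_shared)
}

#' Cluster heat-map rows by Euclidean distance
#'
#' Agglomerative hierarchical clustering of per-sequence profiles, with
#' distance defined as the Euclidean distance between rows
#' (pairwise-complete over defined cells, rescaled by
#' `sqrt(n_total / n_complete)`).  Mirrors the behaviour of interactive
#' heat maps: when the number of rows exceeds `max_rows` no clustering is
#' attempted and the input order is returned with a notice.
#'
#' @param profiles A `shape_tbl` or a numeric matrix (rows = sequences).
#' @param feature Feature to cluster on when `profiles` is a `shape_tbl`.
#' @param max_rows Row cap for clustering (default 3000).
#' @param linkage Agglomeration rule: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @return List of class `row_clustering`: `row_order` (sequence ids in
#'   leaf order), `tree` (an `hclust`, or `NULL` when not clustered),
#'   `clustered` (logical), `linkage`.  Rows with no defined cells are
#'   excluded with a warning and appended after the clustered rows.
#' @export
cluster_rows <- function(profiles, feature = "MGW", max_rows = 3000L,
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles, feature)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (nrow(m) > max_rows) {
    inform(sprintf("%d rows exceed the clustering cap of %d; returning input order.",
                   nrow(m), max_rows))
    return(structure(list(row_order = rownames(m), tree = NULL,
                          clustered = FALSE, linkage = linkage),
                     class = "row_clustering"))
  }
  all_na <- rowSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warn(sprintf("excluding %d all-missing row(s) from clustering.", sum(all_na)))
  }
  mm <- m[!all_na, , drop = FALSE]
  if (nrow(mm) < 2L) {
    return(structure(list(row_order = rownames(m), tree = NULL,
                          clustered = FALSE, linkage = linkage),
                     class = "row_clustering"))
  }
  d <- as.dist(pairwise_complete_ed(mm))
  tree <- hclust(d, method = linkage)
  structure(list(row_order = c(rownames(mm)[tree$order], rownames(m)[all_na]),
                 tree = tree, clustered = TRUE, linkage = linkage),
            class = "row_clustering")
}

#' @export
print.row_clustering <- function(x, ...) {
  cat(sprintf("<row_clustering> %d rows, %s linkage, clustered: %s\n",
              length(x$row_order), x$linkage, x$clustered))
  invisible(x)
}

#' Compare two average shape profiles
#'
#' Aligns the second profile onto the first by an integer position offset
#' and computes, per feature over the overlapping defined positions,
#' Pearson's correlation coefficient (PCC) and the Euclidean distance (ED)
#' — the quantitative measures for comparing two binding-site shape
#' profiles.
#'
#' @param avg1,avg2 Average profiles from [average_profile()].
#' @param offset Integer shift applied to the positions of `avg2` so they
#'   land in the coordinates of `avg1` (alignment of the two motifs).
#' @return Tibble of class `shape_comparison` with columns `feature`,
#'   `pcc`, `ed`, `n_positions`; the offset is stored as an attribute.
#'   Errors when fewer than 2 positions overlap.
#' @export
compare_profiles <- function(avg1, avg2, offset = 0L) {
  stopifnot(is.data.frame(avg1), is.data.frame(avg2))
  if (offset != round(offset)) abort("`offset` must be an integer.")
  a2 <- avg2
  a2$position <- a2$position + offset
  j <- dplyr::inner_join(
    avg1[c("feature", "position", "mean")],
    a2[c("feature", "position", "mean")],
    by = c("feature", "position"), suffix = c("_1", "_2"))
  j <- j[!is.na(j$mean_1) & !is.na(j$mean_2), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$feature),
    pcc = if (dplyr::n() >= 2L) cor(.data$mean_1, .data$mean_2) else NA_real_,
    ed = sqrt(sum((.data$mean_1 - .data$mean_2)^2)),
    n_positions = dplyr::n(),
    .groups = "drop")
  if (nrow(out) == 0L || any(out$n_positions < 2L)) {
    abort("fewer than 2 overlapping defined positions at this offset; adjust the alignment.")
  }
  attr(out, "offset") <- as.integer(offset)
  class(out) <- c("shape_comparison", class(out))
  out
}

#' Per-position Kolmogorov-Smirnov differential shape test
#'
#' For each position shared by the two profile sets, compares the
#' distributions of per-sequence values between the two datasets with a
#' two-sample two-sided K-S test (asymptotic p-values; exact when the
#' combined sample size is at most 25).  Positions are categorised as
#' `strong` (p below the first threshold), `weak` (below the second) or
#' `none`; positions where either group has fewer than `min_n` defined
#' values are reported as untested (`tested = FALSE`).
#'
#' @param profiles1,profiles2 `shape_tbl`s sharing column coordinates.
#' @param features Features to test (default all four).
#' @param thresholds Two descending p-value thresholds,
#'   default `c(strong = 0.001, weak = 0.05)`.
#' @param min_n Minimum per-group sample size for testing (default 8).
#' @return Tibble of class `shape_differential`: `feature`, `position`,
#'   `n1`, `n2`, `statistic` (K-S D), `p_value`, `tested`, `category`.
#' @export
ks_differential <- function(profiles1, profiles2, features = SHAPE_FEATURES,
                            thresholds = c(strong = 0.001, weak = 0.05),
                            min_n = 8L) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  cols1 <- unique(profiles1[c("feature", "position")])
  cols2 <- unique(profiles2[c("feature", "position")])
  shared <- dplyr::inner_join(cols1, cols2, by = c("feature", "position"))
  shared <- shared[shared$feature %in% features, , drop = FALSE]
  if (nrow(shared) == 0L) abort("the two profile sets share no columns.")
  res <- purrr::pmap(list(as.character(shared$feature), shared$position),
                     function(f, p) {
    x <- profiles1$value[profiles1$feature == f & profiles1$position == p]
    y <- profiles2$value[profiles2$feature == f & profiles2$position == p]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < min_n || length(y) < min_n) {
      return(tibble::tibble(feature = f, position = p,
                            n1 = length(x), n2 = length(y),
                            statistic = NA_real_, p_value = NA_real_,
                            tested = FALSE, category = NA_character_))
    }
    kt <- suppressWarnings(
      ks.test(x, y, exact = (length(x) + length(y)) <= 25L))
    tibble::tibble(feature = f, position = p,
                   n1 = length(x), n2 = length(y),
                   statistic = unname(kt$statistic),
                   p_value = kt$p.value, tested = TRUE,
                   category = if (kt$p.value < thresholds[1]) "strong"
                              else if (kt$p.value < thresholds[2]) "weak"
                              else "none")
  })
  out <- dplyr::bind_rows(res)
  out$feature <- factor(out$feature, levels = SHAPE_FEATURES)
  out$category <- factor(out$category, levels = c("none", "weak", "strong"))
  out <- dplyr::arrange(out, .data$feature, .data$position)
  class(out) <- c("shape_differential", class(out))
  out
}

#' Dendrogram of factors from average shape profiles
#'
#' Computes pairwise Euclidean distances between the average profiles
#' (typically MGW) of a set of transcription factors and builds an
#' agglomerative tree, e.g. to separate factor subfamilies with distinct
#' minor-groove preferences.
#'
#' @param avg_profiles A tibble with columns `tf`, `position`, `value`
#'   (one feature, pre-aligned: every factor must cover the same
#'   positions), or a named list of equal-length numeric vectors.
#' @param linkage Agglomeration rule (default `"average"`).
#' @return List of class `shape_dendrogram`: `tree` (`hclust`), `newick`
#'   (string; leaf-to-ancestor depths equal merge heights), `distances`
#'   (the `dist`).  Ties are broken deterministically by factor label.
#' @export
shape_dendrogram <- function(avg_profiles,
                             linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.list(avg_profiles) && !is.data.frame(avg_profiles)) {
    if (length(unique(lengths(avg_profiles))) != 1L) {
      abort("profiles must all have the same length (pre-aligned).")
    }
    m <- do.call(rbind, avg_profiles)
    rownames(m) <- names(avg_profiles)
  } else {
    stopifnot(all(c("tf", "position", "value") %in% names(avg_profiles)))
    w <- tidyr::pivot_wider(avg_profiles[c("tf", "position", "value")],
                            names_from = "position", values_from = "value")
    m <- as.matrix(w[-1])
    rownames(m) <- w$tf
    if (anyNA(m)) abort("profiles are not aligned on common positions (missing cells after widening).")
  }
  if (nrow(m) < 2L) abort("need at least 2 factors to build a dendrogram.")
  m <- m[order(rownames(m)), , drop = FALSE]  # label order fixes ties
  d <- stats::dist(m)
  tree <- hclust(d, method = linkage)
  structure(list(tree = tree, newick = hclust_to_newick(tree),
                 distances = d, linkage = linkage),
            class = "shape_dendrogram")
}

# Newick serialization in which the depth of every internal node (distance
# down to its leaves) equals its merge height in the hclust tree.
hclust_to_newick <- function(tree) {
  labs <- tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1L))
  node_str <- character(nrow(tree$merge))
  node_h <- tree$height
  part <- function(i) {
    if (i < 0) {
      list(str = labs[-i], h = 0)
    } else {
      list(str = node_str[i], h = node_h[i])
    }
  }
  for (k in seq_len(nrow(tree$merge))) {
    a <- part(tree$merge[k, 1]); b <- part(tree$merge[k, 2])
    node_str[k] <- sprintf("(%s:%.12g,%s:%.12g)",
                           a$str, node_h[k] - a$h,
                           b$str, node_h[k] - b$h)
  }
  paste0(node_str[nrow(tree$merge)], ";")
}

#' @export
print.shape_dendrogram <- function(x, ...) {
  cat(sprintf("<shape_dendrogram> %d factors, %s linkage\n",
              length(x$tree$labels), x$linkage))
  cat(x$newick, "\n")
  invisible(x)
}
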