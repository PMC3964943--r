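#' Write and read heat-map profile matrices as TSV
#'
#' Wide layout: one row per sequence (`seq_id` column), one column per
#' position, `NA` for missing cells.  The round trip is bit-exact (values
#' serialized at full precision).
#'
#' @param profiles A `shape_tbl`.
#' @param feature Feature to write.
#' @param path Output path.
#' @return `path` (writer) or a `shape_tbl` restricted to one feature
#'   (reader).
#' @export
write_profile_matrix <- function(profiles, feature, path) {
  m <- profile_matrix(profiles, feature)
  tbl <- tibble::as_tibble(m, rownames = "seq_id")
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path, feature) {
  feature <- match.arg(feature, SHAPE_FEATURES)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    seq_id = readr::col_character(), .default = readr::col_double()))
  long <- tidyr::pivot_longer(tbl, -"seq_id", names_to = "position",
                              values_to = "value")
  out <- tibble::tibble(
    seq_id = long$seq_id,
    feature = factor(feature, levels = SHAPE_FEATURES),
    position = as.numeric(long$position),
    value = long$value
  )
  class(out) <- c("shape_tbl", class(out))
  out
}

#' Write shape profiles in long format
#'
#' TSV with columns `seq_id`, `feature`, `position`, `value`.
#'
#' @param profiles A `shape_tbl`.
#' @param path Output path.
#' @export
write_shape_long <- function(profiles, path) {
  readr::write_tsv(tibble::as_tibble(profiles), path, na = "NA")
  invisible(path)
}

#' Write a profile comparison as JSON
#'
#' `{feature: {pcc, ed, n}}` plus the alignment offset.
#'
#' @param comparison A `shape_comparison` from [compare_profiles()].
#' @param path Output path.
#' @export
write_comparison_json <- function(comparison, path) {
  obj <- setNames(
    lapply(seq_len(nrow(comparison)), function(i) {
      list(pcc = comparison$pcc[i], ed = comparison$ed[i],
           n = comparison$n_positions[i])
    }),
    as.character(comparison$feature))
  obj$alignment_offset <- attr(comparison, "offset")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths are chosen so that the depth of each internal node above
#' its leaves equals its merge height.
#'
#' @param dendrogram A `shape_dendrogram`.
#' @param path Output path.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "shape_dendrogram"))
  writeLines(dendrogram$newick, path)
  invisible(path)
}

#' Write a regression report as JSON
#'
#' Per-variant per-fold held-out R^2, selected penalties, seeds and
#' dropped-site counts.
#'
#' @param report A `regression_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "regression_report"))
  obj <- list(
    variants = lapply(report$variants, function(v) {
      list(r2 = v$r2, r2_mean = v$r2_mean,
           r2_pearson = v$r2_pearson,
           lambda = v$lambda, folds = v$folds, seed = v$seed,
           n = v$n, p = v$p)
    }),
    improvement_pct = report$improvement$improvement_pct,
    n_dropped_missing_shape = report$n_dropped_missing_shape,
    log_intensity = report$log_intensity,
    seed = report$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Colour-scale metadata for shape heat maps
#'
#' The display convention: red for narrow minor groove, blue for wide,
#' white for intermediate values; missing cells render as white margins.
#' Emitted as metadata so any renderer can honour it.
#'
#' @param feature Feature name.
#' @return Named list describing the diverging scale.
#' @export
heatmap_colour_scale <- function(feature = "MGW") {
  feature <- match.arg(feature, SHAPE_FEATURES)
  list(feature = feature, low = "red", mid = "white", high = "blue",
       missing = "white",
       note = "low values red, high values blue, midpoint white; NA cells blank")
}
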