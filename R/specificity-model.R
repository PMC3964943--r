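FEATURE_BLOCKS <- c("seq_mononucleotide", "core_variant",
                    paste0("shape_", SHAPE_FEATURES))

#' Encode sequence and shape features of a TFBS dataset
#'
#' Builds the standardized design matrix for binding-specificity
#' regression.  Blocks:
#' \describe{
#'   \item{seq_mononucleotide}{4 indicator columns per position (flanks and
#'     core); with ridge regularization no reference level is dropped.}
#'   \item{core_variant}{one indicator per observed core sequence variant,
#'     with the most frequent variant as reference — captures
#'     interdependencies within the core motif beyond mononucleotides.}
#'   \item{shape_MGW / shape_ProT / shape_Roll / shape_HelT}{raw
#'     per-position (bp features) or per-step (step features) shape
#'     values.}
#' }
#' All columns are standardized to zero mean and unit variance; constant
#' columns are dropped (recorded).  Sites with missing shape values in a
#' requested block are excluded and counted.
#'
#' @param dataset A `tfbs_dataset`.
#' @param profiles A `shape_tbl` for the dataset (see
#'   [dataset_profiles()]); may be `NULL` when no shape block is requested.
#' @param intensities Data frame with `seq_id`, `intensity`, or a numeric
#'   vector named by `seq_id` (or aligned with the dataset).
#' @param blocks Feature blocks to include; see above.
#' @param log_intensity Model `log(intensity)` (default `TRUE`, the usual
#'   transform for fluorescence signals).
#' @return A `feature_encoding`: list with the design matrix `X`, response
#'   `y`, `blocks` (named character vector mapping columns to blocks),
#'   `site_ids`, `n_dropped_missing_shape`, `dropped_constant`,
#'   standardization parameters `center`/`scale`.
#' @export
encode_features <- function(dataset, profiles = NULL, intensities,
                            blocks = FEATURE_BLOCKS, log_intensity = TRUE) {
  stopifnot(inherits(dataset, "tfbs_dataset"))
  blocks <- match.arg(blocks, FEATURE_BLOCKS, several.ok = TRUE)
  if (is.data.frame(intensities)) {
    if (!all(c("seq_id", "intensity") %in% names(intensities))) {
      abort("`intensities` must have columns `seq_id` and `intensity`.")
    }
    y <- intensities$intensity[match(dataset$seq_id, intensities$seq_id)]
  } else if (!is.null(names(intensities))) {
    y <- unname(intensities[dataset$seq_id])
  } else {
    if (length(intensities) != nrow(dataset)) {
      abort("unnamed `intensities` must align with the dataset rows.")
    }
    y <- intensities
  }
  if (anyNA(y)) abort("missing intensity for some dataset sequences (mismatched ids).")
  if (log_intensity) {
    if (any(y <= 0)) abort("intensities must be positive for the log transform.")
    y <- log(y)
  }

  seqs <- toupper(dataset$sequence)
  n <- length(seqs)
  fw <- flank_width(dataset)
  cl <- core_length(dataset)
  L <- cl + 2L * fw
  cols <- list()
  tags <- character(0)

  if ("seq_mononucleotide" %in% blocks) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
                    byrow = TRUE)
    for (j in seq_len(L)) {
      pos <- j - 1L - fw
      for (b in DNA_BASES) {
        cols[[sprintf("seq_p%d_%s", pos, b)]] <- as.numeric(chars[, j] == b)
        tags <- c(tags, "seq_mononucleotide")
      }
    }
  }
  if ("core_variant" %in% blocks) {
    core <- substr(seqs, fw + 1L, fw + cl)
    freq <- sort(table(core), decreasing = TRUE)
    ref <- names(freq)[1]
    for (v in setdiff(names(freq), ref)) {
      cols[[sprintf("core_%s", v)]] <- as.numeric(core == v)
      tags <- c(tags, "core_variant")
    }
  }

  shape_blocks <- intersect(blocks, paste0("shape_", SHAPE_FEATURES))
  keep <- rep(TRUE, n)
  if (length(shape_blocks) > 0L) {
    if (is.null(profiles)) abort("shape blocks requested but `profiles` is NULL.")
    for (bl in shape_blocks) {
      feat <- sub("^shape_", "", bl)
      m <- profile_matrix(profiles, feat)
      m <- m[match(dataset$seq_id, rownames(m)), , drop = FALSE]
      defined <- colSums(is.na(m)) < nrow(m)
      m <- m[, defined, drop = FALSE]
      keep <- keep & rowSums(is.na(m)) == 0L
      for (j in seq_len(ncol(m))) {
        cols[[sprintf("%s_p%s", bl, colnames(m)[j])]] <- m[, j]
        tags <- c(tags, bl)
      }
    }
  }
  X <- do.call(cbind, cols)
  names(tags) <- colnames(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  constant <- scl == 0 | !is.finite(scl)
  dropped_constant <- colnames(X)[constant]
  X <- X[, !constant, drop = FALSE]
  tags <- tags[!constant]
  X <- scale(X, center = ctr[!constant], scale = scl[!constant])
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(list(X = X, y = y, blocks = tags,
                 site_ids = dataset$seq_id[keep],
                 n_dropped_missing_shape = n_dropped,
                 dropped_constant = dropped_constant,
                 log_intensity = log_intensity,
                 center = ctr[!constant], scale = scl[!constant]),
            class = "feature_encoding")
}

#' @export
print.feature_encoding <- function(x, ...) {
  cat(sprintf("<feature_encoding> %d sites x %d features\n",
              nrow(x$X), ncol(x$X)))
  print(table(x$blocks))
  invisible(x)
}

#' Restrict an encoding to a subset of blocks
#'
#' @param enc A `feature_encoding`.
#' @param blocks Blocks to keep.
#' @return A `feature_encoding` with the matching columns.
#' @export
subset_blocks <- function(enc, blocks) {
  stopifnot(inherits(enc, "feature_encoding"))
  keep <- enc$blocks %in% blocks
  if (!any(keep)) abort("no columns match the requested blocks.")
  out <- enc
  out$X <- enc$X[, keep, drop = FALSE]
  out$blocks <- enc$blocks[keep]
  out$center <- enc$center[keep]
  out$scale <- enc$scale[keep]
  out
}

#' Permute shape columns across sites
#'
#' Independently permutes each shape-block column of the design matrix
#' across sites, destroying any true sequence-shape-intensity linkage while
#' preserving each column's marginal distribution; sequence columns are
#' untouched.  This is the negative control for shape-augmented models.
#'
#' @param enc A `feature_encoding` containing at least one shape block.
#' @param seed Integer seed for the permutations.
#' @return A `feature_encoding` with shuffled shape columns.
#' @export
shuffle_shape_columns <- function(enc, seed = 1L) {
  stopifnot(inherits(enc, "feature_encoding"))
  shape_cols <- which(enc$blocks %in% paste0("shape_", SHAPE_FEATURES))
  if (length(shape_cols) == 0L) abort("encoding contains no shape block.")
  out <- enc
  n <- nrow(enc$X)
  set.seed(seed)
  for (j in shape_cols) {
    out$X[, j] <- enc$X[sample.int(n), j]
  }
  out$shuffle_seed <- seed
  out
}

ridge_cv_folds <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' L2-regularized regression with nested cross-validation
#'
#' Fits ridge regression (glmnet, `alpha = 0`) of the response on the
#' encoded features.  Outer `folds`-fold cross-validation (fold assignment
#' seeded and reproducible) measures held-out accuracy; on each training
#' split the penalty is chosen by inner 5-fold cross-validation over
#' `penalty_grid`.  Reported `r2` is the held-out coefficient of
#' determination per fold (squared Pearson correlation is reported
#' alongside).
#'
#' @param enc A `feature_encoding`.
#' @param folds Outer fold count (default 10).
#' @param penalty_grid Ridge penalties to search (default
#'   `10^seq(-3, 3, length.out = 13)`).
#' @param seed Seed controlling fold assignment (outer and inner).
#' @param variant Label stored in the result.
#' @return A `ridge_cv` list: `variant`, `r2` (per fold), `r2_mean`,
#'   `r2_pearson` (per fold), `r2_pearson_mean`, `lambda` (selected per
#'   fold), `folds`, `seed`, `n`, `p`.
#' @export
fit_ridge_cv <- function(enc, folds = 10L,
                         penalty_grid = 10^seq(-3, 3, length.out = 13),
                         seed = 1L, variant = "model") {
  stopifnot(inherits(enc, "feature_encoding"))
  n <- nrow(enc$X)
  if (n < 5L * folds) {
    abort(sprintf("need at least %d sites for %d-fold cross-validation (have %d).",
                  5L * folds, folds, n))
  }
  fold_id <- ridge_cv_folds(n, folds, seed)
  lambda <- sort(penalty_grid, decreasing = TRUE)
  r2 <- r2p <- lam <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- enc$X[tr, , drop = FALSE]
    ytr <- enc$y[tr]
    set.seed(seed * 1000L + f)
    inner_id <- sample(rep_len(seq_len(5L), sum(tr)))
    cvfit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, lambda = lambda,
                               foldid = inner_id, standardize = FALSE)
    lam[f] <- cvfit$lambda.min
    pred <- as.numeric(predict(cvfit, newx = enc$X[!tr, , drop = FALSE],
                               s = "lambda.min"))
    yte <- enc$y[!tr]
    r2[f] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    r2p[f] <- if (sd(pred) > 0) cor(pred, yte)^2 else 0
  }
  structure(list(variant = variant, r2 = r2, r2_mean = mean(r2),
                 r2_pearson = r2p, r2_pearson_mean = mean(r2p),
                 lambda = lam, folds = folds, seed = seed,
                 n = n, p = ncol(enc$X)),
            class = "ridge_cv")
}

#' @export
print.ridge_cv <- function(x, ...) {
  cat(sprintf("<ridge_cv> %s: mean held-out R^2 = %.3f over %d folds (n = %d, p = %d)\n",
              x$variant, x$r2_mean, x$folds, x$n, x$p))
  invisible(x)
}

#' Shuffled-shape control model
#'
#' Permutes each shape column independently across sites
#' ([shuffle_shape_columns()]) and refits the ridge model.  If the shape
#' features carry real signal beyond sequence, the shuffled model should
#' fall back to sequence-only accuracy.
#'
#' @inheritParams fit_ridge_cv
#' @param shuffle_seed Seed for the column permutations (default `seed`).
#' @return A `ridge_cv` entry labelled `sequence_plus_shuffled_shape`.
#' @export
shuffled_shape_control <- function(enc, folds = 10L,
                                   penalty_grid = 10^seq(-3, 3, length.out = 13),
                                   seed = 1L, shuffle_seed = seed) {
  enc_sh <- shuffle_shape_columns(enc, seed = shuffle_seed)
  fit_ridge_cv(enc_sh, folds = folds, penalty_grid = penalty_grid,
               seed = seed, variant = "sequence_plus_shuffled_shape")
}

#' Fit the three binding-specificity model variants
#'
#' Convenience wrapper fitting `sequence_only` (mononucleotide +
#' core-variant blocks), `sequence_plus_shape` (adding all four shape
#' blocks) and `sequence_plus_shuffled_shape` (the permutation control)
#' under identical fold assignments.
#'
#' @param dataset A `tfbs_dataset`.
#' @param profiles A `shape_tbl` for the dataset.
#' @param intensities Per-site intensities (see [encode_features()]).
#' @inheritParams fit_ridge_cv
#' @param log_intensity Passed to [encode_features()].
#' @return A `regression_report`: list of the three `ridge_cv` entries plus
#'   the improvement summary from [compare_models()].
#' @export
fit_specificity_models <- function(dataset, profiles, intensities,
                                   folds = 10L,
                                   penalty_grid = 10^seq(-3, 3, length.out = 13),
                                   seed = 1L, log_intensity = TRUE) {
  enc <- encode_features(dataset, profiles, intensities,
                         log_intensity = log_intensity)
  seq_blocks <- c("seq_mononucleotide", "core_variant")
  enc_seq <- subset_blocks(enc, seq_blocks)
  fits <- list(
    sequence_only = fit_ridge_cv(enc_seq, folds, penalty_grid, seed,
                                 variant = "sequence_only"),
    sequence_plus_shape = fit_ridge_cv(enc, folds, penalty_grid, seed,
                                       variant = "sequence_plus_shape"),
    sequence_plus_shuffled_shape =
      shuffled_shape_control(enc, folds, penalty_grid, seed)
  )
  report <- structure(list(variants = fits,
                           n_dropped_missing_shape = enc$n_dropped_missing_shape,
                           log_intensity = log_intensity, seed = seed),
                      class = "regression_report")
  report$improvement <- compare_models(report)
  report
}

#' Improvement of the shape-augmented model over sequence alone
#'
#' Percentage improvement `100 * (R2_shape - R2_seq) / R2_seq` of the
#' cross-validated mean, with per-fold paired differences.
#'
#' @param report A `regression_report` (or a bare list of `ridge_cv`
#'   entries) containing `sequence_only` and `sequence_plus_shape`.
#' @return Tibble with `r2_sequence`, `r2_shape`, `improvement_pct`, and a
#'   list-column `fold_differences`.
#' @export
compare_models <- function(report) {
  fits <- if (inherits(report, "regression_report")) report$variants else report
  if (!all(c("sequence_only", "sequence_plus_shape") %in% names(fits))) {
    abort("need both `sequence_only` and `sequence_plus_shape` variants.")
  }
  s <- fits$sequence_only
  h <- fits$sequence_plus_shape
  tibble::tibble(
    r2_sequence = s$r2_mean,
    r2_shape = h$r2_mean,
    improvement_pct = 100 * (h$r2_mean - s$r2_mean) / s$r2_mean,
    fold_differences = list(h$r2 - s$r2)
  )
}

#' @export
print.regression_report <- function(x, ...) {
  for (v in x$variants) {
    cat(sprintf("  %-30s mean R^2 = %.3f\n", v$variant, v$r2_mean))
  }
  cat(sprintf("  shape improvement over sequence: %.1f%%\n",
              x$improvement$improvement_pct))
  invisible(x)
}

#' Tidy a cross-validated regression report
#'
#' @param x A `regression_report`.
#' @param ... Unused.
#' @return One row per (variant, fold): `variant`, `fold`, `r2`,
#'   `r2_pearson`, `lambda`.
#' @export
tidy.regression_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$variants, function(v) {
    tibble::tibble(variant = v$variant, fold = seq_len(v$folds),
                   r2 = v$r2, r2_pearson = v$r2_pearson, lambda = v$lambda)
  }))
}

#' Summarise a regression report in one row
#'
#' @param x A `regression_report`.
#' @param ... Unused.
#' @return Tibble with one row: mean R^2 per variant and the percentage
#'   improvement of the shape model over sequence alone.
#' @export
glance.regression_report <- function(x, ...) {
  tibble::tibble(
    r2_sequence = x$variants$sequence_only$r2_mean,
    r2_shape = x$variants$sequence_plus_shape$r2_mean,
    r2_shuffled = x$variants$sequence_plus_shuffled_shape$r2_mean,
    improvement_pct = x$improvement$improvement_pct,
    folds = x$variants$sequence_only$folds,
    n = x$variants$sequence_only$n,
    seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
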