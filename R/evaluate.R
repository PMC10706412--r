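#' The 13-class oil adulteration scheme
#'
#' Pure quince seed oil (`PQ`), five sunflower admixtures, pure
#' sunflower (`PSu`), five sesame admixtures and pure sesame (`PSe`).
#' The number in a mixture label is the volume percentage of each oil,
#' e.g. `Su10:Q90` is 10% sunflower in 90% quince seed oil.
#'
#' @return Character vector of the 13 class labels in canonical order.
#' @export
oil_classes <- function() {
  c("PQ",
    paste0("Su", seq(10, 50, 10), ":Q", seq(90, 50, -10)), "PSu",
    paste0("Se", seq(10, 50, 10), ":Q", seq(90, 50, -10)), "PSe")
}

#' Class label for an adulterant/fraction pair
#'
#' @param adulterant `"none"`, `"sunflower"` or `"sesame"`.
#' @param fraction volume fraction of the adulterant in `[0, 1]`
#'   (0, 0.1, ..., 0.5 or 1 for the canonical scheme).
#' @return A class label string such as `"Se20:Q80"`.
#' @export
oil_class_label <- function(adulterant = c("none", "sunflower", "sesame"),
                            fraction = 0) {
  adulterant <- match.arg(adulterant)
  if (fraction < 0 || fraction > 1) stopf("`fraction` must be in [0, 1]")
  if (fraction == 0 || adulterant == "none") return("PQ")
  tag <- if (adulterant == "sunflower") "Su" else "Se"
  if (fraction == 1) return(paste0("P", tag))
  sprintf("%s%d:Q%d", tag, round(100 * fraction), round(100 * (1 - fraction)))
}

#' Build a confusion matrix
#'
#' @param truth,pred true and predicted class labels.
#' @param class_order row/column order (default: the 13-class scheme
#'   when all labels belong to it, otherwise the sorted union).
#' @return An object of class `confusion_matrix`: an integer matrix with
#'   rows = true classes, columns = predicted classes.
#' @export
confusion_matrix <- function(truth, pred, class_order = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(class_order)) {
    class_order <- if (all(c(truth, pred) %in% oil_classes()))
      oil_classes() else sort(unique(c(truth, pred)))
  }
  m <- table(factor(truth, levels = class_order),
             factor(pred, levels = class_order))
  structure(unclass(as.matrix(m)), class = "confusion_matrix",
            dimnames = list(true = class_order, predicted = class_order))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  s <- confusion_stats(x)
  cat(sprintf("<confusion_matrix> %d sample(s), %d misclassified (%.2f%% error)\n",
              sum(x), s$misclassified, s$error_pct))
  print(unclass(x))
  invisible(x)
}

#' Summary statistics of a confusion matrix
#'
#' @param cm a [confusion_matrix()] (rows = true, columns = predicted).
#' @return A list with `total`, `misclassified` (off-diagonal sum),
#'   `error_pct` and `per_class_accuracy` (diagonal over row sums; `NA`
#'   for classes with no evaluated sample).
#' @export
confusion_stats <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0 || sum(cm) == 0) stopf("empty confusion matrix")
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  total <- sum(cm)
  mis <- total - sum(diag(cm))
  rs <- rowSums(cm)
  acc <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(acc) <- rownames(cm)
  list(total = total, misclassified = mis, error_pct = 100 * mis / total,
       per_class_accuracy = acc)
}

#' Parse a printed confusion-matrix table
#'
#' Reads a whitespace- or comma-delimited square table with row labels
#' (and an optional header line). Row labels define the class order; a
#' header is used only to validate the column count, so a misprinted
#' header label does not corrupt the matrix.
#'
#' @param text character scalar or vector of lines, or a file path.
#' @return A [confusion_matrix()].
#' @export
parse_confusion_table <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stopf("empty table")
  tok <- lapply(lines, function(l) {
    t <- strsplit(l, "[,\t ]+")[[1]]
    t[nzchar(t)]
  })
  numeric_re <- "^-?[0-9]+\\.?[0-9]*$"
  header <- NULL
  if (all(!grepl(numeric_re, tok[[1]][-1]))) {
    header <- tok[[1]]
    tok <- tok[-1]
  }
  if (!length(tok)) stopf("table has no data rows")
  labels <- vapply(tok, `[[`, "", 1)
  rows <- lapply(tok, function(t) suppressWarnings(as.numeric(t[-1])))
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stopf("ragged rows in confusion table")
  if (any(vapply(rows, anyNA, logical(1)))) stopf("non-numeric cell in table")
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m))
    stopf("confusion table is not square: %d rows, %d columns",
          nrow(m), ncol(m))
  if (!is.null(header) && !length(header) %in% c(ncol(m), ncol(m) + 1L))
    stopf("header width does not match the table")
  storage.mode(m) <- "integer"
  structure(m, class = "confusion_matrix",
            dimnames = list(true = labels, predicted = labels))
}

#' Write a confusion matrix as CSV
#'
#' Rows and columns follow the matrix's class order (the 13-class scheme
#' for adulteration runs).
#'
#' @param cm a [confusion_matrix()].
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(true = rownames(cm), as.data.frame.matrix(unclass(cm)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repeated stratified hold-out evaluation
#'
#' The outer validation loop: `n_repeats` stratified random splits into
#' calibration and prediction subsets (calibration size =
#' `round(train_frac * n)`, half-up). For each split, PCA and predictor
#' standardization are fitted on the calibration part only, the SVM is
#' trained there, and the held-out prediction part is scored. The
#' reported error is the mean over splits.
#'
#' @param x raw feature matrix `n x 18` (PCA is refitted per split).
#' @param y class labels.
#' @param config a [hyperparam_config()] (e.g. from [random_search()]).
#' @param n_components number of principal components fed to the
#'   classifier; `NULL` selects per split by `var_threshold`.
#' @param n_repeats number of random splits (default 10).
#' @param train_frac calibration fraction (default 0.7).
#' @param seed RNG seed (default 0).
#' @param var_threshold cumulative-variance cutoff used when
#'   `n_components` is `NULL` (default 0.95).
#' @return An object of class `csa_evaluation`: list with `mean_error_pct`,
#'   `per_split_error_pct`, `confusion` (per-split [confusion_matrix()]
#'   list), `pooled_confusion`, and the split sizes.
#' @export
repeated_split_evaluate <- function(x, y, config, n_components = NULL,
                                    n_repeats = 10, train_frac = 0.7,
                                    seed = 0, var_threshold = 0.95) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  n_cal <- as.integer(round_half_up(train_frac * n))
  if (n_cal < nlevels(y) || n_cal >= n)
    stopf("infeasible split: %d calibration of %d samples", n_cal, n)
  split_seeds <- derive_seeds(seed, n_repeats)
  errs <- numeric(n_repeats)
  cms <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cal <- stratified_split(y, n_cal, split_seeds[r])
    pca <- fit_pca(x[cal, , drop = FALSE])
    k <- if (is.null(n_components)) select_n_components(pca, var_threshold)
         else n_components
    s_cal <- predict(pca, x[cal, , drop = FALSE], n_components = k)
    s_val <- predict(pca, x[-cal, , drop = FALSE], n_components = k)
    m <- train_svm(s_cal, y[cal], config)
    pred <- predict(m, s_val)
    cms[[r]] <- confusion_matrix(y[-cal], pred, class_order = levels(y))
    errs[r] <- confusion_stats(cms[[r]])$error_pct
  }
  pooled <- Reduce(`+`, lapply(cms, unclass))
  structure(list(
    mean_error_pct = mean(errs),
    per_split_error_pct = errs,
    confusion = cms,
    pooled_confusion = structure(pooled, class = "confusion_matrix",
                                 dimnames = dimnames(cms[[1]])),
    n_calibration = n_cal, n_prediction = n - n_cal,
    n_repeats = n_repeats, seed = seed
  ), class = "csa_evaluation")
}

#' @export
print.csa_evaluation <- function(x, ...) {
  cat(sprintf(
    "<csa_evaluation> %d split(s) of %d/%d samples; mean error %.2f%%\n",
    x$n_repeats, x$n_calibration, x$n_prediction, x$mean_error_pct))
  cat("per-split error (%):", paste(sprintf("%.1f", x$per_split_error_pct),
                                    collapse = " "), "\n")
  invisible(x)
}

# Stratified sample of exactly n_cal calibration indices: proportional
# per-class allocation (floor + largest fractional remainder), keeping
# every class represented in the calibration part, then a seeded draw
# within each class. Retries are unnecessary because the allocation is
# feasible by construction.
stratified_split <- function(y, n_cal, seed) {
  counts <- table(y)
  frac <- n_cal / length(y)
  base <- pmin(pmax(floor(counts * frac), 1), counts)
  remainder <- n_cal - sum(base)
  # distribute one sample at a time in (largest|smallest)-remainder
  # order, cycling while capacity remains
  while (remainder != 0) {
    if (remainder > 0) {
      pref <- order(counts * frac - floor(counts * frac), decreasing = TRUE)
      movable <- pref[base[pref] < counts[pref]]
      if (!length(movable)) stopf("infeasible stratified split")
      take <- movable[seq_len(min(length(movable), remainder))]
      base[take] <- base[take] + 1
      remainder <- remainder - length(take)
    } else {
      pref <- order(counts * frac - floor(counts * frac))
      movable <- pref[base[pref] > 1]
      if (!length(movable)) stopf("infeasible stratified split")
      take <- movable[seq_len(min(length(movable), -remainder))]
      base[take] <- base[take] - 1
      remainder <- remainder + length(take)
    }
  }
  with_seed(seed, {
    unlist(lapply(seq_along(counts), function(i) {
      idx <- which(y == names(counts)[i])
      idx[sample.int(length(idx), base[i])]
    }))
  })
}
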