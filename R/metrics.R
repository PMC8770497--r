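#' Pixel confusion table of a predicted mask against ground truth
#'
#' Entry `p[i, j]` counts pixels of true class `i` predicted as class `j`
#' (classes 0 = background, 1 = microaneurysm). With MA as the positive
#' class, `TP = p[2, 2]`, `FP = p[1, 2]`, `FN = p[2, 1]` (1-based indices).
#'
#' @param pred,truth aligned [mask_image] objects (or 0/1 matrices).
#' @return A 2 x 2 integer matrix of class `confusion_table`, rows = truth,
#'   columns = prediction.
#' @export
confusion_table <- function(pred, truth) {
  check_same_dim(pred, truth, "prediction and truth masks")
  p <- unclass(pred); t <- unclass(truth)
  stopifnot(all(p %in% 0:1), all(t %in% 0:1))
  tab <- matrix(0L, 2, 2, dimnames = list(truth = c("0", "1"),
                                          pred = c("0", "1")))
  idx <- t * 2L + p  # 0:TN 1:FP 2:FN 3:TP
  cnt <- tabulate(idx + 1L, nbins = 4L)
  tab[1, 1] <- cnt[1]; tab[1, 2] <- cnt[2]
  tab[2, 1] <- cnt[3]; tab[2, 2] <- cnt[4]
  structure(tab, class = c("confusion_table", class(matrix())))
}

# ratio with the segmentation-suite convention for empty denominators
safe_ratio <- function(num, den, empty_value) {
  if (den == 0) empty_value else num / den
}

#' Six-metric segmentation report from a confusion table
#'
#' Computes pixel accuracy (PA), mean per-class pixel accuracy (MPA),
#' precision (Pre), recall (Re), F1 and mean intersection-over-union (MIoU)
#' with microaneurysm as the positive class. Conventions for degenerate
#' frames: with no predicted positives, Pre is 1 if there are also no true
#' positives anywhere, else 0 (symmetrically for Re); F1 is 0 when
#' Pre + Re = 0; a class absent from both prediction and truth contributes
#' per-class accuracy 1 and IoU 1 to the means.
#'
#' @param tab a [confusion_table()] (any nonnegative 2 x 2 count matrix).
#' @return A `metrics_report`: named list with elements `PA`, `MPA`, `Pre`,
#'   `Re`, `F1`, `MIoU`, all in \[0, 1\].
#' @examples
#' tab <- matrix(c(90, 3, 5, 2), 2, 2)  # truth rows, pred columns
#' unlist(compute_metrics(tab))
#' @export
compute_metrics <- function(tab) {
  tab <- unclass(tab)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  if (sum(tab) == 0) stop("empty confusion table", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  pa <- sum(diag(tab)) / sum(tab)
  acc <- vapply(1:2, function(i) safe_ratio(tab[i, i], rs[i], 1), numeric(1))
  mpa <- mean(acc)
  tp <- tab[2, 2]; fp <- tab[1, 2]; fn <- tab[2, 1]
  pre <- safe_ratio(tp, tp + fp, empty_value = as.numeric(tp + fn == 0))
  re <- safe_ratio(tp, tp + fn, empty_value = as.numeric(tp + fp == 0))
  f1 <- if (pre + re == 0) 0 else 2 * pre * re / (pre + re)
  iou <- vapply(1:2, function(i) {
    safe_ratio(tab[i, i], rs[i] + cs[i] - tab[i, i], 1)
  }, numeric(1))
  structure(list(PA = pa, MPA = mpa, Pre = pre, Re = re, F1 = f1,
                 MIoU = mean(iou)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x[c("PA", "MPA", "Pre", "Re", "F1", "MIoU")])
  cat("<metrics_report>\n")
  print(round(100 * v, 2))  # percentages, 2 decimals, table style
  invisible(x)
}

#' Aggregate per-image metric reports
#'
#' Per-metric arithmetic mean and sample standard deviation (n - 1
#' denominator; 0 when n = 1) across a set of per-image reports — the
#' "mean +/- std over the test set" aggregation.
#'
#' @param reports non-empty list of `metrics_report` objects.
#' @return A `metrics_summary`: list with elements `mean` and `sd`, each a
#'   named numeric over the six metrics, plus `n`.
#' @export
aggregate_metrics <- function(reports) {
  if (length(reports) == 0) stop("empty report list", call. = FALSE)
  cols <- c("PA", "MPA", "Pre", "Re", "F1", "MIoU")
  m <- do.call(rbind, lapply(reports, function(r) unlist(r[cols])))
  mu <- colMeans(m)
  sd <- if (nrow(m) == 1L) stats::setNames(rep(0, 6), cols) else
    apply(m, 2, stats::sd)
  structure(list(mean = mu, sd = sd, n = nrow(m)), class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary over %d image(s)>\n", x$n))
  for (k in names(x$mean)) {
    cat(sprintf("  %-5s %6.2f +/- %.2f %%\n", k, 100 * x$mean[k], 100 * x$sd[k]))
  }
  invisible(x)
}

# pooled-confusion alternative: sum tables first, then compute once
pool_confusions <- function(tabs) {
  Reduce(`+`, lapply(tabs, unclass))
}

#' Evaluate predicted masks against ground truth on disk
#'
#' Pairs files by name across the two directories, computes a per-image
#' six-metric report and the mean +/- sd aggregate, and optionally writes
#' `metrics.json` and `metrics.csv` (one row per image plus a summary row,
#' columns in the order PA, MPA, Pre, Re, F1, MIoU).
#'
#' @param pred_dir,truth_dir directories of mask PNGs with matching names.
#' @param out_dir if non-`NULL`, directory for `metrics.json`/`metrics.csv`.
#' @param pooled also report metrics of the pooled (summed) confusion table.
#' @return A list with `per_image` (data frame), `summary`
#'   ([aggregate_metrics()] result) and optionally `pooled`.
#' @export
evaluate_masks <- function(pred_dir, truth_dir, out_dir = NULL, pooled = FALSE) {
  pf <- sort(list.files(pred_dir, pattern = "\\.png$"))
  tf <- sort(list.files(truth_dir, pattern = "\\.png$"))
  orphans <- c(setdiff(pf, tf), setdiff(tf, pf))
  if (length(orphans) > 0) {
    stop(sprintf("unmatched mask files: %s",
                 paste(utils::head(orphans, 10), collapse = ", ")),
         call. = FALSE)
  }
  if (length(pf) == 0) stop("no mask files to evaluate", call. = FALSE)
  tabs <- vector("list", length(pf))
  reports <- vector("list", length(pf))
  for (i in seq_along(pf)) {
    tabs[[i]] <- confusion_table(read_mask(file.path(pred_dir, pf[i])),
                                 read_mask(file.path(truth_dir, pf[i])))
    reports[[i]] <- compute_metrics(tabs[[i]])
  }
  per_image <- data.frame(file = pf,
                          do.call(rbind, lapply(reports, function(r)
                            unlist(r[c("PA", "MPA", "Pre", "Re", "F1", "MIoU")]))))
  summary <- aggregate_metrics(reports)
  out <- list(per_image = per_image, summary = summary)
  if (pooled) out$pooled <- compute_metrics(pool_confusions(tabs))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(per_image = per_image,
           summary = list(mean = as.list(summary$mean),
                          sd = as.list(summary$sd), n = summary$n)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    csv <- rbind(per_image,
                 data.frame(file = "mean", t(summary$mean)),
                 data.frame(file = "sd", t(summary$sd)))
    utils::write.csv(csv, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  out
}
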