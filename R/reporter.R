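# In vivo activity-sensor reporter data: container, normalization,
# differential enrichment, volcano tables.

#' Reporter dataset
#'
#' Sample-by-reporter matrix of nonnegative urinary reporter concentrations
#' from multiplexed activity-based nanosensors, with a class label per
#' sample (e.g. `Control` / `KP`) and an optional grouping label (e.g.
#' time point).
#'
#' @param values Numeric matrix, n samples x k reporters, nonnegative.
#' @param class_labels Character vector of length n.
#' @param sample_ids Character vector of length n; defaults to row names.
#' @param group_labels Optional character vector of length n.
#' @param reporter_ids Character vector of length k; defaults to column
#'   names.
#' @return An object of class `reporter_dataset`.
#' @export
reporter_dataset <- function(values, class_labels,
                             sample_ids = rownames(values),
                             group_labels = NULL,
                             reporter_ids = colnames(values)) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(reporter_ids)) reporter_ids <- paste0("R", seq_len(k))
  if (length(class_labels) != n || length(sample_ids) != n) {
    stop("`class_labels` and `sample_ids` must have one entry per sample",
         call. = FALSE)
  }
  if (!is.null(group_labels) && length(group_labels) != n) {
    stop("`group_labels` must have one entry per sample", call. = FALSE)
  }
  if (length(reporter_ids) != k || anyDuplicated(label_key(reporter_ids))) {
    stop("reporter ids must be unique and match the columns", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("reporter concentrations must be nonnegative", call. = FALSE)
  }
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(reporter_ids))
  structure(list(values = values,
                 classes = as.character(class_labels),
                 groups = if (!is.null(group_labels))
                   as.character(group_labels)),
            class = "reporter_dataset")
}

#' @export
print.reporter_dataset <- function(x, ...) {
  cat(sprintf("<reporter_dataset> %d samples x %d reporters; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (%d)", names(table(x$classes)),
                            table(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Read a reporter dataset from CSV
#'
#' Expected layout: first column `sample_id`, second column class label,
#' optional third column group label (`has_group = TRUE`), remaining columns
#' reporter concentrations. Header row required.
#'
#' @param path Path to the file.
#' @param has_group Whether a group column follows the class column.
#' @param delim Field delimiter.
#' @return A [reporter_dataset()].
#' @export
read_reporter_csv <- function(path, has_group = FALSE, delim = ",") {
  df <- read_delim_frame(path, delim)
  min_cols <- if (has_group) 4L else 3L
  if (ncol(df) < min_cols) {
    stop("format error: expected sample_id, class",
         if (has_group) ", group", " and at least one reporter column",
         call. = FALSE)
  }
  meta_n <- if (has_group) 3L else 2L
  vals <- as.matrix(df[, -(seq_len(meta_n)), drop = FALSE])
  if (!is.numeric(vals)) {
    stop("parse error: non-numeric reporter values in ", path, call. = FALSE)
  }
  reporter_dataset(vals, class_labels = df[[2]], sample_ids = df[[1]],
                   group_labels = if (has_group) df[[3]])
}

#' Write a reporter dataset to CSV
#' @param ds A `reporter_dataset`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_reporter_csv <- function(ds, path, delim = ",") {
  meta <- data.frame(sample_id = rownames(ds$values), class = ds$classes,
                     stringsAsFactors = FALSE)
  if (!is.null(ds$groups)) meta$group <- ds$groups
  utils::write.table(cbind(meta, as.data.frame(ds$values)), path,
                     sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Normalize reporter concentrations
#'
#' `"sample_relative"` (default) divides each sample's reporters by that
#' sample's total, removing differences in overall urinary output so each
#' row sums to 1. `"reporter_mean"` additionally divides each reporter by
#' its across-sample mean, putting reporters on a common scale. `"none"`
#' returns the data unchanged.
#'
#' @param ds A `reporter_dataset`.
#' @param method `"sample_relative"`, `"reporter_mean"` or `"none"`.
#' @return A `reporter_dataset` with normalized values; the method is
#'   recorded in the `"normalization"` attribute.
#' @export
normalize_reporters <- function(ds, method = c("sample_relative",
                                               "reporter_mean", "none")) {
  method <- match.arg(method)
  out <- ds
  if (method != "none") {
    totals <- rowSums(ds$values, na.rm = TRUE)
    if (any(totals == 0)) {
      stop("degenerate input: all-zero sample(s): ",
           paste(rownames(ds$values)[totals == 0], collapse = ", "),
           call. = FALSE)
    }
    v <- ds$values / totals
    if (method == "reporter_mean") {
      mu <- colMeans(v, na.rm = TRUE)
      mu[mu == 0] <- 1
      v <- sweep(v, 2L, mu, "/")
    }
    out$values <- v
  }
  attr(out, "normalization") <- method
  out
}

#' Differential enrichment of reporters between two classes
#'
#' Per-reporter two-sided test comparing class A against class B on
#' normalized concentrations, with Benjamini-Hochberg (default) adjustment
#' for multiple testing. The default Mann-Whitney U test uses the exact null
#' distribution when both groups have at most 8 samples and the
#' tie-corrected normal approximation otherwise. Fold changes are ratios of
#' class means of the normalized values.
#'
#' @param ds A `reporter_dataset`.
#' @param class_a,class_b Class labels to compare (fold change is A over B).
#' @param test `"mann_whitney"` (default) or `"t_test"` (Welch).
#' @param fdr Adjusted-p threshold for the significance flag (default 0.05).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param normalize Normalization applied before testing (see
#'   [normalize_reporters()]); use `"none"` if `ds` is already normalized.
#' @return Data frame of class `differential_result` with one row per
#'   reporter: `reporter`, `mean_fold_change`, `log2_fold_change`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
differential_enrichment <- function(ds, class_a, class_b,
                                    test = c("mann_whitney", "t_test"),
                                    fdr = 0.05,
                                    adjust = c("BH", "bonferroni"),
                                    normalize = c("sample_relative",
                                                  "reporter_mean", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  in_a <- ds$classes == class_a
  in_b <- ds$classes == class_b
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    stop("both classes need at least 2 samples (", class_a, ": ", sum(in_a),
         ", ", class_b, ": ", sum(in_b), ")", call. = FALSE)
  }
  nds <- normalize_reporters(ds, match.arg(normalize))
  v <- nds$values
  exact <- sum(in_a) <= 8L && sum(in_b) <= 8L
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[in_a, j]; y <- v[in_b, j]
    p <- if (test == "mann_whitney") {
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          correct = TRUE)$p.value)
    } else {
      stats::t.test(x, y)$p.value
    }
    fc <- if (mean(y, na.rm = TRUE) > 0)
      mean(x, na.rm = TRUE) / mean(y, na.rm = TRUE) else NA_real_
    c(p = p, fc = fc)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  fc <- vapply(res, `[[`, numeric(1), "fc")
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  out <- data.frame(reporter = colnames(v),
                    mean_fold_change = fc,
                    log2_fold_change = log2(fc),
                    p_raw = p_raw,
                    p_adjusted = p_adj,
                    significant = !is.na(p_adj) & p_adj <= fdr,
                    stringsAsFactors = FALSE)
  structure(out, class_a = class_a, class_b = class_b, test = test,
            fdr = fdr, adjust = adjust,
            class = c("differential_result", "data.frame"))
}

#' Volcano table (and optional plot) from a differential result
#'
#' One row per reporter with the log2 fold change, `-log10` adjusted p-value
#' and the significance flag, ready for volcano plotting. When `path` is
#' given, a volcano plot is written there.
#'
#' @param diff A [differential_enrichment()] result.
#' @param path Optional figure path (extension selects the device, e.g.
#'   `.pdf`).
#' @return Data frame with columns `reporter`, `log2_fold_change`,
#'   `neg_log10_p_adjusted`, `significant`.
#' @export
volcano_table <- function(diff, path = NULL) {
  out <- data.frame(reporter = diff$reporter,
                    log2_fold_change = diff$log2_fold_change,
                    neg_log10_p_adjusted = -log10(diff$p_adjusted),
                    significant = diff$significant,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    p <- ggplot2::ggplot(out, ggplot2::aes(
      x = .data$log2_fold_change, y = .data$neg_log10_p_adjusted,
      colour = .data$significant)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_hline(yintercept = -log10(attr(diff, "fdr")),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "firebrick")) +
      ggplot2::labs(x = sprintf("log2 fold change (%s / %s)",
                                attr(diff, "class_a"), attr(diff, "class_b")),
                    y = "-log10 adjusted p") +
      ggplot2::theme_classic()
    ggplot2::ggsave(path, p, width = 5, height = 4)
  }
  out
}
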