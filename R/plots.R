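# Figure generation for kinetic datasets. Plotting is presentation-only:
# every quantity shown is computed by the analysis functions.

utils::globalVariables(".data")

fold_trajectories <- function(ds) {
  raw <- ds$raw
  cfg <- ds$config
  subs <- unique_by_key(raw$series$substrate)
  conds <- unique_by_key(raw$series$condition)
  out <- list()
  for (s in subs) {
    for (p in conds) {
      series <- kinetic_series(raw, s, p)
      if (nrow(series) == 0L) next
      y <- colMeans(series, na.rm = TRUE)
      bg <- switch(cfg$background, none = 0, blank = cfg$blank_value,
                   first_point = y[1])
      base <- y[1] - bg
      if (cfg$background == "first_point") base <- max(base, cfg$floor)
      if (base <= 0) next
      out[[paste(s, p)]] <- data.frame(
        substrate = s, condition = p, time = raw$time_points,
        intensity = y, fold = (y - bg) / base, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Plot a kinetic dataset
#'
#' Writes one figure file for the requested view of a
#' [build_kinetic_dataset()] result:
#' `raw_lines` (intensity over time per substrate, panelled by condition),
#' `fold_lines` (fold change over time), `heatmap` (bidirectionally
#' clustered fold-change heatmap), `sve` (specificity versus efficiency
#' scatter), `pie` (substrate cleavage susceptibility by catalytic class;
#' requires class annotations) and `correlation` (Spearman correlation of
#' initial rates between conditions).
#'
#' @param ds A `kinetic_dataset`.
#' @param kind One of `"raw_lines"`, `"fold_lines"`, `"heatmap"`, `"sve"`,
#'   `"pie"`, `"correlation"`.
#' @param out_dir Output directory (created if needed).
#' @param file_prefix Prefix for the written file name.
#' @param threshold Fold-change threshold for the pie view.
#' @param device Figure device/extension (default `"pdf"`).
#' @return Invisibly, the path of the written file.
#' @export
plot_kinetics <- function(ds, kind = c("raw_lines", "fold_lines", "heatmap",
                                       "sve", "pie", "correlation"),
                          out_dir = ".", file_prefix = "kinetics",
                          threshold = 1.5, device = "pdf") {
  kind <- match.arg(kind)
  stopifnot(inherits(ds, "kinetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(file_prefix, "_", kind, ".", device))
  if (kind %in% c("raw_lines", "fold_lines")) {
    traj <- fold_trajectories(ds)
    yvar <- if (kind == "raw_lines") "intensity" else "fold"
    p <- ggplot2::ggplot(traj, ggplot2::aes(
      x = .data$time, y = .data[[yvar]], colour = .data$substrate)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~condition) +
      ggplot2::labs(x = "Time (min)",
                    y = if (kind == "raw_lines") "Fluorescence intensity"
                    else "Fold change") +
      ggplot2::theme_classic()
    ggplot2::ggsave(path, p, width = 7, height = 5)
  } else if (kind == "heatmap") {
    bc <- cluster_bidirectional(ds$fold_table, standardize = TRUE)
    m <- t(apply(as.matrix(ds$fold_table), 1L, zscore_guard))
    colnames(m) <- condition_labels(ds$fold_table)
    pheatmap::pheatmap(m, cluster_rows = bc$row_hclust,
                       cluster_cols = bc$col_hclust, filename = path,
                       silent = TRUE)
  } else if (kind == "sve") {
    sve <- sve_table(ds)
    p <- ggplot2::ggplot(sve, ggplot2::aes(
      x = .data$efficiency_z, y = .data$specificity_z,
      colour = .data$protease, size = .data$raw_value)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "Efficiency (z across substrates)",
                    y = "Specificity (z across proteases)") +
      ggplot2::theme_classic()
    ggplot2::ggsave(path, p, width = 6, height = 5)
  } else if (kind == "pie") {
    if (is.null(ds$classes)) {
      stop("pie view needs protease class annotations", call. = FALSE)
    }
    cs <- class_summary(ds$fold_table, ds$classes, threshold)
    df <- data.frame(substrate = rep(rownames(cs), times = ncol(cs)),
                     class = rep(colnames(cs), each = nrow(cs)),
                     count = as.vector(cs), stringsAsFactors = FALSE)
    p <- ggplot2::ggplot(df[df$count > 0, , drop = FALSE], ggplot2::aes(
      x = "", y = .data$count, fill = .data$class)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::coord_polar(theta = "y") +
      ggplot2::facet_wrap(~substrate) +
      ggplot2::labs(x = NULL, y = NULL,
                    fill = "Catalytic class") +
      ggplot2::theme_void()
    ggplot2::ggsave(path, p, width = 7, height = 6)
  } else {
    C <- spearman_matrix(ds$rate_table)
    pheatmap::pheatmap(C, filename = path, silent = TRUE)
  }
  invisible(path)
}
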