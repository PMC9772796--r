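# Hand-label validation: how much do non-vegetation objects (boats, fences,
# cars) left in the "unclassified" class bias the structure metrics? Each
# plot is a 10 m x 10 m labelled cloud; every metric is computed twice
# through the production metrics code path — once from the class-1 points,
# once from the hand-labelled vegetation points — and compared.

#' Misclassification rate of a labelled plot
#'
#' The fraction of class-1 ("unclassified", assumed vegetation) points
#' whose hand label is not `"vegetation"`.
#'
#' @param plot an `als_cloud` with a `label` column.
#' @return rate in `[0, 1]`; `NA` (with a message) when the plot has no
#'   class-1 point.
#' @export
misclassification_rate <- function(plot) {
  if (!"label" %in% names(plot)) stop("plot has no hand labels")
  lab <- plot$label[plot$classification == 1L]
  if (length(lab) == 0) {
    message("plot has no class-1 points; misclassification undefined")
    return(NA_real_)
  }
  mean(lab != "vegetation")
}

# Metrics for one labelled plot under both classifications. The plot is
# normalized once (1 m cells anchored at the footprint corner); both runs
# then share the same normalized heights, as in a production run where
# normalization precedes any relabelling.
.plot_metric_pair <- function(plot, cell_size = 10, norm_cell = 1,
                              interpolate = FALSE) {
  org <- attr(plot, "footprint") %||% c(floor(cloud_bounds(plot)[["xmin"]]),
                                        floor(cloud_bounds(plot)[["ymin"]]))
  npc <- normalize_height(plot, cell_size = norm_cell, origin = org[1:2])
  area <- cell_size^2
  orig_veg <- npc$classification == 1L
  hand_veg <- npc$label == "vegetation"
  list(
    original = cell_metrics(npc$nz[orig_veg], npc$x[orig_veg], npc$y[orig_veg],
                            n_ground = sum(npc$classification == 2L),
                            n_all = nrow(npc), cell_area = area,
                            interpolate = interpolate),
    hand = cell_metrics(npc$nz[hand_veg], npc$x[hand_veg], npc$y[hand_veg],
                        n_ground = sum(npc$label == "ground"),
                        n_all = nrow(npc), cell_area = area,
                        interpolate = interpolate)
  )
}

#' Per-metric accuracy over labelled plots
#'
#' For each plot the metric is computed twice — on the original class-1
#' points and on the hand-labelled vegetation points — and the accuracy is
#' the fraction of plots where the two values do not differ
#' (`|difference| <= tolerance`; a tolerance of 0 is the literal
#' "difference = 0" criterion). A metric that is nodata under both
#' classifications counts as no difference; nodata under exactly one counts
#' as differing.
#'
#' @param plots list of labelled plots (see [make_validation_plots()]).
#' @param metric metric identifier.
#' @param tolerance numeric difference below which values count as equal.
#' @return accuracy in `[0, 1]`.
#' @export
metric_accuracy <- function(plots, metric, tolerance = 1e-6) {
  rep <- validate_plots(plots, tolerance = tolerance)
  rep$per_metric[metric_id == metric, accuracy]
}

#' Validate structure metrics against hand-labelled plots
#'
#' Computes per-plot misclassification rates, per-plot-per-metric value
#' differences (hand-labelled vegetation minus original class-1), and
#' per-metric accuracies, with mean +/- sd summaries over plots and over
#' metrics.
#'
#' @param plots list of labelled plots.
#' @param tolerance difference magnitude treated as "did not differ".
#' @param interpolate passed to the percentile metrics.
#' @return an `als_validation` list: `per_plot` (`plot`, `misclassification`),
#'   `differences` (`plot` x `metric_id`, long format, `differs` flag),
#'   `per_metric` (`metric_id`, `accuracy`), `summary`.
#' @export
validate_plots <- function(plots, tolerance = 1e-6, interpolate = FALSE) {
  stopifnot(length(plots) >= 1)
  mnames <- als_metric_names()
  diffs <- vector("list", length(plots))
  mis <- numeric(length(plots))
  for (k in seq_along(plots)) {
    mis[k] <- suppressMessages(misclassification_rate(plots[[k]]))
    pair <- .plot_metric_pair(plots[[k]], interpolate = interpolate)
    d <- pair$hand - pair$original
    both_na <- is.na(pair$hand) & is.na(pair$original)
    one_na <- xor(is.na(pair$hand), is.na(pair$original))
    differs <- (abs(d) > tolerance & !is.na(d)) | one_na
    d[both_na] <- 0
    diffs[[k]] <- data.table::data.table(plot = k, metric_id = mnames,
                                         difference = d, differs = differs)
  }
  differences <- data.table::rbindlist(diffs)
  per_metric <- differences[, .(accuracy = mean(!differs)), by = metric_id]
  per_plot <- data.table::data.table(plot = seq_along(plots),
                                     misclassification = mis)
  structure(list(
    per_plot = per_plot,
    differences = differences,
    per_metric = per_metric,
    summary = list(
      n_plots = length(plots),
      misclassification_mean = mean(mis, na.rm = TRUE),
      misclassification_sd = stats::sd(mis, na.rm = TRUE),
      clean_plot_fraction = mean(mis == 0, na.rm = TRUE),
      accuracy_mean = mean(per_metric$accuracy),
      accuracy_sd = stats::sd(per_metric$accuracy)
    )
  ), class = "als_validation")
}

#' @export
print.als_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<als_validation> %d plots\n", s$n_plots))
  cat(sprintf("  misclassification %.3f +/- %.3f (%.0f%% of plots clean)\n",
              s$misclassification_mean, s$misclassification_sd,
              100 * s$clean_plot_fraction))
  cat(sprintf("  metric accuracy   %.3f +/- %.3f over %d metrics\n",
              s$accuracy_mean, s$accuracy_sd, nrow(x$per_metric)))
  invisible(x)
}

#' Write a validation report to disk
#'
#' Per-plot and per-metric tables as CSV plus a JSON summary.
#'
#' @param report an `als_validation`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(report$per_plot, file.path(dir, "per_plot.csv"))
  data.table::fwrite(report$per_metric, file.path(dir, "per_metric.csv"))
  data.table::fwrite(report$differences, file.path(dir, "differences.csv"))
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
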