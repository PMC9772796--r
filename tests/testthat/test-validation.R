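label_plot <- function(n_veg, n_other, n_ground = 20, veg_max = 1,
                       other_z = 3, seed = 1) {
  set.seed(seed)
  n1 <- n_veg + n_other
  pl <- point_cloud(
    x = runif(n1 + n_ground, 0, 10), y = runif(n1 + n_ground, 0, 10),
    z = c(runif(n_veg, 0, veg_max), rep(other_z, n_other), rep(0, n_ground)),
    classification = c(rep(1L, n1), rep(2L, n_ground)),
    label = c(rep("vegetation", n_veg), rep("other", n_other),
              rep("ground", n_ground))
  )
  data.table::setattr(pl, "footprint", c(0, 0))
  pl
}

test_that("misclassification rate is the mislabelled share of class-1 points", {
  expect_equal(misclassification_rate(label_plot(95, 5)), 0.05)
  expect_equal(misclassification_rate(label_plot(50, 0)), 0)
  expect_equal(misclassification_rate(label_plot(4, 6)), 0.6)
  # no class-1 points: undefined
  g <- point_cloud(1:3, 1:3, rep(0, 3), rep(2L, 3),
                   label = rep("ground", 3))
  expect_message(r <- misclassification_rate(g), "no class-1")
  expect_true(is.na(r))
})

test_that("metric accuracy is 1 for all metrics when clutter is absent", {
  plots <- make_validation_plots(8, clutter_fraction = 0, seed = 5)
  rep <- suppressMessages(validate_plots(plots))
  expect_identical(nrow(rep$per_metric), 26L)
  expect_true(all(rep$per_metric$accuracy == 1))
  expect_true(all(rep$differences$difference == 0))
  expect_equal(rep$summary$misclassification_mean, 0)
  expect_equal(rep$summary$clean_plot_fraction, 1)
})

test_that("a planted clutter block shifts Hmax by the planted height gap", {
  pl <- label_plot(60, 20, veg_max = 1, other_z = 3)
  pair <- suppressMessages(alsmetrics:::.plot_metric_pair(pl))
  d <- pair$hand - pair$original
  # original Hmax is the 3 m block, hand-labelled Hmax the true grass top
  expect_equal(pair$original[["Hmax"]], 3)
  expect_lt(pair$hand[["Hmax"]], 1)
  expect_equal(d[["Hmax"]], pair$hand[["Hmax"]] - 3)
  # both runs keep the band-ratio partition intact
  for (run in pair) {
    expect_lt(abs(run[["BR_below_1"]] + run[["BR_1_2"]] + run[["BR_2_3"]] +
                  run[["BR_above_3"]] - 1), 1e-12)
  }
  rep <- suppressMessages(validate_plots(list(pl)))
  expect_equal(rep$per_metric[metric_id == "Hmax", accuracy], 0)
})

test_that("accuracy counts plots within the tolerance, nodata handled", {
  plots <- c(make_validation_plots(9, clutter_fraction = 0, seed = 2),
             list(label_plot(60, 20)))
  rep <- suppressMessages(validate_plots(plots))
  expect_equal(rep$per_metric[metric_id == "Hmax", accuracy], 0.9)
  # zero tolerance reproduces the literal difference = 0 criterion
  rep0 <- suppressMessages(validate_plots(plots, tolerance = 0))
  expect_true(all(rep0$per_metric$accuracy <= rep$per_metric$accuracy))
  # a plot whose class-1 points are all clutter: hand metrics nodata,
  # original defined -> counts as differing
  allclut <- label_plot(0, 30)
  r1 <- suppressMessages(validate_plots(list(allclut)))
  expect_equal(r1$per_metric[metric_id == "Hmax", accuracy], 0)
  # nodata under both classifications counts as agreement (Sigma_z with
  # too few points)
  tiny <- label_plot(2, 0, n_ground = 5)
  r2 <- suppressMessages(validate_plots(list(tiny)))
  expect_equal(r2$per_metric[metric_id == "Sigma_z", accuracy], 1)
})

test_that("planted fractions are recovered exactly over many plots", {
  fr <- c(0, 0.1, 0.25, 0, 0.5, 0.03)
  plots <- make_validation_plots(60, clutter_fraction = fr, seed = 9)
  rep <- suppressMessages(validate_plots(plots))
  expect_identical(rep$per_plot$misclassification,
                   attr(plots, "planted_fraction"))
  expect_equal(rep$summary$misclassification_mean,
               mean(attr(plots, "planted_fraction")))
})

test_that("validation reports are written as CSV + JSON", {
  plots <- make_validation_plots(3, clutter_fraction = c(0, 0.2, 0), seed = 4)
  rep <- suppressMessages(validate_plots(plots))
  d <- withr::local_tempdir()
  write_validation_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("per_plot.csv", "per_metric.csv",
                                             "differences.csv", "summary.json")))))
  s <- jsonlite::fromJSON(file.path(d, "summary.json"))
  expect_equal(s$misclassification_mean, rep$summary$misclassification_mean)
})

test_that("labelled plots survive the PLY round trip into validation", {
  plots <- make_validation_plots(2, clutter_fraction = c(0, 0.3), seed = 8)
  d <- withr::local_tempdir()
  paths <- file.path(d, sprintf("plot_%d.ply", seq_along(plots)))
  for (k in seq_along(plots)) write_ply(plots[[k]], paths[k])
  back <- lapply(paths, read_ply)
  r1 <- suppressMessages(validate_plots(plots))
  r2 <- suppressMessages(validate_plots(back))
  expect_equal(r1$per_plot$misclassification, r2$per_plot$misclassification)
  expect_equal(r1$per_metric$accuracy, r2$per_metric$accuracy)
})
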