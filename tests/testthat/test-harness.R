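test_that("the packaged reference grids load with the published shape", {
  for (s in c("five_fold", "lobo", "tb")) {
    g <- ref_grid(s)
    expect_s3_class(g, "lagcv_grid")
    expect_equal(nrow(g), 36)
    expect_equal(sort(unique(g$layer1)), c(6, 12, 24, 36, 48, 60))
    gp <- ref_grid(s, permuted = TRUE)
    expect_equal(nrow(gp), 36)
    expect_true(all(gp$cv_error > 0))
  }
  g3 <- ref_grid("lobo", layers = 3)
  expect_equal(nrow(g3), 3)
  expect_true(all(c("layer1", "layer2", "layer3") %in% names(g3)))
})

test_that("best_cell finds the true tabulated minima", {
  b5 <- best_cell(ref_grid("five_fold"))
  expect_equal(b5$cv_error, 60.954)
  expect_equal(b5$layout, c(36L, 24L))
  bl <- best_cell(ref_grid("lobo"))
  expect_equal(bl$cv_error, 53.66)
  expect_equal(bl$layout, c(36L, 24L))
  bt <- best_cell(ref_grid("tb"))
  expect_equal(bt$cv_error, 65.936)
  expect_equal(bt$layout, c(36L, 6L))
  b3 <- best_cell(ref_grid("lobo", layers = 3))
  expect_equal(b3$cv_error, 54.762)
  expect_equal(b3$layout, c(60L, 60L, 60L))
  one <- as_grid(data.frame(layer1 = 6L, layer2 = 6L, cv_error = 5))
  expect_equal(best_cell(one)$row, 1)
  expect_error(best_cell(one[0, ]), "empty")
  tie <- as_grid(data.frame(layer1 = c(6L, 12L), layer2 = 6L,
                            cv_error = c(3, 3)))
  expect_message(bt2 <- best_cell(tie), "tie")
  expect_equal(bt2$row, 1)
})

test_that("row and grand averages match the published summary values", {
  g2 <- ref_grid("five_fold")
  expect_equal(round_half_away(row_average(g2, 6), 2), 79.12)
  expect_equal(round_half_away(row_average(ref_grid("tb"), 60), 2), 73.22)
  const <- as_grid(data.frame(layer1 = 6L, layer2 = c(6L, 12L),
                              cv_error = c(7, 7)))
  expect_equal(row_average(const, 6), 7)
  expect_error(row_average(g2, 13), "no cells")

  expect_equal(round_half_away(grand_average(ref_grid("five_fold",
                                                      permuted = TRUE)), 2),
               82.03)
  expect_equal(round_half_away(grand_average(ref_grid("lobo",
                                                      permuted = TRUE)), 3),
               80.016)
  expect_equal(round_half_away(grand_average(ref_grid("tb",
                                                      permuted = TRUE)), 3),
               83.279)
})

test_that("winner counts split 8 / 28 / 0 across the published grids", {
  wc <- winner_counts(ref_grid("five_fold"), ref_grid("lobo"), ref_grid("tb"))
  expect_equal(wc, list(five_fold = 8L, lobo = 28L, tb = 0L, ties = 0L))
  expect_equal(wc$five_fold + wc$lobo + wc$tb + wc$ties, 36L)
  g <- ref_grid("five_fold")
  expect_equal(winner_counts(g, g, g),
               list(five_fold = 0L, lobo = 0L, tb = 0L, ties = 36L))
  g_small <- as_grid(transform(as.data.frame(g), cv_error = cv_error - 1))
  expect_equal(winner_counts(g_small, g, g)$five_fold, 36L)
  expect_error(winner_counts(g, g[1:10, ], g), "identical cells")
})

test_that("pr tables reproduce the published ratios cell by cell", {
  published <- ref_pr_grid()
  for (s in c("five_fold", "lobo", "tb")) {
    tab <- pr_table(ref_grid(s), ref_grid(s, permuted = TRUE))
    expect_equal(round_half_away(tab$pr, 3), published[[s]])
  }
  tab_l <- pr_table(ref_grid("lobo"), ref_grid("lobo", permuted = TRUE))
  expect_equal(round_half_away(min(tab_l$pr), 3), 0.656)
  tab_t <- pr_table(ref_grid("tb"), ref_grid("tb", permuted = TRUE))
  expect_equal(round_half_away(min(tab_t$pr), 3), 0.705)
  # self-comparison is identically 1; common rescaling changes nothing
  g <- ref_grid("lobo")
  expect_true(all(pr_table(g, g)$pr == 1))
  g10 <- as_grid(transform(as.data.frame(g), cv_error = cv_error * 10))
  gp <- ref_grid("lobo", permuted = TRUE)
  gp10 <- as_grid(transform(as.data.frame(gp), cv_error = cv_error * 10))
  expect_equal(pr_table(g10, gp10)$pr, pr_table(g, gp)$pr)
  expect_error(pr_table(g, g[1:5, ]), "identical cells")
})

test_that("the three-layer table is internally consistent at its precision", {
  for (s in c("five_fold", "lobo", "tb")) {
    g3 <- ref_grid(s, layers = 3)
    expect_equal(round_half_away(g3$cv_error / g3$cv_error_permuted, 2),
                 g3$pr)
  }
})

test_that("table rendering rounds half away from zero at printed precision", {
  expect_equal(round_half_away(0.6555, 3), 0.656)
  expect_equal(round_half_away(81.8345, 3), 81.835)
  expect_equal(round_half_away(-0.6555, 3), -0.656)
  g <- as_grid(data.frame(layer1 = 6L, layer2 = 6L, cv_error = 61.3645))
  expect_equal(format_grid(g)$cv_error, 61.365)
})

test_that("run_grid scores layouts deterministically over a plan", {
  ts <- tiny_setup(n = 150, iters = 80)
  layouts <- list(c(4L, 4L), c(6L, 6L))
  g <- run_grid(ts$fm, ts$plan, layouts, max_iterations = 80, seed = 2)
  expect_equal(nrow(g), 2)
  expect_true(all(is.finite(g$cv_error)))
  expect_equal(g$layer1, c(4, 6))
  g2 <- run_grid(ts$fm, ts$plan, layouts, max_iterations = 80, seed = 2)
  expect_identical(g$cv_error, g2$cv_error)
  expect_error(run_grid(ts$fm, ts$plan, list()), "no layouts")
  expect_error(run_grid(ts$fm, ts$plan, list(c(4L, 4L), 5L)), "same depth")
})

test_that("two_layer_layouts enumerates the grid in published order", {
  l <- two_layer_layouts()
  expect_length(l, 36)
  expect_equal(l[[1]], c(6L, 6L))
  expect_equal(l[[2]], c(6L, 12L))
  expect_equal(l[[36]], c(60L, 60L))
  ref <- ref_grid("lobo")
  expect_equal(do.call(rbind, l),
               unname(as.matrix(as.data.frame(ref)[, c("layer1", "layer2")])))
})
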