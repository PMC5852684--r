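test_that("squared-chord distance matches hand evaluations and its bounds", {
  expect_equal(squared_chord(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(squared_chord(c(1, 0), c(0, 1)), 2)   # disjoint supports
  expect_equal(squared_chord(c(0.5, 0.5), c(1, 0)),
               (sqrt(0.5) - 1)^2 + 0.5, tolerance = 1e-12)
  expect_error(squared_chord(c(0.7, 0.2), c(0.5, 0.5)), "normalized")
  expect_error(squared_chord(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
})

test_that("vectorized distances agree with the brute-force loop on 200 random pairs", {
  set.seed(11)
  for (rep in 1:4) {
    k <- sample(3:8, 1)
    p <- matrix(rgamma(50 * k, 1), 50); p <- p / rowSums(p)
    q <- matrix(rgamma(50 * k, 1), 50); q <- q / rowSums(q)
    D <- matcover:::chord_dist_matrix(p, q)
    for (i in sample(50, 50)) {
      expect_equal(D[i, i], oracle_chord(p[i, ], q[i, ]), tolerance = 1e-12)
      expect_equal(squared_chord(p[i, ], q[i, ]), oracle_chord(p[i, ], q[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("analog selection and prediction match the exhaustive oracle", {
  set.seed(21)
  cal <- tiny_calibration(m = 50)
  model <- mat(cal$x, cal$y, k = 8, T = 0.3)
  fossil <- matrix(rgamma(20 * 3, 1.5), 20); fossil <- fossil / rowSums(fossil)
  pred <- predict(model, fossil)
  for (i in 1:20) {
    o <- oracle_mat_predict(fossil[i, ], cal$x, cal$y, k = 8, T = 0.3)
    expect_equal(pred$fit[i], o$fit, tolerance = 1e-10)
    expect_equal(pred$se[i], o$se, tolerance = 1e-10)
    expect_equal(pred$n_used[i], o$n)
  }
})

test_that("the worked analog example gives 46.667 and SE 10", {
  # two analogs (d, cover) = (0.1, 40), (0.2, 60):
  # prediction (400 + 300) / (10 + 5); SE = sd(40, 60) / sqrt(2) = 10
  w <- c(1 / 0.1, 1 / 0.2)
  expect_equal(sum(w * c(40, 60)) / sum(w), 46.66667, tolerance = 1e-5)
  # reproduce through the package on vectors engineered to those distances
  p <- function(d) {  # two-component vectors at chord distance d from (1, 0)
    s <- (1 - d / 2)
    c(s^2, 1 - s^2)
  }
  cal <- rbind(p(0.1), p(0.2))
  model <- mat(cal, c(40, 60), k = 8, T = 0.3)
  out <- predict(model, matrix(c(1, 0), 1))
  expect_equal(out$fit, 46.666667, tolerance = 1e-4)
  expect_equal(out$se, 10.0, tolerance = 1e-10)
  expect_equal(out$n_used, 2L)
})

test_that("a zero-distance analog dominates via the epsilon guard", {
  cal <- tiny_calibration(m = 12)
  model <- mat(cal$x, cal$y)
  out <- predict(model, cal$x[3, , drop = FALSE])
  # the 1e-9 guard gives the exact match ~1e9 times the weight of any other
  expect_equal(out$fit, cal$y[3], tolerance = 1e-3)
})

test_that("no-analog is flagged exactly beyond the threshold", {
  cal <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  model <- mat(cal, c(10, 90), k = 8, T = 0.3)
  # fossil at squared-chord 0.31 from its nearest analog
  d <- 0.31
  s <- 1 - d / 2
  out <- predict(model, matrix(c(s^2, 1 - s^2), 1))
  expect_equal(out$d_min, 0.31, tolerance = 1e-12)
  expect_true(out$no_analog)
  expect_true(is.na(out$fit))
  expect_equal(out$n_used, 0L)
})

test_that("SE is missing (not zero) with a single retained analog", {
  cal <- rbind(c(1, 0), c(0, 1))
  model <- mat(cal, c(40, 60), k = 8, T = 0.3)
  out <- predict(model, matrix(c(0.99, 0.01), 1))  # only one analog within T
  expect_equal(out$n_used, 1L)
  expect_true(is.na(out$se))
  expect_false(out$no_analog)
})

test_that("predictions are convex combinations of retained analog covers", {
  set.seed(5)
  cal <- tiny_calibration(m = 30)
  model <- mat(cal$x, cal$y)
  fossil <- matrix(rgamma(40 * 3, 2), 40); fossil <- fossil / rowSums(fossil)
  out <- predict(model, fossil)
  an <- attr(out, "analogs")
  for (i in which(!out$no_analog)) {
    expect_gte(out$fit[i], min(an[[i]]$cover) - 1e-9)
    expect_lte(out$fit[i], max(an[[i]]$cover) + 1e-9)
  }
})

test_that("permuting the calibration set never changes predictions", {
  set.seed(6)
  cal <- tiny_calibration(m = 25)
  # inject exact distance ties at the k-th rank
  cal$x[11, ] <- cal$x[12, ]
  model1 <- mat(cal$x, cal$y, k = 3)
  perm <- sample(25)
  model2 <- mat(cal$x[perm, ], cal$y[perm], k = 3,
                ids = rownames(cal$x)[perm])
  fossil <- matrix(rgamma(15 * 3, 2), 15); fossil <- fossil / rowSums(fossil)
  p1 <- predict(model1, fossil)
  p2 <- predict(model2, fossil)
  expect_equal(p1$fit, p2$fit, tolerance = 1e-12)
  expect_equal(p1$n_used, p2$n_used)
})

test_that("distance ties at the k-th rank are all included before thresholding", {
  cal <- rbind(c(1, 0), c(0.5, 0.5), c(0.5, 0.5), c(0, 1))
  model <- mat(cal, c(10, 40, 60, 90), k = 2, T = 2)
  out <- predict(model, matrix(c(1, 0), 1))
  # nearest is the identical entry; ranks 2 and 3 are tied -> 3 analogs used
  expect_equal(out$n_used, 3L)
})

test_that("an all-zero fossil vector is a validation error", {
  cal <- tiny_calibration(m = 10)
  model <- mat(cal$x, cal$y)
  expect_error(predict(model, matrix(0, 1, 3)), "all-zero")
})

test_that("h-block cross-validation is deliberately not part of the interface", {
  exported <- getNamespaceExports("matcover")
  expect_false(any(grepl("h[_.]?block", exported, ignore.case = TRUE)))
})
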