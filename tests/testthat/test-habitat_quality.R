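toy_threats <- function() {
  data.frame(threat = "construction", code = 4L, d_max_km = 0.12,
             weight = 0.9, decay = "exponential",
             stringsAsFactors = FALSE)
}

test_that("decay_impact matches its closed forms", {
  expect_equal(decay_impact(0, 5, "linear"), 1)
  expect_equal(decay_impact(0, 5, "exponential"), 1)
  expect_equal(decay_impact(2.5, 5, "linear"), 0.5)
  expect_equal(decay_impact(5, 5, "exponential"), exp(-2.99))
  expect_equal(decay_impact(6, 5, "exponential"), 0)
  expect_equal(decay_impact(6, 5, "linear"), 0)
  expect_error(decay_impact(-1, 5, "linear"), "negative")
})

test_that("degradation is zero without threats or without sensitivity", {
  lu <- land_raster(matrix(2L, 6, 6))  # all forest grassland, no threats
  D <- degradation(lu)
  expect_true(all(D$values == 0))

  # a land class insensitive to the only threat keeps D = 0
  codes <- matrix(6L, 5, 5); codes[3, 3] <- 4L
  lu2 <- land_raster(codes)
  sens <- sensitivity_table()
  sens$construction[sens$class == "sandy"] <- 0
  D2 <- degradation(lu2, toy_threats(), sens)
  expect_equal(max(abs(D2$values[codes == 6L])), 0)
})

test_that("single-threat degradation equals the closed-form kernel", {
  codes <- matrix(2L, 5, 5); codes[3, 3] <- 4L  # one construction cell
  lu <- land_raster(codes)                      # 30 m cells
  th <- toy_threats()
  D <- degradation(lu, th)
  s_forest <- sensitivity_table()$construction[
    sensitivity_table()$class == "forest_grassland"]
  dmax <- th$d_max_km * 1000
  for (i in 1:5) for (j in 1:5) {
    d <- 30 * sqrt((i - 3)^2 + (j - 3)^2)
    expected <- if (codes[i, j] == 4L)
      sensitivity_table()$construction[
        sensitivity_table()$class == "construction"] * 1
    else s_forest * (if (d <= dmax) exp(-2.99 * d / dmax) else 0)
    expect_equal(D$values[i, j], expected, tolerance = 1e-10)
  }
})

test_that("degradation equals the brute-force oracle on random maps", {
  threats <- threat_table()
  threats$d_max_km <- c(0.09, 0.15, 0.12, 0.12)  # bounded kernels at 30 m
  sens <- sensitivity_table()
  for (seed in 1:10) {
    r <- random_land(9, 9, k = 6, seed = seed + 70,
                     legend = default_legend())
    D <- degradation(r, threats, sens)
    expect_equal(D$values, oracle_degradation(r, threats, sens),
                 tolerance = 1e-10)
  }
})

test_that("quality follows the half-saturation law", {
  lu <- land_raster(matrix(2L, 2, 2))  # forest, H = 1
  spec <- lu$spec
  H <- 1
  expect_equal(quality(cont_raster(matrix(0, 2, 2), spec), lu)$values[1, 1],
               H)
  expect_equal(quality(cont_raster(matrix(0.5, 2, 2), spec), lu,
                       k = 0.5)$values[1, 1], H / 2)
  # worked example: H = 0.4, D = 0.2, k = 0.5, z = 2.5
  lu4 <- land_raster(matrix(1L, 1, 1))  # cultivated, H = 0.4
  q <- quality(cont_raster(matrix(0.2, 1, 1), lu4$spec), lu4,
               k = 0.5, z = 2.5)$values[1, 1]
  expect_equal(q, 0.4 * (1 - 0.2^2.5 / (0.2^2.5 + 0.5^2.5)),
               tolerance = 1e-12)
  expect_equal(round(q, 4), 0.3632)
})

test_that("quality limits: k -> Inf gives H; D/k -> Inf gives 0", {
  lu <- land_raster(matrix(2L, 3, 3))
  D <- cont_raster(matrix(2, 3, 3), lu$spec)
  expect_equal(quality(D, lu, k = 1e9)$values[1, 1], 1, tolerance = 1e-6)
  expect_lt(quality(D, lu, k = 1e-6)$values[1, 1], 1e-6)
})

test_that("adding a threat cell never increases quality anywhere", {
  for (seed in 1:5) {
    set.seed(seed + 7)
    codes <- matrix(2L, 8, 8)
    codes[sample(64, 4)] <- 4L
    lu1 <- land_raster(codes)
    free <- which(codes == 2L)
    codes2 <- codes
    codes2[sample(free, 1)] <- 4L
    lu2 <- land_raster(codes2)
    q1 <- habitat_quality(lu1)$Q$values
    q2 <- habitat_quality(lu2)$Q$values
    same <- codes == codes2
    expect_true(all(q2[same] <= q1[same] + 1e-12))
  }
})

test_that("quality classification uses equal intervals with closed top bin", {
  v <- matrix(c(0, 0.19, 0.2, 0.55, 0.6, 0.79, 0.8, 1, 0.4), 3, 3)
  cls <- classify_quality(cont_raster(v))
  expect_equal(cls$codes[v == 0.55], 3L)   # medium
  expect_equal(cls$codes[v == 0], 1L)      # low
  expect_equal(cls$codes[v == 1], 5L)      # high (closed)
  expect_equal(cls$codes[v == 0.2], 2L)    # left-closed bins
  tab <- quality_class_table(cls)
  expect_equal(sum(tab$percent), 100)
  expect_error(classify_quality(cont_raster(matrix(1.2, 1, 1))), "outside")
})

test_that("quality change categories respect the stated thresholds", {
  q1 <- cont_raster(matrix(0.2, 2, 3))
  q2 <- cont_raster(matrix(c(0.9, 0.2, 0.75, -0.1 + 0.2, 0.7, 0.1), 2, 3))
  # dq = 0.7, 0, 0.55, -0.1, 0.5, -0.1  (column-major)
  qc <- quality_change(q1, q2)
  dq <- q2$values - q1$values
  expect_equal(unname(qc$labels$codes[dq > 0.5]), c(5L, 5L))
  expect_equal(unname(qc$labels$codes[dq == 0]), 3L)
  expect_equal(unname(qc$labels$codes[abs(dq + 0.1) < 1e-9]), c(2L, 2L))
  expect_equal(unname(qc$labels$codes[abs(dq - 0.5) < 1e-9]), 4L)
  expect_equal(sum(qc$areas$percent), 100)
})

test_that("mean_quality is the arithmetic mean over valid cells", {
  expect_equal(mean_quality(cont_raster(matrix(0.37, 4, 4))), 0.37)
  v <- matrix(c(rep(0, 8), rep(1, 8)), 4, 4)
  expect_equal(mean_quality(cont_raster(v)), 0.5)
  set.seed(3)
  v2 <- matrix(stats::runif(30), 5, 6)
  expect_equal(mean_quality(cont_raster(v2)), mean(v2))
})
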