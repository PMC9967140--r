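test_that("markov_demand projects areas through P", {
  P <- diag(2)
  a <- c(a = 30, b = 70)
  expect_equal(markov_demand(P, a, 5), a)
  P2 <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  expect_equal(unname(markov_demand(P2, c(a = 100, b = 100), 1)),
               c(110, 90))
  # conservation for any stochastic P
  set.seed(9)
  P3 <- matrix(stats::runif(16), 4, 4)
  P3 <- P3 / rowSums(P3)
  v <- c(a = 10, b = 0, c = 55, d = 35)
  expect_equal(sum(markov_demand(P3, v, 7)), sum(v))
  expect_error(markov_demand(matrix(c(0.5, 0.2, 0.2, 0.2), 2, 2),
                             c(a = 1, b = 1), 1), "stochastic")
})

make_world <- function(seed, nr = 40, nc = 40) {
  set.seed(seed)
  spec <- grid_spec(nr, nc)
  leg <- c(a = 1L, b = 2L)
  x <- cont_raster(matrix(stats::runif(nr * nc), nr, nc), spec)
  lu1 <- land_raster(matrix(1L, nr, nc), spec, leg)
  codes2 <- matrix(ifelse(x$values > 0.8, 2L, 1L), nr, nc)
  lu2 <- land_raster(codes2, spec, leg)
  list(x = x, lu1 = lu1, lu2 = lu2, spec = spec, leg = leg)
}

test_that("expansion learning recovers a threshold rule", {
  w <- make_world(11)
  noise <- cont_raster(matrix(stats::rnorm(1600), 40, 40), w$spec)
  suit <- suppressWarnings(
    fit_expansion_model(w$lu1, w$lu2, list(x = w$x, noise = noise),
                        seed = 2))
  p <- suit$surfaces[["b"]]
  truth <- w$lu2$codes == 2L
  acc <- mean((p > 0.5) == truth)
  expect_gt(acc, 0.95)
})

test_that("pure-noise drivers give near-flat probability surfaces", {
  set.seed(21)
  spec <- grid_spec(40, 40)
  leg <- c(a = 1L, b = 2L)
  codes2 <- matrix(ifelse(stats::runif(1600) < 0.2, 2L, 1L), 40, 40)
  lu1 <- land_raster(matrix(1L, 40, 40), spec, leg)
  lu2 <- land_raster(codes2, spec, leg)
  drv <- list(n1 = cont_raster(matrix(stats::rnorm(1600), 40, 40), spec),
              n2 = cont_raster(matrix(stats::rnorm(1600), 40, 40), spec))
  suit <- suppressWarnings(fit_expansion_model(lu1, lu2, drv, seed = 3))
  p <- suit$surfaces[["b"]]
  base <- mean(codes2 == 2L)
  # probabilities are trained on a balanced sample; compare to 0.5
  expect_lt(mean(abs(p - mean(p))), 0.1)
  expect_gt(base, 0)  # sanity on the construction
})

test_that("driver order does not change the surfaces", {
  w <- make_world(31)
  noise <- cont_raster(matrix(stats::rnorm(1600), 40, 40), w$spec)
  s1 <- suppressWarnings(fit_expansion_model(
    w$lu1, w$lu2, list(x = w$x, noise = noise), seed = 5))
  s2 <- suppressWarnings(fit_expansion_model(
    w$lu1, w$lu2, list(noise = noise, x = w$x), seed = 5))
  expect_equal(s1$surfaces[["b"]], s2$surfaces[["b"]], tolerance = 1e-8)
})

test_that("a class without expansion gets a flat prior with a warning", {
  w <- make_world(41)
  expect_warning(
    s <- fit_expansion_model(w$lu1, w$lu2, list(x = w$x), seed = 1),
    "no expansion")
  p <- s$surfaces[["a"]]
  expect_equal(length(unique(as.vector(p[!is.na(p)]))), 1L)
})

test_that("ca_simulate is conservative, demand-capped and seeded", {
  w <- make_world(51)
  suit <- list(surfaces = list(
    a = matrix(0.5, 40, 40),
    b = matrix(stats::runif(1600), 40, 40)))
  cell <- (30 / 1000)^2
  cur <- c(a = sum(w$lu2$codes == 1L), b = sum(w$lu2$codes == 2L))

  # demand equal to current areas, zero seeding: nothing changes
  same <- ca_simulate(w$lu2, suit, cur * cell,
                      ca_config(seed_prob = 0, seed = 1))
  expect_identical(same$codes, w$lu2$codes)

  demand <- c(a = unname(cur["a"]) - 120, b = unname(cur["b"]) + 120) * cell
  s1 <- ca_simulate(w$lu2, suit, demand, ca_config(seed = 7))
  s2 <- ca_simulate(w$lu2, suit, demand, ca_config(seed = 7))
  s3 <- ca_simulate(w$lu2, suit, demand, ca_config(seed = 8))
  expect_identical(s1$codes, s2$codes)
  expect_false(identical(s1$codes, s3$codes))
  # exact conservation and demand satisfaction
  expect_equal(sum(!is.na(s1$codes)), 1600)
  expect_equal(sum(s1$codes == 2L), unname(cur["b"]) + 120)
  expect_equal(attr(s1, "unmet"), 0)
})

test_that("allocation concentrates where suitability is high", {
  set.seed(61)
  spec <- grid_spec(50, 50)
  leg <- c(a = 1L, b = 2L)
  initial <- land_raster(matrix(1L, 50, 50), spec, leg)
  sb <- matrix(0.001, 50, 50)
  sb[1:16, 1:16] <- 0.95          # ~10% of cells form the prime region
  suit <- list(surfaces = list(a = matrix(0.5, 50, 50), b = sb))
  cell <- (30 / 1000)^2
  demand <- c(a = 2500 - 50, b = 50) * cell
  sim <- ca_simulate(initial, suit, demand,
                     ca_config(seed = 3, seed_prob = 0.05))
  newb <- which(sim$codes == 2L)
  expect_equal(length(newb), 50)
  expect_gte(mean(sb[newb] > 0.9), 0.8)
})

test_that("forbidden transitions never occur and unmet demand is reported", {
  w <- make_world(71)
  perm <- matrix(TRUE, 2, 2)
  perm[1, 2] <- FALSE             # a may never become b
  suit <- list(surfaces = list(a = matrix(0.5, 40, 40),
                               b = matrix(0.5, 40, 40)))
  cell <- (30 / 1000)^2
  cur <- c(a = sum(w$lu2$codes == 1L), b = sum(w$lu2$codes == 2L))
  demand <- c(a = unname(cur["a"]) - 100, b = unname(cur["b"]) + 100) * cell
  expect_warning(
    sim <- ca_simulate(w$lu2, suit, demand,
                       ca_config(seed = 2, transitions = perm,
                                 max_rounds = 30)),
    "not fully met")
  expect_identical(sim$codes, w$lu2$codes)  # nothing legal to do
  expect_equal(attr(sim, "unmet"), 100)
})

test_that("kappa matches hand-computable cases", {
  leg <- c(a = 1L, b = 2L)
  m1 <- land_raster(matrix(rep(c(1L, 2L), each = 8), 4, 4), legend = leg)
  expect_equal(kappa_statistic(m1, m1), 1)
  m2 <- land_raster(3L - m1$codes, legend = leg)
  expect_equal(kappa_statistic(m1, m2), -1)
  set.seed(4)
  r1 <- random_land(100, 100, k = 2, seed = 14)
  r2 <- random_land(100, 100, k = 2, seed = 15)
  expect_lt(abs(kappa_statistic(r1, r2)), 0.1)
  solo <- land_raster(matrix(1L, 4, 4), legend = leg)
  expect_error(kappa_statistic(solo, m1), "single observed class")
})

test_that("figure of merit counts the four change sets", {
  leg <- c(a = 1L, b = 2L, c = 3L)
  base <- matrix(1L, 5, 5)
  initial <- land_raster(base, legend = leg)
  obs <- base; obs[1, 1:5] <- 2L; obs[2, 1:5] <- 2L    # 10 changed cells
  sim <- base
  sim[1, 1:5] <- 2L                                     # B >= 5
  sim[2, 1] <- 2L                                       # B += 1
  sim[2, 2:5] <- 1L                                     # A = 4 missed
  sim[3, 1:5] <- 2L                                     # D = 5 false alarms
  fom <- figure_of_merit(initial, land_raster(obs, legend = leg),
                         land_raster(sim, legend = leg))
  expect_equal(fom, 6 / (4 + 6 + 0 + 5))
  # perfect prediction of change
  expect_equal(figure_of_merit(initial, land_raster(obs, legend = leg),
                               land_raster(obs, legend = leg)), 1)
  # persistence prediction scores 0
  expect_equal(figure_of_merit(initial, land_raster(obs, legend = leg),
                               initial), 0)
  expect_error(figure_of_merit(initial, initial, initial), "no observed")
})
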