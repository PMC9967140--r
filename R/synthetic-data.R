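#' Define a synthetic desert-landscape scenario
#'
#' A fully seeded description of an artificial study area: grid geometry,
#' driver-field recipe (smoothed Gaussian noise for terrain and climate,
#' distance fields from seeded line/point features for accessibility),
#' per-class linear driver-score coefficients, and a ground-truth Markov
#' transition matrix that drives the temporal land-use series. The same
#' scenario and seed always regenerate identical data.
#'
#' Defaults emulate the study system the package is built around: six land
#' classes on a 30 m grid (200 x 200 cells at desk scale), a sandy-land /
#' forest-grassland dominated landscape, and decadal transitions in which
#' sandy land converts mainly to forest grassland while cultivated and
#' construction land expand.
#'
#' @param n_rows,n_cols grid size (default 200 x 200).
#' @param cell_size cell size in metres (default 30).
#' @param seed master seed; all randomness derives from it.
#' @param n_dates number of land-use dates to generate (default 3).
#' @param smooth_range autocorrelation range of the smooth fields (cells).
#' @param score_noise sd of the smooth noise added to class scores.
#' @param conv_noise sd of the noise perturbing conversion preference.
#' @param P ground-truth per-step Markov matrix (rows = from-class in
#'   legend order, rows sum to 1).
#' @param coef class x driver coefficient matrix (defaults supplied).
#' @return object of class `synth_scenario`.
#' @export
synth_scenario <- function(n_rows = 200, n_cols = 200, cell_size = 30,
                           seed = 42, n_dates = 3, smooth_range = 8,
                           score_noise = 0.6, conv_noise = 0.2,
                           P = default_markov(), coef = default_coef()) {
  stopifnot(nrow(P) == 6, ncol(P) == 6,
            all(abs(rowSums(P) - 1) < 1e-8), all(P >= 0))
  structure(list(spec = grid_spec(n_rows, n_cols, cell_size),
                 seed = as.integer(seed), n_dates = n_dates,
                 smooth_range = smooth_range, score_noise = score_noise,
                 conv_noise = conv_noise, P = P, coef = coef,
                 legend = default_legend()),
            class = "synth_scenario")
}

driver_names <- function() {
  c("dem", "slope", "temperature", "precipitation", "population", "gdp",
    "dist_road", "dist_river", "dist_settlement", "dist_railway")
}

# ground-truth decadal transition probabilities: sandy -> forest grassland
# is the dominant conversion; construction is near-absorbing
default_markov <- function() {
  P <- matrix(0, 6, 6, dimnames = list(names(default_legend()),
                                       names(default_legend())))
  P["cultivated", ]       <- c(0.920, 0.040, 0.010, 0.010, 0.010, 0.010)
  P["forest_grassland", ] <- c(0.020, 0.950, 0.003, 0.002, 0.005, 0.020)
  P["water", ]            <- c(0.050, 0.030, 0.900, 0.000, 0.010, 0.010)
  P["construction", ]     <- c(0.005, 0.005, 0.000, 0.990, 0.000, 0.000)
  P["unused", ]           <- c(0.030, 0.080, 0.000, 0.010, 0.850, 0.030)
  P["sandy", ]            <- c(0.010, 0.120, 0.005, 0.005, 0.010, 0.850)
  P
}

# per-class driver preferences (columns in driver_names() order) plus an
# intercept controlling base shares (last column)
default_coef <- function() {
  m <- rbind(
    cultivated       = c(-0.5, -0.8,  0.3,  0.8,  0.3,  0.2,  0.0, -1.0, -0.3,  0.0, -1.3),
    forest_grassland = c( 0.3,  0.2,  0.2,  1.0, -0.2, -0.2,  0.0,  0.0,  0.2,  0.0,  0.8),
    water            = c(-1.2, -0.5,  0.0,  0.3,  0.0,  0.0,  0.0, -1.5,  0.0,  0.0, -1.5),
    construction     = c(-0.2, -0.6,  0.2,  0.0,  0.7,  0.7, -0.8,  0.0, -1.2, -0.3, -4.2),
    unused           = c( 0.2,  0.0, -0.3, -0.5,  0.0,  0.0,  0.0, -0.5,  0.3,  0.0, -1.2),
    sandy            = c( 0.5,  0.3,  0.3, -1.0, -0.3, -0.2,  0.2,  0.5,  0.3,  0.0,  0.9))
  colnames(m) <- c(driver_names(), "intercept")
  m
}

#' Generate the synthetic driver stack
#'
#' Smoothed Gaussian random fields for terrain, climate and socio-economic
#' surfaces (slope is derived from the synthetic DEM, temperature is
#' negatively coupled to it, GDP follows population, population decays
#' away from the seeded settlements), and exact Euclidean-distance fields
#' from seeded linear features (road, river, railway) and settlement
#' points. All fields are standardised to zero mean and unit variance.
#'
#' @param sc a [synth_scenario()].
#' @return named list of [cont_raster()]s (see `driver_names()`), with the
#'   feature masks attached as attribute `features`.
#' @export
generate_drivers <- function(sc) {
  stopifnot(inherits(sc, "synth_scenario"))
  set.seed(sc$seed)
  nr <- sc$spec$n_rows; nc <- sc$spec$n_cols
  cs <- sc$spec$cell_size
  dem <- smooth_field(nr, nc, sc$smooth_range * 1.5)
  slope <- scale_field(grad_mag(dem))
  temperature <- scale_field(smooth_field(nr, nc, sc$smooth_range) - 0.6 * dem)
  precipitation <- smooth_field(nr, nc, sc$smooth_range)
  feat <- list(road = walk_line(nr, nc, wobble = 0.35),
               river = walk_line(nr, nc, wobble = 0.2),
               railway = walk_line(nr, nc, wobble = 0.1),
               settlement = point_mask(nr, nc, n = 5))
  dist <- lapply(feat, function(m) sqrt(edt_squared(m)) * cs)
  population <- scale_field(-scale_field(dist$settlement) +
                              0.5 * smooth_field(nr, nc, sc$smooth_range))
  gdp <- scale_field(0.7 * population + 0.5 * smooth_field(nr, nc,
                                                           sc$smooth_range))
  # distance fields stay in metres (0 exactly on feature cells); consumers
  # standardise as needed
  out <- list(dem = dem, slope = slope, temperature = temperature,
              precipitation = precipitation, population = population,
              gdp = gdp,
              dist_road = dist$road, dist_river = dist$river,
              dist_settlement = dist$settlement,
              dist_railway = dist$railway)
  out <- lapply(out, cont_raster, spec = sc$spec)
  attr(out, "features") <- feat
  out
}

grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- cbind(m[, 2] - m[, 1],
              (m[, -(1:2), drop = FALSE] - m[, 1:(nc - 2), drop = FALSE]) / 2,
              m[, nc] - m[, nc - 1])
  gy <- rbind(m[2, ] - m[1, ],
              (m[-(1:2), , drop = FALSE] - m[1:(nr - 2), , drop = FALSE]) / 2,
              m[nr, ] - m[nr - 1, ])
  sqrt(gx^2 + gy^2)
}

# random-walk polyline crossing all columns; returns logical mask
walk_line <- function(nr, nc, wobble = 0.3) {
  m <- matrix(FALSE, nr, nc)
  r <- sample.int(nr, 1)
  for (j in seq_len(nc)) {
    m[r, j] <- TRUE
    step <- sample(c(-1L, 0L, 1L), 1,
                   prob = c(wobble, 1 - 2 * wobble, wobble))
    r <- min(max(r + step, 1L), nr)
  }
  m
}

point_mask <- function(nr, nc, n = 5) {
  m <- matrix(FALSE, nr, nc)
  m[cbind(sample.int(nr, n, replace = TRUE),
          sample.int(nc, n, replace = TRUE))] <- TRUE
  m
}

# class-score stack: linear driver combination + smooth noise
class_scores <- function(sc, drivers) {
  nr <- sc$spec$n_rows; nc <- sc$spec$n_cols
  Z <- vapply(driver_names(), function(nm) as.vector(drivers[[nm]]$values),
              numeric(nr * nc))
  Z <- scale(Z)
  lapply(seq_len(6), function(ci) {
    s <- Z %*% sc$coef[ci, driver_names()] + sc$coef[ci, "intercept"]
    matrix(s, nr, nc) +
      sc$score_noise * smooth_field(nr, nc, sc$smooth_range)
  })
}

#' Generate a multi-date land-use series with known Markov structure
#'
#' The first date assigns each cell the class with the highest linear
#' driver score (plus smooth noise). Each later date applies the ground
#' truth Markov matrix: for every ordered class pair (m, n) the number of
#' converting cells is `round(N_m P[m,n])`, and the converted cells are
#' those of class m where the gaining class n scores highest (plus
#' Gumbel-perturbed preference), so conversions are spatially
#' driver-correlated, as a rule-mining expansion model assumes.
#'
#' @param sc a [synth_scenario()].
#' @param drivers a [generate_drivers()] stack for the same scenario.
#' @return list of [land_raster()]s of length `sc$n_dates`; the per-class
#'   score stack is attached as attribute `scores`.
#' @export
generate_landuse_series <- function(sc, drivers) {
  stopifnot(inherits(sc, "synth_scenario"))
  set.seed(sc$seed + 1L)
  scores <- class_scores(sc, drivers)
  nr <- sc$spec$n_rows; nc <- sc$spec$n_cols
  arr <- array(unlist(scores), c(nr, nc, 6))
  first <- matrix(max.col(matrix(arr, nr * nc, 6)), nr, nc)
  if (length(unique(as.vector(first))) < 6)
    warning("a land-use class has no support in the initial map")
  maps <- vector("list", sc$n_dates)
  maps[[1]] <- land_raster(first, sc$spec, sc$legend)
  for (d in seq_len(sc$n_dates - 1L)) {
    maps[[d + 1]] <- step_markov(maps[[d]], sc, scores)
  }
  attr(maps, "scores") <- scores
  maps
}

step_markov <- function(map, sc, scores) {
  orig <- map$codes          # snapshot: one Markov step from the old map
  codes <- orig
  K <- 6L
  for (m in seq_len(K)) {
    cells_m <- which(orig == m)
    N_m <- length(cells_m)
    if (N_m == 0) next
    taken <- rep(FALSE, N_m)
    for (n in setdiff(seq_len(K), m)) {
      k <- round(N_m * sc$P[m, n])
      if (k <= 0) next
      pref <- scores[[n]][cells_m] +
        sc$conv_noise * gumbel(length(cells_m))
      pref[taken] <- -Inf
      sel <- order(pref, decreasing = TRUE)[seq_len(min(k, sum(!taken)))]
      codes[cells_m[sel]] <- n
      taken[sel] <- TRUE
    }
  }
  land_raster(codes, map$spec, map$legend)
}

gumbel <- function(n) -log(-log(stats::runif(n)))
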