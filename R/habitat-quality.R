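#' Default threat-factor definitions
#'
#' The four human-disturbance land classes treated as habitat threats,
#' with maximum effective distance (km), weight and spatial decay mode:
#' cultivated 4 km / 0.6 / linear; construction 8 km / 0.9 / exponential;
#' unused 6 km / 0.5 / linear; sandy 6 km / 0.75 / exponential.
#'
#' @param legend legend resolving threat class names to codes.
#' @return data.frame with columns `threat`, `code`, `d_max_km`, `weight`,
#'   `decay`.
#' @export
threat_table <- function(legend = default_legend()) {
  d <- data.frame(
    threat  = c("cultivated", "construction", "unused", "sandy"),
    d_max_km = c(4, 8, 6, 6),
    weight  = c(0.6, 0.9, 0.5, 0.75),
    decay   = c("linear", "exponential", "linear", "exponential"),
    stringsAsFactors = FALSE)
  d$code <- unname(legend[d$threat])
  d[, c("threat", "code", "d_max_km", "weight", "decay")]
}

#' Default habitat suitability and threat sensitivity table
#'
#' Habitat suitability H_j per land class (forest grassland 1, water 0.9,
#' cultivated 0.4, sandy and unused 0.1, construction 0) and the
#' sensitivity S_jr of each class to each threat factor.
#'
#' @param legend legend resolving class names to codes.
#' @return data.frame with `class`, `code`, `habitat`, and one sensitivity
#'   column per threat.
#' @export
sensitivity_table <- function(legend = default_legend()) {
  d <- data.frame(
    class = c("sandy", "forest_grassland", "water", "unused",
              "cultivated", "construction"),
    habitat      = c(0.1, 1, 0.9, 0.1, 0.4, 0),
    cultivated   = c(0.1, 0.7, 0.6, 0.1, 0.3, 0.1),
    construction = c(0.3, 0.6, 0.2, 0.3, 0.5, 0.3),
    unused       = c(0.3, 0.6, 0.4, 0.1, 0.4, 0.2),
    sandy        = c(0.1, 0.7, 0.3, 0.6, 0.3, 0),
    stringsAsFactors = FALSE)
  d$code <- unname(legend[d$class])
  d[, c("class", "code", "habitat", "cultivated", "construction",
        "unused", "sandy")]
}

#' Read threat / sensitivity tables from CSV
#'
#' CSVs mirror [threat_table()] / [sensitivity_table()] column-for-column.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_threats <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("threat", "code", "d_max_km", "weight", "decay")
  if (!all(need %in% names(d)))
    stop("threat table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$weight <= 0 | d$weight > 1) || any(d$d_max_km <= 0))
    stop("invalid threat weights or distances", call. = FALSE)
  d
}

#' @rdname read_threats
#' @export
read_sensitivity <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "code", "habitat") %in% names(d)))
    stop("sensitivity table must have class, code, habitat columns",
         call. = FALSE)
  d
}

#' Distance decay of a threat's impact
#'
#' Linear: `max(0, 1 - d / d_max)`. Exponential: `exp(-(2.99 / d_max) * d)`,
#' truncated to 0 beyond `d_max` (so the kernel is bounded and identical to
#' the brute-force evaluation).
#'
#' @param d distance(s), same units as `d_max` (>= 0).
#' @param d_max maximum effective distance (> 0).
#' @param mode `"linear"` or `"exponential"`.
#' @return impact in `[0, 1]`.
#' @export
decay_impact <- function(d, d_max, mode = c("linear", "exponential")) {
  mode <- match.arg(mode)
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  stopifnot(d_max > 0)
  out <- if (mode == "linear") pmax(0, 1 - d / d_max)
         else exp(-(2.99 / d_max) * d)
  out[d > d_max] <- 0
  out
}

# kernel matrix of decayed impacts for all integer cell offsets within
# d_max; centre cell (offset 0) has impact 1
threat_kernel <- function(cell_size, d_max_m, mode) {
  R <- floor(d_max_m / cell_size)
  off <- -R:R
  d <- cell_size * sqrt(outer(off^2, off^2, "+"))
  k <- matrix(decay_impact(as.vector(d), d_max_m, mode), 2 * R + 1)
  k
}

#' Habitat degradation from distance-decayed threats
#'
#' D_x = sum_r sum_y (w_r / sum w) r_y i_rxy beta_x S_{j(x),r}: for every
#' cell, the normalised-weight sum over threat classes of the sensitivity
#' of the cell's own class times the accumulated decayed impact of every
#' threat cell within the threat's maximum distance. Threat intensity r_y
#' is the 0/1 class indicator. Computed by FFT convolution of the threat
#' indicator with a bounded decay kernel; agrees with the direct
#' double-loop to ~1e-12.
#'
#' @param lu a [land_raster()].
#' @param threats threat definitions, see [threat_table()].
#' @param sens sensitivity table, see [sensitivity_table()].
#' @param access optional accessibility/protection raster beta_x in `[0,1]`
#'   (matrix or [cont_raster()]); defaults to 1 everywhere.
#' @return a [cont_raster()] of degradation scores.
#' @export
degradation <- function(lu, threats = threat_table(lu$legend),
                        sens = sensitivity_table(lu$legend),
                        access = NULL) {
  stopifnot(inherits(lu, "land_raster"))
  if (!all(threats$code %in% lu$legend))
    stop("threat class absent from land-use legend", call. = FALSE)
  beta <- if (is.null(access)) 1
          else if (inherits(access, "cont_raster")) access$values
          else access
  wsum <- sum(threats$weight)
  D <- matrix(0, lu$spec$n_rows, lu$spec$n_cols)
  sens_cols <- match(threats$threat, names(sens))
  if (anyNA(sens_cols))
    stop("sensitivity table lacks a column for some threat", call. = FALSE)
  for (t in seq_len(nrow(threats))) {
    ind <- matrix(0, lu$spec$n_rows, lu$spec$n_cols)
    ind[!is.na(lu$codes) & lu$codes == threats$code[t]] <- 1
    if (!any(ind > 0)) next
    kern <- threat_kernel(lu$spec$cell_size, threats$d_max_km[t] * 1000,
                          threats$decay[t])
    impact <- conv2_fft(ind, kern)
    # sensitivity of the receiving cell's class to this threat
    s_map <- sens[[sens_cols[t]]][match(lu$codes, sens$code)]
    s_map <- matrix(s_map, lu$spec$n_rows, lu$spec$n_cols)
    D <- D + (threats$weight[t] / wsum) * impact * s_map
  }
  D <- D * beta
  D[is.na(lu$codes)] <- NA
  D[!is.na(D) & D < 0] <- 0  # clip FFT ringing at exact zeros
  cont_raster(D, lu$spec)
}

#' Habitat quality from degradation
#'
#' Q_x = H_{j(x)} * (1 - D_x^z / (D_x^z + k^z)): suitability of the cell's
#' land class damped by a saturating function of degradation. At D = k the
#' quality is exactly H/2 (half-saturation); z controls the steepness.
#'
#' @param D degradation [cont_raster()] (from [degradation()]).
#' @param lu the [land_raster()] the degradation was computed on.
#' @param sens sensitivity table supplying H_j.
#' @param k half-saturation constant (> 0), default 0.5; pass
#'   `k = "half-max"` to use half the maximum observed degradation.
#' @param z saturation exponent (> 0), default 2.5.
#' @return a [cont_raster()] of quality in `[0, 1]`.
#' @export
quality <- function(D, lu, sens = sensitivity_table(lu$legend),
                    k = 0.5, z = 2.5) {
  stopifnot(inherits(D, "cont_raster"), inherits(lu, "land_raster"))
  check_same_spec(D, lu)
  if (identical(k, "half-max")) k <- max(D$values, na.rm = TRUE) / 2
  stopifnot(k > 0, z > 0)
  H <- matrix(sens$habitat[match(lu$codes, sens$code)],
              lu$spec$n_rows, lu$spec$n_cols)
  Dv <- D$values
  Q <- H * (1 - Dv^z / (Dv^z + k^z))
  cont_raster(Q, lu$spec)
}

#' One-call habitat quality assessment
#'
#' Runs [degradation()] then [quality()] and attaches the 5-level quality
#' classification.
#'
#' @inheritParams degradation
#' @inheritParams quality
#' @return object of class `quality_raster`: `D`, `Q` ([cont_raster()]s),
#'   `classes` (a [land_raster()] of the 5 levels), `mean` (area-weighted
#'   mean quality), `config`.
#' @export
habitat_quality <- function(lu, threats = threat_table(lu$legend),
                            sens = sensitivity_table(lu$legend),
                            access = NULL, k = 0.5, z = 2.5) {
  D <- degradation(lu, threats, sens, access)
  Q <- quality(D, lu, sens, k = k, z = z)
  if (identical(k, "half-max")) k <- max(D$values, na.rm = TRUE) / 2
  structure(list(D = D, Q = Q, classes = classify_quality(Q),
                 mean = mean_quality(Q),
                 config = list(k = k, z = z)),
            class = "quality_raster")
}

#' @export
print.quality_raster <- function(x, ...) {
  cat(sprintf("<quality_raster> mean quality %.4f (k = %g, z = %g)\n",
              x$mean, x$config$k, x$config$z))
  print(quality_class_table(x$classes))
  invisible(x)
}

#' Legend of the five equal-interval quality levels
#' @return named integer vector.
#' @export
quality_levels <- function() {
  c(low = 1L, relatively_low = 2L, medium = 3L,
    relatively_high = 4L, high = 5L)
}

#' Classify habitat quality into five equal-interval levels
#'
#' Equal spacing on `[0, 1]`: low `[0, 0.2)`, relatively low `[0.2, 0.4)`,
#' medium `[0.4, 0.6)`, relatively high `[0.6, 0.8)`, high `[0.8, 1]`
#' (last bin closed).
#'
#' @param Q quality [cont_raster()] with values in `[0, 1]`.
#' @return a [land_raster()] with the [quality_levels()] legend.
#' @export
classify_quality <- function(Q) {
  stopifnot(inherits(Q, "cont_raster"))
  v <- Q$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("quality values outside [0, 1]", call. = FALSE)
  lv <- pmin(floor(v / 0.2) + 1L, 5L)
  land_raster(lv, Q$spec, legend = quality_levels())
}

#' Areas and shares of the five quality levels
#'
#' @param cls a classified raster from [classify_quality()].
#' @return data.frame of per-level `area_km2` and `percent`.
#' @export
quality_class_table <- function(cls) {
  at <- area_table(cls)
  names(at)[1] <- "grade"
  at
}

#' Legend of the five quality-change categories
#' @return named integer vector.
#' @export
change_levels <- function() {
  c(severe_degeneration = 1L, slight_degeneration = 2L, invariable = 3L,
    slight_improvement = 4L, obvious_improvement = 5L)
}

#' Categorise habitat-quality change between two dates
#'
#' Delta Q = Q2 - Q1 classed as: obvious improvement (> 0.5), slight
#' improvement (0 < dQ <= 0.5), invariable (exactly 0), slight degeneration
#' (-0.5 <= dQ < 0), severe degeneration (< -0.5). Ties at +-0.5 fall in
#' the slight categories.
#'
#' @param Q1,Q2 aligned quality [cont_raster()]s.
#' @return list: `labels` (a [land_raster()] with [change_levels()]) and
#'   `areas` (per-category km^2 and percent).
#' @export
quality_change <- function(Q1, Q2) {
  stopifnot(inherits(Q1, "cont_raster"), inherits(Q2, "cont_raster"))
  check_same_spec(Q1, Q2)
  dq <- Q2$values - Q1$values
  lab <- matrix(NA_integer_, nrow(dq), ncol(dq))
  lab[!is.na(dq)] <- 3L
  lab[!is.na(dq) & dq < 0] <- 2L
  lab[!is.na(dq) & dq < -0.5] <- 1L
  lab[!is.na(dq) & dq > 0] <- 4L
  lab[!is.na(dq) & dq > 0.5] <- 5L
  lr <- land_raster(lab, Q1$spec, legend = change_levels())
  at <- area_table(lr)
  names(at)[1] <- "category"
  list(labels = lr, areas = at)
}

#' Area-weighted mean habitat quality
#'
#' @param Q quality [cont_raster()].
#' @return scalar mean over non-nodata cells (cells share one area, so the
#'   area-weighted mean is the arithmetic mean).
#' @export
mean_quality <- function(Q) {
  stopifnot(inherits(Q, "cont_raster"))
  v <- Q$values[!is.na(Q$values)]
  if (!length(v)) stop("all-nodata quality raster", call. = FALSE)
  mean(v)
}
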