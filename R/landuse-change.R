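#' Land-use dynamic degree (annualised relative area change)
#'
#' K = ((U_b - U_a) / U_a) * (1 / T) * 100, in percent per year: the
#' annualised relative change in the area of one land-use class over a
#' period of `T` years.
#'
#' @param u_a,u_b class area (km^2) at the start and end of the period.
#' @param t_years period length in years (> 0).
#' @return percent per year.
#' @export
dynamic_degree <- function(u_a, u_b, t_years) {
  if (any(t_years <= 0)) stop("period length must be positive", call. = FALSE)
  if (any(u_a <= 0))
    stop("dynamic degree undefined for zero starting area", call. = FALSE)
  (u_b - u_a) / u_a / t_years * 100
}

#' Comprehensive land-use dynamic degree
#'
#' LC = (sum of gross off-diagonal transfer areas / 2) / (total start-date
#' area) * (1 / T) * 100: the annualised fraction of the landscape involved
#' in inter-class conversion. Requires a transfer matrix, since the gross
#' conversion area (not net class change) enters the numerator.
#'
#' @param tm a [transfer_matrix()] result.
#' @param t_years period length in years.
#' @return percent per year.
#' @export
comprehensive_dynamic_degree <- function(tm, t_years) {
  stopifnot(inherits(tm, "transfer_matrix"))
  if (t_years <= 0) stop("period length must be positive", call. = FALSE)
  total <- sum(tm$area)
  if (total <= 0) stop("zero total area", call. = FALSE)
  off <- sum(tm$area) - sum(diag(tm$area))
  (off / 2) / total / t_years * 100
}

#' Class-to-class area transfer matrix between two dates
#'
#' Cross-tabulates cell counts of `r1` (rows, start date) against `r2`
#' (columns, end date) and converts to km^2. Row sums equal start-date
#' class areas; the matrix total equals the total jointly-observed area.
#' Row-normalising gives the Markov transition probability matrix P.
#'
#' @param r1,r2 [land_raster()]s sharing grid and legend.
#' @param labels optional `c(start, end)` date labels.
#' @return object of class `transfer_matrix` with elements `area`
#'   (class x class km^2 matrix), `prob` (row-stochastic; all-zero rows
#'   for empty classes), `classes`, `labels`.
#' @export
transfer_matrix <- function(r1, r2, labels = c("t1", "t2")) {
  stopifnot(inherits(r1, "land_raster"), inherits(r2, "land_raster"))
  check_same_spec(r1, r2)
  if (!identical(r1$legend, r2$legend))
    stop("legend mismatch between dates", call. = FALSE)
  keep <- !is.na(r1$codes) & !is.na(r2$codes)
  lv <- unname(r1$legend)
  counts <- table(factor(r1$codes[keep], levels = lv),
                  factor(r2$codes[keep], levels = lv))
  area <- unclass(counts) * cell_area_km2(r1$spec)
  dimnames(area) <- list(names(r1$legend), names(r1$legend))
  rs <- rowSums(area)
  prob <- area / ifelse(rs > 0, rs, 1)
  prob[rs == 0, ] <- 0
  structure(list(area = area, prob = prob, classes = r1$legend,
                 labels = labels),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %s -> %s (km^2)\n",
              x$labels[1], x$labels[2]))
  print(round(x$area, 2))
  invisible(x)
}

#' Per-class area table
#'
#' @param r a [land_raster()].
#' @return data.frame with `class`, `code`, `area_km2`, `percent` (share of
#'   total non-nodata area; sums to 100).
#' @export
area_table <- function(r) {
  stopifnot(inherits(r, "land_raster"))
  n_ok <- sum(!is.na(r$codes))
  if (n_ok == 0) stop("all-nodata raster", call. = FALSE)
  counts <- tabulate_codes(r)
  areas <- counts * cell_area_km2(r$spec)
  data.frame(class = names(r$legend), code = unname(r$legend),
             area_km2 = unname(areas),
             percent = unname(areas) / sum(areas) * 100,
             row.names = NULL)
}

tabulate_codes <- function(r) {
  vapply(r$legend, function(code) sum(r$codes == code, na.rm = TRUE),
         numeric(1))
}

#' Dynamic degrees for every class plus the comprehensive degree
#'
#' Convenience wrapper combining [dynamic_degree()] per class (classes with
#' zero start area are reported `NA`) and [comprehensive_dynamic_degree()].
#'
#' @param r1,r2 [land_raster()]s at the period start / end.
#' @param t_years period length in years.
#' @return list with `per_class` data.frame (start/end areas, change, K)
#'   and scalar `lc`.
#' @export
landuse_dynamics <- function(r1, r2, t_years) {
  a1 <- area_table(r1); a2 <- area_table(r2)
  k <- ifelse(a1$area_km2 > 0,
              (a2$area_km2 - a1$area_km2) / a1$area_km2 / t_years * 100,
              NA_real_)
  tm <- transfer_matrix(r1, r2)
  list(per_class = data.frame(class = a1$class,
                              area_start = a1$area_km2,
                              area_end = a2$area_km2,
                              change = a2$area_km2 - a1$area_km2,
                              k_pct_yr = k),
       lc = comprehensive_dynamic_degree(tm, t_years),
       transfer = tm)
}
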