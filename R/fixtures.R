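#' Published-table fixtures for the reference desert study area
#'
#' Numeric transcriptions of the printed summary tables of the reference
#' analysis of the Hobq Desert section along the Yellow River (1991-2019
#' observed, 2030 simulated): per-date class areas and shares, per-period
#' area changes with the land-use dynamic degrees, the habitat-quality
#' grade areas per date, and the 2030 land-use and habitat-quality
#' forecasts. These are inputs for arithmetic-consistency checks (the
#' underlying classified rasters were never published), not outputs of
#' this package.
#'
#' @return a list of data.frames:
#' \describe{
#'   \item{areas}{year x class `area_km2` and `percent`.}
#'   \item{dynamics}{per period and class: area change (km^2), dynamic
#'     degree K (%/yr), comprehensive dynamic degree LC (%/yr), and the
#'     period length `t_years` consistent with the printed K values.}
#'   \item{quality_grades}{per year and quality grade: area and percent.}
#'   \item{forecast_lu}{2019 and 2030 class areas with printed change and
#'     change rate.}
#'   \item{forecast_quality}{2019/2030 quality-grade areas with printed
#'     changes; plus `mean_quality` attribute c(2019, 2030).}
#' }
#' @export
fixture_tables <- function() {
  cls <- c("cultivated", "forest_grassland", "water", "construction",
           "unused", "sandy")
  areas <- data.frame(
    year = rep(c(1991, 2000, 2010, 2019), each = 6),
    class = rep(cls, 4),
    area_km2 = c(284.61, 5254.91, 583.42, 8.45, 162.08, 6718.67,
                 394.73, 6260.96, 467.77, 11.42, 139.30, 5737.09,
                 489.14, 7267.08, 376.69, 27.28, 44.55, 4806.61,
                 511.67, 8827.41, 322.67, 50.76, 158.38, 3140.46),
    percent = c(2.19, 40.39, 4.48, 0.06, 1.25, 51.63,
                3.03, 48.12, 3.60, 0.09, 1.07, 44.09,
                3.76, 55.85, 2.90, 0.21, 0.34, 36.94,
                3.93, 67.84, 2.48, 0.39, 1.22, 24.14))
  periods <- c("1991-2000", "2000-2010", "2010-2019", "1991-2019")
  dynamics <- data.frame(
    period = rep(periods, each = 6),
    t_years = rep(c(9, 10, 10, NA), each = 6),
    class = rep(cls, 4),
    change_km2 = c(110.12, 1006.05, -115.65, 2.97, -22.78, -981.58,
                   94.41, 1006.12, -91.08, 15.86, -94.75, -930.48,
                   22.53, 1560.33, -54.09, 23.48, 113.83, -1666.15,
                   227.06, 3572.50, -260.82, 42.31, -3.70, -3578.21),
    k_pct_yr = c(4.30, 2.13, -2.20, 3.91, -1.57, -1.62,
                 2.39, 1.61, -1.95, 13.89, -6.80, -1.62,
                 0.46, 2.15, -1.44, 8.61, 25.55, -3.47,
                 4.93, 4.50, -8.98, 9.26, -0.26, -12.66),
    lc_pct_yr = rep(c(1.22, 1.08, 1.69, 0.68), each = 6))
  grades <- c("low", "relatively_low", "medium", "relatively_high", "high")
  quality_grades <- data.frame(
    year = rep(c(1991, 2000, 2010, 2019), each = 5),
    grade = rep(grades, 4),
    area_km2 = c(7046.91, 1287.31, 1068.57, 1317.91, 2290.10,
                 1420.42, 5346.16, 764.41, 1299.37, 4180.95,
                 912.78, 4841.59, 288.84, 1229.24, 5738.84,
                 996.03, 3220.80, 395.16, 1462.02, 6937.29),
    percent = c(54.16, 9.89, 8.21, 10.13, 17.60,
                10.92, 41.09, 5.87, 9.99, 32.13,
                7.02, 37.21, 2.22, 9.45, 44.11,
                7.66, 24.75, 3.04, 11.24, 53.32))
  forecast_lu <- data.frame(
    class = cls,
    area_2019 = c(511.67, 8827.41, 322.67, 50.76, 158.38, 3140.46),
    area_2030 = c(522.35, 9719.40, 355.98, 55.72, 216.59, 2139.22),
    change_km2 = c(10.68, 891.99, 33.31, 4.96, 58.21, -1001.24),
    change_rate_pct = c(2.09, 10.10, 10.32, 9.77, 36.75, -31.88))
  forecast_quality <- data.frame(
    grade = grades,
    area_2019 = c(996.03, 3220.80, 395.16, 1462.02, 6937.29),
    percent_2019 = c(7.66, 24.75, 3.04, 11.24, 53.32),
    area_2030 = c(355.99, 739.69, 2229.41, 320.71, 9363.58),
    percent_2030 = c(2.74, 5.69, 17.14, 2.47, 71.98),
    change_km2 = c(-640.04, -2481.11, 1834.25, -1141.31, 2426.29),
    change_pct = c(-4.92, -19.07, 14.10, -8.77, 18.66))
  attr(forecast_quality, "mean_quality") <- c(`2019` = 0.6482,
                                              `2030` = 0.6876)
  list(areas = areas, dynamics = dynamics, quality_grades = quality_grades,
       forecast_lu = forecast_lu, forecast_quality = forecast_quality)
}
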