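#' Grid geometry shared by all rasters in an analysis
#'
#' All rasters entering one analysis must share an identical `grid_spec`:
#' same dimensions, cell size, origin and nodata sentinel. The convention
#' throughout the package is row-major storage, origin at the upper-left
#' corner, 0-based cell offsets, and distances measured between cell
#' centres.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in metres (positive).
#' @param xll,yll x/y coordinate of the lower-left corner (metres).
#' @param nodata integer sentinel written to file for missing cells.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 30, xll = 0, yll = 0,
                      nodata = -9999L) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), xll = as.numeric(xll),
         yll = as.numeric(yll), nodata = as.integer(nodata)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$xll, x$yll))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "cell_size", "xll", "yll")],
                   b[c("n_rows", "n_cols", "cell_size", "xll", "yll")]))
}

check_same_spec <- function(a, b, what = "rasters") {
  if (!same_spec(a$spec, b$spec))
    stop(what, " do not share an identical grid_spec", call. = FALSE)
  invisible(TRUE)
}

#' Default six-class land-use legend
#'
#' Integer codes for the six land-use classes used throughout:
#' cultivated, forest grassland, water, construction, unused, sandy.
#'
#' @return named integer vector, names are class labels.
#' @export
default_legend <- function() {
  c(cultivated = 1L, forest_grassland = 2L, water = 3L,
    construction = 4L, unused = 5L, sandy = 6L)
}

#' Categorical land-use raster
#'
#' @param codes integer matrix of class codes; `NA` marks nodata cells.
#' @param spec a [grid_spec()]; defaults to a 30 m grid matching `codes`.
#' @param legend named integer vector mapping class labels to codes.
#' @return object of class `land_raster`.
#' @export
land_raster <- function(codes, spec = NULL, legend = default_legend()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(spec)) spec <- grid_spec(nrow(codes), ncol(codes))
  stopifnot(nrow(codes) == spec$n_rows, ncol(codes) == spec$n_cols)
  if (anyDuplicated(legend)) stop("legend codes must be distinct")
  present <- unique(codes[!is.na(codes)])
  if (!all(present %in% legend))
    stop("codes present in raster but absent from legend: ",
         paste(setdiff(present, legend), collapse = ", "))
  structure(list(codes = codes, spec = spec, legend = legend),
            class = "land_raster")
}

#' Continuous-valued raster
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param spec a [grid_spec()].
#' @return object of class `cont_raster`.
#' @export
cont_raster <- function(values, spec = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spec)) spec <- grid_spec(nrow(values), ncol(values))
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values outside the nodata mask")
  structure(list(values = values, spec = spec), class = "cont_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  tab <- table(factor(x$codes, levels = x$legend,
                      labels = names(x$legend)))
  cat(sprintf("<land_raster> %d x %d, cell %g m\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size))
  print(tab)
  invisible(x)
}

#' @export
print.cont_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<cont_raster> %d x %d, cell %g m, range [%g, %g]\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# ---- I/O: ESRI ASCII grid -------------------------------------------------

#' Read a raster from an ESRI ASCII grid file
#'
#' The plain-text `.asc` format (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header followed by rows from the top of the grid) is the
#' only supported container: it round-trips integer class codes exactly
#' and needs no binary geospatial library. GeoTIFF input is refused with
#' an informative error.
#'
#' @param path file path to an `.asc` grid.
#' @param kind `"categorical"` for a [land_raster()], `"continuous"` for a
#'   [cont_raster()].
#' @param legend legend used for categorical rasters.
#' @param ref optional reference [grid_spec()]; a mismatch is an error.
#' @return a `land_raster` or `cont_raster`.
#' @export
read_raster <- function(path, kind = c("categorical", "continuous"),
                        legend = default_legend(), ref = NULL) {
  kind <- match.arg(kind)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF is not supported by this build; convert to ESRI ASCII grid",
         call. = FALSE)
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  n_hdr <- 5L + ("nodata_value" %in% names(hdr))
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- grid_spec(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                    as.integer(nodata))
  if (!is.null(ref) && !same_spec(list(spec = spec)$spec, ref))
    stop("grid mismatch against reference grid_spec", call. = FALSE)
  if (kind == "categorical") land_raster(m, spec, legend)
  else cont_raster(m, spec)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param r a `land_raster` or `cont_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  spec <- r$spec
  m <- if (inherits(r, "land_raster")) r$codes else r$values
  hdr <- c(sprintf("ncols %d", spec$n_cols),
           sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.10g", spec$xll),
           sprintf("yllcorner %.10g", spec$yll),
           sprintf("cellsize %.10g", spec$cell_size),
           sprintf("NODATA_value %d", spec$nodata))
  m[is.na(m)] <- spec$nodata
  body <- apply(m, 1L, function(row)
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- basic raster operations ---------------------------------------------

cell_area_km2 <- function(spec) (spec$cell_size / 1000)^2

#' Area occupied by one land-use class
#'
#' @param r a [land_raster()].
#' @param code class code (must be in the legend).
#' @return area in km^2 (cell count times cell area).
#' @export
area_of <- function(r, code) {
  stopifnot(inherits(r, "land_raster"))
  if (!code %in% r$legend) stop("unknown class code: ", code, call. = FALSE)
  sum(r$codes == code, na.rm = TRUE) * cell_area_km2(r$spec)
}

#' Euclidean distance to the nearest source cell
#'
#' Exact Euclidean distance transform (two-pass separable lower-envelope
#' algorithm on squared distances). Distances are between cell centres, in
#' metres; source cells are at distance 0. Nodata cells receive a distance
#' too (threat kernels are truncated later), but are never sources unless
#' coded.
#'
#' @param r a [land_raster()].
#' @param codes source class code(s).
#' @return a [cont_raster()] of distances (m).
#' @export
euclidean_distance <- function(r, codes) {
  stopifnot(inherits(r, "land_raster"))
  src <- matrix(FALSE, r$spec$n_rows, r$spec$n_cols)
  src[!is.na(r$codes) & r$codes %in% codes] <- TRUE
  if (!any(src)) stop("no source cells for codes ",
                      paste(codes, collapse = ","), call. = FALSE)
  d2 <- edt_squared(src)
  cont_raster(sqrt(d2) * r$spec$cell_size, r$spec)
}

# Squared EDT in cell units. Felzenszwalb & Huttenlocher 1-D transform
# applied to columns then rows.
edt_squared <- function(src) {
  INF <- .Machine$double.xmax / 4
  f <- matrix(INF, nrow(src), ncol(src))
  f[src] <- 0
  for (j in seq_len(ncol(f))) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt1d(f[i, ])
  f
}

dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}
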