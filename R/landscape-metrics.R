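#' Label patches (connected components of same-class cells)
#'
#' A patch is a maximal set of same-class cells connected under the chosen
#' adjacency rule. Patch definition defaults to 8-neighbour (queen)
#' connectivity while all adjacency counts used by the metrics are rook
#' (4-neighbour), following the de-facto raster-metrics convention.
#'
#' @param r a [land_raster()].
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return object of class `patch_labeling`: `labels` (integer matrix, NA on
#'   nodata), `patches` (data.frame: id, code, cells, perimeter in cell
#'   edges), plus the source raster and the rule.
#' @export
label_patches <- function(r, connectivity = 8) {
  stopifnot(inherits(r, "land_raster"), connectivity %in% c(4, 8))
  codes <- r$codes
  nr <- nrow(codes); nc <- ncol(codes)
  labels <- matrix(NA_integer_, nr, nc)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  n_patch <- 0L
  ids <- integer(0); pcode <- integer(0); pcells <- integer(0)
  stack <- integer(nr * nc)
  for (start in seq_len(nr * nc)) {
    if (is.na(codes[start]) || !is.na(labels[start])) next
    n_patch <- n_patch + 1L
    cl <- codes[start]
    top <- 1L; stack[1L] <- start
    labels[start] <- n_patch
    cnt <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      cnt <- cnt + 1L
      ci <- (cur - 1L) %% nr + 1L
      cj <- (cur - 1L) %/% nr + 1L
      for (d in seq_along(dr)) {
        ni <- ci + dr[d]; nj <- cj + dc[d]
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        nidx <- (nj - 1L) * nr + ni
        if (!is.na(codes[nidx]) && codes[nidx] == cl &&
            is.na(labels[nidx])) {
          labels[nidx] <- n_patch
          top <- top + 1L; stack[top] <- nidx
        }
      }
    }
    ids <- c(ids, n_patch); pcode <- c(pcode, cl); pcells <- c(pcells, cnt)
  }
  perim_cell <- cell_perimeter(codes)
  perim <- if (n_patch > 0)
    as.vector(rowsum(perim_cell[!is.na(labels)],
                     labels[!is.na(labels)])[as.character(ids), 1])
  else numeric(0)
  structure(list(labels = labels,
                 patches = data.frame(id = ids, code = pcode,
                                      cells = pcells, perimeter = perim),
                 raster = r, connectivity = connectivity),
            class = "patch_labeling")
}

# per-cell count of rook sides facing a different class, nodata, or the
# grid boundary (cell-edge units)
cell_perimeter <- function(codes) {
  nr <- nrow(codes); nc <- ncol(codes)
  p <- matrix(0L, nr, nc)
  diffed <- function(a, b) is.na(b) | (a != b)
  up    <- rbind(codes[-1, , drop = FALSE], NA)      # neighbour below
  down  <- rbind(NA, codes[-nr, , drop = FALSE])     # neighbour above
  left  <- cbind(NA, codes[, -nc, drop = FALSE])
  right <- cbind(codes[, -1, drop = FALSE], NA)
  for (nb in list(up, down, left, right))
    p <- p + (diffed(codes, nb) & !is.na(codes))
  p
}

# class-by-class rook adjacency counts, double-count convention:
# every unordered adjacent pair (a, b) increments G[a,b] and G[b,a],
# so like adjacencies g_ii appear twice. Single-count g_ii = G_ii / 2.
adjacency_counts <- function(r) {
  codes <- r$codes
  lv <- unname(r$legend)
  nr <- nrow(codes); nc <- ncol(codes)
  a <- c(codes[-nr, , drop = FALSE], codes[, -nc, drop = FALSE])
  b <- c(codes[-1, , drop = FALSE], codes[, -1, drop = FALSE])
  keep <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[keep], levels = lv), factor(b[keep], levels = lv))
  G <- unclass(tab) + t(unclass(tab))
  dimnames(G) <- list(names(r$legend), names(r$legend))
  G
}

# minimum perimeter of an integer-sided quasi-square of a cells
min_perimeter <- function(a) {
  n <- floor(sqrt(a))
  ifelse(a == n^2, 4 * n, ifelse(a <= n * (n + 1), 4 * n + 2, 4 * n + 4))
}

# like-adjacency count (single count) of the maximally clumped
# quasi-square arrangement of a cells
max_like_adjacencies <- function(a) {
  n <- floor(sqrt(a))
  m <- a - n^2
  ifelse(m == 0, 2 * n * (n - 1),
         ifelse(m <= n, 2 * n * (n - 1) + 2 * m - 1,
                2 * n * (n - 1) + 2 * m - 2))
}

#' Class-level pattern metrics
#'
#' NP (patch count), PD (patches per km^2 of landscape), LPI (largest patch
#' as % of landscape area), LSI (class edge over the minimum edge of a
#' quasi-square of the same area), AI (% of the maximum possible like
#' adjacencies). Landscape boundary edges count toward perimeter but not
#' toward adjacencies. Classes absent from the raster are omitted; AI is NA
#' for single-cell classes (no like adjacency is possible).
#'
#' @param pl a [label_patches()] result.
#' @return data.frame, one row per non-empty class.
#' @export
class_metrics <- function(pl) {
  stopifnot(inherits(pl, "patch_labeling"))
  r <- pl$raster
  p <- pl$patches
  total_cells <- sum(!is.na(r$codes))
  a_km2 <- total_cells * cell_area_km2(r$spec)
  G <- adjacency_counts(r)
  out <- lapply(unname(r$legend), function(code) {
    sel <- p$code == code
    if (!any(sel)) return(NULL)
    cells <- sum(p$cells[sel])
    gii <- G[match(code, r$legend), match(code, r$legend)] / 2
    maxg <- max_like_adjacencies(cells)
    data.frame(class = names(r$legend)[match(code, r$legend)], code = code,
               np = sum(sel),
               pd = sum(sel) / a_km2,
               lpi = max(p$cells[sel]) / total_cells * 100,
               lsi = sum(p$perimeter[sel]) / min_perimeter(cells),
               ai = if (maxg > 0) gii / maxg * 100 else NA_real_)
  })
  do.call(rbind, out)
}

#' Landscape-level pattern metrics
#'
#' NP, PD, LSI (total edge over the minimum edge of a quasi-square of the
#' whole landscape), SPLIT (A^2 over the sum of squared patch areas), SHDI
#' (Shannon diversity of class proportions), AI (class-proportion-weighted
#' class AI), and CONTAG (contagion from class proportions and rook
#' adjacency frequencies, double-count convention). CONTAG is NA for a
#' single-class landscape.
#'
#' @param pl a [label_patches()] result.
#' @return one-row data.frame.
#' @export
landscape_metrics <- function(pl) {
  stopifnot(inherits(pl, "patch_labeling"))
  r <- pl$raster
  p <- pl$patches
  total_cells <- sum(!is.na(r$codes))
  a_km2 <- total_cells * cell_area_km2(r$spec)
  counts <- tabulate_codes(r)
  pi <- counts[counts > 0] / total_cells
  present <- unname(r$legend)[counts > 0]
  m <- length(present)
  # total edge: boundary/nodata sides once + inter-class rook pairs once
  G <- adjacency_counts(r)
  inter <- (sum(G) - sum(diag(G))) / 2
  boundary <- sum(cell_perimeter(r$codes)) - 2 * inter
  cm <- class_metrics(pl)
  w <- pi[match(cm$code, present)]
  ai_l <- if (all(!is.na(cm$ai))) sum(w * cm$ai) else
    sum(w[!is.na(cm$ai)] * cm$ai[!is.na(cm$ai)])
  contag <- if (m < 2) NA_real_ else {
    Gp <- G[counts > 0, counts > 0, drop = FALSE]
    rs <- rowSums(Gp)
    acc <- 0
    for (i in seq_len(m)) {
      if (rs[i] == 0) next
      for (k in seq_len(m)) {
        t_ik <- pi[i] * Gp[i, k] / rs[i]
        if (t_ik > 0) acc <- acc + t_ik * log(t_ik)
      }
    }
    (1 + acc / (2 * log(m))) * 100
  }
  data.frame(np = nrow(p),
             pd = nrow(p) / a_km2,
             lsi = (boundary + inter) / min_perimeter(total_cells),
             split = unname(total_cells^2 / sum(p$cells^2)),
             shdi = unname(-sum(pi * log(pi))),
             ai = unname(ai_l),
             contag = unname(contag),
             row.names = NULL)
}
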