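# Independent definitional oracles used by the property and acceptance
# suites. These deliberately avoid the production code paths: distances by
# all-pairs minimisation, degradation by an explicit per-cell loop, patch
# labels by iterative label propagation, metrics by direct evaluation of
# their defining formulas.

random_land <- function(nr, nc, k = 3, seed = 1, p = NULL,
                        legend = stats::setNames(seq_len(k),
                                                 paste0("c", seq_len(k)))) {
  set.seed(seed)
  land_raster(matrix(sample(seq_len(k), nr * nc, TRUE, prob = p), nr, nc),
              legend = legend)
}

# all-pairs minimum distance to a source cell (cell units)
oracle_distance <- function(src) {
  nr <- nrow(src); nc <- ncol(src)
  sp <- which(src, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- sqrt(min((sp[, 1] - i)^2 + (sp[, 2] - j)^2))
  }
  out
}

# degradation by direct summation over threat cells, cell by cell
oracle_degradation <- function(lu, threats, sens) {
  cs <- lu$spec$cell_size
  nr <- lu$spec$n_rows; nc <- lu$spec$n_cols
  wsum <- sum(threats$weight)
  D <- matrix(0, nr, nc)
  for (t in seq_len(nrow(threats))) {
    ty <- which(lu$codes == threats$code[t], arr.ind = TRUE)
    if (nrow(ty) == 0) next
    dmax <- threats$d_max_km[t] * 1000
    scol <- sens[[threats$threat[t]]]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(lu$codes[i, j])) next
      d <- cs * sqrt((ty[, 1] - i)^2 + (ty[, 2] - j)^2)
      imp <- ifelse(d <= dmax,
                    if (threats$decay[t] == "linear") pmax(0, 1 - d / dmax)
                    else exp(-(2.99 / dmax) * d),
                    0)
      s <- scol[match(lu$codes[i, j], sens$code)]
      D[i, j] <- D[i, j] + (threats$weight[t] / wsum) * sum(imp) * s
    }
  }
  D[is.na(lu$codes)] <- NA
  D
}

# connected components by iterative min-label propagation to a fixpoint
oracle_patches <- function(codes, connectivity = 8) {
  nr <- nrow(codes); nc <- ncol(codes)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[is.na(codes)] <- NA
  moves <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    moves <- rbind(moves, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(codes[i, j])) next
      for (m in seq_len(nrow(moves))) {
        a <- i + moves[m, 1]; b <- j + moves[m, 2]
        if (a < 1 || a > nr || b < 1 || b > nc) next
        if (!is.na(codes[a, b]) && codes[a, b] == codes[i, j] &&
            lab[a, b] < lab[i, j]) {
          lab[i, j] <- lab[a, b]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# rook adjacency counts between classes, double-count convention: each
# unordered pair contributes 1 to G[i,k] and 1 to G[k,i] (so 2 to the
# diagonal when i == k); like adjacencies single-count = diag(G)/2
oracle_adjacency <- function(codes, classes) {
  K <- length(classes)
  G <- matrix(0, K, K)
  nr <- nrow(codes); nc <- ncol(codes)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (m in list(c(0, 1), c(1, 0))) {
      a <- i + m[1]; b <- j + m[2]
      if (a > nr || b > nc) next
      c1 <- codes[i, j]; c2 <- codes[a, b]
      if (is.na(c1) || is.na(c2)) next
      i1 <- match(c1, classes); i2 <- match(c2, classes)
      G[i1, i2] <- G[i1, i2] + 1
      G[i2, i1] <- G[i2, i1] + 1
    }
  }
  G
}

# direct evaluation of every metric definition on one raster
oracle_metrics <- function(r, connectivity = 8) {
  codes <- r$codes
  lab <- oracle_patches(codes, connectivity)
  ids <- unique(lab[!is.na(lab)])
  cells <- vapply(ids, function(id) sum(lab == id, na.rm = TRUE), numeric(1))
  pcode <- vapply(ids, function(id) codes[which(lab == id)[1]], numeric(1))
  nr <- nrow(codes); nc <- ncol(codes)
  perim <- vapply(ids, function(id) {
    p <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(lab[i, j]) || lab[i, j] != id) next
      for (m in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- i + m[1]; b <- j + m[2]
        if (a < 1 || a > nr || b < 1 || b > nc || is.na(codes[a, b]) ||
            codes[a, b] != codes[i, j]) p <- p + 1
      }
    }
    p
  }, numeric(1))
  total <- sum(!is.na(codes))
  a_km2 <- total * (r$spec$cell_size / 1000)^2
  classes <- unname(r$legend)
  G <- oracle_adjacency(codes, classes)
  quasi_min_e <- function(a) {
    n <- floor(sqrt(a))
    if (a == n^2) 4 * n else if (a <= n * (n + 1)) 4 * n + 2 else 4 * n + 4
  }
  quasi_max_g <- function(a) {
    n <- floor(sqrt(a)); m <- a - n^2
    if (m == 0) 2 * n * (n - 1)
    else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
    else 2 * n * (n - 1) + 2 * m - 2
  }
  cls <- lapply(classes, function(cd) {
    sel <- pcode == cd
    if (!any(sel)) return(NULL)
    a_i <- sum(cells[sel])
    gii <- G[match(cd, classes), match(cd, classes)] / 2
    maxg <- quasi_max_g(a_i)
    data.frame(code = cd, np = sum(sel),
               pd = sum(sel) / a_km2,
               lpi = max(cells[sel]) / total * 100,
               lsi = sum(perim[sel]) / quasi_min_e(a_i),
               ai = if (maxg > 0) gii / maxg * 100 else NA_real_)
  })
  cls <- do.call(rbind, cls)
  p_i <- vapply(classes, function(cd) sum(codes == cd, na.rm = TRUE),
                numeric(1)) / total
  pres <- p_i > 0
  m <- sum(pres)
  shdi <- -sum(p_i[pres] * log(p_i[pres]))
  split <- total^2 / sum(cells^2)
  inter <- 0
  for (i in seq_len(length(classes))) for (k in seq_len(length(classes)))
    if (i != k) inter <- inter + G[i, k]
  inter <- inter / 2
  boundary <- sum(perim) - 2 * inter
  contag <- if (m < 2) NA_real_ else {
    G2 <- G
    acc <- 0
    for (i in which(pres)) {
      rsum <- sum(G2[i, ])
      if (rsum == 0) next
      for (k in which(pres)) {
        t_ik <- p_i[i] * G2[i, k] / rsum
        if (t_ik > 0) acc <- acc + t_ik * log(t_ik)
      }
    }
    (1 + acc / (2 * log(m))) * 100
  }
  ai_w <- cls$ai
  w <- p_i[match(cls$code, classes)]
  ai_l <- sum(w[!is.na(ai_w)] * ai_w[!is.na(ai_w)])
  list(class = cls,
       landscape = data.frame(np = length(ids), pd = length(ids) / a_km2,
                              lsi = (boundary + inter) / quasi_min_e(total),
                              split = split, shdi = shdi, ai = ai_l,
                              contag = contag))
}

# q-statistic straight from its definition
oracle_q <- function(y, s) {
  keep <- !is.na(y) & !is.na(s)
  y <- y[keep]; s <- s[keep]
  N <- length(y)
  sst <- N * mean((y - mean(y))^2)
  ssw <- 0
  for (h in unique(s)) {
    g <- y[s == h]
    ssw <- ssw + length(g) * mean((g - mean(g))^2)
  }
  1 - ssw / sst
}
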