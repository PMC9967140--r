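#' Discretise a continuous raster into strata
#'
#' Default is Jenks natural breaks (exact Fisher dynamic programming on the
#' weighted distinct values; when more than `max_support` distinct values
#' are present the optimisation runs on an evenly spaced quantile grid of
#' that size, which is the standard large-n approximation). Also offers
#' quantile and equal-interval binning. Labels are ordered with the values.
#'
#' @param x a [cont_raster()] or numeric matrix.
#' @param n_classes number of strata (default 7, the usual grading for
#'   driver factors).
#' @param method `"jenks"` (default), `"quantile"` or `"equal"`.
#' @param max_support cap on distinct support points for the Jenks DP.
#' @return object of class `strata_layer`: `strata` (integer matrix in
#'   `1..L`), `breaks`, `L`, `method`.
#' @export
discretize <- function(x, n_classes = 7, method = c("jenks", "quantile",
                                                    "equal"),
                       max_support = 2048) {
  method <- match.arg(method)
  v <- if (inherits(x, "cont_raster")) x$values else as.matrix(x)
  vals <- v[!is.na(v)]
  ux <- sort(unique(vals))
  L <- n_classes
  if (length(ux) < n_classes) {
    warning("fewer distinct values (", length(ux), ") than classes (",
            n_classes, "); reducing")
    L <- max(1L, length(ux))
  }
  breaks <- if (L == 1L) c(-Inf, Inf) else switch(method,
    equal = {
      b <- seq(min(vals), max(vals), length.out = L + 1)
      c(-Inf, b[-c(1, L + 1)], Inf)
    },
    quantile = {
      b <- unique(stats::quantile(vals, probs = seq(0, 1, length.out = L + 1),
                                  names = FALSE))
      c(-Inf, b[-c(1, length(b))], Inf)
    },
    jenks = {
      b <- jenks_breaks(vals, L, max_support = max_support)
      c(-Inf, b, Inf)
    })
  strata <- matrix(NA_integer_, nrow(v), ncol(v))
  strata[!is.na(v)] <- as.integer(cut(vals, breaks, labels = FALSE,
                                      right = FALSE))
  structure(list(strata = strata,
                 breaks = breaks,
                 L = length(unique(strata[!is.na(strata)])),
                 method = method),
            class = "strata_layer")
}

#' Wrap an existing categorical layer as strata
#'
#' Categorical drivers (land-use type, soil type) enter the detector as-is.
#'
#' @param r a [land_raster()] or integer matrix.
#' @return a `strata_layer`.
#' @export
as_strata <- function(r) {
  m <- if (inherits(r, "land_raster")) r$codes else as.matrix(r)
  lev <- sort(unique(m[!is.na(m)]))
  s <- matrix(match(m, lev), nrow(m), ncol(m))
  structure(list(strata = s, breaks = NULL, L = length(lev),
                 method = "categorical"),
            class = "strata_layer")
}

# Exact Fisher-Jenks on weighted distinct values: minimise within-class
# sum of squared deviations. Returns the k-1 interior break values
# (lower edge of each class but the first).
jenks_breaks <- function(x, k, max_support = 2048) {
  ux <- sort(unique(x))
  if (length(ux) > max_support) {
    grid <- stats::quantile(x, probs = seq(0, 1, length.out = max_support),
                            names = FALSE)
    idx <- findInterval(x, grid, all.inside = TRUE)
    # snap each value to its grid cell midpoint representative
    ux <- sort(unique(grid))
    x <- grid[idx]
  }
  vals <- sort(unique(x))
  n <- length(vals)
  if (k >= n) return(vals[-1])
  w <- as.numeric(table(factor(x, levels = vals)))
  cw <- c(0, cumsum(w)); cwx <- c(0, cumsum(w * vals))
  cwx2 <- c(0, cumsum(w * vals^2))
  # within-SS of vals[i..j] for a vector of i at fixed j (prefix sums)
  ssd_vec <- function(i, j) {
    W <- cw[j + 1] - cw[i]
    S <- cwx[j + 1] - cwx[i]
    (cwx2[j + 1] - cwx2[i]) - S^2 / W
  }
  D <- matrix(Inf, k, n)   # D[c, j]: best within-SS for vals[1..j] in c classes
  B <- matrix(0L, k, n)
  D[1, ] <- ssd_vec(rep(1L, n), seq_len(n))
  if (k > 1) for (cc in 2:k) {
    for (j in cc:n) {
      i <- cc:j
      cand <- D[cc - 1, i - 1] + ssd_vec(i, j)
      best <- which.min(cand)
      D[cc, j] <- cand[best]; B[cc, j] <- i[best]
    }
  }
  cuts <- integer(k - 1)
  j <- n
  for (cc in k:2) {
    cuts[cc - 1] <- B[cc, j]
    j <- B[cc, j] - 1L
  }
  vals[cuts]
}

#' Factor-detector q-statistic
#'
#' q = 1 - sum_h N_h sigma_h^2 / (N sigma^2) with population variances, so
#' q is exactly 1 - SSW/SST: the share of the spatial variance of `y`
#' explained by the stratification. Significance by permutation of the
#' stratum labels over cells.
#'
#' @param y outcome [cont_raster()] or numeric matrix.
#' @param strata a `strata_layer` (or matrix of labels).
#' @param n_perm permutation replicates for the p-value (default 999; 0
#'   skips the test).
#' @return object of class `q_result`: `q`, `p`, `n`, `L`, per-stratum
#'   table.
#' @export
factor_q <- function(y, strata, n_perm = 999) {
  v <- if (inherits(y, "cont_raster")) y$values else as.matrix(y)
  s <- if (inherits(strata, "strata_layer")) strata$strata
       else as.matrix(strata)
  stopifnot(all(dim(v) == dim(s)))
  keep <- !is.na(v) & !is.na(s)
  yv <- v[keep]; sv <- s[keep]
  n <- length(yv)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  sst <- sum((yv - mean(yv))^2)
  if (sst <= 0) stop("outcome is constant; q undefined", call. = FALSE)
  q <- q_from_labels(yv, sv, sst)
  p <- NA_real_
  if (n_perm > 0) {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      qb <- q_from_labels(yv, sample(sv), sst)
      if (qb >= q) ge <- ge + 1L
    }
    p <- (ge + 1) / (n_perm + 1)
  }
  grp <- split(yv, sv)
  tab <- data.frame(stratum = names(grp),
                    n = lengths(grp),
                    mean = vapply(grp, mean, numeric(1)),
                    var_pop = vapply(grp, function(g)
                      mean((g - mean(g))^2), numeric(1)),
                    row.names = NULL)
  structure(list(q = q, p = p, n = n, L = length(grp), strata_table = tab),
            class = "q_result")
}

q_from_labels <- function(yv, sv, sst) {
  gs <- rowsum(cbind(yv, yv^2, 1), sv)
  ssw <- sum(gs[, 2] - gs[, 1]^2 / gs[, 3])
  max(0, min(1, 1 - ssw / sst))
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> q = %.4f (L = %d strata, n = %d cells", x$q,
              x$L, x$n))
  if (!is.na(x$p)) cat(sprintf(", permutation p = %.3f", x$p))
  cat(")\n")
  invisible(x)
}

#' Interaction detector
#'
#' q of the cross-product stratification of two factors, classified against
#' the single-factor q values: nonlinear weaken (q12 < min), single-factor
#' weaken (min <= q12 < max), bivariate enhance (q12 > max), independent
#' (q12 = q1 + q2), nonlinear enhance (q12 > q1 + q2).
#'
#' @param y outcome raster.
#' @param s1,s2 `strata_layer`s.
#' @param n_perm permutations for the interaction q (default 0: the
#'   classification, not the test, is usually wanted).
#' @return list: `q12` (a `q_result`), `q1`, `q2`, `interaction` label.
#' @export
interaction_q <- function(y, s1, s2, n_perm = 0) {
  m1 <- if (inherits(s1, "strata_layer")) s1$strata else as.matrix(s1)
  m2 <- if (inherits(s2, "strata_layer")) s2$strata else as.matrix(s2)
  stopifnot(all(dim(m1) == dim(m2)))
  cross <- matrix(NA_integer_, nrow(m1), ncol(m1))
  ok <- !is.na(m1) & !is.na(m2)
  cross[ok] <- (m1[ok] - 1L) * (max(m2, na.rm = TRUE) + 1L) + m2[ok]
  q1 <- factor_q(y, m1, n_perm = 0)$q
  q2 <- factor_q(y, m2, n_perm = 0)$q
  r12 <- factor_q(y, cross, n_perm = n_perm)
  tol <- 1e-9
  lab <- if (r12$q < min(q1, q2) - tol) "nonlinear_weaken"
    else if (r12$q < max(q1, q2) - tol) "single_factor_weaken"
    else if (abs(r12$q - (q1 + q2)) <= tol) "independent"
    else if (r12$q > q1 + q2 + tol) "nonlinear_enhance"
    else "bivariate_enhance"
  list(q12 = r12, q1 = q1, q2 = q2, interaction = lab)
}
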