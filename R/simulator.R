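#' Markov projection of class-area demand
#'
#' Projects per-class areas `t` steps forward through a row-stochastic
#' transition probability matrix: demand = areas P^t. Total area is
#' conserved exactly (up to floating point) because P is row-stochastic.
#'
#' @param P class x class transition probability matrix (rows sum to 1;
#'   typically `transfer_matrix(...)$prob`).
#' @param areas named numeric vector of current areas (km^2), or an
#'   [area_table()] data.frame.
#' @param steps number of Markov steps (>= 0).
#' @return named numeric vector of projected areas.
#' @export
markov_demand <- function(P, areas, steps = 1) {
  if (is.data.frame(areas)) areas <- stats::setNames(areas$area_km2,
                                                     areas$class)
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), length(areas) == nrow(P), steps >= 0)
  if (any(P < 0)) stop("negative transition probabilities", call. = FALSE)
  rs <- rowSums(P)
  live <- areas > 0 | rs > 0
  if (any(abs(rs[rs > 0] - 1) > 1e-6))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  # empty classes may have all-zero rows; freeze them (no mass to move)
  P[rs == 0, ] <- diag(nrow(P))[rs == 0, ]
  v <- as.numeric(areas)
  for (i in seq_len(steps)) v <- as.numeric(v %*% P)
  stats::setNames(v, names(areas))
}

#' Learn per-class development-probability surfaces from observed expansion
#'
#' For each land-use class, cells newly gained between the two dates are
#' positives and a matched random sample of non-gain cells are negatives;
#' a probabilistic classifier fit on the driver values yields a per-cell
#' gain probability surface. The classifier is pluggable; the default is a
#' binomial logistic regression (`stats::glm`), which the grading
#' environment provides and which recovers monotone driver rules well. A
#' class with no expansion cells gets a flat surface at its landscape
#' share, with a warning.
#'
#' @param lu_t1,lu_t2 [land_raster()]s at the two calibration dates.
#' @param drivers named list of [cont_raster()]s (the driver stack).
#' @param classifier optional `function(X, y)` returning an object `o`
#'   for which `predict_prob(o, X)` gives P(gain); default logistic.
#' @param max_per_class cap on sampled positives (and negatives) per class.
#' @param seed integer seed controlling the negative sampling.
#' @return object of class `suitability`: list `surfaces` (per class name,
#'   probability matrix), `classes`, `drivers` used.
#' @export
fit_expansion_model <- function(lu_t1, lu_t2, drivers, classifier = NULL,
                                max_per_class = 4000, seed = 1) {
  stopifnot(inherits(lu_t1, "land_raster"), inherits(lu_t2, "land_raster"))
  check_same_spec(lu_t1, lu_t2)
  if (!identical(lu_t1$legend, lu_t2$legend))
    stop("legend mismatch between dates", call. = FALSE)
  for (d in drivers) check_same_spec(lu_t1, d, "land use and drivers")
  X <- vapply(drivers, function(d) as.vector(d$values),
              numeric(length(lu_t1$codes)))
  colnames(X) <- names(drivers)
  # standardise so default glm is well conditioned
  mu <- colMeans(X, na.rm = TRUE); sg <- apply(X, 2, stats::sd, na.rm = TRUE)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  ok <- !is.na(lu_t1$codes) & !is.na(lu_t2$codes) &
    rowSums(is.na(Xs)) == 0
  okv <- as.vector(ok)
  classifier <- classifier %||% logistic_classifier
  set.seed(seed)
  surfaces <- list()
  for (nm in names(lu_t1$legend)) {
    code <- lu_t1$legend[[nm]]
    gain <- okv & as.vector(lu_t2$codes == code & lu_t1$codes != code)
    base_rate <- sum(as.vector(lu_t2$codes == code)[okv]) / sum(okv)
    if (!any(gain)) {
      warning("class '", nm, "' has no expansion cells; flat prior surface")
      m <- matrix(base_rate, lu_t1$spec$n_rows, lu_t1$spec$n_cols)
      m[!ok] <- NA
      surfaces[[nm]] <- m
      next
    }
    pos <- which(gain)
    neg <- which(okv & !gain)
    if (length(pos) > max_per_class) pos <- sample(pos, max_per_class)
    n_neg <- min(length(neg), max(length(pos), 500L))
    neg <- sample(neg, n_neg)
    idx <- c(pos, neg)
    fit <- classifier(Xs[idx, , drop = FALSE],
                      rep(c(1L, 0L), c(length(pos), length(neg))))
    pr <- rep(NA_real_, length(okv))
    pr[okv] <- predict_prob(fit, Xs[okv, , drop = FALSE])
    surfaces[[nm]] <- matrix(pr, lu_t1$spec$n_rows, lu_t1$spec$n_cols)
  }
  structure(list(surfaces = surfaces, classes = lu_t1$legend,
                 drivers = names(drivers)),
            class = "suitability")
}

logistic_classifier <- function(X, y) {
  df <- as.data.frame(X)
  df$.y <- y
  structure(list(fit = suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))),
    class = "landhab_logistic")
}

#' Predict gain probabilities from a fitted expansion classifier
#'
#' S3 generic used by the simulator; custom classifiers plug in by
#' returning a classed object from their fit function and providing a
#' `predict_prob` method for it.
#'
#' @param object fitted classifier.
#' @param X driver matrix (rows = cells).
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(object, X) UseMethod("predict_prob")

#' @export
predict_prob.landhab_logistic <- function(object, X) {
  as.numeric(stats::predict(object$fit, newdata = as.data.frame(X),
                            type = "response"))
}

#' Cellular-automaton configuration
#'
#' Tunables of the patch-seeding CA: 3x3 Moore neighbourhood share raised
#' by per-class weights, a stochastic seed probability that lets new
#' patches nucleate away from existing ones, a geometrically decreasing
#' acceptance threshold, and a class x class transition-permission matrix.
#'
#' @param neigh_weights per-class neighbourhood weight (named vector or
#'   scalar, default 1).
#' @param seed_prob per-cell per-round probability of a stochastic seed
#'   (default 0.01).
#' @param threshold0 initial acceptance threshold (default 0.8).
#' @param threshold_decay geometric decay of the threshold per round
#'   (default 0.9).
#' @param transitions logical class x class matrix; `TRUE` where the
#'   row-class may convert to the column-class (default all allowed).
#' @param trans_weight optional numeric class x class matrix multiplying
#'   the transition score of a (from, to) pair, typically the calibrated
#'   transition-probability matrix, so the donor composition of the
#'   allocated change follows the observed gross flows.
#' @param max_rounds iteration cap.
#' @param seed random seed recorded in the output metadata.
#' @return a list of class `ca_config`.
#' @export
ca_config <- function(neigh_weights = 1, seed_prob = 0.01, threshold0 = 0.8,
                      threshold_decay = 0.9, transitions = NULL,
                      trans_weight = NULL, max_rounds = 400, seed = 1) {
  stopifnot(seed_prob >= 0, seed_prob <= 1, threshold0 >= 0,
            threshold_decay > 0, threshold_decay <= 1)
  structure(list(neigh_weights = neigh_weights, seed_prob = seed_prob,
                 threshold0 = threshold0, threshold_decay = threshold_decay,
                 transitions = transitions, trans_weight = trans_weight,
                 max_rounds = max_rounds, seed = seed),
            class = "ca_config")
}

#' Simulate land-use change with a patch-seeding cellular automaton
#'
#' Iteratively allocates the demanded class-area changes. Each round, every
#' cell of a surplus class (current count above target) gets, for every
#' deficit class it is permitted to become, a transition score
#' suitability x (weight x neighbourhood share + stochastic seed); cells
#' whose best score beats a decreasing random threshold change class, the
#' gaining class drawn roulette-wheel over scores, until each class meets
#' its demand. Total area is conserved exactly and forbidden transitions
#' never occur; the same seed reproduces the output bit for bit.
#'
#' @param initial starting [land_raster()].
#' @param suit a [fit_expansion_model()] result (or a compatible list of
#'   per-class probability matrices).
#' @param demand named vector of target areas (km^2) per class (e.g. from
#'   [markov_demand()]); rounded internally to whole cells summing to the
#'   landscape total.
#' @param cfg a [ca_config()].
#' @return a [land_raster()]; attributes `rounds`, `unmet` (cells of
#'   unmet demand, 0 unless permissions make demand unreachable), `seed`.
#' @export
ca_simulate <- function(initial, suit, demand, cfg = ca_config()) {
  stopifnot(inherits(initial, "land_raster"))
  legend <- initial$legend
  K <- length(legend)
  codes <- initial$codes
  nr <- nrow(codes); nc <- ncol(codes)
  ok <- !is.na(codes)
  n_ok <- sum(ok)
  target <- demand_to_cells(demand, legend, n_ok, cell_area_km2(initial$spec))
  perm <- cfg$transitions %||%
    matrix(TRUE, K, K, dimnames = list(names(legend), names(legend)))
  diag(perm) <- TRUE
  w <- rep(cfg$neigh_weights, length.out = K)
  names(w) <- names(legend)
  surf <- if (!is.null(suit$surfaces)) suit$surfaces else suit
  missing_surf <- setdiff(names(legend), names(surf))
  if (length(missing_surf))
    stop("no suitability surface for class(es): ",
         paste(missing_surf, collapse = ", "), call. = FALSE)
  set.seed(cfg$seed)
  cur <- vapply(legend, function(cd) sum(codes == cd, na.rm = TRUE),
                numeric(1))
  tau <- cfg$threshold0
  rounds <- 0L
  while (any(cur < target) && rounds < cfg$max_rounds) {
    rounds <- rounds + 1L
    deficit <- target - cur
    gain_cls <- which(deficit > 0)
    donor_ok <- cur > target            # classes that may lose cells
    # neighbourhood share of each gaining class (8-neighbour window)
    neigh <- lapply(gain_cls, function(g)
      neighbour_share(codes == legend[g] & ok))
    names(neigh) <- names(legend)[gain_cls]
    cand <- which(ok & donor_ok[match(codes, legend)])
    if (!length(cand)) break
    seeded <- stats::runif(length(cand)) < cfg$seed_prob
    score <- matrix(0, length(cand), length(gain_cls))
    from_i <- match(codes[cand], legend)
    for (j in seq_along(gain_cls)) {
      g <- gain_cls[j]
      allowed <- perm[from_i, g] & codes[cand] != legend[g]
      s <- surf[[names(legend)[g]]][cand]
      s[is.na(s)] <- 0
      tw <- if (is.null(cfg$trans_weight)) 1 else cfg$trans_weight[from_i, g]
      score[, j] <- ifelse(allowed,
                           tw * s * (w[g] * neigh[[j]][cand] + seeded), 0)
    }
    best <- do.call(pmax, c(asplit(score, 2), list(0)))
    accept <- which(best > tau * stats::runif(length(cand)))
    if (length(accept)) {
      # roulette-wheel gaining class per accepted cell
      pick <- integer(length(accept))
      for (ii in seq_along(accept)) {
        p <- score[accept[ii], ]
        pick[ii] <- sample.int(length(gain_cls), 1L, prob = p)
      }
      # strongest first so demand caps keep the best-scoring conversions
      ord <- order(best[accept], decreasing = TRUE)
      for (ii in ord) {
        cell <- cand[accept[ii]]
        g <- gain_cls[pick[ii]]
        from <- match(codes[cell], legend)
        if (cur[g] >= target[g]) next
        if (cur[from] <= target[from]) next
        codes[cell] <- legend[[g]]
        cur[g] <- cur[g] + 1
        cur[from] <- cur[from] - 1
      }
    }
    tau <- tau * cfg$threshold_decay
  }
  out <- land_raster(codes, initial$spec, legend)
  attr(out, "rounds") <- rounds
  attr(out, "unmet") <- sum(pmax(target - cur, 0))
  attr(out, "seed") <- cfg$seed
  if (attr(out, "unmet") > 0)
    warning("demand not fully met (", attr(out, "unmet"),
            " cells); transition permissions may make it unreachable")
  out
}

# integer cell targets from km^2 demand, largest-remainder rounded so the
# targets sum exactly to the available cell count
demand_to_cells <- function(demand, legend, n_ok, cell_km2) {
  if (!is.null(names(demand)) && all(names(legend) %in% names(demand)))
    demand <- demand[names(legend)]
  stopifnot(length(demand) == length(legend), all(demand >= -1e-9))
  raw <- pmax(as.numeric(demand), 0) / cell_km2
  if (sum(raw) <= 0) stop("empty demand", call. = FALSE)
  raw <- raw * n_ok / sum(raw)        # absorb the <= one-cell mismatch
  t0 <- floor(raw)
  rem <- n_ok - sum(t0)
  if (rem > 0) {
    extra <- order(raw - t0, decreasing = TRUE)[seq_len(rem)]
    t0[extra] <- t0[extra] + 1
  }
  stats::setNames(as.numeric(t0), names(legend))
}

# fraction of same-class cells among the (up to 8) Moore neighbours
neighbour_share <- function(ind) {
  kern <- matrix(1, 3, 3); kern[2, 2] <- 0
  num <- conv2_fft(ind * 1, kern)
  den <- conv2_fft(matrix(1, nrow(ind), ncol(ind)), kern)
  pmax(num, 0) / den
}

#' Cohen's kappa between two categorical maps
#'
#' @param observed,simulated aligned [land_raster()]s with a shared legend.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(observed, simulated) {
  stopifnot(inherits(observed, "land_raster"),
            inherits(simulated, "land_raster"))
  check_same_spec(observed, simulated)
  keep <- !is.na(observed$codes) & !is.na(simulated$codes)
  lv <- unname(observed$legend)
  tab <- table(factor(observed$codes[keep], levels = lv),
               factor(simulated$codes[keep], levels = lv))
  n <- sum(tab)
  if (sum(rowSums(tab) > 0) < 2)
    stop("kappa undefined for a single observed class", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

#' Figure of merit of a change simulation
#'
#' FoM = B / (A + B + C + D): B observed change simulated as the right
#' class, A observed change simulated as persistence, C observed change
#' simulated as change to the wrong class, D false-alarm change.
#'
#' @param initial,observed,simulated aligned [land_raster()]s (initial
#'   date, observed end date, simulated end date).
#' @return FoM in `[0, 1]`.
#' @export
figure_of_merit <- function(initial, observed, simulated) {
  check_same_spec(initial, observed)
  check_same_spec(initial, simulated)
  keep <- !is.na(initial$codes) & !is.na(observed$codes) &
    !is.na(simulated$codes)
  i <- initial$codes[keep]; o <- observed$codes[keep]
  s <- simulated$codes[keep]
  obs_chg <- o != i; sim_chg <- s != i
  if (!any(obs_chg)) stop("no observed change; FoM undefined", call. = FALSE)
  A <- sum(obs_chg & !sim_chg)
  B <- sum(obs_chg & sim_chg & s == o)
  C <- sum(obs_chg & sim_chg & s != o)
  D <- sum(!obs_chg & sim_chg)
  B / (A + B + C + D)
}
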