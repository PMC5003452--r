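# Automated threshold mapping (ATM): locate the knee of the probe-set
# retention curve and return a suggested cut-off x_ATM together with a
# target interval I' (candidate cut-offs) and a tolerance interval I
# (feasible cut-offs).
#
# Pipeline: project the (threshold, pairs, sets) curve onto a learning set,
# cluster it by fuzzy c-means, decode the hotspot from the anchors of the
# first two clusters, take the fuzzy boundary between those clusters, and
# invert the probe-set component of the curve at the boundary mean.

# ---------------------------------------------------------------------------
# Projection
# ---------------------------------------------------------------------------

#' Build an orthogonal projector from a basis matrix
#'
#' @param basis Numeric matrix `B` (3 x r) with independent columns.
#' @return List with elements `basis` and `projector`
#'   (`P = B (B'B)^{-1} B'`, idempotent and symmetric).
#' @export
projection_spec <- function(basis = matrix(c(0, 0, 1), ncol = 1)) {
  basis <- as.matrix(basis)
  if (nrow(basis) != 3L) stop("basis must have 3 rows")
  btb <- crossprod(basis)
  if (abs(det(btb)) < 1e-12) stop("basis columns are not independent")
  p <- basis %*% solve(btb, t(basis))
  list(basis = basis, projector = p)
}

#' Project a retention curve onto a learning set
#'
#' Each curve point `v = (x, pairs, sets)` is mapped through the projector;
#' the learning set is the resulting coordinate along the basis.  With the
#' default basis `[0,0,1]'` this is simply the retained probe-set component,
#' the coordinate the knee lives on.
#'
#' @param curve A [retention_curve()].
#' @param basis 3 x r basis matrix (default `[0,0,1]'`).
#' @return Numeric vector (one value per curve point): for a rank-1 basis,
#'   the coefficient of the projection along the (normalized) basis
#'   direction; for general bases, the norm of the projected vector signed
#'   by its dominant coordinate.
#' @export
project_curve <- function(curve, basis = matrix(c(0, 0, 1), ncol = 1)) {
  spec <- projection_spec(basis)
  v <- t(cbind(curve$threshold, curve$retained_pairs, curve$retained_sets))
  u <- spec$projector %*% v
  if (ncol(spec$basis) == 1L) {
    b <- spec$basis / sqrt(sum(spec$basis^2))
    as.vector(crossprod(b, u))
  } else {
    sgn <- sign(colSums(u * v))
    sgn[sgn == 0] <- 1
    sqrt(colSums(u^2)) * sgn
  }
}

# ---------------------------------------------------------------------------
# Fuzzy c-means
# ---------------------------------------------------------------------------

#' Fuzzy c-means clustering (1-D alternating optimization)
#'
#' Minimizes the weighted within-class sum of squares
#' \deqn{J_q = \sum_i \sum_j m_{ij}^q \, d_{ij}^2}
#' under the constraint that every membership column sums to 1, by
#' alternating the membership update
#' \eqn{m_{ij} = 1 / \sum_l (d_{ij}/d_{lj})^{2/(q-1)}} with the centroid
#' update \eqn{\omega_i = \sum_j m_{ij}^q u_j / \sum_j m_{ij}^q}.
#' Runs `restarts` random initializations (data points sampled as seeds)
#' and keeps the solution with the lowest objective.  Clusters are
#' relabelled in descending centroid order, so cluster 1 is the
#' high-retention (plateau) side when the input is a projected retention
#' curve.
#'
#' @param data Numeric vector (the learning set).
#' @param c Number of clusters (1 < c < n).
#' @param q Fuzzifier (> 1); 2 is the common default.
#' @param tol Convergence tolerance on the maximum centroid shift.
#' @param max_iter Iteration cap per restart.
#' @param restarts Number of seeded restarts.
#' @param seed Integer seed making the run deterministic.
#' @return An object of class `fuzzy_partition`: list with `memberships`
#'   (c x n), `centroids`, `objective`, `objective_trace`, `n_iter`,
#'   `converged`, `c`, `q`.
#' @export
fcm <- function(data, c = 3L, q = 2, tol = 1e-6, max_iter = 300L,
                restarts = 10L, seed = 1L) {
  data <- as.numeric(data)
  n <- length(data)
  if (c <= 1L || c >= n) stop("need 1 < c < n")
  if (q <= 1) stop("fuzzifier q must be > 1")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- sample(data, c)
    # coincident inits collapse the membership update; nudge them apart
    if (anyDuplicated(init))
      init <- init + stats::runif(c, -1e-8, 1e-8) * (diff(range(data)) + 1)
    fit <- fcm_once(data, init, q, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  ord <- order(best$centroids, decreasing = TRUE)
  best$centroids <- best$centroids[ord]
  best$memberships <- best$memberships[ord, , drop = FALSE]
  best$c <- c; best$q <- q
  class(best) <- "fuzzy_partition"
  best
}

fcm_once <- function(data, centroids, q, tol, max_iter) {
  n <- length(data)
  c <- length(centroids)
  trace <- numeric(0)
  converged <- FALSE
  m <- NULL
  for (it in seq_len(max_iter)) {
    m <- fcm_memberships(data, centroids, q)
    mq <- m^q
    new_cent <- as.vector((mq %*% data) / rowSums(mq))
    d2 <- outer(new_cent, data, function(w, u) (u - w)^2)
    trace <- c(trace, sum(mq * d2))
    shift <- max(abs(new_cent - centroids))
    centroids <- new_cent
    if (shift < tol) { converged <- TRUE; break }
  }
  list(memberships = fcm_memberships(data, centroids, q),
       centroids = centroids, objective = trace[length(trace)],
       objective_trace = trace, n_iter = length(trace),
       converged = converged)
}

# membership update; points coinciding with a centroid get full membership
# there (split equally over coincident centroids)
fcm_memberships <- function(data, centroids, q) {
  c <- length(centroids)
  n <- length(data)
  d2 <- outer(centroids, data, function(w, u) (u - w)^2)
  m <- matrix(0, nrow = c, ncol = n)
  zero <- colSums(d2 == 0) > 0
  if (any(zero)) {
    for (j in which(zero)) {
      hit <- d2[, j] == 0
      m[hit, j] <- 1 / sum(hit)
    }
  }
  if (any(!zero)) {
    e <- 1 / (q - 1)
    w <- (1 / d2[, !zero, drop = FALSE])^e
    m[, !zero] <- sweep(w, 2L, colSums(w), "/")
  }
  m
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("fuzzy_partition: c=%d, q=%g, J=%.6g, %d iterations (%s)\n",
              x$c, x$q, x$objective, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("centroids:", format(x$centroids, digits = 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cluster validity indices
# ---------------------------------------------------------------------------

#' Fukuyama-Sugeno cluster validity index
#'
#' \deqn{FS_q = \sum_i \sum_j m_{ij}^q
#'   (\|u_j - \omega_i\|^2 - \|\omega_i - \bar u\|^2)}
#' where \eqn{\bar u} is the grand mean of the data.  Lower (more negative)
#' values indicate compact, well-separated partitions.
#'
#' @param partition A `fuzzy_partition` from [fcm()].
#' @param data The clustered data vector.
#' @return Scalar index value.
#' @export
fukuyama_sugeno <- function(partition, data) {
  data <- as.numeric(data)
  mq <- partition$memberships^partition$q
  d2 <- outer(partition$centroids, data, function(w, u) (u - w)^2)
  sep <- (partition$centroids - mean(data))^2
  sum(mq * d2) - sum(rowSums(mq) * sep)
}

#' Partition entropy cluster validity index
#'
#' \deqn{PE = -\frac{1}{n} \sum_j \sum_i m_{ij} \ln m_{ij}} with
#' \eqn{0 \ln 0 = 0}.  Zero for crisp partitions, `ln c` for uniform
#' memberships; lower is better.
#'
#' @param partition A `fuzzy_partition` from [fcm()].
#' @return Scalar index value.
#' @export
partition_entropy <- function(partition) {
  m <- partition$memberships
  terms <- ifelse(m > 0, m * log(m), 0)
  -sum(terms) / ncol(m)
}

#' Select the number of clusters by a validity index
#'
#' Fits [fcm()] for every candidate `c` and returns the one minimizing the
#' requested index.
#'
#' @param data Numeric vector.
#' @param c_range Candidate cluster counts (default 2..6).
#' @param index `"fs"` (Fukuyama-Sugeno) or `"pe"` (partition entropy).
#' @param q Fuzzifier.
#' @param restarts,seed Passed to [fcm()].
#' @return Integer: the selected number of clusters.
#' @export
select_c <- function(data, c_range = 2:6, index = c("fs", "pe"), q = 2,
                     restarts = 10L, seed = 1L) {
  index <- match.arg(index)
  c_range <- c_range[c_range > 1L & c_range < length(data)]
  if (!length(c_range)) stop("no admissible cluster count in c_range")
  scores <- vapply(c_range, function(cc) {
    part <- fcm(data, c = cc, q = q, restarts = restarts,
                seed = seed + cc)
    if (index == "fs") fukuyama_sugeno(part, data)
    else partition_entropy(part)
  }, numeric(1))
  as.integer(c_range[which.min(scores)])
}

# ---------------------------------------------------------------------------
# Hotspot, fuzzy boundary, interpolation
# ---------------------------------------------------------------------------

#' Tolerance interval from the first two clusters
#'
#' The anchors of the hotspot are the curve points with maximal membership
#' in cluster 1 (plateau side) and cluster 2 (first drop cluster); the index
#' set J runs between them and the tolerance interval I is the threshold
#' span of J.
#'
#' @param partition A `fuzzy_partition` with clusters ordered plateau-first.
#' @param curve The [retention_curve()] that was clustered (same length as
#'   the membership columns).
#' @return List with `j` (integer index set), `interval` (`c(lo, hi)` in
#'   threshold units) and the anchor indices `j_inf`, `j_sup`.
#' @export
hotspot_interval <- function(partition, curve) {
  m <- partition$memberships
  if (ncol(m) != nrow(curve))
    stop("partition and curve lengths differ")
  # ties (crisp memberships) resolve towards the knee: last plateau point,
  # first drop-cluster point
  j_inf <- max(which(m[1L, ] == max(m[1L, ])))
  j_sup <- min(which(m[2L, ] == max(m[2L, ])))
  if (j_inf > j_sup)
    stop(paste("cluster anchors are out of order (non-monotone memberships);",
               "try a different number of clusters c or fuzzifier q"))
  j <- seq.int(j_inf, j_sup)
  list(j = j,
       interval = c(curve$threshold[j_inf], curve$threshold[j_sup]),
       j_inf = j_inf, j_sup = j_sup)
}

#' Fuzzy boundary between the first two clusters
#'
#' Elements belonging to both of the first two clusters with membership at
#' least `epsilon` form the boundary; its extreme indices (l, k) span the
#' target interval I'.  If no element qualifies, `epsilon` is halved until
#' `eps_min` before giving up.
#'
#' @param partition A `fuzzy_partition` with clusters ordered plateau-first.
#' @param epsilon Overlap threshold in (0, 0.5].
#' @param eps_min Smallest `epsilon` tried before erroring.
#' @return List with `boundary` (integer indices), `l`, `k`, and the
#'   `epsilon` actually used.
#' @export
fuzzy_boundary <- function(partition, epsilon = 0.1, eps_min = 1e-3) {
  m <- partition$memberships
  eps <- epsilon
  repeat {
    idx <- which(pmin(m[1L, ], m[2L, ]) >= eps)
    if (length(idx)) break
    eps <- eps / 2
    if (eps < eps_min)
      stop("empty fuzzy boundary even at minimal epsilon; clusters do not overlap")
  }
  list(boundary = idx, l = min(idx), k = max(idx), epsilon = eps)
}

#' Interpolate the suggested cut-off from the boundary mean
#'
#' Takes the arithmetic mean `u_bar` of the projected (retained probe-set)
#' values of the boundary elements and inverts the probe-set component of
#' the curve at `u_bar` by piecewise-linear interpolation restricted to the
#' target interval.  Flat runs equal to `u_bar` resolve to their midpoint;
#' a `u_bar` outside the range of the curve over I' clamps to the nearer
#' endpoint with a warning.
#'
#' @param curve A [retention_curve()].
#' @param boundary Integer indices of the boundary elements (from
#'   [fuzzy_boundary()]).
#' @param values Optional projected values aligned to the curve (defaults to
#'   `curve$retained_sets`).
#' @param method `"linear"` (default) or `"lagrange"` (quadratic through the
#'   bracketing knots, when three are available).
#' @return List with `x_atm` and `u_bar`.
#' @export
interpolate_xatm <- function(curve, boundary, values = NULL,
                             method = c("linear", "lagrange")) {
  method <- match.arg(method)
  if (is.null(values)) values <- curve$retained_sets
  u_bar <- mean(values[boundary])
  l <- min(boundary); k <- max(boundary)
  idx <- seq.int(l, k)
  x <- curve$threshold[idx]
  y <- values[idx]
  # y is non-increasing in x; invert at u_bar
  if (u_bar > max(y)) {
    warning("boundary mean above curve range over the target interval; clamping")
    return(list(x_atm = x[1L], u_bar = u_bar))
  }
  if (u_bar < min(y)) {
    warning("boundary mean below curve range over the target interval; clamping")
    return(list(x_atm = x[length(x)], u_bar = u_bar))
  }
  hits <- which(y == u_bar)
  if (length(hits)) {                       # flat run (or exact knot)
    return(list(x_atm = mean(range(x[hits])), u_bar = u_bar))
  }
  hi <- max(which(y > u_bar))               # last knot above u_bar
  lo <- hi + 1L                             # first knot below
  x_atm <- if (method == "lagrange" && hi >= 2L) {
    # quadratic through the three knots around the crossing, evaluated as
    # x(y) since y is strictly monotone there
    yy <- y[(hi - 1L):lo]; xx <- x[(hi - 1L):lo]
    sum(vapply(1:3, function(a) {
      others <- setdiff(1:3, a)
      xx[a] * prod((u_bar - yy[others]) / (yy[a] - yy[others]))
    }, numeric(1)))
  } else {
    x[hi] + (x[lo] - x[hi]) * (y[hi] - u_bar) / (y[hi] - y[lo])
  }
  list(x_atm = x_atm, u_bar = u_bar)
}

# ---------------------------------------------------------------------------
# Full pipeline
# ---------------------------------------------------------------------------

#' Run automated threshold mapping on a retention curve
#'
#' Projection, (optional) cluster-count selection, fuzzy c-means, hotspot
#' decoding, fuzzy boundary and interpolation, returning the 3-tuple
#' (`x_atm`, target interval, tolerance interval).  Deterministic for a
#' given seed.  Projected values are rescaled to \[0, 1\] before clustering
#' (scale invariance); all reported intervals are in original threshold
#' units.
#'
#' The result carries a `low_confidence` flag, raised when the tolerance
#' interval spreads over more than 30 percent of the threshold span — the
#' situation on plateau-free (quasi-linear) curves, where no sharp knee
#' exists and the suggestion is only loosely localized.
#'
#' @param curve A [retention_curve()].
#' @param c Number of clusters, or `"auto"` to pick from `c_range` by the
#'   validity index.
#' @param q Fuzzifier.
#' @param epsilon Fuzzy-boundary overlap threshold.
#' @param index Validity index for `c = "auto"`: `"fs"` or `"pe"`.
#' @param c_range Candidate cluster counts for `c = "auto"`.
#' @param basis Projection basis (default `[0,0,1]'`: retained probe-sets).
#' @param interpolation `"linear"` or `"lagrange"`.
#' @param restarts,seed Passed to [fcm()].
#' @return An object of class `atm_result`: list with `x_atm`,
#'   `target_interval`, `tolerance_interval`, `boundary_indices` (l, k),
#'   `hotspot_j`, `u_bar`, `epsilon`, `index`, `index_value`, `c`,
#'   `low_confidence` and the `partition`.
#' @export
run_atm <- function(curve, c = 3L, q = 2, epsilon = 0.1,
                    index = c("fs", "pe"), c_range = 2:6,
                    basis = matrix(c(0, 0, 1), ncol = 1),
                    interpolation = c("linear", "lagrange"),
                    restarts = 10L, seed = 1L) {
  index <- match.arg(index)
  interpolation <- match.arg(interpolation)
  proj <- project_curve(curve, basis)
  span <- diff(range(proj))
  if (span <= 0) stop("projected curve is constant; nothing to map")
  scaled <- (proj - min(proj)) / span
  if (identical(c, "auto"))
    c <- select_c(scaled, c_range = c_range, index = index, q = q,
                  restarts = restarts, seed = seed)
  part <- fcm(scaled, c = c, q = q, restarts = restarts, seed = seed)
  hs <- hotspot_interval(part, curve)
  fb <- fuzzy_boundary(part, epsilon = epsilon)
  # the boundary is decoded within the hotspot span
  fb$boundary <- fb$boundary[fb$boundary >= hs$j_inf &
                             fb$boundary <= hs$j_sup]
  if (!length(fb$boundary)) fb$boundary <- hs$j
  fb$l <- min(fb$boundary); fb$k <- max(fb$boundary)
  ip <- interpolate_xatm(curve, fb$boundary, values = proj,
                         method = interpolation)
  idx_val <- if (index == "fs") fukuyama_sugeno(part, scaled)
             else partition_entropy(part)
  # confidence = localization: when the tolerance interval spreads over a
  # large share of the threshold span (as on plateau-free, quasi-linear
  # curves) the knee is poorly localized and the suggestion is tentative
  x_span <- diff(range(curve$threshold))
  low_conf <- diff(hs$interval) > 0.3 * x_span
  structure(list(
    x_atm = ip$x_atm,
    target_interval = c(curve$threshold[fb$l], curve$threshold[fb$k]),
    tolerance_interval = hs$interval,
    boundary_indices = c(l = fb$l, k = fb$k),
    hotspot_j = hs$j,
    u_bar = ip$u_bar,
    epsilon = fb$epsilon,
    index = index,
    index_value = idx_val,
    c = part$c,
    low_confidence = low_conf,
    partition = part), class = "atm_result")
}

#' @export
print.atm_result <- function(x, ...) {
  cat(sprintf("ATM 3-tuple: x_atm = %.2f, target I' = [%g, %g], tolerance I = [%g, %g]\n",
              x$x_atm, x$target_interval[1], x$target_interval[2],
              x$tolerance_interval[1], x$tolerance_interval[2]))
  cat(sprintf("  c = %d clusters, %s index = %.4g%s\n", x$c, x$index,
              x$index_value,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Relative difference between a chosen and a suggested cut-off
#'
#' `100 * |selected - suggested| / selected`, the percentage used to compare
#' a manually selected probe-mask cut-off with the ATM suggestion.
#'
#' @param selected Manually chosen cut-off (> 0).
#' @param suggested ATM-suggested cut-off.
#' @return Percentage relative difference.
#' @export
cutoff_relative_difference <- function(selected, suggested) {
  if (any(selected <= 0)) stop("selected cut-off must be positive")
  100 * abs(selected - suggested) / selected
}
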