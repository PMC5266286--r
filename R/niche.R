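# Isotopic-niche geometry in the d13C-d15N plane: the standard ellipse
# (1-SD contour of the bivariate scatter, area SEA = pi * sqrt(det(Sigma))),
# its small-sample correction SEAc = SEA * (n-1)/(n-2), the convex-hull
# total area TA, and pairwise ellipse overlap (intersection over union).

#' Construct a niche ellipse directly from moments
#'
#' @param centroid Length-2 numeric (d13C, d15N centroid, permil).
#' @param cov 2x2 symmetric positive semi-definite covariance (permil^2).
#' @param n Sample count behind the ellipse (>= 3 for SEAc).
#' @param group Optional label.
#' @return A `niche_ellipse` with `SEA`, `SEAc` and a `degenerate` flag.
#' @export
niche_ellipse <- function(centroid, cov, n, group = NULL) {
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("covariance must be symmetric")
  dt <- det(cov)
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("covariance must be positive semi-definite")
  if (n < 3L) stop("need n >= 3 samples for an ellipse")
  sea <- pi * sqrt(max(dt, 0))
  structure(list(group = group, centroid = as.numeric(centroid), cov = cov,
                 n = as.integer(n), SEA = sea,
                 SEAc = sea * (n - 1) / (n - 2),
                 degenerate = dt <= 1e-12),
            class = "niche_ellipse")
}

#' Standard ellipse of a bivariate isotope scatter
#'
#' Fits the sample mean and covariance (n-1 denominator) of the points and
#' returns the 1-SD standard ellipse; its area SEA = pi * sqrt(det(Sigma))
#' covers roughly 40 percent of a bivariate-normal population, and SEAc
#' applies the small-sample correction (n-1)/(n-2). Collinear samples give
#' SEA = 0 with the `degenerate` flag set.
#'
#' @param samples Two-column matrix/data.frame of (d13C, d15N) points, or a
#'   pair of vectors via `y`.
#' @param y Optional second coordinate vector.
#' @param group Optional label.
#' @return A `niche_ellipse`.
#' @export
standard_ellipse <- function(samples, y = NULL, group = NULL) {
  xy <- if (is.null(y)) as.matrix(samples) else cbind(samples, y)
  if (ncol(xy) != 2L) stop("samples must be bivariate")
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 samples, got ", n)
  niche_ellipse(colMeans(xy), stats::cov(xy), n, group = group)
}

#' Convex-hull total area (TA)
#'
#' The minimum convex area bounding all individuals on the isotope bi-plot,
#' computed from the convex hull and the shoelace formula. Interior points
#' do not change TA; fewer than three distinct points, or collinear points,
#' give 0 with a `degenerate` attribute.
#'
#' @param samples Two-column matrix/data.frame of (d13C, d15N) points.
#' @return Hull area (permil^2) with attribute `degenerate`.
#' @export
total_area <- function(samples) {
  xy <- unique(as.matrix(samples))
  if (ncol(xy) != 2L) stop("samples must be bivariate")
  if (nrow(xy) < 3L)
    return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(structure(0, degenerate = TRUE))
  v <- xy[h, , drop = FALSE]
  i2 <- c(seq_len(nrow(v))[-1], 1L)
  area <- abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
  structure(area, degenerate = area <= 1e-12)
}

# is each point (rows of xy) inside ellipse (mu, S) at Mahalanobis radius 1
.in_ellipse <- function(xy, mu, Sinv) {
  dx <- xy[, 1] - mu[1]; dy <- xy[, 2] - mu[2]
  q <- Sinv[1, 1] * dx^2 + 2 * Sinv[1, 2] * dx * dy + Sinv[2, 2] * dy^2
  q <= 1
}

.ellipse_bbox <- function(mu, S) {
  hw <- sqrt(pmax(diag(S), 0))
  rbind(mu - hw, mu + hw)
}

#' Pairwise ellipse overlap (intersection over union)
#'
#' Overlap between two (SEAc-scaled) standard ellipses as
#' area(E1 intersect E2) / area(E1 union E2): symmetric, in \[0, 1\], equal
#' to 1 only for identical ellipses and 0 for disjoint ones. The
#' intersection area is integrated on a midpoint grid over the overlap of
#' the two bounding boxes, refined (grid doubling) until two successive
#' estimates of the overlap fraction agree within `tol`; the computation is
#' deterministic (no randomness).
#'
#' @param e1,e2 `niche_ellipse` objects (non-degenerate).
#' @param scale `"seac"` (default: axes inflated so the area equals SEAc)
#'   or `"sea"` (raw 1-SD standard ellipse).
#' @param tol Refinement tolerance on the overlap fraction (default 0.002).
#' @return Overlap fraction in \[0, 1\].
#' @export
ellipse_overlap <- function(e1, e2, scale = c("seac", "sea"), tol = 0.002) {
  scale <- match.arg(scale)
  for (e in list(e1, e2)) {
    if (!inherits(e, "niche_ellipse")) stop("inputs must be niche_ellipse objects")
    if (isTRUE(e$degenerate)) stop("degenerate ellipse: overlap undefined")
  }
  f1 <- if (scale == "seac") (e1$n - 1) / (e1$n - 2) else 1
  f2 <- if (scale == "seac") (e2$n - 1) / (e2$n - 2) else 1
  S1 <- e1$cov * f1; S2 <- e2$cov * f2
  mu1 <- e1$centroid; mu2 <- e2$centroid
  if (isTRUE(all.equal(mu1, mu2, tolerance = 1e-12)) &&
      isTRUE(all.equal(S1, S2, tolerance = 1e-12))) return(1)
  a1 <- pi * sqrt(det(S1)); a2 <- pi * sqrt(det(S2))
  b1 <- .ellipse_bbox(mu1, S1); b2 <- .ellipse_bbox(mu2, S2)
  lo <- pmax(b1[1, ], b2[1, ]); hi <- pmin(b1[2, ], b2[2, ])
  if (any(hi <= lo)) return(0)
  Sinv1 <- solve(S1); Sinv2 <- solve(S2)
  inter_frac <- function(nside) {
    gx <- seq(lo[1], hi[1], length.out = nside + 1L)
    gy <- seq(lo[2], hi[2], length.out = nside + 1L)
    cx <- (gx[-1] + gx[-length(gx)]) / 2
    cy <- (gy[-1] + gy[-length(gy)]) / 2
    cell <- diff(gx)[1] * diff(gy)[1]
    xy <- cbind(rep(cx, times = nside), rep(cy, each = nside))
    inside <- .in_ellipse(xy, mu1, Sinv1) & .in_ellipse(xy, mu2, Sinv2)
    sum(inside) * cell
  }
  nside <- 128L
  inter <- inter_frac(nside)
  ov_prev <- inter / (a1 + a2 - inter)
  repeat {
    nside <- nside * 2L
    inter <- inter_frac(nside)
    ov <- inter / (a1 + a2 - inter)
    if (abs(ov - ov_prev) < tol || nside >= 2048L) break
    ov_prev <- ov
  }
  min(max(ov, 0), 1)
}

#' Apply an affine map to a niche ellipse
#'
#' Area ratios (and hence overlap) are invariant under a common invertible
#' affine transform; this helper supports checking that property and
#' re-expressing ellipses in rotated/rescaled coordinates.
#'
#' @param e A `niche_ellipse`.
#' @param A Invertible 2x2 matrix.
#' @param b Length-2 offset (default 0).
#' @return The transformed `niche_ellipse` (same `n`).
#' @export
affine_transform <- function(e, A, b = c(0, 0)) {
  A <- as.matrix(A)
  if (abs(det(A)) < 1e-12) stop("transform must be invertible")
  niche_ellipse(as.numeric(A %*% e$centroid + b), A %*% e$cov %*% t(A),
                e$n, group = e$group)
}

#' Per-group niche metrics and pairwise overlap
#'
#' @param samples An `isotope_samples` data.frame (consumer groups).
#' @param groups Group labels to include (default: all with n >= 3).
#' @return A list with `metrics` (data.frame: group, n, SEA, SEAc, TA) and
#'   `overlap` (symmetric matrix of pairwise SEAc ellipse overlaps).
#' @export
niche_metrics <- function(samples, groups = NULL) {
  samples <- as.data.frame(samples)
  if (is.null(groups)) {
    tab <- table(samples$group)
    groups <- names(tab)[tab >= 3]
  }
  ell <- lapply(groups, function(g) {
    s <- samples[samples$group == g, , drop = FALSE]
    standard_ellipse(cbind(s$d13C, s$d15N), group = g)
  })
  names(ell) <- groups
  metrics <- data.frame(
    group = groups,
    n = vapply(ell, function(e) e$n, integer(1)),
    SEA = vapply(ell, function(e) e$SEA, numeric(1)),
    SEAc = vapply(ell, function(e) e$SEAc, numeric(1)),
    TA = vapply(groups, function(g) {
      s <- samples[samples$group == g, , drop = FALSE]
      as.numeric(total_area(cbind(s$d13C, s$d15N)))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(metrics) <- NULL
  ov <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  diag(ov) <- 1
  if (length(groups) > 1L) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      ov[i, j] <- ov[j, i] <- ellipse_overlap(ell[[i]], ell[[j]])
    }
  }
  list(metrics = metrics, overlap = ov, ellipses = ell)
}
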