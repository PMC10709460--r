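#' Gyration tensor of a weighted point set
#'
#' Second-moment tensor about the weighted centroid,
#' \deqn{S_{ab} = \sum_i w_i (r_i - \bar r)_a (r_i - \bar r)_b / \sum_i w_i,}
#' with mass weights by default (uniform if none supplied). Its eigenvalues
#' are the principal moments of the squared radius of gyration.
#'
#' @param points \code{n x 3} coordinate matrix (nm).
#' @param weights optional non-negative weights, not all zero.
#' @return symmetric 3 x 3 matrix (nm^2).
#' @export
gyration_tensor <- function(points, weights = NULL) {
  x <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(x)
  if (n < 1L) stopf("need at least one point")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stopf("one weight per point required")
  if (any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be non-negative and not all zero")
  ctr <- colSums(x * weights) / sum(weights)
  xc <- sweep(x, 2L, ctr)
  crossprod(xc * sqrt(weights)) / sum(weights)
}

#' Shape descriptors from a gyration tensor
#'
#' Eigen-decomposes the tensor (eigenvalues sorted descending,
#' lambda1 >= lambda2 >= lambda3) and derives the radius of gyration
#' \eqn{R_g = \sqrt{\lambda_1 + \lambda_2 + \lambda_3}}, the relative shape
#' anisotropy
#' \deqn{\kappa^2 = 1 - 3\,\frac{\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#'   \lambda_1\lambda_3}{(\lambda_1 + \lambda_2 + \lambda_3)^2}}
#' (0 for a fully symmetric distribution, 1 for an ideal linear chain), and
#' the asphericity \eqn{b = \lambda_1 - (\lambda_2 + \lambda_3)/2} (0 for a
#' sphere). kappa^2 is clamped to [0, 1] only against round-off excursions
#' below 1e-10; a zero tensor maps to kappa^2 = 0 (a point is perfectly
#' symmetric; continuity of the symmetric limit) and b = 0.
#'
#' @param tensor symmetric positive-semidefinite 3 x 3 matrix (nm^2).
#' @return list with \code{lambda} (descending, nm^2), \code{rg} (nm),
#'   \code{kappa2}, \code{b} (nm^2).
#' @export
shape_descriptors <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (!all(dim(tensor) == c(3L, 3L)) ||
      max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
    stopf("gyration tensor must be a symmetric 3 x 3 matrix")
  lam <- sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  # clamp eigenvalue round-off on PSD input
  lam[lam < 0 & lam > -1e-12 * max(1, lam[1])] <- 0
  if (any(lam < 0)) stopf("tensor is not positive semi-definite")
  tr <- sum(lam)
  if (tr <= 0) {
    kappa2 <- 0; b <- 0
  } else {
    kappa2 <- 1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] + lam[1] * lam[3]) / tr^2
    if (kappa2 < 0 && kappa2 > -1e-10) kappa2 <- 0
    if (kappa2 > 1 && kappa2 < 1 + 1e-10) kappa2 <- 1
    b <- lam[1] - (lam[2] + lam[3]) / 2
  }
  list(lambda = lam, rg = sqrt(tr), kappa2 = kappa2, b = b)
}

#' Per-frame shape descriptor series
#'
#' Applies \code{\link{gyration_tensor}} and \code{\link{shape_descriptors}}
#' to one atom group over a trajectory. Mass weighting is the default when
#' the topology carries masses; uniform weighting is always available.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology}.
#' @param group atom indices to analyse (default: every atom that is not
#'   water and not guest, i.e. the host macrocycle).
#' @param weighting \code{"mass"} (uses topology masses when present,
#'   otherwise uniform) or \code{"uniform"}.
#' @param window \code{NULL}, a \code{\link{tail_window}} or an index vector.
#' @return data.frame with columns \code{frame}, \code{lambda1..lambda3},
#'   \code{rg}, \code{kappa2}, \code{b}.
#' @export
shape_series <- function(trajectory, topology, group = NULL,
                         weighting = c("mass", "uniform"), window = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(group))
    group <- which(atom_group_labels(topology) == "CD")
  w <- NULL
  if (weighting == "mass" && !is.null(topology$masses)) w <- topology$masses[group]
  idx <- resolve_window(trajectory, window)
  rows <- lapply(idx, function(f) {
    sd <- shape_descriptors(gyration_tensor(frame_coords(trajectory, f)[group, , drop = FALSE], w))
    data.frame(frame = f, lambda1 = sd$lambda[1], lambda2 = sd$lambda[2],
               lambda3 = sd$lambda[3], rg = sd$rg, kappa2 = sd$kappa2, b = sd$b)
  })
  do.call(rbind, rows)
}

#' Probability density of a descriptor series
#'
#' Normalized histogram (default) or Gaussian kernel density of a scalar
#' descriptor series on a stated support, with the mode location reported.
#' The histogram density integrates to 1 over the support.
#'
#' @param series numeric samples (>= 2 unless all identical).
#' @param support length-2 range; default \code{c(0, 0.5)}-style ranges are
#'   chosen by the caller; when \code{NULL} the sample range (padded for the
#'   degenerate constant case) is used.
#' @param bins number of histogram bins (default 50).
#' @param method \code{"histogram"} or \code{"kde"}.
#' @param bandwidth kernel bandwidth for \code{"kde"}; must be > 0 when the
#'   series is constant.
#' @return list with \code{grid} (bin midpoints or kde grid),
#'   \code{density}, \code{width} (bin width, NA for kde), \code{mode}.
#' @export
descriptor_density <- function(series, support = NULL, bins = 50L,
                               method = c("histogram", "kde"),
                               bandwidth = NULL) {
  method <- match.arg(method)
  series <- series[is.finite(series)]
  if (length(series) < 1L) stopf("no finite samples")
  if (is.null(support)) {
    support <- range(series)
    if (diff(support) == 0) support <- support + c(-0.5, 0.5) * max(abs(support[1]), 1) * 0.1
  }
  if (method == "histogram") {
    edges <- seq(support[1], support[2], length.out = bins + 1L)
    width <- edges[2] - edges[1]
    x <- pmin(pmax(series, support[1]), support[2])
    cnt <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                    nbins = bins)
    dens <- cnt / (length(x) * width)
    mid <- (edges[-1] + edges[-(bins + 1L)]) / 2
    list(grid = mid, density = dens, width = width, mode = mid[which.max(dens)])
  } else {
    if (length(unique(series)) == 1L && (is.null(bandwidth) || bandwidth <= 0))
      stopf("constant series needs a positive bandwidth for kde")
    kd <- if (is.null(bandwidth))
      stats::density(series, from = support[1], to = support[2], n = 512L)
    else
      stats::density(series, bw = bandwidth, from = support[1], to = support[2], n = 512L)
    list(grid = kd$x, density = kd$y, width = NA_real_,
         mode = kd$x[which.max(kd$y)])
  }
}
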