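#' Weighted RMSD after optimal (Kabsch) superposition
#'
#' Removes the weighted centroids of both coordinate sets, finds the
#' optimal proper rotation (singular value decomposition of the covariance
#' with the determinant +1 enforced, so reflections are never applied) and
#' returns the weighted root-mean-square deviation of the residual. Zero
#' for any rigid motion of the reference. RMSD after superposition is
#' symmetric in its arguments but is not a metric (no triangle inequality
#' is implied).
#'
#' @param coords,reference \code{n x 3} coordinate matrices (nm), equal
#'   atom counts, n >= 3 and not collinear.
#' @param weights optional non-negative fitting weights.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(coords, reference, weights = NULL) {
  x <- as.matrix(coords); y <- as.matrix(reference)
  if (!all(dim(x) == dim(y))) stopf("coordinate sets differ in size")
  n <- nrow(x)
  if (n < 3L) stopf("need at least 3 atoms for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  xc <- sweep(x, 2L, colSums(x * w))
  yc <- sweep(y, 2L, colSums(y * w))
  h <- crossprod(xc * w, yc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- yc - xc %*% t(rot)
  sqrt(sum(w * rowSums(resid^2)))
}

#' Collective-variable series (RMSD, Rg) for a trajectory
#'
#' Per-frame Kabsch RMSD against a fixed reference frame and radius of
#' gyration of the same atom group: the two collective variables of the
#' conformational free-energy landscape.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology}.
#' @param reference \code{n x 3} reference coordinates for the group (e.g.
#'   an energy-minimized structure); default: the group in frame 1.
#' @param group atom indices; default the host (non-water, non-guest) atoms.
#' @param window \code{NULL}, a \code{\link{tail_window}} or index vector.
#' @return data.frame with columns \code{frame}, \code{rmsd} (nm), \code{rg}
#'   (nm).
#' @export
cv_series <- function(trajectory, topology, reference = NULL, group = NULL,
                      window = NULL) {
  if (is.null(group)) group <- which(atom_group_labels(topology) == "CD")
  if (is.null(reference)) reference <- frame_coords(trajectory, 1L)[group, , drop = FALSE]
  w <- if (!is.null(topology$masses)) topology$masses[group] else NULL
  idx <- resolve_window(trajectory, window)
  rows <- lapply(idx, function(f) {
    xyz <- frame_coords(trajectory, f)[group, , drop = FALSE]
    sdsc <- shape_descriptors(gyration_tensor(xyz, w))
    data.frame(frame = f, rmsd = kabsch_rmsd(xyz, reference, w), rg = sdsc$rg)
  })
  do.call(rbind, rows)
}

#' Two-dimensional free-energy landscape by Boltzmann inversion
#'
#' Bins the two collective variables on a regular grid, converts bin
#' probabilities to relative free energies \eqn{F = -kT \ln(P / P_{max})}
#' so the global minimum is exactly 0, and masks (NA) bins that were never
#' visited instead of assigning them a finite value.
#'
#' @param x,y collective-variable samples (equal length); alternatively
#'   \code{x} may be a data.frame with columns \code{rmsd} and \code{rg}.
#' @param kT thermal energy, kJ/mol (2.577 at 310 K).
#' @param bins number of bins per axis (default 60).
#' @param ranges optional list of two length-2 ranges; default: observed
#'   range of each variable padded by 5\%.
#' @return object of class \code{fel_landscape}: list with \code{F} (matrix,
#'   kJ/mol, NA on empty bins), \code{counts}, \code{xedges}, \code{yedges},
#'   \code{kT}.
#' @export
fel_2d <- function(x, y = NULL, kT = 2.577, bins = 60L, ranges = NULL) {
  if (is.data.frame(x)) { y <- x$rg; x <- x$rmsd }
  if (kT <= 0) stopf("'kT' must be > 0")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stopf("no samples to bin")
  pad_range <- function(v) {
    r <- range(v); p <- diff(r) * 0.05
    if (p == 0) p <- max(abs(r[1]), 1e-6) * 0.05
    r + c(-p, p)
  }
  rx <- if (is.null(ranges)) pad_range(x) else ranges[[1]]
  ry <- if (is.null(ranges)) pad_range(y) else ranges[[2]]
  xe <- seq(rx[1], rx[2], length.out = bins + 1L)
  ye <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  fmat <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  fmat[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(F = fmat, counts = counts, xedges = xe, yedges = ye, kT = kT),
            class = "fel_landscape")
}

#' @export
print.fel_landscape <- function(x, ...) {
  cat(sprintf("fel_landscape: %d x %d bins, %d occupied, F range [0, %.3f] kJ/mol\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Local minima and inter-basin barriers of a landscape
#'
#' Identifies basin minima on the occupied bins of a 2-D landscape and
#' estimates pairwise barriers as the minimax path level over the
#' occupied-bin adjacency graph (4-connectivity): occupied bins are merged
#' in ascending order of F (a watershed sweep with union-find); a bin with
#' no lower processed neighbour seeds a new basin, and when two basins
#' first join, the merge level is their barrier.
#'
#' Sampling noise on a histogrammed landscape creates many spurious shallow
#' dips; a basin whose prominence (merge level minus its minimum) is below
#' \code{min_prominence} is absorbed into its deeper neighbour instead of
#' being reported.
#'
#' @param landscape a \code{\link{fel_2d}} result.
#' @param depth_threshold report only minima with F at or below this level
#'   (default \code{Inf}: all basin minima).
#' @param min_prominence minimal basin prominence in kJ/mol (default 0:
#'   every strict basin is reported).
#' @return list with \code{minima} (data.frame ix, iy, x, y, F) and
#'   \code{barriers} (data.frame from/to bin centres, barrier in kJ/mol,
#'   empty for a single basin).
#' @export
find_minima <- function(landscape, depth_threshold = Inf, min_prominence = 0) {
  fmat <- landscape$F
  nb <- nrow(fmat)
  occ <- which(!is.na(fmat), arr.ind = TRUE)
  if (nrow(occ) == 0L) stopf("landscape has no occupied bins")
  fv <- fmat[occ]
  ord <- order(fv)
  id <- matrix(NA_integer_, nb, ncol(fmat))
  id[occ] <- seq_len(nrow(occ))
  parent <- seq_len(nrow(occ))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  basin_of <- integer(nrow(occ))      # representative minimum per component
  minima <- integer()
  barriers <- list()
  processed <- logical(nrow(occ))
  for (oi in ord) {
    r <- occ[oi, 1]; c2 <- occ[oi, 2]
    nbrs <- rbind(c(r - 1L, c2), c(r + 1L, c2), c(r, c2 - 1L), c(r, c2 + 1L))
    nbrs <- nbrs[nbrs[, 1] >= 1L & nbrs[, 1] <= nb &
                 nbrs[, 2] >= 1L & nbrs[, 2] <= ncol(fmat), , drop = FALSE]
    nid <- id[nbrs]; nid <- nid[!is.na(nid)]
    nid <- nid[processed[nid]]
    processed[oi] <- TRUE
    if (length(nid) == 0L) {        # new basin: this bin is its minimum
      minima <- c(minima, oi)
      basin_of[find(oi)] <- oi
      next
    }
    roots <- unique(vapply(nid, find, integer(1)))
    # attach to the first component, then merge any others at this level
    main <- roots[1]
    parent[find(oi)] <- main
    if (length(roots) > 1L) {
      for (rt in roots[-1]) {
        a <- basin_of[find(main)]; b <- basin_of[rt]
        shallow <- if (fv[a] <= fv[b]) b else a
        deep <- if (fv[a] <= fv[b]) a else b
        if (fv[oi] - fv[shallow] < min_prominence) {
          # noise dip: absorb silently
          minima <- setdiff(minima, shallow)
        } else {
          barriers[[length(barriers) + 1L]] <-
            data.frame(from = deep, to = shallow, barrier = fv[oi])
        }
        parent[rt] <- find(main)
        basin_of[find(main)] <- deep
      }
    }
  }
  keep <- minima[fv[minima] <= depth_threshold]
  xm <- (landscape$xedges[-1] + landscape$xedges[-length(landscape$xedges)]) / 2
  ym <- (landscape$yedges[-1] + landscape$yedges[-length(landscape$yedges)]) / 2
  mins <- data.frame(ix = occ[keep, 1], iy = occ[keep, 2],
                     x = xm[occ[keep, 1]], y = ym[occ[keep, 2]],
                     F = fv[keep])
  mins <- mins[order(mins$F), , drop = FALSE]
  bar_df <- if (length(barriers)) {
    b <- do.call(rbind, barriers)
    data.frame(from_x = xm[occ[b$from, 1]], from_y = ym[occ[b$from, 2]],
               to_x = xm[occ[b$to, 1]], to_y = ym[occ[b$to, 2]],
               barrier = b$barrier)
  } else data.frame(from_x = numeric(), from_y = numeric(),
                    to_x = numeric(), to_y = numeric(), barrier = numeric())
  list(minima = mins, barriers = bar_df)
}
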