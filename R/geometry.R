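#' Least-squares best-fit plane
#'
#' Fits the plane minimizing the sum of squared point-plane distances via
#' the singular value decomposition of the centered coordinates: the normal
#' is the right singular vector of the smallest singular value.
#'
#' @param points \code{n x 3} matrix, n >= 3, not collinear.
#' @return list with \code{centroid} (length 3), \code{normal} (unit length
#'   3), \code{basis} (3 x 2 in-plane orthonormal basis), \code{rmsd}
#'   (root-mean-square point-plane distance).
#' @export
best_fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stopf("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)
  # collinear (or coincident) points: the second singular value vanishes
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-10)
    stopf("points are collinear or coincident; plane is undefined")
  list(centroid = ctr, normal = sv$v[, 3L], basis = sv$v[, 1:2],
       rmsd = sqrt(mean((x %*% sv$v[, 3L])^2)))
}

# test segments (p1,p2) and (p3,p4) for proper intersection in 2-D
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Planar area of an ordered ring of atoms
#'
#' The ring points are projected onto their least-squares plane and the
#' enclosed area computed with the shoelace formula (absolute value). This
#' is the rim-area descriptor for the three oxygen rims of the macrocycle.
#' A self-intersecting projected polygon (badly distorted rim) still
#' returns the shoelace value but raises a warning.
#'
#' @param ring_points \code{n x 3} matrix (n >= 3) in cyclic ring order.
#' @return area in nm^2.
#' @export
rim_area <- function(ring_points) {
  ring_points <- as.matrix(ring_points)
  n <- nrow(ring_points)
  if (n < 3L) stopf("a ring needs at least 3 points")
  pl <- best_fit_plane(ring_points)
  uv <- sweep(ring_points, 2L, pl$centroid) %*% pl$basis
  j <- c(2:n, 1L)
  area <- abs(sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2])) / 2
  # warn on self-intersection of non-adjacent edges
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a + 1L || (a == 1L && b == n)) next
      if (segments_cross(uv[a, ], uv[j[a], ], uv[b, ], uv[j[b], ])) {
        warning("projected rim polygon is self-intersecting; shoelace area returned")
        return(area)
      }
    }
  }
  area
}

#' Rim circularity
#'
#' Ratio of the smallest to the largest characteristic chord of a rim; 1
#' for a perfectly regular ring. Two conventions:
#' \describe{
#'   \item{\code{"cross_ring"} (default)}{for each atom take its
#'     maximal-separation partners across the ring (chords i to i+floor(n/2)
#'     and i to i+ceiling(n/2)); the ratio is min/max over that chord set. A
#'     regular n-gon scores exactly 1 for any n.}
#'   \item{\code{"literal"}}{min/max over all atom pairs, including ring
#'     neighbours; a regular heptagon then scores
#'     sin(pi/7)/sin(3*pi/7) ~ 0.445, so 1 is unattainable for n > 4.}
#' }
#' The cross-ring convention is the default because reported circularities
#' near 0.99 for a 7-ring are only reachable under it; the literal reading
#' is retained as an option.
#'
#' @param ring_points \code{n x 3} matrix in cyclic ring order, n >= 3.
#' @param convention \code{"cross_ring"} or \code{"literal"}.
#' @return dimensionless ratio in (0, 1].
#' @export
circularity <- function(ring_points, convention = c("cross_ring", "literal")) {
  convention <- match.arg(convention)
  p <- as.matrix(ring_points)
  n <- nrow(p)
  if (n < 3L) stopf("a ring needs at least 3 points")
  dmat <- as.matrix(stats::dist(p))
  if (any(dmat[upper.tri(dmat)] < 1e-12)) stopf("coincident ring points")
  if (convention == "literal") {
    d <- dmat[upper.tri(dmat)]
    return(min(d) / max(d))
  }
  half <- c(floor(n / 2), ceiling(n / 2))
  chords <- unlist(lapply(seq_len(n), function(i) {
    dmat[i, ((i - 1L + half) %% n) + 1L]
  }))
  min(chords) / max(chords)
}

#' Distance between the centres of mass of two rims
#'
#' Mass-weighted centroids (uniform masses when none are supplied), as in
#' the inter-rim height descriptors h12 and h16 of the macrocycle.
#'
#' @param ring_a,ring_b \code{n x 3} coordinate matrices.
#' @param masses_a,masses_b optional per-point masses (u).
#' @return distance in nm.
#' @export
rim_height <- function(ring_a, ring_b, masses_a = NULL, masses_b = NULL) {
  com <- function(x, w) {
    x <- as.matrix(x)
    if (nrow(x) == 0L) stopf("empty ring")
    if (is.null(w)) w <- rep(1, nrow(x))
    colSums(x * w) / sum(w)
  }
  sqrt(sum((com(ring_a, masses_a) - com(ring_b, masses_b))^2))
}

#' Cavity volume from rim areas and heights
#'
#' Models the macrocycle cavity as two stacked conical frustums sharing the
#' middle rim: one from the middle rim to the primary hydroxyl rim (height
#' h16) and one from the middle rim to the secondary hydroxyl rim (height
#' h12):
#' \deqn{V = \frac{h_{16}}{3}(A_{PHR} + A_{MID} + \sqrt{A_{PHR} A_{MID}})
#'         + \frac{h_{12}}{3}(A_{SHR} + A_{MID} + \sqrt{A_{SHR} A_{MID}})}
#' With equal areas the model degenerates to a cylinder (V = 2Ah); with a
#' vanishing outer area, to a cone (V = Ah/3).
#'
#' @param a_phr,a_mid,a_shr rim areas, nm^2 (> 0; an outer area of 0 gives
#'   the cone limit).
#' @param h12,h16 inter-rim heights, nm (> 0).
#' @return cavity volume in nm^3.
#' @export
cavity_volume <- function(a_phr, a_mid, a_shr, h12, h16) {
  if (a_mid <= 0 || a_phr < 0 || a_shr < 0 || h12 <= 0 || h16 <= 0)
    stopf("areas and heights must be positive (outer areas may be 0 for the cone limit)")
  h16 / 3 * (a_phr + a_mid + sqrt(a_phr * a_mid)) +
    h12 / 3 * (a_shr + a_mid + sqrt(a_shr * a_mid))
}

#' Cavity centre and axis of one frame
#'
#' The cavity axis is the unit vector from the SHR rim centroid to the PHR
#' rim centroid; the cavity centre is the midpoint of that segment. Both
#' are frame-local and deterministic.
#'
#' @param xyz \code{n_atoms x 3} coordinates of one frame (nm).
#' @param topology a \code{cd_topology} with the rim rings.
#' @return list with \code{center}, \code{axis} (unit, PHR-pointing),
#'   \code{phr_centroid}, \code{shr_centroid}.
#' @export
cavity_frame <- function(xyz, topology) {
  c_phr <- colMeans(xyz[topology$phr_oxygens, , drop = FALSE])
  c_shr <- colMeans(xyz[topology$shr_oxygens, , drop = FALSE])
  ax <- c_phr - c_shr
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) stopf("degenerate macrocycle: PHR and SHR centroids coincide")
  list(center = (c_phr + c_shr) / 2, axis = ax / nrm,
       phr_centroid = c_phr, shr_centroid = c_shr)
}

#' Per-frame rim geometry descriptors
#'
#' Computes, for every frame (or a window), the three rim areas, the three
#' circularities, the inter-rim heights h12 (O1 ring to SHR), h16 (O1 ring
#' to PHR) and total height h (PHR to SHR), and the two-frustum cavity
#' volume, plus tail-window means with block-averaged standard errors.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology} with the three rim rings.
#' @param window \code{NULL} (all frames), a \code{\link{tail_window}}, or an
#'   index vector; the summary is computed over this window.
#' @param convention circularity convention, see \code{\link{circularity}}.
#' @param n_blocks blocks for the standard error of the window mean.
#' @return list with \code{per_frame} (data.frame, one row per window frame)
#'   and \code{summary} (data.frame of mean/se per descriptor).
#' @export
rim_geometry <- function(trajectory, topology, window = NULL,
                         convention = "cross_ring", n_blocks = 5L) {
  idx <- resolve_window(trajectory, window)
  use_mass <- !is.null(topology$masses)
  res <- lapply(idx, function(f) {
    xyz <- frame_coords(trajectory, f)
    phr <- xyz[topology$phr_oxygens, , drop = FALSE]
    mid <- xyz[topology$mid_oxygens, , drop = FALSE]
    shr <- xyz[topology$shr_oxygens, , drop = FALSE]
    m <- function(g) if (use_mass) topology$masses[g] else NULL
    a_phr <- rim_area(phr); a_mid <- rim_area(mid); a_shr <- rim_area(shr)
    h12 <- rim_height(mid, shr, m(topology$mid_oxygens), m(topology$shr_oxygens))
    h16 <- rim_height(mid, phr, m(topology$mid_oxygens), m(topology$phr_oxygens))
    h <- rim_height(phr, shr, m(topology$phr_oxygens), m(topology$shr_oxygens))
    data.frame(frame = f,
               A_PHR = a_phr, A_MID = a_mid, A_SHR = a_shr,
               omega_MID = circularity(mid, convention),
               omega_SHR = circularity(shr, convention),
               omega_PHR = circularity(phr, convention),
               h12 = h12, h16 = h16, h = h,
               V_C = cavity_volume(a_phr, a_mid, a_shr, h12, h16))
  })
  per_frame <- do.call(rbind, res)
  cols <- setdiff(names(per_frame), "frame")
  summ <- do.call(rbind, lapply(cols, function(cn) {
    ba <- block_average(per_frame[[cn]], n_blocks = min(n_blocks, nrow(per_frame)))
    data.frame(descriptor = cn, mean = ba$mean, se = ba$se)
  }))
  list(per_frame = per_frame, summary = summ)
}

#' Centre-of-geometry distance series between two atom groups
#'
#' Per-frame minimum-image distance between the unweighted geometric centres
#' of two groups (e.g. guest vs. host), the standard binding-kinetics
#' observable.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param group_a,group_b integer atom index vectors.
#' @param pbc apply minimum-image wrapping to the centre difference.
#' @return numeric vector, one distance (nm) per frame.
#' @export
cog_distance <- function(trajectory, group_a, group_b, pbc = TRUE) {
  if (length(group_a) == 0L || length(group_b) == 0L) stopf("empty atom group")
  vapply(seq_len(n_frames(trajectory)), function(f) {
    xyz <- frame_coords(trajectory, f)
    d <- colMeans(xyz[group_a, , drop = FALSE]) -
         colMeans(xyz[group_b, , drop = FALSE])
    if (pbc) d <- min_image(d, trajectory$box[f, ])
    sqrt(sum(d^2))
  }, numeric(1))
}

# dominant axis of an atom group: principal eigenvector of the uniform
# gyration tensor (sign unspecified)
principal_axis <- function(xyz) {
  s <- gyration_tensor(xyz)
  eigen(s, symmetric = TRUE)$vectors[, 1L]
}

#' Classify guest binding state and orientation per frame
#'
#' A frame is \code{inserted} when the guest centre of geometry lies within
#' \code{d_insert} of the cavity centre (midpoint of the PHR and SHR rim
#' centroids) and the guest long axis is within \code{max_angle} of the
#' cavity axis; \code{surface} when the centre is within \code{d_surface}
#' but the insertion criterion fails; \code{unbound} otherwise. For bound
#' frames the orientation is the sign of the guest hydroxyl-oxygen position
#' (relative to the guest centre) projected on the PHR-pointing cavity
#' axis: positive means the oxygen points toward the primary hydroxyl rim.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology} with guest atoms and guest oxygen.
#' @param d_insert insertion distance threshold, nm.
#' @param d_surface surface-association distance threshold, nm (>
#'   \code{d_insert}).
#' @param max_angle maximal angle (degrees) between guest long axis and
#'   cavity axis for insertion.
#' @return data.frame with columns \code{frame}, \code{time},
#'   \code{distance} (nm), \code{angle} (deg), \code{state},
#'   \code{orientation}.
#' @export
classify_binding <- function(trajectory, topology, d_insert = 0.35,
                             d_surface = 0.80, max_angle = 45) {
  if (d_insert >= d_surface) stopf("need d_insert < d_surface")
  ga <- topology$guest_atoms
  if (length(ga) < 2L) stopf("topology has no guest (need >= 2 guest atoms)")
  go <- topology$guest_oxygen
  nf <- n_frames(trajectory)
  out <- data.frame(frame = seq_len(nf),
                    time = trajectory$t0 + (seq_len(nf) - 1L) * trajectory$dt,
                    distance = NA_real_, angle = NA_real_,
                    state = character(nf), orientation = character(nf),
                    stringsAsFactors = FALSE)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(trajectory, f)
    cav <- cavity_frame(xyz, topology)
    gxyz <- xyz[ga, , drop = FALSE]
    cog <- colMeans(gxyz)
    d <- min_image(cog - cav$center, trajectory$box[f, ])
    dist <- sqrt(sum(d^2))
    gax <- principal_axis(gxyz)
    ang <- acos(min(1, abs(sum(gax * cav$axis)))) * 180 / pi
    state <- if (dist <= d_insert && ang <= max_angle) "inserted"
             else if (dist <= d_surface) "surface" else "unbound"
    orient <- "undefined"
    if (state != "unbound" && !is.na(go)) {
      proj <- sum((xyz[go, ] - cog) * cav$axis)
      orient <- if (proj >= 0) "O_toward_PHR" else "O_toward_SHR"
    }
    out$distance[f] <- dist; out$angle[f] <- ang
    out$state[f] <- state; out$orientation[f] <- orient
  }
  out
}
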