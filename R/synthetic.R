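#' Specification of a synthetic macrocycle ring system
#'
#' Describes a 7-unit (by default) macrocycle as three stacked rings of
#' labelled oxygens: primary hydroxyl rim (PHR, O6), middle glycosidic rim
#' (MID, O1) and secondary hydroxyl rim (SHR, O3). Default radii and rim
#' offsets reproduce the beta-cyclodextrin scale: rim areas near 1.10 /
#' 0.83 / 1.32 nm^2 and heights h16 = 0.33 nm, h12 = 0.22 nm. An
#' ellipticity factor > 1 stretches a rim along one in-plane axis
#' (degrading its circularity); Gaussian jitter emulates thermal disorder.
#'
#' @param n_units glucose units (ring size), >= 3; 7 for beta-cyclodextrin.
#' @param radius named numeric: circumradii (nm) of the \code{phr},
#'   \code{mid}, \code{shr} rims.
#' @param z_offset named numeric: axial position (nm) of each rim relative
#'   to the middle rim (PHR positive, SHR negative).
#' @param ellipticity named numeric >= 1: in-plane stretch factor per rim.
#' @param jitter_sd per-atom isotropic Gaussian jitter sigma, nm.
#' @param box box edge lengths, nm (ring centred in the box).
#' @param seed RNG seed for the jitter.
#' @return list of class \code{ring_spec}.
#' @export
ring_spec <- function(n_units = 7L,
                      radius = c(phr = 0.6340, mid = 0.5507, shr = 0.6946),
                      z_offset = c(phr = 0.33, mid = 0, shr = -0.22),
                      ellipticity = c(phr = 1, mid = 1, shr = 1),
                      jitter_sd = 0, box = c(4, 4, 4), seed = 1L) {
  if (n_units < 3L) stopf("'n_units' must be >= 3")
  if (any(radius <= 0)) stopf("rim radii must be > 0")
  if (any(ellipticity < 1)) stopf("ellipticity factors must be >= 1")
  structure(list(n_units = as.integer(n_units), radius = radius,
                 z_offset = z_offset, ellipticity = ellipticity,
                 jitter_sd = jitter_sd, box = box, seed = seed),
            class = "ring_spec")
}

#' Ring specification at the methylated-derivative scale
#'
#' Convenience variant with the smaller rim areas (1.05 / 0.70 / 1.08 nm^2)
#' and reduced heights (h16 = 0.22, h12 = 0.12 nm) characteristic of the
#' methylated derivative, whose cavity volume is markedly below the parent
#' macrocycle's.
#'
#' @inheritParams ring_spec
#' @return a \code{ring_spec}.
#' @export
ring_spec_methylated <- function(jitter_sd = 0, seed = 1L) {
  ring_spec(radius = c(phr = 0.6194, mid = 0.5058, shr = 0.6283),
            z_offset = c(phr = 0.22, mid = 0, shr = -0.12),
            jitter_sd = jitter_sd, seed = seed)
}

rim_positions <- function(spec, rim, center) {
  n <- spec$n_units
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- spec$radius[[rim]]; e <- spec$ellipticity[[rim]]
  cbind(center[1] + e * r * cos(th),
        center[2] + r * sin(th),
        center[3] + spec$z_offset[[rim]])
}

#' Generate a synthetic macrocycle ring
#'
#' Builds the three stacked oxygen rims of a \code{\link{ring_spec}} as a
#' topology plus a single coordinate frame. With zero jitter and unit
#' ellipticity every rim is an exact regular n-gon at its stated
#' circumradius and axial offset.
#'
#' @param spec a \code{\link{ring_spec}}.
#' @return list with \code{topology} (a \code{cd_topology}), \code{coords}
#'   (\code{3n x 3} matrix, nm), \code{box}.
#' @export
make_cd_ring <- function(spec) {
  stopifnot(inherits(spec, "ring_spec"))
  n <- spec$n_units
  ctr <- spec$box / 2
  xyz <- rbind(rim_positions(spec, "phr", ctr),
               rim_positions(spec, "mid", ctr),
               rim_positions(spec, "shr", ctr))
  if (spec$jitter_sd > 0) {
    old <- .Random.seed_save()
    set.seed(spec$seed)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$jitter_sd), ncol = 3L)
    .Random.seed_restore(old)
  }
  atoms <- data.frame(
    name = c(sprintf("O6%d", 1:n), sprintf("O1%d", 1:n), sprintf("O3%d", 1:n)),
    element = "O",
    resname = "GLC",
    resid = rep(1:n, 3L),
    stringsAsFactors = FALSE)
  topo <- cd_topology(atoms,
                      phr_oxygens = 1:n,
                      mid_oxygens = (n + 1L):(2L * n),
                      shr_oxygens = (2L * n + 1L):(3L * n),
                      acceptors = 1:(3L * n),
                      masses = rep(15.999, 3L * n))
  list(topology = topo, coords = xyz, box = spec$box)
}

#' Script for a synthetic binding event
#'
#' Deterministic guest path with a known ground truth. Mechanisms:
#' \code{direct_insert} (axial approach from the secondary-rim side,
#' insertion complete at \code{insertion_frame}), \code{surface_then_insert}
#' (approach, then a horizontal dwell lying across the secondary rim, then
#' an upright rotation over 10 frames finishing at \code{insertion_frame} --
#' the two-stage pathway), and \code{never_bind} (the guest stays > 1 nm
#' from the cavity centre throughout).
#'
#' @param mechanism one of \code{"direct_insert"},
#'   \code{"surface_then_insert"}, \code{"never_bind"}.
#' @param orientation \code{"O_toward_PHR"} or \code{"O_toward_SHR"}: which
#'   rim the guest hydroxyl oxygen points to once inserted.
#' @param insertion_frame frame at which insertion completes (ignored for
#'   \code{never_bind}).
#' @param approach_distance initial guest-centre distance from the cavity
#'   centre, nm (default 1.5, the conventional starting separation from the
#'   secondary hydroxyl rim).
#' @param noise_sd per-frame Gaussian positional noise on guest beads, nm.
#' @param seed RNG seed for the noise.
#' @return list of class \code{binding_script}.
#' @export
binding_script <- function(mechanism = c("direct_insert", "surface_then_insert",
                                         "never_bind"),
                           orientation = c("O_toward_PHR", "O_toward_SHR"),
                           insertion_frame = 50L, approach_distance = 1.5,
                           noise_sd = 0.01, seed = 1L) {
  mechanism <- match.arg(mechanism)
  orientation <- match.arg(orientation)
  structure(list(mechanism = mechanism, orientation = orientation,
                 insertion_frame = as.integer(insertion_frame),
                 approach_distance = approach_distance,
                 noise_sd = noise_sd, seed = seed),
            class = "binding_script")
}

# rigid 8-bead rod guest: bead offsets along its axis, oxygen at one end
guest_beads <- function(cog, axis, oxygen_sign, length_nm = 1.7) {
  s <- seq(-length_nm / 2, length_nm / 2, length.out = 8L)
  if (oxygen_sign < 0) s <- rev(s)   # bead 8 (oxygen) at the negative end
  outer(s, axis) + matrix(cog, 8L, 3L, byrow = TRUE)
}

#' Generate a synthetic binding trajectory with ground truth
#'
#' Combines a static (optionally jittered) macrocycle with a rigid 8-bead
#' rod guest (~1.7 nm long, one end bead tagged as the guest hydroxyl
#' oxygen) moved along the scripted path. The returned ground truth records
#' the deterministic (noise-free) per-frame state and orientation under the
#' same geometric thresholds the classifier defaults to, plus the true
#' insertion frame -- analyses are tested against this ledger, never against
#' re-derived quantities.
#'
#' @param spec a \code{\link{ring_spec}} for the host.
#' @param script a \code{\link{binding_script}}.
#' @param n_frames number of frames.
#' @param dt frame spacing, ps.
#' @param d_insert,d_surface,max_angle thresholds used to derive the
#'   ground-truth state labels (mirroring the classifier defaults).
#' @return list with \code{topology}, \code{trajectory}, and
#'   \code{ground_truth} (data.frame frame/distance/state/orientation plus
#'   attribute-free list fields \code{insertion_frame}).
#' @export
make_binding_trajectory <- function(spec, script, n_frames = 200L, dt = 10,
                                    d_insert = 0.35, d_surface = 0.80,
                                    max_angle = 45) {
  stopifnot(inherits(spec, "ring_spec"), inherits(script, "binding_script"))
  if (script$mechanism != "never_bind" && script$insertion_frame >= n_frames)
    stopf("insertion_frame must be < n_frames")
  ring <- make_cd_ring(spec)
  n_host <- nrow(ring$coords)
  # cavity centre = midpoint of the PHR/SHR rim planes (not the box centre:
  # unequal rim offsets displace it axially)
  ctr <- spec$box / 2 +
    c(0, 0, (spec$z_offset[["phr"]] + spec$z_offset[["shr"]]) / 2)
  up <- c(0, 0, 1)                       # cavity axis (SHR -> PHR) of the host
  osign <- if (script$orientation == "O_toward_PHR") 1 else -1
  d0 <- script$approach_distance
  t_ins <- script$insertion_frame

  cogs <- matrix(NA_real_, n_frames, 3L)
  axes <- matrix(NA_real_, n_frames, 3L)
  if (script$mechanism == "direct_insert") {
    for (f in seq_len(n_frames)) {
      d <- d0 * max(0, 1 - (f - 1) / (t_ins - 1))
      cogs[f, ] <- ctr - up * d
      axes[f, ] <- up
    }
  } else if (script$mechanism == "surface_then_insert") {
    d_surf_pos <- 0.55                   # lying across the SHR plane
    t_rot0 <- t_ins - 10L
    t_app <- max(2L, min(t_rot0 - 1L, as.integer(round(0.15 * n_frames))))
    if (t_rot0 < 2L) stopf("insertion_frame too early for the two-stage pathway")
    for (f in seq_len(n_frames)) {
      if (f <= t_app) {
        d <- d0 + (d_surf_pos - d0) * (f - 1) / (t_app - 1)
        cogs[f, ] <- ctr - up * d
        axes[f, ] <- c(1, 0, 0)
      } else if (f <= t_rot0) {          # horizontal dwell on the surface
        cogs[f, ] <- ctr - up * d_surf_pos
        axes[f, ] <- c(1, 0, 0)
      } else if (f < t_ins) {            # upright rotation over 10 frames
        u <- (f - t_rot0) / (t_ins - t_rot0)
        th <- u * pi / 2
        cogs[f, ] <- ctr - up * d_surf_pos * (1 - u)
        axes[f, ] <- c(cos(th), 0, sin(th))
      } else {
        cogs[f, ] <- ctr
        axes[f, ] <- up
      }
    }
  } else {                               # never_bind
    for (f in seq_len(n_frames)) {
      cogs[f, ] <- ctr - up * d0
      axes[f, ] <- up
    }
  }

  # deterministic ground truth under the classifier's geometric rules
  state <- character(n_frames); orient <- character(n_frames)
  dist <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    dist[f] <- sqrt(sum((cogs[f, ] - ctr)^2))
    ang <- acos(min(1, abs(sum(axes[f, ] * up)))) * 180 / pi
    state[f] <- if (dist[f] <= d_insert && ang <= max_angle) "inserted"
                else if (dist[f] <= d_surface) "surface" else "unbound"
    orient[f] <- if (state[f] == "unbound") "undefined"
                 else if (osign * sum(axes[f, ] * up) >= 0) "O_toward_PHR"
                 else "O_toward_SHR"
  }
  old <- .Random.seed_save()
  set.seed(script$seed)
  coords <- array(NA_real_, dim = c(n_host + 8L, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    host <- ring$coords
    if (spec$jitter_sd > 0)
      host <- host + matrix(rnorm(length(host), sd = spec$jitter_sd), ncol = 3L)
    g <- guest_beads(cogs[f, ], axes[f, ], osign)
    if (script$noise_sd > 0)
      g <- g + matrix(rnorm(24L, sd = script$noise_sd), ncol = 3L)
    coords[, , f] <- rbind(host, g)
  }
  .Random.seed_restore(old)

  atoms <- rbind(ring$topology$atoms,
                 data.frame(name = c(sprintf("C%d", 1:7), "O"),
                            element = c(rep("C", 7L), "O"),
                            resname = "CHO", resid = spec$n_units + 1L,
                            stringsAsFactors = FALSE))
  gidx <- n_host + 1:8
  topo <- cd_topology(atoms,
                      phr_oxygens = ring$topology$phr_oxygens,
                      mid_oxygens = ring$topology$mid_oxygens,
                      shr_oxygens = ring$topology$shr_oxygens,
                      guest_atoms = gidx, guest_oxygen = n_host + 8L,
                      acceptors = c(1:n_host, n_host + 8L),
                      masses = c(ring$topology$masses, rep(14, 7L), 15.999))
  traj <- cd_trajectory(coords, spec$box, dt = dt)
  gt <- data.frame(frame = seq_len(n_frames), distance = dist,
                   state = state, orientation = orient,
                   stringsAsFactors = FALSE)
  ins <- which(state == "inserted")
  list(topology = topo, trajectory = traj, ground_truth = gt,
       insertion_frame = if (length(ins)) ins[1] else NA_integer_)
}

#' Place water oxygens in prescribed radial shells
#'
#' Samples exactly \code{shell_counts[k]} points uniformly within each
#' spherical shell \code{[edges[k], edges[k+1])} around \code{center}
#' (inverse-CDF radial sampling, r^3 uniform, so uniform density is exact),
#' plus \code{n_bulk} points uniform in the box but outside the outermost
#' edge.
#'
#' @param center length-3 centre (nm).
#' @param shell_counts integer counts, one per shell
#'   (\code{length(edges) - 1}).
#' @param edges strictly increasing shell edges, nm.
#' @param box box edge lengths, nm.
#' @param n_bulk additional points placed outside \code{max(edges)}.
#' @param seed RNG seed.
#' @return matrix of water-oxygen positions (nm).
#' @export
make_water_bath <- function(center, shell_counts, edges = c(0, 0.5, 0.8, 0.9, 1.0),
                            box = c(4, 4, 4), n_bulk = 0L, seed = 1L) {
  if (length(shell_counts) != length(edges) - 1L)
    stopf("need one count per shell (length(edges) - 1)")
  if (is.unsorted(edges, strictly = TRUE) || any(edges < 0))
    stopf("edges must be non-negative and strictly increasing")
  if (any(shell_counts > 0 & diff(edges) <= 0))
    stopf("cannot place points in a zero-width shell")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pts <- list()
  for (k in seq_along(shell_counts)) {
    m <- shell_counts[k]
    if (m == 0L) next
    lo <- edges[k]; hi <- edges[k + 1L]
    r <- (lo^3 + runif(m) * (hi^3 - lo^3))^(1 / 3)
    # guard the half-open bin convention against round-off at the top edge
    r <- pmin(r, hi * (1 - 1e-12))
    z <- runif(m, -1, 1); phi <- runif(m, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pts[[length(pts) + 1L]] <-
      cbind(center[1] + r * s * cos(phi), center[2] + r * s * sin(phi),
            center[3] + r * z)
  }
  if (n_bulk > 0L) {
    r_out <- max(edges)
    got <- matrix(NA_real_, 0L, 3L)
    while (nrow(got) < n_bulk) {
      cand <- cbind(runif(2L * n_bulk, 0, box[1]), runif(2L * n_bulk, 0, box[2]),
                    runif(2L * n_bulk, 0, box[3]))
      d <- min_image_dist(cand, center, box)
      got <- rbind(got, cand[d >= r_out, , drop = FALSE])
    }
    pts[[length(pts) + 1L]] <- got[seq_len(n_bulk), , drop = FALSE]
  }
  if (length(pts) == 0L) return(matrix(numeric(), 0L, 3L))
  do.call(rbind, pts)
}

#' Attach water oxygens to a system
#'
#' Appends water-oxygen atoms (resname SOL) to a topology/coordinate pair,
#' replicating the static water positions across frames when building a
#' trajectory.
#'
#' @param topology a \code{cd_topology}.
#' @param coords host coordinate matrix for one frame.
#' @param water_xyz matrix of water oxygen positions (nm).
#' @param box box edge lengths.
#' @param n_frames frames in the returned trajectory (static coordinates).
#' @param dt frame spacing, ps.
#' @return list with \code{topology} and \code{trajectory}.
#' @export
with_waters <- function(topology, coords, water_xyz, box, n_frames = 1L, dt = 10) {
  nw <- nrow(water_xyz)
  n0 <- nrow(coords)
  atoms <- rbind(topology$atoms,
                 data.frame(name = rep("OW", nw), element = "O",
                            resname = "SOL",
                            resid = max(topology$atoms$resid) + seq_len(nw),
                            stringsAsFactors = FALSE))
  topo <- cd_topology(atoms, topology$phr_oxygens, topology$mid_oxygens,
                      topology$shr_oxygens, topology$guest_atoms,
                      topology$guest_oxygen,
                      water_oxygens = n0 + seq_len(nw),
                      donors = topology$donors, hydrogens = topology$hydrogens,
                      acceptors = c(topology$acceptors, n0 + seq_len(nw)),
                      masses = c(topology$masses %||% rep(1, n0), rep(15.999, nw)))
  xyz <- rbind(coords, water_xyz)
  arr <- array(rep(xyz, n_frames), dim = c(nrow(xyz), 3L, n_frames))
  list(topology = topo, trajectory = cd_trajectory(arr, box, dt = dt))
}

#' Crooks-consistent work samples for estimator validation
#'
#' Draws forward work samples from Normal(dG + sigma^2/(2 kT), sigma^2) and
#' reverse work samples from Normal(-dG + sigma^2/(2 kT), sigma^2), the
#' unique Gaussian pair satisfying the Crooks fluctuation relation in
#' distribution, so any consistent estimator must recover \code{dg_true}.
#'
#' @param dg_true ground-truth free-energy difference, kJ/mol.
#' @param sigma_w work standard deviation, kJ/mol (> 0).
#' @param kT thermal energy, kJ/mol.
#' @param n_forward,n_reverse sample counts (>= 1).
#' @param seed RNG seed.
#' @return a \code{\link{lambda_samples}} object (lambda 0 and 1, one
#'   forward/reverse pair) with attribute \code{dg_true}.
#' @export
make_bar_samples <- function(dg_true, sigma_w = 5, kT = 2.577,
                             n_forward = 1e4, n_reverse = n_forward, seed = 1L) {
  if (sigma_w <= 0) stopf("'sigma_w' must be > 0")
  if (n_forward < 1L || n_reverse < 1L) stopf("need at least one sample per direction")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shift <- sigma_w^2 / (2 * kT)
  wf <- rnorm(n_forward, dg_true + shift, sigma_w)
  wr <- rnorm(n_reverse, -dg_true + shift, sigma_w)
  out <- lambda_samples(c(0, 1), forward = list(wf), reverse = list(wr),
                        temperature = kT / 0.00831446)
  attr(out, "dg_true") <- dg_true
  out
}

#' Planted hydrogen-bond episode series
#'
#' Builds a boolean existence matrix (pairs x frames) with known on-episode
#' structure for validating lifetime estimators. Episodes for each pair are
#' placed at random non-overlapping positions separated by at least one off
#' frame; the exact planted episodes are returned as the ledger attribute.
#'
#' @param n_pairs number of donor-acceptor pairs (rows).
#' @param n_frames number of frames (columns).
#' @param episode_lengths integer vector (recycled across pairs) or list
#'   (one vector per pair) of episode lengths in frames, each >= 1.
#' @param seed RNG seed.
#' @return logical matrix with attribute \code{ledger} (data.frame pair,
#'   start, length).
#' @export
make_hbond_episodes <- function(n_pairs, n_frames, episode_lengths, seed = 1L) {
  if (!is.list(episode_lengths))
    episode_lengths <- rep(list(as.integer(episode_lengths)),
                           length.out = n_pairs)
  if (length(episode_lengths) != n_pairs)
    episode_lengths <- rep(episode_lengths, length.out = n_pairs)
  if (any(unlist(episode_lengths) < 1L)) stopf("episode lengths must be >= 1 frame")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- matrix(FALSE, n_pairs, n_frames)
  ledger <- list()
  for (p in seq_len(n_pairs)) {
    lens <- episode_lengths[[p]]
    need <- sum(lens) + (length(lens) - 1L)
    if (need > n_frames)
      stopf("episodes for pair %d need %d frames but only %d are available (would overlap)",
            p, need, n_frames)
    slack <- n_frames - need
    # distribute the slack over the gaps before/between episodes
    cuts <- sort(sample.int(slack + length(lens), length(lens)) - seq_len(length(lens)))
    gaps <- diff(c(0L, cuts)) + c(0L, rep(1L, length(lens) - 1L))
    pos <- 1L
    for (e in seq_along(lens)) {
      pos <- pos + gaps[e]
      m[p, pos:(pos + lens[e] - 1L)] <- TRUE
      ledger[[length(ledger) + 1L]] <-
        data.frame(pair = p, start = pos, length = lens[e])
      pos <- pos + lens[e]
    }
  }
  attr(m, "ledger") <- do.call(rbind, ledger)
  m
}
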