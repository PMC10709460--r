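# per-atom group label used for hydrogen-bond bookkeeping and default
# analysis groups: water (resname SOL or listed water oxygen), guest, or CD
atom_group_labels <- function(topology) {
  lab <- rep("CD", n_atoms(topology))
  lab[topology$atoms$resname == "SOL"] <- "water"
  lab[topology$water_oxygens] <- "water"
  lab[topology$guest_atoms] <- "guest"
  lab
}

pair_label <- function(a, b) {
  ord <- c(water = 1L, CD = 2L, guest = 3L)
  p <- c(a, b)[order(ord[c(a, b)])]
  paste(p, collapse = "-")
}

#' Geometric hydrogen-bond detection in one frame
#'
#' A donor-hydrogen-acceptor triple forms a bond when the minimum-image
#' donor-acceptor distance is at most \code{r_cut} and the H-D-A angle is
#' at most \code{angle_cut} (defaults 0.35 nm / 30 degrees, the conventional
#' geometric criterion). The trivial case donor == acceptor is excluded.
#'
#' @param xyz \code{n_atoms x 3} coordinate matrix (nm) of one frame.
#' @param box length-3 box edge lengths (nm).
#' @param topology a \code{cd_topology} with donors/hydrogens/acceptors.
#' @param r_cut donor-acceptor distance cutoff, nm.
#' @param angle_cut H-D-A angle cutoff, degrees.
#' @return data.frame with columns \code{donor}, \code{hydrogen},
#'   \code{acceptor}, \code{pair} (group-pair label such as "water-CD").
#' @export
find_hbonds <- function(xyz, box, topology, r_cut = 0.35, angle_cut = 30) {
  if (r_cut <= 0 || angle_cut <= 0) stopf("cutoffs must be > 0")
  H <- topology$hydrogens; D <- topology$donors; A <- topology$acceptors
  if (length(H) != length(D))
    stopf("every hydrogen must be covalently assigned to exactly one donor")
  lab <- atom_group_labels(topology)
  cos_cut <- cos(angle_cut * pi / 180)
  out <- vector("list", length(H))
  for (i in seq_along(H)) {
    d <- D[i]; h <- H[i]
    acc <- A[A != d]
    if (length(acc) == 0L) next
    vDA <- min_image(sweep(xyz[acc, , drop = FALSE], 2L, xyz[d, ]), box)
    rDA <- sqrt(rowSums(vDA^2))
    keep <- rDA <= r_cut
    if (!any(keep)) next
    vDH <- as.numeric(min_image(xyz[h, ] - xyz[d, ], box))
    nDH <- sqrt(sum(vDH^2))
    cosang <- as.vector(vDA[keep, , drop = FALSE] %*% vDH) /
      (rDA[keep] * nDH)
    hit <- acc[keep][cosang >= cos_cut]
    if (length(hit))
      out[[i]] <- data.frame(donor = d, hydrogen = h, acceptor = hit,
                             pair = vapply(hit, function(a2)
                               pair_label(lab[d], lab[a2]), character(1)),
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), pair = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Hydrogen-bond counts per group pair over a trajectory
#'
#' Detects bonds in every window frame, aggregates counts by group-pair
#' label (water-CD, water-guest, guest-CD, CD-CD, water-water), and reports
#' window means with block-averaged standard errors, plus the per-pair
#' existence matrices needed for lifetime estimation.
#'
#' @inheritParams find_hbonds
#' @param trajectory a \code{cd_trajectory}.
#' @param window \code{NULL}, a \code{\link{tail_window}} or index vector.
#' @param n_blocks blocks for the standard error.
#' @return list with \code{per_frame} (long data.frame frame/pair/count),
#'   \code{summary} (pair, mean, se, lifetime_ps), \code{existence} (named
#'   list of boolean matrices, one row per distinct D-H-A triple),
#'   \code{dt}.
#' @export
pair_counts <- function(trajectory, topology, r_cut = 0.35, angle_cut = 30,
                        window = NULL, n_blocks = 5L) {
  idx <- resolve_window(trajectory, window)
  pairs_all <- c("water-CD", "water-guest", "CD-guest", "CD-CD", "water-water")
  bonds <- lapply(seq_along(idx), function(k) {
    b <- find_hbonds(frame_coords(trajectory, idx[k]),
                     trajectory$box[idx[k], ], topology, r_cut, angle_cut)
    if (nrow(b)) b$frame_pos <- k
    b
  })
  all_b <- do.call(rbind, bonds[vapply(bonds, nrow, integer(1)) > 0])
  per_frame <- expand.grid(frame = idx, pair = pairs_all,
                           stringsAsFactors = FALSE)
  per_frame$count <- 0L
  if (!is.null(all_b) && nrow(all_b)) {
    tab <- table(factor(all_b$pair, levels = pairs_all), all_b$frame_pos)
    for (p in rownames(tab)) {
      cnt <- as.integer(tab[p, as.character(seq_along(idx))])
      cnt[is.na(cnt)] <- 0L
      per_frame$count[per_frame$pair == p] <- cnt
    }
  }
  summ <- do.call(rbind, lapply(pairs_all, function(p) {
    v <- per_frame$count[per_frame$pair == p]
    ba <- block_average(v, n_blocks = min(n_blocks, length(v)))
    data.frame(pair = p, mean = ba$mean, se = ba$se, stringsAsFactors = FALSE)
  }))
  # existence matrices per pair class for lifetime estimation
  existence <- list()
  if (!is.null(all_b) && nrow(all_b)) {
    key <- paste(all_b$donor, all_b$hydrogen, all_b$acceptor)
    for (p in unique(all_b$pair)) {
      sel <- all_b$pair == p
      triples <- unique(key[sel])
      m <- matrix(FALSE, length(triples), length(idx),
                  dimnames = list(triples, NULL))
      m[cbind(match(key[sel], triples), all_b$frame_pos[sel])] <- TRUE
      existence[[p]] <- m
    }
  }
  summ$lifetime_ps <- vapply(summ$pair, function(p) {
    if (is.null(existence[[p]])) return(NA_real_)
    lifetimes(existence[[p]], trajectory$dt)$lifetime_ps
  }, numeric(1))
  list(per_frame = per_frame, summary = summ, existence = existence,
       dt = trajectory$dt)
}

#' Hydrogen-bond lifetimes from an existence matrix
#'
#' \code{definition = "continuous"} (default): the mean length of
#' uninterrupted on-episodes across all rows, times \code{dt}. Episodes
#' touching the first or last frame are censored (still counted, flagged).
#' \code{definition = "intermittent"}: dt times the sum of the normalized
#' existence autocorrelation C(t) from t = 0 up to (and excluding) its
#' first decay below 1/e.
#'
#' @param existence_matrix logical matrix, rows = bonds, columns = frames.
#' @param dt frame spacing, ps (> 0).
#' @param definition \code{"continuous"} or \code{"intermittent"}.
#' @return list with \code{lifetime_ps} (NA when no bond is ever present),
#'   \code{n_episodes}, \code{censored} (TRUE when any episode touches the
#'   trajectory boundary).
#' @export
lifetimes <- function(existence_matrix, dt,
                      definition = c("continuous", "intermittent")) {
  definition <- match.arg(definition)
  if (dt <= 0) stopf("'dt' must be > 0")
  m <- matrix(as.logical(existence_matrix), nrow = NROW(existence_matrix))
  if (!any(m))
    return(list(lifetime_ps = NA_real_, n_episodes = 0L, censored = FALSE))
  if (definition == "continuous") {
    eps <- integer(); censored <- FALSE
    for (r in seq_len(nrow(m))) {
      rl <- rle(m[r, ])
      on <- rl$lengths[rl$values]
      if (length(on)) {
        eps <- c(eps, on)
        if (m[r, 1] || m[r, ncol(m)]) censored <- TRUE
      }
    }
    list(lifetime_ps = mean(eps) * dt, n_episodes = length(eps),
         censored = censored)
  } else {
    nt <- ncol(m)
    x <- m * 1
    c0 <- sum(x * x)
    ct <- vapply(0:(nt - 1L), function(tau) {
      if (tau == 0) return(1)
      sum(x[, 1:(nt - tau), drop = FALSE] * x[, (tau + 1L):nt, drop = FALSE]) / c0
    }, numeric(1))
    below <- which(ct < exp(-1))
    upto <- if (length(below)) below[1] - 1L else nt
    list(lifetime_ps = sum(ct[seq_len(upto)]) * dt,
         n_episodes = NA_integer_, censored = !length(below))
  }
}
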