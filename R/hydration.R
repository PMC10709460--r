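#' Shell-wise water occupancy of the cavity
#'
#' Counts, per frame, the water oxygens whose minimum-image distance to the
#' cavity centre (midpoint of the PHR and SHR rim centroids) falls in each
#' half-open radial shell \code{[edge_k, edge_{k+1})} (lower edge
#' inclusive). Default shells 0-0.5, 0.5-0.8, 0.8-0.9, 0.9-1.0 nm. Window
#' means carry block-averaged standard errors; the total over the full
#' radial range is the exact sum of the shells on every frame.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology} with water oxygens and rim rings.
#' @param edges strictly increasing non-negative shell edges, nm.
#' @param window \code{NULL}, a \code{\link{tail_window}} or index vector.
#' @param center optional fixed centre (length 3, nm) overriding the
#'   per-frame cavity centre (used when no macrocycle is present).
#' @param n_blocks blocks for the standard error.
#' @return list with \code{edges}, \code{per_frame} (matrix, one row per
#'   window frame, one column per shell plus \code{total}), \code{summary}
#'   (shell, mean, se).
#' @export
shell_counts <- function(trajectory, topology, edges = c(0, 0.5, 0.8, 0.9, 1.0),
                         window = NULL, center = NULL, n_blocks = 5L) {
  if (length(topology$water_oxygens) == 0L) stopf("topology defines no water oxygens")
  if (any(edges < 0) || is.unsorted(edges, strictly = TRUE))
    stopf("shell edges must be non-negative and strictly increasing")
  idx <- resolve_window(trajectory, window)
  ns <- length(edges) - 1L
  cnts <- matrix(0L, length(idx), ns)
  for (k in seq_along(idx)) {
    xyz <- frame_coords(trajectory, idx[k])
    ctr <- if (is.null(center)) cavity_frame(xyz, topology)$center else center
    d <- min_image_dist(xyz[topology$water_oxygens, , drop = FALSE], ctr,
                        trajectory$box[idx[k], ])
    # half-open bins [edge_k, edge_{k+1}), lower-inclusive
    bin <- findInterval(d, edges)
    cnts[k, ] <- tabulate(bin[bin >= 1L & bin <= ns], nbins = ns)
  }
  shell_names <- sprintf("%g-%g nm", edges[-length(edges)], edges[-1])
  total <- rowSums(cnts)
  per_frame <- cbind(cnts, total)
  colnames(per_frame) <- c(shell_names, "total")
  summ <- do.call(rbind, lapply(seq_len(ns + 1L), function(j) {
    ba <- block_average(per_frame[, j], n_blocks = min(n_blocks, nrow(per_frame)))
    data.frame(shell = colnames(per_frame)[j], mean = ba$mean, se = ba$se,
               stringsAsFactors = FALSE)
  }))
  list(edges = edges, per_frame = per_frame, summary = summ, frames = idx)
}

#' Radial distribution function of water around the cavity centre
#'
#' \deqn{g(r) = \langle n(r) \rangle / (\rho_{bulk}\, 4\pi r^2 \Delta r)}
#' with a single reference point per frame (the cavity centre) and the bulk
#' density \eqn{\rho_{bulk} = N_{water} / V_{box}}.
#'
#' @inheritParams shell_counts
#' @param bin_width radial bin width, nm.
#' @param r_max maximal radius, nm; must not exceed half the smallest box
#'   edge.
#' @return data.frame with columns \code{r} (bin midpoint, nm) and \code{g}.
#' @export
rdf <- function(trajectory, topology, bin_width = 0.02, r_max = NULL,
                window = NULL, center = NULL) {
  if (bin_width <= 0) stopf("'bin_width' must be > 0")
  idx <- resolve_window(trajectory, window)
  half_box <- min(trajectory$box[idx, ]) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-9)
    stopf("r_max (%.3f nm) exceeds half the smallest box edge (%.3f nm)",
          r_max, half_box)
  nw <- length(topology$water_oxygens)
  if (nw == 0L) stopf("topology defines no water oxygens")
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  acc <- numeric(nb); rho_acc <- 0
  for (k in seq_along(idx)) {
    xyz <- frame_coords(trajectory, idx[k])
    ctr <- if (is.null(center)) cavity_frame(xyz, topology)$center else center
    d <- min_image_dist(xyz[topology$water_oxygens, , drop = FALSE], ctr,
                        trajectory$box[idx[k], ])
    bin <- findInterval(d, edges)
    acc <- acc + tabulate(bin[bin >= 1L & bin <= nb], nbins = nb)
    rho_acc <- rho_acc + nw / prod(trajectory$box[idx[k], ])
  }
  mean_n <- acc / length(idx)
  rho <- rho_acc / length(idx)
  mid <- (edges[-1] + edges[-(nb + 1L)]) / 2
  shell_vol <- 4 * pi * mid^2 * bin_width
  data.frame(r = mid, g = mean_n / (rho * shell_vol))
}
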