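# shared fixtures built in code at test time

regular_polygon <- function(n, radius = 1, z = 0, center = c(0, 0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), center[3] + z)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# quaternion (Horn) superposition oracle, independent of the SVD route
quaternion_rmsd <- function(x, y, w = NULL) {
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  xc <- sweep(x, 2, colSums(x * w)); yc <- sweep(y, 2, colSums(y * w))
  S <- crossprod(xc * w, yc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- sum(w * rowSums(xc^2)) + sum(w * rowSums(yc^2)) - 2 * lam
  sqrt(max(0, msd))
}

# one-frame trajectory around a coordinate matrix
one_frame_traj <- function(xyz, box = c(4, 4, 4), dt = 10) {
  cd_trajectory(array(xyz, c(nrow(xyz), 3, 1)), box, dt = dt)
}

# cavity centre of a single coordinate frame (midpoint of PHR/SHR centroids)
ring_center <- function(xyz, topo) {
  (colMeans(xyz[topo$phr_oxygens, , drop = FALSE]) +
   colMeans(xyz[topo$shr_oxygens, , drop = FALSE])) / 2
}

# distance from point p to the segment a-b (guest rod axis)
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}
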