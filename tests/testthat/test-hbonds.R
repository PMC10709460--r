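# random donor/hydrogen/acceptor fixture in a periodic box
random_hb_system <- function(n_donors = 100, box = c(3, 3, 3), seed = 1) {
  set.seed(seed)
  nd <- n_donors
  d_xyz <- cbind(runif(nd, 0, box[1]), runif(nd, 0, box[2]), runif(nd, 0, box[3]))
  # hydrogens near their donors, acceptors scattered
  h_xyz <- d_xyz + matrix(rnorm(nd * 3, sd = 0.07), nd)
  a_xyz <- cbind(runif(nd, 0, box[1]), runif(nd, 0, box[2]), runif(nd, 0, box[3]))
  xyz <- rbind(d_xyz, h_xyz, a_xyz)
  atoms <- data.frame(name = c(sprintf("OD%d", 1:nd), sprintf("H%d", 1:nd),
                               sprintf("OA%d", 1:nd)),
                      element = c(rep("O", nd), rep("H", nd), rep("O", nd)),
                      resname = "SOL", resid = seq_len(3 * nd))
  # rims are irrelevant here; reuse the first donors to satisfy the contract
  topo <- cd_topology(atoms, phr_oxygens = 1:3, mid_oxygens = 4:6,
                      shr_oxygens = 7:9,
                      donors = 1:nd, hydrogens = nd + 1:nd,
                      acceptors = 2 * nd + 1:nd)
  list(xyz = xyz, topo = topo, box = box, nd = nd)
}

# exhaustive double-loop reference detector
oracle_hbonds <- function(xyz, box, topo, r_cut, angle_cut) {
  hits <- list()
  for (i in seq_along(topo$hydrogens)) {
    d <- topo$donors[i]; h <- topo$hydrogens[i]
    for (a in topo$acceptors) {
      if (a == d) next
      vda <- xyz[a, ] - xyz[d, ]
      vda <- vda - box * round(vda / box)
      rda <- sqrt(sum(vda^2))
      if (rda > r_cut) next
      vdh <- xyz[h, ] - xyz[d, ]
      vdh <- vdh - box * round(vdh / box)
      ang <- acos(max(-1, min(1, sum(vda * vdh) /
                                (rda * sqrt(sum(vdh^2)))))) * 180 / pi
      if (ang <= angle_cut) hits[[length(hits) + 1]] <- c(d, h, a)
    }
  }
  if (!length(hits)) return(matrix(integer(), 0, 3))
  do.call(rbind, hits)
}

test_that("ideal and out-of-range geometries classify correctly", {
  atoms <- data.frame(name = c(sprintf("O%d", 1:9), "OD", "HD", "OA"),
                      element = c(rep("O", 9), "O", "H", "O"),
                      resname = c(rep("GLC", 9), "SOL", "SOL", "SOL"),
                      resid = c(rep(1, 9), 2, 2, 3))
  topo <- cd_topology(atoms, 1:3, 4:6, 7:9, donors = 10L, hydrogens = 11L,
                      acceptors = 12L)
  base <- rbind(regular_polygon(3, 0.5, z = 0.3, center = c(1.5, 1.5, 1.5)),
                regular_polygon(3, 0.5, z = 0, center = c(1.5, 1.5, 1.5)),
                regular_polygon(3, 0.5, z = -0.3, center = c(1.5, 1.5, 1.5)))
  # D at origin-ish, H on the D->A axis: ideal geometry at 0.28 nm
  xyz <- rbind(base, c(0.5, 0.5, 0.5), c(0.6, 0.5, 0.5), c(0.78, 0.5, 0.5))
  b <- find_hbonds(xyz, c(3, 3, 3), topo)
  expect_equal(nrow(b), 1L)
  expect_equal(b$pair, "water-water")
  # beyond the distance cutoff: no bond regardless of angle
  xyz2 <- xyz; xyz2[12, 1] <- 0.5 + 0.40
  expect_equal(nrow(find_hbonds(xyz2, c(3, 3, 3), topo)), 0L)
  # angle beyond 30 degrees at a valid distance
  xyz3 <- xyz
  xyz3[11, ] <- c(0.5 + 0.07 * cos(40 * pi / 180), 0.5 + 0.07 * sin(40 * pi / 180), 0.5)
  expect_equal(nrow(find_hbonds(xyz3, c(3, 3, 3), topo)), 0L)
})

test_that("detection matches the exhaustive oracle over random criteria", {
  sys <- random_hb_system(100, seed = 41)
  set.seed(43)
  for (k in 1:20) {
    r_cut <- runif(1, 0.2, 0.6)
    a_cut <- runif(1, 10, 60)
    got <- find_hbonds(sys$xyz, sys$box, sys$topo, r_cut, a_cut)
    want <- oracle_hbonds(sys$xyz, sys$box, sys$topo, r_cut, a_cut)
    got_key <- sort(sprintf("%d-%d-%d", got$donor, got$hydrogen, got$acceptor))
    want_key <- if (nrow(want)) sort(sprintf("%d-%d-%d", want[, 1], want[, 2], want[, 3])) else character()
    expect_identical(got_key, want_key)
  }
})

test_that("counts are monotone in both cutoffs and rotation invariant", {
  sys <- random_hb_system(80, seed = 47)
  n_of <- function(r, a) nrow(find_hbonds(sys$xyz, sys$box, sys$topo, r, a))
  for (r in c(0.25, 0.35, 0.45)) expect_lte(n_of(r, 30), n_of(r + 0.1, 30))
  for (a in c(15, 30, 45)) expect_lte(n_of(0.35, a), n_of(0.35, a + 15))
  # global rotation about the box centre preserves the bond set size
  rot <- random_rotation()
  ctr <- sys$box / 2
  xyz_r <- sweep(sweep(sys$xyz, 2, ctr) %*% t(rot), 2, ctr, "+")
  big_box <- c(30, 30, 30)   # suppress wrapping differences under rotation
  n0 <- nrow(find_hbonds(sys$xyz, big_box, sys$topo))
  n1 <- nrow(find_hbonds(xyz_r, big_box, sys$topo))
  expect_equal(n0, n1)
})

test_that("continuous and intermittent lifetimes recover planted episodes", {
  m <- matrix(FALSE, 1, 20); m[1, 6:10] <- TRUE
  lt <- lifetimes(m, dt = 10)
  expect_equal(lt$lifetime_ps, 50)         # one 5-frame episode at 10 ps
  expect_false(lt$censored)
  always <- matrix(TRUE, 1, 30)
  lt2 <- lifetimes(always, dt = 10)
  expect_equal(lt2$lifetime_ps, 300)
  expect_true(lt2$censored)
  never <- matrix(FALSE, 2, 10)
  expect_true(is.na(lifetimes(never, dt = 10)$lifetime_ps))
  # planted mixed-length episodes across many pairs
  eps <- make_hbond_episodes(60, 400, episode_lengths = list(c(2, 5), c(3, 7), 4),
                             seed = 51)
  led <- attr(eps, "ledger")
  est <- lifetimes(eps, dt = 10)
  expect_equal(est$n_episodes, nrow(led))
  expect_lt(abs(est$lifetime_ps - mean(led$length) * 10) / (mean(led$length) * 10),
            0.05)
  # intermittent definition on an uninterrupted episode is positive and finite
  expect_gt(lifetimes(m, dt = 10, definition = "intermittent")$lifetime_ps, 0)
})

test_that("pair counts aggregate by group label with block errors", {
  # one persistent water-guest bond: water donor + guest acceptor
  atoms <- data.frame(name = c(sprintf("O%d", 1:9), "OW", "HW", "C1", "OG"),
                      element = c(rep("O", 9), "O", "H", "C", "O"),
                      resname = c(rep("GLC", 9), "SOL", "SOL", "CHO", "CHO"),
                      resid = c(rep(1, 9), 2, 2, 3, 3))
  topo <- cd_topology(atoms, 1:3, 4:6, 7:9, guest_atoms = 12:13,
                      guest_oxygen = 13L, water_oxygens = 10L,
                      donors = 10L, hydrogens = 11L, acceptors = c(9L, 13L))
  base <- rbind(regular_polygon(3, 0.5, z = 0.3, center = c(2, 2, 2)),
                regular_polygon(3, 0.5, z = 0, center = c(2, 2, 2)),
                regular_polygon(3, 0.5, z = -0.3, center = c(2, 2, 2)))
  xyz <- rbind(base, c(0.5, 0.5, 0.5), c(0.6, 0.5, 0.5),
               c(1.2, 1.2, 1.2), c(0.78, 0.5, 0.5))
  tr <- cd_trajectory(array(rep(xyz, 10), c(13, 3, 10)), c(4, 4, 4), dt = 10)
  pc <- pair_counts(tr, topo)
  wg <- pc$summary[pc$summary$pair == "water-guest", ]
  expect_equal(wg$mean, 1.0)
  expect_equal(wg$se, 0)
  expect_equal(wg$lifetime_ps, 100)        # persistent over all 10 frames
  # no guest donors: the CD-guest class stays 0
  expect_equal(pc$summary$mean[pc$summary$pair == "CD-guest"], 0)
})

test_that("fewer donors yield fewer water-CD bonds (derivative direction)", {
  # host with 6 hydroxyl donors vs methylated host with 2, same water probe
  mk <- function(n_donors) {
    nd <- n_donors
    host <- rbind(regular_polygon(3, 0.4, z = 0.2, center = c(2, 2, 2)),
                  regular_polygon(3, 0.4, z = 0, center = c(2, 2, 2)),
                  regular_polygon(3, 0.4, z = -0.2, center = c(2, 2, 2)))
    # water acceptors placed 0.28 nm outside each rim oxygen
    wat <- sweep(host[1:6, , drop = FALSE], 2, c(2, 2, 2)) * 1.7
    wat <- sweep(wat, 2, c(2, 2, 2), "+")
    hyd <- host[1:nd, , drop = FALSE] +
      0.07 * (wat[1:nd, , drop = FALSE] - host[1:nd, , drop = FALSE]) /
      sqrt(rowSums((wat[1:nd, , drop = FALSE] - host[1:nd, , drop = FALSE])^2))
    xyz <- rbind(host, hyd, wat)
    atoms <- data.frame(name = c(sprintf("O%d", 1:9), sprintf("HO%d", 1:nd),
                                 sprintf("OW%d", 1:6)),
                        element = c(rep("O", 9), rep("H", nd), rep("O", 6)),
                        resname = c(rep("GLC", 9), rep("GLC", nd), rep("SOL", 6)),
                        resid = c(rep(1, 9 + nd), 2:7))
    topo <- cd_topology(atoms, 1:3, 4:6, 7:9,
                        water_oxygens = (9 + nd) + 1:6,
                        donors = 1:nd, hydrogens = 9 + 1:nd,
                        acceptors = (9 + nd) + 1:6)
    nrow(find_hbonds(xyz, c(4, 4, 4), topo))
  }
  expect_gt(mk(6), mk(2))
})
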