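test_that("best_fit_plane matches the SVD oracle and flags degeneracy", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- best_fit_plane(sq)
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(pl$centroid, c(0.5, 0.5, 0))
  expect_equal(pl$rmsd, 0)
  # jittered heptagon: residuals equal the smallest-singular-vector residuals
  set.seed(7)
  hep <- regular_polygon(7, 0.65) + matrix(rnorm(21, sd = 0.03), 7)
  pl2 <- best_fit_plane(hep)
  sv <- svd(sweep(hep, 2, colMeans(hep)))
  expect_equal(abs(sum(pl2$normal * sv$v[, 3])), 1, tolerance = 1e-10)
  expect_error(best_fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("rim_area reproduces closed forms and is rotation invariant", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(rim_area(sq), 1.0)
  hep <- regular_polygon(7, 0.65)
  expect_equal(rim_area(hep), 3.5 * 0.65^2 * sin(2 * pi / 7), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3)
    moved <- sweep(hep %*% t(rot), 2, shift, "+")
    expect_equal(rim_area(moved), rim_area(hep), tolerance = 1e-10)
  }
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_warning(rim_area(bow), "self-intersecting")
})

test_that("circularity conventions agree with exhaustive chord oracles", {
  for (n in 3:12)
    expect_equal(circularity(regular_polygon(n)), 1.0, tolerance = 1e-12)
  hep <- regular_polygon(7)
  expect_equal(circularity(hep, "literal"), sin(pi / 7) / sin(3 * pi / 7),
               tolerance = 1e-12)
  # squashed heptagon: compare against a brute-force scan over cross chords
  sq <- hep; sq[, 1] <- sq[, 1] * 0.8
  dm <- as.matrix(dist(sq))
  cross <- unlist(lapply(1:7, function(i) dm[i, ((i - 1 + c(3, 4)) %% 7) + 1]))
  expect_equal(circularity(sq), min(cross) / max(cross), tolerance = 1e-12)
  expect_lt(circularity(sq), 1)
  # literal <= cross_ring always (random distorted rings)
  set.seed(5)
  for (i in 1:20) {
    ring <- regular_polygon(7, 0.6) + matrix(rnorm(21, sd = 0.05), 7)
    expect_lte(circularity(ring, "literal"), circularity(ring) + 1e-12)
  }
})

test_that("rim_height is the centroid distance, mass-weighted when given", {
  a <- regular_polygon(7, 0.6, z = 0.33)
  b <- regular_polygon(7, 0.65, z = 0)
  expect_equal(rim_height(a, b), 0.33)
  expect_equal(rim_height(a, a), 0)
  set.seed(2)
  x <- matrix(rnorm(15), 5); y <- matrix(rnorm(12), 4)
  wx <- runif(5); wy <- runif(4)
  oracle <- sqrt(sum((colSums(x * wx) / sum(wx) - colSums(y * wy) / sum(wy))^2))
  expect_equal(rim_height(x, y, wx, wy), oracle, tolerance = 1e-12)
})

test_that("cavity_volume has cylinder/cone limits and is monotone", {
  expect_equal(cavity_volume(1, 1, 1, 0.5, 0.5), 2 * 1 * 0.5)
  expect_equal(cavity_volume(0, 1, 0, 0.3, 0.3), 2 * (0.3 / 3) * 1)
  # frustum value for the parent-macrocycle scale, computed independently
  frustum <- function(a1, a2, h) h / 3 * (a1 + a2 + sqrt(a1 * a2))
  expect_equal(cavity_volume(1.10, 0.83, 1.32, 0.22, 0.33),
               frustum(1.10, 0.83, 0.33) + frustum(1.32, 0.83, 0.22),
               tolerance = 1e-12)
  base <- cavity_volume(1.1, 0.83, 1.32, 0.22, 0.33)
  for (d in list(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0),
                 c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))) {
    args <- c(1.1, 0.83, 1.32, 0.22, 0.33) + d * 0.05
    expect_gt(do.call(cavity_volume, as.list(args)), base)
  }
  expect_error(cavity_volume(1, -1, 1, 0.1, 0.1), "positive")
})

test_that("per-frame rim geometry reproduces the generating ring spec", {
  spec <- ring_spec()   # parent-macrocycle scale, no jitter
  ring <- make_cd_ring(spec)
  geo <- rim_geometry(one_frame_traj(ring$coords, ring$box), ring$topology)
  pf <- geo$per_frame
  expect_equal(pf$A_MID, 3.5 * spec$radius[["mid"]]^2 * sin(2 * pi / 7),
               tolerance = 1e-10)
  expect_equal(pf$h12, 0.22, tolerance = 1e-12)
  expect_equal(pf$h16, 0.33, tolerance = 1e-12)
  expect_equal(pf$h, pf$h12 + pf$h16, tolerance = 1e-12)  # collinear centroids
  expect_equal(pf$omega_MID, 1, tolerance = 1e-12)
  expect_gt(pf$V_C, 0)
  # ellipticity on the SHR rim lowers its circularity only
  ell <- ring_spec(ellipticity = c(phr = 1, mid = 1, shr = 1.25))
  ring2 <- make_cd_ring(ell)
  geo2 <- rim_geometry(one_frame_traj(ring2$coords, ring2$box), ring2$topology)
  expect_lt(geo2$per_frame$omega_SHR, geo2$per_frame$omega_MID)
})

test_that("cog_distance tracks constructed separations with minimum image", {
  ring <- make_cd_ring(ring_spec())
  sys <- make_binding_trajectory(ring_spec(), binding_script("never_bind",
                                                             noise_sd = 0),
                                 n_frames = 5)
  d <- cog_distance(sys$trajectory, sys$topology$guest_atoms,
                    seq_len(nrow(ring$coords)))
  # guest COG sits 1.5 nm from the cavity centre; the full-ring COG is close
  # to but not exactly the cavity centre, so compare against direct arithmetic
  xyz <- frame_coords(sys$trajectory, 1)
  oracle <- sqrt(sum((colMeans(xyz[sys$topology$guest_atoms, ]) -
                      colMeans(xyz[seq_len(nrow(ring$coords)), ]))^2))
  expect_equal(d[1], oracle, tolerance = 1e-12)
  expect_equal(cog_distance(sys$trajectory, 1:5, 1:5), rep(0, 5))
  # minimum image: two points 3.5 nm apart in a 4 nm box are 0.5 nm apart
  xy <- rbind(c(0.25, 2, 2), c(3.75, 2, 2))
  tr <- one_frame_traj(xy, c(4, 4, 4))
  expect_equal(cog_distance(tr, 1L, 2L), 0.5)
})

test_that("binding classification recovers scripted mechanisms", {
  spec <- ring_spec(jitter_sd = 0.005)
  # direct insertion
  sys <- make_binding_trajectory(spec, binding_script("direct_insert",
                                                      "O_toward_SHR",
                                                      insertion_frame = 50,
                                                      seed = 7),
                                 n_frames = 200)
  cls <- classify_binding(sys$trajectory, sys$topology)
  expect_lte(abs(which(cls$state == "inserted")[1] - sys$insertion_frame), 2)
  ins <- cls$state == "inserted"
  expect_true(all(cls$orientation[ins] == "O_toward_SHR"))
  # never bind
  nb <- make_binding_trajectory(spec, binding_script("never_bind", seed = 3),
                                n_frames = 50)
  cls_nb <- classify_binding(nb$trajectory, nb$topology)
  expect_true(all(cls_nb$state == "unbound"))
  expect_true(all(cls_nb$orientation == "undefined"))
  expect_true(all(cls_nb$distance > 1.0))
  # two-stage pathway passes through a surface phase
  st <- make_binding_trajectory(spec, binding_script("surface_then_insert",
                                                     "O_toward_PHR",
                                                     insertion_frame = 120,
                                                     seed = 8),
                                n_frames = 200)
  cls_st <- classify_binding(st$trajectory, st$topology)
  expect_gt(sum(cls_st$state == "surface"), 50)
  expect_lte(abs(which(cls_st$state == "inserted")[1] - st$insertion_frame), 2)
  expect_true(all(cls_st$orientation[cls_st$state == "inserted"] == "O_toward_PHR"))
})
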