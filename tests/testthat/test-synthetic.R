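test_that("generators are bitwise reproducible from their seeds", {
  s1 <- make_cd_ring(ring_spec(jitter_sd = 0.02, seed = 7))
  s2 <- make_cd_ring(ring_spec(jitter_sd = 0.02, seed = 7))
  expect_identical(s1$coords, s2$coords)
  b1 <- make_bar_samples(-70, 5, 2.577, 100, seed = 9)
  b2 <- make_bar_samples(-70, 5, 2.577, 100, seed = 9)
  expect_identical(b1$forward, b2$forward)
  w1 <- make_water_bath(c(2, 2, 2), c(5, 5), edges = c(0, 0.5, 1), seed = 3)
  w2 <- make_water_bath(c(2, 2, 2), c(5, 5), edges = c(0, 0.5, 1), seed = 3)
  expect_identical(w1, w2)
  t1 <- make_binding_trajectory(ring_spec(jitter_sd = 0.01),
                                binding_script("direct_insert",
                                               insertion_frame = 10, seed = 4),
                                n_frames = 20)
  t2 <- make_binding_trajectory(ring_spec(jitter_sd = 0.01),
                                binding_script("direct_insert",
                                               insertion_frame = 10, seed = 4),
                                n_frames = 20)
  expect_identical(t1$trajectory$coords, t2$trajectory$coords)
  # generators do not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(make_bar_samples(-1, 1, 2.577, 10, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the generated ring realizes its specified geometry exactly", {
  spec <- ring_spec()
  ring <- make_cd_ring(spec)
  xyz <- ring$coords
  mid <- xyz[ring$topology$mid_oxygens, ]
  expect_equal(rim_area(mid), 3.5 * spec$radius[["mid"]]^2 * sin(2 * pi / 7),
               tolerance = 1e-10)
  expect_equal(rim_height(xyz[ring$topology$mid_oxygens, ],
                          xyz[ring$topology$phr_oxygens, ]), 0.33)
  expect_equal(circularity(xyz[ring$topology$shr_oxygens, ]), 1, tolerance = 1e-12)
  # ellipticity degrades circularity of the targeted rim
  ell <- make_cd_ring(ring_spec(ellipticity = c(phr = 1, mid = 1, shr = 1.25)))
  expect_lt(circularity(ell$coords[ell$topology$shr_oxygens, ]),
            circularity(ell$coords[ell$topology$mid_oxygens, ]))
})

test_that("binding scripts encode their ground truth faithfully", {
  spec <- ring_spec()
  # never_bind keeps the guest out at every frame
  nb <- make_binding_trajectory(spec, binding_script("never_bind", noise_sd = 0),
                                n_frames = 30)
  expect_true(all(nb$ground_truth$distance > 1.0))
  expect_true(all(nb$ground_truth$state == "unbound"))
  expect_true(is.na(nb$insertion_frame))
  # direct insertion reaches the centre at the scripted frame
  di <- make_binding_trajectory(spec, binding_script("direct_insert",
                                                     "O_toward_PHR",
                                                     insertion_frame = 40,
                                                     noise_sd = 0),
                                n_frames = 100)
  expect_lte(di$insertion_frame, 40)
  expect_true(all(di$ground_truth$state[40:100] == "inserted"))
  expect_true(all(di$ground_truth$orientation[di$ground_truth$state == "inserted"]
                  == "O_toward_PHR"))
  # oxygen bead projects positively toward PHR in inserted frames
  xyz <- frame_coords(di$trajectory, 60)
  cav <- cavity_frame(xyz, di$topology)
  proj <- sum((xyz[di$topology$guest_oxygen, ] -
               colMeans(xyz[di$topology$guest_atoms, ])) * cav$axis)
  expect_gt(proj, 0)
  expect_error(make_binding_trajectory(spec,
                                       binding_script(insertion_frame = 300),
                                       n_frames = 100), "n_frames")
})

test_that("water bath placement honours shell counts and exclusions", {
  ctr <- c(2, 2, 2)
  edges <- c(0, 0.5, 0.8, 0.9, 1.0)
  w <- make_water_bath(ctr, c(9, 20, 22, 46), edges, box = c(4, 4, 4),
                       n_bulk = 200, seed = 21)
  d <- sqrt(rowSums(sweep(w, 2, ctr)^2))
  expect_equal(nrow(w), 97 + 200)
  expect_equal(unname(table(cut(d[1:97], edges, right = FALSE))),
               c(9, 20, 22, 46), ignore_attr = TRUE)
  expect_true(all(d[98:297] >= 1.0 |
                  sqrt(rowSums(pmin(abs(sweep(w[98:297, ], 2, ctr)),
                                    4 - abs(sweep(w[98:297, ], 2, ctr)))^2)) >= 1.0))
  expect_error(make_water_bath(ctr, c(1, 2), edges = c(0, 0.5)), "one count")
  expect_error(make_water_bath(ctr, 5, edges = c(0.5, 0.5)), "increasing")
  # no points below 1.0 nm in a pure bulk bath -> empty inner region
  bulk <- make_water_bath(ctr, 0L, edges = c(0, 1.0), box = c(4, 4, 4),
                          n_bulk = 1000, seed = 22)
  db <- sqrt(rowSums(sweep(bulk, 2, ctr)^2))
  expect_true(all(db >= 1.0))
})

test_that("Crooks work samples satisfy the planted-gap construction", {
  kT <- 2.577; sw <- 5
  s <- make_bar_samples(-70, sw, kT, n_forward = 5e3, seed = 23)
  shift <- sw^2 / (2 * kT)
  expect_equal(mean(s$forward[[1]]), -70 + shift, tolerance = 4 * sw / sqrt(5e3) / abs(-70 + shift) * abs(-70 + shift))
  expect_equal(sd(s$forward[[1]]), sw, tolerance = 0.2)
  expect_equal(mean(s$reverse[[1]]), 70 + shift, tolerance = 0.3)
  # symmetric samples about zero estimate zero
  z <- make_bar_samples(0, 2, kT, 5e3, seed = 24)
  expect_lt(abs(bar_estimate(z, kT = kT, n_boot = 0)$dG), 0.2)
})

test_that("episode matrices route through counting to the generator ledger", {
  eps <- make_hbond_episodes(5, 50, episode_lengths = 5, seed = 25)
  led <- attr(eps, "ledger")
  expect_equal(nrow(led), 5L)
  expect_true(all(led$length == 5))
  # no overlaps: each row's episodes separated by at least one off frame
  for (p in 1:5) {
    rl <- rle(eps[p, ])
    expect_equal(sum(rl$lengths[rl$values]), 5)
  }
  expect_error(make_hbond_episodes(1, 10, episode_lengths = c(6, 6)), "overlap")
  lt <- lifetimes(eps, dt = 10)
  expect_equal(lt$lifetime_ps, 50)
})
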