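test_that("featureless reference reproduces symmetric input and is seeded", {
  # spherically symmetric input: rotation averaging must return it
  box <- 21
  g <- as.matrix(expand.grid(0:(box - 1), 0:(box - 1), 0:(box - 1)))
  r2 <- rowSums((g - (box - 1) / 2)^2)
  sym <- voxel_volume(array(exp(-r2 / 18), dim = c(box, box, box)),
                      voxel_size = 13.68)
  ref <- build_featureless_reference(list(sym, sym, sym), seed = 41)
  expect_gt(cor(as.numeric(ref$density$data), as.numeric(sym$data)), 0.99)

  # determinism under the seed
  asym <- structured_template(17)
  r1 <- build_featureless_reference(rep(list(asym), 10), seed = 42)
  r2b <- build_featureless_reference(rep(list(asym), 10), seed = 42)
  expect_identical(r1$density$data, r2b$density$data)
  r3 <- build_featureless_reference(rep(list(asym), 10), seed = 43)
  expect_false(identical(r1$density$data, r3$density$data))

  expect_error(build_featureless_reference(list(sym)),
               class = "ng_invalid_argument")
})

test_that("averaging many random orientations erases angular structure", {
  box <- 17
  asym <- structured_template(box)
  ref <- build_featureless_reference(rep(list(asym), 300), seed = 44)
  g <- as.matrix(expand.grid(0:(box - 1), 0:(box - 1), 0:(box - 1)))
  r <- sqrt(rowSums((g - (box - 1) / 2)^2))
  vals <- as.numeric(ref$density$data)
  # angular variance: spread on a mid-radius shell; radial variance:
  # spread of the shell means across radii
  shell_of <- round(r)
  mid <- round((box - 1) / 4)
  ang_var <- var(vals[shell_of == mid])
  shell_means <- tapply(vals[shell_of <= (box - 1) / 2],
                        shell_of[shell_of <= (box - 1) / 2], mean)
  rad_var <- var(as.numeric(shell_means))
  expect_lt(ang_var, 0.1 * rad_var)
})

test_that("reference truncation is local, masked and idempotent outside", {
  tpl <- template_volume(structured_template(11))
  # removal sphere entirely outside: identity
  t0 <- truncate_reference(tpl, c(100, 100, 100), 3)
  expect_identical(t0$density$data, tpl$density$data)
  expect_identical(t0$mask, tpl$mask)

  # removal changes exactly the voxels inside the sphere
  ctr <- c(3, 5, 5); rad <- 2.5
  t1 <- truncate_reference(tpl, ctr, rad)
  g <- as.matrix(expand.grid(0:10, 0:10, 0:10))
  inside <- rowSums((g - rep(ctr, each = nrow(g)))^2) <= rad^2
  changed <- as.numeric(t1$density$data) != as.numeric(tpl$density$data)
  expect_true(all(changed[!inside] == FALSE))
  expect_false(any(t1$mask[array(inside, dim = c(11, 11, 11))]))
  expect_true(all(t1$mask[!array(inside, dim = c(11, 11, 11))] ==
                    tpl$mask[!array(inside, dim = c(11, 11, 11))]))

  # two different truncations agree bit-exactly where both masks survive
  t2 <- truncate_reference(tpl, c(8, 5, 5), 2.5)
  both <- t1$mask & t2$mask
  expect_identical(t1$density$data[both], tpl$density$data[both])
  expect_identical(t2$density$data[both], tpl$density$data[both])

  expect_error(truncate_reference(tpl, c(5, 5, 5), 50),
               class = "ng_empty_template")
})

test_that("a planted template is found at its exact position with score 1", {
  tpl_vol <- structured_template(11)
  vol <- voxel_volume(array(0, dim = c(48, 48, 48)), voxel_size = 13.68)
  vol <- insert_template(vol, tpl_vol$data, c(20, 14, 9))
  hits <- match_template(vol, template_volume(tpl_vol), top_n = 5)
  expect_equal(unlist(hits[1, c("x", "y", "z")]),
               c(x = 25, y = 19, z = 14))
  expect_equal(hits$score[1], 1, tolerance = 1e-3)

  # template not smaller than volume errors
  expect_error(match_template(tpl_vol, template_volume(tpl_vol)),
               class = "ng_template_too_large")
})

test_that("planted copies at SNR 1 are recovered among the top peaks", {
  set.seed(45)
  tpl_vol <- structured_template(11)
  sig_sd <- sd(tpl_vol$data)
  corners <- as.matrix(expand.grid(x = c(4, 22, 40, 58, 76),
                                   y = c(10, 50), z = c(15, 55)))
  vol <- voxel_volume(array(rnorm(96^3, 0, sig_sd), dim = c(96, 96, 96)),
                      voxel_size = 13.68)
  for (i in seq_len(nrow(corners)))
    vol <- insert_template(vol, tpl_vol$data, corners[i, ])
  hits <- match_template(vol, template_volume(tpl_vol), top_n = 100)
  centers <- corners + 5
  top40 <- hits[1:40, ]
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((top40$x - centers[i, 1])^2 + (top40$y - centers[i, 2])^2 +
                (top40$z - centers[i, 3])^2)
    expect_lt(min(d), 1 + 1e-9)
  }
})

test_that("match scores are invariant to affine intensity changes", {
  set.seed(46)
  tpl_vol <- structured_template(9)
  vol <- voxel_volume(array(rnorm(32^3), dim = c(32, 32, 32)),
                      voxel_size = 13.68)
  h1 <- match_template(vol, template_volume(tpl_vol), top_n = 20)
  vol2 <- vol; vol2$data <- 3 * vol$data + 7
  h2 <- match_template(vol2, template_volume(tpl_vol), top_n = 20)
  expect_equal(h1$x, h2$x)
  expect_lt(max(abs(h1$score - h2$score)), 1e-6)
})

test_that("fewer surviving peaks than top_n yields a shorter list", {
  tpl_vol <- structured_template(9)
  vol <- voxel_volume(array(0, dim = c(32, 32, 32)), voxel_size = 13.68)
  vol <- insert_template(vol, tpl_vol$data, c(10, 10, 10))
  hits <- match_template(vol, template_volume(tpl_vol), top_n = 50,
                         nms_radius = 40)
  expect_lt(nrow(hits), 50)
})

test_that("consensus keeps mutual pairs within the distance bound only", {
  a <- particle_table(rep("t", 3), c(10, 20, 30), c(10, 10, 10),
                      c(5, 5, 5), score = c(0.9, 0.8, 0.7))
  # identical lists: everything retained in place
  cc <- consensus_filter(a, a)
  expect_equal(nrow(cc), 3)
  expect_equal(cc$x, a$x)
  expect_equal(cc$score, a$score)

  # boundary: distance 4.0 retained, 4.1 dropped
  b40 <- particle_table("t", 14, 10, 5, score = 0.5)
  b41 <- particle_table("t", 14.1, 10, 5, score = 0.5)
  one <- particle_table("t", 10, 10, 5, score = 0.9)
  expect_equal(nrow(consensus_filter(one, b40)), 1)
  expect_equal(nrow(consensus_filter(one, b41)), 0)
  # the retained particle is the midpoint with the mean score
  m <- consensus_filter(one, b40)
  expect_equal(m$x, 12)
  expect_equal(m$score, 0.7)

  expect_error(consensus_filter(one,
                                particle_table("other", 1, 1, 1)),
               class = "ng_invalid_argument")
})

test_that("consensus is symmetric in its arguments", {
  set.seed(47)
  a <- particle_table(rep("t", 60), runif(60, 0, 60), runif(60, 0, 60),
                      runif(60, 0, 60), score = runif(60))
  b <- particle_table(rep("t", 60), runif(60, 0, 60), runif(60, 0, 60),
                      runif(60, 0, 60), score = runif(60))
  ab <- consensus_filter(a, b)
  ba <- consensus_filter(b, a)
  expect_equal(nrow(ab), nrow(ba))
  ord <- function(d) d[order(d$x, d$y, d$z), c("x", "y", "z", "score")]
  expect_equal(ord(as.data.frame(ab)), ord(as.data.frame(ba)),
               ignore_attr = TRUE)
})

test_that("random lists are retained at the analytic proximity rate", {
  # two uniform 400-point lists in a 256^3 box; expected number of
  # <= 4-voxel pairs ~ n_a n_b (4/3 pi 4^3) / 256^3 = 2.56
  set.seed(48)
  lambda <- 400 * 400 * (4 / 3 * pi * 4^3) / 256^3
  n_draw <- 50
  counts <- replicate(n_draw, {
    a <- particle_table(rep("t", 400), runif(400, 0, 256),
                        runif(400, 0, 256), runif(400, 0, 256),
                        score = runif(400))
    b <- particle_table(rep("t", 400), runif(400, 0, 256),
                        runif(400, 0, 256), runif(400, 0, 256),
                        score = runif(400))
    nrow(consensus_filter(a, b))
  })
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / n_draw))
})

test_that("dual truncated references on pure noise retain only chance hits", {
  # the bias-mitigation property: matching two differently truncated
  # references against featureless noise and intersecting keeps far fewer
  # hits than either top-N list, at the chance rate of min-separated
  # random positions
  # complementary erasures leave near-disjoint scoring masks, so the two
  # score fields carry independent noise
  set.seed(49)
  tpl <- template_volume(structured_template(11))
  ta <- truncate_reference(tpl, c(10, 5, 5), 8.5)
  tb <- truncate_reference(tpl, c(0, 5, 5), 8.5)
  noise <- voxel_volume(array(rnorm(96^3), dim = c(96, 96, 96)),
                        voxel_size = 13.68)
  top_n <- 300
  nms <- 5
  ha <- match_template(noise, ta, top_n = top_n, nms_radius = nms)
  hb <- match_template(noise, tb, top_n = top_n, nms_radius = nms)
  kept <- consensus_filter(ha, hb, max_distance = 4)
  expect_lt(nrow(kept), top_n / 4)

  # chance oracle: random positions with the same minimum separation in
  # the same valid search region
  valid <- 96 - 11 + 1
  draw_thinned <- function() {
    cand <- matrix(runif(3 * 4000, 0, valid - 1), ncol = 3)
    keep <- nucleogradient:::.nms_select(cand, nms, top_n)
    cand[keep, , drop = FALSE] + 5
  }
  oracle <- replicate(60, {
    pa <- draw_thinned(); pb <- draw_thinned()
    nrow(consensus_filter(
      particle_table(rep("t", nrow(pa)), pa[, 1], pa[, 2], pa[, 3],
                     score = 0.1),
      particle_table(rep("t", nrow(pb)), pb[, 1], pb[, 2], pb[, 3],
                     score = 0.1),
      max_distance = 4))
  })
  expect_lt(abs(nrow(kept) - mean(oracle)),
            3 * max(sd(oracle), sqrt(mean(oracle))))
})
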