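# granule segmentation, enrichment, tracking and fusion counting

disk_image <- function(dim = c(60, 60), centers, radius = 3,
                       level = 1, background = 0) {
  img <- matrix(background, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
    cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2] <-
      level
  }
  img
}

test_that("component labelling is 8-connected and matches flood fill", {
  m <- matrix(0, 5, 5)
  m[2, 2] <- 1; m[3, 3] <- 1  # diagonal touch: one component
  lab <- label_components(m)
  expect_equal(max(lab), 1)

  set.seed(2)
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    ours <- label_components(mask)
    oracle <- flood_fill_label(mask)
    expect_equal(max(ours), max(oracle))
    # identical partitions (labels may be permuted)
    expect_equal(length(unique(paste(ours[mask], oracle[mask]))),
                 max(oracle))
  }
})

test_that("segmentation counts well-separated disks exactly", {
  centers <- rbind(c(15, 15), c(15, 45), c(30, 30), c(45, 15),
                   c(45, 45))
  img <- disk_image(centers = centers, level = 1, background = 0.05)
  cells <- matrix(1L, 60, 60)
  seg <- segment_granules(img, cells)
  expect_equal(seg$cells$n_granules, 5)
  expect_equal(seg$cells$mean_area, 29)  # 29 px in a radius-3 disk

  # uniform image: nothing above threshold
  seg0 <- segment_granules(matrix(0.5, 30, 30), matrix(1L, 30, 30))
  expect_equal(seg0$cells$n_granules, 0)

  # two touching disks merge into one 8-connected component
  img2 <- disk_image(centers = rbind(c(20, 20), c(20, 25)),
                     level = 1, background = 0)
  seg2 <- segment_granules(img2, matrix(1L, 60, 60),
                           threshold = "fixed", fixed_value = 0.5)
  expect_equal(seg2$cells$n_granules, 1)
  oracle <- flood_fill_label(img2 > 0.5)
  expect_equal(max(oracle), 1)

  expect_error(segment_granules(img, matrix(0L, 60, 60)), "empty")
})

test_that("enrichment is the granule mean over the cell mean", {
  img <- matrix(100, 40, 40)
  cell <- matrix(0L, 40, 40); cell[6:25, 6:25] <- 1L  # 400 px
  gl <- matrix(0L, 40, 40); gl[10:13, 10:19] <- 1L    # 40 px = 10%
  img[gl == 1L] <- 200
  es <- enrichment_score(img, gl, cell)
  expect_equal(es$enrichment, 200 / (0.1 * 200 + 0.9 * 100))
  # scale invariance
  es2 <- enrichment_score(img * 3.7, gl, cell)
  expect_equal(es2$enrichment, es$enrichment)
  # uniform image scores exactly 1
  esu <- enrichment_score(matrix(5, 40, 40), gl, cell)
  expect_equal(esu$enrichment, 1)
  # no granules: missing
  esn <- enrichment_score(img, matrix(0L, 40, 40), cell)
  expect_true(is.na(esn$enrichment))
})

test_that("greedy tracking links particles and measures displacement", {
  # static particles
  still <- replicate(5, data.frame(x = c(5, 20), y = c(5, 20)),
                     simplify = FALSE)
  ts <- track_particles(still, max_disp = 4)
  expect_equal(ts$mean_step, 0)

  # one particle moving 3 px/frame
  mov <- lapply(0:9, function(t) data.frame(x = 5 + 3 * t, y = 10))
  tm <- track_particles(mov, max_disp = 5)
  expect_equal(tm$mean_step, 3.0)
  expect_equal(length(unique(tm$tracks$track)), 1)

  # equals optimal matching when particles are well separated
  set.seed(6)
  for (i in 1:5) {
    a <- data.frame(x = c(5, 30, 55), y = c(5, 30, 55))
    b <- a + matrix(rnorm(6, 0, 1), 3)
    tr <- track_particles(list(a, b), max_disp = 5)
    got <- tr$tracks
    oracle <- brute_force_match(a, b, max_disp = 5)
    for (k in seq_len(nrow(oracle))) {
      tid <- got$track[got$frame == 1][oracle[k, 1]]
      expect_equal(got$x[got$frame == 2 & got$track == tid],
                   b$x[oracle[k, 2]])
    }
  }
})

test_that("fusion events require convergence plus area conservation", {
  # two particles converge; one persists with the combined area
  frames <- list(
    data.frame(x = c(10, 20), y = c(10, 10), area = c(10, 10)),
    data.frame(x = c(13, 17), y = c(10, 10), area = c(10, 10)),
    data.frame(x = 15, y = 10, area = 19),
    data.frame(x = 15, y = 10, area = 19))
  tr <- track_particles(frames, max_disp = 4)
  ev <- count_fusion_events(tr, merge_radius = 4)
  expect_equal(ev$n_events, 1)
  expect_true(ev$has_event)

  # never within the merge radius: no events
  far <- lapply(1:4, function(t)
    data.frame(x = c(10, 40), y = c(10, 10), area = c(10, 10)))
  expect_equal(count_fusion_events(track_particles(far, 4),
                                   merge_radius = 4)$n_events, 0)

  # area check: a vanishing particle near a small survivor is not a
  # fusion
  shrink <- list(
    data.frame(x = c(10, 13), y = c(10, 10), area = c(10, 10)),
    data.frame(x = 13, y = 10, area = 10),
    data.frame(x = 13, y = 10, area = 10))
  expect_equal(count_fusion_events(track_particles(shrink, 4),
                                   merge_radius = 4)$n_events, 0)

  # disappearance at the image border is excluded
  border <- list(
    data.frame(x = c(2, 6), y = c(2, 2), area = c(10, 10)),
    data.frame(x = 6, y = 2, area = 20),
    data.frame(x = 6, y = 2, area = 20))
  ev_b <- count_fusion_events(track_particles(border, 5),
                              merge_radius = 5, dims = c(50, 50),
                              border_margin = 3)
  expect_equal(ev_b$n_events, 0)
})

test_that("the imaging pipeline recovers planted movie truth", {
  mv <- simulate_movie(n_cells = 4, granules_per_cell = 5,
                       planted_fusions = 2, frames = 8, seed = 2)
  seg1 <- segment_granules(mv$frames[[1]], mv$cell_masks)
  expect_equal(seg1$cells$n_granules,
               unname(mv$truth$counts))

  dets <- lapply(mv$frames, function(fr) {
    s <- segment_granules(fr, mv$cell_masks)
    data.frame(x = s$granules$x, y = s$granules$y,
               area = s$granules$area)
  })
  fus <- count_fusion_events(track_particles(dets, max_disp = 5),
                             merge_radius = 5)
  expect_equal(fus$n_events, nrow(mv$truth$fusions))

  # no planted fusions -> none recovered; zero motion -> near-zero
  # tracked displacement
  mv0 <- simulate_movie(n_cells = 2, granules_per_cell = 4,
                        planted_fusions = 0, motion_sd = 0,
                        frames = 5, seed = 3)
  dets0 <- lapply(mv0$frames, function(fr) {
    s <- segment_granules(fr, mv0$cell_masks)
    data.frame(x = s$granules$x, y = s$granules$y,
               area = s$granules$area)
  })
  tr0 <- track_particles(dets0, max_disp = 5)
  expect_equal(count_fusion_events(tr0, merge_radius = 5)$n_events, 0)
  expect_lt(tr0$mean_step, 0.25)  # pixel-quantization jitter only
})

test_that("movies round-trip through TIFF files", {
  mv <- simulate_movie(n_cells = 1, granules_per_cell = 3,
                       planted_fusions = 0, frames = 2, seed = 4)
  dir <- withr::local_tempdir()
  write_movie_tiff(mv, dir)
  frames <- read_movie_tiff(dir)
  # cell_masks.tif sorts first; the two frames follow
  expect_equal(length(frames), 3)
  expect_equal(dim(frames[[2]]), dim(mv$frames[[1]]))
  expect_equal(max(abs(frames[[2]] - mv$frames[[1]])), 0,
               tolerance = 1 / 255)
})
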