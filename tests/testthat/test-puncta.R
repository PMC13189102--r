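test_that("background threshold is mean + k * SD of negative-control pixels", {
  const <- matrix(7, 20, 20)
  expect_equal(background_threshold(list(const), "ch")$value, 7)
  expect_equal(background_threshold(list(const), "ch", k = 2)$value, 7)
  set.seed(3)
  noisy <- matrix(rnorm(5000, 100, 15), 50, 100)
  thr <- background_threshold(list(noisy), "ch")
  expect_lt(abs(thr$value - 100), 3 * 15 / sqrt(5000))
  thr2 <- background_threshold(list(noisy), "ch", k = 1)
  expect_equal(thr2$value - thr$value, sd(noisy), tolerance = 1e-9)
  expect_error(background_threshold(list(), "ch"), "negative-control")
})

test_that("sub-threshold images contain no puncta", {
  im <- blank_channel(mean = 100, sd = 5, seed = 6)
  thr <- structure(list(channel = "ch", value = 100, k = 0, n_wells = 1),
                   class = "intensity_threshold")
  det <- detect_puncta(im, threshold = thr, background_sd = 5)
  expect_equal(nrow(det), 0)
  expect_error(detect_puncta(im, threshold = thr, channel = "other"),
               "does not match")
})

test_that("the 0.4-4 um gate excludes small and large spots but keeps 1 um", {
  px <- 0.3
  m <- matrix(100, 128, 128)
  add <- function(m, x, y, d_um, amp = 500, level = 60) {
    s <- (d_um / px / 2) / sqrt(2 * log(amp / level))
    ext <- ceiling(5 * s)
    xs <- (x - ext):(x + ext); ys <- (y - ext):(y + ext)
    m[ys, xs] <- m[ys, xs] + amp * outer(exp(-(ys - y)^2 / (2 * s^2)),
                                         exp(-(xs - x)^2 / (2 * s^2)))
    m
  }
  m <- add(m, 30, 30, 0.25)  # below the gate
  m <- add(m, 64, 64, 1.0)   # inside
  m <- add(m, 100, 100, 5)   # above
  thr <- structure(list(channel = "ch", value = 100, k = 0, n_wells = 1),
                   class = "intensity_threshold")
  det <- detect_puncta(channel_image(m, px), threshold = thr,
                       background_sd = 15)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x - 64)^2 + (det$y - 64)^2), 1)
  expect_equal(det$diameter_um, 1, tolerance = 0.25)
})

test_that("well-separated generated spots are all detected within 1 px of truth", {
  plate <- clean_plate(seed = 29)
  fd <- plate$wells$W01[[1]]
  thr <- background_threshold(
    lapply(plate$wells$W03, function(f) f$channels$puncta_a), "puncta_a")
  det <- detect_puncta(channel_image(fd$channels$puncta_a, 0.3),
                       threshold = thr, background_sd = 15)
  tr <- fd$truth$puncta[fd$truth$puncta$channel == "puncta_a", ]
  mm <- match_puncta(det, tr, max_dist_px = 1.5)
  expect_gte(mm$recall, 0.95)
  expect_gte(mm$precision, 0.95)
})

test_that("size-gate set equality holds on a noise-free constructed field", {
  px <- 0.3
  m <- matrix(100, 160, 160)
  diameters <- c(0.3, 0.8, 1.5, 2.5, 4.5, 6)
  xs <- c(20, 50, 80, 110, 140, 30)
  ys <- c(20, 50, 80, 110, 140, 120)
  level <- 60
  for (i in seq_along(diameters)) {
    s <- (diameters[i] / px / 2) / sqrt(2 * log(500 / level))
    ext <- ceiling(5 * s)
    xr <- (xs[i] - ext):(xs[i] + ext); yr <- (ys[i] - ext):(ys[i] + ext)
    m[yr, xr] <- m[yr, xr] + 500 * outer(exp(-(yr - ys[i])^2 / (2 * s^2)),
                                         exp(-(xr - xs[i])^2 / (2 * s^2)))
  }
  thr <- structure(list(channel = "ch", value = 100, k = 0, n_wells = 1),
                   class = "intensity_threshold")
  det <- detect_puncta(channel_image(m, px), threshold = thr,
                       background_sd = 15)
  inside <- diameters >= 0.4 & diameters <= 4
  expect_equal(nrow(det), sum(inside))
  for (i in which(inside)) {
    expect_true(any(sqrt((det$x - xs[i])^2 + (det$y - ys[i])^2) < 2))
  }
})

test_that("raising the threshold never increases the number of retained puncta", {
  plate <- clean_plate(seed = 31)
  fd <- plate$wells$W01[[1]]
  im <- channel_image(fd$channels$puncta_a, 0.3)
  counts <- vapply(c(100, 200, 350, 480), function(v) {
    thr <- structure(list(channel = "puncta_a", value = v, k = 0,
                          n_wells = 1), class = "intensity_threshold")
    nrow(detect_puncta(im, threshold = thr, background_sd = 15))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("colocalization counts overlap fractions with the at-least rule", {
  # constructed 4-px footprints with overlaps 1/4, 2/4, 3/4
  mk <- function(y, x) cbind(y = rep(y, 4), x = x + 0:3)
  A <- manual_puncta_set(list(mk(10, 10), mk(20, 10), mk(30, 10)), 64, 64)
  B <- manual_puncta_set(list(mk(10, 13), mk(20, 12), mk(30, 11)), 64, 64,
                         channel = "b")
  res <- colocalize(A, B, min_overlap = 0.5)
  expect_equal(res$pairs$overlap_fraction, c(0.25, 0.5, 0.75))
  expect_equal(res$colocalized_count, 2)  # the exact 0.50 tie counts
  # brute-force pixel oracle
  fa <- attr(A, "footprints"); fb <- attr(B, "footprints")
  oracle <- vapply(1:3, function(i)
    sum(fa == i & fb > 0) / sum(fa == i), numeric(1))
  expect_equal(res$pairs$overlap_fraction, oracle)
  # disjoint footprints -> none
  C <- manual_puncta_set(list(mk(50, 40)), 64, 64, channel = "b")
  expect_equal(colocalize(A, C)$colocalized_count, 0)
})

test_that("an A punctum overlapping two B puncta is counted once and bounds hold", {
  mk <- function(y, x, n = 4) cbind(y = rep(y, n), x = x + 0:(n - 1))
  A <- manual_puncta_set(list(mk(10, 10, 6)), 64, 64)
  B <- manual_puncta_set(list(mk(10, 10, 2), mk(10, 14, 2)), 64, 64, "b")
  res <- colocalize(A, B)
  expect_equal(res$colocalized_count, 1)
  expect_lte(res$colocalized_count, res$n_a)
  # simultaneous translation of both channels leaves the result unchanged
  A2 <- manual_puncta_set(list(mk(20, 22, 6)), 64, 64)
  B2 <- manual_puncta_set(list(mk(20, 22, 2), mk(20, 26, 2)), 64, 64, "b")
  expect_equal(colocalize(A2, B2)$pairs$overlap_fraction,
               res$pairs$overlap_fraction)
})

test_that("matched channel-B partners raise measured colocalization on simulated wells", {
  plate <- generate_plate_images(image_sim_config(
    rng_seed = 37, n_wells_per_group = 1, min_separation_um = 3,
    coloc_fraction = 0.6))
  fd <- plate$wells$W01[[1]]
  thr_a <- background_threshold(
    lapply(plate$wells$W03, function(f) f$channels$puncta_a), "puncta_a")
  thr_b <- background_threshold(
    lapply(plate$wells$W03, function(f) f$channels$puncta_b), "puncta_b")
  da <- detect_puncta(channel_image(fd$channels$puncta_a, 0.3),
                      threshold = thr_a, background_sd = 15)
  db <- detect_puncta(channel_image(fd$channels$puncta_b, 0.3),
                      threshold = thr_b, background_sd = 15)
  res <- colocalize(da, db)
  expect_gte(res$colocalized_count / nrow(da), 0.4)
  expect_lte(res$colocalized_count, nrow(da))
})
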