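test_that("directional deviation is the mean absolute deviation from the ray mean", {
  expect_equal(directional_deviation(c(50, 50, 50)), 0)
  expect_equal(directional_deviation(c(10, 20, 30)), 20 / 3)
  expect_equal(directional_deviation(c(0, 255, 0, 255)), 127.5)
  expect_error(directional_deviation(5), "length >= 2")
  expect_error(directional_deviation(numeric(0)), "length >= 2")
})

test_that("sampling regions sit at the quartering intersections with quarter windows", {
  # 40x40: 0-based centers {10,20,30}^2, 10x10 windows
  regs <- sampling_regions(matrix(0L, 40, 40))
  expect_length(regs, 9L)
  centers0 <- t(vapply(regs, function(r) r$center - 1L, numeric(2)))
  expect_equal(unique(centers0[, 1]), c(10, 20, 30))
  expect_equal(as.vector(centers0[, 2]), rep(c(10, 20, 30), 3))
  for (r in regs) {
    w <- r$window
    expect_equal(w[["r1"]] - w[["r0"]] + 1, 10)
    expect_equal(w[["c1"]] - w[["c0"]] + 1, 10)
    # window contains its center strictly inside
    expect_true(r$center[["row"]] > w[["r0"]] && r$center[["row"]] < w[["r1"]])
  }
  # 400x400: centers {100,200,300}^2, 100x100 windows
  regs4 <- sampling_regions(matrix(0L, 400, 400))
  centers0 <- t(vapply(regs4, function(r) r$center - 1L, numeric(2)))
  expect_equal(unique(centers0[, 1]), c(100, 200, 300))
  expect_true(all(vapply(regs4, function(r)
    r$window[["r1"]] - r$window[["r0"]] + 1 == 100, logical(1))))
})

test_that("sampling regions honor the mask bounding rectangle and error contracts", {
  img <- matrix(0L, 64, 64)
  mask <- matrix(0L, 64, 64)
  mask[11:50, 21:60] <- 1L   # 40x40 rectangle offset by (10, 20)
  regs <- sampling_regions(img, mask)
  base <- sampling_regions(matrix(0L, 40, 40))
  for (k in 1:9) {
    expect_equal(regs[[k]]$center[["row"]], base[[k]]$center[["row"]] + 10)
    expect_equal(regs[[k]]$center[["col"]], base[[k]]$center[["col"]] + 20)
  }
  expect_error(sampling_regions(img, matrix(0L, 64, 64)), "no nonzero")
  expect_error(sampling_regions(matrix(0L, 11, 40)), ">= 12")
  small_mask <- matrix(0L, 64, 64); small_mask[1:5, 1:30] <- 1L
  expect_error(sampling_regions(img, small_mask), ">= 12")
})

test_that("region rays walk from the center to the window edge", {
  img <- matrix(seq_len(25 * 25), 25, 25)
  # craft a region with a 5x5 window centered at (13, 13)
  region <- list(center = c(row = 13, col = 13),
                 window = c(r0 = 11, r1 = 15, c0 = 11, c1 = 15))
  rays <- region_rays(region, img)
  # direction 4 = east: center plus the two pixels to its right
  expect_equal(rays[[4]], c(img[13, 13], img[13, 14], img[13, 15]))
  # direction 1 = north-west diagonal
  expect_equal(rays[[1]], c(img[13, 13], img[12, 12], img[11, 11]))
  expect_true(all(lengths(rays) == 3L))
  # 3x3 window: every ray has exactly 2 pixels
  region3 <- list(center = c(row = 13, col = 13),
                  window = c(r0 = 12, r1 = 14, c0 = 12, c1 = 14))
  expect_true(all(lengths(region_rays(region3, img)) == 2L))
  # constant window yields 8 constant rays
  rays_c <- region_rays(region, matrix(42, 25, 25))
  expect_true(all(vapply(rays_c, function(v) all(v == 42), logical(1))))
})

test_that("checkerboard region roughness matches direct ray evaluation", {
  # 0/255 checkerboard: axis rays alternate, diagonal rays are constant
  img <- outer(1:40, 1:40, function(r, c) ((r + c) %% 2) * 255)
  reg <- sampling_regions(img)[[5]]
  rays <- region_rays(reg, img)
  di <- vapply(rays, directional_deviation, numeric(1))
  expect_equal(di[c(1, 3, 5, 7)], rep(0, 4))      # diagonals constant
  for (d in c(2, 4, 6, 8)) {
    v <- rays[[d]]
    expect_equal(di[d], mean(abs(v - mean(v))))
    expect_gt(di[d], 0)
  }
  expect_equal(region_roughness(reg, img), mean(di))
  # all nine regions are congruent on the periodic pattern
  rep_full <- peel_roughness(img)
  expect_true(all(abs(rep_full$per_region_pi - rep_full$per_region_pi[1]) < 1e-12))
  expect_equal(rep_full$overall, rep_full$per_region_pi[1])
})

test_that("roughness report satisfies its internal identities", {
  img <- rand_img(48, 36, seed = 9)
  rep <- peel_roughness(img)
  expect_equal(dim(rep$per_region_di), c(9L, 8L))
  expect_true(all(rep$per_region_di >= 0))
  expect_equal(rep$per_region_pi, unname(rowMeans(rep$per_region_di)))
  expect_equal(rep$overall, mean(rep$per_region_pi))
  expect_output(print(rep), "overall roughness")
})

test_that("constant images have exactly zero roughness", {
  rep <- peel_roughness(matrix(137L, 30, 30))
  expect_identical(unique(as.vector(rep$per_region_di)), 0)
  expect_identical(rep$overall, 0)
})

test_that("roughness is invariant under intensity inversion and periodic shift", {
  img <- rand_img(40, 40, seed = 31)
  expect_equal(peel_roughness(255 - img)$overall, peel_roughness(img)$overall)
  # periodic texture shifted by its period gives identical overall
  cb <- outer(1:48, 1:48, function(r, c) ((r + c) %% 2) * 255)
  big <- outer(1:52, 1:52, function(r, c) ((r + c) %% 2) * 255)
  shifted <- big[3:50, 3:50]
  expect_equal(peel_roughness(cb)$overall, peel_roughness(shifted)$overall)
})

test_that("roughness scales linearly with intensity on float-valued images", {
  set.seed(77)
  imgf <- matrix(runif(40 * 40, 0, 50), 40, 40)
  base <- peel_roughness(imgf)
  scaled <- peel_roughness(imgf * 3.5)
  expect_equal(scaled$overall, base$overall * 3.5)
  expect_equal(scaled$per_region_di, base$per_region_di * 3.5)
})

test_that("roughness increases with i.i.d. noise amplitude across seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    lo <- matrix(pmin(pmax(round(128 + rnorm(40 * 40, 0, 5)), 0), 255), 40, 40)
    set.seed(seed + 1000)
    hi <- matrix(pmin(pmax(round(128 + rnorm(40 * 40, 0, 40)), 0), 255), 40, 40)
    expect_gt(peel_roughness(hi)$overall, peel_roughness(lo)$overall)
  }
})
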