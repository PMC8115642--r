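test_that("a one-voxel lesion cannot host a 3 mm disc", {
  arr <- array(FALSE, c(5, 5, 5)); arr[3, 3, 3] <- TRUE
  m <- lesion_mask(arr, c(1, 1, 1))
  expect_error(enumerate_roi_placements(m), class = "washout_no_placement")
})

test_that("an empty mask signals the empty-lesion condition", {
  m <- lesion_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(enumerate_roi_placements(m), class = "washout_empty_mask")
})

test_that("placement enumeration equals brute force on a solid cuboid", {
  arr <- array(FALSE, c(13, 13, 5)); arr[2:12, 2:12, 2:4] <- TRUE
  m <- lesion_mask(arr, c(1, 1, 1))
  pl <- enumerate_roi_placements(m)
  bf <- oracle_roi_placements(m)
  expect_equal(nrow(pl), nrow(bf))
  # identical sets under the deterministic ordering
  o1 <- pl[order(pl$plane_axis, pl$slice, pl$row, pl$col), ]
  o2 <- bf[order(bf$plane_axis, bf$slice, bf$row, bf$col), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("every placement in a sphere satisfies full disc containment", {
  m <- make_sphere_mask(c(23, 23, 23), c(1, 1, 1), c(12, 12, 12), 10)
  pl <- enumerate_roi_placements(m)
  set.seed(7)
  for (i in sample(nrow(pl), 40)) {
    vox <- roi_member_voxels(m, pl[i, ], diameter = 3)
    expect_true(all(m$data[vox]))
  }
})

test_that("ROI mean signal averages the member voxels", {
  arr <- array(FALSE, c(9, 9, 3)); arr[2:8, 2:8, 2] <- TRUE
  m <- lesion_mask(arr, c(1, 1, 1))
  pl <- enumerate_roi_placements(m, planes = "axial")
  const <- phase_volume(array(7, c(9, 9, 3)), c(1, 1, 1), "pre")
  expect_equal(roi_mean_signal(const, pl[1, ]), 7)
  # planted gradient: mean equals direct summation over the members
  grad <- array(0, c(9, 9, 3))
  for (i in 1:9) for (j in 1:9) for (k in 1:3) grad[i, j, k] <- i + 10 * j + 100 * k
  gv <- phase_volume(grad, c(1, 1, 1), "early")
  p <- pl[3, ]
  vox <- oracle_roi_members(c(1, 1, 1), p, 3)
  expect_equal(roi_mean_signal(gv, p), mean(grad[vox]))
})

test_that("max-WI search equals brute force and recovers planted kinetics exactly", {
  spec <- phantom_spec(dim = c(20, 20, 14), spacing = c(1, 1, 1),
                       lesion = list(center = c(10, 10, 7), radius = 7),
                       subregions = list(list(center = c(8, 10, 7), radius = 4,
                                              si_pre = 100, ratio = 260, wi = 25)),
                       noise_sd = 0)
  ph <- simulate_phantom(spec)
  lk <- lesion_max_wi(ph$pre, ph$early, ph$delay, ph$mask)
  expect_equal(lk$wi, 25, tolerance = 1e-6)
  expect_equal(lk$curve_class, "fast_washout")
  bf <- oracle_max_wi(ph$pre, ph$early, ph$delay, ph$mask)
  expect_equal(lk$wi, bf$wi, tolerance = 1e-9)
  expect_equal(lk$n_placements, bf$n_placements)
  expect_equal(unlist(lk$placement[c("plane_axis", "slice", "row", "col")]),
               unlist(bf$placement), ignore_attr = TRUE)
  # the winning ROI lies inside the planted washout subregion
  vox <- roi_member_voxels(ph$mask, lk$placement, 3)
  ctr <- sweep(vox, 2, c(1, 1, 1), "*")
  expect_true(all(sqrt(rowSums(sweep(ctr, 2, c(8, 10, 7), "-")^2)) <= 4 + 1e-9))
})

test_that("uniform enhancement gives the voxelwise WI exactly", {
  spec <- phantom_spec(dim = c(16, 16, 12), spacing = c(1, 1, 1),
                       lesion = list(center = c(8, 8, 6), radius = 6),
                       lesion_template = list(si_pre = 150, ratio = 240, wi = 18),
                       noise_sd = 0)
  ph <- simulate_phantom(spec)
  lk <- lesion_max_wi(ph$pre, ph$early, ph$delay, ph$mask)
  expect_equal(lk$wi, 18, tolerance = 1e-12)
})

test_that("max-WI search matches brute force under anisotropic voxels", {
  arr <- array(FALSE, c(14, 14, 6)); arr[3:12, 3:12, 2:5] <- TRUE
  sp <- c(0.8, 1.2, 3)
  m <- lesion_mask(arr, sp)
  set.seed(5)
  mk <- function(base) phase_volume(array(base + runif(prod(dim(arr)), 0, 50),
                                          dim(arr)), sp, "pre")
  pre <- mk(100); early <- mk(220); delay <- mk(180)
  lk <- lesion_max_wi(pre, early, delay, m)
  bf <- oracle_max_wi(pre, early, delay, m)
  expect_equal(lk$wi, bf$wi, tolerance = 1e-9)
  expect_equal(lk$n_placements, bf$n_placements)
})

test_that("voxel fallback serves lesions smaller than the disc", {
  arr <- array(FALSE, c(6, 6, 6)); arr[3, 3, 3] <- TRUE; arr[4, 3, 3] <- TRUE
  m <- lesion_mask(arr, c(1, 1, 1))
  pre <- phase_volume(array(100, c(6, 6, 6)), c(1, 1, 1), "pre")
  early <- phase_volume(array(260, c(6, 6, 6)), c(1, 1, 1), "early")
  darr <- array(240, c(6, 6, 6)); darr[4, 3, 3] <- 220
  delay <- phase_volume(darr, c(1, 1, 1), "delay")
  expect_error(lesion_max_wi(pre, early, delay, m),
               class = "washout_no_placement")
  lk <- lesion_max_wi(pre, early, delay, m, fallback = "voxel")
  expect_equal(lk$wi, 40)   # the better of the two single voxels
  expect_equal(lk$n_placements, 2L)
})

test_that("longest diameter follows the in-plane Feret convention", {
  sp <- c(1, 1, 1)
  expect_equal(longest_diameter(lesion_mask(array(FALSE, c(4, 4, 4)), sp)), 0)
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  expect_equal(longest_diameter(lesion_mask(one, sp)), 0)
  # 30 x 10 x 10 voxel box: best single-slice span is sqrt(29^2 + 9^2)
  box <- array(FALSE, c(32, 12, 12)); box[2:31, 2:11, 2:11] <- TRUE
  expect_equal(longest_diameter(lesion_mask(box, sp)), sqrt(29^2 + 9^2),
               tolerance = 1e-9)
})

test_that("longest diameter equals the pairwise oracle on irregular masks", {
  set.seed(31)
  for (rep in 1:5) {
    arr <- array(runif(10 * 10 * 6) < 0.2, c(10, 10, 6))
    m <- lesion_mask(arr, c(1.1, 0.9, 2))
    expect_equal(longest_diameter(m), oracle_feret(m), tolerance = 1e-9)
  }
})

test_that("longest diameter is invariant under translation and axis permutation", {
  base <- array(FALSE, c(16, 16, 16)); base[4:9, 5:12, 6:8] <- TRUE
  sp <- c(1, 1.5, 2)
  d0 <- longest_diameter(lesion_mask(base, sp))
  shifted <- array(FALSE, c(16, 16, 16)); shifted[8:13, 3:10, 9:11] <- TRUE
  expect_equal(longest_diameter(lesion_mask(shifted, sp)), d0)
  perm <- aperm(base, c(3, 1, 2))
  expect_equal(longest_diameter(lesion_mask(perm, sp[c(3, 1, 2)])), d0)
})

test_that("longest diameter is monotone under dilation", {
  m0 <- make_sphere_mask(c(15, 15, 15), c(1, 1, 1), c(8, 8, 8), 4)
  m1 <- make_sphere_mask(c(15, 15, 15), c(1, 1, 1), c(8, 8, 8), 6)
  expect_true(longest_diameter(m1) >= longest_diameter(m0))
})

test_that("shrinkage proxy separates concentric from fragmented or eccentric shrinkage", {
  sp <- c(1, 1, 1)
  big <- make_sphere_mask(c(25, 25, 25), sp, c(13, 13, 13), 10)
  small <- make_sphere_mask(c(25, 25, 25), sp, c(13, 13, 13), 6)
  expect_equal(classify_shrinkage(big, small), "concentric")
  # fragmentation into three disjoint foci
  frag <- array(FALSE, c(25, 25, 25))
  for (cen in list(c(9, 9, 13), c(17, 9, 13), c(13, 18, 13)))
    frag <- frag | make_sphere_mask(c(25, 25, 25), sp, cen, 2)$data
  expect_equal(classify_shrinkage(big, lesion_mask(frag, sp)), "dendritic")
  # crescent hugging the original boundary: uneven shrinkage
  crescent <- big$data & !make_sphere_mask(c(25, 25, 25), sp, c(10, 13, 13), 9)$data
  expect_equal(classify_shrinkage(big, lesion_mask(crescent, sp)), "dendritic")
  # empty follow-up is CR, pattern undefined
  empty <- lesion_mask(array(FALSE, c(25, 25, 25)), sp)
  expect_error(classify_shrinkage(big, empty),
               class = "washout_undefined_shrinkage")
})

test_that("grid misalignment is rejected with the offending axis named", {
  a <- phase_volume(array(1, c(4, 4, 4)), c(1, 1, 1), "pre")
  b <- phase_volume(array(1, c(4, 4, 5)), c(1, 1, 1), "early")
  expect_error(washoutMRI:::check_grid_alignment(a, b), "axis 3")
  c2 <- phase_volume(array(1, c(4, 4, 4)), c(1, 2, 1), "early")
  expect_error(washoutMRI:::check_grid_alignment(a, c2), "axis 2")
})
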