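test_that("a 200 um confinement with 25 um rings has 4 rings at the expected mid-radii", {
  geo <- confinement_geometry(110, 110, 100, 1)
  rim <- build_ring_index(geo, c(220, 220), ring_thickness_um = 25)
  expect_equal(attr(rim, "ring_count"), 4L)
  rings <- attr(rim, "rings")
  expect_equal(rings$r_mid_um, c(12.5, 37.5, 62.5, 87.5))
  expect_equal(rings$r_inner_um, c(0, 25, 50, 75))
  expect_equal(rings$r_outer_um, c(25, 50, 75, 100))
})

test_that("ring thickness at or above the radius collapses to a single ring", {
  geo <- confinement_geometry(11, 11, 8, 1)
  rim <- build_ring_index(geo, c(21, 21), ring_thickness_um = 10)
  expect_equal(attr(rim, "ring_count"), 1L)
  inside <- !is.na(rim)
  expect_true(all(rim[inside] == 0L))
})

test_that("ring assignment matches exhaustive per-pixel enumeration", {
  geo <- confinement_geometry(11, 11, 9, 1)
  rim <- build_ring_index(geo, c(21, 21), ring_thickness_um = 3)
  brute <- brute_force_rings(geo, c(21, 21), 3)
  expect_identical(unclass(rim)[TRUE], brute[TRUE])
  # partition: every in-circle pixel sits in exactly one ring
  expect_equal(sum(!is.na(rim)), sum(!is.na(brute)))
})

test_that("per-ring pixel counts and class tallies equal brute force on random maps", {
  for (seed in 1:5) {
    for (side in c(21, 64)) {
      lm <- random_label_map(c(side, side), seed = seed)
      geo <- confinement_geometry((side + 1) / 2, (side + 1) / 2,
                                  side * 0.45, 1.5)
      rim <- build_ring_index(geo, dim(lm), ring_thickness_um = 20)
      prof <- compute_ring_fractions(lm, rim)
      brute <- brute_force_rings(geo, dim(lm), 20)
      for (k in prof$ring) {
        in_ring <- !is.na(brute) & brute == k
        expect_equal(prof$n_pixels[prof$ring == k], sum(in_ring))
        for (cls in 1:3) {
          expected <- if (sum(in_ring) > 0) {
            sum(lm[in_ring] == cls) / sum(in_ring)
          } else NA_real_
          got <- prof[[paste0("frac_", STAIN_LEVELS[cls])]][prof$ring == k]
          expect_equal(got, expected)
        }
      }
      sums <- prof$frac_adipogenic + prof$frac_osteogenic + prof$frac_negative
      expect_true(all(abs(sums[prof$n_pixels > 0] - 1) < 1e-9))
      expect_equal(sum(prof$n_pixels), sum(!is.na(brute)))
    }
  }
})

test_that("uniform and constructed two-zone maps give exact fractions", {
  geo <- confinement_geometry(16, 16, 12, 1)
  rim <- build_ring_index(geo, c(31, 31), ring_thickness_um = 6)
  all_osteo <- as_label_map(matrix(2L, 31, 31))
  prof <- compute_ring_fractions(all_osteo, rim)
  expect_true(all(prof$frac_osteogenic[prof$n_pixels > 0] == 1))
  expect_true(all(prof$frac_adipogenic[prof$n_pixels > 0] == 0))

  # inner two rings adipogenic, outer rings osteogenic, by construction
  lm <- matrix(2L, 31, 31)
  lm[unclass(rim) %in% c(0L, 1L)] <- 1L
  prof2 <- compute_ring_fractions(as_label_map(lm), rim)
  expect_equal(prof2$frac_adipogenic[prof2$n_pixels > 0],
               c(1, 1, 0, 0)[seq_len(sum(prof2$n_pixels > 0))])
})

test_that("empty rings are flagged NA, never silently zero", {
  # tiny image far smaller than the confinement: outer rings are empty
  geo <- confinement_geometry(3, 3, 40, 1)
  rim <- build_ring_index(geo, c(5, 5), ring_thickness_um = 20)
  prof <- compute_ring_fractions(as_label_map(matrix(1L, 5, 5)), rim)
  expect_equal(attr(rim, "ring_count"), 2L)
  expect_equal(prof$n_pixels[2], 0L)
  expect_true(is.na(prof$frac_adipogenic[2]))
  expect_equal(prof$frac_adipogenic[1], 1)
})

test_that("contract violations are rejected", {
  geo <- confinement_geometry(5, 5, 4, 1)
  expect_error(build_ring_index(geo, c(9, 9), ring_thickness_um = 0),
               "positive")
  rim <- build_ring_index(geo, c(9, 9), 2)
  expect_error(compute_ring_fractions(as_label_map(matrix(1L, 4, 4)), rim),
               "dimensions differ")
})
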