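test_that("layout_patches orders patches thin to thick and fills the box", {
  # deliberately shuffled input order
  lip <- lipid_specs(c("DGPC", "DYPC", "DNPC", "DOPC"),
                     c(4.56, 3.34, 4.95, 4.11))
  lay <- layout_patches(lip, box_length_x = 40, overlap_widths = c(2, 2, 2))
  expect_equal(lay$reference_thickness, sort(lay$reference_thickness))
  expect_equal(lay$x_lo[1], 0)
  expect_equal(lay$x_hi[4], 40)
  # equal pure widths after subtracting overlaps
  expect_equal(unique(round(lay$x_hi - lay$x_lo, 10)), (40 - 6) / 4)
  # pure widths + overlaps tile the box exactly
  expect_equal(sum(lay$x_hi - lay$x_lo) + 6, 40)
  # deterministic
  expect_identical(lay, layout_patches(lip, 40, c(2, 2, 2)))
})

test_that("layout_patches validates its inputs", {
  lip <- four_lipids()
  expect_error(layout_patches(lip, 5, c(2, 2, 2)), class = "memgrad_sizing_error")
  expect_error(layout_patches(lip, 40, c(2, 2)), class = "memgrad_validation_error")
  expect_error(lipid_specs(c("A", "A"), c(3, 4)), class = "memgrad_validation_error")
  # single lipid, no overlaps -> one patch covering the box
  one <- layout_patches(lipid_specs("DOPC", 4.11), 40, numeric())
  expect_equal(c(one$x_lo, one$x_hi), c(0, 40))
})

test_that("predicted profile is constant in pure patches and linear across overlaps", {
  lip <- lipid_specs(c("A", "B"), c(3, 4))
  # pure [0,9) and [11,20) with overlap [9,11): midpoint interpolates to 3.5
  lay <- layout_patches(lip, 20, overlap_widths = 2)
  expect_equal(blueprint_thickness_at(lay, 10), 3.5)
  expect_equal(blueprint_thickness_at(lay, c(4, 15)), c(3, 4))
  expect_equal(blueprint_thickness_at(lay, 9.5), 3.25)

  # zero overlap -> step function
  lay0 <- layout_patches(lip, 20, overlap_widths = 0)
  expect_equal(blueprint_thickness_at(lay0, c(9.99, 10)), c(3, 4))

  # single-lipid layout -> constant profile
  prof1 <- predict_thickness_profile(layout_patches(lipid_specs("A", 4.2), 40,
                                                    numeric()))
  expect_true(all(prof1$thickness == 4.2))

  # four-lipid layout spans the single-component anchor thicknesses
  prof4 <- predict_thickness_profile(layout_patches(four_lipids(), 40,
                                                    c(2, 2, 2)), 0.25)
  expect_equal(range(prof4$thickness), c(3.34, 4.95))
  expect_true(all(diff(prof4$thickness) >= 0))  # monotone for ordered lipids
})

test_that("optimize_overlap picks the candidate minimizing max deviation", {
  lip <- four_lipids()
  target <- thickness_target(0.077, c(8, 32))
  cand <- c(0, 1, 2, 3, 4, 5, 6)
  best <- optimize_overlap(lip, 40, target, cand)
  scan <- attr(best, "candidates")
  # exhaustive oracle: returned objective is the minimum over all candidates
  expect_equal(attr(best, "objective"), min(scan$objective))
  for (w in cand) {
    lay_w <- layout_patches(lip, 40, rep(w, 3))
    expect_gte(memgrad:::overlap_objective(lay_w, target, 0.1) + 1e-12,
               attr(best, "objective"))
  }
  # single candidate is returned as-is
  single <- optimize_overlap(lip, 40, target, 2)
  expect_equal(single$overlap_right[1], 2)
  expect_error(optimize_overlap(lip, 40, target, numeric()),
               class = "memgrad_validation_error")
})

test_that("a perfectly linear two-lipid ramp yields objective ~ 0", {
  lip <- lipid_specs(c("A", "B"), c(3, 4))
  # overlap = entire middle: with pure width w and overlap v, profile is linear
  # over the ramp; choose target region inside the ramp of the v = 10 layout
  target <- thickness_target(0.1, c(6, 14))
  best <- optimize_overlap(lip, 20, target, c(2, 6, 10), bin_width = 0.05)
  expect_equal(best$overlap_right[1], 10)
  expect_lt(attr(best, "objective"), 1e-10)
})

test_that("flat-bottom restraints round-trip and obey the closed form", {
  lay <- layout_patches(four_lipids(), 40, c(2, 2, 2),
                        restraint = restraint_spec(force_constant = 1000))
  path <- withr::local_tempfile(fileext = ".itp")
  tab <- write_flat_bottom_restraints(lay, path)
  back <- read_flat_bottom_restraints(path)
  expect_equal(back$name, tab$name)
  expect_equal(back$center, tab$center)
  expect_equal(back$half_width, tab$half_width)
  expect_equal(back$force_constant, tab$force_constant)
  # bit-stable serialization
  path2 <- withr::local_tempfile(fileext = ".itp")
  write_flat_bottom_restraints(lay, path2)
  expect_identical(readLines(path), readLines(path2))

  # zero-force region covers pure interval plus shared overlaps
  expect_equal(tab$center[1], (0 + 10.5) / 2)
  expect_equal(tab$half_width[1], 10.5 / 2)
  # potential: 0 at centre, half k r^2 one nm beyond the wall
  expect_equal(flat_bottom_energy(tab$center[1], tab$center[1],
                                  tab$half_width[1], 1000), 0)
  expect_equal(flat_bottom_energy(tab$center[1] + tab$half_width[1] + 1,
                                  tab$center[1], tab$half_width[1], 1000),
               0.5 * 1000)
})

test_that("thickness profile CSV round-trips", {
  prof <- predict_thickness_profile(layout_patches(four_lipids(), 40,
                                                   c(2, 2, 2)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thickness_profile(prof, path)
  back <- read_thickness_profile(path)
  expect_equal(back$x, prof$x)
  expect_equal(back$thickness, prof$thickness)
})
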