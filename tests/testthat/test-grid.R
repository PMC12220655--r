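test_that("grid construction enforces the geometric invariants", {
  expect_error(structured_grid(8, 8, dx = 0, dy = 0.1), "positive")
  # fully blocked axial station
  m <- matrix(FALSE, 8, 8); m[3, ] <- TRUE
  expect_error(structured_grid(8, 8, 0.1, 0.1, mask = m, periodic_x = FALSE),
               "blocked")
  # axial periodicity demands identical masks at the seam stations
  m2 <- matrix(FALSE, 8, 8); m2[1, 4] <- TRUE
  expect_error(structured_grid(8, 8, 0.1, 0.1, mask = m2, periodic_x = TRUE),
               "identical")
  expect_silent(structured_grid(8, 8, 0.1, 0.1, mask = m2, periodic_x = FALSE))
  # isolated single-cell fluid hole
  m3 <- matrix(FALSE, 8, 8)
  m3[3:5, 3:5] <- TRUE; m3[4, 4] <- FALSE
  expect_error(structured_grid(8, 8, 0.1, 0.1, mask = m3, periodic_x = FALSE),
               "isolated")
})

test_that("open area counts only fluid cells and is positive", {
  m <- matrix(FALSE, 8, 10); m[4, 3:6] <- TRUE; m[5, 3:6] <- TRUE
  m[1, ] <- FALSE
  g <- structured_grid(8, 10, 0.2, 0.1, mask = m, periodic_x = FALSE)
  expect_equal(open_area(g)[1], 10 * 0.1)
  expect_equal(open_area(g)[4], 6 * 0.1)
  expect_true(all(open_area(g) > 0))
})

test_that("axial tiling replicates the mask and opens the ends", {
  m <- matrix(FALSE, 8, 6); m[3:4, 2:3] <- TRUE
  g <- structured_grid(8, 6, 0.2, 0.2, mask = m, periodic_x = TRUE,
                       n_segments = 3L)
  gt <- tile_grid(g)
  expect_equal(gt$nx, 24L)
  expect_false(gt$periodic_x)
  expect_equal(gt$mask[1:8, ], gt$mask[9:16, ])
  expect_equal(gt$mask[1:8, ], m)
  expect_equal(gt$Lx, 3 * g$Lx)
})
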