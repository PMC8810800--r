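# 2D tissue: obstacle generators, neighbor topology, CV estimator

test_that("random obstacle masks honor the exact count contract", {
  m <- generate_random_obstacles(100, 100, 0.15, seed = 11)
  expect_identical(sum(m), 1500L)
  expect_identical(sum(generate_random_obstacles(100, 100, 0, seed = 1)), 0L)
  for (fr in c(0.01, 0.2, 0.333)) {
    for (s in 1:2) {
      expect_identical(sum(generate_random_obstacles(50, 40, fr, seed = s)),
                       as.integer(round(fr * 2000)))
    }
  }
  expect_error(generate_random_obstacles(10, 10, 1), class = "bacnavsim_invalid_input")
  expect_error(generate_random_obstacles(10, 10, -0.1), class = "bacnavsim_invalid_input")
})

test_that("obstacle masks are reproducible by seed and leave the RNG untouched", {
  a <- generate_random_obstacles(100, 100, 0.1, seed = 5)
  b <- generate_random_obstacles(100, 100, 0.1, seed = 5)
  c <- generate_random_obstacles(100, 100, 0.1, seed = 6)
  expect_identical(a, b)
  expect_gt(sum(a != c), 0)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_random_obstacles(50, 50, 0.2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("vertical obstacle masks hit exact coverage with vertical texture", {
  m <- generate_vertical_obstacles(100, 100, 0.20, strip_length = 10, seed = 2)
  expect_identical(sum(m), 2000L)
  # strips run along y (the second index) at a fixed x-index
  runs_in <- function(mat) {
    unlist(apply(mat, 1, function(line) {
      r <- rle(line)
      r$lengths[r$values]
    }))
  }
  vert <- runs_in(m)       # runs along y within each x line
  horiz <- runs_in(t(m))   # runs along x within each y line
  expect_gt(mean(vert), 2 * mean(horiz))
  expect_error(generate_vertical_obstacles(100, 100, 0.2, strip_length = 0),
               class = "bacnavsim_invalid_input")
})

test_that("strip length one is statistically indistinguishable from random placement", {
  m <- generate_vertical_obstacles(100, 100, 0.15, strip_length = 1, seed = 8)
  expect_identical(sum(m), 1500L)
  counts <- colSums(m)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("grid neighbor topology severs obstacle connections and boundaries", {
  mask <- matrix(FALSE, 3, 3)
  mask[2, 2] <- TRUE                  # center node removed
  g <- bacnavsim:::grid_neighbors(mask)
  expect_identical(length(g$active), 8L)
  # corner node (1,1): right neighbor (2,1) and up neighbor (1,2); ids 0-based
  id <- function(ix, iy) which(g$ix == ix & g$iy == iy) - 1L
  n11 <- g$nbrs[id(1, 1) + 1L, ]
  expect_setequal(n11[n11 >= 0], c(id(2, 1), id(1, 2)))
  # edge node (2,1) must NOT connect to the obstacle at (2,2)
  n21 <- g$nbrs[id(2, 1) + 1L, ]
  expect_setequal(n21[n21 >= 0], c(id(1, 1), id(3, 1)))
})

test_that("average 2D CV recovers analytic planar and circular fronts", {
  fields <- analytic_fields(v_cm_s = 30)
  expect_equal(average_cv_2d(fields$planar, dx_cm = 0.01), 30,
               tolerance = 1e-9)
  expect_equal(average_cv_2d(fields$circular, dx_cm = 0.01), 30,
               tolerance = 0.03)
})

test_that("insufficient activation raises a conduction-block condition", {
  act <- matrix(NA_real_, 50, 50)
  act[1:10, 1:10] <- 1
  expect_error(average_cv_2d(act, 0.01), class = "bacnavsim_block")
})

test_that("obstacle severing conserves charge under pure diffusion", {
  cell <- make_toy_model(list(t_scale = 1e12))
  mask <- generate_random_obstacles(20, 20, 0.2, seed = 4)
  g <- bacnavsim:::grid_neighbors(mask)
  n <- length(g$active)
  set.seed(10)
  st <- matrix(rep(cell$state, n), ncol = n)
  st[1, ] <- runif(n, -80, 20)
  pm <- matrix(cell$params, ncol = 1)
  r <- bacnavsim:::run_nodes("toy", pm, st, 0.01, 10, coupling = 12.5,
                             nbrs = g$nbrs)
  expect_equal(sum(r$state[1, ]), sum(st[1, ]), tolerance = 1e-10)
})
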