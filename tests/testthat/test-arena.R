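test_that("default T-maze geometry is a T with nest, food and baseline field", {
  ar <- build_tmaze()
  expect_equal(ar$height * ar$width, 1600L)
  # walkable count = bar + stem (no overlap: stem stops at the bar)
  cw <- 6L
  expect_equal(sum(ar$walkable), cw * 40L + cw * (40L - cw))
  expect_true(ar$walkable[ar$nest[1], ar$nest[2]])
  expect_true(ar$walkable[ar$food_left[1], ar$food_left[2]])
  expect_true(ar$walkable[ar$food_right[1], ar$food_right[2]])
  expect_equal(ar$nest[1], 40L)                # nest on the bottom row
  expect_equal(ar$food_left[2], 1L)            # food at the arm ends
  expect_equal(ar$food_right[2], 40L)
  expect_true(all(ar$pheromone == 1L))
  expect_false(any(ar$walkable[(ar$corridor_width + 1L):40L,
                               setdiff(1:40, ar$stem_cols)]))
})

test_that("impossible geometries are configuration errors", {
  expect_error(build_tmaze(corridor_width = 0), "corridor_width")
  expect_error(build_tmaze(height = 10, corridor_width = 4, stem_length = 8),
               "does not fit")
  expect_error(build_tmaze(width = 4, corridor_width = 6), "does not fit")
})

test_that("reallocation matrix is one-hot at each cell's level and tracks deposits", {
  ar <- build_tmaze()
  M <- make_reallocation_matrix(ar)
  expect_equal(dim(M), c(1600L, 10L))
  expect_equal(rowSums(M), rep(1, 1600))
  expect_true(all(M[, 1] == 1))                # fresh arena: all level 1
  cell <- ar$nest
  ar2 <- deposit_pheromone(ar, cell)
  M2 <- make_reallocation_matrix(ar2)
  lin <- (cell[2] - 1L) * ar$height + cell[1]
  changed <- which(rowSums(M != M2) > 0)
  expect_equal(changed, lin)                   # only the deposited row moves
  expect_equal(M2[lin, 2], 1)
})

test_that("deposition increments with saturation at level 10", {
  ar <- build_tmaze()
  cell <- ar$nest
  ar <- deposit_pheromone(ar, cell)
  expect_equal(ar$pheromone[cell[1], cell[2]], 2L)
  for (i in 1:11) ar <- deposit_pheromone(ar, cell)
  expect_equal(ar$pheromone[cell[1], cell[2]], 10L)   # min(1 + 12, 10)
  expect_error(deposit_pheromone(ar, c(40L, 1L)), "non-walkable")
})

test_that("local window reads the canonical 9-neighborhood with wall masking", {
  ar <- build_tmaze()
  mid <- c(3L, 20L)  # bar interior
  w <- local_window(ar, mid)
  expect_equal(w$levels, rep(1L, 9))
  expect_true(all(w$feasible))
  # against the left wall of the bar: W, NW, SW infeasible (and N row exists)
  edge <- c(3L, 1L)
  we <- local_window(ar, edge)
  lbl <- direction_labels()
  expect_false(any(we$feasible[lbl %in% c("W", "NW", "SW")]))
  # painted level-10 cell due east shows up at window slot E only
  ar$pheromone[mid[1], mid[2] + 1L] <- 10L
  wp <- local_window(ar, mid)
  expect_equal(wp$levels[lbl == "E"], 10L)
  expect_equal(sum(wp$levels == 10L), 1L)
  expect_error(local_window(ar, c(40L, 1L)), "not walkable")
})

test_that("window is local: distant cells never affect it", {
  ar <- build_tmaze()
  pos <- c(3L, 20L)
  base <- local_window(ar, pos)
  set.seed(42)
  for (rep in 1:20) {
    cells <- which(ar$walkable &
                     (abs(row(ar$walkable) - pos[1]) > 1 |
                        abs(col(ar$walkable) - pos[2]) > 1))
    pick <- sample(cells, 30)
    ar$pheromone[pick] <- sample(1:10, 30, replace = TRUE)
    expect_identical(local_window(ar, pos), base)
  }
})

test_that("decay respects bounds, monotonicity and the binomial rate", {
  ar <- build_tmaze()
  cells <- which(ar$walkable)
  ar$pheromone[cells] <- 5L
  expect_identical(decay_step(ar, p_decay = 0)$pheromone, ar$pheromone)
  d1 <- decay_step(ar, p_decay = 1)
  expect_true(all(d1$pheromone[cells] == 4L))  # p = 1: every cell drops one
  expect_error(decay_step(ar, p_decay = 1.5), "p_decay")
  # decay is mass-non-increasing and never goes below baseline
  s <- rng_stream(7)
  ar2 <- ar
  for (i in 1:50) {
    nxt <- decay_step(ar2, s, p_decay = 0.2)
    expect_lte(sum(nxt$pheromone), sum(ar2$pheromone))
    expect_true(all(nxt$pheromone >= 1L))
    ar2 <- nxt
  }
  # expected decrement count matches n * p over many trials
  ar3 <- build_tmaze()
  ar3$pheromone[ar3$nest[1], ar3$nest[2]] <- 10L
  s <- rng_stream(11)
  n_trials <- 4000; p <- 0.05
  drops <- sum(replicate(n_trials,
    10L - decay_step(ar3, s, p_decay = p)$pheromone[ar3$nest[1], ar3$nest[2]]))
  expect_equal(drops / n_trials, p, tolerance = 0.3)
  # reset mode drops straight to baseline
  rs <- decay_step(ar3, p_decay = 1, mode = "reset")
  expect_equal(rs$pheromone[ar3$nest[1], ar3$nest[2]], 1L)
})

test_that("food schedule alternates every switch_period with period 2*switch_period", {
  ar <- build_tmaze()
  expect_equal(current_food_position(ar, 0), ar$food_left)
  expect_equal(current_food_position(ar, 499), ar$food_left)
  expect_equal(current_food_position(ar, 500), ar$food_right)
  expect_equal(current_food_position(ar, 1501), current_food_position(ar, 1999))
  expect_false(identical(current_food_position(ar, 1501),
                         current_food_position(ar, 1499)))
  for (t in c(0, 123, 500, 999, 1500)) {
    expect_identical(current_food_position(ar, t),
                     current_food_position(ar, t + 1000))
  }
  arr <- build_tmaze(initial_arm = "right")
  expect_equal(current_food_position(arr, 0), arr$food_right)
})

test_that("scent triggers fire by Chebyshev distance", {
  ar <- build_tmaze()
  expect_true(sense_triggers(ar, ar$food_left, 0)$food_scent)
  expect_false(sense_triggers(ar, ar$food_left, 500)$food_scent)  # food moved
  expect_true(sense_triggers(ar, ar$nest, 0)$home_scent)
  expect_false(sense_triggers(ar, c(3L, 20L), 0)$food_scent)
  ar2 <- build_tmaze(scent_radius = 1L)
  diagonal <- ar2$food_left + c(1L, 1L)
  expect_true(sense_triggers(ar2, diagonal, 0)$food_scent)
})

test_that("arm masses split at the stem centerline and mirror symmetrically", {
  ar <- build_tmaze()
  expect_equal(arm_pheromone_mass(ar), c(left = 0, right = 0))
  ar1 <- deposit_pheromone(ar, ar$food_left)
  expect_equal(arm_pheromone_mass(ar1), c(left = 1, right = 0))
  # mirror the field: masses swap
  ar2 <- ar
  ar2$pheromone[3, 5] <- 7L
  ar2$pheromone[3, 36] <- 7L
  m <- arm_pheromone_mass(ar2)
  expect_equal(m[["left"]], m[["right"]])
})

test_that("field grids round-trip through plain text", {
  ar <- build_tmaze()
  ar$pheromone[ar$walkable][1:10] <- 2:11 %% 10 + 1L
  f <- withr::local_tempfile(fileext = ".txt")
  write_field_grid(ar$pheromone, f)
  back <- read_field_grid(f)
  expect_equal(unname(as.matrix(back)), unname(ar$pheromone),
               ignore_attr = TRUE)
})
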