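flat_bias_maps <- function(res = 1) {
  grid <- bubblegaze:::bias_grid(geom, res)
  central <- matrix(1, grid$ny, grid$nx)
  central <- central / sum(central)
  saccade <- matrix(1, 2 * grid$ny - 1, 2 * grid$nx - 1)
  saccade <- saccade / sum(saccade)
  structure(list(central = central, saccade = saccade, grid = grid,
                 smooth_sd_deg = 0, n_trials = 0L), class = "bias_maps")
}

test_that("a single fixation yields a smoothed point mass at its location", {
  ctr <- geom$center
  tr <- data.frame(participant = "b1", trial = 1, fix_index = 1,
                   x_deg = ctr["x"], y_deg = ctr["y"])
  maps <- estimate_bias_maps(tr, geom, res = 2, smooth_sd_deg = 0.5)
  expect_equal(sum(maps$central), 1, tolerance = 1e-9)
  peak <- which(maps$central == max(maps$central), arr.ind = TRUE)
  expect_lt(abs(peak[1, "row"] - ctr["y"] * 2), 1.5)
  expect_lt(abs(peak[1, "col"] - ctr["x"] * 2), 1.5)
})

test_that("trials contribute equal mass regardless of fixation count", {
  long <- data.frame(participant = "b1", trial = 1, fix_index = 1:100,
                     x_deg = 5, y_deg = 5)
  short <- data.frame(participant = "b1", trial = 2, fix_index = 1,
                      x_deg = 25, y_deg = 18)
  maps <- estimate_bias_maps(rbind(long, short), geom, res = 2,
                             smooth_sd_deg = 0.25)
  i1 <- bubblegaze:::grid_cell(maps$grid, 5, 5)
  i2 <- bubblegaze:::grid_cell(maps$grid, 25, 18)
  m1 <- sum(maps$central[(i1[1] - 2):(i1[1] + 2), (i1[2] - 2):(i1[2] + 2)])
  m2 <- sum(maps$central[(i2[1] - 2):(i2[1] + 2), (i2[2] - 2):(i2[2] + 2)])
  expect_equal(m1, m2, tolerance = 0.02)
})

test_that("180-degree symmetric displacements give a symmetric saccade map", {
  set.seed(21)
  n <- 500
  x0 <- 15; y0 <- 12
  dx <- sample(c(-3, 3), n, replace = TRUE) + rnorm(n, 0, 0.5)
  dy <- rnorm(n, 0, 0.5)
  a <- x0 + rnorm(n, 0, 0.5); b <- y0 + rnorm(n, 0, 0.5)
  ## every trial paired with its point reflection through (x0, y0)
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(data.frame(participant = "b1", trial = 2 * i - 1, fix_index = 1:2,
                     x_deg = c(a[i], a[i] + dx[i]),
                     y_deg = c(b[i], b[i] + dy[i])),
          data.frame(participant = "b1", trial = 2 * i, fix_index = 1:2,
                     x_deg = 2 * x0 - c(a[i], a[i] + dx[i]),
                     y_deg = 2 * y0 - c(b[i], b[i] + dy[i])))
  }))
  maps <- estimate_bias_maps(tr, geom, res = 2, smooth_sd_deg = 0.5)
  s <- maps$saccade
  flipped <- s[rev(seq_len(nrow(s))), rev(seq_len(ncol(s)))]
  expect_lt(sum(abs(s - flipped)) / 2, 1e-8)
})

test_that("flat maps make bubble probabilities proportional to mask integrals", {
  maps <- flat_bias_maps(res = 1)
  ss <- manual_stimset("gender",
                       centers = list(A = c(8, 12), B = c(22, 12)),
                       stimuli_bubbles = list(s1 = c("A", "B")))
  lens <- data.frame(participant = rep(sprintf("v%03d", 1:100), each = 1),
                     stimulus = "s1", n_fix = 50)
  sim <- simulate_trajectories(ss, maps, lens, seed = 3)
  asn <- bubblegaze:::assign_fixation_table(sim, ss, geom)
  counts <- table(asn$bubble_id[asn$category == "bubble"])
  ## exhaustive-summation oracle on the coarse grid: with flat central and
  ## saccade maps every fixation is drawn from the bubble mask itself, so
  ## P(bubble) is the mask integral over the cells assigned to it
  grid <- maps$grid
  mask <- bubble_position_map(ss, "s1", grid)
  cx <- (seq_len(grid$nx) - 0.5) / grid$res
  cy <- (seq_len(grid$ny) - 0.5) / grid$res
  dA <- outer((cy - 12)^2, (cx - 8)^2, "+")
  dB <- outer((cy - 12)^2, (cx - 22)^2, "+")
  inA <- dA <= 9 & dA <= dB
  inB <- dB <= 9 & dB < dA
  pA <- sum(mask[inA]) / (sum(mask[inA]) + sum(mask[inB]))
  fA <- counts[["A"]] / sum(counts)
  expect_equal(fA, pA, tolerance = 0.02)
})

test_that("single-bubble stimuli concentrate samples within 3 degrees", {
  ## central bias and saccade constraints both tighten the envelope mass
  res <- 3
  grid <- bubblegaze:::bias_grid(geom, res)
  ctr <- geom$center
  cx <- (seq_len(grid$nx) - 0.5) / res
  cy <- (seq_len(grid$ny) - 0.5) / res
  central <- exp(-outer((cy - ctr["y"])^2, (cx - ctr["x"])^2, "+") / (2 * 25))
  central <- central / sum(central)
  sx <- seq(-(grid$nx - 1), grid$nx - 1) / res
  sy <- seq(-(grid$ny - 1), grid$ny - 1) / res
  saccade <- exp(-outer(sy^2, sx^2, "+") / (2 * 16))
  saccade <- saccade / sum(saccade)
  maps <- structure(list(central = central, saccade = saccade, grid = grid,
                         smooth_sd_deg = 0, n_trials = 0L),
                    class = "bias_maps")
  ss <- manual_stimset("gender",
                       centers = list(A = c(ctr["x"], ctr["y"])),
                       stimuli_bubbles = list(s1 = "A"))
  lens <- data.frame(participant = "v1", stimulus = "s1", n_fix = 5000)
  sim <- simulate_trajectories(ss, maps, lens, seed = 4)
  sim <- sim[sim$fix_index > 0, ]
  d <- sqrt((sim$x_deg - ctr["x"])^2 + (sim$y_deg - ctr["y"])^2)
  expect_gte(mean(d <= 3), 0.99)
})

test_that("identical seeds reproduce identical trajectories", {
  maps <- flat_bias_maps(res = 2)
  ss <- manual_stimset("gender", centers = list(A = c(15, 12), B = c(20, 16)),
                       stimuli_bubbles = list(s1 = c("A", "B")))
  lens <- data.frame(participant = "v1", stimulus = "s1", n_fix = 20)
  expect_identical(simulate_trajectories(ss, maps, lens, seed = 9),
                   simulate_trajectories(ss, maps, lens, seed = 9))
})

test_that("per-step sampling maps are valid densities", {
  ## the sampler renormalizes internally; check the intermediate map and a
  ## shifted product map directly
  w <- make_world(n_stimuli = 50, seed = 71)
  bl <- generate_baseline(geom, n_participants = 5, trials_each = 20, seed = 72)
  maps <- estimate_bias_maps(bl, geom, res = 2)
  expect_true(all(maps$central >= 0))
  expect_equal(sum(maps$central), 1, tolerance = 1e-6)
  expect_true(all(maps$saccade >= 0))
  expect_equal(sum(maps$saccade), 1, tolerance = 1e-6)
  sid <- w$stimset$stimuli$stimulus_id[w$stimset$stimuli$n_bubbles >= 2][1]
  mask <- bubble_position_map(w$stimset, sid, maps$grid)
  inter <- maps$central * mask
  expect_true(all(inter >= 0) && sum(inter) > 0)
})

test_that("symmetric bubbles under symmetric maps get equal salience; central beats peripheral", {
  grid_res <- 2
  grid <- bubblegaze:::bias_grid(geom, grid_res)
  cx <- (seq_len(grid$nx) - 0.5) / grid_res
  cy <- (seq_len(grid$ny) - 0.5) / grid_res
  ctr <- geom$center
  central <- exp(-outer((cy - ctr["y"])^2, (cx - ctr["x"])^2, "+") / (2 * 25))
  central <- central / sum(central)
  sx <- seq(-(grid$nx - 1), grid$nx - 1) / grid_res
  sy <- seq(-(grid$ny - 1), grid$ny - 1) / grid_res
  saccade <- exp(-outer(sy^2, sx^2, "+") / (2 * 16))
  saccade <- saccade / sum(saccade)
  maps <- structure(list(central = central, saccade = saccade, grid = grid,
                         smooth_sd_deg = 0, n_trials = 0L),
                    class = "bias_maps")
  ## two bubbles mirrored about the screen center plus a peripheral one
  ss <- manual_stimset("gender",
                       centers = list(L = c(ctr["x"] - 5, ctr["y"]),
                                      R = c(ctr["x"] + 5, ctr["y"]),
                                      P = c(ctr["x"] + 11, ctr["y"] + 7)),
                       stimuli_bubbles = list(s1 = c("L", "R"),
                                              s2 = c("L", "P"),
                                              s3 = c("R", "P")))
  lens <- expand.grid(participant = sprintf("v%02d", 1:40),
                      stimulus = c("s1", "s2", "s3"))
  lens$n_fix <- 40
  sim <- simulate_trajectories(ss, maps, lens, seed = 5)
  st <- spatial_bias_salience(sim, ss, geom)
  sal <- setNames(st$salience, st$bubble_id)
  expect_equal(sum(st$salience), 1, tolerance = 1e-9)
  expect_equal(unname(sal["L"] / sal["R"]), 1, tolerance = 0.1)
  expect_gt(sal["L"], sal["P"])
  expect_gt(sal["R"], sal["P"])
})
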