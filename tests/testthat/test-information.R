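test_that("stimulus information spans 0 to log2(C) bits", {
  expect_equal(stimulus_information(rep(0.25, 4)), 0)
  expect_equal(stimulus_information(c(1, 0, 0, 0)), 2)
  expect_equal(stimulus_information(c(0.5, 0.5)), 0)
  expect_equal(stimulus_information(c(1, 0)), 1)
  ## direct entropy computation
  expect_equal(stimulus_information(c(0.75, 0.25)),
               1 - (-0.75 * log2(0.75) - 0.25 * log2(0.25)))
  expect_equal(round(stimulus_information(c(0.75, 0.25)), 4), 0.1887)
  expect_error(stimulus_information(numeric(0)), "empty")
  expect_error(stimulus_information(c(0.7, 0.7)), "summing")
})

test_that("p-model integration matches hand evaluation", {
  expect_equal(integrate_pmodel(list(c(0.8, 0.2), c(0.8, 0.2))),
               c(0.64, 0.04) / 0.68)
  expect_equal(round(integrate_pmodel(list(c(0.8, 0.2), c(0.8, 0.2))), 4),
               c(0.9412, 0.0588))
  expect_equal(integrate_pmodel(list(c(0.9, 0.1), c(0.1, 0.9))), c(0.5, 0.5))
  ## flat is the identity
  d <- c(0.3, 0.1, 0.4, 0.2)
  expect_equal(integrate_pmodel(list(d, rep(0.25, 4))), d)
  ## contradictory deltas are degenerate
  expect_error(integrate_pmodel(list(c(1, 0), c(0, 1))), "degenerate")
})

test_that("Z is commutative, associative, flat-neutral and zero-absorbing (property sweep)", {
  set.seed(42)
  for (rep in seq_len(300)) {
    C <- sample(2:4, 1)
    m <- random_dists(3, C)
    z12 <- integrate_pmodel(m[1:2, ])
    z21 <- integrate_pmodel(m[2:1, ])
    expect_equal(z12, z21, tolerance = 1e-12)
    ## associativity
    left <- integrate_pmodel(rbind(z12, m[3, ]))
    right <- integrate_pmodel(rbind(m[1, ], integrate_pmodel(m[2:3, ])))
    expect_equal(left, right, tolerance = 1e-12)
    ## flat identity
    expect_equal(integrate_pmodel(rbind(m[1, ], rep(1 / C, C))), m[1, ],
                 tolerance = 1e-12)
    ## zeros absorb per class
    z <- m[1, ]
    z[1] <- 0
    z <- z / sum(z)
    expect_equal(integrate_pmodel(rbind(z, m[2, ]))[1], 0)
  }
})

test_that("n-fold self-integration increases information towards the maximum", {
  d <- c(0.6, 0.4)
  info <- vapply(1:20, function(n) {
    stimulus_information(integrate_pmodel(matrix(rep(d, n), n, byrow = TRUE)))
  }, numeric(1))
  expect_true(all(diff(info) > 0))
  expect_lt(1 - info[20], 0.01)
})

test_that("max-model keeps the most informative distribution with first-index ties", {
  expect_equal(integrate_maxmodel(list(c(0.5, 0.5), c(0.9, 0.1))), c(0.9, 0.1))
  expect_equal(integrate_maxmodel(list(c(0.5, 0.5), c(0.5, 0.5))), c(0.5, 0.5))
  expect_equal(integrate_maxmodel(list(c(0.8, 0.2), c(0.2, 0.8))), c(0.8, 0.2))
})

test_that("single-bubble MLE reproduces observed proportions", {
  ss <- manual_stimset("gender", centers = list(A = c(10, 10)),
                       stimuli_bubbles = list(s1 = "A"))
  resp <- data.frame(
    participant = "p1", stimulus = "s1",
    response = rep(c("male", "female"), c(750, 250)),
    stringsAsFactors = FALSE
  )
  fit <- fit_bubble_distributions(resp, ss, task_classes("gender"), seed = 1)
  expect_equal(unname(fit$distributions["A", ]), c(0.75, 0.25),
               tolerance = 1e-4)
  expect_equal(unname(fit$information["A"]), 0.189, tolerance = 1e-2)
  expect_equal(fit$n_parameters, 1L)
})

test_that("free-parameter bookkeeping is bubbles times classes minus one", {
  w <- make_world(task = "expression", n_bubbles = 94, n_images = 24,
                  n_stimuli = 100, seed = 71)
  ex <- generate_experiment(w$stimset, w$truth,
                            experiment_design(n_participants = 8,
                                              trials_per_participant = 50,
                                              tasks = "expression",
                                              n_stimuli_per_task = 100),
                            geom, fixations = FALSE, seed = 72)
  fit <- fit_bubble_distributions(ex$responses, w$stimset,
                                  task_classes("expression"), n_starts = 2,
                                  seed = 73)
  expect_equal(fit$n_parameters, 94 * 3)
  ## both scalar-equation conventions are reported
  expect_equal(unname(fit$n_equations["per_class"]), fit$n_stimuli * 4)
  expect_equal(unname(fit$n_equations["per_free_class"]), fit$n_stimuli * 3)
})

test_that("predicted information per bubble count behaves like the p-model", {
  pool <- rbind(c(0.8, 0.2), c(0.7, 0.3), c(0.55, 0.45))
  pr <- predict_info_vs_count(pool, 1:2, reps = 400, seed = 5)
  expect_equal(pr$mean_information[1],
               mean(apply(pool, 1, stimulus_information)), tolerance = 0.02)
  ## identical pool: two bubbles integrate to the hand-computed value
  same <- matrix(rep(c(0.8, 0.2), 4), 4, byrow = TRUE)
  pr2 <- predict_info_vs_count(same, 1:3, reps = 50, seed = 5)
  expect_equal(pr2$mean_information[2],
               stimulus_information(c(0.9412, 0.0588)), tolerance = 1e-3)
  expect_true(all(diff(pr2$mean_information) > 0))
})

test_that("information prediction error is zero for a perfectly consistent fit", {
  ss <- manual_stimset("gender", centers = list(A = c(10, 10)),
                       stimuli_bubbles = list(s1 = "A"))
  resp <- data.frame(participant = "p1", stimulus = "s1",
                     response = rep(c("male", "female"), c(6, 2)),
                     stringsAsFactors = FALSE)
  fit <- fit_bubble_distributions(resp, ss, task_classes("gender"), seed = 1)
  pe <- info_prediction_error(fit, resp, ss, reps = 200, seed = 2)
  expect_lt(pe$mean_abs_error_bits, 1e-3)
  ## eight responses per stimulus fluctuate: the bound is strictly positive
  expect_gt(pe$lower_bound_bits, 0)
})

test_that("the sampling bound is below the out-of-sample prediction error", {
  w <- make_world(task = "gender", n_bubbles = 30, n_images = 8,
                  n_stimuli = 100, seed = 81)
  des <- experiment_design(n_participants = 25, trials_per_participant = 80,
                           tasks = "gender", n_stimuli_per_task = 100)
  ex_fit <- generate_experiment(w$stimset, w$truth, des, geom,
                                fixations = FALSE, seed = 82)
  ex_new <- generate_experiment(w$stimset, w$truth, des, geom,
                                fixations = FALSE, seed = 83)
  fit <- fit_bubble_distributions(ex_fit$responses, w$stimset,
                                  task_classes("gender"), n_starts = 2,
                                  seed = 84)
  pe <- info_prediction_error(fit, ex_new$responses, w$stimset,
                              reps = 100, seed = 85)
  expect_lte(pe$lower_bound_bits, pe$mean_abs_error_bits)
})

test_that("bootstrap intervals are seeded and degenerate cells collapse", {
  x <- rep(2.5, 10)
  ci <- bootstrap_ci(x, mean, reps = 200, seed = 3)
  expect_equal(ci$lower, 2.5)
  expect_equal(ci$upper, 2.5)
  ci1 <- bootstrap_ci(rnorm(50), mean, reps = 500, seed = 9)
  ci2 <- bootstrap_ci(rnorm(50), mean, reps = 500, seed = 9)
  ## the data differ but identical seeds on identical data agree
  set.seed(1); y <- rnorm(50)
  expect_identical(bootstrap_ci(y, mean, reps = 500, seed = 4),
                   bootstrap_ci(y, mean, reps = 500, seed = 4))
  ## singleton cells are flagged undefined
  s <- bootstrap_ci(3, mean, reps = 100, seed = 1)
  expect_true(is.na(s$lower))
})

test_that("identical response pairs always lie inside the null region", {
  a <- c(30L, 10L)
  out <- permutation_position_test(list(list(a, a)), reps = 300, seed = 2)
  expect_equal(out$fraction_inside, 1)
  expect_equal(unname(out$statistics[1]), 0)
})

test_that("planted position effects push pairs outside the null region", {
  set.seed(12)
  pairs <- lapply(1:60, function(i) {
    list(rmultinom(1, 40, c(0.8, 0.2))[, 1],
         rmultinom(1, 40, c(0.3, 0.7))[, 1])
  })
  out <- permutation_position_test(pairs, reps = 400, seed = 13)
  expect_lt(out$fraction_inside, 0.5)
})
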