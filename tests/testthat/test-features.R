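test_that("constant images have zero contrast everywhere", {
  imgs <- list(a = matrix(0.4, 60, 80))
  fm <- contrast_maps(imgs, px_per_deg = 8)
  expect_true(all(fm$LC$a == 0))
  expect_true(all(fm$TC$a == 0))
})

test_that("luminance contrast matches a direct sliding-window oracle", {
  set.seed(5)
  img <- matrix(runif(40 * 50), 40, 50)
  fm <- contrast_maps(list(a = img), px_per_deg = 8, sigma_outer_deg = 0.5)
  ## brute-force windowed sd at interior pixels with an explicit kernel
  sp <- 0.5 * 8
  half <- ceiling(4 * sp)
  kern1 <- dnorm(seq(-half, half), sd = sp)
  K <- outer(kern1, kern1)
  K <- K / sum(K)
  for (pt in list(c(20, 25), c(18, 30), c(22, 22))) {
    i <- pt[1]; j <- pt[2]
    wnd <- img[(i - half):(i + half), (j - half):(j + half)]
    mu <- sum(K * wnd)
    s <- sqrt(sum(K * (wnd - mu)^2))
    expect_equal(fm$LC$a[i, j], s / mean(img), tolerance = 1e-8)
  }
})

test_that("contrast maps are invariant to luminance scaling of the task set", {
  set.seed(6)
  imgs <- list(a = matrix(runif(40, 0.3, 0.7), 8, 5) %x% matrix(1, 5, 8))
  fm1 <- contrast_maps(imgs, 8)
  fm2 <- contrast_maps(lapply(imgs, function(m) 3 * m), 8)
  expect_equal(fm1$LC$a, fm2$LC$a, tolerance = 1e-10)
})

test_that("doubling the contrast field doubles the measured LC map", {
  fld <- matrix(0.05, 100, 120)
  fld[30:70, 40:80] <- 0.12
  i1 <- generate_images(list(a = fld), px_per_deg = 8, seed = 3)
  i2 <- generate_images(list(a = 2 * fld), px_per_deg = 8, seed = 3)
  fm1 <- contrast_maps(i1, 8)
  fm2 <- contrast_maps(i2, 8)
  ## same seed and mean luminance, doubled field: LC doubles pointwise
  expect_equal(mean(fm2$LC$a[40:60, 50:70]) / mean(fm1$LC$a[40:60, 50:70]),
               2, tolerance = 0.02)
})

test_that("requested mean luminance is met and zero fields give constants", {
  fld0 <- matrix(0, 30, 30)
  img <- generate_images(list(a = fld0), mean_luminance = 0.37,
                         px_per_deg = 8, seed = 2)$a
  expect_equal(max(abs(img - 0.37)), 0, tolerance = 1e-12)
  fld <- matrix(0.1, 50, 60)
  img2 <- generate_images(list(a = fld), mean_luminance = 0.61,
                          px_per_deg = 8, seed = 2)$a
  expect_equal(mean(img2), 0.61, tolerance = 0.61 * 0.01)
})

test_that("equal-population binning puts five of 1..100 in each of 20 bins", {
  b <- equal_population_bins(1:100, 20)
  counts <- table(bin_of(1:100, b))
  expect_equal(unname(c(counts)), rep(5L, 20))
})

test_that("degenerate and tied inputs are handled explicitly", {
  expect_error(equal_population_bins(rep(3, 50), 20), "distinct")
  vals <- c(rep(1, 60), seq(2, 3, length.out = 40))
  b <- equal_population_bins(vals, 20)
  expect_true(b$flagged_unequal)
})

test_that("bins over uniform draws are equal within one location", {
  set.seed(8)
  v <- runif(1e5)
  b <- equal_population_bins(v, 20)
  counts <- table(bin_of(v, b))
  expect_lte(max(counts) / min(counts), 1.001)
})

test_that("uniform fixations give flat bin probabilities; duplication changes nothing", {
  set.seed(9)
  avail <- runif(5e4)
  b <- equal_population_bins(avail, 20)
  fix <- sample(avail, 2e4, replace = TRUE)
  m <- feature_fixation_mapping(fix, b)
  expect_lt(max(abs(m$prob - 0.05)), 0.01)
  m2 <- feature_fixation_mapping(c(fix, fix), b)
  expect_equal(m$prob, m2$prob)
})

test_that("fixations selected by feature value give a monotone mapping", {
  set.seed(10)
  avail <- runif(2e5)
  b <- equal_population_bins(avail, 20)
  fix <- sample(avail, 1e5, replace = TRUE, prob = avail)
  m <- feature_fixation_mapping(fix, b)
  expect_gte(cor(seq_len(20), m$prob, method = "spearman"), 0.95)
  ## and the shape is the planted linear selection
  mids <- (c(0, b$edges) + c(b$edges, 1)) / 2
  expect_gt(cor(mids, m$prob), 0.99)
})

test_that("bubble salience is the product of the two feature probabilities", {
  mk <- function(p) structure(list(prob = p,
                                   bins = equal_population_bins(1:40 / 40, 20),
                                   n_fixations = 100), class = "bin_mapping")
  p <- rep(0.05, 20)
  ml <- mk(p); mt <- mk(p)
  imgs <- list(img1 = matrix(runif(100 * 120, 0.3, 0.7), 100, 120))
  fm <- contrast_maps(imgs, 8)
  pool <- data.frame(bubble_id = c("A", "B"), task = "gender",
                     source_image_id = "img1", source_class = "male",
                     center_x_deg = c(5, 9), center_y_deg = c(5, 9),
                     stringsAsFactors = FALSE)
  st <- stimulus_dependent_salience(pool, fm, ml, mt)
  expect_equal(st$salience, c(0.0025, 0.0025))
})

test_that("planted high-contrast bubble centers are recovered in rank", {
  g <- geom
  pool <- sample_bubble_pool("gender", 40, 10, g, seed = 101)
  truth <- sample_ground_truth(pool, feature_log_sd = 0.7, seed = 102)
  fields <- planted_contrast_fields(pool, truth, g, px_per_deg = 8)
  ## a smooth ramp spreads the available contrast values over all bins so
  ## the equal-population binning does not quantize the bubble centers
  fields <- lapply(fields, function(f) {
    f + outer(rep(1, nrow(f)), seq(0, 0.15, length.out = ncol(f)))
  })
  imgs <- generate_images(fields, px_per_deg = 8, seed = 103)
  fm <- contrast_maps(imgs, 8)
  bl <- equal_population_bins(unlist(fm$LC))
  bt <- equal_population_bins(unlist(fm$TC))
  ## strong known selection, flat spatial bias: clean calibration data
  base <- generate_baseline(g, n_participants = 30, trials_each = 60,
                            mean_fixations = 12, central_sd_deg = Inf,
                            images = imgs, feature_maps = fm,
                            feature_fun = function(v) v, seed = 104)
  lcv <- mapply(function(im, x, y) feature_value_at(fm, im, x, y, "LC"),
                base$image, base$x_deg, base$y_deg)
  tcv <- mapply(function(im, x, y) feature_value_at(fm, im, x, y, "TC"),
                base$image, base$x_deg, base$y_deg)
  ml <- feature_fixation_mapping(lcv, bl)
  mt <- feature_fixation_mapping(tcv, bt)
  st <- stimulus_dependent_salience(pool, fm, ml, mt)
  ## planted contrast at the bubble centers is the known generator
  ppd <- 8
  fld_ctr <- mapply(function(im, x, y) {
    fields[[im]][pmax(1, round(y * ppd)), pmax(1, round(x * ppd))]
  }, pool$source_image_id, pool$center_x_deg, pool$center_y_deg)
  expect_gte(cor(st$salience, fld_ctr, method = "spearman"), 0.9)
  ## log salience is additive in the two per-feature log probabilities
  lc_ctr <- mapply(function(im, x, y) feature_value_at(fm, im, x, y, "LC"),
                   pool$source_image_id, pool$center_x_deg, pool$center_y_deg)
  tc_ctr <- mapply(function(im, x, y) feature_value_at(fm, im, x, y, "TC"),
                   pool$source_image_id, pool$center_x_deg, pool$center_y_deg)
  expect_equal(log(st$salience),
               unname(log(ml$prob[bin_of(lc_ctr, ml$bins)]) +
                        log(mt$prob[bin_of(tc_ctr, mt$bins)])),
               tolerance = 1e-12)
})
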