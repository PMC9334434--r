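# synthetic toy images: two templates plus pixel noise
make_image_set <- function(template, n, class_label, prefix, noise_sd, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    px <- pmin(255, pmax(0, template + rnorm(length(template), 0, noise_sd)))
    stimulus_image(matrix(px, nrow(template)), sprintf("%s%02d", prefix, i),
                   class_label)
  })
}

templates <- local({
  set.seed(55)
  ta <- matrix(runif(2500, 0, 255), 50)
  tb <- matrix(runif(2500, 0, 255), 50)
  list(a = ta, b = tb)
})

test_that("pixelwise correlation has the analytic values on toys", {
  a <- stimulus_image(matrix(c(1, 2, 3, 4), 2), "a", "X")
  expect_equal(pixelwise_correlation(a, a), 1)

  neg <- stimulus_image(255 - a$pixels, "neg", "Y")
  expect_equal(pixelwise_correlation(a, neg), -1)

  # hand Pearson on (1,2,3,4) vs (1,2,4,3)
  b <- stimulus_image(matrix(c(1, 2, 4, 3), 2), "b", "Y")
  expect_equal(pixelwise_correlation(a, b), 0.8)

  # symmetry and affine intensity invariance
  expect_equal(pixelwise_correlation(b, a), 0.8)
  resc <- stimulus_image(a$pixels * 0.5 + 10, "r", "Y")
  expect_equal(pixelwise_correlation(resc, b), 0.8)

  expect_error(pixelwise_correlation(a, stimulus_image(matrix(0:5, 2), "c", "Y")),
               "dimensions differ")
  expect_error(pixelwise_correlation(a, stimulus_image(matrix(7, 2, 2), "k", "Y")),
               "constant image")
})

test_that("selection keeps the least cross-class-correlated exemplars", {
  # heavy pixel noise keeps every regular cross-class correlation near zero,
  # so the duplicated exemplar's self-correlation of 1.0 dominates its score
  class_a <- make_image_set(templates$a, 10, "X", "a", noise_sd = 150, seed = 1)
  class_b <- make_image_set(templates$b, 10, "Y", "b", noise_sd = 150, seed = 2)

  # an image duplicated into both classes scores highest in both and is
  # excluded first
  dup <- stimulus_image(templates$a, "zz_dup", "X")
  dup_b <- stimulus_image(templates$a, "zz_dup", "Y")
  rep <- select_stimuli(c(class_a, list(dup)), c(class_b, list(dup_b)),
                        n_select = 10)
  expect_false(any(rep$scores$selected[rep$scores$id == "zz_dup"]))
  expect_equal(rep$scores$score[rep$scores$id == "zz_dup" &
                                  rep$scores$class == "X"],
               max(rep$scores$score[rep$scores$class == "X"]))

  # requested counts are honored
  expect_length(rep$selected_a, 10)
  expect_length(rep$selected_b, 10)

  # input-order invariance (ids break ties)
  rep2 <- select_stimuli(rev(c(class_a, list(dup))),
                         rev(c(class_b, list(dup_b))), n_select = 10)
  ids <- function(r) sort(vapply(r$selected_a, `[[`, "", "id"))
  expect_equal(ids(rep2), ids(rep))

  expect_error(select_stimuli(class_a[1:3], class_b, n_select = 10))
})

test_that("selection is monotone in cross-template correlation", {
  # class-b images built as mixtures of the two templates: the more
  # template-a is mixed in, the higher the cross-class score
  mix <- function(w, id) stimulus_image(
    w * templates$a + (1 - w) * templates$b, id, "Y")
  class_a <- make_image_set(templates$a, 4, "X", "a", noise_sd = 5, seed = 3)
  class_b <- list(mix(0.0, "m0"), mix(0.3, "m3"), mix(0.6, "m6"),
                  mix(0.9, "m9"))
  rep <- select_stimuli(class_a, class_b, n_select = 2)
  sc <- rep$scores[rep$scores$class == "Y", ]
  expect_equal(sc$score[order(sc$id)], sort(sc$score))  # m0 < m3 < m6 < m9
  expect_equal(sort(vapply(rep$selected_b, `[[`, "", "id")), c("m0", "m3"))
})

test_that("confound check counts object and black pixels per class", {
  # identical images in both classes: t = 0 on both measures
  img <- matrix(c(rep(0, 200), rep(200, 200)), 20)
  same <- list(stimulus_image(img, "x1", "X"), stimulus_image(img, "x2", "X"),
               stimulus_image(img, "y1", "Y"), stimulus_image(img, "y2", "Y"))
  res <- confound_check(same)
  expect_equal(res$object_size$t, 0)
  expect_equal(res$black_area$t, 0)
  expect_equal(res$object_size$p, 1)

  # all-white vs all-black: object-size difference maximal
  white <- matrix(255, 10, 10); black <- matrix(0, 10, 10)
  res <- confound_check(list(
    stimulus_image(white, "w1", "X"), stimulus_image(white, "w2", "X"),
    stimulus_image(black, "b1", "Y"), stimulus_image(black, "b2", "Y")))
  expect_equal(res$per_stimulus$object_pixels[1:2], c(100, 100))
  expect_equal(res$per_stimulus$object_pixels[3:4], c(0, 0))
  expect_true(is.infinite(res$object_size$t) && res$object_size$t > 0)

  # threshold sensitivity: +/- 5 around the default leaves high-contrast
  # counts unchanged
  img_b <- matrix(c(rep(0, 200), rep(120, 200)), 20)
  hc <- list(stimulus_image(img, "x1", "X"), stimulus_image(img_b, "y1", "Y"))
  for (thr in c(5, 10, 15)) {
    res <- confound_check(hc, black_threshold = thr)
    expect_equal(res$per_stimulus$object_pixels, c(200, 200))
  }

  expect_error(confound_check(list(stimulus_image(img, "x1", "X"))),
               "both classes")
})

test_that("image files round-trip through the readers", {
  # plain-text PGM (P2)
  px <- matrix(sample(0:255, 24), 4, 6)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# toy", "6 4", "255",
               paste(as.vector(t(px)), collapse = " ")), pgm)
  img <- read_stimulus_image(pgm, class_label = "X")
  expect_equal(img$pixels, px)
  expect_equal(img$class_label, "X")

  # PNG via the png package
  png_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px / 255, png_path)
  img2 <- read_stimulus_image(png_path, id = "p", class_label = "Y")
  expect_equal(dim(img2$pixels), dim(px))
  expect_equal(img2$pixels, px, tolerance = 0.51)  # 8-bit quantization

  expect_error(read_stimulus_image("foo.bmp", class_label = "X"),
               "unsupported image format")
})
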