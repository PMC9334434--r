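test_that("knn_predict handles exhaustive toy cases", {
  # all training labels identical
  set.seed(2)
  tr <- matrix(runif(40), 20, 2)
  expect_equal(knn_predict(tr, rep("X", 20), matrix(runif(10), 5, 2), k = 5),
               rep("X", 5))

  # 2-1 vote
  tr <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  expect_equal(knn_predict(tr, c("X", "X", "Y"), rbind(c(0.2, 0.1)), k = 3),
               "X")
  # k = 1 nearest wins
  expect_equal(knn_predict(tr, c("X", "X", "Y"), rbind(c(4.9, 4.9)), k = 1),
               "Y")
  expect_error(knn_predict(tr, c("X", "X", "Y"), rbind(c(0, 0)), k = 5),
               "fewer than k")
})

test_that("knn_predict matches the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:5) {
    n_train <- sample(20:100, 1)
    tr <- matrix(runif(2 * n_train, 0, 5), ncol = 2)
    labs <- sample(c("X", "Y"), n_train, replace = TRUE)
    te <- matrix(runif(40, 0, 5), ncol = 2)
    for (k in c(1, 5, 15)) {
      if (k > n_train) next
      expect_equal(knn_predict(tr, labs, te, k),
                   unname(brute_knn(tr, labs, te, k)),
                   info = sprintf("rep %d, k = %d", rep, k))
    }
  }
})

test_that("knn distance ties break by training insertion order", {
  # two equidistant neighbours with different labels, k = 1
  tr <- rbind(c(1, 0), c(-1, 0))
  expect_equal(knn_predict(tr, c("Y", "X"), rbind(c(0, 0)), k = 1), "Y")
  expect_equal(knn_predict(tr[2:1, ], c("X", "Y"), rbind(c(0, 0)), k = 1), "X")
})

test_that("train/test sampling is disjoint and boundary-checked", {
  ev <- random_pool(500, seed = 3)
  set.seed(1)
  st <- sample_train_test(ev, classifier_config())
  expect_equal(nrow(st$train), 250)
  expect_equal(nrow(st$test), 250)
  key <- function(d) paste(d$x, d$y, d$trial_index)
  expect_length(intersect(key(st$train), key(st$test)), 0)
  # class balance is achieved when both classes suffice
  expect_equal(as.integer(table(st$train$stimulus_class)), c(125L, 125L))

  expect_error(sample_train_test(random_pool(499, seed = 3),
                                 classifier_config()),
               "insufficient")
})

test_that("one-peck-per-trial reduction keeps one event per trial", {
  s <- tiny_session(n_per_class = 300, n_pecks = 8)
  pool <- select_pool(s, outcomes = "correct")
  expect_equal(nrow(pool$events), 600 * 8)
  set.seed(4)
  st <- sample_train_test(pool, classifier_config(one_peck_per_trial = TRUE))
  expect_equal(nrow(st$train), 250)
  expect_equal(nrow(st$test), 250)
  both <- rbind(st$train, st$test)
  expect_false(anyDuplicated(both$trial_index) > 0)
})

test_that("decoding is deterministic under a fixed seed", {
  s <- generate_session(make_archetype("two_class"), generator_config(seed = 3))
  pool <- select_pool(s, outcomes = "correct")
  a <- run_decoding(pool, mode = "CC", config = classifier_config(seed = 11))
  b <- run_decoding(pool, mode = "CC", config = classifier_config(seed = 11))
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$verdict, b$verdict)
})

test_that("label-independent pools decode at chance; shuffled null is calibrated", {
  pool <- random_pool(1200, seed = 6)  # labels independent of position
  rep <- run_decoding(pool, mode = "CC", config = classifier_config(seed = 12))
  expect_equal(rep$verdict, "at_chance")
  expect_lt(abs(rep$mean_accuracy - 50), 5)
  expect_lt(abs(rep$mean_shuffled - 50), 3)

  # shuffled mean stays near 50% even for a decodable pool
  s <- generate_session(make_archetype("two_class"), generator_config(seed = 3))
  rep2 <- run_decoding(select_pool(s, outcomes = "correct"), mode = "CC",
                       config = classifier_config(seed = 13))
  expect_lt(abs(rep2$mean_shuffled - 50), 3)
})

test_that("accuracies are symmetric under a global X/Y label swap", {
  # exact at the prediction level
  set.seed(7)
  tr <- matrix(runif(100, 0, 5), ncol = 2)
  labs <- sample(c("X", "Y"), 50, replace = TRUE)
  te <- matrix(runif(30, 0, 5), ncol = 2)
  pred <- knn_predict(tr, labs, te, k = 5)
  swap <- function(l) ifelse(l == "X", "Y", "X")
  expect_equal(knn_predict(tr, swap(labs), te, k = 5), swap(pred))

  # statistical at the report level
  s <- generate_session(make_archetype("two_class"), generator_config(seed = 3))
  pool <- select_pool(s, outcomes = "correct")
  swapped <- pool
  swapped$events$stimulus_class <- swap(swapped$events$stimulus_class)
  a <- run_decoding(pool, mode = "CC", config = classifier_config(seed = 14))
  b <- run_decoding(swapped, mode = "CC", config = classifier_config(seed = 14))
  expect_lt(abs(a$mean_accuracy - b$mean_accuracy), 5)
  expect_equal(a$verdict, b$verdict)
})

test_that("strategy archetypes are recovered in the expected order", {
  cfg <- classifier_config(seed = 15)
  acc <- vapply(c("two_class", "one_class", "lateralized"), function(name) {
    s <- generate_session(make_archetype(name), generator_config(seed = 41))
    run_decoding(select_pool(s, outcomes = "correct"), mode = "CC",
                 config = cfg)$mean_accuracy
  }, numeric(1))
  expect_gt(acc[["two_class"]], acc[["one_class"]])
  expect_gt(acc[["one_class"]], acc[["lateralized"]])
  expect_lt(abs(acc[["lateralized"]] - 50), 5)
  expect_gte(acc[["two_class"]], 80)
})

test_that("error-trial decoding modes reflect the generative error model", {
  cfg <- classifier_config(seed = 16)
  gen <- function(name) {
    s <- generate_session(make_archetype(name, p_correct = 0.7, n_trials = 600),
                          generator_config(seed = 43))
    list(correct = select_pool(s, outcomes = "correct"),
         error = select_pool(s, outcomes = "error"))
  }

  conf <- gen("confusion")
  ce <- run_decoding(conf$correct, conf$error, mode = "CE", config = cfg)
  expect_lt(ce$mean_accuracy, 50)
  expect_equal(ce$verdict, "below_chance")
  ee <- run_decoding(conf$error, conf$error, mode = "EE", config = cfg)
  expect_gt(ee$mean_accuracy, 50)

  disp <- gen("two_class")
  expect_gt(run_decoding(disp$correct, disp$error, mode = "CE",
                         config = cfg)$mean_accuracy, 50)
  expect_gt(run_decoding(disp$error, disp$error, mode = "EE",
                         config = cfg)$mean_accuracy, 50)

  unif <- gen("random_error")
  expect_lt(abs(run_decoding(unif$correct, unif$error, mode = "CE",
                             config = cfg)$mean_accuracy - 50), 5)
  expect_lt(abs(run_decoding(unif$error, unif$error, mode = "EE",
                             config = cfg)$mean_accuracy - 50), 5)
})

test_that("the >500-event gate blocks CE/EE on scarce errors", {
  s <- generate_session(make_archetype("two_class", p_correct = 0.98,
                                       n_trials = 100),
                        generator_config(seed = 45))
  pc <- select_pool(s, outcomes = "correct")
  pe <- select_pool(s, outcomes = "error")
  res <- run_decoding(pc, pe, mode = "CE", config = classifier_config(seed = 1))
  expect_s3_class(res, "decoder_insufficient")
  expect_match(res$reason, "insufficient error events")
  res <- run_decoding(pe, pe, mode = "EE", config = classifier_config(seed = 1))
  expect_s3_class(res, "decoder_insufficient")
})

test_that("peck-order decoding exposes orienting pecks", {
  cfg <- classifier_config(seed = 18)
  s <- generate_session(make_archetype("two_class", orienting_pecks = 1L,
                                       n_trials = 700),
                        generator_config(seed = 47))
  po <- peck_order_decoding(select_pool(s, outcomes = "correct"), cfg)
  accs <- vapply(po$results, function(r) r$mean_accuracy, numeric(1))
  expect_lt(accs[1], accs[3])  # rank 1 is orienting, hence less informative
  expect_lt(abs(accs[1] - 50), 8)

  # no orienting pecks, constant sd: flat within noise
  s0 <- generate_session(make_archetype("two_class", orienting_pecks = 0L,
                                        n_trials = 700),
                         generator_config(seed = 49))
  po0 <- peck_order_decoding(select_pool(s0, outcomes = "correct"), cfg)
  accs0 <- vapply(po0$results, function(r) r$mean_accuracy, numeric(1))
  expect_lt(max(accs0) - min(accs0), 10)

  # a rank with too few events is skipped with a notice
  s_small <- suppressWarnings(
    tiny_session(n_per_class = 30, n_pecks = 2,
                 at_X = c(1.5, 2.5), at_Y = c(3.5, 2.5)))
  po_small <- peck_order_decoding(select_pool(s_small, outcomes = "correct"),
                                  cfg, ranks = 1:3)
  expect_true(isTRUE(po_small$results[[3]]$skipped))
})
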