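test_that("stratified 7:3 split gives 70/30 per class on the default corpus", {
  ds <- simulate_dataset(sim_config(seed = 2))
  sp <- split_dataset(ds, seed = 2)
  expect_equal(nrow(sp$train$rfu), 420)
  expect_equal(nrow(sp$test$rfu), 180)
  expect_equal(as.vector(table(sp$train$label)), rep(70L, 6))
  expect_equal(as.vector(table(sp$test$label)), rep(30L, 6))
  # disjoint and exhaustive
  expect_equal(sort(c(sp$train$well_id, sp$test$well_id)), sort(ds$well_id))
  # deterministic membership
  sp2 <- split_dataset(ds, seed = 2)
  expect_identical(sp$train$well_id, sp2$train$well_id)
  sp3 <- split_dataset(ds, seed = 3)
  expect_false(identical(sp$train$well_id, sp3$train$well_id))
})

test_that("split handles small classes and rejects singletons", {
  ds <- simulate_dataset(sim_config(per_class_n = 2, seed = 1))
  sp <- split_dataset(ds, train_fraction = 0.5, seed = 1)
  expect_equal(as.vector(table(sp$train$label)), rep(1L, 6))
  expect_equal(as.vector(table(sp$test$label)), rep(1L, 6))

  one <- simulate_dataset(sim_config(per_class_n = 1, seed = 1))
  expect_error(split_dataset(one, seed = 1), ">= 2 samples")
  expect_error(split_dataset(ds, train_fraction = 1.2), "train_fraction")
})

test_that("grid search is an exhaustive argmax with grid-order ties", {
  ds <- small_corpus()
  norm <- normalize_fit(ds)
  x <- normalize_apply(norm, ds$rfu)
  y <- ds$label

  single <- model_spec("knn", grid = list(list(k = 3)))
  gs1 <- grid_search(single, x, y, seed = 1)
  expect_equal(gs1$best_params$k, 3)

  spec <- model_spec("knn")
  gs <- grid_search(spec, x, y, seed = 1)
  expect_true(all(gs$best_score >= gs$results$cv_accuracy))
  # tie-break: the chosen point is the first attaining the max
  first_max <- which(gs$results$cv_accuracy == gs$best_score)[1]
  expect_equal(gs$best_params, spec$grid[[first_max]])

  expect_error(grid_search(model_spec("knn", cv_folds = 40), x, y, seed = 1),
               "smallest class count")
  expect_error(model_spec("knn", grid = list()), "grid is empty")
})

test_that("each family trains, predicts factors, and is deterministic", {
  ds <- small_corpus()
  norm <- normalize_fit(ds)
  x <- normalize_apply(norm, ds$rfu)
  y <- ds$label
  params <- list(svc = list(C = 0.5, kernel = "rbf", gamma = 0.1),
                 lrc = list(C = 1), knn = list(k = 3),
                 dtc = list(max_depth = 5), lda = list())
  for (fam in names(params)) {
    m1 <- train_final(fam, params[[fam]], x, y)
    m2 <- train_final(fam, params[[fam]], x, y)
    p1 <- predict(m1, x)
    expect_s3_class(p1, "factor")
    expect_identical(levels(p1), curve_classes())
    expect_identical(p1, predict(m2, x))
    # each family clearly beats chance on its own training set
    expect_gt(mean(p1 == y), 0.8)
  }
})

test_that("frozen models survive serialization with identical predictions", {
  fx <- trained_small()
  ds <- small_corpus()
  x <- normalize_apply(fx$normalizer, ds$rfu)
  path <- tempfile(fileext = ".rds")
  model_save(fx$model, path)
  back <- model_load(path)
  expect_identical(predict(back, x), predict(fx$model, x))
  saveRDS(1:3, path)
  expect_error(model_load(path), "curve_model")
})

test_that("a one-class training set always predicts that class", {
  x <- matrix(rnorm(200), 20, 10)
  y <- factor(rep("class_C", 20), levels = "class_C")
  for (fam in c("knn", "dtc")) {
    m <- train_final(fam, list(k = 1, max_depth = 3)[
      switch(fam, knn = "k", dtc = "max_depth")], x, y)
    expect_true(all(predict(m, matrix(rnorm(50), 5, 10)) == "class_C"))
  }
})

test_that("evaluate reports exact confusion identities and macro metrics", {
  fx <- trained_small()
  ds <- small_corpus()
  x <- normalize_apply(fx$normalizer, ds$rfu)
  rep <- evaluate(fx$model, x, ds$label)

  expect_equal(sum(rep$confusion), length(ds$label))
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.integer(table(ds$label))))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))

  # independent per-class tally oracle
  pred <- predict(fx$model, x)
  oracle <- macro_metrics_oracle(as.character(ds$label), as.character(pred),
                                 curve_classes())
  expect_equal(rep$precision, oracle$precision, tolerance = 1e-12)
  expect_equal(rep$recall, oracle$recall, tolerance = 1e-12)
  expect_equal(rep$f1, oracle$f1, tolerance = 1e-12)
  expect_equal(rep$accuracy, oracle$accuracy, tolerance = 1e-12)

  expect_error(evaluate(fx$model, x, rep("class_Z", nrow(x))),
               "outside the model's classes")
})

test_that("perfect predictions give all-1 metrics and a diagonal confusion", {
  ds <- small_corpus()
  norm <- normalize_fit(ds)
  x <- normalize_apply(norm, ds$rfu)
  m <- train_final("knn", list(k = 1), x, ds$label) # 1-NN on itself is exact
  rep <- evaluate(m, x, ds$label)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_equal(sum(rep$confusion) - sum(diag(rep$confusion)), 0)
})

test_that("predict_curve returns the six-way label and three-way group", {
  fx <- trained_small()
  neg <- noiseless_curve("class_C")
  pos <- noiseless_curve("class_A", 2)
  drift <- noiseless_curve("class_F", 3)
  expect_equal(predict_curve(fx$model, fx$normalizer, neg)$group, "negative")
  expect_equal(predict_curve(fx$model, fx$normalizer, pos)$group, "positive")
  expect_equal(predict_curve(fx$model, fx$normalizer, drift)$group, "abnormal")
  expect_equal(curve_group("class_F"), "abnormal")
  expect_error(predict_curve(fx$model, fx$normalizer, rnorm(12)),
               "does not match")
})

test_that("in-package SVC is a working kernel machine", {
  # XOR-style problem: linearly inseparable, RBF separates it
  set.seed(1)
  n <- 40
  x <- rbind(matrix(rnorm(n, sd = 0.3), ncol = 2) + rep(c(0, 0), each = n / 2),
             matrix(rnorm(n, sd = 0.3), ncol = 2) + rep(c(2, 2), each = n / 2),
             matrix(rnorm(n, sd = 0.3), ncol = 2) + rep(c(0, 2), each = n / 2),
             matrix(rnorm(n, sd = 0.3), ncol = 2) + rep(c(2, 0), each = n / 2))
  y <- factor(rep(c("p", "p", "q", "q"), each = n / 2))
  rbf <- svc_fit(x, y, C = 10, kernel = "rbf", gamma = 1)
  expect_gt(mean(predict(rbf, x) == y), 0.95)
  lin <- svc_fit(x, y, C = 10, kernel = "linear")
  expect_lt(mean(predict(lin, x) == y), 0.8)
  # KKT optimality gap of every binary subproblem is below the tolerance
  expect_lt(max(vapply(rbf$fits, function(f) f$kkt_gap, 0)), 1e-3 + 1e-12)
})
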