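test_that("surrogate pre-training is deterministic and learns separable data", {
  sp <- fixture_split()
  cfg <- train_config(epochs = 50, learning_rate = 2, seed = 4)
  a <- pretrain("surrogate", sp$pretrain, sp$test, cfg)
  b <- pretrain("surrogate", sp$pretrain, sp$test, cfg)
  expect_identical(a$model$params, b$model$params)
  expect_gt(dplyr::last(a$history$IoU), 0.5)
  expect_true(all(diff(a$history$epoch) > 0))
})

test_that("leaf- and rust-target models segment different regions", {
  sp <- fixture_split()
  cfg <- function(t) train_config(epochs = 50, learning_rate = 2, seed = 4,
                                  target = t)
  leaf_m <- pretrain("surrogate", sp$pretrain, sp$test, cfg("leaf"))$model
  rust_m <- pretrain("surrogate", sp$pretrain, sp$test, cfg("rust"))$model
  leaf_area <- mean(vapply(sp$test$items,
                           function(it) sum(predict_mask(leaf_m, it$image)),
                           numeric(1)))
  rust_area <- mean(vapply(sp$test$items,
                           function(it) sum(predict_mask(rust_m, it$image)),
                           numeric(1)))
  expect_gt(leaf_area, rust_area)
})

test_that("snapshot/restore round-trips bit-exactly, also through a file", {
  pre <- fixture_pretrain()
  sp <- fixture_split()
  img <- sp$test[[1]]$image
  blob <- snapshot(pre$model)
  expect_identical(predict_mask(restore(blob), img),
                   predict_mask(pre$model, img))
  path <- withr::local_tempfile(fileext = ".rds")
  save_snapshot(pre$model, path)
  expect_identical(predict_mask(load_snapshot(path), img),
                   predict_mask(pre$model, img))
  expect_error(restore(structure(list(), class = "seg_snapshot")), "corrupt")
  bad <- blob; bad$arch_id <- "mystery"
  expect_error(restore(bad), "unknown backend")
})

test_that("fine-tuning is pure, seeded, and stable at a tiny learning rate", {
  pre <- fixture_pretrain()
  sp <- fixture_split()
  before <- lapply(sp$test$items, function(it) predict_mask(pre$model, it$image))
  blob <- snapshot(pre$model)
  doubled <- concat_image_vectors(sp$pretrain, sp$pretrain)
  cfg <- train_config(epochs = 3, learning_rate = 1e-4, seed = 6)
  ft1 <- finetune(restore(blob), doubled, cfg)
  ft2 <- finetune(restore(blob), doubled, cfg)
  expect_identical(ft1$params, ft2$params)
  expect_false(identical(ft1$params, pre$model$params))
  # input model untouched
  after <- lapply(sp$test$items, function(it) predict_mask(pre$model, it$image))
  expect_identical(before, after)
  # small-lr fine-tuning barely moves the test IoU
  ev0 <- evaluate_model(pre$model, sp$test)
  ev1 <- evaluate_model(ft1, sp$test)
  expect_lt(abs(ev1$metrics$IoU - ev0$metrics$IoU), 0.05)
  # zero-epoch fine-tuning is the identity on parameters
  expect_identical(finetune(restore(blob), doubled,
                            train_config(epochs = 0))$params,
                   pre$model$params)
})

test_that("restoring the snapshot erases any fine-tuning history", {
  pre <- fixture_pretrain()
  sp <- fixture_split()
  blob <- snapshot(pre$model)
  base <- evaluate_model(restore(blob), sp$test)
  for (i in 1:3) {
    child <- apply_action_vector(sp$pretrain, rep(i, length(sp$pretrain)))
    invisible(finetune(restore(blob), concat_image_vectors(sp$pretrain, child),
                       train_config(epochs = 3, learning_rate = 0.3, seed = i)))
    again <- evaluate_model(restore(blob), sp$test)
    expect_identical(again$ious, base$ious)
    expect_identical(again$metrics, base$metrics)
  }
})

test_that("predictions are binary, deterministic and dimension-checked", {
  pre <- fixture_pretrain()
  img <- fixture_split()$test[[2]]$image
  m1 <- predict_mask(pre$model, img)
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_identical(dim(m1), dim(img)[1:2])
  expect_identical(m1, predict_mask(pre$model, img))
  expect_error(predict_mask(pre$model, matrix(0, 4, 4)), "raster")
})

test_that("the oracle backend is perfect on known images and the evaluator
           reports it", {
  sp <- fixture_split()
  oracle <- pretrain("oracle", sp$pretrain, sp$test, train_config())$model
  ev <- evaluate_model(oracle, sp$test)
  expect_equal(ev$ious, rep(1, length(sp$test)))
  expect_equal(ev$dice$d, 2)
  expect_true(all(ev$metrics == 1))
})

test_that("unknown and unimplemented backends raise", {
  sp <- fixture_split()
  expect_error(pretrain("nope", sp$pretrain, sp$test), "unknown backend")
  expect_error(pretrain("deeplabv3plus", sp$pretrain, sp$test),
               "not implemented")
})
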