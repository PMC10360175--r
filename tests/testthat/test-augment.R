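test_that("action 0 is the identity and flips are involutions", {
  it <- generate_leaf_image(tiny_gen(), 0L)
  expect_identical(apply_action(it, 0L), it)
  for (a in 1:2) {
    expect_identical(apply_action(apply_action(it, a), a), it)
  }
  # action 3 is the composition of the two flips, bit-exactly
  expect_identical(apply_action(it, 3L),
                   apply_action(apply_action(it, 1L), 2L))
})

test_that("flips permute pixels: value multisets are conserved", {
  it <- generate_leaf_image(tiny_gen(seed = 3L), 1L)
  for (a in 1:3) {
    out <- apply_action(it, a)
    expect_identical(sort(as.vector(out$image)), sort(as.vector(it$image)))
    expect_identical(sum(out$rust_label), sum(it$rust_label))
    expect_identical(sum(out$leaf_label), sum(it$leaf_label))
  }
})

test_that("every action preserves dimensions and the binary label alphabet", {
  it <- generate_leaf_image(tiny_gen(image_size = 48L), 1L)
  for (a in 0:7) {
    out <- apply_action(it, a, noise_seed = 5L)
    expect_identical(dim(out$image), dim(it$image))
    expect_true(all(out$rust_label %in% c(0L, 1L)))
    expect_true(all(out$leaf_label %in% c(0L, 1L)))
  }
})

test_that("labels co-transform with the image under the same geometric map", {
  it <- generate_leaf_image(tiny_gen(image_size = 40L, seed = 9L), 2L)
  for (a in 1:6) {
    out <- apply_action(it, a)
    expect_identical(out$rust_label,
                     adaptaug:::transform_raster(it$rust_label, a, "nearest"))
    expect_identical(out$leaf_label,
                     adaptaug:::transform_raster(it$leaf_label, a, "nearest"))
  }
})

test_that("the affine shear displaces markers by 0.2 times their row", {
  h <- w <- 64L
  rust <- matrix(0L, h, w)
  x0 <- 12L
  for (y in c(10L, 20L, 40L)) rust[y + 1L, x0 + 1L] <- 1L
  it <- labeled_image(array(128, c(h, w, 3)), rust, matrix(1L, h, w), "m")
  out <- apply_action(it, 5L)
  for (y in c(10L, 20L, 40L)) {
    hits <- which(out$rust_label[y + 1L, ] == 1L) - 1L
    expect_true(length(hits) >= 1)
    # forward map x' = x + 0.2 y, nearest-neighbour rasterization
    expect_lte(min(abs(hits - (x0 + 0.2 * y))), 1)
  }
})

test_that("rotation is 30 degrees clockwise about the image centre", {
  h <- w <- 65L
  rust <- matrix(0L, h, w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  rust[cy + 1L, cx + 21L] <- 1L   # marker at (cx + 20, cy)
  it <- labeled_image(array(128, c(h, w, 3)), rust, matrix(1L, h, w), "m")
  out <- apply_action(it, 4L)
  hits <- which(out$rust_label == 1L)
  expect_true(length(hits) >= 1)
  ys <- (hits - 1L) %% h
  xs <- (hits - 1L) %/% h
  th <- 30 * pi / 180
  # forward clockwise map (y down): (dx, dy) -> (dx cos - dy sin, dx sin + dy cos)
  exp_x <- cx + 20 * cos(th)
  exp_y <- cy + 20 * sin(th)
  expect_lte(min(sqrt((xs - exp_x)^2 + (ys - exp_y)^2)), 1.5)
})

test_that("noise perturbs only the image, with near-zero mean change", {
  it <- labeled_image(array(128, c(64, 64, 3)),
                      matrix(0L, 64, 64), matrix(1L, 64, 64), "n")
  out <- apply_action(it, 7L, noise_sd = 10, noise_seed = 2L)
  expect_identical(out$rust_label, it$rust_label)
  expect_identical(out$leaf_label, it$leaf_label)
  n <- length(it$image)
  expect_lt(abs(mean(out$image - it$image)), 3 * 10 / sqrt(n))
  expect_true(all(out$image >= 0 & out$image <= 255))
  expect_false(identical(out$image, it$image))
})

test_that("apply_action_vector preserves order, index and determinism", {
  vec <- generate_dataset(tiny_gen(n_images = 3L))
  child0 <- apply_action_vector(vec, c(0L, 0L, 0L))
  expect_identical(child0$items, vec$items)
  expect_identical(child0$generation_index, 1L)

  child <- apply_action_vector(vec, c(1L, 2L, 0L))
  expect_identical(child[[1]], apply_action(vec[[1]], 1L))
  expect_identical(child[[2]], apply_action(vec[[2]], 2L))

  n1 <- apply_action_vector(vec, c(7L, 7L, 7L), noise_seed = 42L)
  n2 <- apply_action_vector(vec, c(7L, 7L, 7L), noise_seed = 42L)
  expect_identical(n1, n2)
})

test_that("invalid actions and undersized crops raise", {
  it <- make_item()
  expect_error(apply_action(it, 8L), "unknown action")
  expect_error(apply_action(it, -1L), "unknown action")
  expect_error(apply_action(it, 6L), "crop")
  expect_error(apply_action_vector(generate_dataset(tiny_gen(n_images = 2L)),
                                   c(0L, 0L, 0L)),
               "length")
})
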