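# analytic parameter-count enumeration, written independently of the
# package's shape table: conv3x3 = (9*cin + 1)*cout, upconv2x2 =
# (4*cin + 1)*cout, conv1x1 = (cin + 1)*cout
enum_params <- function(variant, depth, base) {
  cl <- base * 2^(seq_len(depth) - 1)
  cb <- base * 2^depth
  conv3 <- function(cin, cout) (9 * cin + 1) * cout
  upc <- function(cin, cout) (4 * cin + 1) * cout
  conv1 <- function(cin, cout) (cin + 1) * cout
  dbl <- function(cin, cout) conv3(cin, cout) + conv3(cout, cout)
  total <- 0
  if (variant %in% c("single", "hybrid1")) {
    in1 <- if (variant == "single") 1 else 2
    for (l in seq_len(depth))
      total <- total + dbl(if (l == 1) in1 else cl[l - 1], cl[l])
    total <- total + dbl(cl[depth], cb)
    for (l in depth:1)
      total <- total + upc(if (l == depth) cb else cl[l + 1], cl[l]) +
        dbl(2 * cl[l], cl[l])
    total <- total + conv1(cl[1], 2)
  } else if (variant == "hybrid2") {
    for (l in seq_len(depth))
      total <- total + 2 * dbl(if (l == 1) 1 else cl[l - 1], cl[l])
    total <- total + dbl(2 * cl[depth], cb)
    for (l in depth:1)
      total <- total + upc(if (l == depth) cb else cl[l + 1], cl[l]) +
        dbl(3 * cl[l], cl[l])
    total <- total + conv1(cl[1], 2)
  } else {
    for (l in seq_len(depth))
      total <- total + 2 * dbl(if (l == 1) 1 else 2 * cl[l - 1], cl[l])
    total <- total + 2 * dbl(2 * cl[depth], cb)
    for (l in depth:1)
      total <- total + 2 * (upc(if (l == depth) cb else cl[l + 1], cl[l]) +
                              dbl(4 * cl[l], cl[l]))
    total <- total + conv1(2 * cl[1], 2)
  }
  total
}

test_that("parameter counts match exact enumeration, ordered h3 > h2 > h1", {
  for (depth in 2:4) for (base in c(4, 8, 16)) {
    counts <- vapply(c("single", "hybrid1", "hybrid2", "hybrid3"),
                     function(v) count_params(network_spec(v, depth, base)),
                     numeric(1))
    expected <- vapply(c("single", "hybrid1", "hybrid2", "hybrid3"),
                       enum_params, numeric(1), depth = depth, base = base)
    expect_equal(unname(counts), unname(expected))
    expect_gt(counts[["hybrid3"]], counts[["hybrid2"]])
    expect_gt(counts[["hybrid2"]], counts[["hybrid1"]])
    expect_gt(counts[["hybrid1"]], counts[["single"]])
  }
})

test_that("hybrid1 concatenates the two images at the input layer", {
  net <- build_network(network_spec("hybrid1", depth = 2, base_channels = 4))
  # first convolution consumes 2 input channels: 9*2 weight rows
  expect_equal(nrow(net$params[["e1.c1.w"]]), 18L)
  single <- build_network(network_spec("single", depth = 2, base_channels = 4))
  expect_equal(nrow(single$params[["e1.c1.w"]]), 9L)
})

test_that("invalid specs are rejected", {
  expect_error(network_spec("hybrid4"))
  expect_error(network_spec("single", depth = 1), class = "brainext_value")
  expect_error(network_spec("single", base_channels = 2),
               class = "brainext_value")
})

test_that("probability maps are valid and keep the input shape under padding", {
  set.seed(2)
  net <- build_network(network_spec("single", depth = 3, base_channels = 4))
  # 20x20 slices need padding to 24 (multiple of 2^3) and cropping back
  sl <- lapply(1:3, function(i) matrix(runif(400), 20, 20))
  st <- stack_of(sl, "transverse", c(20, 20, 3))
  pr <- predict_stack(net, st)
  expect_length(pr$slices, 3)
  expect_equal(dim(pr$slices[[1]]), c(20L, 20L))
  expect_true(all(vapply(pr$slices, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
})

test_that("training is deterministic for a fixed seed", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 6))
  d <- phantom_stacks(ph, "transverse", stride = 4)
  run <- function() {
    net <- build_network(network_spec("single", depth = 2, base_channels = 4),
                         seed = 3)
    unet_train(net, stack_of(d$x1, "transverse", d$shape),
               stack_of(d$y, "transverse", d$shape),
               train_config(epochs = 3, batch_size = 4, seed = 11))
  }
  a <- run(); b <- run()
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$params, b$params)
})

test_that("a small network overfits a handful of slices", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 12))
  d <- phantom_stacks(ph, "transverse")
  idx <- seq(5, 19, by = 2) # 8 slices through the head
  net <- build_network(network_spec("single", depth = 2, base_channels = 8),
                       seed = 2)
  net <- unet_train(net, stack_of(d$x1[idx], "transverse", d$shape),
                    stack_of(d$y[idx], "transverse", d$shape),
                    train_config(epochs = 200, batch_size = 8, seed = 9))
  expect_lt(min(net$history$loss), 0.05 * net$history$loss[1])
  expect_equal(net$best_epoch, which.min(net$history$loss))
})

test_that("hybrid variants train end-to-end and background slices stay dark", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 14))
  d <- phantom_stacks(ph, "transverse", hybrid = TRUE, stride = 2)
  net <- build_network(network_spec("hybrid2", depth = 2, base_channels = 8),
                       seed = 4)
  net <- unet_train(net, list(stack_of(d$x1, "transverse", d$shape),
                              stack_of(d$x2, "transverse", d$shape)),
                    stack_of(d$y, "transverse", d$shape),
                    train_config(epochs = 30, batch_size = 8, seed = 21))
  # an all-background slice should get near-zero brain probability
  bg <- matrix(0, 24, 24)
  pr <- predict_stack(net, list(stack_of(list(bg), "transverse", d$shape),
                                stack_of(list(bg), "transverse", d$shape)))
  expect_lt(mean(pr$slices[[1]]), 0.1)
})

test_that("misaligned stacks are rejected", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 15))
  d <- phantom_stacks(ph, "transverse")
  net <- build_network(network_spec("single", depth = 2, base_channels = 4))
  expect_error(
    unet_train(net, stack_of(d$x1[1:5], "transverse", d$shape),
               stack_of(d$y[1:4], "transverse", d$shape),
               train_config(epochs = 1)),
    class = "brainext_shape")
  expect_error(predict_stack(net, list(stack_of(d$x1, "transverse", d$shape),
                                       stack_of(d$x1, "transverse", d$shape))),
               class = "brainext_value")
})
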