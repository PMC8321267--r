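# Translator: network contracts, loss arithmetic, smoke training dynamics
# and round-trip consistency.

test_that("generator preserves shape with tanh range and configurable depth", {
  set.seed(1)
  g <- build_generator(generator_spec(64, base_channels = 8,
                                      n_residual_blocks = 12))
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  y <- g$forward(x)
  expect_equal(dim(y), c(64, 64, 3))
  expect_true(all(y >= -1 & y <= 1))
  expect_equal(count_residual_blocks(g), 12)
  g9 <- build_generator(generator_spec(64, 8, n_residual_blocks = 9))
  expect_equal(count_residual_blocks(g9), 9)
  expect_error(generator_spec(62), "divisible by 4")
  # zeroed final conv gives tanh(0) = 0 everywhere
  mods <- derm2macro:::collect_modules(g)
  last_conv <- mods[[max(which(vapply(mods, function(m) m$type == "conv",
                                      TRUE)))]]
  last_conv$params$W[] <- 0
  last_conv$params$b[] <- 0
  expect_equal(g$forward(x), array(0, c(64, 64, 3)))
})

test_that("discriminator produces a probability patch map scaling with input", {
  set.seed(2)
  d <- build_discriminator(discriminator_spec(64, 8))
  p64 <- d$forward(array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3)))
  expect_equal(dim(p64), c(2, 2, 1))          # 64 / 2^5
  expect_true(all(p64 > 0 & p64 < 1))
  p128 <- d$forward(array(runif(128 * 128 * 3, -1, 1), c(128, 128, 3)))
  expect_equal(dim(p128), c(4, 4, 1))
  expect_error(discriminator_spec(16, 8), "receptive")
})

test_that("adversarial loss is the mean patch cross-entropy", {
  p <- array(0.5, c(2, 2, 1))
  expect_equal(adversarial_loss(p, "ones"), log(2))
  expect_lt(adversarial_loss(array(1 - 1e-9, c(2, 2, 1)), "ones"), 1e-6)
  mixed <- array(c(0.9, 0.8, 0.6, 0.7), c(2, 2, 1))
  expect_equal(adversarial_loss(mixed, "ones"),
               mean(-log(c(0.9, 0.8, 0.6, 0.7))))
  expect_equal(adversarial_loss(mixed, "zeros"),
               mean(-log(1 - c(0.9, 0.8, 0.6, 0.7))))
  expect_error(adversarial_loss(array(c(0, 0.5), c(2, 1, 1)), "ones"),
               "strictly")
})

test_that("cycle and total losses follow their definitions", {
  set.seed(3)
  x <- array(runif(12), c(2, 2, 3))
  y <- array(runif(12), c(2, 2, 3))
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(cycle_loss(x, x + 0.1, y, y), 0.1)
  xr <- array(runif(12), c(2, 2, 3))
  yr <- array(runif(12), c(2, 2, 3))
  expect_equal(cycle_loss(x, xr, y, yr),
               mean(abs(x - xr)) + mean(abs(y - yr)))
  expect_equal(total_loss(0.5, 0.7, 0.2, 10), 3.2)
  expect_equal(total_loss(0.5, 0.7, 0, 10), 1.2)
  expect_equal(formals(total_loss)$lambda_cyc, 10)
  expect_equal(formals(cyclegan_config)$lambda_cyc, 10)
})

test_that("smoke training yields finite decreasing losses and reproducible history", {
  syn <- smoke_domains(n = 8, size = 32, seed = 5)
  cfg <- cyclegan_config(gen_spec = generator_spec(32, 8, 2),
                         disc_spec = discriminator_spec(32, 8),
                         max_epochs = 3, early_stop_window = 99, seed = 21)
  b1 <- train_cyclegan(sym_ds(syn$dermo), sym_ds(syn$macro), cfg)
  expect_lte(nrow(b1$history), 3)
  expect_true(all(is.finite(as.matrix(b1$history))))
  expect_lt(b1$history$loss_cyc[3], b1$history$loss_cyc[1])
  # loss decomposition at every epoch
  expect_equal(b1$history$loss_gen_total,
               total_loss(b1$history$loss_gan_F, b1$history$loss_gan_G,
                          b1$history$loss_cyc, 10) + b1$history$loss_idt)
  b2 <- train_cyclegan(sym_ds(syn$dermo), sym_ds(syn$macro), cfg)
  expect_identical(b1$history, b2$history)
  expect_error(train_cyclegan(derm2macro:::new_dataset(list()),
                              sym_ds(syn$macro), cfg), "nonempty")
})

test_that("translate tags domains, carries masks and closes the cycle-loss loop", {
  syn <- smoke_domains(n = 6, size = 32, seed = 9)
  cfg <- cyclegan_config(gen_spec = generator_spec(32, 8, 2),
                         disc_spec = discriminator_spec(32, 8),
                         max_epochs = 2, early_stop_window = 99, seed = 4)
  b <- train_cyclegan(sym_ds(syn$dermo), sym_ds(syn$macro), cfg)
  dermo_sym <- sym_ds(syn$dermo)
  tm <- translate(b, dermo_sym, "dermo2macro")
  expect_length(tm, 6)
  expect_true(all(vapply(tm, `[[`, "", "domain") == "trans_macro"))
  for (i in seq_along(tm)) {
    expect_equal(dim(tm[[i]]$image), dim(dermo_sym[[i]]$image))
    expect_identical(tm[[i]]$mask, dermo_sym[[i]]$mask)
  }
  td <- translate(b, sym_ds(syn$macro), "macro2dermo")
  expect_true(all(vapply(td, `[[`, "", "domain") == "trans_dermo"))
  # round trip: translate there and back, compare with cycle_loss on the
  # same batch
  back <- translate(b, tm, "macro2dermo")
  l1 <- mean(vapply(seq_along(back), function(i)
    mean(abs(back[[i]]$image - dermo_sym[[i]]$image)), 0))
  per_image <- vapply(seq_along(back), function(i)
    cycle_loss(dermo_sym[[i]]$image, back[[i]]$image,
               dermo_sym[[i]]$image, back[[i]]$image) / 2, 0)
  expect_equal(l1, mean(per_image))
  expect_true(is.finite(l1))
})
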