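# Evaluation stack: embedding statistics, Frechet distance, Variation
# Ratio, confusion counts, the six-metric suite, overlays and normalized
# error rates.

fstats <- function(mu, sigma, n = 10) {
  structure(list(mu = mu, sigma = as.matrix(sigma), n = n),
            class = "feature_stats")
}

test_that("embedding statistics are the sample mean and covariance", {
  mean_embedder <- function(img) apply(img, 3, mean)
  imgs <- list(array(0.2, c(8, 8, 3)), array(0.4, c(8, 8, 3)),
               array(c(0.6, 0.1, 0.5), c(8, 8, 3))[, , c(1, 2, 3)])
  imgs[[3]] <- array(rep(c(0.6, 0.1, 0.5), each = 64), c(8, 8, 3))
  st <- embed_images(imgs, mean_embedder)
  E <- rbind(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4), c(0.6, 0.1, 0.5))
  expect_equal(st$mu, colMeans(E))
  expect_equal(st$sigma, cov(E), ignore_attr = TRUE)
  expect_equal(st$n, 3)
  # identical images: zero covariance
  st0 <- embed_images(imgs[c(1, 1)], mean_embedder)
  expect_equal(st0$sigma, matrix(0, 3, 3), ignore_attr = TRUE)
  # permutation invariance
  st_perm <- embed_images(imgs[c(3, 1, 2)], mean_embedder)
  expect_equal(st_perm$mu, st$mu)
  expect_equal(st_perm$sigma, st$sigma)
  expect_error(embed_images(imgs[1], mean_embedder), "at least 2")
})

test_that("Frechet distance reproduces closed forms", {
  set.seed(31)
  # identical stats
  S <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  a <- fstats(rnorm(5), S)
  expect_equal(frechet_distance(a, a), 0, tolerance = 1e-8)
  # identity covariances: squared mean distance
  d <- rnorm(5)
  expect_equal(frechet_distance(fstats(d, diag(5)), fstats(rep(0, 5),
                                                           diag(5))),
               sum(d^2), tolerance = 1e-8)
  # 1-D closed form over random scalars
  for (i in 1:100) {
    mu <- rnorm(2)
    v <- runif(2, 0.01, 4)
    got <- frechet_distance(fstats(mu[1], v[1]), fstats(mu[2], v[2]))
    expect_lt(abs(got - ((mu[1] - mu[2])^2 + (sqrt(v[1]) - sqrt(v[2]))^2)),
              1e-8)
  }
  # diagonal covariances decompose per dimension
  va <- runif(4, 0.1, 2)
  vb <- runif(4, 0.1, 2)
  mua <- rnorm(4); mub <- rnorm(4)
  expect_equal(frechet_distance(fstats(mua, diag(va)), fstats(mub, diag(vb))),
               sum((mua - mub)^2 + (sqrt(va) - sqrt(vb))^2),
               tolerance = 1e-8)
  # symmetry and nonnegativity on random PSD pairs
  for (i in 1:20) {
    A <- fstats(rnorm(4), crossprod(matrix(rnorm(16), 4, 4)) / 4)
    B <- fstats(rnorm(4), crossprod(matrix(rnorm(16), 4, 4)) / 4)
    dab <- frechet_distance(A, B)
    expect_gte(dab, 0)
    expect_equal(dab, frechet_distance(B, A), tolerance = 1e-7)
  }
  expect_error(frechet_distance(fstats(rnorm(3), diag(3)),
                                fstats(rnorm(4), diag(4))), "dimensions")
})

test_that("Variation Ratio follows (reference - value) / reference with report rounding", {
  expect_equal(variation_ratio(167.9, 160.2), (167.9 - 160.2) / 167.9)
  expect_equal(variation_ratio(167.9, 160.2, digits = 2), 0.05)
  expect_equal(variation_ratio(167.9, 186.4, digits = 2), -0.11)
  expect_equal(variation_ratio(100, 100), 0)
  expect_error(variation_ratio(0, 10), "positive")
  expect_error(variation_ratio(-5, 10), "positive")
  # half-away-from-zero at an exactly representable half (0.125)
  expect_equal(variation_ratio(1000, 875, digits = 2), 0.13)
  expect_equal(variation_ratio(1000, 1125, digits = 2), -0.13)
})

test_that("confusion counts equal a per-pixel loop oracle", {
  set.seed(17)
  truth <- (matrix(runif(64), 8, 8) > 0.5) * 1L
  expect_equal(confusion_counts(truth, truth)[c("FP", "FN")],
               c(FP = 0L, FN = 0L))
  expect_equal(confusion_counts(1L - truth, truth)[c("TP", "TN")],
               c(TP = 0L, TN = 0L))
  for (i in 1:10) {
    pred <- (matrix(runif(64), 8, 8) > 0.5) * 1L
    cc <- confusion_counts(pred, truth)
    expect_equal(cc, confusion_loop(pred, truth))
    expect_equal(sum(cc), 64)
  }
  expect_error(confusion_counts(truth, truth[1:4, ]), "shapes")
})

test_that("segmentation metrics implement the thresholded Jaccard suite", {
  truth <- matrix(0L, 8, 8)
  truth[2:5, 2:5] <- 1L
  perfect <- segmentation_metrics(list(list(pred = truth, truth = truth)))
  for (m in c("TJA", "JA", "DI", "AC", "SE", "SP"))
    expect_equal(perfect[[m]], 1)
  # JA = 0.60 contributes 0 to TJA but 0.60 to JA
  t10 <- matrix(0L, 8, 8); t10[1, 1:10 %% 8 + 1] <- 1L
  t10 <- matrix(0L, 8, 8); t10[1:2, 1:5] <- 1L        # 10 foreground pixels
  p6 <- matrix(0L, 8, 8); p6[1, 1:5] <- 1L; p6[2, 1] <- 1L   # 6 of them
  r <- segmentation_metrics(list(list(pred = p6, truth = t10)))
  expect_equal(r$JA, 0.6)
  expect_equal(r$TJA, 0)
  # two pairs with per-image JA 0.70 and 0.60
  p7 <- matrix(0L, 8, 8); p7[1:2, 1:3] <- 1L; p7[1, 4] <- 1L  # 7 of the 10
  r2 <- segmentation_metrics(list(list(pred = p7, truth = t10),
                                  list(pred = p6, truth = t10)))
  expect_equal(r2$JA, 0.65)
  expect_equal(r2$TJA, 0.35)
  # DI = 2 JA / (1 + JA) per image, exactly
  set.seed(23)
  for (i in 1:50) {
    pred <- (matrix(runif(256), 16, 16) > runif(1)) * 1L
    tr <- (matrix(runif(256), 16, 16) > runif(1)) * 1L
    rec <- segmentation_metrics(list(list(pred = pred, truth = tr)))
    ja <- rec$per_image$JA
    expect_equal(rec$per_image$DI, 2 * ja / (1 + ja))
    expect_lte(rec$TJA, rec$JA + 1e-12)
  }
  # empty/empty convention
  z <- matrix(0L, 4, 4)
  rz <- segmentation_metrics(list(list(pred = z, truth = z)))
  expect_equal(c(rz$JA, rz$DI, rz$SE), c(1, 1, 1))
})

test_that("overlay colors match the confusion classes bit-exactly", {
  truth <- matrix(0L, 8, 8); truth[3:6, 3:6] <- 1L
  pred <- matrix(0L, 8, 8); pred[4:7, 3:6] <- 1L
  ov <- overlay(pred, truth)
  cc <- confusion_counts(pred, truth)
  is_col <- function(r, g, b) sum(ov[, , 1] == r & ov[, , 2] == g &
                                    ov[, , 3] == b)
  expect_equal(is_col(1, 1, 0), unname(cc["TP"]))   # yellow
  expect_equal(is_col(1, 0, 0), unname(cc["FP"]))   # red
  expect_equal(is_col(0, 1, 0), unname(cc["FN"]))   # green
  expect_equal(is_col(0, 0, 0), unname(cc["TN"]))   # black
  ident <- overlay(truth, truth)
  expect_equal(sum(ident[, , 1] != ident[, , 2]), 0)   # yellow + black only
  empty <- overlay(matrix(0L, 8, 8), truth)
  expect_equal(sum(empty[, , 1]), 0)                    # green + black only
})

test_that("normalized error rates divide by the ground-truth foreground", {
  truth <- matrix(0L, 10, 10); truth[3:6, 3:6] <- 1L    # 16 pixels
  perfect <- normalized_error_rates(list(list(pred = truth, truth = truth)))
  expect_equal(perfect, c(fp = 0, fn = 0))
  # a prediction whose FP count equals the foreground area
  pred <- truth
  pred[7:8, 1:8] <- 1L                                   # 16 extra pixels
  r <- normalized_error_rates(list(list(pred = pred, truth = truth)))
  expect_equal(r[["fp"]], 1)
  # three-pair toy set against an explicit loop
  set.seed(41)
  pairs <- lapply(1:3, function(i) {
    list(pred = (matrix(runif(100), 10, 10) > 0.5) * 1L,
         truth = (matrix(runif(100), 10, 10) > 0.4) * 1L)
  })
  got <- normalized_error_rates(pairs)
  manual <- sapply(pairs, function(pr) {
    cc <- confusion_loop(pr$pred, pr$truth)
    fg <- cc["TP"] + cc["FN"]
    c(cc["FP"] / fg, cc["FN"] / fg)
  })
  expect_equal(got, c(fp = mean(manual[1, ]), fn = mean(manual[2, ])))
  # total-pixel normalizer option
  gt <- normalized_error_rates(pairs, normalizer = "total")
  expect_lt(gt[["fp"]], got[["fp"]])
})

test_that("the bundled FID reference table carries both comparison sets", {
  tab <- fid_reference_table()
  expect_true(all(c("subset", "preprocessing", "pair", "fid") %in%
                    names(tab)))
  expect_equal(tab$fid[tab$subset == "EDRA" & tab$pair == "macro_dermo"],
               167.9)
  expect_equal(tab$fid[tab$pair == "setM_setMartificial"], 102.4)
  expect_gte(nrow(tab), 15)
})
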