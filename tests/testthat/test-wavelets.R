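test_that("filter banks expose the standard spline biorthogonal filters", {
  fb <- get_filter_bank("bior1.1")
  expect_equal(fb$lo_d, c(1, 1) / sqrt(2), tolerance = 1e-15)
  expect_equal(fb$hi_d, c(-1, 1) / sqrt(2), tolerance = 1e-15)

  fb22 <- get_filter_bank("bior2.2")
  expect_length(fb22$lo_d, 5)   # spline 2/2 analysis low-pass
  expect_length(fb22$lo_r, 3)   # synthesis low-pass

  # case-insensitive lookup, sqrt(2) DC gain across all families
  expect_identical(get_filter_bank("Bior4.4"), get_filter_bank("bior4.4"))
  for (fam in bior_families()) {
    expect_equal(sum(get_filter_bank(fam)$lo_d), sqrt(2),
                 tolerance = 1e-12)
  }
  expect_error(get_filter_bank("bior9.9"), "bior1.1")
  expect_length(bior_families(), 15)
})

test_that("dwt_step reproduces frozen reference coefficients", {
  r <- dwt_step(c(1, 2, 3, 4), get_filter_bank("bior1.1"))
  expect_equal(r$approx, c(2.121320343559643, 4.949747468305834),
               tolerance = 1e-12)
  expect_equal(r$detail, c(-0.7071067811865476, -0.7071067811865475),
               tolerance = 1e-12)

  x24 <- c(0.496714, -0.138264, 0.647689, 1.52303, -0.234153, -0.234137,
           1.579213, 0.767435, -0.469474, 0.54256, -0.463418, -0.46573,
           0.241962, -1.91328, -1.724918, -0.562288, -1.012831, 0.314247,
           -0.908024, -1.412304, 1.465649, -0.225776, 0.067528, -1.424748)
  r22 <- dwt_step(x24, get_filter_bank("bior2.2"))
  expect_length(r22$approx, 14)
  expect_equal(r22$approx[1:3],
               c(-0.099087226801, 0.563521501422, 1.130151974584),
               tolerance = 1e-10)
  expect_equal(r22$detail[1:3],
               c(-0.224498624852, 0.502374972849, -0.930737786018),
               tolerance = 1e-10)
  r68 <- dwt_step(x24, get_filter_bank("bior6.8"))
  expect_length(r68$approx, 20)
  expect_equal(r68$approx[1:2], c(1.225985997113, 0.160771789121),
               tolerance = 1e-10)
  expect_equal(r68$detail[1:2], c(-1.178029565769, 0.771228012014),
               tolerance = 1e-10)
})

test_that("constant inputs are killed by the high-pass branch", {
  r <- dwt_step(rep(3, 4), get_filter_bank("bior1.1"))
  expect_equal(r$approx, rep(3 * sqrt(2), 2), tolerance = 1e-12)
  expect_equal(r$detail, rep(0, 2), tolerance = 1e-12)
})

test_that("dwt_step matches the naive convolution oracle on every family", {
  withr::local_seed(7)
  for (fam in bior_families()) {
    fb <- get_filter_bank(fam)
    for (n in c(8, 24, 37)) {
      x <- rnorm(n)
      got <- dwt_step(x, fb)
      want <- oracle_dwt(x, fb$padded$lo_d, fb$padded$hi_d)
      expect_equal(got$approx, want$approx, tolerance = 1e-12)
      expect_equal(got$detail, want$detail, tolerance = 1e-12)
      expect_length(got$approx, (n + fb$filter_length - 1) %/% 2)
      expect_length(got$detail, length(got$approx))
    }
  }
})

test_that("analysis followed by synthesis reconstructs perfectly", {
  withr::local_seed(11)
  for (fam in bior_families()) {
    fb <- get_filter_bank(fam)
    for (n in sample(8:64, 6)) {
      x <- rnorm(n)
      s <- dwt_step(x, fb)
      expect_equal(idwt_step(s$approx, s$detail, fb, n), x,
                   tolerance = 1e-8)
    }
  }
})

test_that("the 3-level cascade has the documented geometry", {
  d <- decompose(sin(1:24), "bior1.1")
  expect_equal(unname(lengths(d$A)), c(12L, 6L, 3L))
  expect_equal(unname(lengths(d$A)), unname(lengths(d$D)))

  z <- decompose(rep(0, 24), "bior3.5")
  expect_true(all(abs(unlist(z$A)) == 0) && all(abs(unlist(z$D)) == 0))

  # long filters: length rule applied three times
  fb <- get_filter_bank("bior6.8")
  F <- fb$filter_length
  d68 <- decompose(rnorm(24), "bior6.8")
  l1 <- (24 + F - 1) %/% 2
  l2 <- (l1 + F - 1) %/% 2
  l3 <- (l2 + F - 1) %/% 2
  expect_equal(unname(lengths(d68$D)), c(l1, l2, l3))

  expect_error(decompose(rnorm(10), "bior6.8"), "minimum length is 18")
})

test_that("the cascade is linear in its input", {
  withr::local_seed(13)
  x <- rnorm(24)
  y <- rnorm(24)
  for (fam in c("bior1.3", "bior2.4", "bior4.4")) {
    dx <- decompose(x, fam)
    dy <- decompose(y, fam)
    dz <- decompose(2.5 * x - 1.25 * y, fam)
    for (k in 1:3) {
      expect_equal(dz$D[[k]], 2.5 * dx$D[[k]] - 1.25 * dy$D[[k]],
                   tolerance = 1e-10)
      expect_equal(dz$A[[k]], 2.5 * dx$A[[k]] - 1.25 * dy$A[[k]],
                   tolerance = 1e-10)
    }
  }
})

test_that("biorN.M detail coefficients annihilate polynomials of degree < N", {
  n <- 64
  t <- seq(0, 1, length.out = n)
  for (fam in bior_families()) {
    N <- as.integer(substring(fam, 5, 5))
    fb <- get_filter_bank(fam)
    x <- rowSums(sapply(0:(N - 1), function(k) t^k))
    d <- dwt_step(x, fb)$detail
    interior <- d[(fb$filter_length + 1):(length(d) - fb$filter_length)]
    expect_lt(max(abs(interior)), 1e-8)
  }
})

test_that("decompositions flatten to the long coefficient layout", {
  d <- decompose(rnorm(24), "bior1.1", subject_id = 4, start_s = 48)
  long <- as.data.frame(d)
  expect_equal(nrow(long), 2 * (12 + 6 + 3))
  expect_setequal(unique(long$subband), c("A1", "A2", "A3",
                                          "D1", "D2", "D3"))
  expect_equal(long$value[long$subband == "A1"], d$A$A1)
  expect_true(all(long$subject_id == 4) && all(long$start_s == 48))
})
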