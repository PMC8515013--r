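test_that("the STA is null for unrelated responses and weighting-invariant", {
  clip <- generate_white_noise(2019, 5, 5, seed = 1)
  ws <- make_windows(clip, 10)
  n <- dim(ws$windows)[1]
  set.seed(2)
  resp <- rexp(n)                        # independent of the stimulus
  sta <- compute_sta(ws, resp)
  # binary noise has sd 0.5; response-weighted mean stays near 0
  expect_lt(max(abs(sta)), 3 * 0.5 / sqrt(n) * 3)
  # duplicating the dataset leaves the STA unchanged
  dup_w <- array(0, c(2 * n, 10, 5, 5))
  dup_w[1:n, , , ] <- ws$windows; dup_w[n + 1:n, , , ] <- ws$windows
  expect_equal(unclass(compute_sta(dup_w, c(resp, resp))), unclass(sta),
               tolerance = 1e-12)
  expect_error(compute_sta(ws, numeric(n)), "all-zero")
})

test_that("the STA recovers a known LN filter from white noise", {
  # rectified projection of one subunit filter on 5e4 binary noise samples
  su <- build_subunit_bank()[[3]]
  truth <- subunit_window_tensor(su)
  clip <- generate_white_noise(50019, 8, 8, seed = 3)
  ws <- make_windows(clip, 20)
  X <- matrix(ws$windows - 0.5, nrow = dim(ws$windows)[1])
  resp <- pmax(X %*% as.numeric(truth), 0)
  sta <- compute_sta(ws, as.numeric(resp))
  expect_gte(cosine_similarity(sta, truth), 0.9)
})

test_that("SVD factorization is exact on separable filters and stable", {
  s <- matrix(exp(-outer((1:7 - 4)^2, (1:6 - 3)^2, "+") / 6), 7, 6)
  k <- c(0.2, 0.9, 0.4, -0.6, -0.3)
  f <- array(0, c(5, 7, 6))
  for (l in 1:5) f[l, , ] <- k[l] * s
  fz <- factorize_rf(f)
  expect_equal(abs(cosine_similarity(fz$spatial, s)), 1, tolerance = 1e-10)
  expect_equal(abs(cosine_similarity(fz$temporal, k)), 1, tolerance = 1e-10)
  expect_equal(fz$singular_value, sqrt(sum(s^2)) * sqrt(sum(k^2)),
               tolerance = 1e-10)
  # sign convention: dominant temporal lobe positive
  expect_gt(fz$temporal[which.max(abs(fz$temporal))], 0)
  expect_equal(fz$polarity, "ON")
  f_off <- -f
  expect_equal(factorize_rf(f_off)$polarity, "OFF")

  # orthogonal rank-1 perturbation at 1% energy barely moves the factors
  k2 <- c(1, 0, 0, 0, 0); k2 <- k2 - k * sum(k2 * k) / sum(k^2)
  s2 <- matrix(rnorm(42), 7); s2 <- s2 - s * sum(s2 * s) / sum(s^2)
  pert <- f
  eps <- 0.01 * sqrt(sum(f^2) / (sum(k2^2) * sum(s2^2)))
  for (l in 1:5) pert[l, , ] <- pert[l, , ] + eps * k2[l] * s2
  fz2 <- factorize_rf(pert)
  expect_gt(abs(cosine_similarity(fz2$spatial, s)), 0.999)
  expect_gt(abs(cosine_similarity(fz2$temporal, k)), 0.999)

  # Eckart-Young: rank-1 reconstruction error = energy - sigma1^2
  M <- matrix(f, 5, 42)
  recon <- fz$singular_value * (fz$temporal %*% t(as.numeric(fz$spatial)))
  expect_lt(sum((M - recon)^2) - (sum(M^2) - fz$singular_value^2), 1e-9)
  expect_error(factorize_rf(array(0, c(3, 2, 2))), "zero")
})

test_that("the 2D Gaussian fit recovers generator parameters", {
  h <- 12; w <- 12
  yy <- matrix(1:h, h, w); xx <- matrix(1:w, h, w, byrow = TRUE)
  map <- 2 * exp(-0.5 * (((xx - 7) / 2)^2 + ((yy - 4) / 1)^2))
  g <- fit_gaussian_rf(map)
  expect_true(g$valid)
  expect_equal(as.numeric(g$center), c(7, 4), tolerance = 0.02)
  expect_equal(as.numeric(g$sigma), c(2, 1), tolerance = 0.02)
  expect_equal(g$amplitude, 2, tolerance = 0.02)
  expect_lt(abs(sin(g$theta)), 0.02)     # axis-aligned

  # isotropic blob: equal axes
  iso <- exp(-0.5 * (((xx - 6) / 1.5)^2 + ((yy - 6) / 1.5)^2))
  gi <- fit_gaussian_rf(iso)
  expect_equal(gi$sigma[["major"]], gi$sigma[["minor"]], tolerance = 0.01)

  # an OFF-polarity blob is flipped before fitting
  gn <- fit_gaussian_rf(-map)
  expect_true(gn$valid)
  expect_equal(as.numeric(gn$center), c(7, 4), tolerance = 0.05)

  # pure white noise has no dominant blob
  set.seed(5)
  flagged <- fit_gaussian_rf(matrix(rnorm(144), 12))
  expect_false(flagged$valid)
})

test_that("RF cosine distance matches a brute-force grid oracle", {
  mk <- function(cx, cy, s) list(center = c(cx, cy), sigma = c(s, s),
                                 theta = 0, amplitude = 1, valid = TRUE)
  a <- mk(8, 10, 1); b <- mk(10, 10, 1)
  expect_equal(rf_cosine_distance(a, a, c(20, 20)), 0, tolerance = 1e-12)
  far <- mk(3, 3, 0.8); faraway <- mk(17, 17, 0.8)   # >10 combined sigma
  expect_gte(rf_cosine_distance(far, faraway, c(20, 20)), 0.99)
  # brute-force double-sum oracle
  da <- db <- matrix(0, 20, 20)
  for (y in 1:20) for (x in 1:20) {
    da[y, x] <- exp(-0.5 * ((x - 8)^2 + (y - 10)^2))
    db[y, x] <- exp(-0.5 * ((x - 10)^2 + (y - 10)^2))
  }
  num <- 0; na <- 0; nb <- 0
  for (y in 1:20) for (x in 1:20) {
    num <- num + da[y, x] * db[y, x]
    na <- na + da[y, x]^2; nb <- nb + db[y, x]^2
  }
  expect_equal(rf_cosine_distance(a, b, c(20, 20)),
               1 - num / sqrt(na * nb), tolerance = 1e-9)
})

test_that("Moran's I equals the double-loop oracle; checkerboard gives -1", {
  moran_oracle <- function(m) {
    h <- nrow(m); w <- ncol(m); z <- m - mean(m)
    num <- 0; wsum <- 0
    for (i1 in 1:h) for (j1 in 1:w) for (i2 in 1:h) for (j2 in 1:w) {
      wij <- as.numeric(abs(i1 - i2) + abs(j1 - j2) == 1)
      num <- num + wij * z[i1, j1] * z[i2, j2]
      wsum <- wsum + wij
    }
    (h * w / wsum) * num / sum(z^2)
  }
  expect_equal(spatial_autocorrelation(matrix(c(1, -1, -1, 1), 2)), -1,
               tolerance = 1e-12)
  blob <- outer(dnorm(1:7, 4, 1.5), dnorm(1:7, 4, 1.5))
  expect_gt(spatial_autocorrelation(blob), 0)
  set.seed(6)
  for (rep in 1:8) {
    m <- matrix(rnorm(25), 5)
    expect_equal(spatial_autocorrelation(m), moran_oracle(m),
                 tolerance = 1e-12)
  }
  expect_warning(z <- spatial_autocorrelation(matrix(1, 3, 3)), "constant")
  expect_equal(z, 0)
})

test_that("temporal regularity matches a term-by-term oracle", {
  eps <- 5e-4
  oracle <- function(w) {
    T_ <- length(w); den <- sqrt(sum((w - mean(w))^2)) + eps
    s <- 0
    for (i in seq_len(T_)) s <- s + (abs(abs(w[i]) - max(abs(w))) - eps) / den
    s / T_
  }
  # constant kernel: every numerator -eps over denominator eps gives -1
  expect_equal(temporal_regularity(rep(2.7, 9)), -1, tolerance = 1e-12)
  # two-point kernel [0, M], M >> eps: -> sqrt(2)/2
  expect_equal(temporal_regularity(c(0, 1e4)), sqrt(2) / 2, tolerance = 1e-3)
  set.seed(7)
  for (rep in 1:50) {
    w <- rnorm(sample(2:30, 1), sd = 10^runif(1, -2, 1))
    expect_equal(temporal_regularity(w), oracle(w), tolerance = 1e-12)
  }
  # scale invariance away from the eps floor
  w <- rnorm(20)
  expect_equal(temporal_regularity(1e4 * w), temporal_regularity(1e5 * w),
               tolerance = 1e-4)
  # the alternative parse is available and differs in general
  expect_false(isTRUE(all.equal(temporal_regularity(w),
                                temporal_regularity(w, parse = "signed_dev"))))
})

test_that("kernel-to-subunit matching recovers permutations sign-agnostically", {
  bank <- build_subunit_bank()
  tensors <- lapply(bank, subunit_window_tensor)
  m <- match_kernels_to_subunits(tensors, bank)
  expect_equal(m$kernel, 1:8)
  expect_equal(m$similarity, rep(1, 8), tolerance = 1e-12)
  # sign flips are absorbed
  m2 <- match_kernels_to_subunits(lapply(tensors, function(x) -x), bank)
  expect_equal(m2$kernel, 1:8)
  expect_equal(m2$similarity, rep(1, 8), tolerance = 1e-12)
  # a shuffled kernel list is unshuffled by the assignment
  set.seed(8)
  perm <- sample(8)
  m3 <- match_kernels_to_subunits(tensors[perm], bank)
  expect_equal(perm[m3$kernel], 1:8)
})
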