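test_that("framewise displacement is the summed absolute parameter change", {
  const <- matrix(1.3, 10, 6)
  expect_equal(framewise_displacement(const), rep(0, 10))

  step <- matrix(0, 3, 6)
  step[2, ] <- 0.1
  step[3, ] <- 0.2
  expect_equal(framewise_displacement(step), c(0, 0.6, 0.6))

  set.seed(1)
  tr <- matrix(rnorm(60), 10, 6)
  oracle <- c(0, vapply(2:10, function(t) sum(abs(tr[t, ] - tr[t - 1, ])),
                        numeric(1)))
  expect_equal(framewise_displacement(tr), oracle)

  # invariance to constant offsets per column
  tr2 <- sweep(tr, 2, c(5, -2, 0.4, 100, -7, 3), "+")
  expect_equal(framewise_displacement(tr2), framewise_displacement(tr))

  expect_error(framewise_displacement(matrix(c(tr[, -6], rep(NA, 10)), 10, 6)),
               "non-finite")
})

test_that("censoring applies the spike, successor, and isolation rules", {
  m1 <- censor_mask(c(0, 0.6, 0, 0, 0))
  expect_equal(m1$keep, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(m1$usable)

  # spikes at TRs 3 and 6 (1-based) of an 8-TR run: TR 5 is isolated
  fd <- rep(0, 8)
  fd[c(3, 6)] <- 0.8
  m2 <- censor_mask(fd)
  expect_equal(which(!m2$keep), 3:7)

  fd3 <- rep(0, 225)
  fd3[1:120] <- 0.6
  m3 <- censor_mask(fd3)
  expect_false(m3$usable)
  expect_gt(1 - m3$retained_fraction, 0.5)
})

test_that("censor masks are fixed points of the rules", {
  set.seed(42)
  for (rep in 1:20) {
    fd <- abs(rnorm(80, 0.2, 0.25))
    m <- censor_mask(fd)
    keep <- m$keep
    over <- which(fd > 0.5)
    expect_true(all(!keep[over]))
    expect_true(all(!keep[pmin(over + 1, 80)]))
    inner <- which(keep)
    inner <- inner[inner > 1 & inner < 80]
    expect_false(any(!keep[inner - 1] & !keep[inner + 1]))
  }
})

test_that("nuisance regression removes the modeled signals exactly", {
  set.seed(3)
  n <- 120
  motion <- matrix(cumsum(rnorm(n * 6, 0, 0.02)), n, 6)
  csf <- rnorm(n)
  wm <- rnorm(n)

  # a node equal to one motion regressor is annihilated
  y <- cbind(motion[, 2], rnorm(n))
  res <- nuisance_regress(y, motion, csf, wm)
  expect_lt(max(abs(res[, 1])), 1e-10)

  # residuals orthogonal to every design column
  X <- cbind(1, dynfc:::volterra_design(motion), csf, wm)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  # construct-and-remove: signal + 0.5 * R1^2
  sig <- sin(seq_len(n) / 9)
  y2 <- matrix(sig + 0.5 * motion[, 1]^2)
  res2 <- nuisance_regress(y2, motion, csf, wm)
  expect_lt(abs(cor(res2[, 1], motion[, 1]^2)), 1e-6)

  # a series orthogonal to the design passes through unchanged
  y0 <- rnorm(n)
  yorth <- qr.resid(qr(X), y0)
  res3 <- nuisance_regress(matrix(yorth), motion, csf, wm)
  expect_equal(res3[, 1], yorth, tolerance = 1e-10)

  # collinear design columns are dropped with a warning
  expect_warning(nuisance_regress(matrix(rnorm(n)), motion, csf, csf),
                 "collinear")
})

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  T_ <- 512
  tt <- seq_len(T_) * 2
  core <- 100:412   # away from filtfilt edge transients

  inband <- sin(2 * pi * 0.05 * tt)
  y <- bandpass(matrix(inband), tr_seconds = 2)
  expect_lt(abs(sqrt(mean(y[core]^2) / mean(inband[core]^2)) - 1), 0.05)

  outband <- sin(2 * pi * 0.24 * tt)
  y2 <- bandpass(matrix(outband), tr_seconds = 2)
  expect_lt(sqrt(mean(y2[core]^2) / mean(outband[core]^2)), 0.1)

  mixed <- sin(2 * pi * 0.005 * tt) + sin(2 * pi * 0.05 * tt)
  y3 <- bandpass(matrix(mixed), tr_seconds = 2)
  amp <- function(x, f) {
    X <- cbind(sin(2 * pi * f * tt[core]), cos(2 * pi * f * tt[core]))
    sqrt(sum(lm.fit(X, x)$coefficients^2))
  }
  expect_gt(amp(y3[core], 0.05), 10 * amp(y3[core], 0.005))

  expect_error(bandpass(matrix(inband), low_hz = 0.01, high_hz = 0.3,
                        tr_seconds = 2), "Nyquist")
})
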