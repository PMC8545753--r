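test_that("force_trace validates time, finiteness and protocol order", {
  expect_error(force_trace(c(1, 1, 2), c(0, 0, 0),
                           c("approach", "approach", "retract")),
               "strictly increasing")
  expect_error(force_trace(1:3, c(0, NA, 0),
                           c("approach", "pause", "retract")), "finite")
  expect_error(force_trace(1:3, c(0, 0, 0),
                           c("retract", "approach", "retract")),
               "protocol order")
  expect_error(force_trace(1:2, c(0, 0), c("approach", "flight")),
               "unknown stage")
})

test_that("resampling preserves constant traces and stage boundaries", {
  n <- 700
  tr <- force_trace(seq_len(2 * n) / 984, rep(c(5, -3), each = n),
                    rep(c("approach", "retract"), each = n))
  out <- resample_per_step(tr, 100)
  expect_equal(nrow(out), 200)
  expect_equal(out$force[out$stage == "approach"], rep(5, 100))
  expect_equal(out$force[out$stage == "retract"], rep(-3, 100))
  expect_identical(rle(out$stage)$values, c("approach", "retract"))
  # a short stage keeps native sampling, with a warning
  short <- force_trace(seq_len(50) / 984, rep(1, 50), rep("pause", 50))
  expect_warning(out2 <- resample_per_step(short, 512), "native sampling")
  expect_equal(nrow(out2), 50)
})

test_that("block averaging shrinks white noise by sqrt(M / points)", {
  M <- 4096L; pts <- 128L
  sds <- vapply(1:100, function(s) {
    set.seed(s)
    tr <- force_trace(seq_len(M) / 984, rnorm(M, 0, 2), rep("retract", M))
    sd(resample_per_step(tr, pts)$force)
  }, numeric(1))
  expect_lt(abs(mean(sds) / (2 / sqrt(M / pts)) - 1), 0.2)
})

test_that("background subtraction is exact for identical and zero backgrounds", {
  tb <- synth_trace(pulloff = -300, seed = 7)
  same <- background_subtract(tb$trace, tb$trace)
  expect_true(all(same$force == 0))
  zero <- force_trace(tb$trace$time, rep(0, nrow(tb$trace)), tb$trace$stage)
  ident <- background_subtract(tb$trace, zero)
  expect_equal(ident$force, tb$trace$force)
})

test_that("background subtraction rejects mismatched recordings", {
  tb <- synth_trace(seed = 1)
  other <- force_trace(tb$trace$time[1:10], rep(0, 10), rep("approach", 10))
  expect_error(background_subtract(tb$trace, other), "protocol mismatch")
  shifted <- force_trace(tb$background$time + 1e5, tb$background$force,
                         tb$background$stage)
  expect_error(background_subtract(tb$trace, shifted), "disjoint")
})

test_that("pull-off is the retraction minimum; non-negative retractions are flagged", {
  n <- 100
  f <- rep(0, n); f[60] <- -100
  tr <- force_trace(seq_len(n), f, rep("retract", n))
  po <- pulloff_force(tr)
  expect_equal(po$force, -100)
  expect_equal(po$magnitude, 100)
  expect_false(po$no_adhesion)
  bad <- force_trace(seq_len(n), abs(rnorm(n)) + 0.1, rep("retract", n))
  po2 <- pulloff_force(bad)
  expect_equal(po2$force, 0)
  expect_true(po2$no_adhesion)
  expect_error(pulloff_force(force_trace(1:5, rep(0, 5), rep("pause", 5))),
               "no retract")
})

test_that("replicate averaging reports mean and n", {
  expect_equal(replicate_mean(rep(-42, 5))$mean, -42)
  expect_equal(replicate_mean(-(1:5))$mean, -3)
  expect_equal(replicate_mean(-(1:5))$n, 5)
})

test_that("trace files round-trip through delimited text", {
  tb <- synth_trace(seed = 3)
  small <- resample_per_step(tb$trace, 32)
  path <- tempfile(fileext = ".csv")
  write_trace(small, path)
  back <- read_trace(path)
  expect_equal(back$force, small$force, tolerance = 1e-12)
  expect_identical(back$stage, small$stage)
})

test_that("synthetic traces are seed-deterministic with embedded ground truth", {
  a <- synth_trace(pulloff = -500, seed = 11)
  b <- synth_trace(pulloff = -500, seed = 11)
  expect_identical(a$trace$force, b$trace$force)
  expect_equal(attr(a$trace, "metadata")$true_pulloff, -500)
  c1 <- synth_trace(pulloff = -500, seed = 12)
  expect_false(identical(a$trace$force, c1$trace$force))
})

test_that("subtract-then-resample matches resample-then-subtract for smooth backgrounds", {
  tb <- synth_trace(pulloff = -600, noise_sd = 0, seed = 5)
  a <- resample_per_step(background_subtract(tb$trace, tb$background), 128)
  b <- background_subtract(resample_per_step(tb$trace, 128),
                           resample_per_step(tb$background, 128))
  expect_lt(max(abs(a$force - b$force)) /
              max(abs(attr(tb$trace, "metadata")$true_pulloff)), 0.01)
})
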