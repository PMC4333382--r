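test_that("fraction_unwound implements the band ratio with scale invariance", {
  expect_equal(fraction_unwound(30, 70), 0.30)
  expect_equal(fraction_unwound(0, 55), 0)
  set.seed(42)
  for (i in 1:50) {
    p <- runif(1, 0, 100); s <- runif(1, 0, 100) + 1e-6
    k <- runif(1, 1e-3, 1e3)
    f <- fraction_unwound(p, s)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(fraction_unwound(k * p, k * s), f)
  }
  expect_error(fraction_unwound(0, 0), "empty lane")
  expect_error(fraction_unwound(-1, 10), "negative")
})

test_that("build_progress_curve assembles ordered fractions and flags bad lanes", {
  lanes <- data.frame(
    sample_id = "s1",
    time_s = c(60, 60, 0, 0),
    band = c("duplex", "single_strand", "duplex", "single_strand"),
    intensity = c(50, 50, 100, 0))
  cv <- build_progress_curve(lanes, "unwinding", substrate_conc = 1)
  expect_s3_class(cv, "progress_curve")
  expect_equal(cv$times, c(0, 60))
  expect_equal(cv$fraction, c(0, 0.5))

  # annealing mode: the duplex band is the product
  ca <- build_progress_curve(lanes, "annealing")
  expect_equal(ca$fraction, c(1, 0.5))

  miss <- lanes[-1, ]
  expect_error(build_progress_curve(miss, "unwinding"), "incomplete lane")
  dup <- rbind(lanes, lanes[1, ])
  expect_error(build_progress_curve(dup, "unwinding"), "incomplete lane")
})

test_that("zero-noise generated lanes round-trip to the generating curve", {
  times <- seq(0, 600, by = 30)
  tab <- gen_progress_curves(0.002, substrate_conc = 2, times = times,
                             spec = generator_spec(7, noise_scale = 0))
  cv <- build_progress_curve(tab, "unwinding", substrate_conc = 2)
  expect_equal(cv$fraction, 1 - exp(-0.002 * times))
})

test_that("initial_velocity recovers an exact line and bounds exponential bias", {
  lanes <- data.frame(
    sample_id = "s", time_s = rep(c(0, 30, 60), each = 2),
    band = rep(c("duplex", "single_strand"), 3),
    intensity = c(100, 0, 95, 5, 90, 10))
  cv <- build_progress_curve(lanes, "unwinding", substrate_conc = 1)
  expect_equal(initial_velocity(cv), 0.10)

  # finely sampled exponential in the linear range: slope within 5% of the
  # analytic t -> 0 derivative k (per minute, times substrate)
  k <- 0.002
  t <- seq(0, 40, by = 2)
  cv2 <- structure(list(times = t, fraction = 1 - exp(-k * t),
                        substrate_conc = 1, mode = "unwinding"),
                   class = "progress_curve")
  v <- initial_velocity(cv2)
  expect_lt(abs(v - k * 60) / (k * 60), 0.05)

  cv3 <- cv2; cv3$fraction <- cv3$fraction + 0.5
  expect_error(initial_velocity(cv3), "insufficient linear range")
})

test_that("velocity unit converters invert each other", {
  expect_equal(velocity_to_per_s(41.4, 1), 0.69)
  expect_equal(per_s_to_velocity(velocity_to_per_s(12.3, 2), 2), 12.3)
})

test_that("fit_annealing recovers plateau and rate from noiseless curves", {
  t <- seq(0, 1200, by = 60)
  for (truth in list(c(0.5, 0.3), c(0.15, 0.3))) {
    f <- truth[1] * (1 - exp(-truth[2] * t / 60))
    cv <- structure(list(times = t, fraction = f, substrate_conc = 1,
                         mode = "annealing"), class = "progress_curve")
    fit <- fit_annealing(cv)
    expect_equal(fit$A_max, truth[1], tolerance = 1e-6)
    expect_equal(fit$k_ann, truth[2], tolerance = 1e-6)
    expect_equal(predict(fit, t), f, tolerance = 1e-6)
  }
  flat <- structure(list(times = t, fraction = rep(0, length(t)),
                         substrate_conc = 1, mode = "annealing"),
                    class = "progress_curve")
  expect_equal(fit_annealing(flat)$A_max, 0)
  expect_error(fit_annealing(structure(list(times = t, fraction = rep(0, length(t)),
                                            substrate_conc = 1, mode = "unwinding"),
                                       class = "progress_curve")),
               "annealing-mode")
})

test_that("annealing plateau recovery stays within 0.02 under 2% noise", {
  t <- seq(0, 1200, by = 60)
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    f <- 0.5 * (1 - exp(-0.3 * t / 60)) + rnorm(length(t), 0, 0.02)
    cv <- structure(list(times = t, fraction = pmin(pmax(f, 0), 1),
                         substrate_conc = 1, mode = "annealing"),
                    class = "progress_curve")
    abs(fit_annealing(cv)$A_max - 0.5)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("control-curve subtraction clamps the net curve into [0,1]", {
  t <- c(0, 60, 120)
  mk <- function(f) structure(list(times = t, fraction = f, substrate_conc = 1,
                                   mode = "unwinding"), class = "progress_curve")
  net <- subtract_control_curve(mk(c(0.1, 0.5, 0.9)), mk(c(0.2, 0.1, 0.1)))
  expect_equal(net$fraction, c(0, 0.4, 0.8))
})

test_that("define_duplex characterises the printed substrate geometry", {
  d <- define_duplex("GCGUCGAUCCGAAACUAUACUUAAUUUUAA", "GUUUCGGAUCGACGC")
  expect_equal(d$duplex_len, 15)
  expect_equal(d$overhang_len, 15)
  expect_equal(d$overhang_end, "3prime")
  expect_equal(d$gc_fraction, 9 / 15)

  d2 <- define_duplex("GCGC", "GCGC")
  expect_equal(d2$duplex_len, 4)
  expect_equal(d2$overhang_len, 0)

  expect_error(define_duplex("AAAA", "GGGG"), "no contiguous")
  expect_error(define_duplex("ACGT", "ACG"), "RNA")
})

test_that("define_duplex matches a string-construction oracle on random RNA", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (i in 1:25) {
    len <- sample(10:40, 1)
    x <- random_rna(len)
    n <- sample(4:len, 1)
    short <- as.character(
      Biostrings::reverseComplement(Biostrings::RNAString(substr(x, 1, n))))
    d <- define_duplex(x, short)
    expect_equal(d$duplex_len, n)
    expect_equal(d$overhang_len, len - n)
  }
})
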