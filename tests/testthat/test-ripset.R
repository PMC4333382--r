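test_that("fpkm implements the fragments-per-kilobase-per-million formula", {
  expect_equal(fpkm(0, 1000, 1e7), 0)
  expect_equal(fpkm(100, 1000, 1e7), 10)
  expect_equal(fpkm(100, 1000, 2e7), 5)      # doubling the library halves FPKM
  expect_error(fpkm(1, 0, 1e7), "invalid denominator")
  expect_error(fpkm(1, 1000, 0), "invalid denominator")
})

test_that("call_rip uses a strict threshold with 0.5 itself non-RIP", {
  lib <- rip_library("L1", "DMSO", "RHA", c(A = 0.6, B = 0.4, C = 0.5))
  expect_equal(call_rip(lib), "A")
  expect_setequal(call_rip(lib, 0), c("A", "B", "C"))
  empty <- rip_library("L0", "DMSO", "RHA", setNames(numeric(0), character(0)))
  expect_length(call_rip(empty), 0)
})

test_that("blocked-antibody subtraction is a set difference within the target calls", {
  target <- rip_library("t", "DMSO", "RHA", c(A = 1, B = 2))
  blocked <- rip_library("b", "DMSO", "RHA_block", c(B = 3))
  expect_equal(subtract_blocked(target, blocked), "A")
  none <- rip_library("b0", "DMSO", "RHA_block", c(B = 0.1))
  expect_setequal(subtract_blocked(target, none), c("A", "B"))
  super <- rip_library("b2", "DMSO", "RHA_block", c(A = 5, B = 5, C = 5))
  expect_length(subtract_blocked(target, super), 0)

  # calling is monotone in the threshold, and the subtracted set always
  # stays inside the target's own calls
  set.seed(2)
  vals <- setNames(runif(200, 0, 5), sprintf("g%03d", 1:200))
  bvals <- setNames(runif(200, 0, 2), sprintf("g%03d", 1:200))
  t1 <- rip_library("x", "DMSO", "FLI1", vals)
  b1 <- rip_library("y", "DMSO", "FLI1_block", bvals)
  prev <- call_rip(t1, 0.1)
  for (thr in c(0.5, 1, 2)) {
    expect_true(all(call_rip(t1, thr) %in% prev))
    expect_true(all(subtract_blocked(t1, b1, thr) %in% call_rip(t1, thr)))
    prev <- call_rip(t1, thr)
  }
})

test_that("hypergeometric tail matches brute-force enumeration and phyper", {
  expect_equal(hypergeom_overlap(10, 5, 4, 3)$p, 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_overlap(10, 5, 4, 0)$p, 1)

  # exhaustive equivalence on small universes against direct summation
  for (N in c(5, 9, 14, 20)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_overlap(N, K, n, k)$p,
                   hyper_tail_bruteforce(N, K, n, k),
                   tolerance = 1e-10)
    }
  }
  # random spot checks up to N = 200 against both oracles
  set.seed(3)
  for (i in 1:60) {
    N <- sample(21:200, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    res <- hypergeom_overlap(N, K, n, k)
    expect_equal(res$p, hyper_tail_bruteforce(N, K, n, k), tolerance = 1e-9)
    expect_equal(res$log10_p,
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                        log.p = TRUE) / log(10),
                 tolerance = 1e-6)
    # symmetry in the two set sizes
    expect_equal(hypergeom_overlap(N, n, K, k)$p, res$p, tolerance = 1e-9)
  }
  expect_error(hypergeom_overlap(10, 11, 4, 1), "invalid counts")
})

test_that("hypergeometric tail is monotone in k and finite at survey scale", {
  p <- vapply(0:50, function(k) hypergeom_overlap(100, 60, 50, k)$p, 1)
  expect_true(all(diff(p) < 1e-15))
  # reconstructed-scale input: log10_p reportable far below double underflow
  big <- hypergeom_overlap(96071, 7974, 5956, 1345)
  expect_true(is.finite(big$log10_p))
  expect_lt(big$log10_p, -200)
  expect_equal(big$log10_p,
               phyper(1344, 7974, 96071 - 7974, 5956, lower.tail = FALSE,
                      log.p = TRUE) / log(10),
               tolerance = 1e-9)
})

test_that("treatment partition reproduces the four-way counts and percents", {
  ids <- sprintf("tx%04d", 1:1345)
  ef <- c(ids[1:615], ids[616:921])           # retained + EF-only
  rha <- c(ids[1:615], ids[922:1164])         # retained + RHA-only
  part <- partition_treatment(ids, ef, rha)
  expect_equal(unname(part$counts), c(615, 306, 243, 181))
  expect_equal(part$percents, c(46, 23, 18, 13))
  expect_equal(part$total, 1345)
  expect_equal(sum(part$counts), part$total)

  all_kept <- partition_treatment(ids, ids, ids)
  expect_equal(all_kept$percents, c(100, 0, 0, 0))
  all_lost <- partition_treatment(ids, character(0), character(0))
  expect_equal(all_lost$percents, c(0, 0, 0, 100))
  expect_error(partition_treatment(character(0), ids, ids), "empty input")
})

test_that("partition percents always sum close to 100 over random sets", {
  set.seed(9)
  for (i in 1:30) {
    common <- sprintf("g%d", 1:sample(50:2000, 1))
    ef <- sample(common, sample(0:length(common), 1))
    rha <- sample(common, sample(0:length(common), 1))
    part <- partition_treatment(common, ef, rha)
    expect_equal(sum(part$counts), length(common))
    expect_lte(abs(sum(part$percents) - 100), 2)
  }
})

test_that("unique_fractions partitions the universe into four shares", {
  uni <- sprintf("u%04d", 1:1000)
  rha <- c(uni[1:69], uni[118:131])           # 69 unique + 14 shared
  ef <- c(uni[70:117], uni[118:131])          # 48 unique + 14 shared
  sh <- unique_fractions(rha, ef, uni)
  expect_equal(unname(sh), c(6.9, 4.8, 86.9, 1.4))
  expect_equal(sum(sh), 100)

  half <- unique_fractions(uni[1:500], uni[501:1000], uni)
  expect_equal(unname(half), c(50, 50, 0, 0))
  full <- unique_fractions(uni, uni, uni)
  expect_equal(unname(full), c(0, 0, 0, 100))
  expect_error(unique_fractions(c(uni, "zz"), ef, uni), "universe mismatch")
})

test_that("noise-free planted libraries are inverted exactly by the pipeline", {
  libs <- gen_rip_tables(n_transcripts = 5000, n_common = 300,
                         n_rha_only = 80, n_ef_only = 60,
                         spec = generator_spec(4, noise_scale = 0))
  truth <- attr(libs, "truth")
  res <- rip_pipeline(libs)
  expect_setequal(res$rha_set, c(truth$common, truth$rha_only))
  expect_setequal(res$ef_set, c(truth$common, truth$ef_only))
  expect_setequal(res$common, truth$common)
  expect_equal(unname(res$partition$counts),
               unname(truth$partition_counts))
})

test_that("planted overlap recall stays above 0.95 under negative-binomial noise", {
  libs <- gen_rip_tables(n_transcripts = 5000, n_common = 300,
                         n_rha_only = 80, n_ef_only = 60,
                         planted_fpkm = 5,
                         spec = generator_spec(5, "negative_binomial", 1))
  truth <- attr(libs, "truth")
  res <- rip_pipeline(libs)
  recall <- length(intersect(res$common, truth$common)) / length(truth$common)
  expect_gte(recall, 0.95)
})
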