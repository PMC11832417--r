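test_that("in-vivo simulation matches first-order closed forms", {
  sites <- synthetic_sites(5, classes = "ORF")
  # k = 0, f0 = 0: never methylated
  ms0 <- simulate_states(sites, "in_vivo", design = c(60, 240), n_cells = 50,
                         rate = 0, f0 = 0, half_time = 0, sigma_cell = 0,
                         seed = 1)
  expect_false(any(ms0$states))
  expect_equal(max(ms0$truth), 0)
  # instant induction, k = 0.01/min, t = 100: fraction 1 - e^-1
  ms <- simulate_states(sites, "in_vivo", design = 100, n_cells = 2000,
                        rate = 0.01, f0 = 0, half_time = 0, sigma_cell = 0,
                        seed = 2)
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(realized_fractions(ms)) - p), 3 * se)
  expect_equal(unique(as.vector(ms$truth)), p, tolerance = 1e-12)
})

test_that("methylation is monotone along the design axis within each cell", {
  sites <- synthetic_sites(4, classes = c("ORF", "NDR"))
  for (mode in c("in_vivo", "nuclei")) {
    ms <- simulate_states(sites, mode, design = c(1, 5, 20, 100),
                          n_cells = 100,
                          rate = c(ORF = 0.01, NDR = 0.013),
                          plateau = c(ORF = 0.3, NDR = 0.7),
                          f0 = 0.02, half_time = 40, seed = 3)
    for (i in 1:3)
      expect_true(all(ms$states[, , i + 1] | !ms$states[, , i]), label = mode)
    fr <- realized_fractions(ms)
    expect_true(all(apply(fr, 1, function(x) all(diff(x) >= 0))))
  }
})

test_that("nuclei mode saturates at the accessible fraction", {
  sites <- synthetic_sites(10, classes = "ORF")
  conc <- c(0, 0.77, 1.5, 2.9, 5.6)
  ms <- simulate_states(sites, "nuclei", design = conc, n_cells = 2000,
                        plateau = 0.7, c0 = 0.1, seed = 4)  # c0 << max conc
  top <- mean(realized_fractions(ms)[, length(conc)])
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(top - 0.7), 3 * se)
  # concentration 0 with f0 = 0: nothing methylated
  expect_equal(unique(realized_fractions(ms)[, 1]), 0)
})

test_that("unknown kinetics class and invalid inputs error", {
  sites <- synthetic_sites(2, classes = c("ORF", "CEN"))
  expect_error(simulate_states(sites, "in_vivo", 10, 5,
                               rate = c(ORF = 0.01), seed = 5),
               "CEN")
  expect_error(simulate_states(sites, "in_vivo", c(10, 10), 5, rate = 0.01,
                               seed = 5), "strictly increasing")
  expect_error(simulate_states(sites, "in_vivo", 10, 5, rate = 0.01),
               "seed")
})

test_that("DpnI blunt-cut and terminal-loss arithmetic is exact", {
  sx <- data.frame(chrom = "c", start = 100L, motif = "GATC", midpoint = 102L,
                   region_class = "ORF")
  msx <- simulate_states(sx, "in_vivo", design = 10, n_cells = 1, rate = 100,
                         half_time = 0, sigma_cell = 0, seed = 6)
  stopifnot(msx$states[1, 1, 1])
  # q = 0: cut between A and T -> [., 102) ends on the A, [102, .) starts on T
  f0 <- fragmentize(msx, c(c = 500), frag_params(1e9, 0, 0, 0), seed = 7)
  expect_identical(f0$start, c(0L, 102L))
  expect_identical(f0$end, c(102L, 500L))
  # q = 1: left fragment ends on the G, right starts on the C
  f1 <- fragmentize(msx, c(c = 500), frag_params(1e9, 0, 0, 1), seed = 7)
  expect_identical(f1$start, c(0L, 103L))
  expect_identical(f1$end, c(101L, 500L))
  # no methylation, no sonication: one full-length fragment
  ms0 <- simulate_states(sx, "in_vivo", design = 10, n_cells = 1, rate = 0,
                         half_time = 0, sigma_cell = 0, seed = 8)
  ff <- fragmentize(ms0, c(c = 500), frag_params(1e9, 0, 0, 0), seed = 9)
  expect_identical(ff[, c("start", "end")], data.frame(start = 0L, end = 500L))
})

test_that("fragments tile each molecule exactly when recovery and loss are off", {
  sites <- synthetic_sites(10, gap = 300, chrom = "c")
  len <- max(sites$start) + 1000
  ms <- simulate_states(sites, "in_vivo", design = 120, n_cells = 8,
                        rate = 0.02, half_time = 0, seed = 10)
  fr <- fragmentize(ms, stats::setNames(len, "c"), frag_params(350, 0, 0, 0),
                    seed = 11)
  for (ci in unique(fr$cell)) {
    f <- fr[fr$cell == ci, ]
    f <- f[order(f$start), ]
    expect_identical(f$start[1], 0L)
    expect_identical(f$end[nrow(f)], as.integer(len))
    expect_identical(f$start[-1], f$end[-nrow(f)])   # disjoint, no gaps
  }
})

test_that("simulation and fragmentation are seed-reproducible; extending cells preserves earlier cells", {
  sites <- synthetic_sites(6, classes = c("ORF", "NDR"))
  a <- simulate_states(sites, "in_vivo", c(30, 120), 40,
                       rate = c(ORF = 0.01, NDR = 0.013), seed = 12)
  b <- simulate_states(sites, "in_vivo", c(30, 120), 40,
                       rate = c(ORF = 0.01, NDR = 0.013), seed = 12)
  expect_identical(a$states, b$states)
  expect_identical(a$cells, b$cells)
  big <- simulate_states(sites, "in_vivo", c(30, 120), 60,
                         rate = c(ORF = 0.01, NDR = 0.013), seed = 12)
  expect_identical(big$states[1:40, , ], a$states)
  sz <- c(chrS = max(sites$start) + 1000)
  fa <- fragmentize(a, sz, frag_params(), seed = 13)
  fb <- fragmentize(b, sz, frag_params(), seed = 13)
  expect_identical(fa, fb)
})

test_that("ground-truth table counts methylated cells exactly", {
  sites <- synthetic_sites(3, classes = "ORF")
  ms <- simulate_states(sites, "in_vivo", design = c(10, 1e4), n_cells = 2000,
                        rate = 1e-4, half_time = 0, seed = 14)
  gt <- ground_truth_table(ms)
  fr <- realized_fractions(ms)
  expect_equal(gt$frac_10, fr[, 1])
  expect_equal(gt$frac_10000, fr[, 2])
  expect_equal(gt$frac_10,
               apply(ms$states[, , 1], 2, mean))
  # forced extremes
  all_on <- simulate_states(sites, "in_vivo", design = 1, n_cells = 10,
                            rate = 1e6, half_time = 0, seed = 15)
  expect_equal(unique(ground_truth_table(all_on)$frac_1), 1)
})

test_that("long-read call emission groups nearby CGs and demands CG sites", {
  g <- c(c = "AAAAACGTACGAAAAAA")
  cg <- scan_motif_sites(g, "CG")
  cg$region_class <- "ORF"
  ms <- simulate_states(cg, "in_vivo", design = 1000, n_cells = 2, rate = 1,
                        half_time = 0, sigma_cell = 0, seed = 16)
  calls <- emit_longread_calls(ms, g, group_gap = 5, seed = 17)
  expect_identical(unique(calls$num_motifs), 2L)   # 4 bp apart < gap 5
  expect_identical(nrow(calls), 2L)                # one row per read
  expect_true(all(calls$log_lik_ratio > 0))        # all methylated, error 0
  far <- emit_longread_calls(ms, g, group_gap = 4, seed = 17)
  expect_identical(unique(far$num_motifs), 1L)     # distance 4 not < 4
  gatc <- synthetic_sites(2, classes = "ORF")
  msg <- simulate_states(gatc, "in_vivo", 10, 1, rate = 1, seed = 18)
  expect_error(emit_longread_calls(msg, g, seed = 19), "CG sites")
})
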