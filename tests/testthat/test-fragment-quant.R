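test_that("BEDPE/BED fragment loading handles both layouts and filters", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t350", path)
  fr <- load_fragments(path)
  expect_identical(fr$start, 100L)
  expect_identical(fr$end, 350L)
  # 6-column BEDPE: mates merged; cross-chromosome pair skipped with count
  path2 <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t150\tchr1\t300\t351",
               "chr1\t0\t50\tchr2\t300\t350"), path2)
  fr2 <- load_fragments(path2)
  expect_identical(nrow(fr2), 1L)
  expect_identical(fr2$end - fr2$start, 251L)
  expect_identical(attr(fr2, "n_skipped_pairs"), 1L)
  # fragments beyond the aligner ceiling are dropped
  path3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t6000", "chr1\t0\t400"), path3)
  fr3 <- load_fragments(path3, max_len = 5000)
  expect_identical(nrow(fr3), 1L)
  expect_identical(attr(fr3, "n_dropped_long"), 1L)
  # optional duplicate removal
  path4 <- withr::local_tempfile(fileext = ".bed")
  writeLines(rep("chr1\t10\t60", 3), path4)
  expect_identical(nrow(load_fragments(path4)), 3L)
  expect_identical(nrow(load_fragments(path4, dedup = TRUE)), 1L)
})

test_that("BAM proper pairs become half-open fragments via POS and TLEN", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- paste(rep("A", 50), collapse = "")
  q50 <- paste(rep("I", 50), collapse = "")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:1000",
    paste("r1", 99, "chrT", 101, 60, "50M", "=", 302, 251, seq50, q50,
          sep = "\t"),
    paste("r1", 147, "chrT", 302, 60, "50M", "=", 101, -251, seq50, q50,
          sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  fr <- load_fragments(bam, format = "bam")
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$start, 100L)   # SAM POS 101 is 0-based 100
  expect_identical(fr$end, 351L)
  expect_identical(fr$end - fr$start, 251L)
})

test_that("coverage and end tracks are exact", {
  tr <- coverage_and_ends(data.frame(chrom = "c", start = 5L, end = 8L),
                          c(c = 12))
  expect_identical(tr$c$coverage, c(rep(0L, 5), 1L, 1L, 1L, rep(0L, 4)))
  expect_identical(which(tr$c$left_ends == 1L), 6L)   # 0-based 5
  expect_identical(which(tr$c$right_ends == 1L), 8L)  # 0-based 7
  two <- coverage_and_ends(data.frame(chrom = "c", start = c(0L, 5L),
                                      end = c(10L, 15L)), c(c = 20))
  expect_identical(two$c$coverage[8], 2L)              # 0-based base 7
  expect_identical(sum(two$c$left_ends), 2L)
  expect_identical(sum(two$c$right_ends), 2L)
  empty <- coverage_and_ends(data.frame(chrom = character(), start = integer(),
                                        end = integer()), c(c = 10))
  expect_true(all(empty$c$coverage == 0L))
  expect_error(coverage_and_ends(data.frame(chrom = "c", start = 5L, end = 15L),
                                 c(c = 10)), "out-of-bounds")
})

test_that("per-site fcut implements the A+G / T+C end correction", {
  # hand-checked example: two fragments end at the site (one on G, one on A),
  # two start at it (one on T, one on C)
  fr <- data.frame(chrom = "c", start = c(40L, 50L, 102L, 103L),
                   end = c(101L, 102L, 160L, 200L))
  tr <- coverage_and_ends(fr, c(c = 500))
  st <- site_fcut(data.frame(chrom = "c", start = 100L, midpoint = 102L), tr,
                  min_coverage = 1)
  expect_identical(st$n_right_G, 1L)
  expect_identical(st$n_right_A, 1L)
  expect_identical(st$n_left_T, 1L)
  expect_identical(st$n_left_C, 1L)
  expect_identical(st$cov_G, 2L)
  expect_identical(st$cov_C, 2L)
  expect_equal(st$fcut_right, 1)
  expect_equal(st$fcut_left, 1)
  expect_equal(st$fcut, 1)
  # covered but never cut: fcut 0
  fr2 <- data.frame(chrom = "c", start = rep(0L, 100), end = rep(400L, 100))
  st2 <- site_fcut(data.frame(chrom = "c", start = 100L, midpoint = 102L),
                   coverage_and_ends(fr2, c(c = 500)))
  expect_equal(st2$fcut_right, 0)
  expect_equal(st2$fcut, 0)
  expect_identical(st2$status, "ok")
  # no coverage at all: a status, not an error
  st3 <- site_fcut(data.frame(chrom = "c", start = 450L, midpoint = 452L),
                   coverage_and_ends(fr, c(c = 500)))
  expect_identical(st3$status, "no_coverage")
  expect_true(is.na(st3$fcut))
})

test_that("fcut equals the brute-force per-fragment oracle on random instances", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(100:1000, 1)
    fr <- data.frame(chrom = "chrT", start = sample(0:9500, n, replace = TRUE))
    fr$end <- pmin(fr$start + sample(20:600, n, replace = TRUE), 10000L)
    sites <- data.frame(chrom = "chrT",
                        start = sort(sample(0:9990, 40)))
    sites$midpoint <- sites$start + 2L
    got <- site_fcut(sites, coverage_and_ends(fr, c(chrT = 10000)),
                     min_coverage = 1)
    orc <- oracle_site_fcut(sites, fr)
    expect_equal(got$fcut_right, unname(orc[, "fcut_right"]))
    expect_equal(got$fcut_left, unname(orc[, "fcut_left"]))
    ok <- !is.na(got$fcut_right)
    expect_true(all(got$fcut_right[ok] >= 0 & got$fcut_right[ok] <= 1))
  }
})

test_that("neighbor policy excludes, substitutes, or averages", {
  base <- data.frame(chrom = "c", start = c(1000L, 2000L, 3000L),
                     midpoint = c(1002L, 2002L, 3002L),
                     left_gap = c(150, 150, 500),
                     right_gap = c(150, 500, 500),
                     n_right_A = 0L, n_right_G = 0L, n_left_T = 0L,
                     n_left_C = 0L, cov_G = 100L, cov_C = 100L,
                     fcut_right = c(0.5, 0.6, 0.6),
                     fcut_left = c(0.5, 0.2, 0.4),
                     fcut = c(0.5, 0.4, 0.5),
                     status = "ok", stringsAsFactors = FALSE)
  attr(base, "min_coverage") <- 8
  out <- apply_neighbor_policy(base)
  expect_identical(out$status, c("excluded", "substituted_left", "ok"))
  expect_true(is.na(out$fcut[1]))
  expect_equal(out$fcut[2], 0.6)       # close left side takes the right value
  expect_equal(out$fcut_left[2], 0.6)
  expect_equal(out$fcut[3], 0.5)       # mean of (0.4, 0.6)
  # substitution impossible when the far side is unusable -> excluded
  low <- base[2, ]
  low$cov_G <- 3L
  attr(low, "min_coverage") <- 8
  expect_identical(apply_neighbor_policy(low)$status, "excluded")
  expect_error(apply_neighbor_policy(base[, setdiff(names(base), "left_gap")]),
               "left_gap")
})

test_that("fcut tables join per-sample columns and filter excluded sites", {
  s1 <- data.frame(chrom = "c", start = c(100L, 200L), fcut = c(0.2, NA),
                   status = c("ok", "excluded"))
  s2 <- data.frame(chrom = "c", start = c(100L, 200L), fcut = c(0.3, NA),
                   status = c("ok", "excluded"))
  tb <- fcut_table(list(t0 = s1, t30 = s2))
  expect_identical(dim(tb), c(2L, 6L))
  expect_identical(names(tb),
                   c("chrom", "start", "fcut_t0", "status_t0",
                     "fcut_t30", "status_t30"))
  dropped <- fcut_table(list(t0 = s1, t30 = s2), drop_excluded = TRUE)
  expect_identical(nrow(dropped), 1L)
  expect_error(fcut_table(list(s1, s2)), "names")
  expect_error(fcut_table(list(a = s1, a = s2)), "names")
  # lossless TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$fcut_t0, tb$fcut_t0)
})
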