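test_that("motif scan finds forward-strand occurrences exactly once, sorted", {
  expect_identical(nrow(scan_motif_sites(c(chr = "AAAAAA"), "GATC")), 0L)
  s <- scan_motif_sites(c(chr = "GGATCGATC"), "GATC")
  expect_identical(s$start, c(1L, 5L))
  expect_identical(s$midpoint, c(3L, 7L))
  # two chromosomes, output sorted by (chrom, start)
  s2 <- scan_motif_sites(c(b = "GATCAA", a = "TTGATC"), "GATC")
  expect_identical(s2$chrom, c("a", "b"))
  expect_identical(s2$start, c(2L, 0L))
})

test_that("motif scan matches a naive sliding-window oracle on random sequences", {
  set.seed(71)
  naive_scan <- function(seq, motif) {
    m <- nchar(motif)
    n <- nchar(seq)
    hits <- vapply(seq_len(n - m + 1),
                   function(i) substr(seq, i, i + m - 1) == motif, logical(1))
    which(hits) - 1L
  }
  for (rep in 1:20) {
    g <- random_chrom(3000)
    for (motif in c("GATC", "CG")) {
      got <- scan_motif_sites(c(chr = g), motif)$start
      expect_identical(got, naive_scan(g, motif), label = paste(motif, rep))
    }
  }
  # overlapping occurrences of a longer palindrome are all reported
  expect_identical(scan_motif_sites(c(c = "ATATATAT"), "ATAT")$start,
                   c(0L, 2L, 4L))
})

test_that("motif validation: non-ACGT and non-palindromic motifs rejected, N never matches", {
  expect_error(scan_motif_sites(c(c = "ACGT"), "GANC"), "invalid motif")
  expect_error(scan_motif_sites(c(c = "ACGT"), "gatc"), "invalid motif")
  expect_error(scan_motif_sites(c(c = "ACGT"), ""), "invalid motif")
  expect_error(scan_motif_sites(c(c = "ACGTACGT"), "GAT"), "non-palindromic")
  s <- scan_motif_sites(c(c = "GATCNGANCNNNNGATC"), "GATC")
  expect_identical(s$start, c(0L, 13L))
})

test_that("neighbor gaps use cut midpoints and chromosome ends", {
  lone <- data.frame(chrom = "c", start = 5000L, motif = "GATC", midpoint = 5002L)
  g <- neighbor_gaps(lone, c(c = 10000))
  expect_equal(g$left_gap, 5002)
  expect_equal(g$right_gap, 4998)
  two <- data.frame(chrom = "c", start = c(100L, 250L), motif = "GATC",
                    midpoint = c(102L, 252L))
  g2 <- neighbor_gaps(two, c(c = 10000))
  expect_equal(g2$right_gap[1], 150)   # facing sides share the gap
  expect_equal(g2$left_gap[2], 150)
  bad <- two[2:1, ]
  expect_error(neighbor_gaps(bad, c(c = 10000)), "sorted")
  expect_error(neighbor_gaps(two, c(x = 10000)), "chrom_sizes")
})

test_that("region classification: precedence, 'other' fallback, unknown labels", {
  sites <- data.frame(chrom = "c", start = 98L, motif = "GATC", midpoint = 100L)
  expect_identical(
    classify_sites(sites, data.frame(chrom = character(), start = integer(),
                                     end = integer(), class = character()))$region_class,
    "other")
  reg <- data.frame(chrom = "c", start = c(0L, 50L), end = c(500L, 150L),
                    class = c("ORF", "TEL"))
  expect_identical(classify_sites(sites, reg)$region_class, "TEL")
  # midpoint containment is half-open: interval [0,100) misses midpoint 100
  edge <- data.frame(chrom = "c", start = 0L, end = 100L, class = "ORF")
  expect_identical(classify_sites(sites, edge)$region_class, "other")
  expect_error(classify_sites(sites, data.frame(chrom = "c", start = 0L,
                                                end = 10L, class = "promoter")),
               "unknown region class")
})

test_that("classification is idempotent and invariant to region record order", {
  set.seed(72)
  sites <- data.frame(chrom = "c", start = seq(0L, 9900L, by = 100L),
                      motif = "GATC")
  sites$midpoint <- sites$start + 2L
  reg <- data.frame(
    chrom = "c",
    start = sample(0:9000, 30),
    class = sample(REGION_CLASSES, 30, replace = TRUE))
  reg$end <- reg$start + sample(100:800, 30, replace = TRUE)
  a <- classify_sites(sites, reg)
  b <- classify_sites(a, reg)                      # idempotent
  expect_identical(a$region_class, b$region_class)
  d <- classify_sites(sites, reg[sample(nrow(reg)), ])  # permutation-invariant
  expect_identical(a$region_class, d$region_class)
  expect_identical(sum(table(a$region_class)), nrow(sites))
})

test_that("decile assignment balances block sizes and breaks ties by gene id", {
  g10 <- data.frame(gene_id = sprintf("g%02d", 1:10), polII_signal = 10:1)
  d10 <- assign_deciles(g10)
  expect_identical(d10$decile, 1:10)
  g23 <- data.frame(gene_id = sprintf("g%02d", 1:23),
                    polII_signal = rev(seq_len(23)))
  d23 <- assign_deciles(g23)
  expect_identical(as.integer(table(d23$decile)),
                   c(3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  # monotone: decile never decreases as signal decreases
  o <- order(-d23$polII_signal)
  expect_true(all(diff(d23$decile[o]) >= 0))
  tie <- data.frame(gene_id = sprintf("g%02d", 20:1), polII_signal = 1)
  dt <- assign_deciles(tie)
  expect_identical(dt$decile[order(dt$gene_id)], rep(1:10, each = 2))
  expect_error(assign_deciles(g10[1:9, ]), "at least 10")
  g10$polII_signal[1] <- NA
  expect_error(assign_deciles(g10), "polII_signal")
})

test_that("site-gene mapping is strand-corrected and multi-assigns near genes", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "c",
                      strand = c("+", "-"), plus_one_dyad = c(1000L, 1000L))
  site <- data.frame(chrom = "c", start = 1048L, motif = "GATC", midpoint = 1050L)
  m <- map_sites_to_genes(site, genes)
  expect_equal(m$dyad_offset[m$gene_id == "gp"], 50)
  expect_equal(m$dyad_offset[m$gene_id == "gm"], -50)
  # two genes 600 bp apart, one site between them, assigned to both
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "c", strand = "+",
                   plus_one_dyad = c(1000L, 1600L))
  s2 <- data.frame(chrom = "c", start = 1298L, motif = "GATC", midpoint = 1300L)
  m2 <- map_sites_to_genes(s2, g2)
  expect_identical(sort(m2$gene_id), c("a", "b"))
  expect_equal(sort(m2$dyad_offset), c(-300, 300))
  # outside every window: kept once, unassigned
  far <- data.frame(chrom = "c", start = 50000L, motif = "GATC", midpoint = 50002L)
  mf <- map_sites_to_genes(far, genes)
  expect_identical(nrow(mf), 1L)
  expect_true(is.na(mf$gene_id))
  genes$plus_one_dyad[2] <- NA
  expect_warning(map_sites_to_genes(site, genes), "skipped")
})

test_that("site table round-trips through TSV", {
  sites <- scan_motif_sites(c(chr = "GGATCGATCAAGATC"), "GATC")
  sites <- neighbor_gaps(sites, c(chr = 15))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites_table(sites, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$start, sites$start)
  expect_equal(back$left_gap, sites$left_gap)
})
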