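test_that("gc_fraction counts G+C over unambiguous bases only", {
  expect_equal(gc_fraction("GCGC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("GGGAACCCCT"), 0.7)
  # ambiguity codes (even S = G-or-C) leave both numerator and denominator
  expect_equal(gc_fraction("GCNN"), 1.0)
  expect_equal(gc_fraction("GCSWAT"), 0.5)
  expect_error(gc_fraction("NNNN"), "unambiguous")
})

test_that("find_gc_stretches returns maximal runs >= k", {
  expect_equal(find_gc_stretches("GCGTTT")$start, 0L)
  expect_equal(find_gc_stretches("GCGTTT")$end, 3L)
  expect_equal(nrow(find_gc_stretches("GGTTCC")), 0)
  st <- find_gc_stretches("GGGAACCCC")
  expect_equal(st$start, c(0L, 5L))
  expect_equal(st$end, c(3L, 9L))
  expect_equal(nrow(find_gc_stretches("")), 0)
  # N breaks a run
  expect_equal(find_gc_stretches("GGGNGGG")$length, c(3L, 3L))
})

test_that("stretch finder agrees with the quadratic brute-force oracle", {
  set.seed(21)
  for (i in 1:200) {
    s <- random_dna(sample(1:120, 1), gc = runif(1, 0.2, 0.8))
    k <- sample(1:5, 1)
    expect_equal(find_gc_stretches(s, k), brute_force_stretches(s, k),
                 info = paste("seq", s, "k", k))
  }
})

test_that("stretch statistics are monotone in k and bounded under concatenation", {
  set.seed(22)
  for (i in 1:100) {
    s <- random_dna(sample(10:150, 1), gc = runif(1, 0.3, 0.8))
    t <- random_dna(sample(10:150, 1), gc = runif(1, 0.3, 0.8))
    n_k <- vapply(1:6, function(k) nrow(find_gc_stretches(s, k)), integer(1))
    tot_k <- vapply(1:6, function(k) sum(find_gc_stretches(s, k)$length),
                    integer(1))
    expect_true(all(diff(n_k) <= 0))
    expect_true(all(diff(tot_k) <= 0))
    n_s <- nrow(find_gc_stretches(s))
    n_t <- nrow(find_gc_stretches(t))
    n_st <- nrow(find_gc_stretches(paste0(s, t)))
    expect_true(n_st >= n_s + n_t - 1 && n_st <= n_s + n_t + 1)
  }
})

test_that("composition metrics match hand-computed values", {
  metrics <- composition_metrics(as_records(c("GGGAACCCC", "GGGGGG",
                                              "ATATATAT")))
  expect_equal(metrics$gc_fraction, c(7 / 9, 1, 0))
  expect_equal(metrics$n_stretches, c(2L, 1L, 0L))
  expect_equal(metrics$mean_stretch_len, c(3.5, 6, NA))
  expect_equal(metrics$max_stretch_len, c(4L, 6L, 0L))
  expect_equal(metrics$total_stretch_nt, c(7L, 6L, 0L))
  # invariant: total stretch nt never exceeds the G+C base count
  expect_true(all(metrics$total_stretch_nt <=
                    round(metrics$gc_fraction * metrics$length_nt)))
})

test_that("composition statistics are reverse-complement invariant", {
  set.seed(23)
  for (i in 1:300) {
    s <- random_dna(sample(20:200, 1), gc = runif(1, 0.2, 0.8))
    rc <- reverse_complement(s)
    m1 <- composition_metrics(as_records(s))
    m2 <- composition_metrics(as_records(rc))
    expect_equal(m1$gc_fraction, m2$gc_fraction)
    expect_equal(m1$n_stretches, m2$n_stretches)
    expect_equal(m1$mean_stretch_len, m2$mean_stretch_len)
    expect_equal(m1$max_stretch_len, m2$max_stretch_len)
    expect_equal(m1$total_stretch_nt, m2$total_stretch_nt)
  }
})

test_that("quadruplex scan finds canonical motifs on both strands", {
  plus <- scan_quadruplex("GGGTGGGTGGGTGGG")
  expect_equal(nrow(plus), 1)
  expect_equal(c(plus$start, plus$end), c(0L, 15L))
  expect_equal(plus$strand, "+")
  expect_equal(plus$n_tracts, 4L)

  minus <- scan_quadruplex("CCCACCCACCCACCC")
  expect_equal(minus$start, 0L)
  expect_equal(minus$end, 15L)
  expect_equal(minus$strand, "-")
  expect_equal(nrow(scan_quadruplex("ATATATAT")), 0)
  # loop longer than max_loop breaks the motif
  expect_equal(nrow(scan_quadruplex("GGGTTTTTTTTGGGTGGGTGGG")), 0)
  expect_equal(nrow(scan_quadruplex("GGGTTTTTTTTGGGTGGGTGGGTGGG")), 1)
})

test_that("quadruplex hits mirror under reverse complement", {
  set.seed(24)
  for (i in 1:100) {
    s <- random_dna(sample(40:150, 1), gc = runif(1, 0.5, 0.9))
    h <- scan_quadruplex(s)
    h_rc <- scan_quadruplex(reverse_complement(s))
    expect_equal(sum(h$strand == "+"), sum(h_rc$strand == "-"))
    expect_equal(sum(h$strand == "-"), sum(h_rc$strand == "+"))
  }
})

test_that("quadruplex set scan writes 6-column BED with 0-based coords", {
  records <- as_records(c("AAGGGTGGGTGGGTGGGAA", "ATATAT"), c("q1", "q2"))
  bed <- tempfile(fileext = ".bed")
  hits <- scan_quadruplex_set(records, path = bed)
  expect_equal(hits$id, "q1")
  lines <- readLines(bed)
  expect_equal(length(lines), 1)
  fields <- strsplit(lines, "\t")[[1]]
  expect_equal(length(fields), 6)
  expect_equal(fields[1:3], c("q1", "2", "17"))
  expect_equal(fields[6], "+")
})
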