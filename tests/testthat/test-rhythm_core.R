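test_that("inter-onset intervals honour the cap and record breaks", {
  io <- compute_iois(c(0, 2, 4))
  expect_equal(io$values, c(2, 2))
  expect_equal(io$segment, c(1L, 1L))

  io <- compute_iois(c(0, 2, 9, 11))
  expect_equal(io$values, c(2, 2))
  expect_equal(io$segment, c(1L, 2L))       # the 7 s gap splits segments
  expect_equal(io$break_after, c(1L, 2L))   # break after t1, and at the end

  expect_equal(length(compute_iois(c(3.2))$values), 0L)
  expect_error(compute_iois(c(0, 1, 1)), "strictly increasing")

  # boundary: an interval of exactly `cap` seconds is retained
  expect_equal(compute_iois(c(0, 5))$values, 5)
})

test_that("drop_adjacent also discards the intervals flanking a long gap", {
  onsets <- c(0, 2, 4, 11, 13, 15)
  expect_equal(compute_iois(onsets)$values, c(2, 2, 2, 2))
  strict <- compute_iois(onsets, drop_adjacent = TRUE)
  expect_equal(strict$values, c(2, 2))
  expect_equal(strict$segment, c(1L, 2L))   # survivors cannot pair up
  expect_length(compute_ratios(strict), 0L)
})

test_that("rhythmic ratios follow r = t_k / (t_k + t_k+1), never crossing breaks", {
  expect_equal(compute_ratios(c(2, 2)), 0.5)
  expect_equal(compute_ratios(c(1, 2)), 1 / 3)
  expect_equal(compute_ratios(c(2, 1)), 2 / 3)

  # brute-force oracle over the retained pairs of a broken sequence
  io <- compute_iois(c(0, 2, 4, 12, 15, 18))  # 8 s gap discarded
  expect_equal(io$values, c(2, 2, 3, 3))
  expect_equal(compute_ratios(io), c(0.5, 0.5))

  expect_length(compute_ratios(numeric(0)), 0L)
  expect_length(compute_ratios(5), 0L)
})

test_that("triples normalize three consecutive intervals within a segment", {
  expect_equal(compute_triples(c(2, 2, 2)),
               data.frame(t1 = 1 / 3, t2 = 1 / 3, t3 = 1 / 3))
  expect_equal(compute_triples(c(2, 2, 4)),
               data.frame(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  expect_equal(compute_triples(c(4, 2, 2)),
               data.frame(t1 = 0.5, t2 = 0.25, t3 = 0.25))
  # a break in the middle suppresses all windows that span it
  io <- compute_iois(c(0, 2, 4, 12, 14, 16))
  expect_equal(nrow(compute_triples(io)), 0L)
  io <- compute_iois(c(0, 2, 4, 6, 16, 18, 20, 22))
  expect_equal(nrow(compute_triples(io)), 2L)
})

test_that("the default bin scheme is the exact-fraction partition", {
  s <- default_bin_scheme()
  expect_equal(nrow(s), 9L)
  # on ranges
  expect_equal(s$lo[s$bin == "on_R12"], 1 / 3.25)
  expect_equal(s$hi[s$bin == "on_R12"], 1 / 2.75)
  expect_equal(s$lo[s$bin == "on_R11"], 1 / 2.25)
  expect_equal(s$hi[s$bin == "on_R11"], 1 - 1 / 2.25)
  expect_equal(s$lo[s$bin == "on_R21"], 1 - 1 / 2.75)
  expect_equal(s$hi[s$bin == "on_R21"], 1 - 1 / 3.25)
  # contiguous tiling of [1/3.5, 1 - 1/3.5]
  expect_equal(s$hi[-9], s$lo[-1])
  expect_equal(attr(s, "span"), c(1 / 3.5, 1 - 1 / 3.5))
  # category references
  expect_equal(unname(attr(s, "centers")), c(1 / 3, 1 / 2, 2 / 3))
  # off width is the sum of the two flanking sub-ranges
  w <- bin_widths(s)
  expect_equal(w[["off_R11"]],
               (1 / 2.25 - 1 / 2.5) + ((1 - 1 / 2.5) - (1 - 1 / 2.25)))
  expect_true(all(w > 0))
})

test_that("ratio classification matches the spot examples", {
  expect_equal(classify_ratio(0.5), "on_R11")
  expect_equal(classify_ratio(0.30), "off_R12")  # left off sub-range
  expect_true(is.na(classify_ratio(0.25)))       # below the covered span
  expect_equal(classify_ratio(1 / 3.5), "off_R12")      # lower edge in
  expect_equal(classify_ratio(1 - 1 / 3.5), "off_R21")  # global max closed
  expect_error(classify_ratio(1.2), "strictly in")
  expect_error(classify_ratio(0), "strictly in")
})

test_that("classification of 1e5 random ratios matches the brute-force oracle", {
  set.seed(202)
  r <- runif(1e5, 1e-6, 1 - 1e-6)
  # include the exact boundaries themselves
  s <- default_bin_scheme()
  r <- c(r, s$lo, s$hi)
  expect_identical(classify_ratio(r), brute_force_classify(r))
})

test_that("bin counting is exhaustive and matches per-ratio classification", {
  cb <- count_bins(c(0.5, 0.5, 0.33))
  expect_equal(unname(cb$counts[c("on_R11", "on_R12")]), c(2L, 1L))
  expect_equal(sum(cb$counts), 3L)
  expect_equal(cb$n_unclassified, 0L)

  cb0 <- count_bins(numeric(0))
  expect_true(all(cb0$counts == 0L))

  set.seed(99)
  r <- runif(1000)
  cb <- count_bins(r)
  oracle <- table(factor(brute_force_classify(r), levels = bin_labels()))
  expect_equal(unname(cb$counts[bin_labels()]),
               as.integer(oracle[bin_labels()]))
  expect_equal(sum(cb$counts) + cb$n_unclassified, 1000L)
})

test_that("ratios and triples are invariant to rescaling time", {
  set.seed(11)
  for (rep in 1:20) {
    onsets <- cumsum(c(0, runif(15, 0.5, 4.5)))
    r0 <- compute_ratios(compute_iois(onsets, cap = Inf))
    t0 <- compute_triples(compute_iois(onsets, cap = Inf))
    # powers of two rescale exactly
    r2 <- compute_ratios(compute_iois(onsets * 4, cap = Inf))
    expect_identical(r0, r2)
    c_any <- runif(1, 0.2, 3)
    r1 <- compute_ratios(compute_iois(onsets * c_any, cap = Inf))
    t1 <- compute_triples(compute_iois(onsets * c_any, cap = Inf))
    expect_equal(r0, r1, tolerance = 1e-12)
    expect_equal(t0, t1, tolerance = 1e-12)
  }
})

test_that("time reversal maps the ratio sequence to reversed 1 - r", {
  set.seed(12)
  for (rep in 1:20) {
    iois <- runif(12, 0.3, 4.9)
    r_fwd <- compute_ratios(iois)
    r_rev <- compute_ratios(rev(iois))
    expect_equal(r_rev, rev(1 - r_fwd), tolerance = 1e-12)
  }
})

test_that("isochronous sequences give r = 0.5 and centred triples exactly", {
  for (tempo in c(0.7, 2, 3.3)) {
    # exactly equal intervals give exact results
    iois <- rep(tempo, 29)
    expect_true(all(compute_ratios(iois) == 0.5))
    tr <- compute_triples(iois)
    expect_true(all(tr$t1 == tr$t2 & tr$t2 == tr$t3))
    expect_true(all(abs(tr$t1 + tr$t2 + tr$t3 - 1) < 1e-12))
    # onsets built by accumulation carry rounding; still 0.5 to 1e-12
    io <- compute_iois(cumsum(c(0, iois)))
    expect_equal(compute_ratios(io), rep(0.5, 28), tolerance = 1e-12)
  }
})
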