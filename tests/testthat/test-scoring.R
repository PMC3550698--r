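test_that("17-segment mask is an exact partition for all supported geometries", {
  for (nr in c(4L, 9L, 18L, 36L, 45L)) {
    for (ns in c(12L, 24L, 36L, 60L, 120L)) {
      m <- build_segment_mask(nr, ns)
      expect_equal(dim(m), c(nr, ns))
      expect_true(all(m %in% 1:17))
      expect_equal(sort(unique(as.vector(m))), 1:17) # all segments non-empty
      expect_equal(length(m), nr * ns) # every bin assigned exactly once
    }
  }
  expect_error(build_segment_mask(36, 50), "divisible")
  expect_error(build_segment_mask(2, 60), "at least 4")
})

test_that("mask layout follows the standard polar display", {
  m <- build_segment_mask(36, 60)
  expect_equal(m[1, 1], 17L)               # centre bin is the apex
  expect_equal(m[36, 1], 1L)               # outermost ring, anterior sector
  expect_equal(m[36, 11], 2L)              # 60 deg ccw: basal anteroseptal
  expect_equal(m[36, 31], 4L)              # opposite anterior: basal inferior
  expect_equal(m[20, 1], 7L)               # mid anterior
  expect_equal(m[10, 1], 13L)              # apical anterior
  expect_equal(m[10, 31], 15L)             # apical inferior
})

test_that("segment means average the bins of each segment", {
  mask <- build_segment_mask(18, 24)
  pm <- structure(list(uptake = matrix(100, 18, 24), n_rings = 18,
                       n_sectors = 24, normalized = TRUE,
                       normalization_max = 1000), class = "polar_map")
  expect_equal(unname(segment_mean_uptake(pm, mask)), rep(100, 17))

  pm2 <- pm
  pm2$uptake[mask == 4] <- 20
  m <- segment_mean_uptake(pm2, mask)
  expect_equal(unname(m[4]), 20)
  expect_equal(unname(m[-4]), rep(100, 16))

  pm3 <- pm
  bins <- which(mask == 9)
  expect_true(length(bins) %% 2 == 0)
  pm3$uptake[bins[seq(1, length(bins), by = 2)]] <- 0 # checkerboard 0/100
  expect_equal(unname(segment_mean_uptake(pm3, mask)[9]), 50)

  bad <- build_segment_mask(9, 24)
  expect_error(segment_mean_uptake(pm, bad), "dimensions differ")
})

test_that("segment scoring applies the threshold bands with downward ties", {
  th <- threshold_table()
  db <- uniform_normal_db()
  expect_equal(score_segment(85, "TL_STRESS", th, db, 1), 0)
  expect_equal(score_segment(5, "TL_STRESS", th, db, 1), 4)
  expect_equal(score_segment(70, "TL_STRESS", th, db, 1), 0) # tie -> milder
  expect_equal(score_segment(69.9, "TL_STRESS", th, db, 1), 1)
  expect_equal(score_segment(50, "TL_STRESS", th, db, 1), 1)
  expect_equal(score_segment(10, "TL_STRESS", th, db, 1), 3)
  expect_error(score_segment(101, "TL_STRESS", th, db, 1), "\\[0, 100\\]")
  expect_error(score_segment(50, "TL_STRESS", th, db, 18), "unknown segment")
})

test_that("scoring is relative to the normal-database segment mean", {
  th <- threshold_table()
  db <- normal_db(data.frame(tracer = "BMIPP", segment = 1:17,
                             mean = c(80, rep(100, 16)), sd = 5))
  # 60% absolute uptake is 75% of a normal mean of 80 -> score 0
  expect_equal(score_segment(60, "BMIPP", th, db, 1), 0)
  expect_equal(score_segment(60, "BMIPP", th, db, 2), 1)
  # relative uptake is capped at 100
  expect_equal(score_segment(100, "BMIPP", th, db, 1), 0)
  expect_error(score_segment(50, "TL_REST", th, db, 1), "no entry")
})

test_that("score monotonicity and locality hold over random inputs", {
  th <- threshold_table()
  db <- uniform_normal_db()
  set.seed(42)
  for (i in 1:200) {
    u <- runif(1, 0, 100)
    drop <- runif(1, 0, u)
    s1 <- score_segment(u, "TL_STRESS", th, db, 3)
    s2 <- score_segment(u - drop, "TL_STRESS", th, db, 3)
    expect_gte(s2, s1) # lower uptake never scores milder
    # locality: same uptake, any other segment, same uniform db -> same score
    expect_equal(score_segment(u, "TL_STRESS", th, db, 11), s1)
  }
})

test_that("summed scores are plain sums with validated inputs", {
  expect_equal(summed_score(rep(0L, 17)), 0)
  expect_equal(summed_score(rep(4L, 17)), 68)
  set.seed(7)
  for (i in 1:25) {
    v <- sample(0:4, 17, replace = TRUE)
    tot <- 0; for (x in v) tot <- tot + x # independent summation
    expect_equal(summed_score(v), tot)
    expect_gte(summed_score(v), 0)
    expect_lte(summed_score(v), 68)
  }
  expect_error(summed_score(c(rep(0L, 16), 5L)), "0-4")
  expect_error(summed_score(rep(1L, 16)), "0-4")
})

test_that("SDS clamps per-segment reversals to zero", {
  set.seed(11)
  mk <- function(v, tr) segment_scores(v, tr)
  stress <- mk(sample(0:4, 17, TRUE), "TL_STRESS")
  zero_rest <- mk(rep(0L, 17), "TL_REST")
  expect_equal(summed_difference(stress, zero_rest), summed_score(stress))
  same <- mk(stress$scores, "TL_REST")
  expect_equal(summed_difference(stress, same), 0)

  s <- rep(0L, 17); r <- rep(0L, 17)
  s[5] <- 1L; r[5] <- 3L; s[9] <- 2L
  expect_equal(summed_difference(mk(s, "TL_STRESS"), mk(r, "TL_REST")), 2)

  expect_error(summed_difference(stress, mk(rep(0L, 17), "BMIPP")),
               "tracer mismatch")

  # SDS = SSS - SRS whenever no segment reverses; SDS >= 0 always
  for (i in 1:50) {
    sv <- sample(0:4, 17, TRUE)
    rv <- vapply(sv, function(x) sample(0:x, 1), integer(1))
    sds <- summed_difference(mk(sv, "TL_STRESS"), mk(rv, "TL_REST"))
    expect_equal(sds, sum(sv) - sum(rv))
    expect_gte(sds, 0)
  }
})

test_that("abnormality cutoff is >= 4 with 3 and below normal", {
  expect_true(classify_abnormal(4))
  expect_false(classify_abnormal(3))
  expect_false(classify_abnormal(0))
  expect_true(classify_abnormal(10))
  expect_equal(classify_abnormal(c(0, 3, 4, 68)), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_abnormal(-1), "non-negative")
})

test_that("threshold tables and normal databases validate their invariants", {
  expect_error(threshold_table(c(70, 70, 30, 10)), "strictly decreasing")
  expect_error(threshold_table(c(100, 50, 30, 10)), "strictly decreasing|\\(0, 100\\)")
  expect_error(normal_db(data.frame(tracer = "BMIPP", segment = 1:17,
                                    mean = 100, sd = 0)), "positive")
  expect_error(normal_db(data.frame(tracer = "BMIPP", segment = 1:17,
                                    mean = 101, sd = 5)), "\\(0, 100\\]")
})
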