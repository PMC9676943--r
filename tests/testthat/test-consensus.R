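test_that("SOR matches direct evaluation of its definition", {
  expect_equal(compute_sor(10, 10, 5, 5), log(2), tolerance = 1e-12)
  # pseudocounts make an all-reference site balanced
  expect_equal(compute_sor(10, 10, 0, 0), log(2), tolerance = 1e-12)
  # single-strand alt support blows past the default cutoff of 4
  val <- compute_sor(10, 10, 10, 0)
  expect_equal(val, log(11 * 1 / (11 * 11) + 11 * 11 / (11 * 1)) +
                 log(1) - log(1 / 11), tolerance = 1e-12)
  expect_gt(val, 4)
  expect_error(compute_sor(-1, 0, 0, 0), "non-negative")
})

test_that("SOR agrees with an independent re-implementation on random counts", {
  set.seed(5)
  for (i in 1:300) {
    q <- rpois(4, lambda = sample(c(1, 10, 200), 1))
    expect_equal(compute_sor(q[1], q[2], q[3], q[4]),
                 oracle_sor(q[1], q[2], q[3], q[4]), tolerance = 1e-9)
  }
})

test_that("SOR is symmetric under simultaneous strand exchange", {
  set.seed(6)
  for (i in 1:100) {
    q <- rpois(4, 20)
    expect_equal(compute_sor(q[1], q[2], q[3], q[4]),
                 compute_sor(q[2], q[1], q[4], q[3]), tolerance = 1e-12)
  }
})

test_that("site filters return complete reason-code sets", {
  cfg <- filter_config()
  calls <- make_calls(c(100, 200, 300), c("G", "G", "G"),
                      c(0.05, 0.05, 0.05))
  calls$mean_mapping_quality[1] <- 19   # mapping failure
  calls$mean_base_quality[2] <- 10      # quality failure
  out <- apply_site_filters(calls, cfg)
  expect_equal(out$fail_reasons[1], "mapping")
  expect_equal(out$fail_reasons[2], "quality")
  expect_true(out$pass[3])

  # strand bias: all alt reads on one strand at depth >= 20
  biased <- make_calls(400, "G", 0.5, ref_fw = 10, ref_rv = 10)
  biased$alt_fw <- 20; biased$alt_rv <- 0
  out <- apply_site_filters(biased, cfg)
  expect_match(out$fail_reasons[1], "strand_bias")

  # two alternative alleles above the mono-allelic floor at one position
  multi <- make_calls(c(500, 500), c("G", "T"), c(0.1, 0.1))
  out <- apply_site_filters(multi, cfg)
  expect_true(all(grepl("multi_allelic", out$fail_reasons)))

  # a trace alt below the floor does not mark the site multi-allelic
  trace <- make_calls(c(600, 600), c("G", "T"), c(0.10, 0.0005))
  out <- apply_site_filters(trace, cfg)
  expect_false(grepl("multi_allelic", out$fail_reasons[1]))

  # zero-depth site fails as no_coverage, not an error
  zero <- make_calls(700, "G", 0)
  zero[, c("ref_fw", "ref_rv", "alt_fw", "alt_rv")] <- 0
  out <- apply_site_filters(zero, cfg)
  expect_match(out$fail_reasons[1], "no_coverage")
})

test_that("tightening thresholds never adds passing calls (monotonicity)", {
  set.seed(8)
  calls <- make_calls(seq(100, 1900, by = 100), rep("G", 19),
                      runif(19, 0.01, 0.6))
  calls$mean_base_quality <- runif(19, 10, 40)
  calls$alt_fw <- rbinom(19, calls$alt_fw + calls$alt_rv, 0.9)
  calls$alt_rv <- pmax(round(calls$heteroplasmy_fraction * 1000) -
                         calls$alt_fw, 0)
  loose <- apply_site_filters(calls, filter_config(min_base_quality = 20,
                                                   max_sor = 4))
  tightq <- apply_site_filters(calls, filter_config(min_base_quality = 30,
                                                    max_sor = 4))
  tights <- apply_site_filters(calls, filter_config(min_base_quality = 20,
                                                    max_sor = 2))
  expect_true(all(which(tightq$pass) %in% which(loose$pass)))
  expect_true(all(which(tights$pass) %in% which(loose$pass)))
})

test_that("consensus merge honours strict intersection and majority rules", {
  a <- make_calls(c(100, 200, 300), c("G", "G", "G"), c(0.10, 0.20, 0.30))
  b <- make_calls(c(100, 200), c("G", "G"), c(0.12, 0.18))
  c3 <- make_calls(c(100, 400), c("G", "G"), c(0.08, 0.05))

  strict <- consensus_merge(a, b, c3, rule = "strict_intersection")
  expect_equal(strict$position, 100L)
  expect_equal(strict$callers, "A,B,C")
  expect_equal(strict$heteroplasmy_fraction, 0.10)  # median of .10/.12/.08

  maj <- consensus_merge(a, b, c3, rule = "majority")
  expect_setequal(maj$position, c(100L, 200L))
  expect_equal(maj$heteroplasmy_fraction[maj$position == 200], 0.19)

  # consensus subset property under strict intersection
  expect_true(all(paste(strict$position, strict$alt_allele) %in%
                    paste(a$position, a$alt_allele)))
  expect_true(all(paste(strict$position, strict$alt_allele) %in%
                    paste(b$position, b$alt_allele)))

  # merged fraction always inside the supporting callers' range
  for (i in seq_len(nrow(maj))) {
    key <- paste(maj$position[i], maj$alt_allele[i])
    hfs <- c(a$heteroplasmy_fraction[paste(a$position, a$alt_allele) == key],
             b$heteroplasmy_fraction[paste(b$position, b$alt_allele) == key],
             c3$heteroplasmy_fraction[paste(c3$position, c3$alt_allele) == key])
    expect_gte(maj$heteroplasmy_fraction[i], min(hfs))
    expect_lte(maj$heteroplasmy_fraction[i], max(hfs))
  }

  expect_equal(nrow(consensus_merge(a[0, ], b[0, ], c3[0, ])), 0)

  bad <- b; bad$ref_allele[1] <- "C"
  expect_error(consensus_merge(a, bad, c3), "conflicting ref")
})

test_that("contamination gate applies the >1% AND used-minor rule strictly", {
  rep_contam <- data.frame(sample_id = "S", level = 0.107,
                           used_minor_count = 3)
  expect_equal(contamination_gate(rep_contam), "exclude_from_heteroplasmy")
  expect_equal(contamination_gate(data.frame(sample_id = "S", level = 0.005,
                                             used_minor_count = 3)),
               "include_all")
  # boundary: exactly 1% is retained (strict inequality)
  expect_equal(contamination_gate(data.frame(sample_id = "S", level = 0.01,
                                             used_minor_count = 3)),
               "include_all")
  expect_equal(contamination_gate(data.frame(sample_id = "S", level = 0.2,
                                             used_minor_count = 0)),
               "include_all")
  expect_warning(res <- contamination_gate(NULL), "missing")
  expect_equal(res, "include_all")
  expect_error(contamination_gate(NULL, missing_action = "error"))
})
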