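test_that("coarse heteroplasmy bins follow the class boundaries", {
  expect_equal(bin_heteroplasmy(0.003), "0.4%-0%")
  expect_equal(bin_heteroplasmy(0.05), "15%-5%")
  expect_equal(bin_heteroplasmy(0.0095), "0.9%-0.5%")  # [0.5%,1%) convention
  expect_equal(bin_heteroplasmy(c(0.005, 0.01, 0.0499, 0.15)),
               c("0.9%-0.5%", "4.9%-1%", "4.9%-1%", "15%-5%"))
  expect_error(bin_heteroplasmy(0.2), "0.15")
  expect_error(bin_heteroplasmy(0))
})

test_that("every fraction maps to exactly one coarse and one fine bin", {
  set.seed(41)
  f <- runif(500, 1e-4, 0.15)
  coarse <- bin_heteroplasmy(f, "coarse")
  fine <- bin_heteroplasmy(f, "fine")
  expect_length(coarse, 500)
  expect_length(fine, 500)
  expect_true(all(coarse %in% c("0.4%-0%", "0.9%-0.5%", "4.9%-1%", "15%-5%")))
  # bin counts sum to the variant total
  expect_equal(sum(table(coarse)), 500)
  expect_equal(sum(table(fine)), 500)
  # fine partitions (0,5%) into 0.1%-wide classes plus one [5,15] class
  expect_lte(length(unique(fine)), 51)
})

test_that("de novo detection applies the window and the inheritance rule", {
  mother <- make_calls(c(1000, 2000), c("G", "G"), c(0.01, 0.001))
  off <- make_calls(c(1000, 2000, 3000, 4000, 5000), rep("G", 5),
                    c(0.03, 0.03, 0.03, 0.20, 0.001))
  ds <- detect_denovo_mtdna(off, mother, pair_id = "m->o")
  # 1000 inherited (mother 1%); 2000 de novo (mother below floor);
  # 3000 de novo; 4000 above ceiling; 5000 below floor
  expect_equal(sort(ds$variants$position), c(2000L, 3000L))
  expect_equal(ds$n_denovo, 2L)
  expect_equal(ds$variants$mother_fraction[ds$variants$position == 2000],
               0.001)
  # a different alt allele at the same position is not inheritance
  mother2 <- make_calls(3000, "T", 0.05)
  ds2 <- detect_denovo_mtdna(off[off$position == 3000, ], mother2)
  expect_equal(ds2$n_denovo, 1L)
  expect_error(detect_denovo_mtdna(off, NULL, pair_id = "p1"), "p1")
})

test_that("mutational rate reproduces the worked pair counts", {
  expect_equal(mutational_rate(295, 117)$rate, 295 / (117 * 16569))
  expect_equal(signif(mutational_rate(295, 117)$rate, 3), 1.52e-4)
  expect_equal(signif(mutational_rate(51, 39)$rate, 2), 7.9e-5)
  expect_equal(mutational_rate(0, 50)$rate, 0)
  expect_error(mutational_rate(10, 0), "n_pairs")
  # bootstrap CI brackets the point estimate and is seed-reproducible
  counts <- c(rep(0, 20), rep(2, 20), rep(5, 10))
  r1 <- mutational_rate(sum(counts), 50, pair_counts = counts, seed = 9)
  r2 <- mutational_rate(sum(counts), 50, pair_counts = counts, seed = 9)
  expect_equal(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$rate)
  expect_gte(r1$ci[2], r1$rate)
})

test_that("pooled de novo counts equal the sum over disjoint pair groups", {
  set.seed(43)
  groups <- split(rpois(60, 3), rep(1:3, each = 20))
  total <- mutational_rate(sum(unlist(groups)), 60)
  by_group <- vapply(groups, sum, numeric(1))
  expect_equal(total$n_denovo, sum(by_group))
  expect_equal(total$rate,
               sum(by_group) / (60 * 16569))
})

test_that("nuclear trio filter enforces every high-confidence criterion", {
  base <- data.frame(
    variant_id = "v", child_id = "c1",
    child_dp = 30L, mother_dp = 30L, father_dp = 30L,
    child_gq = 60L, mother_gq = 60L, father_gq = 60L,
    child_gt = "0/1", mother_gt = "0/0", father_gt = "0/0",
    child_ab = 0.5, population_maf = 0, caller1 = TRUE, caller2 = TRUE,
    stringsAsFactors = FALSE)
  pass <- filter_nuclear_dnm(base)
  expect_equal(nrow(pass$retained), 1L)
  expect_equal(pass$per_child_counts$n_dnm, 1L)

  fail_cases <- list(
    within(base, father_dp <- 11L),      # depth below 12
    within(base, child_ab <- 0.29),      # allele balance window
    within(base, child_gq <- 20L),       # GQ strictly > 20
    within(base, mother_gt <- "0/1"),    # parent not hom-ref
    within(base, caller2 <- FALSE),      # both callers required
    within(base, population_maf <- 0.05) # common in the population
  )
  for (fc in fail_cases)
    expect_equal(nrow(filter_nuclear_dnm(fc)$retained), 0L)

  # missing MAF treated as zero; direction configurable
  na_maf <- within(base, population_maf <- NA_real_)
  expect_equal(nrow(filter_nuclear_dnm(na_maf)$retained), 1L)
  expect_equal(nrow(filter_nuclear_dnm(base,
                                       maf_direction = "exclude_rare")$retained),
               0L)

  bad_gt <- within(base, child_gt <- "./.")
  expect_warning(out <- filter_nuclear_dnm(bad_gt), "malformed")
  expect_equal(nrow(out$retained), 0L)
})
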