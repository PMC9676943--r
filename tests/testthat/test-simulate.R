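test_that("configuration validation names the offending field", {
  expect_error(simulation_config(simplex_fraction = 1.2), "simplex_fraction")
  expect_error(simulation_config(denovo_rate_mu = -1), "denovo_rate_mu")
  expect_error(simulation_config(haplogroup_freqs = c(H = 0.5, J = 0.4)),
               "haplogroup_freqs")
  expect_error(simulation_config(haplogroup_freqs = c(ZZ = 1)), "ZZ")
  expect_error(simulation_config(strand_bias = 2), "strand_bias")
})

test_that("simplex family count matches the configured proportion", {
  co <- simulate_cohort(simulation_config(n_families = 98,
                                          simplex_fraction = 73 / 98,
                                          sibling_rate = 0, seed = 61))
  fams <- co$pedigree[co$pedigree$role == "mother", ]
  expect_equal(sum(fams$family_type == "simplex"), 73L)
  expect_equal(nrow(fams), 98L)
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- test_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
})

test_that("site-count simulation obeys the binomial model", {
  # zero fraction -> never an alt read
  z <- simulate_site_counts(rep(0, 50), 1000, seed = 62)
  expect_true(all(z$alt_fw == 0 & z$alt_rv == 0))
  # empirical alt fraction within 3 binomial SE of truth
  x <- simulate_site_counts(0.5, 10000, strand_bias = 0, seed = 63)
  frac <- (x$alt_fw + x$alt_rv) / 10000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # full strand bias: all alt reads on one strand, SOR beyond the cutoff
  b <- simulate_site_counts(0.5, 100, strand_bias = 1, seed = 64)
  expect_equal(b$alt_rv, 0L)
  expect_gt(compute_sor(b$ref_fw, b$ref_rv, b$alt_fw, b$alt_rv), 4)
  expect_error(simulate_site_counts(0.5, 0), "coverage")
  expect_error(simulate_site_counts(1.5, 10), "\\[0,1\\]")
})

test_that("pedigree closure and position bounds hold", {
  co <- simulate_cohort(test_config())
  ped <- co$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  expect_true(all(kids$mother_id %in% ped$individual_id))
  expect_true(all(kids$father_id %in% ped$individual_id))
  expect_true(all(co$calls$position >= 1 &
                    co$calls$position <= MT_GENOME_LENGTH))
  # roles partition the cohort
  expect_setequal(unique(ped$role),
                  c("mother", "father", "proband", "sibling"))
})

test_that("truth record is consistent with the simulated data", {
  co <- simulate_cohort(test_config())
  ped <- co$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  for (i in seq_len(nrow(kids))) {
    id <- kids$individual_id[i]
    mom <- kids$mother_id[i]
    dn_pos <- co$truth[[id]]$denovo_positions
    if (!length(dn_pos)) next
    mom_calls <- co$calls[co$calls$sample_id == mom &
                            co$calls$heteroplasmy_fraction >= 0.002, ]
    # no true de novo position is detectable in the mother
    expect_length(intersect(dn_pos, mom_calls$position), 0)
  }
  # every sample's true haplogroup is recorded
  expect_setequal(names(co$truth), ped$individual_id)
})

test_that("classifier recovers every simulated haplogroup", {
  co <- simulate_cohort(test_config())
  hg <- classify_cohort(co$genotypes)
  truth_hap <- vapply(co$truth[hg$sample_id], `[[`, character(1),
                      "haplogroup")
  expect_false(any(hg$undetermined))
  expect_equal(hg$label, unname(truth_hap))
})

test_that("contamination injection plants donor markers as minor alleles", {
  # clean haplogroup-H host: single backbone marker call at 2706A
  prof <- list(sample_id = "host",
               calls = make_calls(2706, "A", 0.999, sample_id = "host"),
               haplogroup = "H",
               contamination = list(level = 0, used_minor_count = 0))
  out <- inject_contamination(prof, 0.107, "U5a")
  expect_equal(out$contamination$level, 0.107)
  expect_gt(out$contamination$used_minor_count, 0)
  # U5a path markers absent from H now present near 10.7%
  minor <- out$calls[out$calls$position %in% c(11467, 16270, 3197), ]
  expect_gt(nrow(minor), 0)
  expect_true(all(abs(minor$heteroplasmy_fraction - 0.107) < 0.02))
  # level 0 leaves the profile untouched
  expect_identical(inject_contamination(prof, 0, "U5a"), prof)
  expect_error(inject_contamination(prof, 0.6, "U5a"), "0.5")
  # discordant-marker construction at 5%: H vs U5a host
  out5 <- inject_contamination(prof, 0.05, "U5a")
  m5 <- out5$calls[out5$calls$position == 11467, ]
  expect_equal(m5$heteroplasmy_fraction, 0.05, tolerance = 0.02)
})

test_that("VCF output round-trips through vcfR", {
  co <- simulate_cohort(test_config())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  id <- co$pedigree$individual_id[1]
  back <- read_sample_vcf(file.path(dir, "vcf", paste0(id, ".vcf")))
  orig <- co$calls[co$calls$sample_id == id, ]
  orig <- orig[order(orig$position, orig$alt_allele), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$position, orig$position)
  expect_equal(back$alt_allele, orig$alt_allele)
  expect_equal(back$ref_fw + back$ref_rv + back$alt_fw + back$alt_rv,
               orig$ref_fw + orig$ref_rv + orig$alt_fw + orig$alt_rv)
  expect_equal(back$heteroplasmy_fraction, orig$heteroplasmy_fraction,
               tolerance = 1e-5)
  whole <- read_cohort(dir)
  expect_equal(nrow(whole$calls), nrow(co$calls))
  expect_equal(whole$pedigree$individual_id, co$pedigree$individual_id)
})
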