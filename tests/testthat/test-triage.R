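test_that("privacy partition routes markers, private and low-level variants", {
  calls <- make_calls(c(2706, 5000, 6000, 7000), c("A", "G", "G", "G"),
                      c(0.99, 0.16, 0.14, 0.15))
  out <- partition_private(calls, marker_keys = c("2706A"))
  expect_equal(out$privacy,
               c("haplogroup_defining", "private", "low_level", "low_level"))
  # every variant lands in exactly one stream
  expect_true(all(out$privacy %in%
                    c("haplogroup_defining", "private", "low_level")))
})

test_that("pathogenicity rules apply MITOMAP, GenBank and score thresholds", {
  ann <- data.frame(
    position = c(3890L, 5000L, 15884L, 5600L, 5601L, 6000L, 6001L),
    ref = "A", alt = "G",
    gene = c("MT-ND1", "MT-CO1", "MT-CYB", "tRNA_or_intergenic",
             "tRNA_or_intergenic", "MT-CO2", "MT-CO3"),
    functional_class = c("missense", "missense", "missense", "tRNA", "tRNA",
                         "missense", "synonymous"),
    mitomap_status = c("confirmed", "absent", "reported", "absent", "absent",
                       "absent", "absent"),
    genbank_count = c(5L, 0L, 12L, 0L, 0L, 0L, 0L),
    cadd_phred = c(10, 25, 30, NA, NA, 25, NA),
    mtoolbox_score = c(0.2, 0.6, 0.9, NA, NA, NA, NA),
    mitotip_raw = c(NA, NA, NA, 12.66, 15, NA, NA),
    stringsAsFactors = FALSE)
  out <- classify_pathogenicity(ann)
  # confirmed in MITOMAP wins regardless of scores
  expect_equal(out$pathogenicity[1], "confirmed_pathogenic")
  # rare missense above both score thresholds
  expect_equal(out$pathogenicity[2], "predicted_deleterious")
  # common variant is not rare, whatever the predictions say
  expect_equal(out$pathogenicity[3], "not_flagged")
  expect_equal(out$rationale[3], "seen_in_genbank")
  # tRNA boundary: MitoTip exactly at threshold fails the strict rule
  expect_equal(out$pathogenicity[4], "not_flagged")
  expect_equal(out$pathogenicity[5], "predicted_deleterious")
  # missing required score
  expect_equal(out$rationale[6], "missing_annotation")
  # class without a scoring rule
  expect_equal(out$pathogenicity[7], "not_flagged")
  # every not_flagged row names its first failed criterion
  expect_true(all(nzchar(out$rationale[out$pathogenicity == "not_flagged"])))
})

test_that("raising the CADD threshold never flags more variants", {
  set.seed(31)
  n <- 200
  ann <- data.frame(
    position = seq_len(n), ref = "A", alt = "G", gene = "MT-ND1",
    functional_class = "missense",
    mitomap_status = "absent",
    genbank_count = rbinom(n, 1, 0.5) * rpois(n, 5),
    cadd_phred = runif(n, 0, 40),
    mtoolbox_score = runif(n),
    mitotip_raw = NA_real_, stringsAsFactors = FALSE)
  n15 <- sum(classify_pathogenicity(ann, cadd_threshold = 15)$pathogenicity ==
               "predicted_deleterious")
  n25 <- sum(classify_pathogenicity(ann, cadd_threshold = 25)$pathogenicity ==
               "predicted_deleterious")
  expect_lte(n25, n15)
})

test_that("complex burden deduplicates variants within a family line", {
  ped <- data.frame(
    individual_id = c("F1.M", "F1.P1", "F1.F", "F2.M", "F2.P1"),
    family_id = c("F1", "F1", "F1", "F2", "F2"),
    mother_id = c(NA, "F1.M", NA, NA, "F2.M"),
    role = c("mother", "proband", "father", "mother", "proband"),
    stringsAsFactors = FALSE)
  # same CV missense variant in mother+child of F1 (one line) and in F2 (a
  # second line): counted once per line, twice across lines
  tri <- data.frame(
    sample_id = c("F1.M", "F1.P1", "F2.M"),
    position = 8530L, ref_allele = "A", alt_allele = "G",
    privacy = "private", functional_class = "missense", complex = "CV",
    pathogenicity = "not_flagged", stringsAsFactors = FALSE)
  out <- complex_burden(tri, ped, grouping = "maternal_lines")
  expect_equal(out$n_variants[out$complex == "CV"], 2L)
  expect_equal(out$n_variants[out$complex == "overall"], 2L)
  expect_equal(out$n_variants[out$complex == "CI"], 0L)
  expect_equal(unique(out$n_lines), 2L)

  # empty cohort -> all-zero table
  empty <- complex_burden(tri[0, ], ped, grouping = "maternal_lines")
  expect_true(all(empty$n_variants == 0))

  # CV-only injection concentrates the burden in the CV row
  expect_true(all(out$n_variants[!out$complex %in% c("CV", "overall")] == 0))
})

test_that("mitochondrial gene map assigns genes and complexes", {
  hits <- mt_gene_at(c(3400, 14800, 6000, 8400, 300, 1000, 577))
  expect_equal(hits$gene[1:4], c("MT-ND1", "MT-CYB", "MT-CO1", "MT-ATP8"))
  expect_equal(hits$complex[1:4], c("CI", "CIII", "CIV", "CV"))
  expect_equal(hits$class[5], "control_region")
  expect_equal(hits$class[6], "rRNA")
  expect_equal(hits$class[7], "tRNA")
  expect_equal(oxphos_complex(c("MT-ND6", "MT-CYB", "MT-CO3", "MT-ATP6",
                                "MT-RNR1")),
               c("CI", "CIII", "CIV", "CV", "none"))
})
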