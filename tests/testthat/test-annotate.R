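test_that("impact score binning follows the HDIV convention boundaries", {
  expect_identical(impact_category_from_score(0), "benign")
  expect_identical(impact_category_from_score(0.452), "benign")
  expect_identical(impact_category_from_score(0.4521), "possibly_damaging")
  expect_identical(impact_category_from_score(0.7), "possibly_damaging")
  expect_identical(impact_category_from_score(0.956), "possibly_damaging")
  expect_identical(impact_category_from_score(0.9561), "probably_damaging")
  expect_identical(impact_category_from_score(1), "probably_damaging")
  expect_error(impact_category_from_score(1.2), "outside")
  expect_error(impact_category_from_score(-0.1), "outside")
  # total monotone step function
  s <- seq(0, 1, by = 0.01)
  lv <- c("benign", "possibly_damaging", "probably_damaging")
  expect_true(all(diff(match(impact_category_from_score(s), lv)) >= 0))
})

test_that("start-codon-loss override supersedes score-based labels", {
  cand <- data.frame(aa_change = c("p.M1V", "p.T23I", NA, "garbled"),
                     impact_category = c("benign", "benign", "benign",
                                         "benign"),
                     stringsAsFactors = FALSE)
  expect_warning(out <- apply_start_loss_override(cand), "unparseable")
  expect_identical(out$impact_category,
                   c("start_loss", "benign", "benign", "benign"))
  # M1M synonymous start is not a loss
  keep <- apply_start_loss_override(
    data.frame(aa_change = "p.M1M", impact_category = "benign"))
  expect_identical(keep$impact_category, "benign")
})

test_that("annotation join is a lossless left join and rejects duplicate keys", {
  cand <- data.frame(chrom = c("1", "1", "2"), pos = c(100L, 200L, 300L),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    aa_change = "p.K10R", impact_score = 0.99,
                    impact_category = NA_character_, tf_site = NA_character_,
                    mirna_site = NA_character_, af_chinese = 0.01,
                    af_east_asian = NA_real_, stringsAsFactors = FALSE)
  out <- join_annotations(cand, ann)
  expect_equal(nrow(out), nrow(cand))
  # category derived from score when the table omits it
  expect_identical(out$impact_category[1L], "probably_damaging")
  expect_true(all(is.na(out$impact_category[2:3])))

  dup <- rbind(ann, ann)
  expect_error(join_annotations(cand, dup), "duplicate annotation keys")
})

test_that("regulatory impact requires the matching genic region", {
  cand <- data.frame(
    genic_region = c("promoter", "utr3", "exon", "exon", "promoter"),
    tf_site = c("PAX5_01", NA, NA, "ELK1_01", NA),
    mirna_site = c(NA, "miR-130/301", NA, NA, NA),
    stringsAsFactors = FALSE)
  out <- regulatory_impact(cand)
  expect_identical(out$regulatory_impact,
                   c("tf_site_hit", "mirna_site_hit", "none", "none", "none"))
  # TF annotation outside a promoter is kept but flagged inconsistent
  expect_identical(out$regulatory_inconsistent,
                   c(FALSE, FALSE, FALSE, TRUE, FALSE))
})
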