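# End-to-end checks of the reconstructed reported-variant cohort.
bundle <- reported_variants_cohort()
res <- screen_bundle(bundle)
tab <- reported_snvs()

test_that("the regions arm reproduces every reported in-region SNV row", {
  expected <- tab[tab$arm == "regions", ]
  got <- res$regions
  expect_equal(nrow(got), nrow(expected))
  m <- match(paste(expected$gene, expected$ref, expected$alt,
                   expected$aa_change),
             paste(got$gene, got$ref, got$alt, got$aa_change))
  expect_false(anyNA(m))
  expect_identical(got$category[m], expected$genotype)
  expect_identical(got$cytoband[m], expected$cytoband)
  expect_identical(got$carriers[m], expected$samples)
  # rsIDs carried through from the VCF ID column
  expect_identical(got$site_id[m], ifelse(is.na(expected$snv_id), "NA",
                                          expected$snv_id))
})

test_that("the gene-set arm reproduces every reported dopamine-gene SNV row", {
  expected <- tab[tab$arm == "geneset", ]
  got <- res$gene_set
  expect_equal(nrow(got), nrow(expected))
  m <- match(paste(expected$gene, expected$ref, expected$alt),
             paste(got$gene, got$ref, got$alt))
  expect_false(anyNA(m))
  expect_identical(got$category[m], expected$genotype)
  expect_identical(got$carriers[m], expected$samples)
  # the two X-linked FLNA rows exercise hemizygous male handling
  flna <- got[got$gene == "FLNA", ]
  expect_equal(nrow(flna), 2L)
  expect_true(all(flna$category == "homo_gain"))
  expect_true(all(grepl("hemizygous", flna$flags)))
})

test_that("regulatory hits are exactly the two promoter and one 3'-UTR sites", {
  prom <- res$regions[res$regions$regulatory_impact == "tf_site_hit", ]
  expect_setequal(prom$gene, c("ZNF598", "WFS1"))
  expect_setequal(prom$tf_site, c("ELK1_01", "PAX5_01"))
  expect_true(all(prom$genic_region == "promoter"))
  mir <- res$regions[res$regions$regulatory_impact == "mirna_site_hit", ]
  expect_equal(mir$gene, "ULK2")
  expect_equal(mir$mirna_site, "miR-130/301")
  expect_equal(mir$genic_region, "utr3")
  # no regulatory hits in the dopamine arm
  expect_true(all(res$gene_set$regulatory_impact == "none"))
})

test_that("the fixture reproduces the printed cohort-frequency cells", {
  freq_of <- function(cand, gene, id) {
    row <- cand[cand$gene == gene & cand$site_id == id, ]
    c(row$frequency, row$carriers)
  }
  expect_equal(freq_of(res$regions, "WFS1", "rs866882393"),
               c("3/25", "42/65/78"))
  expect_equal(freq_of(res$regions, "CACNA1H", "rs61734410"),
               c("2/25", "99/100"))
  expect_equal(freq_of(res$gene_set, "FLNA", "rs143873938"),
               c("3/25", "5/65/69"))
  expect_equal(freq_of(res$gene_set, "LAMA2", "rs2229848"),
               c("3/25", "5/43/88"))
})

test_that("the start-codon mutation is relabelled start_loss, missense kept", {
  gna12 <- res$gene_set[res$gene_set$gene == "GNA12", ]
  expect_identical(gna12$impact_category[gna12$site_id == "rs798488"],
                   "start_loss")
  expect_identical(gna12$impact_category[gna12$site_id == "rs2644275"],
                   "benign")
})

test_that("the fixture bundle itself is deterministic and files round-trip", {
  d1 <- withr::local_tempdir()
  write_cohort_bundle(bundle, d1)
  cohort <- read_pedigree(file.path(d1, "cohort.ped"))
  expect_equal(n_trios(cohort), 25L)
  geno <- read_cohort_vcf(file.path(d1, "cohort.vcf"), cohort)
  expect_identical(geno$sites, bundle$geno$sites)
  expect_identical(geno$geno[, colnames(bundle$geno$geno)],
                   bundle$geno$geno)
})
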