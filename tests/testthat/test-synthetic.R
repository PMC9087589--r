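test_that("the generator is deterministic: same seed, byte-identical bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_bundle(generate_cohort(generator_config(seed = 4L)), d1)
  write_cohort_bundle(generate_cohort(generator_config(seed = 4L)), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  write_cohort_bundle(generate_cohort(generator_config(seed = 5L)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("a default-config cohort has 25 trios, 75 samples and consistent files", {
  bundle <- generate_cohort(generator_config(seed = 2L))
  expect_equal(n_trios(bundle$cohort), 25L)
  expect_length(cohort_samples(bundle$cohort), 75L)
  expect_equal(ncol(bundle$geno$geno), 75L)
  # every planted gene has a model and an expression value
  expect_true(all(bundle$truth$gene %in% bundle$gene_models$gene))
  expect_true(all(bundle$gene_models$gene %in% bundle$expression$gene))
  # every planted site is present in the genotype matrix
  skey <- paste(bundle$geno$sites$chrom, bundle$geno$sites$pos,
                bundle$geno$sites$alt)
  expect_true(all(paste(bundle$truth$chrom, bundle$truth$pos,
                        bundle$truth$alt) %in% skey))
})

test_that("the screen recovers exactly the planted truth on generated cohorts", {
  for (seed in c(13L, 101L, 999L)) {
    bundle <- generate_cohort(generator_config(seed = seed))
    rset <- resolve_bands(bundle$region_bands, bundle$cytobands)
    cand <- run_screen(bundle$geno, bundle$cohort,
                       screen_config("susceptible_regions",
                                     region_set = rset),
                       bundle$gene_models, bundle$expression,
                       bundle$annotations, bundle$cytobands)
    chk <- screen_truth_check(bundle, cand)
    expect_true(chk$recovered, label = paste("seed", seed))
    expect_true(chk$categories_ok, label = paste("seed", seed))
    expect_true(chk$carriers_ok, label = paste("seed", seed))
    # decoys dropped for their intended reasons
    drops <- attr(cand, "drops")
    decoys <- bundle$truth[!bundle$truth$expected_to_survive, ]
    m <- match(paste(decoys$chrom, decoys$pos, decoys$alt),
               paste(drops$chrom, drops$pos, drops$alt))
    expect_false(anyNA(m))
    expect_identical(drops$reason[m], decoys$expected_drop_reason)
  }
})

test_that("each decoy fails exactly its intended filter", {
  bundle <- generate_cohort(generator_config(seed = 21L))
  tt <- bundle$truth
  run_with <- function(region_bands = bundle$region_bands, rpkm = 1) {
    rset <- resolve_bands(region_bands, bundle$cytobands)
    run_screen(bundle$geno, bundle$cohort,
               screen_config("susceptible_regions", region_set = rset,
                             rpkm_threshold = rpkm),
               bundle$gene_models, bundle$expression, bundle$annotations,
               bundle$cytobands)
  }
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  # out-of-region decoy survives once its band is included
  oor <- tt[tt$class == "out_of_region", ]
  cand <- run_with(region_bands = c(bundle$region_bands, "2q24", "7p21",
                                    "19p12", "1q31"))
  expect_true(all(key(oor) %in% key(cand)))
  # low-expression decoy survives with the filter threshold at zero
  low <- tt[tt$class == "low_expression_gene", ]
  cand <- run_with(rpkm = 0)
  expect_true(all(key(low) %in% key(cand)))
  # neither survives the default screen
  cand <- run_with()
  expect_false(any(key(rbind(oor, low)) %in% key(cand)))
})

test_that("impossible generator configs fail loudly", {
  expect_error(generator_config(n_trios = 0L))
  # one-trio cohort: the only child is male, so the X plant is possible;
  # but a cohort of one female child cannot host it
  cfg <- generator_config(n_trios = 2L, seed = 1L)
  bundle <- generate_cohort(cfg)   # child 1 male, child 2 female: fine
  expect_equal(n_trios(bundle$cohort), 2L)
})
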