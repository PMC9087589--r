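bundle <- reported_variants_cohort()
res <- screen_bundle(bundle)

test_that("category-matrix marginals agree with candidate frequencies", {
  m <- category_matrix(res$regions, bundle$cohort)
  expect_equal(nrow(m), nrow(res$regions))
  expect_equal(ncol(m), 25L)
  carriers_per_row <- rowSums(m != "none")
  key <- sprintf("%s:%s:%d:%s>%s", res$regions$gene, res$regions$chrom,
                 res$regions$pos, res$regions$ref, res$regions$alt)
  expect_equal(unname(carriers_per_row[key]), res$regions$n_carriers)
  # rows grouped by genic region in promoter -> utr3 order
  reg <- attr(m, "genic_region")
  order_idx <- match(reg, c("promoter", "utr5", "exon", "utr3", "intron",
                            "intergenic"))
  expect_true(!is.unsorted(order_idx))
  # a two-carrier row has exactly two non-none cells
  cac <- m[grep("CACNA1H", rownames(m)), ]
  expect_equal(sum(cac != "none"), 2L)
  expect_setequal(names(cac)[cac != "none"], c("99", "100"))
  # empty candidate list -> empty matrix
  empty <- category_matrix(res$regions[0, ], bundle$cohort)
  expect_equal(nrow(empty), 0L)
})

test_that("function membership matrix is plain boolean membership", {
  gf <- data.frame(gene = c("CACNA1H", "CACNA1H", "LRP6", "UNRELATED"),
                   term = c("ion channel activity", "midbrain development",
                            "Wnt signaling pathway", "ion channel activity"),
                   stringsAsFactors = FALSE)
  m <- function_membership_matrix(c("CACNA1H", "LRP6", "RGS11"), gf)
  expect_true(m["CACNA1H", "ion channel activity"])
  expect_true(m["LRP6", "Wnt signaling pathway"])
  expect_false(m["CACNA1H", "Wnt signaling pathway"])
  # gene with no terms -> all-false row
  expect_false(any(m["RGS11", ]))
  # genes outside the candidate list are ignored
  expect_false("UNRELATED" %in% rownames(m))
  empty <- function_membership_matrix(character(0), gf)
  expect_equal(dim(empty)[1L], 0L)
})

test_that("run summaries are self-consistent with monotone filtering", {
  s <- summary_counts(res$regions)
  expect_true(all(diff(unlist(s$stages)) <= 0))
  expect_equal(s$n_candidates, nrow(res$regions))
  expect_equal(s$n_carrier_events, sum(res$regions$n_carriers))
  expect_equal(sum(unlist(s$by_category)), s$n_candidates)
  out <- withr::local_tempfile(fileext = ".json")
  write_summary_json(res$regions, out)
  back <- jsonlite::read_json(out)
  expect_equal(back$n_candidates, nrow(res$regions))
})
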