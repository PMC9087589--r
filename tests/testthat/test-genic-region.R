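# Fixture gene: tx 405000..424999, CDS 406001..422999 (+1 conventions from
# the 0-based file), exons rel 1..2000, 6001..10000, 16001..20000.
model_plus <- mini_gene_models(tx_start = 405001L, strand = "+")

test_that("plus-strand genic regions are assigned with correct boundaries", {
  tss <- model_plus$tx_start
  expect_identical(assign_genic_region(tss - 500L, model_plus), "promoter")
  expect_identical(assign_genic_region(tss - 1L, model_plus), "promoter")
  expect_identical(assign_genic_region(tss - 1000L, model_plus), "promoter")
  expect_identical(assign_genic_region(tss - 1001L, model_plus), "intergenic")
  expect_identical(assign_genic_region(tss + 500L, model_plus), "utr5")
  expect_identical(assign_genic_region(tss + 7000L, model_plus), "exon")
  expect_identical(assign_genic_region(tss + 3000L, model_plus), "intron")
  # terminal exon 3' of the CDS end
  expect_identical(assign_genic_region(tss + 18500L, model_plus), "utr3")
  expect_identical(assign_genic_region(tss + 30000L, model_plus), "intergenic")
  # promoter window is configurable
  expect_identical(assign_genic_region(tss - 1500L, model_plus,
                                       promoter_len = 2000L), "promoter")
})

test_that("minus-strand assignment mirrors the gene structure", {
  model_minus <- mini_gene_models(tx_start = 405001L, strand = "-")
  tss_end <- model_minus$tx_end
  # promoter is downstream of tx_end on the minus strand
  expect_identical(assign_genic_region(tss_end + 500L, model_minus),
                   "promoter")
  expect_identical(assign_genic_region(tss_end + 1001L, model_minus),
                   "intergenic")
  # low-coordinate exon flank is the 3'-UTR, high-coordinate the 5'-UTR
  expect_identical(assign_genic_region(model_minus$tx_start + 500L,
                                       model_minus), "utr3")
  expect_identical(assign_genic_region(model_minus$tx_start + 18500L,
                                       model_minus), "utr5")
  expect_identical(assign_genic_region(model_minus$tx_start + 7000L,
                                       model_minus), "exon")
})

test_that("gene-model validation rejects inconsistent structures", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds",
               "BAD\t1\t+\t100\t5000\t50\t4000\t100,\t5000,"), tsv)
  expect_error(read_gene_models(tsv), "CDS outside transcript")
  writeLines(c("gene\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds",
               "BAD\t1\t+\t100\t5000\t200\t4000\t100,90,\t150,5000,"), tsv)
  expect_error(read_gene_models(tsv), "unsorted|overlap")
})
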