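lookup <- utils::read.table(test_path("fixtures", "classify_lookup.tsv"),
                            header = TRUE, sep = "\t",
                            colClasses = c(rep("integer", 3),
                                           rep("character", 3)))

test_that("classify_site matches the hand-written dosage lookup table exactly", {
  for (i in seq_len(nrow(lookup))) {
    got <- classify_site(lookup$child[i], lookup$mother[i], lookup$father[i],
                         child_sex = lookup$sex[i],
                         context = lookup$context[i])
    expect_identical(got$category, lookup$category[i],
                     label = sprintf("row %d (c=%d m=%d f=%d %s)", i,
                                     lookup$child[i], lookup$mother[i],
                                     lookup$father[i], lookup$context[i]))
  }
})

test_that("classification properties hold over the full dosage space", {
  combos <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  for (i in seq_len(nrow(combos))) {
    c_ <- combos$child[i]; m <- combos$mother[i]; f <- combos$father[i]
    res <- classify_site(c_, m, f)
    # symmetry under swapping mother and father on autosomes
    expect_identical(res$category, classify_site(c_, f, m)$category)
    # Mendelian sanity
    if (res$category == "homo_inherit") expect_true(m >= 1 && f >= 1)
    if (res$category == "hetero_gain") expect_true(m == 0 && f == 0)
    # single-site calls never produce the gene-level category
    expect_false(res$category == "compound_hetero_gain")
  }
  # missing dosage disqualifies the trio
  expect_identical(classify_site(NA, 0, 0)$category, "none")
  expect_identical(classify_site(NA, 0, 0)$reason, "missing")
  expect_identical(classify_site(1, NA, 0)$category, "none")
  # female X uses ordinary diploid rules
  expect_identical(
    classify_site(2, 1, 1, child_sex = "female", context = "x_nonpar")$category,
    "homo_inherit")
  expect_error(classify_site(3, 0, 0), "invalid dosage")
})

test_that("double de novo homozygotes are classified homo_gain and flagged", {
  res <- classify_site(2, 0, 0)
  expect_identical(res$category, "homo_gain")
  expect_true("double_de_novo" %in% res$flags)
})

test_that("parental origin calls follow carrier status", {
  expect_identical(call_origin(1, 1, 0), "maternal")
  expect_identical(call_origin(1, 0, 1), "paternal")
  expect_identical(call_origin(1, 0, 0), "de_novo")
  expect_identical(call_origin(1, 1, 1), "ambiguous")
  expect_identical(call_origin(1, NA, 0), "ambiguous")
  expect_error(call_origin(0, 1, 0), "child dosage")
})

test_that("compound-het pairing agrees with enumeration over origin pairs", {
  origins <- c("de_novo", "maternal", "paternal", "ambiguous")
  # expected by definition: trans-compatible (not both maternal, not both
  # paternal) and, when required, containing a de novo member
  for (require_dn in c(TRUE, FALSE)) {
    for (a in origins) for (b in origins) {
      got <- find_compound_het(c(a, b), require_de_novo = require_dn)
      trans_ok <- !(a == "maternal" && b == "maternal") &&
        !(a == "paternal" && b == "paternal")
      dn_ok <- !require_dn || "de_novo" %in% c(a, b)
      expect_equal(nrow(got), as.integer(trans_ok && dn_ok),
                   label = paste(a, b, require_dn))
      if (nrow(got) == 1L)
        expect_equal(got$phase_uncertain, "ambiguous" %in% c(a, b))
    }
  }
  expect_equal(nrow(find_compound_het("de_novo")), 0L)  # single het site
  expect_equal(nrow(find_compound_het(character(0))), 0L)
})

test_that("hemizygous normalization maps any alt call to dosage 2", {
  expect_identical(normalize_hemizygous(c(0L, 1L, 2L, NA)),
                   c(0L, 2L, 2L, NA))
})
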