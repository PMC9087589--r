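#' The bundled table of reported candidate SNVs
#'
#' The published candidate SNVs (coding, promoter and 3'-UTR rows from both
#' screening arms) shipped with the package as a plain-text input table:
#' SNV id, gene, cytoband, genotype category, alleles, amino-acid change,
#' 1000 Genomes allele frequencies, impact category, TF/miRNA site, and the
#' carrier children.
#'
#' @return data.frame, one row per reported SNV.
#' @export
reported_snvs <- function() {
  path <- system.file("extdata", "reported_snvs.tsv", package = "trioscreen",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = "NA")
}

#' Deterministic cohort fixture reproducing the reported candidate SNVs
#'
#' Builds a complete synthetic 25-trio cohort in which, for every reported
#' candidate SNV, the listed carrier children receive trio genotypes
#' satisfying the row's genotype category at a site carrying the row's
#' ref/alt alleles inside a synthetic model of the row's gene (placed in the
#' row's cytoband of the miniature genome), the annotation table carries the
#' row's impact/TF/miRNA/frequency values, and every other sample is
#' homozygous reference. Children listed as carriers of the X-linked (FLNA)
#' sites are male and hemizygous; homozygous-inherited rows give both
#' parents a heterozygous genotype; de novo rows give both parents
#' homozygous-reference genotypes. All genes are assigned brain-expression
#' values above the RPKM filter. The fixture is fully deterministic (no
#' random draws).
#'
#' Running [run_screen()] on this bundle with the regions arm reproduces the
#' reported in-region rows (including exactly two promoter TF-site
#' candidates and one 3'-UTR miRNA-site candidate), and with the gene-set
#' arm (dopamine-related genes) the remaining rows.
#'
#' @return A `trio_bundle` (see [generate_cohort()]) with elements `cohort`,
#'   `geno`, `gene_models`, `expression`, `annotations`, `cytobands`,
#'   `region_bands` (susceptible bands plus the additional cytobands of the
#'   reported in-region rows), and `gene_set` (the dopamine-arm genes).
#' @export
reported_variants_cohort <- function() {
  tab <- reported_snvs()
  cytobands <- cytoband_fixture()

  ## 25-trio cohort with child sample IDs matching the reported tables ------
  listed <- sort(unique(as.integer(unlist(strsplit(tab$samples, "/")))))
  filler <- setdiff(1:100, listed)
  children <- sort(c(listed, filler[seq_len(25L - length(listed))]))
  parent_pool <- setdiff(1:100, children)
  mothers <- parent_pool[seq(1L, 49L, by = 2L)]
  fathers <- parent_pool[seq(2L, 50L, by = 2L)]
  children <- as.character(children)
  mothers <- as.character(mothers)
  fathers <- as.character(fathers)

  x_rows <- tab$cytoband == "Xq28"
  male_children <- unique(unlist(strsplit(tab$samples[x_rows], "/")))
  child_sex <- ifelse(children %in% male_children, "male",
                      ifelse(seq_along(children) %% 2L == 1L, "male",
                             "female"))
  sex <- c(stats::setNames(child_sex, children),
           stats::setNames(rep("female", 25L), mothers),
           stats::setNames(rep("male", 25L), fathers))
  aff <- stats::setNames(c(rep("affected", 25L), rep("unaffected", 50L)),
                         c(children, mothers, fathers))
  cohort <- structure(list(
    trios = data.frame(family = sprintf("F%02d", 1:25), child = children,
                       mother = mothers, father = fathers,
                       stringsAsFactors = FALSE),
    sex = sex, affected = aff), class = "trio_cohort")

  ## one synthetic gene model per reported gene, placed in its cytoband -----
  alloc <- band_slot_allocator(cytobands)
  gene_tab <- unique(tab[, c("gene", "cytoband")])
  gene_models <- do.call(rbind, lapply(seq_len(nrow(gene_tab)), function(i) {
    q <- parse_band_query(gene_tab$cytoband[i])
    synthetic_gene_model(gene_tab$gene[i], q$chrom,
                         alloc(gene_tab$cytoband[i]))
  }))
  expression <- data.frame(gene = gene_models$gene,
                           rpkm = 2 + 0.5 * seq_len(nrow(gene_models)),
                           stringsAsFactors = FALSE)

  ## sites: coding variants inside the CDS, promoter/3'-UTR variants in
  ## their regulatory windows; multiple variants of one gene offset apart
  seen <- integer(0)
  sites <- list(); geno_rows <- list(); ann_rows <- list()
  samples <- cohort_samples(cohort)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    gm <- gene_models[gene_models$gene == row$gene, , drop = FALSE]
    j <- sum(names(seen) == row$gene)
    seen <- c(seen, stats::setNames(1L, row$gene))
    pos <- switch(row$region,
                  exon = gm$tx_start + 7000L + 137L * j,
                  promoter = gm$tx_start - 500L - 10L * j,
                  utr3 = gm$tx_start + 18500L + 10L * j)
    sites[[i]] <- data.frame(chrom = gm$chrom, pos = pos, ref = row$ref,
                             alt = row$alt,
                             site_id = ifelse(is.na(row$snv_id), "NA",
                                              row$snv_id),
                             stringsAsFactors = FALSE)
    dose <- stats::setNames(rep(0L, length(samples)), samples)
    carriers <- strsplit(row$samples, "/")[[1L]]
    hemizygous <- gm$chrom == "X"
    for (ch in carriers) {
      tr <- cohort$trios[match(ch, cohort$trios$child), ]
      if (row$genotype == "homo_inherit") {
        dose[tr$child] <- 2L; dose[tr$mother] <- 1L; dose[tr$father] <- 1L
      } else if (row$genotype == "hetero_gain") {
        dose[tr$child] <- 1L
      } else if (row$genotype == "homo_gain") {
        if (hemizygous) {
          dose[tr$child] <- 1L          # hemizygous alt, mother hom-ref
        } else if (row$gene == "PALM") {
          dose[tr$child] <- 2L; dose[tr$mother] <- 1L  # one allele maternal
        } else {
          dose[tr$child] <- 2L          # fully de novo homozygote
        }
      } else stop("unknown genotype category in reported table: ",
                  row$genotype)
    }
    geno_rows[[i]] <- dose
    ann_rows[[i]] <- data.frame(
      chrom = gm$chrom, pos = pos, ref = row$ref, alt = row$alt,
      aa_change = row$aa_change, impact_score = NA_real_,
      impact_category = row$impact,
      tf_site = if (row$region == "promoter") row$tf_mirna else NA_character_,
      mirna_site = if (row$region == "utr3") row$tf_mirna else NA_character_,
      af_chinese = as.numeric(row$af_chinese),
      af_east_asian = as.numeric(row$af_east_asian),
      stringsAsFactors = FALSE)
  }

  geno_obj <- sort_genotypes(structure(list(
    sites = do.call(rbind, sites),
    geno = matrix(unlist(geno_rows), nrow = length(geno_rows), byrow = TRUE,
                  dimnames = list(NULL, samples)),
    n_dropped_non_snv = 0L, n_malformed_gt = 0L),
    class = "trio_genotypes"))

  # the reported in-region rows span a few cytobands beyond the canonical
  # susceptible-band list; the fixture's region arm covers their union
  extra_bands <- c("2q24.3", "5q33.3", "11q22.3", "12p13.2", "12p13.32")
  structure(list(
    cohort = cohort, geno = geno_obj, gene_models = gene_models,
    expression = expression, annotations = do.call(rbind, ann_rows),
    cytobands = cytobands,
    region_bands = c(susceptible_bands(), extra_bands),
    gene_set = unique(tab$gene[tab$arm == "geneset"]),
    truth = NULL), class = "trio_bundle")
}

#' Run both screening arms on a cohort bundle
#'
#' Convenience wrapper: resolves the bundle's region bands, runs the
#' susceptible-regions arm, and (when the bundle carries a gene set) the
#' gene-set arm with the susceptible regions as exclusion mask.
#'
#' @param bundle A `trio_bundle`.
#' @param ... Passed on to [screen_config()] (e.g. `rpkm_threshold`,
#'   `exclusion_mode`).
#' @return list with elements `regions` and (possibly `NULL`) `gene_set`,
#'   each a candidate data.frame from [run_screen()].
#' @export
screen_bundle <- function(bundle, ...) {
  region_set <- resolve_bands(bundle$region_bands, bundle$cytobands)
  regions <- run_screen(
    bundle$geno, bundle$cohort,
    screen_config(arm = "susceptible_regions", region_set = region_set, ...),
    bundle$gene_models, bundle$expression, bundle$annotations,
    bundle$cytobands)
  gene_set <- NULL
  if (!is.null(bundle$gene_set))
    gene_set <- run_screen(
      bundle$geno, bundle$cohort,
      screen_config(arm = "gene_set", gene_set = bundle$gene_set,
                    region_set = region_set, ...),
      bundle$gene_models, bundle$expression, bundle$annotations,
      bundle$cytobands)
  list(regions = regions, gene_set = gene_set)
}
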