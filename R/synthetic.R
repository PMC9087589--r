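#' Miniature cytoband table for synthetic cohorts
#'
#' A scaled-down genome in which every cytoband used by the screen (the
#' reported ADHD-susceptible bands and the bands hosting the published
#' candidate genes) exists as a fixed-width interval. Coordinates are
#' synthetic: real genome-build coordinates are deliberately not reproduced.
#'
#' @param band_width Width of each band in bases (default 200000).
#' @return data.frame in the internal cytoband layout (`chrom`, `start`,
#'   `end` 1-based closed, `band`).
#' @export
cytoband_fixture <- function(band_width = 200000L) {
  bands <- list(
    "1" = c("p11", "q11", "q25.1", "q25.2", "q25.3", "q31", "q32.1", "q32.2"),
    "2" = c("p11", "q11", "q24.1", "q24.2", "q24.3", "q25"),
    "4" = c("p16.3", "p16.2", "p16.1", "p15", "p11", "q11"),
    "5" = c("p13.3", "p13.2", "p13.1", "p12", "p11", "q11", "q33.1",
            "q33.2", "q33.3", "q34"),
    "6" = c("p11", "q11", "q12", "q13", "q14.1", "q14.2", "q14.3", "q15",
            "q22.31", "q22.32", "q22.33", "q23"),
    "7" = c("p22.3", "p22.2", "p22.1", "p21", "p11", "q11"),
    "10" = c("p11", "q11", "q25", "q26.11", "q26.12", "q26.13", "q26.2",
             "q26.3"),
    "11" = c("p15.5", "p15.4", "p14", "p11", "q11", "q22.1", "q22.2",
             "q22.3", "q23", "q24", "q25"),
    "12" = c("p13.33", "p13.32", "p13.31", "p13.2", "p13.1", "p12", "p11",
             "q11", "q13.11", "q13.12", "q13.13", "q14", "q23.1", "q23.2",
             "q23.3", "q24"),
    "16" = c("p13.3", "p13.2", "p13.13", "p13.12", "p13.11", "p12", "p11",
             "q11"),
    "17" = c("p12", "p11.2", "p11.1", "q11", "q21", "q22", "q23"),
    "19" = c("p13.3", "p13.2", "p13.11", "p12", "q11"),
    "20" = c("p11", "q11", "q13.11", "q13.12", "q13.13", "q13.2", "q13.33"),
    "X" = c("p11", "q11", "q27", "q28"))
  rows <- lapply(names(bands), function(chrom) {
    b <- bands[[chrom]]
    data.frame(chrom = chrom,
               start = (seq_along(b) - 1L) * band_width + 1L,
               end = seq_along(b) * band_width,
               band = b, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The reported ADHD-susceptible cytoband names
#'
#' The linkage-derived susceptible regions used as the default region arm:
#' 4p16.1, 5p12-13, 6q12-14, 10q26, 11p15.5, 11q25, 12q23, 16p13, 17p11,
#' 20q13.
#'
#' @return Character vector of band names accepted by [resolve_bands()].
#' @export
susceptible_bands <- function() {
  c("4p16.1", "5p12-13", "6q12-14", "10q26", "11p15.5", "11q25", "12q23",
    "16p13", "17p11", "20q13")
}

#' Write a cytoband table in the UCSC dialect
#'
#' @param cytobands data.frame (`chrom`, `start`, `end` 1-based closed,
#'   `band`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytobands <- function(cytobands, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\tgneg", cytobands$chrom,
                   cytobands$start - 1L, cytobands$end, cytobands$band)
  writeLines(lines, path)
  invisible(path)
}

# Canonical synthetic gene shape: 20 kb, three exons, CDS from rel 1001 to
# rel 18000, so rel 1..1000 is 5'-UTR and rel 18001..20000 is 3'-UTR on the
# plus strand.
synthetic_gene_model <- function(gene, chrom, tx_start, strand = "+") {
  s <- as.integer(tx_start)
  data.frame(gene = gene, chrom = chrom, strand = strand,
             tx_start = s, tx_end = s + 19999L,
             cds_start = s + 1000L, cds_end = s + 17999L,
             exon_starts = I(list(c(s, s + 6000L, s + 16000L))),
             exon_ends = I(list(c(s + 1999L, s + 9999L, s + 19999L))),
             stringsAsFactors = FALSE)
}

# Allocate non-overlapping gene slots inside bands of the miniature genome.
band_slot_allocator <- function(cytobands) {
  used <- new.env(parent = emptyenv())
  function(band_name) {
    q <- parse_band_query(band_name)
    hit <- which(cytobands$chrom == q$chrom &
                   vapply(cytobands$band, function(b) {
                     p <- parse_band(b)
                     !is.null(p) && p$arm == q$arm && p$major == q$major_lo &&
                       (is.na(q$sub) || identical(p$sub, q$sub))
                   }, logical(1)))
    if (length(hit) == 0L) stop("fixture band not found: ", band_name)
    hit <- hit[1L]
    k <- if (is.null(used[[band_name]])) 0L else used[[band_name]]
    used[[band_name]] <- k + 1L
    start <- cytobands$start[hit] + 4999L + k * 25000L
    if (start + 19999L > cytobands$end[hit])
      stop("band ", band_name, " exhausted")
    start
  }
}

#' Generator configuration for synthetic trio cohorts
#'
#' @param n_trios Number of trios (default 25, the cohort design).
#' @param n_homo_gain,n_hetero_gain,n_homo_inherit Planted counts of
#'   single-site categories (coding sites).
#' @param n_compound Planted compound-heterozygote pairs (each two het sites
#'   in one gene: one de novo, one maternally inherited).
#' @param n_x_homo_gain Planted hemizygous male-X homo_gain sites.
#' @param n_promoter_tf Planted de novo promoter sites with a TF motif
#'   annotation.
#' @param n_utr3_mirna Planted de novo 3'-UTR sites with a miRNA-site
#'   annotation.
#' @param decoys Named integer vector of decoy counts; classes:
#'   `inherited_het`, `parental_hom_carrier`, `low_expression_gene`,
#'   `out_of_region`, `missing_genotype`. Each decoy violates exactly one
#'   filter.
#' @param n_background Background polymorphic sites (parental hets, half of
#'   them transmitted) placed in dedicated background genes.
#' @param seed Integer seed fixing all randomness end to end.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trios = 25L, n_homo_gain = 2L,
                             n_hetero_gain = 2L, n_homo_inherit = 2L,
                             n_compound = 1L, n_x_homo_gain = 1L,
                             n_promoter_tf = 1L, n_utr3_mirna = 1L,
                             decoys = c(inherited_het = 1L,
                                        parental_hom_carrier = 1L,
                                        low_expression_gene = 1L,
                                        out_of_region = 1L,
                                        missing_genotype = 1L),
                             n_background = 20L, seed = 1L) {
  stopifnot(n_trios >= 1L, n_homo_gain >= 0L, n_hetero_gain >= 0L,
            n_homo_inherit >= 0L, n_compound >= 0L, n_x_homo_gain >= 0L,
            n_promoter_tf >= 0L, n_utr3_mirna >= 0L, n_background >= 0L,
            all(decoys >= 0L))
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic trio cohort with a planted-variant truth table
#'
#' Builds a fully self-consistent input bundle — cohort model, genotype
#' matrix, gene models, cytobands, expression table, annotation table — in
#' which every planted site satisfies exactly one genotype category's
#' defining pattern and every decoy violates exactly one screening filter.
#' The accompanying truth table states, per planted/decoy site, whether it
#' must survive the default susceptible-regions screen and, if not, the
#' stage reason with which it must be dropped. All randomness is fixed by
#' `config$seed`: the same config yields a byte-identical bundle.
#'
#' @param config A [generator_config()].
#' @return A `trio_bundle`: list with `cohort`, `geno`, `gene_models`,
#'   `expression`, `annotations`, `cytobands`, `region_bands`, `truth`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_trios

  children <- as.character(seq_len(n))
  mothers <- as.character(n + seq_len(n))
  fathers <- as.character(2L * n + seq_len(n))
  sex <- c(stats::setNames(ifelse(seq_len(n) %% 2L == 1L, "male", "female"),
                           children),
           stats::setNames(rep("female", n), mothers),
           stats::setNames(rep("male", n), fathers))
  aff <- stats::setNames(c(rep("affected", n), rep("unaffected", 2L * n)),
                         c(children, mothers, fathers))
  cohort <- structure(list(
    trios = data.frame(family = sprintf("F%02d", seq_len(n)),
                       child = children, mother = mothers, father = fathers,
                       stringsAsFactors = FALSE),
    sex = sex, affected = aff), class = "trio_cohort")
  males <- children[sex[children] == "male"]
  if (config$n_x_homo_gain > 0L && length(males) == 0L)
    stop("impossible config: X-linked plant requested but cohort has no male child")

  cytobands <- cytoband_fixture()
  alloc <- band_slot_allocator(cytobands)
  in_bands <- c("16p13.3", "4p16.1", "10q26.2", "17p11.2", "12q23.2",
                "11p15.5", "20q13.13", "6q13", "5p13.2", "11q25")
  out_bands <- c("2q24.1", "7p21", "19p12", "1q31")
  next_in_band <- local({ i <- 0L; function() {
    i <<- i + 1L; in_bands[(i - 1L) %% length(in_bands) + 1L] } })

  gene_rows <- list(); sites <- list(); truth <- list()
  expr_rows <- list(); ann_rows <- list()
  geno_cells <- list()  # list of (site_key, sample, dosage)
  gene_n <- 0L
  new_gene <- function(band) {
    gene_n <<- gene_n + 1L
    name <- sprintf("SYNG%03d", gene_n)
    q <- parse_band_query(band)
    gm <- synthetic_gene_model(name, q$chrom, alloc(band))
    gene_rows[[length(gene_rows) + 1L]] <<- gm
    gm
  }
  rand_alleles <- function() sample(c("A", "C", "G", "T"), 2L)
  add_site <- function(chrom, pos, ref, alt, id = "NA") {
    sites[[length(sites) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      site_id = id, stringsAsFactors = FALSE)
    length(sites)
  }
  set_dose <- function(site_key, sample, dosage) {
    geno_cells[[length(geno_cells) + 1L]] <<-
      list(site = site_key, sample = sample, dosage = dosage)
  }
  plant_trio <- function(site_key, trio_idx, child_d, mother_d, father_d) {
    tr <- cohort$trios[trio_idx, ]
    set_dose(site_key, tr$child, child_d)
    set_dose(site_key, tr$mother, mother_d)
    set_dose(site_key, tr$father, father_d)
  }
  add_truth <- function(site_key, gene, class, expected_category, carriers,
                        survive, drop_reason = NA_character_) {
    s <- sites[[site_key]]
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt, gene = gene,
      class = class, expected_category = expected_category,
      carriers = paste(sort(as.integer(carriers)), collapse = "/"),
      expected_to_survive = survive, expected_drop_reason = drop_reason,
      stringsAsFactors = FALSE)
  }
  add_expr <- function(gene, rpkm)
    expr_rows[[length(expr_rows) + 1L]] <<- data.frame(
      gene = gene, rpkm = rpkm, stringsAsFactors = FALSE)
  add_ann <- function(s_key, aa = NA, score = NA, category = NA, tf = NA,
                      mirna = NA) {
    s <- sites[[s_key]]
    ann_rows[[length(ann_rows) + 1L]] <<- data.frame(
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      aa_change = as.character(aa), impact_score = as.numeric(score),
      impact_category = as.character(category), tf_site = as.character(tf),
      mirna_site = as.character(mirna),
      af_chinese = round(stats::runif(1, 0, 0.5), 4),
      af_east_asian = round(stats::runif(1, 0, 0.5), 4),
      stringsAsFactors = FALSE)
  }
  pick_children <- function(k) sample(children, k)
  coding_pos <- function(gm, j = 0L) gm$tx_start + 7000L + 137L * j
  aa_string <- function() sprintf("p.%s%d%s",
                                  sample(setdiff(LETTERS, c("B","J","O","U","X","Z","M")), 1),
                                  sample(2:900, 1),
                                  sample(setdiff(LETTERS, c("B","J","O","U","X","Z")), 1))

  ## planted single-site categories ----------------------------------------
  plant_simple <- function(n_plants, pattern, class) {
    for (p in seq_len(n_plants)) {
      gm <- new_gene(next_in_band())
      add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
      al <- rand_alleles()
      key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
      carriers <- pick_children(sample(seq_len(min(3L, n)), 1L))
      for (ch in carriers)
        plant_trio(key, match(ch, children), pattern[1L], pattern[2L],
                   pattern[3L])
      add_ann(key, aa = aa_string(),
              score = if (p %% 2L == 0L) round(stats::runif(1), 3) else NA,
              category = if (p %% 2L == 1L)
                sample(c("benign", "possibly_damaging", "probably_damaging"), 1)
              else NA)
      add_truth(key, gm$gene, class, class, carriers, TRUE)
    }
  }
  plant_simple(config$n_homo_inherit, c(2L, 1L, 1L), "homo_inherit")
  plant_simple(config$n_hetero_gain, c(1L, 0L, 0L), "hetero_gain")
  plant_simple(config$n_homo_gain, c(2L, 1L, 0L), "homo_gain")

  ## hemizygous male-X homo_gain -------------------------------------------
  for (p in seq_len(config$n_x_homo_gain)) {
    gm <- new_gene("Xq28")
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site("X", coding_pos(gm), al[1L], al[2L])
    ch <- sample(males, 1L)
    plant_trio(key, match(ch, children), 1L, 0L, 0L)
    add_ann(key, aa = aa_string(), category = "probably_damaging")
    add_truth(key, gm$gene, "x_homo_gain", "homo_gain", ch, TRUE)
  }

  ## compound heterozygote pairs -------------------------------------------
  for (p in seq_len(config$n_compound)) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    ch <- pick_children(1L)
    al1 <- rand_alleles(); al2 <- rand_alleles()
    k1 <- add_site(gm$chrom, coding_pos(gm, 0L), al1[1L], al1[2L])
    k2 <- add_site(gm$chrom, coding_pos(gm, 2L), al2[1L], al2[2L])
    plant_trio(k1, match(ch, children), 1L, 0L, 0L)      # de novo member
    plant_trio(k2, match(ch, children), 1L, 1L, 0L)      # maternal member
    add_ann(k1, aa = aa_string(), category = "possibly_damaging")
    add_ann(k2, aa = aa_string(), category = "possibly_damaging")
    add_truth(k1, gm$gene, "compound_pair", "hetero_gain", ch, TRUE)
    add_truth(k2, gm$gene, "compound_pair", "compound_hetero_gain", ch, TRUE)
  }

  ## regulatory-region plants ----------------------------------------------
  for (p in seq_len(config$n_promoter_tf)) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, gm$tx_start - 500L, al[1L], al[2L])
    carriers <- pick_children(1L)
    plant_trio(key, match(carriers, children), 1L, 0L, 0L)
    add_ann(key, tf = sprintf("TFBS_%02d", p))
    add_truth(key, gm$gene, "promoter_tf", "hetero_gain", carriers, TRUE)
  }
  for (p in seq_len(config$n_utr3_mirna)) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, gm$tx_start + 18500L, al[1L], al[2L])
    carriers <- pick_children(1L)
    plant_trio(key, match(carriers, children), 1L, 0L, 0L)
    add_ann(key, mirna = sprintf("miR-%d", 100L + p))
    add_truth(key, gm$gene, "utr3_mirna", "hetero_gain", carriers, TRUE)
  }

  ## decoys: each violates exactly one filter ------------------------------
  dk <- config$decoys
  for (p in seq_len(dk[["inherited_het"]])) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
    ch <- pick_children(1L)
    plant_trio(key, match(ch, children), 1L, 1L, 0L)
    add_truth(key, gm$gene, "inherited_het", "none", ch, FALSE,
              "not_categorized")
  }
  for (p in seq_len(dk[["parental_hom_carrier"]])) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
    ch <- pick_children(1L)
    plant_trio(key, match(ch, children), 2L, 1L, 1L)
    other <- setdiff(children, ch)[1L]
    set_dose(key, cohort$trios$mother[match(other, children)], 2L)
    add_truth(key, gm$gene, "parental_hom_carrier", "homo_inherit", ch,
              FALSE, "parent_hom_alt")
  }
  for (p in seq_len(dk[["low_expression_gene"]])) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, 0.3)
    al <- rand_alleles()
    key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
    ch <- pick_children(1L)
    plant_trio(key, match(ch, children), 2L, 1L, 1L)
    add_truth(key, gm$gene, "low_expression_gene", "homo_inherit", ch, FALSE,
              "low_expression")
  }
  for (p in seq_len(dk[["out_of_region"]])) {
    gm <- new_gene(out_bands[(p - 1L) %% length(out_bands) + 1L])
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
    ch <- pick_children(1L)
    plant_trio(key, match(ch, children), 2L, 1L, 1L)
    add_truth(key, gm$gene, "out_of_region", "homo_inherit", ch, FALSE,
              "out_of_scope")
  }
  for (p in seq_len(dk[["missing_genotype"]])) {
    gm <- new_gene(next_in_band())
    add_expr(gm$gene, round(stats::runif(1, 1.5, 60), 2))
    al <- rand_alleles()
    key <- add_site(gm$chrom, coding_pos(gm), al[1L], al[2L])
    ch <- pick_children(1L)
    tr <- cohort$trios[match(ch, children), ]
    set_dose(key, tr$child, 2L)
    set_dose(key, tr$mother, 1L)
    set_dose(key, tr$father, NA_integer_)
    add_truth(key, gm$gene, "missing_genotype", "none", ch, FALSE,
              "missing_genotype")
  }

  ## background polymorphisms in dedicated genes ---------------------------
  if (config$n_background > 0L) {
    bg_genes <- lapply(1:3, function(i) {
      gm <- new_gene(next_in_band())
      add_expr(gm$gene, 5)
      gm
    })
    rel_pos <- sample(seq(10L, 19990L, by = 10L), config$n_background)
    for (b in seq_len(config$n_background)) {
      gm <- bg_genes[[(b - 1L) %% 3L + 1L]]
      al <- rand_alleles()
      key <- add_site(gm$chrom, gm$tx_start + rel_pos[b], al[1L], al[2L])
      t_idx <- sample(n, 1L)
      set_dose(key, cohort$trios$mother[t_idx], 1L)
      if (stats::runif(1) < 0.5)
        set_dose(key, cohort$trios$child[t_idx], 1L)
    }
  }

  ## assemble ---------------------------------------------------------------
  sites_df <- do.call(rbind, sites)
  samples <- cohort_samples(cohort)
  geno <- matrix(0L, nrow = nrow(sites_df), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (cell in geno_cells)
    geno[cell$site, cell$sample] <- cell$dosage
  geno_obj <- sort_genotypes(structure(
    list(sites = sites_df, geno = geno, n_dropped_non_snv = 0L,
         n_malformed_gt = 0L), class = "trio_genotypes"))

  gene_models <- do.call(rbind, gene_rows)
  truth_df <- do.call(rbind, truth)
  bundle <- structure(list(
    cohort = cohort, geno = geno_obj, gene_models = gene_models,
    expression = do.call(rbind, expr_rows),
    annotations = if (length(ann_rows)) do.call(rbind, ann_rows) else NULL,
    cytobands = cytobands,
    # the hemizygous-X plant lives on Xq28; the generated study's region arm
    # covers it so X handling is exercised by the screen
    region_bands = c(susceptible_bands(),
                     if (config$n_x_homo_gain > 0L) "Xq28"),
    truth = truth_df, config = config), class = "trio_bundle")
  bundle
}

#' Write a cohort bundle to disk
#'
#' Emits every input the screening pipeline reads: `cohort.vcf`,
#' `cohort.ped`, `cytoband.tsv`, `gene_models.tsv`, `expression.tsv`,
#' `annotations.tsv`, `region_bands.txt`, and (when present)
#' `truth_table.tsv` and `gene_set.txt`. Output is deterministic: the same
#' bundle always writes byte-identical files.
#'
#' @param bundle A `trio_bundle` from [generate_cohort()] or
#'   [reported_variants_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  chroms <- unique(bundle$cytobands$chrom)
  contigs <- stats::setNames(
    vapply(chroms, function(ch)
      max(bundle$cytobands$end[bundle$cytobands$chrom == ch]), numeric(1)),
    chroms)
  write_cohort_vcf(bundle$geno, bundle$cohort, p("cohort.vcf"),
                   contig_lengths = contigs)
  write_pedigree(bundle$cohort, p("cohort.ped"))
  write_cytobands(bundle$cytobands, p("cytoband.tsv"))
  write_gene_models(bundle$gene_models, p("gene_models.tsv"))
  utils::write.table(bundle$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$annotations))
    utils::write.table(bundle$annotations, p("annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  writeLines(bundle$region_bands, p("region_bands.txt"))
  if (!is.null(bundle$truth))
    utils::write.table(bundle$truth, p("truth_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(bundle$gene_set))
    writeLines(bundle$gene_set, p("gene_set.txt"))
  invisible(dir)
}
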