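#' Configuration for a screening run
#'
#' @param arm `"susceptible_regions"` (restrict sites to a cytoband-derived
#'   region set) or `"gene_set"` (restrict sites to a list of genes, e.g.
#'   dopamine-related genes, excluding any site inside the susceptible
#'   region set when one is supplied).
#' @param region_set [GenomicRanges::GRanges] from [resolve_bands()];
#'   required for the regions arm, optional (as an exclusion mask) for the
#'   gene-set arm.
#' @param gene_set Character vector of gene symbols; required for the
#'   gene-set arm.
#' @param rpkm_threshold Brain-expression cutoff: genes with RPKM strictly
#'   below it are considered very low expressed and their SNVs dropped
#'   (default 1; the threshold itself survives).
#' @param promoter_len Promoter window upstream of the TSS, in bases
#'   (default 1000).
#' @param exclusion_mode `"genotype_match"` (default: homozygote candidates
#'   are excluded when any cohort parent is hom-alt; de novo gain candidates
#'   when any parent outside the carrier trios carries the allele) or
#'   `"any_carrier"` (any parent carrying the allele excludes the site).
#' @param expression_filter Apply the RPKM filter (default `TRUE`).
#' @param require_de_novo_compound Compound-het pairs must contain a de novo
#'   member (default `TRUE`).
#' @return A `screen_config` list.
#' @export
screen_config <- function(arm = c("susceptible_regions", "gene_set"),
                          region_set = NULL, gene_set = NULL,
                          rpkm_threshold = 1, promoter_len = 1000L,
                          exclusion_mode = c("genotype_match", "any_carrier"),
                          expression_filter = TRUE,
                          require_de_novo_compound = TRUE) {
  arm <- match.arg(arm)
  exclusion_mode <- match.arg(exclusion_mode)
  stopifnot(rpkm_threshold >= 0, promoter_len >= 0)
  if (arm == "susceptible_regions" && is.null(region_set))
    stop("susceptible_regions arm needs a region_set")
  if (arm == "gene_set" && (is.null(gene_set) || length(gene_set) == 0L))
    stop("gene_set arm needs a non-empty gene_set")
  structure(list(arm = arm, region_set = region_set, gene_set = gene_set,
                 rpkm_threshold = rpkm_threshold,
                 promoter_len = as.integer(promoter_len),
                 exclusion_mode = exclusion_mode,
                 expression_filter = expression_filter,
                 require_de_novo_compound = require_de_novo_compound),
            class = "screen_config")
}

gain_categories <- c("hetero_gain", "homo_gain", "compound_hetero_gain")

# Per-trio categories for one site; returns data.frame over trios.
classify_site_for_cohort <- function(dose, cohort, chrom) {
  tr <- cohort$trios
  ctx <- ploidy_context(chrom)
  res <- lapply(seq_len(nrow(tr)), function(i) {
    cl <- classify_site(dose[[tr$child[i]]], dose[[tr$mother[i]]],
                        dose[[tr$father[i]]],
                        child_sex = cohort$sex[[tr$child[i]]],
                        context = ctx)
    data.frame(child = tr$child[i], category = cl$category,
               reason = cl$reason,
               flags = paste(cl$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Cohort-wide unaffected-parent exclusion for one site.
# Returns list(keep, reason).
parent_exclusion <- function(dose, categories, cohort, mode) {
  tr <- cohort$trios
  parents <- c(tr$mother, tr$father)
  pdose <- unlist(dose[parents])
  carrier_idx <- which(categories$category != "none")
  if (mode == "any_carrier") {
    if (any(pdose >= 1L, na.rm = TRUE))
      return(list(keep = FALSE, reason = "parent_carrier"))
    return(list(keep = TRUE, reason = NA_character_))
  }
  cats <- categories$category[carrier_idx]
  if (any(cats %in% gain_categories)) {
    carrier_children <- categories$child[carrier_idx]
    own <- tr$child %in% carrier_children
    outside_parents <- c(tr$mother[!own], tr$father[!own])
    if (any(unlist(dose[outside_parents]) >= 1L, na.rm = TRUE))
      return(list(keep = FALSE, reason = "parent_carrier"))
  }
  if (any(cats == "homo_inherit")) {
    if (any(pdose == 2L, na.rm = TRUE))
      return(list(keep = FALSE, reason = "parent_hom_alt"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Cohort-wide unaffected-parent exclusion for a classified site
#'
#' Implements the rule that a candidate genotype must not be found in the
#' corresponding genotypes of the cohort's unaffected parents: under the
#' default `genotype_match` mode a homozygote candidate is dropped when any
#' of the cohort parents is hom-alt, and a de novo gain candidate is dropped
#' when any parent outside the carrier trios carries the allele at all
#' (carrier trios' own parents may legitimately contribute the inherited
#' portion of a homozygous or compound gain). Under `any_carrier` any
#' carrying parent excludes the site.
#'
#' @param dose Named list/vector of alt dosages over all cohort samples at
#'   the site.
#' @param categories data.frame (`child`, `category`) of per-trio categories
#'   at the site.
#' @param cohort A `trio_cohort`.
#' @param mode `"genotype_match"` or `"any_carrier"`.
#' @return list with logical `keep` and a `reason` when dropped.
#' @export
cohort_parent_exclusion <- function(dose, categories, cohort,
                                    mode = "genotype_match") {
  parent_exclusion(as.list(dose), categories, cohort, mode)
}

#' Carrier frequency of a candidate in the cohort
#'
#' @param carrier_children Character vector of carrier child IDs.
#' @param cohort A `trio_cohort`.
#' @return list with `n_carriers`, `frequency` (the printed `"n/25"`-style
#'   string) and `carriers` (IDs in ascending order joined with `"/"`).
#' @export
compute_cohort_frequency <- function(carrier_children, cohort) {
  ids <- unique(carrier_children)
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (!any(is.na(num))) ids[order(num)] else sort(ids)
  list(n_carriers = length(ids),
       frequency = sprintf("%d/%d", length(ids), n_trios(cohort)),
       carriers = paste(ids, collapse = "/"))
}

#' Run the variant screen end to end
#'
#' Applies the screening stages in order: (1) restriction of sites to the
#' arm's scope (cytoband region set, or gene-set membership minus the
#' susceptible regions); (2) brain-expression filter on the host gene;
#' (3) per-trio genotype-category classification including gene-level
#' compound heterozygotes; (4) cohort-wide unaffected-parent exclusion;
#' (5) carrier-frequency computation; (6) annotation join with impact
#' categories, the start-codon-loss override, and regulatory-site impact.
#' Output order is deterministic: chromosome, position, alt allele, gene.
#'
#' @param geno A `trio_genotypes` object from [read_cohort_vcf()].
#' @param cohort A `trio_cohort` from [read_pedigree()].
#' @param config A [screen_config()].
#' @param gene_models data.frame from [read_gene_models()].
#' @param expression data.frame from [read_expression()] (may be `NULL` when
#'   `config$expression_filter` is `FALSE`).
#' @param annotations data.frame from [read_annotations()], or `NULL`.
#' @param cytobands data.frame from [read_cytobands()] for band labels, or
#'   `NULL`.
#' @return data.frame of candidate variants (one row per surviving
#'   gene-site pair) with columns `chrom`, `pos`, `ref`, `alt`, `site_id`,
#'   `gene`, `cytoband`, `category`, `genic_region`, `flags`, annotation
#'   columns, `regulatory_impact`, `n_carriers`, `frequency`, `carriers`.
#'   Attributes: `stage_log` (per-stage site counts), `drops` (per-site drop
#'   reasons), `trio_categories` (long per-(site, gene, child) categories of
#'   the surviving candidates).
#' @export
run_screen <- function(geno, cohort, config, gene_models,
                       expression = NULL, annotations = NULL,
                       cytobands = NULL) {
  stopifnot(inherits(geno, "trio_genotypes"), inherits(cohort, "trio_cohort"),
            inherits(config, "screen_config"))
  if (n_trios(cohort) == 0L) stop("empty cohort")
  geno <- sort_genotypes(geno)
  sites <- geno$sites
  n_sites0 <- nrow(sites)
  drops <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), stage = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  drop_site <- function(idx, stage, reason, gene = NA_character_) {
    if (length(idx) == 0L) return()
    drops <<- rbind(drops, data.frame(
      chrom = sites$chrom[idx], pos = sites$pos[idx], ref = sites$ref[idx],
      alt = sites$alt[idx], gene = gene, stage = stage, reason = reason,
      stringsAsFactors = FALSE))
  }

  ## stage 1: arm scope -----------------------------------------------------
  if (config$arm == "susceptible_regions") {
    in_scope <- in_region_set(sites$chrom, sites$pos, config$region_set)
    drop_site(which(!in_scope), "scope", "out_of_scope")
    scoped <- which(in_scope)
    pairs <- map_sites_to_genes(sites$chrom, sites$pos, gene_models,
                                config$promoter_len)
    pairs <- pairs[pairs$site %in% scoped, , drop = FALSE]
    no_gene <- setdiff(scoped, pairs$site)
    drop_site(no_gene, "scope", "no_gene_model")
  } else {
    models_in_set <- which(gene_models$gene %in% config$gene_set)
    pairs <- map_sites_to_genes(sites$chrom, sites$pos, gene_models,
                                config$promoter_len)
    pairs <- pairs[pairs$gene_row %in% models_in_set, , drop = FALSE]
    in_region <- in_region_set(sites$chrom, sites$pos, config$region_set)
    excl <- pairs$site %in% which(in_region)
    if (any(excl))
      drop_site(unique(pairs$site[excl]), "scope", "in_susceptible_region")
    pairs <- pairs[!excl, , drop = FALSE]
    out <- setdiff(seq_len(nrow(sites)), c(pairs$site, which(in_region)))
    drop_site(out, "scope", "out_of_scope")
  }
  pairs$gene <- gene_models$gene[pairs$gene_row]
  n_sites1 <- length(unique(pairs$site))

  ## stage 2: expression filter --------------------------------------------
  if (config$expression_filter && nrow(pairs) > 0L) {
    rpkm <- if (is.null(expression)) rep(NA_real_, nrow(pairs)) else
      expression$rpkm[match(pairs$gene, expression$gene)]
    absent <- is.na(rpkm)
    low <- !absent & rpkm < config$rpkm_threshold
    if (any(absent)) {
      warning("gene(s) absent from expression table dropped: ",
              paste(unique(pairs$gene[absent]), collapse = ", "))
      for (i in which(absent))
        drop_site(pairs$site[i], "expression", "gene_not_in_expression_table",
                  pairs$gene[i])
    }
    for (i in which(low))
      drop_site(pairs$site[i], "expression", "low_expression", pairs$gene[i])
    pairs <- pairs[!(absent | low), , drop = FALSE]
  }
  n_sites2 <- length(unique(pairs$site))

  ## stage 3: per-trio classification incl. compound het --------------------
  site_idx <- sort(unique(pairs$site))
  dose_list <- lapply(site_idx, function(s) as.list(geno$geno[s, ]))
  names(dose_list) <- as.character(site_idx)
  cats <- lapply(site_idx, function(s)
    classify_site_for_cohort(as.list(geno$geno[s, ]), cohort, sites$chrom[s]))
  names(cats) <- as.character(site_idx)
  had_missing <- vapply(cats, function(cc) any(cc$reason %in% "missing"),
                        logical(1))

  # gene-level compound het: upgrade inherited het members of a qualifying
  # trans pair from none to compound_hetero_gain
  for (g in unique(pairs$gene_row)) {
    g_sites <- sort(unique(pairs$site[pairs$gene_row == g]))
    tx_ok <- sites$pos[g_sites] >= gene_models$tx_start[g] &
      sites$pos[g_sites] <= gene_models$tx_end[g]
    g_sites <- g_sites[tx_ok]
    if (length(g_sites) < 2L) next
    for (t in seq_len(n_trios(cohort))) {
      tr <- cohort$trios[t, ]
      het <- g_sites[vapply(g_sites, function(s) {
        d <- geno$geno[s, tr$child]
        !is.na(d) && d == 1L
      }, logical(1))]
      if (length(het) < 2L) next
      origins <- vapply(het, function(s)
        call_origin(geno$geno[s, tr$child], geno$geno[s, tr$mother],
                    geno$geno[s, tr$father]), character(1))
      ch_pairs <- find_compound_het(origins, config$require_de_novo_compound)
      if (nrow(ch_pairs) == 0L) next
      members <- unique(c(het[ch_pairs$a], het[ch_pairs$b]))
      uncertain <- unique(c(het[ch_pairs$a[ch_pairs$phase_uncertain]],
                            het[ch_pairs$b[ch_pairs$phase_uncertain]]))
      for (s in members) {
        cc <- cats[[as.character(s)]]
        row <- which(cc$child == tr$child)
        if (cc$category[row] == "none") {
          cc$category[row] <- "compound_hetero_gain"
          cc$reason[row] <- NA_character_
        }
        if (s %in% uncertain)
          cc$flags[row] <- paste(c(cc$flags[row][cc$flags[row] != ""],
                                   "phase_uncertain"), collapse = ",")
        cats[[as.character(s)]] <- cc
      }
    }
  }

  has_carrier <- vapply(cats, function(cc) any(cc$category != "none"),
                        logical(1))
  for (k in which(!has_carrier)) {
    reason <- if (had_missing[k]) "missing_genotype" else "not_categorized"
    drop_site(site_idx[k], "classification", reason)
  }
  keep_sites <- site_idx[has_carrier]
  pairs <- pairs[pairs$site %in% keep_sites, , drop = FALSE]
  n_sites3 <- length(keep_sites)

  ## stage 4: cohort parent exclusion ---------------------------------------
  kept <- logical(length(keep_sites))
  for (k in seq_along(keep_sites)) {
    s <- keep_sites[k]
    res <- parent_exclusion(as.list(geno$geno[s, ]), cats[[as.character(s)]],
                            cohort, config$exclusion_mode)
    kept[k] <- res$keep
    if (!res$keep) drop_site(s, "parent_exclusion", res$reason)
  }
  keep_sites <- keep_sites[kept]
  pairs <- pairs[pairs$site %in% keep_sites, , drop = FALSE]
  n_sites4 <- length(keep_sites)

  ## stage 5 + 6: assemble candidates ---------------------------------------
  cand_rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$site[i]; g <- pairs$gene_row[i]
    cc <- cats[[as.character(s)]]
    carrier <- cc[cc$category != "none", , drop = FALSE]
    freq <- compute_cohort_frequency(carrier$child, cohort)
    # category shown for the row: the carriers' category (majority rule on
    # ties broken by a fixed category order)
    cat_order <- c("homo_gain", "hetero_gain", "compound_hetero_gain",
                   "homo_inherit")
    tab <- table(factor(carrier$category, levels = cat_order))
    category <- names(tab)[which.max(tab)]
    region <- assign_genic_region(sites$pos[s], gene_models[g, ],
                                  config$promoter_len)
    flags <- unique(unlist(strsplit(carrier$flags, ",")))
    flags <- flags[flags != ""]
    data.frame(chrom = sites$chrom[s], pos = sites$pos[s], ref = sites$ref[s],
               alt = sites$alt[s], site_id = sites$site_id[s],
               gene = pairs$gene[i], category = category,
               genic_region = region,
               flags = paste(flags, collapse = ","),
               n_carriers = freq$n_carriers, frequency = freq$frequency,
               carriers = freq$carriers, stringsAsFactors = FALSE)
  })
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), site_id = character(0), gene = character(0),
               category = character(0), genic_region = character(0),
               flags = character(0), n_carriers = integer(0),
               frequency = character(0), carriers = character(0),
               stringsAsFactors = FALSE)

  candidates$cytoband <- if (!is.null(cytobands) && nrow(candidates) > 0L)
    cytoband_of(candidates$chrom, candidates$pos, cytobands)
  else rep(NA_character_, nrow(candidates))

  candidates <- join_annotations(candidates, annotations)
  candidates <- apply_start_loss_override(candidates)
  candidates <- regulatory_impact(candidates)

  o <- order(chrom_rank(candidates$chrom), candidates$pos, candidates$alt,
             candidates$gene)
  candidates <- candidates[o, , drop = FALSE]
  rownames(candidates) <- NULL

  trio_cats <- if (nrow(candidates) > 0L) do.call(rbind, lapply(
    seq_len(nrow(pairs)), function(i) {
      s <- pairs$site[i]
      cc <- cats[[as.character(s)]]
      cc <- cc[cc$category != "none", , drop = FALSE]
      if (nrow(cc) == 0L) return(NULL)
      data.frame(chrom = sites$chrom[s], pos = sites$pos[s],
                 ref = sites$ref[s], alt = sites$alt[s],
                 gene = pairs$gene[i], child = cc$child,
                 category = cc$category, stringsAsFactors = FALSE)
    })) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene = character(0), child = character(0),
               category = character(0), stringsAsFactors = FALSE)

  stage_log <- data.frame(
    stage = c("input", "scope", "expression", "classification",
              "parent_exclusion"),
    n_sites = c(n_sites0, n_sites1, n_sites2, n_sites3, n_sites4))
  attr(candidates, "stage_log") <- stage_log
  attr(candidates, "drops") <- drops
  attr(candidates, "trio_categories") <- trio_cats
  candidates
}

#' Gene membership in the gene set and the susceptible region set
#'
#' @param gene_set Character vector of gene symbols.
#' @param region_set [GenomicRanges::GRanges] of susceptible regions.
#' @param gene_models data.frame from [read_gene_models()].
#' @return data.frame with `gene`, logical `in_gene_set`,
#'   `in_susceptible_region`, and `unknown` (no model available; region
#'   membership is `NA` there).
#' @export
overlap_matrix <- function(gene_set, region_set, gene_models) {
  genes <- unique(gene_set)
  if (length(genes) == 0L)
    return(data.frame(gene = character(0), in_gene_set = logical(0),
                      in_susceptible_region = logical(0),
                      unknown = logical(0)))
  rows <- lapply(genes, function(g) {
    m <- gene_models[gene_models$gene == g, , drop = FALSE]
    if (nrow(m) == 0L)
      return(data.frame(gene = g, in_gene_set = TRUE,
                        in_susceptible_region = NA, unknown = TRUE))
    q <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(start = m$tx_start, end = m$tx_end))
    hit <- any(IRanges::overlapsAny(q, region_set))
    data.frame(gene = g, in_gene_set = TRUE, in_susceptible_region = hit,
               unknown = FALSE)
  })
  do.call(rbind, rows)
}

#' Keep candidates whose host gene passes the expression threshold
#'
#' @param candidates data.frame with a `gene` column.
#' @param expression data.frame from [read_expression()].
#' @param threshold RPKM cutoff; genes with RPKM strictly below are dropped,
#'   genes absent from the table are dropped with a warning.
#' @return Filtered candidates.
#' @export
filter_by_expression <- function(candidates, expression, threshold = 1) {
  stopifnot(threshold >= 0)
  rpkm <- expression$rpkm[match(candidates$gene, expression$gene)]
  absent <- is.na(rpkm)
  if (any(absent))
    warning("gene(s) absent from expression table dropped: ",
            paste(unique(candidates$gene[absent]), collapse = ", "))
  candidates[!absent & rpkm >= threshold, , drop = FALSE]
}
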