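#' Genotype-category matrix (candidate site x child)
#'
#' Builds the heatmap-style matrix underlying the cohort-distribution
#' figures: one row per candidate gene-site pair, one column per affected
#' child, cells holding the genotype category for carrier children and
#' `"none"` otherwise. Rows are grouped by genic region in the order
#' promoter, 5'-UTR, exon, 3'-UTR, intron, and ordered deterministically
#' within a group.
#'
#' @param candidates Candidate data.frame from [run_screen()] (its
#'   `trio_categories` attribute supplies the per-child categories).
#' @param cohort A `trio_cohort`.
#' @return Character matrix with rownames `gene:chrom:pos:ref>alt` and one
#'   column per child; attribute `genic_region` gives each row's region.
#' @export
category_matrix <- function(candidates, cohort) {
  children <- cohort$trios$child
  num <- suppressWarnings(as.numeric(children))
  children <- if (!any(is.na(num))) children[order(num)] else sort(children)
  tc <- attr(candidates, "trio_categories")
  region_order <- c("promoter", "utr5", "exon", "utr3", "intron",
                    "intergenic")
  if (is.null(tc) || nrow(candidates) == 0L) {
    m <- matrix(character(0), nrow = 0, ncol = length(children),
                dimnames = list(NULL, children))
    attr(m, "genic_region") <- character(0)
    return(m)
  }
  o <- order(match(candidates$genic_region, region_order),
             chrom_rank(candidates$chrom), candidates$pos, candidates$alt,
             candidates$gene)
  cand <- candidates[o, , drop = FALSE]
  key <- function(gene, chrom, pos, ref, alt)
    sprintf("%s:%s:%d:%s>%s", gene, chrom, pos, ref, alt)
  m <- matrix("none", nrow = nrow(cand), ncol = length(children),
              dimnames = list(key(cand$gene, cand$chrom, cand$pos, cand$ref,
                                  cand$alt), children))
  tkey <- key(tc$gene, tc$chrom, tc$pos, tc$ref, tc$alt)
  for (i in seq_len(nrow(tc))) {
    if (tkey[i] %in% rownames(m))
      m[tkey[i], tc$child[i]] <- tc$category[i]
  }
  attr(m, "genic_region") <- cand$genic_region
  m
}

#' Gene-by-function membership matrix
#'
#' Boolean membership of candidate genes in user-supplied function terms
#' (e.g. GO / Reactome annotations provided as a two-column table). No
#' enrichment statistic is computed.
#'
#' @param genes Character vector of (candidate) gene symbols.
#' @param gene_function_table data.frame with columns `gene` and `term`.
#' @return Logical matrix genes x terms.
#' @export
function_membership_matrix <- function(genes, gene_function_table) {
  genes <- unique(genes)
  tab <- gene_function_table[gene_function_table$gene %in% genes, ,
                             drop = FALSE]
  terms <- sort(unique(tab$term))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, terms))
  for (i in seq_len(nrow(tab))) m[tab$gene[i], tab$term[i]] <- TRUE
  m
}

#' Machine-readable run summary
#'
#' @param candidates Candidate data.frame from [run_screen()].
#' @return list (JSON-ready) with per-stage site counts, per-category
#'   candidate counts, per-genic-region counts, and total carrier events.
#' @export
summary_counts <- function(candidates) {
  stage_log <- attr(candidates, "stage_log")
  stages <- as.list(stats::setNames(stage_log$n_sites, stage_log$stage))
  list(stages = stages,
       n_candidates = nrow(candidates),
       by_category = as.list(table(candidates$category)),
       by_genic_region = as.list(table(candidates$genic_region)),
       n_carrier_events = sum(candidates$n_carriers))
}

#' Write a run summary as JSON
#'
#' @param candidates Candidate data.frame from [run_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(candidates, path) {
  jsonlite::write_json(summary_counts(candidates), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write a category or membership matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(row = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
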