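#' Read a gene expression table
#'
#' @param path TSV with header columns `gene` and `rpkm` (brain expression in
#'   RPKM units, e.g. derived from ENCODE tissue data).
#' @return data.frame with `gene` and numeric `rpkm`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("gene", "rpkm") %in% names(tab)))
    stop("expression table needs columns gene, rpkm")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene in expression table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  data.frame(gene = tab$gene, rpkm = as.numeric(tab$rpkm),
             stringsAsFactors = FALSE)
}

#' Read a variant annotation table
#'
#' Consumes the per-site functional annotation produced upstream (ANNOVAR-style
#' protein impact plus TRANSFAC / TargetScanS regulatory-site columns and
#' 1000 Genomes population allele frequencies), keyed by chrom, pos, ref, alt.
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#'   `aa_change`, `impact_score`, `impact_category`, `tf_site`, `mirna_site`,
#'   `af_chinese`, `af_east_asian`. Empty strings or `"NA"` mean absent.
#' @return data.frame with typed columns (`impact_score`, `af_*` numeric).
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "aa_change", "impact_score",
            "impact_category", "tf_site", "mirna_site", "af_chinese",
            "af_east_asian")
  if (!all(need %in% names(tab)))
    stop("annotation table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  out <- tab[, need]
  out$chrom <- sub("^chr", "", out$chrom)
  out$pos <- as.integer(out$pos)
  out$impact_score <- as.numeric(out$impact_score)
  out$af_chinese <- as.numeric(out$af_chinese)
  out$af_east_asian <- as.numeric(out$af_east_asian)
  validate_annotations(out)
  out
}

validate_annotations <- function(ann) {
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key))
    stop("duplicate annotation keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  sc <- ann$impact_score[!is.na(ann$impact_score)]
  if (any(sc < 0 | sc > 1)) stop("impact_score outside [0,1]")
  for (f in c("af_chinese", "af_east_asian")) {
    v <- ann[[f]][!is.na(ann[[f]])]
    if (any(v < 0 | v > 1)) stop(f, " outside [0,1]")
  }
  invisible(ann)
}

#' Read a one-gene-per-line gene-set file
#'
#' @param path Plain text file; lines starting with `#` and blank lines are
#'   ignored.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[lines != "" & !startsWith(lines, "#")])
}

impact_display <- c(benign = "Benign",
                    possibly_damaging = "Possibly damaging",
                    probably_damaging = "Probably damaging",
                    start_loss = "Start codon mutation")
region_display <- c(promoter = "Promoter", utr5 = "5'-UTR", exon = "Exon",
                    utr3 = "3'-UTR", intron = "Intron",
                    intergenic = "Intergenic")

fmt_na <- function(x) {
  out <- as.character(x)
  out[is.na(out) | out == ""] <- "NA"
  out
}

#' Write a candidate report table
#'
#' Emits the candidate SNVs as a TSV in one of two layouts: `"coding"`
#' (SNV id, gene, cytoband, genotype category, alleles, amino-acid change,
#' population allele frequencies, protein-impact category, cohort frequency,
#' carrier samples) or `"regulatory"` (amino-acid columns replaced by genic
#' region and TF/miRNA site). Carrier sample IDs are joined with `"/"`;
#' absent values print as `NA`.
#'
#' @param candidates data.frame of candidates from [run_screen()].
#' @param path Output TSV path.
#' @param style `"coding"` or `"regulatory"`.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path,
                                  style = c("coding", "regulatory")) {
  style <- match.arg(style)
  cat_disp <- fmt_na(unname(impact_display[candidates$impact_category]))
  tfmir <- ifelse(!is.na(candidates$tf_site), candidates$tf_site,
                  candidates$mirna_site)
  if (style == "coding") {
    header <- c("SNV_ID", "Gene", "CytoBand", "Genotype", "Ref", "Alt",
                "AAChange", "X1000g_Chinese", "X1000g_EAST",
                "Polyphen2_HDIV_category", "Frequency_in_cohort", "Sample")
    cols <- cbind(fmt_na(candidates$site_id), candidates$gene,
                  fmt_na(candidates$cytoband), candidates$category,
                  candidates$ref, candidates$alt, fmt_na(candidates$aa_change),
                  fmt_na(candidates$af_chinese), fmt_na(candidates$af_east_asian),
                  cat_disp, candidates$frequency, candidates$carriers)
  } else {
    header <- c("SNV_ID", "Gene", "Cytoband", "Genotype", "Ref", "Alt",
                "X1000g_Chinese", "X1000g_EAST", "Region", "TF/miRNA_Sites",
                "Frequency_in_cohort", "Sample")
    cols <- cbind(fmt_na(candidates$site_id), candidates$gene,
                  fmt_na(candidates$cytoband), candidates$category,
                  candidates$ref, candidates$alt,
                  fmt_na(candidates$af_chinese), fmt_na(candidates$af_east_asian),
                  unname(region_display[candidates$genic_region]),
                  fmt_na(tfmir), candidates$frequency, candidates$carriers)
  }
  lines <- paste(header, collapse = "\t")
  if (nrow(candidates) > 0L)
    lines <- c(lines, apply(cols, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
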