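#' Read a multi-sample cohort VCF into a genotype matrix
#'
#' Reads GT fields for every cohort sample, decomposes multi-allelic records
#' into biallelic SNV rows, drops non-SNV alleles (indels, MNVs) with a
#' logged count, and maps genotypes to alt-allele dosage 0/1/2 (haploid calls
#' map to 0/1; hemizygous normalization is applied later, at classification
#' time, where sex and ploidy context are known). Missing genotypes ("./."
#' or ".") become `NA`.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param cohort A `trio_cohort`; every cohort sample must be a VCF column.
#' @return A `trio_genotypes` object: list with `sites` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`, `site_id`), `geno` (integer matrix, one row
#'   per site, one column per cohort sample, values 0/1/2/NA), and counters
#'   `n_dropped_non_snv`, `n_malformed_gt`.
#' @export
read_cohort_vcf <- function(path, cohort) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT", IDtoRowNames = FALSE)
  samples <- cohort_samples(cohort)
  missing_cols <- setdiff(samples, colnames(gt_raw))
  if (length(missing_cols))
    stop("VCF is missing cohort sample column(s): ",
         paste(missing_cols, collapse = ", "))
  gt_raw <- gt_raw[, samples, drop = FALSE]

  chrom <- sub("^chr", "", fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- "NA"

  n_dropped <- 0L
  n_malformed <- 0L
  site_rows <- list()
  geno_rows <- list()

  for (r in seq_along(pos)) {
    tokens <- strsplit(gsub("|", "/", gt_raw[r, ], fixed = TRUE), "/",
                       fixed = TRUE)
    for (a in seq_along(alts[[r]])) {
      alt <- alts[[r]][a]
      if (nchar(ref[r]) != 1L || nchar(alt) != 1L || alt == ref[r] ||
          !alt %in% c("A", "C", "G", "T")) {
        n_dropped <- n_dropped + 1L
        next
      }
      dose <- vapply(tokens, function(tk) {
        if (length(tk) == 0L || any(!tk %in% c(".", as.character(0:9)))) {
          n_malformed <<- n_malformed + 1L
          return(NA_integer_)
        }
        if (any(tk == ".")) return(NA_integer_)
        sum(tk == as.character(a))
      }, integer(1))
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(chrom = chrom[r], pos = pos[r], ref = ref[r], alt = alt,
                   site_id = ids[r], stringsAsFactors = FALSE)
      geno_rows[[length(geno_rows) + 1L]] <- dose
    }
  }

  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), site_id = character(0))
  geno <- if (length(geno_rows))
    matrix(unlist(geno_rows), nrow = length(geno_rows), byrow = TRUE,
           dimnames = list(NULL, samples))
  else matrix(integer(0), nrow = 0, ncol = length(samples),
              dimnames = list(NULL, samples))

  out <- structure(list(sites = sites, geno = geno,
                        n_dropped_non_snv = n_dropped,
                        n_malformed_gt = n_malformed),
                   class = "trio_genotypes")
  sort_genotypes(out)
}

# Deterministic site order: chromosome (natural order), position, alt.
chrom_rank <- function(chrom) {
  order_levels <- c(as.character(1:22), "X", "Y", "MT")
  r <- match(chrom, order_levels)
  ifelse(is.na(r), length(order_levels) + as.integer(factor(chrom)), r)
}

sort_genotypes <- function(geno_obj) {
  o <- order(chrom_rank(geno_obj$sites$chrom), geno_obj$sites$pos,
             geno_obj$sites$alt)
  geno_obj$sites <- geno_obj$sites[o, , drop = FALSE]
  rownames(geno_obj$sites) <- NULL
  geno_obj$geno <- geno_obj$geno[o, , drop = FALSE]
  geno_obj
}

#' @export
print.trio_genotypes <- function(x, ...) {
  cat("trio_genotypes:", nrow(x$sites), "SNV sites x", ncol(x$geno),
      "samples (", x$n_dropped_non_snv, "non-SNV alleles dropped )\n")
  invisible(x)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' Emits a plain-text VCF 4.2 file with a GT-only FORMAT. Sites on the X
#' chromosome are written haploid for male samples (hemizygous convention);
#' all other genotypes are unphased diploid. Rows already decomposed to
#' biallelic SNVs are written one per record.
#'
#' @param geno_obj A `trio_genotypes` object.
#' @param cohort The matching `trio_cohort` (for sample sex).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(geno_obj, cohort, path, contig_lengths = NULL) {
  samples <- colnames(geno_obj$geno)
  header <- c("##fileformat=VCFv4.2",
              "##source=trioscreen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths), contig_lengths))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  male <- cohort$sex[samples] == "male"
  gt_string <- function(dose, haploid) {
    if (haploid) {
      if (is.na(dose)) "." else if (dose >= 1L) "1" else "0"
    } else {
      if (is.na(dose)) "./." else c("0/0", "0/1", "1/1")[dose + 1L]
    }
  }
  body <- vapply(seq_len(nrow(geno_obj$sites)), function(r) {
    s <- geno_obj$sites[r, ]
    hap <- male & s$chrom %in% c("X", "Y")
    gts <- vapply(seq_along(samples), function(j)
      gt_string(geno_obj$geno[r, j], hap[j]), character(1))
    paste(c(s$chrom, s$pos, s$site_id, s$ref, s$alt, ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
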