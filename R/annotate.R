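#' Bin a protein-damage score into an impact category
#'
#' Applies the published PolyPhen-2 HDIV convention: scores at or below 0.452
#' are benign, scores above 0.452 up to 0.956 possibly damaging, scores above
#' 0.956 probably damaging. Used only when the annotation table supplies a
#' score without a category.
#'
#' @param score Numeric score(s) in \[0, 1\].
#' @return Character vector of `"benign"`, `"possibly_damaging"`,
#'   `"probably_damaging"`.
#' @export
impact_category_from_score <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("impact score outside [0,1]")
  ifelse(score <= 0.452, "benign",
         ifelse(score <= 0.956, "possibly_damaging", "probably_damaging"))
}

# Parse "p.M1V" into list(ref, pos, alt); NULL when unparseable.
parse_aa_change <- function(aa_change) {
  if (is.na(aa_change) || aa_change == "") return(NULL)
  m <- regmatches(aa_change,
                  regexec("^p\\.([A-Z*])([0-9]+)([A-Z*])$", aa_change))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(ref = m[2L], pos = as.integer(m[3L]), alt = m[4L])
}

#' Apply the start-codon-loss override to candidate impact categories
#'
#' A substitution of the initiator methionine (amino-acid change at protein
#' position 1 from M to anything else) abolishes or truncates translation
#' regardless of its missense damage score, so `start_loss` supersedes any
#' score-derived category. Candidates whose `aa_change` cannot be parsed as
#' `p.<ref><pos><alt>` are left unchanged with a warning.
#'
#' @param candidates data.frame with `aa_change` and `impact_category`
#'   columns.
#' @return The data.frame with `impact_category` set to `"start_loss"` where
#'   the override triggers.
#' @export
apply_start_loss_override <- function(candidates) {
  for (i in seq_len(nrow(candidates))) {
    aa <- candidates$aa_change[i]
    if (is.na(aa) || aa == "") next
    p <- parse_aa_change(aa)
    if (is.null(p)) {
      warning("unparseable amino-acid change, no start-loss check: ", aa)
      next
    }
    if (p$pos == 1L && p$ref == "M" && p$alt != "M")
      candidates$impact_category[i] <- "start_loss"
  }
  candidates
}

#' Join an annotation table onto candidates
#'
#' Left join by (chrom, pos, ref, alt): every candidate is retained;
#' unmatched candidates carry empty annotation fields. Duplicate annotation
#' keys are fatal (they would make the join ambiguous).
#'
#' @param candidates data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param annotations data.frame from [read_annotations()], or `NULL`.
#' @return `candidates` with columns `aa_change`, `impact_score`,
#'   `impact_category`, `tf_site`, `mirna_site`, `af_chinese`,
#'   `af_east_asian` attached.
#' @export
join_annotations <- function(candidates, annotations = NULL) {
  ann_cols <- c("aa_change", "impact_score", "impact_category", "tf_site",
                "mirna_site", "af_chinese", "af_east_asian")
  if (is.null(annotations) || nrow(candidates) == 0L) {
    for (cl in ann_cols)
      candidates[[cl]] <- rep(
        if (cl == "impact_score" || startsWith(cl, "af_")) NA_real_
        else NA_character_, nrow(candidates))
    return(candidates)
  }
  validate_annotations(annotations)
  key_c <- paste(candidates$chrom, candidates$pos, candidates$ref,
                 candidates$alt)
  key_a <- paste(annotations$chrom, annotations$pos, annotations$ref,
                 annotations$alt)
  idx <- match(key_c, key_a)
  for (cl in ann_cols) candidates[[cl]] <- annotations[[cl]][idx]
  # derive a category from the score where none was supplied directly
  derive <- is.na(candidates$impact_category) &
    !is.na(candidates$impact_score)
  if (any(derive))
    candidates$impact_category[derive] <-
      impact_category_from_score(candidates$impact_score[derive])
  candidates
}

#' Regulatory-site impact of candidates
#'
#' A TF-motif annotation counts only for promoter candidates and a
#' miRNA-site annotation only for 3'-UTR candidates (that is where the
#' corresponding cis-elements act). Site annotations found outside the
#' matching genic region are kept but flagged inconsistent rather than
#' silently dropped.
#'
#' @param candidates data.frame with `genic_region`, `tf_site`, `mirna_site`.
#' @return `candidates` with `regulatory_impact` (`"tf_site_hit"`,
#'   `"mirna_site_hit"` or `"none"`) and logical
#'   `regulatory_inconsistent` columns.
#' @export
regulatory_impact <- function(candidates) {
  tf <- !is.na(candidates$tf_site)
  mir <- !is.na(candidates$mirna_site)
  promoter <- candidates$genic_region == "promoter"
  utr3 <- candidates$genic_region == "utr3"
  candidates$regulatory_impact <-
    ifelse(tf & promoter, "tf_site_hit",
           ifelse(mir & utr3, "mirna_site_hit", "none"))
  candidates$regulatory_inconsistent <- (tf & !promoter) | (mir & !utr3)
  candidates
}
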