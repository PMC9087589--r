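#' Classify one trio's genotypes at a single site
#'
#' Maps a (child, mother, father) alt-allele dosage triple to one of the
#' single-site genotype categories used throughout the screen:
#'
#' * `hetero_gain` — child heterozygous, neither parent carries the allele
#'   (a de novo heterozygote);
#' * `homo_inherit` — child homozygous alternate with both parents
#'   heterozygous carriers;
#' * `homo_gain` — child homozygous alternate with at least one parent
#'   carrying zero alternate alleles, so at least one child allele cannot be
#'   attributed to a parent;
#' * `none` — every other combination (no alt in the child, ordinarily
#'   inherited genotypes, other Mendelian inconsistencies, or any missing
#'   dosage).
#'
#' On the non-pseudoautosomal X of a male child the genotype is hemizygous:
#' any alt call is normalized to dosage 2, the father's X is ignored, and the
#' mother alone determines gain (`mother = 0`) versus inheritance
#' (`mother >= 1`).
#'
#' Compound heterozygotes are a gene-level call and are never produced here;
#' see [find_compound_het()].
#'
#' @param child,mother,father Alt-allele dosages in `0:2`, or `NA` for a
#'   missing genotype.
#' @param child_sex `"male"`, `"female"` or `"unknown"`.
#' @param context Ploidy context: `"autosomal"`, `"x_nonpar"`, `"y"` or
#'   `"mito"`. Sites on `y`/`mito` are not classified (always `none`).
#' @return list with `category` (character), `reason` (why `none`, else
#'   `NA`), and `flags` (character vector; e.g. `"double_de_novo"` when a
#'   hom-alt child has two non-carrier parents, `"mendelian_error"` for
#'   unclassified inconsistent combinations).
#' @export
classify_site <- function(child, mother, father, child_sex = "unknown",
                          context = "autosomal") {
  ok <- function(x) is.na(x) || (is.numeric(x) && x %in% 0:2)
  if (!ok(child) || !ok(mother) || !ok(father))
    stop("invalid dosage value; expected 0, 1, 2 or NA")
  none <- function(reason, flags = character(0))
    list(category = "none", reason = reason, flags = flags)
  hit <- function(category, flags = character(0))
    list(category = category, reason = NA_character_, flags = flags)

  if (context %in% c("y", "mito")) return(none("unsupported_ploidy"))

  if (context == "x_nonpar" && identical(child_sex, "male")) {
    # hemizygous child: any alt call counts as a full (normalized 2) genotype
    if (is.na(child) || is.na(mother)) return(none("missing"))
    child <- normalize_hemizygous(child)
    if (child == 0L) return(none("no_alt_in_child"))
    if (mother == 0L) return(hit("homo_gain", "hemizygous"))
    return(hit("homo_inherit", "hemizygous"))
  }

  if (is.na(child) || is.na(mother) || is.na(father)) return(none("missing"))
  if (child == 0L) return(none("no_alt_in_child"))
  if (child == 1L) {
    if (mother == 0L && father == 0L) return(hit("hetero_gain"))
    if (mother == 2L && father == 2L) return(none("inherited", "mendelian_error"))
    return(none("inherited"))
  }
  # child == 2
  if (mother == 1L && father == 1L) return(hit("homo_inherit"))
  if (mother == 0L || father == 0L) {
    flags <- if (mother == 0L && father == 0L) "double_de_novo" else character(0)
    return(hit("homo_gain", flags))
  }
  none("inherited")
}

#' Normalize a hemizygous genotype call to diploid-equivalent dosage
#'
#' A male X (non-PAR) call carrying any alternate allele represents the whole
#' genotype; it is recorded as dosage 2 so downstream homozygote logic
#' applies unchanged.
#'
#' @param dosage Raw dosage 0/1/2 or `NA`.
#' @return 0, 2 or `NA`.
#' @export
normalize_hemizygous <- function(dosage) {
  ifelse(is.na(dosage), NA_integer_, ifelse(dosage >= 1L, 2L, 0L))
}

#' Parental origin of a child's alternate allele
#'
#' @param child,mother,father Alt-allele dosages (child must carry the
#'   allele: dosage >= 1).
#' @return One of `"maternal"`, `"paternal"`, `"de_novo"`, `"ambiguous"`.
#' @export
call_origin <- function(child, mother, father) {
  if (is.na(child) || child < 1L) stop("call_origin requires child dosage >= 1")
  if (is.na(mother) || is.na(father)) return("ambiguous")
  m <- mother >= 1L; f <- father >= 1L
  if (m && !f) "maternal" else if (f && !m) "paternal" else if (!m && !f)
    "de_novo" else "ambiguous"
}

#' Gene-level compound heterozygote detection
#'
#' Given the child-heterozygous sites of one trio inside one gene, returns
#' the site pairs compatible with a compound heterozygote in which at least
#' one member arose de novo: origins must not be both maternal and not both
#' paternal (trans-compatible), and at least one member must have origin
#' `de_novo`. Pairs containing a member of ambiguous origin cannot be
#' phased by pedigree alone; they are retained and flagged
#' `phase_uncertain`.
#'
#' @param origins Character vector of [call_origin()] results, one per
#'   child-het site in the gene.
#' @param require_de_novo If `FALSE`, purely inherited trans pairs
#'   (maternal + paternal) are also reported.
#' @return data.frame with columns `a`, `b` (indices into `origins`) and
#'   logical `phase_uncertain`; zero rows when no pair qualifies.
#' @export
find_compound_het <- function(origins, require_de_novo = TRUE) {
  empty <- data.frame(a = integer(0), b = integer(0),
                      phase_uncertain = logical(0))
  n <- length(origins)
  if (n < 2L) return(empty)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      oi <- origins[i]; oj <- origins[j]
      if (oi == "maternal" && oj == "maternal") next
      if (oi == "paternal" && oj == "paternal") next
      if (require_de_novo && !("de_novo" %in% c(oi, oj))) next
      rows[[length(rows) + 1L]] <- data.frame(
        a = i, b = j,
        phase_uncertain = "ambiguous" %in% c(oi, oj))
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# Ploidy context of a chromosome (PAR handling out of scope: the whole X is
# treated as non-PAR).
ploidy_context <- function(chrom) {
  ifelse(chrom == "X", "x_nonpar",
         ifelse(chrom == "Y", "y",
                ifelse(chrom %in% c("MT", "M"), "mito", "autosomal")))
}
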