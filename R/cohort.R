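#' Read a pedigree file into a trio cohort model
#'
#' Parses a 6-column PED file (family, individual, father, mother, sex,
#' phenotype) and assembles parent-offspring trios. The cohort design this
#' package screens requires every child to be affected and both parents to be
#' present and unaffected; any deviation is a fatal error, not a warning,
#' because the downstream parent-exclusion filter is meaningless otherwise.
#'
#' @param path Path to a whitespace-delimited PED file. Sex coded 1 = male,
#'   2 = female, 0 = unknown; phenotype coded 2 = affected, 1 = unaffected.
#' @return A `trio_cohort` object: a list with `trios` (data.frame with
#'   columns `family`, `child`, `mother`, `father`), `sex` (named character
#'   vector over all samples, values `"male"`, `"female"`, `"unknown"`) and
#'   `affected` (named character vector, values `"affected"`, `"unaffected"`).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  if (nrow(ped) == 0L) stop("no trios: pedigree file is empty")
  if (anyDuplicated(ped$id))
    stop("duplicate individual in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  build_cohort(ped)
}

build_cohort <- function(ped) {
  is_child <- ped$father != "0" & ped$mother != "0"
  children <- ped[is_child, , drop = FALSE]
  if (nrow(children) == 0L) stop("no trios: no individual has two parents")
  missing_parent <- !(children$father %in% ped$id) | !(children$mother %in% ped$id)
  if (any(missing_parent))
    stop("child with <2 parents in file: ",
         paste(children$id[missing_parent], collapse = ", "))

  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown")
  sex <- unname(sex_map[ped$sex])
  sex[is.na(sex)] <- "unknown"
  names(sex) <- ped$id

  aff <- ifelse(ped$phenotype == "2", "affected", "unaffected")
  names(aff) <- ped$id

  if (any(aff[children$id] != "affected"))
    stop("trio child is not affected: ",
         paste(children$id[aff[children$id] != "affected"], collapse = ", "))
  parents <- unique(c(children$father, children$mother))
  if (any(aff[parents] != "unaffected"))
    stop("affected parent found (", paste(parents[aff[parents] != "unaffected"],
                                          collapse = ", "),
         "): each trio must consist of an affected child and ",
         "his/her unaffected parents")

  role_count <- table(c(children$id, children$father, children$mother))
  if (any(role_count > 1L))
    stop("sample appears in more than one trio/role: ",
         paste(names(role_count)[role_count > 1L], collapse = ", "))
  extras <- setdiff(ped$id, names(role_count))
  if (length(extras))
    stop("samples outside any trio: ", paste(extras, collapse = ", "))

  trios <- data.frame(family = children$family, child = children$id,
                      mother = children$mother, father = children$father,
                      stringsAsFactors = FALSE)
  structure(list(trios = trios, sex = sex, affected = aff),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", nrow(x$trios), "trios,",
      3L * nrow(x$trios), "samples\n")
  invisible(x)
}

#' All sample identifiers of a cohort
#'
#' @param cohort A `trio_cohort`.
#' @return Character vector of child, mother and father IDs (children first).
#' @export
cohort_samples <- function(cohort) {
  c(cohort$trios$child, cohort$trios$mother, cohort$trios$father)
}

#' Number of trios in a cohort
#' @param cohort A `trio_cohort`.
#' @return Integer count of trios.
#' @export
n_trios <- function(cohort) nrow(cohort$trios)

#' Write a cohort back to PED format
#'
#' @param cohort A `trio_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(cohort, path) {
  tr <- cohort$trios
  sex_code <- c(male = "1", female = "2", unknown = "0")
  row_for <- function(id, father, mother, pheno) {
    fam <- tr$family[match(id, tr$child)]
    if (is.na(fam)) {
      idx <- which(tr$mother == id | tr$father == id)[1L]
      fam <- tr$family[idx]
    }
    paste(fam, id, father, mother, sex_code[[cohort$sex[[id]]]], pheno,
          sep = "\t")
  }
  lines <- character(0)
  for (i in seq_len(nrow(tr))) {
    lines <- c(lines,
               row_for(tr$father[i], "0", "0", "1"),
               row_for(tr$mother[i], "0", "0", "1"),
               row_for(tr$child[i], tr$father[i], tr$mother[i], "2"))
  }
  writeLines(lines, path)
  invisible(path)
}
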