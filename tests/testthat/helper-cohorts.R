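# Shared helpers: tiny cohorts and genotype objects built in code.

# A minimal cohort of n trios with children "1".."n" (odd-indexed children
# male), written through PED and re-read so the reader is on the hot path.
mini_cohort <- function(n = 3L) {
  children <- as.character(seq_len(n))
  mothers <- as.character(n + seq_len(n))
  fathers <- as.character(2L * n + seq_len(n))
  lines <- unlist(lapply(seq_len(n), function(i) c(
    sprintf("F%02d\t%s\t0\t0\t1\t1", i, fathers[i]),
    sprintf("F%02d\t%s\t0\t0\t2\t1", i, mothers[i]),
    sprintf("F%02d\t%s\t%s\t%s\t%d\t2", i, children[i], fathers[i],
            mothers[i], if (i %% 2L == 1L) 1L else 2L))))
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  read_pedigree(path)
}

# Genotype object from a site table and a dosage matrix (samples in cohort
# order: children, mothers, fathers).
mini_geno <- function(sites, dose, cohort) {
  m <- matrix(as.integer(dose), nrow = nrow(sites),
              dimnames = list(NULL, cohort_samples(cohort)))
  trioscreen:::sort_genotypes(structure(
    list(sites = sites, geno = m, n_dropped_non_snv = 0L,
         n_malformed_gt = 0L), class = "trio_genotypes"))
}

site_row <- function(chrom, pos, ref = "A", alt = "G", id = "NA") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             site_id = id, stringsAsFactors = FALSE)
}

# One-gene model table (UCSC dialect) read through the parser: a 20 kb gene
# with three exons and CDS rel 1001..18000, starting at tx_start.
mini_gene_models <- function(gene = "GENE1", chrom = "16",
                             tx_start = 405000L, strand = "+") {
  s0 <- tx_start - 1L  # 0-based
  tsv <- c("gene\tchrom\tstrand\ttxStart\ttxEnd\tcdsStart\tcdsEnd\texonStarts\texonEnds",
           sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d,%d,%d,\t%d,%d,%d,",
                   gene, chrom, strand, s0, s0 + 20000L, s0 + 1000L,
                   s0 + 18000L, s0, s0 + 6000L, s0 + 16000L,
                   s0 + 2000L, s0 + 10000L, s0 + 20000L))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(tsv, path)
  read_gene_models(path)
}

mini_expression <- function(genes, rpkm = 5) {
  data.frame(gene = genes, rpkm = rep_len(rpkm, length(genes)),
             stringsAsFactors = FALSE)
}

screen_truth_check <- function(bundle, candidates) {
  tt <- bundle$truth
  surv <- tt[tt$expected_to_survive, ]
  key <- function(d) paste(d$chrom, d$pos, d$alt, d$gene)
  m <- match(key(surv), key(candidates))
  list(
    recovered = setequal(key(surv), key(candidates)) && !anyNA(m),
    categories_ok = !anyNA(m) &&
      all(surv$expected_category == candidates$category[m]),
    carriers_ok = !anyNA(m) && all(surv$carriers == candidates$carriers[m]))
}
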