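#' Read a gene-model table
#'
#' Consumes a refGene-like TSV with header columns `gene`, `chrom`, `strand`,
#' `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exonStarts`, `exonEnds` where
#' coordinates are 0-based half-open and exon columns are comma-separated
#' lists (UCSC dialect). Internally everything is converted to 1-based closed
#' coordinates.
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per transcript model: `gene`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end` and list-columns
#'   `exon_starts`, `exon_ends`. A non-coding model has `cds_start` > `cds_end`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("gene", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonStarts", "exonEnds")
  if (!all(need %in% names(tab)))
    stop("gene-model table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  parse_list <- function(x) lapply(strsplit(x, ","), function(v)
    as.integer(v[v != ""]))
  out <- data.frame(gene = tab$gene,
                    chrom = sub("^chr", "", tab$chrom),
                    strand = tab$strand,
                    tx_start = as.integer(tab$txStart) + 1L,
                    tx_end = as.integer(tab$txEnd),
                    cds_start = as.integer(tab$cdsStart) + 1L,
                    cds_end = as.integer(tab$cdsEnd),
                    stringsAsFactors = FALSE)
  out$exon_starts <- lapply(parse_list(tab$exonStarts), function(v) v + 1L)
  out$exon_ends <- parse_list(tab$exonEnds)
  validate_gene_models(out)
  out
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    if (models$tx_start[i] > models$tx_end[i])
      stop("gene ", models$gene[i], ": txStart >= txEnd")
    if (length(es) != length(ee) || any(es > ee))
      stop("gene ", models$gene[i], ": malformed exon spans")
    if (is.unsorted(es, strictly = TRUE) ||
        any(utils::head(ee, -1L) >= utils::tail(es, -1L)))
      stop("gene ", models$gene[i], ": exons overlap or are unsorted")
    coding <- models$cds_start[i] <= models$cds_end[i]
    if (coding && (models$cds_start[i] < models$tx_start[i] ||
                   models$cds_end[i] > models$tx_end[i]))
      stop("gene ", models$gene[i], ": CDS outside transcript span")
  }
  invisible(models)
}

#' Write gene models back to the UCSC-dialect TSV
#'
#' @param models data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- c(paste(c("gene", "chrom", "strand", "txStart", "txEnd",
                     "cdsStart", "cdsEnd", "exonStarts", "exonEnds"),
                   collapse = "\t"))
  for (i in seq_len(nrow(models))) {
    lines <- c(lines, paste(
      models$gene[i], models$chrom[i], models$strand[i],
      models$tx_start[i] - 1L, models$tx_end[i],
      models$cds_start[i] - 1L, models$cds_end[i],
      paste0(paste(models$exon_starts[[i]] - 1L, collapse = ","), ","),
      paste0(paste(models$exon_ends[[i]], collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assign a genic region to a position relative to one gene model
#'
#' Strand-aware assignment into promoter / 5'-UTR / coding exon / 3'-UTR /
#' intron / intergenic. The promoter is the `promoter_len` bases immediately
#' upstream of the transcription start site (downstream of `tx_end` on the
#' minus strand). When features would overlap, precedence is
#' exon > utr5 > utr3 > promoter > intron > intergenic.
#'
#' @param pos 1-based position(s) on the model's chromosome.
#' @param model One row of a gene-model data.frame.
#' @param promoter_len Promoter window length in bases upstream of the TSS
#'   (default 1000).
#' @return Character vector over `pos` with values in
#'   `c("promoter","utr5","exon","utr3","intron","intergenic")`.
#' @export
assign_genic_region <- function(pos, model, promoter_len = 1000L) {
  stopifnot(nrow(model) == 1L)
  es <- model$exon_starts[[1L]]; ee <- model$exon_ends[[1L]]
  plus <- model$strand == "+"
  coding <- model$cds_start <= model$cds_end
  vapply(pos, function(p) {
    in_tx <- p >= model$tx_start && p <= model$tx_end
    in_exon <- any(p >= es & p <= ee)
    if (in_exon) {
      if (!coding) return("exon")
      if (p >= model$cds_start && p <= model$cds_end) return("exon")
      upstream_of_cds <- if (plus) p < model$cds_start else p > model$cds_end
      return(if (upstream_of_cds) "utr5" else "utr3")
    }
    if (in_tx) return("intron")
    in_promoter <- if (plus)
      p >= model$tx_start - promoter_len && p < model$tx_start
    else
      p > model$tx_end && p <= model$tx_end + promoter_len
    if (in_promoter) return("promoter")
    "intergenic"
  }, character(1))
}

# Genes whose promoter-extended span contains each position; returns a
# data.frame of (site index, gene-model row index) pairs.
map_sites_to_genes <- function(chrom, pos, models, promoter_len = 1000L) {
  lo <- ifelse(models$strand == "+", models$tx_start - promoter_len,
               models$tx_start)
  hi <- ifelse(models$strand == "+", models$tx_end,
               models$tx_end + promoter_len)
  pairs <- lapply(seq_len(nrow(models)), function(g) {
    hit <- which(chrom == models$chrom[g] & pos >= lo[g] & pos <= hi[g])
    if (length(hit) == 0L) return(NULL)
    data.frame(site = hit, gene_row = g)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) data.frame(site = integer(0), gene_row = integer(0))
  else out[order(out$site, out$gene_row), , drop = FALSE]
}
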