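#' Read a UCSC-style cytoband table
#'
#' Consumes the UCSC `cytoBand` schema: chrom, chromStart, chromEnd, name
#' (band without chromosome prefix), and optionally gieStain. Coordinates in
#' the file are 0-based half-open and are converted to the 1-based closed
#' convention used internally (GenomicRanges).
#'
#' @param path Path to a tab-separated cytoband table (4 or 5 columns, no
#'   header).
#' @return data.frame with columns `chrom` (no "chr" prefix), `start`, `end`
#'   (1-based closed) and `band` (e.g. `"p13.3"`).
#' @export
read_cytobands <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 4L) stop("cytoband table needs >= 4 columns")
  data.frame(chrom = sub("^chr", "", tab[[1L]]),
             start = as.integer(tab[[2L]]) + 1L,
             end = as.integer(tab[[3L]]),
             band = tab[[4L]],
             stringsAsFactors = FALSE)
}

# Parse a band label "p13.2" into arm / major / sub components.
parse_band <- function(band) {
  m <- regmatches(band, regexec("^([pq])([0-9]+)(?:\\.([0-9]+))?$", band))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(arm = m[2L], major = as.integer(m[3L]),
       sub = if (m[4L] == "") NA_character_ else m[4L])
}

# Parse a query like "16p13", "4p16.1" or "5p12-13" into chrom/arm/major
# range/sub.
parse_band_query <- function(name) {
  m <- regmatches(name,
    regexec("^([0-9XY]+|MT)([pq])([0-9]+)(?:\\.([0-9]+))?(?:-([0-9]+)(?:\\.([0-9]+))?)?$",
            name))[[1L]]
  if (length(m) == 0L) return(NULL)
  lo <- as.integer(m[4L])
  hi <- if (m[6L] == "") lo else as.integer(m[6L])
  list(chrom = m[2L], arm = m[3L],
       major_lo = lo, major_hi = hi,
       sub = if (m[5L] == "" || m[6L] != "") NA_character_ else m[5L])
}

#' Resolve cytoband names to a merged genomic region set
#'
#' A coarse name such as `"16p13"` matches every sub-band with that major
#' number (16p13.11 ... 16p13.3); a fully qualified name such as `"4p16.1"`
#' matches only that sub-band; a range such as `"5p12-13"` expands to every
#' band from 5p12 through 5p13.* inclusive. Resolved intervals are merged
#' per chromosome.
#'
#' @param band_names Character vector of band names.
#' @param cytobands data.frame from [read_cytobands()].
#' @return A [GenomicRanges::GRanges] with merged, non-overlapping intervals;
#'   the originating band names are kept in `metadata(x)$bands`.
#' @export
resolve_bands <- function(band_names, cytobands) {
  if (length(band_names) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$bands <- character(0)
    return(gr)
  }
  parsed <- lapply(cytobands$band, parse_band)
  hits_list <- lapply(band_names, function(name) {
    q <- parse_band_query(name)
    if (is.null(q)) stop("unresolvable band name: ", name)
    hit <- vapply(seq_len(nrow(cytobands)), function(i) {
      p <- parsed[[i]]
      if (is.null(p)) return(FALSE)
      if (cytobands$chrom[i] != q$chrom || p$arm != q$arm) return(FALSE)
      if (p$major < q$major_lo || p$major > q$major_hi) return(FALSE)
      if (!is.na(q$sub)) {
        # fully qualified query: match the sub-band and its subdivisions
        if (is.na(p$sub)) return(FALSE)
        if (!(p$sub == q$sub || startsWith(p$sub, q$sub))) return(FALSE)
      }
      TRUE
    }, logical(1))
    if (!any(hit)) stop("unknown band name: ", name)
    which(hit)
  })
  idx <- sort(unique(unlist(hits_list)))
  gr <- GenomicRanges::GRanges(
    seqnames = cytobands$chrom[idx],
    ranges = IRanges::IRanges(start = cytobands$start[idx],
                              end = cytobands$end[idx]))
  gr <- GenomicRanges::reduce(gr)
  S4Vectors::metadata(gr)$bands <- band_names
  gr
}

#' Cytoband label for genomic positions
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param cytobands data.frame from [read_cytobands()].
#' @return Character vector of full band names (e.g. `"16p13.3"`), `NA` where
#'   no band contains the position.
#' @export
cytoband_of <- function(chrom, pos, cytobands) {
  vapply(seq_along(pos), function(i) {
    hit <- cytobands$chrom == chrom[i] &
      cytobands$start <= pos[i] & cytobands$end >= pos[i]
    if (!any(hit)) return(NA_character_)
    paste0(cytobands$chrom[which(hit)[1L]], cytobands$band[which(hit)[1L]])
  }, character(1))
}

# TRUE for positions falling inside the region set.
in_region_set <- function(chrom, pos, region_set) {
  if (is.null(region_set) || length(region_set) == 0L)
    return(rep(FALSE, length(pos)))
  # share one seqlevel set so findOverlaps does not warn when the query
  # carries chromosomes absent from the region set (those simply miss)
  lv <- union(unique(as.character(chrom)),
              GenomeInfoDb::seqlevels(region_set))
  q <- GenomicRanges::GRanges(seqnames = factor(chrom, levels = lv),
                              ranges = IRanges::IRanges(start = pos, end = pos))
  s <- region_set
  GenomeInfoDb::seqlevels(s) <- lv
  IRanges::overlapsAny(q, s)
}
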