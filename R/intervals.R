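#' Read repeat or gene annotation intervals
#'
#' Reads BED (0-based, half-open) or GFF3 (1-based, closed) intervals into a
#' [GenomicRanges::GRanges] using the usual R convention (1-based, closed),
#' so the two dialects are converted exactly once, at the boundary. The
#' returned ranges carry a `category` metadata column.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @param category tag stored in `mcols(gr)$category`, typically `"repeat"`
#'   or `"gene"`.
#' @return a `GRanges`; gene identifiers (GFF3 `ID=` attribute or a
#'   synthesized `bed_<i>`) are kept in `mcols(gr)$feature_id`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3"),
                           category = "feature") {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = paste0("V", 1:12)[1:max(3, count_bed_cols(path))],
                      fill = TRUE)
    start0 <- suppressWarnings(as.numeric(tab$V2))
    end0 <- suppressWarnings(as.numeric(tab$V3))
    if (anyNA(start0) || anyNA(end0))
      stop2("BED parse error: non-numeric coordinates")
    if (any(start0 < 0)) stop2("BED parse error: negative coordinates")
    if (any(end0 <= start0))
      stop2("BED parse error: end <= start at line %d",
            which(end0 <= start0)[1])
    gr <- GenomicRanges::GRanges(tab$V1,
                                 IRanges::IRanges(start = start0 + 1,
                                                  end = end0))
    ids <- if ("V4" %in% names(tab) && any(nzchar(tab$V4) & !is.na(tab$V4)))
      as.character(tab$V4) else paste0("bed_", seq_along(gr))
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      quote = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 9) stop2("GFF3 parse error: expected 9 columns")
    start1 <- suppressWarnings(as.numeric(tab[[4]]))
    end1 <- suppressWarnings(as.numeric(tab[[5]]))
    if (anyNA(start1) || anyNA(end1))
      stop2("GFF3 parse error: non-numeric coordinates")
    if (any(start1 < 1)) stop2("GFF3 parse error: coordinates must be >= 1")
    if (any(end1 < start1))
      stop2("GFF3 parse error: end < start at line %d",
            which(end1 < start1)[1])
    gr <- GenomicRanges::GRanges(tab[[1]],
                                 IRanges::IRanges(start = start1, end = end1))
    ids <- sub(".*ID=([^;]+).*", "\\1", tab[[9]])
    ids[!grepl("ID=", tab[[9]])] <- paste0("gff_", which(!grepl("ID=", tab[[9]])))
  }
  S4Vectors::mcols(gr)$category <- category
  S4Vectors::mcols(gr)$feature_id <- ids
  gr
}

#' Point-in-interval membership for variant positions
#'
#' @param chrom,pos vectors of sequence name and 1-based position.
#' @param intervals a `GRanges` (from [read_intervals()]).
#' @return logical vector: does each position fall inside any interval.
#' @export
positions_in_intervals <- function(chrom, pos, intervals) {
  if (length(pos) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, intervals, ignore.strand = TRUE) > 0
}

# feature ids of intervals hit by each position (list parallel to pos)
features_at_positions <- function(chrom, pos, intervals) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, intervals, ignore.strand = TRUE)
  ids <- S4Vectors::mcols(intervals)$feature_id
  unique(ids[S4Vectors::subjectHits(hits)])
}

count_bed_cols <- function(path) {
  l <- readLines(path, n = 50)
  l <- l[nzchar(l) & !startsWith(l, "#")]
  if (!length(l)) return(3L)
  max(lengths(strsplit(l, "[ \t]+")))
}

#' Write intervals to BED or GFF3
#'
#' Inverse of [read_intervals()]; used by the synthetic-annotation
#' generator. BED output is 0-based half-open; GFF3 is 1-based closed.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param format `"bed"` or `"gff3"`.
#' @param source,type GFF3 source and type columns.
#' @export
write_intervals <- function(gr, path, format = c("bed", "gff3"),
                            source = "polyplex", type = "gene") {
  format <- match.arg(format)
  ids <- S4Vectors::mcols(gr)$feature_id %||%
    paste0("feat_", seq_along(gr))
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                     ids)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                       as.character(GenomicRanges::seqnames(gr)), source,
                       type, GenomicRanges::start(gr),
                       GenomicRanges::end(gr), ids))
  }
  writeLines(lines, path)
  invisible(path)
}
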