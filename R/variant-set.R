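#' Columnar container for multi-sample variant calls
#'
#' A `variant_set` holds one row per VCF site together with the per-sample
#' genotype (`GT`) and allele-depth (`AD`) calls, in a columnar layout so the
#' filter, ploidy and population-genetic stages can operate on whole matrices.
#' Genotypes are kept verbatim as VCF genotype strings (`"0/1"`,
#' `"0/0/1/1"`, `"./."`), which is what makes mixed-ploidy cohorts — diploids
#' next to tetraploids and hexaploids — representable in one object.
#'
#' @param chrom character vector of sequence names.
#' @param pos 1-based positions (integer).
#' @param ref,alt reference allele and comma-collapsed alternate alleles.
#' @param qual site quality (QUAL), `NA` allowed.
#' @param info data.frame (or NULL) with numeric site annotations; the
#'   filtering stage looks for `MQ`, `QD`, `FS`, `MQRankSum`,
#'   `ReadPosRankSum`, `SOR` and `DP`.
#' @param gt character matrix, sites x samples, of VCF genotype strings.
#' @param ad character matrix of comma-separated allele depths aligned to
#'   `[ref] + alts`, or `NA` where AD was not emitted.
#' @param samples sample names (column names of `gt`).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, gt, ad = NULL, qual = NA_real_,
                        info = NULL, samples = colnames(gt)) {
  n <- length(pos)
  gt <- as.matrix(gt)
  if (is.null(samples)) stop2("sample names are required (colnames of gt)")
  if (anyDuplicated(samples)) stop2("duplicated sample names")
  if (length(chrom) == 1L) chrom <- rep_len(chrom, n)
  if (length(ref) == 1L) ref <- rep_len(ref, n)
  if (length(alt) == 1L) alt <- rep_len(alt, n)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(gt) == n, ncol(gt) == length(samples))
  if (any(pos < 1)) stop2("positions must be >= 1")
  if (is.null(ad)) ad <- matrix(NA_character_, n, length(samples))
  ad <- as.matrix(ad)
  stopifnot(nrow(ad) == n, ncol(ad) == ncol(gt))
  qual <- rep_len(as.numeric(qual), n)
  info_cols <- c("MQ", "QD", "FS", "MQRankSum", "ReadPosRankSum", "SOR", "DP")
  if (is.null(info)) {
    info <- as.data.frame(setNames(
      rep(list(rep(NA_real_, n)), length(info_cols)), info_cols))
  } else {
    info <- as.data.frame(info)
    stopifnot(nrow(info) == n)
    for (k in setdiff(info_cols, names(info))) info[[k]] <- NA_real_
  }
  dimnames(gt) <- dimnames(ad) <- list(NULL, samples)
  structure(list(
    meta = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      ref = as.character(ref), alt = as.character(alt),
                      qual = qual, stringsAsFactors = FALSE),
    info = info, gt = gt, ad = ad, samples = as.character(samples)
  ), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples\n", n_sites(x),
              length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  if (n_sites(x) > 0) {
    cat(sprintf("seqnames: %s; biallelic sites: %d; indel sites: %d\n",
                paste(unique(x$meta$chrom), collapse = ","),
                sum(n_alt(x) == 1L), sum(is_indel(x))))
  }
  invisible(x)
}

#' @rdname variant_set
#' @param x a `variant_set`.
#' @export
n_sites <- function(x) nrow(x$meta)

#' Subset a variant_set by site and/or sample
#'
#' @param x a `variant_set`.
#' @param i site index (logical or integer).
#' @param j sample index or names.
#' @param ... unused.
#' @export
`[.variant_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_along(x$samples)
  variant_set(chrom = x$meta$chrom[i], pos = x$meta$pos[i],
              ref = x$meta$ref[i], alt = x$meta$alt[i],
              gt = x$gt[i, j, drop = FALSE], ad = x$ad[i, j, drop = FALSE],
              qual = x$meta$qual[i], info = x$info[i, , drop = FALSE])
}

# --- per-site allele helpers -------------------------------------------------

#' @rdname variant_set
#' @export
n_alt <- function(x) {
  a <- x$meta$alt
  ifelse(a == "" | a == ".", 0L,
         nchar(a) - nchar(gsub(",", "", a, fixed = TRUE)) + 1L)
}

#' @rdname variant_set
#' @export
is_snv <- function(x) {
  alts <- strsplit(x$meta$alt, ",", fixed = TRUE)
  nchar(x$meta$ref) == 1L &
    vapply(alts, function(a) length(a) > 0 && all(nchar(a) == 1L), logical(1))
}

#' @rdname variant_set
#' @export
is_indel <- function(x) {
  alts <- strsplit(x$meta$alt, ",", fixed = TRUE)
  rl <- nchar(x$meta$ref)
  mapply(function(a, r) length(a) > 0 && any(nchar(a) != r), alts, rl)
}

# --- genotype matrix helpers -------------------------------------------------

#' Genotype matrix accessors
#'
#' `gt_missing()` flags genotypes containing a missing allele (`.`);
#' `gt_ploidy()` returns the number of allele copies per call; `gt_dosage()`
#' returns the count of alternate-allele copies for biallelic sites (`NA`
#' where missing); `ad_counts()` splits biallelic AD strings into numeric
#' `ref` and `alt` depth matrices.
#'
#' @param x a `variant_set`.
#' @return matrices with one row per site and one column per sample.
#' @export
gt_missing <- function(x) {
  m <- grepl(".", x$gt, fixed = TRUE)
  dim(m) <- dim(x$gt); dimnames(m) <- dimnames(x$gt)
  m
}

#' @rdname gt_missing
#' @export
gt_ploidy <- function(x) {
  g <- gsub("[^/|]", "", x$gt)
  p <- nchar(g) + 1L
  dim(p) <- dim(x$gt); dimnames(p) <- dimnames(x$gt)
  p
}

#' @rdname gt_missing
#' @export
gt_dosage <- function(x) {
  if (any(n_alt(x) > 1L))
    stop2("gt_dosage is defined for biallelic sites only; filter first")
  d <- nchar(x$gt) - nchar(gsub("1", "", x$gt, fixed = TRUE))
  d[grepl(".", x$gt, fixed = TRUE)] <- NA_integer_
  dim(d) <- dim(x$gt); dimnames(d) <- dimnames(x$gt)
  d
}

#' @rdname gt_missing
#' @export
ad_counts <- function(x) {
  if (any(n_alt(x) > 1L))
    stop2("ad_counts is defined for biallelic sites only; filter first")
  ref <- suppressWarnings(as.numeric(sub(",.*", "", x$ad)))
  alt <- suppressWarnings(as.numeric(sub(".*,", "", x$ad)))
  dim(ref) <- dim(alt) <- dim(x$ad)
  dimnames(ref) <- dimnames(alt) <- dimnames(x$ad)
  list(ref = ref, alt = alt)
}

# het = genotype mixes ref and alt copies; hom-alt = all copies alt.
# Defined for any ploidy (0/0/1/1 is heterozygous, 1/1/1/1 homozygous-alt).
#' @rdname gt_missing
#' @export
gt_class <- function(x) {
  dos <- gt_dosage(x)
  pl <- gt_ploidy(x)
  cl <- matrix(NA_character_, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  cl[!is.na(dos) & dos == 0] <- "hom_ref"
  cl[!is.na(dos) & dos == pl] <- "hom_alt"
  cl[!is.na(dos) & dos > 0 & dos < pl] <- "het"
  cl
}
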