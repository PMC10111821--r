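#' Hard-filter thresholds for SNVs and indels
#'
#' Defaults reproduce the GATK-style hard filters used throughout the
#' package: SNVs pass when MQ > 40, QD > 2, FS < 60, MQRankSum > -12.5,
#' ReadPosRankSum > -8, SOR < 3 and DP >= 10 (the depth rule is the only
#' non-strict comparison), the site is biallelic and no sample genotype is
#' missing. Indels pass when QD > 2, QUAL > 30.0, FS < 200, no genotype is
#' missing and the indel allele is carried by at least two individuals.
#'
#' @param snv,indel named lists overriding individual thresholds.
#' @param drop_missing drop sites where any sample genotype is missing.
#' @param drop_multiallelic drop SNV sites with more than two alleles.
#' @param drop_singleton_support drop indels supported by one individual.
#' @param missing_annotation `"fail"` (default, conservative) or `"pass"`:
#'   policy when a required INFO annotation is absent from a record.
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(snv = list(), indel = list(),
                              drop_missing = TRUE, drop_multiallelic = TRUE,
                              drop_singleton_support = TRUE,
                              missing_annotation = c("fail", "pass")) {
  s <- list(MQ_min = 40, QD_min = 2, FS_max = 60, MQRankSum_min = -12.5,
            ReadPosRankSum_min = -8, SOR_max = 3, DP_min = 10)
  i <- list(QD_min = 2, QUAL_min = 30.0, FS_max = 200)
  s[names(snv)] <- snv
  i[names(indel)] <- indel
  stopifnot(all(is.finite(unlist(s))), all(is.finite(unlist(i))))
  structure(list(snv = s, indel = i, drop_missing = drop_missing,
                 drop_multiallelic = drop_multiallelic,
                 drop_singleton_support = drop_singleton_support,
                 missing_annotation = match.arg(missing_annotation)),
            class = "filter_thresholds")
}

#' SNV hard-filter decisions with per-rule reasons
#'
#' Evaluates every site of `x` against the SNV thresholds. Comparisons are
#' strict (`>`, `<`) except the depth rule, which is `DP >= DP_min`. A
#' failing site carries one reason per violated rule; passing sites carry
#' none.
#'
#' @param x a [variant_set].
#' @param thresholds a [filter_thresholds] object.
#' @return list with `pass` (logical vector) and `reasons` (list of
#'   character vectors, empty for passing sites).
#' @export
snv_filter_status <- function(x, thresholds = filter_thresholds()) {
  th <- thresholds$snv
  n <- n_sites(x)
  reasons <- vector("list", n)
  add <- function(which, tag) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  rule <- function(values, ok_fun, tag) {
    missing <- is.na(values)
    if (thresholds$missing_annotation == "fail") {
      add(which(missing), paste0("missing_annotation:", tag))
    }
    add(which(!missing & !ok_fun(values)), tag)
  }
  rule(x$info$MQ, function(v) v > th$MQ_min, "MQ")
  rule(x$info$QD, function(v) v > th$QD_min, "QD")
  rule(x$info$FS, function(v) v < th$FS_max, "FS")
  rule(x$info$MQRankSum, function(v) v > th$MQRankSum_min, "MQRankSum")
  rule(x$info$ReadPosRankSum, function(v) v > th$ReadPosRankSum_min,
       "ReadPosRankSum")
  rule(x$info$SOR, function(v) v < th$SOR_max, "SOR")
  rule(x$info$DP, function(v) v >= th$DP_min, "DP")
  if (thresholds$drop_multiallelic) {
    add(which(n_alt(x) > 1L), "multiallelic")
    add(which(n_alt(x) == 0L), "no_alt")
  }
  if (thresholds$drop_missing) {
    add(which(rowSums(gt_missing(x)) > 0), "missing")
  }
  list(pass = lengths(reasons) == 0L, reasons = reasons)
}

#' Indel hard-filter decisions with per-rule reasons
#'
#' @param x a [variant_set] whose sites are all indels (ref and at least one
#'   alt of different length); anything else is an error.
#' @param thresholds a [filter_thresholds] object.
#' @param support number of individuals carrying an indel allele per site;
#'   computed from the genotypes when `NULL` (an individual supports the
#'   site if it carries >= 1 alternate-allele copy, regardless of zygosity).
#' @return list with `pass`, `reasons` and the `support` vector used.
#' @export
indel_filter_status <- function(x, thresholds = filter_thresholds(),
                                support = NULL) {
  if (any(!is_indel(x))) stop2("not_an_indel: site %d", which(!is_indel(x))[1])
  th <- thresholds$indel
  n <- n_sites(x)
  if (is.null(support)) support <- indel_support(x)
  stopifnot(length(support) == n)
  reasons <- vector("list", n)
  add <- function(which, tag) {
    for (i in which) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  qd <- x$info$QD
  fs <- x$info$FS
  if (thresholds$missing_annotation == "fail") {
    add(which(is.na(qd)), "missing_annotation:QD")
    add(which(is.na(fs)), "missing_annotation:FS")
  }
  add(which(!is.na(qd) & !(qd > th$QD_min)), "QD")
  add(which(is.na(x$meta$qual) | !(x$meta$qual > th$QUAL_min)), "QUAL")
  add(which(!is.na(fs) & !(fs < th$FS_max)), "FS")
  if (thresholds$drop_missing) add(which(rowSums(gt_missing(x)) > 0), "missing")
  if (thresholds$drop_singleton_support) add(which(support < 2), "singleton")
  list(pass = lengths(reasons) == 0L, reasons = reasons, support = support)
}

# individuals carrying >= 1 alternate-allele copy, per site
indel_support <- function(x) {
  carrier <- grepl("[1-9]", x$gt) & !grepl(".", x$gt, fixed = TRUE)
  dim(carrier) <- dim(x$gt)
  rowSums(carrier)
}

#' Apply hard filters and report per-rule removal counts
#'
#' `filter_snvs()` restricts `x` to its SNV records and keeps the sites
#' passing [snv_filter_status()]; `filter_indels()` does the same for indel
#' records and [indel_filter_status()]. Both return the filtered
#' [variant_set] together with a removal-count report, one row per rule.
#'
#' @param x a [variant_set].
#' @param thresholds a [filter_thresholds] object.
#' @return list with `variants` (filtered set), `report` (data.frame rule /
#'   n_failed), `n_input`, `n_pass`.
#' @export
filter_snvs <- function(x, thresholds = filter_thresholds()) {
  snv <- x[which(is_snv(x)), ]
  st <- snv_filter_status(snv, thresholds)
  list(variants = snv[which(st$pass), ],
       report = reason_report(st$reasons),
       n_input = n_sites(snv), n_pass = sum(st$pass))
}

#' @rdname filter_snvs
#' @export
filter_indels <- function(x, thresholds = filter_thresholds()) {
  ind <- x[which(is_indel(x)), ]
  st <- indel_filter_status(ind, thresholds)
  list(variants = ind[which(st$pass), ],
       report = reason_report(st$reasons),
       n_input = n_sites(ind), n_pass = sum(st$pass))
}

reason_report <- function(reasons) {
  tab <- table(unlist(reasons))
  data.frame(rule = as.character(names(tab) %||% character(0)),
             n_failed = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample indel summary
#'
#' For each sample: counts of homozygous and heterozygous indel sites (a
#' sample counts a site iff it carries at least one indel allele; zygosity
#' from its own genotype), indels longer than 100 bp, and indels overlapping
#' gene annotations; plus the global indel length range. Indel length is
#' `|len(alt) - len(ref)|` (maximum over carried alternates at multiallelic
#' sites).
#'
#' @param x a [variant_set] of filtered indels.
#' @param genes a `GRanges` of gene intervals (or NULL to skip the genic
#'   column).
#' @return list with `per_sample` data.frame and `min_length`/`max_length`.
#' @export
summarize_indels <- function(x, genes = NULL) {
  n <- n_sites(x)
  alts <- strsplit(x$meta$alt, ",", fixed = TRUE)
  reflen <- nchar(x$meta$ref)
  site_len <- as.numeric(mapply(
    function(a, r) if (length(a)) max(abs(nchar(a) - r)) else 0L,
    alts, reflen))
  genic <- if (is.null(genes)) rep(FALSE, n) else
    positions_in_intervals(x$meta$chrom, x$meta$pos, genes)

  per_sample <- lapply(x$samples, function(s) {
    g <- x$gt[, s]
    parts <- strsplit(g, "[/|]")
    carries <- vapply(parts, function(a) any(a %in% as.character(1:9)),
                      logical(1)) & !grepl(".", g, fixed = TRUE)
    hom <- carries & vapply(parts, function(a) length(unique(a)) == 1L,
                            logical(1))
    het <- carries & !hom
    data.frame(sample = s, homozygous = sum(hom), heterozygous = sum(het),
               total = sum(carries), large = sum(carries & site_len > 100),
               genic = sum(carries & genic), stringsAsFactors = FALSE)
  })
  list(per_sample = do.call(rbind, per_sample),
       min_length = if (n) min(site_len) else NA_integer_,
       max_length = if (n) max(site_len) else NA_integer_)
}

#' Per-sample SNV density (SNVs per kilobase)
#'
#' Splits each sample's SNV sites into homozygous-alternate (all allele
#' copies alternate) and heterozygous (mixed copies, e.g. a tetraploid
#' 0/0/1/1) classes and scales by genome length.
#'
#' @param x a [variant_set] of filtered biallelic SNVs.
#' @param genome_length_bp total genome length in bp, > 0.
#' @return data.frame: sample, hom_count, het_count, hom_per_kb, het_per_kb.
#' @export
snv_density <- function(x, genome_length_bp) {
  if (!is.numeric(genome_length_bp) || genome_length_bp <= 0)
    stop2("genome_length_bp must be > 0")
  cl <- gt_class(x)
  kb <- genome_length_bp / 1000
  hom <- colSums(cl == "hom_alt", na.rm = TRUE)
  het <- colSums(cl == "het", na.rm = TRUE)
  data.frame(sample = x$samples, hom_count = as.integer(hom),
             het_count = as.integer(het), hom_per_kb = hom / kb,
             het_per_kb = het / kb, row.names = NULL,
             stringsAsFactors = FALSE)
}
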