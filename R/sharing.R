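#' Find SNVs exclusive to one diploid group
#'
#' An exclusive SNV of a focal diploid group is a biallelic site where every
#' focal member carries the alternate allele (in >= 1 copy) while every
#' member of every other diploid group is homozygous reference. Sites are
#' classified `homozygous_only` when all focal members are homozygous
#' alternate, and `includes_heterozygous` when at least one focal member is
#' heterozygous (groups where *every* member is heterozygous also qualify;
#' their sub-count is reported separately). Restricting exclusivity to the
#' variant allele is what makes exclusivity mutually exclusive across
#' groups: were the reference allele eligible too, a fixed difference
#' between two groups would be "exclusive" to both at once. Polyploid
#' samples must be excluded from this step; sites with a missing genotype
#' in any involved sample are dropped.
#'
#' @param x a [variant_set] of filtered biallelic SNVs.
#' @param focal character vector of focal-group sample names (diploid).
#' @param others character vector of all other diploid-group sample names.
#' @return data.frame (`chrom`, `pos`, `allele` — the exclusive allele index
#'   0/1, `class`) with attributes `n_all_het` (sub-count of sites where all
#'   focal members are heterozygous) and `focal`.
#' @export
find_exclusive_snvs <- function(x, focal, others) {
  stopifnot(length(focal) >= 1, length(others) >= 1)
  bad <- setdiff(c(focal, others), x$samples)
  if (length(bad)) stop2("unknown samples: %s", paste(bad, collapse = ", "))
  pl <- gt_ploidy(x)[, c(focal, others), drop = FALSE]
  miss <- gt_missing(x)[, c(focal, others), drop = FALSE]
  if (any(pl[!miss] != 2L))
    stop2("configuration error: non-diploid genotype among focal/other samples")
  dos <- gt_dosage(x)
  f <- dos[, focal, drop = FALSE]
  o <- dos[, others, drop = FALSE]
  callable <- rowSums(is.na(f)) == 0 & rowSums(is.na(o)) == 0

  # exclusive alternate allele: others carry no alt, all focal carry >= 1 alt
  excl <- callable & rowSums(o != 0) == 0 & rowSums(f == 0) == 0
  all_hom <- rowSums(f != 2L) == 0
  sel <- which(excl)
  out <- data.frame(
    chrom = x$meta$chrom[sel],
    pos = x$meta$pos[sel],
    allele = rep(1L, length(sel)),
    class = ifelse(all_hom[sel], "homozygous_only", "includes_heterozygous"),
    site = sel,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  all_het <- rowSums(f == 1L) == ncol(f)
  attr(out, "n_all_het") <- sum(all_het[out$site])
  attr(out, "focal") <- paste(focal, collapse = ",")
  out
}

#' Count exclusive SNVs shared by a polyploid
#'
#' A site is shared when the polyploid genotype contains at least one copy
#' of the focal group's exclusive allele. Shared sites are split by the
#' polyploid's *own* zygosity class — homozygous (all allele copies
#' alternate) or heterozygous (mixed copies) — and expressed as
#' percentages of the polyploid's SNV totals of the same class, so each
#' percentage is a fraction of the matching denominator and stays in
#' `[0, 100]`. Totals may be supplied (e.g. fixed genome-wide counts) or
#' computed from `x`; supplied totals win.
#'
#' @param excl exclusive set from [find_exclusive_snvs()].
#' @param x the [variant_set] holding the polyploid's genotypes.
#' @param polyploid polyploid sample name.
#' @param totals optional `list(hom = , het = )` denominators; both > 0.
#' @return one-row data.frame with shared counts, denominators and
#'   percentages per zygosity class.
#' @export
shared_with_polyploid <- function(excl, x, polyploid, totals = NULL) {
  stopifnot(polyploid %in% x$samples)
  dos <- gt_dosage(x)[, polyploid]
  pl <- gt_ploidy(x)[, polyploid]
  computed <- list(hom = sum(!is.na(dos) & dos == pl),
                   het = sum(!is.na(dos) & dos > 0 & dos < pl))
  if (is.null(totals)) totals <- computed
  if (is.null(totals$hom) || is.null(totals$het) ||
      totals$hom <= 0 || totals$het <= 0)
    stop2("polyploid SNV totals must be positive")
  d <- dos[excl$site]
  p <- pl[excl$site]
  # a heterozygote carries both alleles; a homozygote only the alternate
  hom_here <- !is.na(d) & d == p
  het_here <- !is.na(d) & d > 0 & d < p
  shares <- ifelse(excl$allele == 1L, !is.na(d) & d >= 1L,
                   !is.na(d) & d < p)
  sh_hom <- sum(shares & hom_here)
  sh_het <- sum(shares & het_here)
  data.frame(
    polyploid = polyploid,
    shared_hom = sh_hom, total_hom = totals$hom,
    pct_hom = 100 * sh_hom / totals$hom,
    shared_het = sh_het, total_het = totals$het,
    pct_het = 100 * sh_het / totals$het,
    stringsAsFactors = FALSE)
}

#' Exclusive-SNV sharing matrix between diploid groups and polyploids
#'
#' For every focal diploid group, finds its exclusive SNVs (against the
#' union of the remaining diploid groups) and computes the percentage of
#' each polyploid's SNVs shared with that group, split by the polyploid's
#' zygosity class. The true parental lineages of an allopolyploid are
#' expected to show the largest percentages in its column.
#'
#' @param x a [variant_set] of filtered biallelic SNVs.
#' @param diploid_groups named list: group label -> diploid sample names.
#' @param polyploids character vector of polyploid sample names.
#' @param totals optional named list: polyploid -> `list(hom=, het=)`.
#' @return object of class `sharing_matrix`: `pct` and `shared` matrices
#'   (rows `<group>:homozygous` / `<group>:heterozygous`, columns
#'   polyploids), `denominators`, and the per-group exclusive-set sizes.
#' @export
sharing_matrix <- function(x, diploid_groups, polyploids, totals = NULL) {
  stopifnot(length(diploid_groups) >= 2, length(polyploids) >= 1)
  if (length(inter <- intersect(unlist(diploid_groups), polyploids)))
    stop2("configuration error: polyploid sample(s) inside a diploid group: %s",
          paste(inter, collapse = ", "))
  classes <- c("homozygous", "heterozygous")
  rows <- as.vector(t(outer(names(diploid_groups), classes, paste, sep = ":")))
  pct <- shared <- matrix(0, length(rows), length(polyploids),
                          dimnames = list(rows, polyploids))
  denom <- matrix(0, 2, length(polyploids),
                  dimnames = list(c("hom", "het"), polyploids))
  excl_sizes <- setNames(integer(length(diploid_groups)),
                         names(diploid_groups))
  for (g in names(diploid_groups)) {
    others <- unlist(diploid_groups[setdiff(names(diploid_groups), g)],
                     use.names = FALSE)
    excl <- find_exclusive_snvs(x, diploid_groups[[g]], others)
    excl_sizes[g] <- nrow(excl)
    for (p in polyploids) {
      row <- shared_with_polyploid(excl, x, p,
                                   totals = totals[[p]] %||% NULL)
      pct[paste0(g, ":homozygous"), p] <- row$pct_hom
      pct[paste0(g, ":heterozygous"), p] <- row$pct_het
      shared[paste0(g, ":homozygous"), p] <- row$shared_hom
      shared[paste0(g, ":heterozygous"), p] <- row$shared_het
      denom["hom", p] <- row$total_hom
      denom["het", p] <- row$total_het
    }
  }
  structure(list(pct = pct, shared = shared, denominators = denom,
                 exclusive_set_sizes = excl_sizes), class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("exclusive-SNV sharing (% of polyploid SNVs of matching class):\n")
  print(round(x$pct, 2))
  invisible(x)
}

#' Rank candidate parental groups of a polyploid
#'
#' Orders the diploid groups by total shared exclusive SNVs in the
#' polyploid's column (both zygosity classes pooled).
#'
#' @param sm a [sharing_matrix()] result.
#' @param polyploid column name.
#' @return character vector of group labels, best-supported first.
#' @export
rank_parents <- function(sm, polyploid) {
  stopifnot(polyploid %in% colnames(sm$shared))
  groups <- unique(sub(":.*", "", rownames(sm$shared)))
  tot <- vapply(groups, function(g) {
    sum(sm$shared[startsWith(rownames(sm$shared), paste0(g, ":")), polyploid])
  }, numeric(1))
  names(sort(tot, decreasing = TRUE))
}
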