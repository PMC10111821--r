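#' Export disjoint Structure-format subsets of polymorphic positions
#'
#' Draws `n_subsets` pairwise-disjoint random subsets of `subset_size`
#' polymorphic positions each and writes one plain-text matrix per subset:
#' one row per allele copy per individual (a diploid contributes 2 rows, a
#' hexaploid 6), the sample name first, then one integer-coded allele per
#' position (reference 1, alternate 2, missing -9). Identical seeds yield
#' byte-identical files.
#'
#' @param x a [variant_set] of biallelic sites; positions where at least
#'   two genotype states are observed count as polymorphic.
#' @param n_subsets,subset_size number and size of the subsets;
#'   `n_subsets * subset_size` must not exceed the polymorphic-site count.
#' @param seed RNG seed (required for reproducibility).
#' @param out_dir output directory (created if needed).
#' @param per_chromosome draw positions stratified by chromosome
#'   (proportional allocation) instead of genome-wide uniform.
#' @return character vector of the written file paths.
#' @export
write_structure_subsets <- function(x, n_subsets, subset_size, seed, out_dir,
                                    per_chromosome = FALSE) {
  stopifnot(is_count(n_subsets), is_count(subset_size))
  dos <- gt_dosage(x)
  pl <- gt_ploidy(x)
  # polymorphic: more than one distinct observed allele across all copies
  any_ref <- rowSums(dos < pl, na.rm = TRUE) > 0
  any_alt <- rowSums(dos > 0, na.rm = TRUE) > 0
  poly <- which(any_ref & any_alt)
  need <- n_subsets * subset_size
  if (need > length(poly))
    stop2("insufficient polymorphic positions: need %d, have %d",
          need, length(poly))
  chosen <- with_seed(seed, {
    if (per_chromosome) {
      chr <- x$meta$chrom[poly]
      alloc <- round(need * table(chr) / length(poly))
      # fix rounding so the total is exact
      while (sum(alloc) != need) {
        j <- which.max(table(chr) - alloc)
        alloc[j] <- alloc[j] + sign(need - sum(alloc))
      }
      unlist(lapply(names(alloc), function(cn) {
        sample(poly[chr == cn], alloc[[cn]])
      }), use.names = FALSE)
    } else {
      sample(poly, need)
    }
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subsets <- split(chosen, rep(seq_len(n_subsets), each = subset_size))
  paths <- character(n_subsets)
  for (s in seq_len(n_subsets)) {
    idx <- sort(subsets[[s]])
    paths[s] <- file.path(out_dir, sprintf("subset_%02d.str", s))
    lines <- character(0)
    for (smp in x$samples) {
      copies <- strsplit(x$gt[idx, smp], "[/|]")
      k <- max(lengths(copies))
      rows <- vapply(seq_len(k), function(ci) {
        allele <- vapply(copies, function(a) {
          v <- a[min(ci, length(a))]
          if (is.na(v) || v == ".") "-9" else as.character(as.integer(v) + 1L)
        }, character(1))
        paste(c(smp, allele), collapse = " ")
      }, character(1))
      lines <- c(lines, rows)
    }
    writeLines(lines, paths[s])
  }
  attr(paths, "positions") <- lapply(subsets, function(i)
    x$meta$pos[sort(i)])
  paths
}
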