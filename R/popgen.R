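#' Per-site alternate-allele frequencies of a sample group
#'
#' Frequencies are computed over all non-missing allele copies, so mixed
#' ploidies pool naturally (a tetraploid contributes 4 copies).
#'
#' @param x a [variant_set] of biallelic sites.
#' @param samples group member names.
#' @return list: `freq` (alt-allele frequency per site, `NaN` where no
#'   copies are callable) and `n_copies` (callable allele copies per site).
#' @export
group_allele_freqs <- function(x, samples) {
  stopifnot(all(samples %in% x$samples))
  dos <- gt_dosage(x)[, samples, drop = FALSE]
  pl <- gt_ploidy(x)[, samples, drop = FALSE]
  pl[is.na(dos)] <- 0L
  dos[is.na(dos)] <- 0L
  n <- rowSums(pl)
  list(freq = ifelse(n > 0, rowSums(dos) / n, NaN), n_copies = n)
}

#' Nei's gene diversity (H) of a sample group
#'
#' Per site, with `n` callable allele copies and allele frequencies `p_i`,
#' the unbiased gene diversity is `h = n/(n-1) * (1 - sum(p_i^2))`; `H` is
#' the mean of `h` over all callable sites (monomorphic sites contribute 0),
#' which puts genome-wide values on the familiar ~1e-3 scale when invariant
#' sites are included in the denominator.
#'
#' @param x a [variant_set] of biallelic sites for the callable positions.
#' @param samples group member names (>= 2 allele copies required).
#' @param n_total_sites optional total callable site count; when larger than
#'   `n_sites(x)`, the remaining sites are treated as monomorphic (h = 0).
#' @return list: `H`, `n_sites` averaged over, `mean_copies`.
#' @export
nei_gene_diversity <- function(x, samples, n_total_sites = NULL) {
  fr <- group_allele_freqs(x, samples)
  ok <- fr$n_copies >= 2
  if (!any(ok)) stop2("no site has >= 2 callable allele copies")
  p <- fr$freq[ok]
  n <- fr$n_copies[ok]
  h <- n / (n - 1) * (1 - p^2 - (1 - p)^2)
  denom <- max(n_total_sites %||% sum(ok), sum(ok))
  list(H = sum(h) / denom, n_sites = denom, mean_copies = mean(n))
}

#' ABBA/BABA site-pattern contributions
#'
#' Frequency-weighted pattern probabilities for one site of a
#' `(((P1, P2), P3), outgroup)` trio: `abba = (1-p1) p2 p3 (1-p4)` and
#' `baba = p1 (1-p2) p3 (1-p4)`, where the `p` are derived-allele
#' frequencies (the outgroup defines the ancestral state) — a polymorphic
#' outgroup down-weights the site by `1 - p4` rather than discarding it.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in `[0, 1]` (vectors
#'   allowed; `p4` is the outgroup).
#' @return list with `abba` and `baba` vectors.
#' @export
site_patterns <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4)) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop2("allele frequencies must lie in [0, 1]")
  }
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Patterson's D from summed pattern counts
#'
#' @param abba,baba summed (weighted) ABBA and BABA counts; their sum must
#'   be positive.
#' @return `D = (abba - baba) / (abba + baba)`, in `[-1, 1]`.
#' @export
d_statistic <- function(abba, baba) {
  if (abba + baba <= 0) stop2("no_informative_sites: ABBA + BABA is zero")
  (abba - baba) / (abba + baba)
}

#' Block-jackknife significance of Patterson's D
#'
#' Sites are partitioned into `n_blocks` contiguous blocks (a linkage-aware
#' analogue of Mb-scale genomic blocks); D is recomputed leaving each block
#' out, and the delete-one jackknife variance yields a standard error, a
#' Z score `D / SE` and a two-sided normal p-value. At least 20 informative
#' blocks (positive ABBA + BABA) are required.
#'
#' @param abba,baba per-site pattern contributions, in genome order.
#' @param n_blocks number of contiguous blocks (default 50).
#' @param block long-form alternative: explicit block id per site.
#' @return list: `D`, `SE`, `Z`, `p`, `n_blocks_informative`, `abba`,
#'   `baba` (the summed counts).
#' @export
jackknife_D <- function(abba, baba, n_blocks = 50, block = NULL) {
  stopifnot(length(abba) == length(baba))
  if (is.null(block)) {
    block <- ceiling(seq_along(abba) / (length(abba) / n_blocks))
  }
  a_tot <- sum(abba); b_tot <- sum(baba)
  D <- d_statistic(a_tot, b_tot)
  a_blk <- tapply(abba, block, sum)
  b_blk <- tapply(baba, block, sum)
  informative <- (a_blk + b_blk) > 0
  m <- sum(informative)
  if (m < 20)
    stop2("only %d informative jackknife blocks (< 20); use more sites or fewer blocks",
          m)
  a_blk <- a_blk[informative]; b_blk <- b_blk[informative]
  d_loo <- (a_tot - a_blk - (b_tot - b_blk)) / (a_tot - a_blk + b_tot - b_blk)
  se <- sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))
  z <- if (se > 0) D / se else 0
  list(D = D, SE = se, Z = z, p = 2 * pnorm(-abs(z)),
       n_blocks_informative = m, abba = a_tot, baba = b_tot)
}

#' ABBA-BABA test for one trio
#'
#' Computes derived-allele frequencies for P1, P2, P3 and the outgroup
#' (polarizing on the outgroup's major allele), accumulates the
#' frequency-weighted ABBA/BABA patterns and runs the block jackknife. A
#' significantly positive D indicates gene flow between P2 and P3, a
#' negative D between P1 and P3.
#'
#' @param x a [variant_set] of biallelic SNVs in genome order.
#' @param p1,p2,p3,outgroup character vectors of sample names per
#'   population.
#' @param n_blocks jackknife blocks (default 50).
#' @param strict_outgroup drop sites where the outgroup is polymorphic or
#'   carries the derived allele, instead of down-weighting.
#' @return one-row data.frame: P1, P2, P3, ABBA, BABA, D, SE, Z, p.
#' @export
abba_baba <- function(x, p1, p2, p3, outgroup, n_blocks = 50,
                      strict_outgroup = FALSE) {
  f1 <- group_allele_freqs(x, p1)$freq
  f2 <- group_allele_freqs(x, p2)$freq
  f3 <- group_allele_freqs(x, p3)$freq
  f4 <- group_allele_freqs(x, outgroup)$freq
  ok <- !is.na(f1) & !is.na(f2) & !is.na(f3) & !is.na(f4) &
    !is.nan(f1) & !is.nan(f2) & !is.nan(f3) & !is.nan(f4)
  # outgroup major allele is ancestral; flip so p4 is the derived frequency
  flip <- ok & f4 > 0.5
  f1[flip] <- 1 - f1[flip]; f2[flip] <- 1 - f2[flip]
  f3[flip] <- 1 - f3[flip]; f4[flip] <- 1 - f4[flip]
  if (strict_outgroup) ok <- ok & f4 == 0
  sp <- site_patterns(f1[ok], f2[ok], f3[ok], f4[ok])
  jk <- jackknife_D(sp$abba, sp$baba, n_blocks = n_blocks)
  data.frame(P1 = paste(p1, collapse = ","), P2 = paste(p2, collapse = ","),
             P3 = paste(p3, collapse = ","), ABBA = jk$abba, BABA = jk$baba,
             D = jk$D, SE = jk$SE, Z = jk$Z, p = jk$p,
             stringsAsFactors = FALSE)
}

#' Enumerate trios compatible with a guide tree
#'
#' Given a tree whose tips are group labels and a designated outgroup,
#' returns the trios `(P1, P2, P3)` in which `(P1, P2)` are sisters
#' relative to `P3` — the arrangement under which D tests gene flow without
#' presupposing it. Triples unresolved in the tree (polytomies) are
#' skipped.
#'
#' @param tree an [ape::phylo] tree containing all group labels and the
#'   outgroup as tips.
#' @param groups character vector of group labels to test.
#' @param outgroup tip label used to root the tree.
#' @return data.frame with columns P1, P2, P3.
#' @export
trios_from_tree <- function(tree, groups, outgroup) {
  stopifnot(inherits(tree, "phylo"), outgroup %in% tree$tip.label,
            all(groups %in% tree$tip.label))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  groups <- setdiff(groups, outgroup)
  if (length(groups) < 3) return(data.frame(P1 = character(),
                                            P2 = character(),
                                            P3 = character()))
  out <- list()
  for (tri in utils::combn(groups, 3, simplify = FALSE)) {
    mrca_all <- ape::getMRCA(rooted, tri)
    pairs <- utils::combn(tri, 2, simplify = FALSE)
    inner <- vapply(pairs, function(pr) ape::getMRCA(rooted, pr) != mrca_all,
                    logical(1))
    if (sum(inner) != 1) next  # polytomy or inconsistent
    pr <- pairs[[which(inner)]]
    out[[length(out) + 1L]] <- data.frame(
      P1 = pr[1], P2 = pr[2], P3 = setdiff(tri, pr),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(P1 = character(), P2 = character(),
                                      P3 = character()))
  do.call(rbind, out)
}

#' ABBA-BABA over all (tree-compatible) trios with FDR correction
#'
#' @param x a [variant_set] of biallelic SNVs.
#' @param groups named list: group label -> member sample names.
#' @param outgroup group label used as outgroup.
#' @param tree optional guide tree over group labels; when supplied, only
#'   tree-compatible trios are tested, otherwise every ordered triple (each
#'   unordered triple in its three pair arrangements).
#' @param n_blocks jackknife blocks.
#' @return data.frame of [abba_baba()] rows plus a BH-adjusted `q` column.
#' @export
abba_baba_all <- function(x, groups, outgroup, tree = NULL, n_blocks = 50) {
  stopifnot(outgroup %in% names(groups))
  testable <- setdiff(names(groups), outgroup)
  trios <- if (!is.null(tree)) {
    trios_from_tree(tree, testable, outgroup)
  } else {
    do.call(rbind, lapply(utils::combn(testable, 3, simplify = FALSE),
                          function(tri) data.frame(
                            P1 = tri[c(1, 1, 2)], P2 = tri[c(2, 3, 3)],
                            P3 = tri[c(3, 2, 1)], stringsAsFactors = FALSE)))
  }
  if (is.null(trios) || nrow(trios) == 0)
    stop2("no testable trio (need >= 3 non-outgroup groups)")
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    r <- abba_baba(x, groups[[trios$P1[i]]], groups[[trios$P2[i]]],
                   groups[[trios$P3[i]]], groups[[outgroup]],
                   n_blocks = n_blocks)
    r$P1 <- trios$P1[i]; r$P2 <- trios$P2[i]; r$P3 <- trios$P3[i]
    r
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values (step-up, monotone).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop2("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
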