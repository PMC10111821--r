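#' Allele balance at heterozygous sites
#'
#' The allele balance (AB) of a heterozygous call is the fraction of reads
#' supporting the alternate allele, `alt / (ref + alt)`. In a k-ploid an
#' alternate allele present in i of k copies is expected at AB ~ i/k, which
#' is what makes the AB distribution informative about ploidy.
#'
#' @param ref_depth,alt_depth non-negative read depths (vectors allowed).
#' @return numeric vector of AB values in `[0, 1]`.
#' @export
allele_balance <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  if (any(tot <= 0)) stop2("no_coverage: zero total depth")
  alt_depth / tot
}

#' Extract a sample's allele-balance profile from a variant_set
#'
#' Collects AB over the biallelic sites where the sample's genotype is
#' heterozygous *and* the depths are informative (0 < alt depth < total
#' depth): a site with all reads on one allele contradicts a heterozygous
#' call and is excluded, so every AB lies strictly inside (0, 1). Sites
#' without AD are skipped (AB is undefined without depths).
#'
#' @param x a [variant_set] of biallelic SNVs.
#' @param sample sample name.
#' @param chroms optional chromosome whitelist (e.g. pseudo-chromosomes
#'   only); default all sequences.
#' @return data.frame (`chrom`, `pos`, `ab`) with attribute `sample`.
#' @export
allele_balance_profile <- function(x, sample, chroms = NULL) {
  stopifnot(sample %in% x$samples)
  keep <- rep(TRUE, n_sites(x))
  if (!is.null(chroms)) keep <- x$meta$chrom %in% chroms
  cl <- gt_class(x)[, sample]
  ad <- ad_counts(x)
  ref <- ad$ref[, sample]
  alt <- ad$alt[, sample]
  use <- keep & !is.na(cl) & cl == "het" & !is.na(ref) & !is.na(alt) &
    alt > 0 & ref > 0
  out <- data.frame(chrom = x$meta$chrom[use], pos = x$meta$pos[use],
                    ab = alt[use] / (ref[use] + alt[use]),
                    stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  out
}

#' Expected allele-balance peak template for a k-ploid
#'
#' A k-ploid heterozygote can carry the alternate allele in 1..k-1 copies,
#' so its AB density is expected to peak at `i/k`: a diploid at 0.50, a
#' tetraploid at 0.25/0.50/0.75, a hexaploid at 0.17/0.33/0.50/0.67/0.83
#' (two-decimal rounding).
#'
#' @param k ploidy, even and >= 2.
#' @return sorted numeric vector `(1:(k-1))/k`.
#' @export
expected_peaks <- function(k) {
  if (!is_count(k) || k < 2 || k %% 2 != 0)
    stop2("ploidy k must be an even integer >= 2")
  seq_len(k - 1) / k
}

#' Detect modes of an allele-balance distribution
#'
#' Fits a Gaussian kernel density estimate on a fixed 512-point grid over
#' (0, 1) and reports the local maxima, discarding minor wiggles below
#' `min_rel_density` of the global maximum. The result is invariant to the
#' order of the input values.
#'
#' @param profile numeric AB vector, or a profile data.frame from
#'   [allele_balance_profile()].
#' @param bandwidth kernel standard deviation on the AB scale; 0.02 resolves
#'   hexaploid peaks spaced 1/6 apart at ~30x depth.
#' @param min_rel_density modes below this fraction of the highest density
#'   are dropped (default 0.1, low enough to keep a broad low-balance
#'   secondary mode visible).
#' @param grid_n number of KDE evaluation points.
#' @return data.frame (`position`, `height`, `rel_height`) sorted by
#'   position.
#' @export
detect_modes <- function(profile, bandwidth = 0.02, min_rel_density = 0.1,
                         grid_n = 512) {
  ab <- if (is.data.frame(profile)) profile$ab else as.numeric(profile)
  if (length(ab) == 0) stop2("no_het_sites: empty allele-balance profile")
  stopifnot(bandwidth > 0, min_rel_density >= 0, min_rel_density < 1)
  d <- density(ab, bw = bandwidth, n = grid_n, from = 0, to = 1)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  idx <- which(is_max)
  idx <- idx[y[idx] >= min_rel_density * max(y)]
  out <- data.frame(position = d$x[idx], height = y[idx],
                    rel_height = y[idx] / max(y))
  out[order(out$position), , drop = FALSE]
}

#' Call ploidy by matching detected modes to peak templates
#'
#' Each candidate ploidy k is scored by greedily matching the detected modes
#' to its expected template `{i/k}` within `tol`; the candidate explaining
#' the most template peaks wins, ties broken toward the lower mean absolute
#' deviation of matched peaks and then toward the smaller k. Modes inside
#' the low-balance window `[lo, hi)` are held to the stricter `low_tol`:
#' a broad low mode occurs in that window even in true diploids (collapsed
#' repeats, segmental duplications), so window evidence only counts when it
#' falls almost exactly on a template peak — a tetraploid mode at 0.243
#' still supports the 0.25 peak, while a diploid's secondary bump at 0.12
#' is not accepted as the hexaploid's 0.167 peak. Low-window modes left
#' unmatched never count against a candidate; they are reported through
#' `secondary_mode`.
#'
#' @param modes data.frame from [detect_modes()] (or numeric mode
#'   positions).
#' @param candidates candidate ploidies, default `c(2, 4, 6)`.
#' @param tol maximum template-to-mode distance, in (0, 0.1].
#' @param low_tol stricter matching tolerance applied to modes inside
#'   `low_window`.
#' @param low_window AB window whose unmatched modes set the secondary-mode
#'   flag instead of penalizing the call.
#' @return list of class `ploidy_call`: `ploidy`, `matched` (template peak,
#'   mode position, deviation), `fit` (mean absolute deviation),
#'   `secondary_mode` flag, `unmatched_modes`, and the per-candidate `scores`
#'   table.
#' @export
call_ploidy <- function(modes, candidates = c(2, 4, 6), tol = 0.05,
                        low_tol = 0.02, low_window = c(0.05, 0.25)) {
  pos <- if (is.data.frame(modes)) modes$position else as.numeric(modes)
  if (length(pos) == 0) stop2("no modes supplied")
  stopifnot(tol > 0, tol <= 0.1, low_tol > 0)
  in_low <- pos >= low_window[1] & pos < low_window[2]
  mode_tol <- ifelse(in_low, min(tol, low_tol), tol)

  score_one <- function(k) {
    template <- expected_peaks(k)
    used <- rep(FALSE, length(pos))
    match_pos <- rep(NA_real_, length(template))
    for (i in seq_along(template)) {
      d <- abs(pos - template[i])
      d[used | d > mode_tol] <- NA
      if (all(is.na(d))) next
      j <- which.min(d)
      used[j] <- TRUE
      match_pos[i] <- pos[j]
    }
    dev <- abs(match_pos - template)
    list(k = k, n_matched = sum(!is.na(match_pos)),
         mad = if (any(!is.na(dev))) mean(dev, na.rm = TRUE) else Inf,
         template = template, match_pos = match_pos, used = used)
  }
  scored <- lapply(sort(candidates), score_one)
  scores <- data.frame(
    ploidy = vapply(scored, `[[`, numeric(1), "k"),
    n_matched = vapply(scored, `[[`, numeric(1), "n_matched"),
    mad = vapply(scored, `[[`, numeric(1), "mad"))
  if (all(scores$n_matched == 0))
    stop2("no candidate ploidy matches any detected mode (modes: %s)",
          paste(round(pos, 3), collapse = ", "))
  ord <- order(-scores$n_matched, scores$mad, scores$ploidy)
  best <- scored[[ord[1]]]
  unmatched <- pos[!best$used]
  secondary <- any(unmatched >= low_window[1] & unmatched < low_window[2])
  structure(list(
    ploidy = best$k,
    matched = data.frame(template = best$template, mode = best$match_pos,
                         deviation = abs(best$match_pos - best$template)),
    fit = best$mad, secondary_mode = secondary,
    unmatched_modes = unmatched, scores = scores), class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy call: %dx (matched %d/%d template peaks, MAD %.4f)%s\n",
              x$ploidy, sum(!is.na(x$matched$mode)), nrow(x$matched), x$fit,
              if (x$secondary_mode) " [low-balance secondary mode]" else ""))
  invisible(x)
}

#' Classify low-allele-balance positions against annotations
#'
#' Positions whose AB falls in `window` (default the 0.05–0.25 band below
#' the lowest genuine ploidy peak) are tallied against repeat and gene
#' interval sets independently — a position inside both is counted in both
#' categories. Percentages are relative to the number of selected
#' positions.
#'
#' @param profile data.frame from [allele_balance_profile()].
#' @param window `c(lo, hi)` inclusive AB window, `0 <= lo < hi <= 1`.
#' @param repeats,genes `GRanges` interval sets (either may be NULL).
#' @return list: `n_selected`, `n_repeat`, `pct_repeat`, `n_gene`,
#'   `pct_gene`, `gene_ids`.
#' @export
classify_low_balance <- function(profile, window = c(0.05, 0.25),
                                 repeats = NULL, genes = NULL) {
  stopifnot(length(window) == 2, window[1] >= 0, window[1] < window[2],
            window[2] <= 1)
  sel <- profile$ab >= window[1] & profile$ab <= window[2]
  n <- sum(sel)
  in_rep <- if (is.null(repeats) || n == 0) logical(n) else
    positions_in_intervals(profile$chrom[sel], profile$pos[sel], repeats)
  in_gene <- if (is.null(genes) || n == 0) logical(n) else
    positions_in_intervals(profile$chrom[sel], profile$pos[sel], genes)
  gene_ids <- if (is.null(genes) || n == 0) character() else
    features_at_positions(profile$chrom[sel], profile$pos[sel], genes)
  list(n_selected = n,
       n_repeat = sum(in_rep),
       pct_repeat = if (n) 100 * sum(in_rep) / n else 0,
       n_gene = sum(in_gene),
       pct_gene = if (n) 100 * sum(in_gene) / n else 0,
       gene_ids = gene_ids)
}

#' Plot an allele-balance density with its detected modes
#'
#' @param profile data.frame from [allele_balance_profile()] or numeric AB
#'   vector.
#' @param bandwidth,min_rel_density passed to [detect_modes()].
#' @param main plot title.
#' @return the detected modes, invisibly.
#' @export
plot_allele_balance <- function(profile, bandwidth = 0.02,
                                min_rel_density = 0.1, main = NULL) {
  ab <- if (is.data.frame(profile)) profile$ab else as.numeric(profile)
  d <- density(ab, bw = bandwidth, n = 512, from = 0, to = 1)
  modes <- detect_modes(ab, bandwidth, min_rel_density)
  graphics::plot(d, main = main %||% attr(profile, "sample") %||% "",
                 xlab = "alternative-allele balance", xlim = c(0, 1))
  graphics::abline(v = modes$position, col = "firebrick", lty = 2)
  invisible(modes)
}
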