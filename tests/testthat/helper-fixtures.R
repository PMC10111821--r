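# Fixture builders and independent brute-force oracles.
# The oracles deliberately use slow, loop-based, rule-by-rule logic so they
# share no code path with the package implementations they check.

# Minimal variant_set builder with all-passing INFO annotations.
make_vs <- function(gt, ad = NULL, chrom = "chr1", pos = NULL, ref = "A",
                    alt = "T", qual = 100, info = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  pos <- pos %||% seq_len(n)
  if (is.null(info)) {
    info <- data.frame(MQ = rep(60, n), QD = 20, FS = 1, MQRankSum = 0,
                       ReadPosRankSum = 0, SOR = 1, DP = 30)
  }
  variant_set(chrom = rep_len(chrom, n), pos = pos, ref = rep_len(ref, n),
              alt = rep_len(alt, n), gt = gt, ad = ad, qual = qual,
              info = info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random fuzz variant_set exercising thresholds boundaries, missing data,
# multiallelic sites and indels.
random_vs <- function(n, samples = c("s1", "s2", "s3"), seed = 1) {
  withr::with_seed(seed, {
    n_alts <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    ref <- sample(c("A", "C", "G", "T", "AT", "ATTT"), n, replace = TRUE,
                  prob = c(rep(0.2, 4), 0.1, 0.1))
    alt <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "TA", "TAAAG"), n_alts[i]),
            collapse = ",")
    }, character(1))
    info <- data.frame(
      MQ = round(runif(n, 30, 70), 3), QD = round(runif(n, 0, 10), 3),
      FS = round(runif(n, 0, 120), 3), MQRankSum = round(runif(n, -20, 5), 3),
      ReadPosRankSum = round(runif(n, -12, 4), 3),
      SOR = round(runif(n, 0, 6), 3), DP = sample(5:40, n, replace = TRUE))
    for (k in names(info)) info[[k]][runif(n) < 0.05] <- NA
    gt <- matrix("", n, length(samples))
    ad <- matrix("", n, length(samples))
    for (j in seq_along(samples)) {
      for (i in seq_len(n)) {
        if (runif(1) < 0.07) {
          gt[i, j] <- "./."
          ad[i, j] <- NA_character_
        } else {
          a <- sample(0:n_alts[i], 2, replace = TRUE)
          gt[i, j] <- paste(sort(a), collapse = "/")
          ad[i, j] <- paste(sample(0:30, n_alts[i] + 1, replace = TRUE),
                            collapse = ",")
        }
      }
    }
    variant_set(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                pos = sort(sample.int(10 * n, n)), ref = ref, alt = alt,
                gt = gt, ad = ad, qual = round(runif(n, 10, 200), 2),
                info = info, samples = samples)
  })
}

# --- independent oracles ----------------------------------------------------

# SNV hard filter, re-coded rule by rule from the printed thresholds.
oracle_snv_pass <- function(x, i) {
  inf <- x$info[i, ]
  vals <- c(inf$MQ, inf$QD, inf$FS, inf$MQRankSum, inf$ReadPosRankSum,
            inf$SOR, inf$DP)
  if (any(is.na(vals))) return(FALSE)
  if (!(inf$MQ > 40)) return(FALSE)
  if (!(inf$QD > 2)) return(FALSE)
  if (!(inf$FS < 60)) return(FALSE)
  if (!(inf$MQRankSum > -12.5)) return(FALSE)
  if (!(inf$ReadPosRankSum > -8)) return(FALSE)
  if (!(inf$SOR < 3)) return(FALSE)
  if (!(inf$DP >= 10)) return(FALSE)
  alts <- strsplit(x$meta$alt[i], ",")[[1]]
  if (length(alts) != 1) return(FALSE)
  for (g in x$gt[i, ]) if (grepl(".", g, fixed = TRUE)) return(FALSE)
  TRUE
}

# Point-in-interval by linear scan over a data.frame of 1-based closed
# intervals.
oracle_point_in <- function(chrom, pos, iv) {
  for (r in seq_len(nrow(iv))) {
    if (iv$chrom[r] == chrom && pos >= iv$start1[r] && pos <= iv$end1[r])
      return(TRUE)
  }
  FALSE
}

# Columns a strict "keep variable sites" trim should retain.
oracle_trim_keep <- function(seqm) {
  keep <- logical(ncol(seqm))
  for (j in seq_len(ncol(seqm))) {
    st <- unique(seqm[, j])
    st <- st[st != "N"]
    keep[j] <- length(st) >= 2
  }
  keep
}

# Pairwise mismatch fraction with pairwise N deletion, by double loop.
oracle_p_distance <- function(seqm) {
  n <- nrow(seqm)
  d <- matrix(0, n, n, dimnames = list(rownames(seqm), rownames(seqm)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- seqm[i, ] != "N" & seqm[j, ] != "N"
    d[i, j] <- sum(seqm[i, ok] != seqm[j, ok]) / sum(ok)
  }
  d
}

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    val <- min(prev, p[o[r]] * n / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

# Unrooted bipartition set of a phylo tree as a canonical string set.
bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  parts <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    other <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(other) < 2) return(NA_character_)
    paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
          collapse = "")
  }, character(1))
  sort(unique(parts[!is.na(parts)]))
}

default_diploid_groups <- function(sheet) {
  dip <- sheet$ploidy == 2
  split(sheet$sample[dip], sheet$group[dip])
}
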