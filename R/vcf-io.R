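#' Read a multi-sample VCF into a variant_set
#'
#' Parses a plain-text (or gzipped) VCF v4.2 with `GT` and `AD` FORMAT
#' fields. Records are returned in file order; missing genotypes are kept as
#' missing, never imputed; allele and AD ordering is preserved verbatim.
#' Multi-allelic records are retained here and rejected later by the filter
#' stage, so that filter removal counts stay observable.
#'
#' @param path path to the VCF file.
#' @param sample_sheet optional sample sheet (see [read_sample_sheet()]);
#'   every sheet sample must be present in the VCF header.
#' @return a [variant_set] carrying all samples in header order.
#' @export
read_vcf <- function(path, sample_sheet = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !identical(hdr, seq_along(hdr)))
    stop2("VCF parse error at line %d: header lines must precede records",
          if (length(hdr)) hdr[length(hdr)] else 1L)
  chrom_line <- grep("^#CHROM\t", lines[hdr])
  if (length(chrom_line) != 1)
    stop2("VCF parse error: expected exactly one #CHROM header line")
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT")
  if (length(cols) < 10 || !identical(cols[1:9], fixed_cols))
    stop2("VCF parse error at line %d: malformed #CHROM line (GT/AD data requires FORMAT and >= 1 sample)",
          chrom_line)
  samples <- cols[-(1:9)]
  if (!is.null(sample_sheet)) {
    missing_s <- setdiff(sample_sheet$sample, samples)
    if (length(missing_s))
      stop2("configuration error: sample sheet samples absent from VCF header: %s",
            paste(missing_s, collapse = ", "))
  }

  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  n <- length(body_idx)
  if (n == 0) {
    return(variant_set(character(), integer(), character(), character(),
                       gt = matrix(character(), 0, length(samples),
                                   dimnames = list(NULL, samples))))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(cols))
  if (length(bad))
    stop2("VCF parse error at line %d: %d fields, expected %d",
          body_idx[bad[1]], nf[bad[1]], length(cols))
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)

  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop2("VCF parse error at line %d: non-integer POS",
          body_idx[which(is.na(pos))[1]])
  qual <- suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6])))
  alt <- m[, 5]
  n_alts <- ifelse(alt == ".", 0L,
                   nchar(alt) - nchar(gsub(",", "", alt, fixed = TRUE)) + 1L)

  info <- parse_info(m[, 8])
  fmt <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_i <- vapply(fmt, function(f) match("GT", f), integer(1))
  ad_i <- vapply(fmt, function(f) match("AD", f), integer(1))
  if (anyNA(gt_i))
    stop2("VCF parse error at line %d: FORMAT lacks GT",
          body_idx[which(is.na(gt_i))[1]])

  gt <- matrix(NA_character_, n, length(samples))
  ad <- matrix(NA_character_, n, length(samples))
  for (j in seq_along(samples)) {
    sf <- strsplit(m[, 9 + j], ":", fixed = TRUE)
    gt[, j] <- mapply(function(f, i) f[i], sf, gt_i)
    ad[, j] <- mapply(function(f, i) if (is.na(i) || i > length(f)) NA_character_ else f[i],
                      sf, ad_i)
  }
  ad[!is.na(ad) & (ad == "." | ad == "")] <- NA_character_

  # AD, when present, must align to [ref] + alts
  ad_n <- nchar(ad) - nchar(gsub(",", "", ad, fixed = TRUE)) + 1L
  bad_ad <- which(!is.na(ad) & ad_n != rep(1L + n_alts, length(samples)))
  if (length(bad_ad)) {
    r <- (bad_ad[1] - 1L) %% n + 1L
    stop2("VCF parse error at line %d: AD has %d entries, expected %d",
          body_idx[r], ad_n[bad_ad[1]], 1L + n_alts[r])
  }
  # genotype allele indices must be < 1 + n_alts
  max_idx <- suppressWarnings(vapply(strsplit(gt, "[/|]"), function(a) {
    a <- suppressWarnings(as.integer(a[a != "."]))
    if (length(a) == 0) -1L else max(a)
  }, integer(1)))
  bad_gt <- which(max_idx > rep(n_alts, length(samples)))
  if (length(bad_gt)) {
    r <- (bad_gt[1] - 1L) %% n + 1L
    stop2("VCF parse error at line %d: genotype allele index %d exceeds declared alleles",
          body_idx[r], max_idx[bad_gt[1]])
  }

  variant_set(chrom = m[, 1], pos = pos, ref = m[, 4], alt = alt,
              gt = gt, ad = ad, qual = qual, info = info,
              samples = samples)
}

# Extract the numeric INFO keys the filter stage consumes.
parse_info <- function(info_strings) {
  keys <- c("MQ", "QD", "FS", "MQRankSum", "ReadPosRankSum", "SOR", "DP")
  out <- lapply(keys, function(k) {
    v <- rep(NA_character_, length(info_strings))
    pat <- paste0("(?:^|;)", k, "=([^;]*)")
    hit <- regexpr(pat, info_strings, perl = TRUE)
    has <- hit > 0
    v[has] <- sub(paste0(".*(?:^|;)", k, "=([^;]*).*"), "\\1",
                  info_strings[has])
    suppressWarnings(as.numeric(v))
  })
  as.data.frame(setNames(out, keys))
}

#' Write a variant_set as VCF v4.2
#'
#' @param x a [variant_set].
#' @param path output path (plain text; `.gz` suffix gzips).
#' @param contig_lengths optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=polyplex",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank-sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank-sum">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  chroms <- unique(x$meta$chrom)
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                          as.integer(contig_lengths)))
  } else if (length(chroms)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", chroms))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", x$samples), collapse = "\t"))

  fmt_num <- function(v) ifelse(is.na(v), ".",
                                formatC(v, format = "g", digits = 6))
  info_keys <- c("MQ", "QD", "FS", "MQRankSum", "ReadPosRankSum", "SOR", "DP")
  info_str <- apply(x$info[info_keys], 1, function(r) {
    has <- !is.na(r)
    if (!any(has)) return(".")
    paste(paste0(info_keys[has], "=", fmt_num(r[has])), collapse = ";")
  })
  ad_dp <- x$ad
  dp_str <- matrix(".", nrow(ad_dp), ncol(ad_dp))
  present <- !is.na(ad_dp)
  dp_str[present] <- vapply(strsplit(ad_dp[present], ",", fixed = TRUE),
                            function(a) as.character(sum(as.numeric(a))),
                            character(1))
  cells <- matrix(paste(x$gt, ifelse(is.na(x$ad), ".", x$ad), dp_str,
                        sep = ":"),
                  nrow = nrow(x$gt))
  body <- paste(x$meta$chrom, x$meta$pos, ".", x$meta$ref, x$meta$alt,
                ifelse(is.na(x$meta$qual), ".", fmt_num(x$meta$qual)),
                "PASS", info_str, "GT:AD:DP",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  if (n_sites(x) == 0) body <- character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a tab-separated sample sheet
#'
#' Columns: `sample`, `group`, `ploidy` (2, 4 or 6), `compartment`
#' (`nuclear`, `plastid` or `mitochondrial`). Sample names must be unique;
#' ploidy must be even and at least 2.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path else
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "group", "ploidy", "compartment")
  if (!all(need %in% names(sheet)))
    stop2("sample sheet must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample))
    stop2("duplicate sample names in sample sheet")
  sheet$ploidy <- as.integer(sheet$ploidy)
  if (any(is.na(sheet$ploidy) | sheet$ploidy < 2 | sheet$ploidy %% 2 != 0))
    stop2("ploidy must be even and >= 2")
  bad <- setdiff(unique(sheet$compartment),
                 c("nuclear", "plastid", "mitochondrial"))
  if (length(bad))
    stop2("unknown compartment: %s", paste(bad, collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame.
#' @param path output TSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
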