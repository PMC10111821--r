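#' Build a SNV pseudo-alignment against a reference
#'
#' Each sample's sequence is obtained by substituting its SNV alleles into
#' the reference at the variant positions, one alignment column per
#' retained site. In `nuclear` mode only homozygous positions are used:
#' any site with a heterozygous call in *any* sample is dropped (a column
#' needs one state per sample), unless `het_policy = "mask"`, which instead
#' writes `N` for the heterozygous samples. In `organelle` mode calls are
#' treated as haploid (first allele, with a warning on within-sample
#' heterozygosity). Missing genotypes become `N`.
#'
#' @param x a [variant_set] of filtered biallelic SNVs.
#' @param reference a [Biostrings::DNAStringSet] or FASTA path covering all
#'   record positions; record REF alleles are checked against it.
#' @param samples samples to include (default all).
#' @param mode `"nuclear"` or `"organelle"`.
#' @param het_policy nuclear-mode handling of heterozygous sites:
#'   `"drop_site"` (default) or `"mask"`.
#' @param include_reference add the reference itself as a row.
#' @return object of class `pseudo_alignment`: character matrix `seq`
#'   (samples x columns over A/C/G/T/N), `labels`, `provenance`
#'   (chrom, pos per column), `compartment`.
#' @export
build_pseudoalignment <- function(x, reference, samples = NULL,
                                  mode = c("nuclear", "organelle"),
                                  het_policy = c("drop_site", "mask"),
                                  include_reference = FALSE) {
  mode <- match.arg(mode)
  het_policy <- match.arg(het_policy)
  samples <- samples %||% x$samples
  if (is.character(reference) && length(reference) == 1)
    reference <- Biostrings::readDNAStringSet(reference)
  ref_names <- sub("\\s.*", "", names(reference))
  if (any(!(x$meta$chrom %in% ref_names)))
    stop2("reference lacks sequence(s): %s",
          paste(setdiff(unique(x$meta$chrom), ref_names), collapse = ", "))
  if (any(n_alt(x) != 1L)) stop2("pseudo-alignment requires biallelic sites")

  # verify the record REF alleles against the reference sequence
  ref_base <- character(n_sites(x))
  for (chr in unique(x$meta$chrom)) {
    i <- which(x$meta$chrom == chr)
    seq_chr <- reference[[match(chr, ref_names)]]
    if (any(x$meta$pos[i] > length(seq_chr)))
      stop2("position %d beyond end of %s",
            max(x$meta$pos[i]), chr)
    ref_base[i] <- as.character(Biostrings::extractAt(
      seq_chr, IRanges::IRanges(x$meta$pos[i], x$meta$pos[i])))
  }
  mism <- which(toupper(ref_base) != toupper(x$meta$ref))
  if (length(mism))
    stop2("REF allele mismatch at %s:%d (record %s, reference %s)",
          x$meta$chrom[mism[1]], x$meta$pos[mism[1]],
          x$meta$ref[mism[1]], ref_base[mism[1]])

  dos <- gt_dosage(x)[, samples, drop = FALSE]
  pl <- gt_ploidy(x)[, samples, drop = FALSE]
  keep <- rep(TRUE, n_sites(x))
  if (mode == "nuclear") {
    het <- !is.na(dos) & dos > 0 & dos < pl
    if (het_policy == "drop_site") {
      keep <- rowSums(het) == 0
      state_alt <- !is.na(dos) & dos == pl
      state_n <- is.na(dos)
    } else {
      state_alt <- !is.na(dos) & dos == pl
      state_n <- is.na(dos) | het
    }
  } else {
    first <- sub("[/|].*", "", x$gt[, samples, drop = FALSE])
    dim(first) <- dim(dos)
    if (any(!is.na(dos) & dos > 0 & dos < pl))
      warning("heterozygous call(s) in organelle mode; using first allele")
    state_alt <- first == "1"
    state_n <- first == "."
  }
  idx <- which(keep)
  seqm <- matrix(rep(toupper(x$meta$ref[idx]), length(samples)),
                 nrow = length(samples), byrow = TRUE)
  altm <- matrix(rep(toupper(x$meta$alt[idx]), length(samples)),
                 nrow = length(samples), byrow = TRUE)
  sa <- t(state_alt[idx, , drop = FALSE])
  sn <- t(state_n[idx, , drop = FALSE])
  seqm[sa] <- altm[sa]
  seqm[sn] <- "N"
  labels <- samples
  if (include_reference) {
    seqm <- rbind(seqm, toupper(x$meta$ref[idx]))
    labels <- c(labels, "reference")
  }
  rownames(seqm) <- labels
  structure(list(seq = seqm, labels = labels,
                 provenance = data.frame(chrom = x$meta$chrom[idx],
                                         pos = x$meta$pos[idx],
                                         stringsAsFactors = FALSE),
                 compartment = mode), class = "pseudo_alignment")
}

#' @export
print.pseudo_alignment <- function(x, ...) {
  cat(sprintf("pseudo_alignment: %d sequences x %d columns (%s)\n",
              nrow(x$seq), ncol(x$seq), x$compartment))
  invisible(x)
}

#' Trim a pseudo-alignment to its informative columns
#'
#' Retains exactly the variable columns — those with at least two distinct
#' non-N states — a strict trimAl-style removal of non-informative
#' positions. Idempotent; provenance is carried along.
#'
#' @param aln a [build_pseudoalignment()] result.
#' @return trimmed `pseudo_alignment` (possibly zero columns, with a
#'   warning).
#' @export
trim_alignment <- function(aln) {
  stopifnot(inherits(aln, "pseudo_alignment"))
  keep <- apply(aln$seq, 2, function(col) {
    length(unique(col[col != "N"])) >= 2
  })
  if (!any(keep)) warning("no variable columns; alignment trimmed to zero")
  aln$seq <- aln$seq[, keep, drop = FALSE]
  aln$provenance <- aln$provenance[keep, , drop = FALSE]
  aln
}

#' Pairwise p-distance matrix of a pseudo-alignment
#'
#' `d(i, j)` is the mismatch fraction over the columns where neither
#' sequence is `N` (pairwise deletion), computed through
#' [ape::dist.dna()] with the raw model.
#'
#' @param aln a `pseudo_alignment`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "pseudo_alignment"), nrow(aln$seq) >= 2,
            ncol(aln$seq) >= 1)
  bin <- ape::as.DNAbin(tolower(aln$seq))
  d <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  if (any(!is.finite(d)))
    stop2("a sequence pair shares no comparable (non-N) column")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]); additive distance matrices
#' are recovered exactly, topology and branch lengths.
#'
#' @param d symmetric non-negative distance matrix, >= 3 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop2("neighbor joining needs >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop2("distance matrix is not symmetric")
  if (any(d < 0)) stop2("distance matrix has negative entries")
  ape::nj(as.dist(d))
}

#' Bootstrap support for the NJ tree of a pseudo-alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and reports for every internal edge of
#' the full-data tree the percentage of replicates containing the same
#' bipartition. Seeded and reproducible.
#'
#' @param aln a `pseudo_alignment`.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return the full-data NJ tree with integer percent supports in
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (ncol(aln$seq) < 2)
    warning("single-column alignment; bootstrap support is degenerate")
  ref <- nj_tree(p_distance_matrix(aln))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(aln$seq), replace = TRUE)
      b <- aln
      b$seq <- aln$seq[, cols, drop = FALSE]
      b$provenance <- aln$provenance[cols, , drop = FALSE]
      tryCatch(nj_tree(p_distance_matrix(b)), error = function(e) NULL)
    })
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_reps))
  ref$node.label <- as.character(support)
  ref$node.label[1] <- ""  # root of the unrooted representation
  ref
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree; duplicate leaf labels are an error.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop2("duplicate leaf label: %s",
          tree$tip.label[duplicated(tree$tip.label)][1])
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a pseudo-alignment as FASTA or relaxed PHYLIP
#'
#' @param aln a `pseudo_alignment`.
#' @param path output path.
#' @param format `"fasta"` or `"phylip"` (relaxed: labels of any length,
#'   one space separator).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(c(sprintf("%d %d", nrow(aln$seq), ncol(aln$seq)),
                 paste(names(seqs), seqs)), path)
  }
  invisible(path)
}
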