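#' Configuration for the synthetic species-complex simulator
#'
#' The simulator emulates the data shape the pipeline is built for: a set
#' of diverged diploid lineages related by a ladder (caterpillar) tree —
#' the last lineage splitting first, so it behaves as the natural
#' outgroup — one allotetraploid formed as the union of two parental
#' diploid genomes, optionally one allohexaploid formed from the
#' tetraploid plus a third diploid genome, optional introgression between
#' lineages, and binomially sampled read depths at every genotype.
#'
#' Mutations follow an infinite-sites biallelic model (no recurrent
#' mutation, no recombination; sites are independent given the lineage
#' tree) in four classes: fixed differences on internal branches, fixed
#' lineage-private differences, within-lineage segregating sites
#' (Hardy-Weinberg), and ancestral polymorphisms whose frequencies drift
#' down the tree by hierarchical binomial resampling — the class that
#' yields the incomplete-lineage-sorting noise an ABBA-BABA test needs.
#'
#' @param genome_length total genome length in bp.
#' @param n_chrom chromosomes (equal length).
#' @param n_lineages number of diploid lineages (>= 2).
#' @param divergence expected substitutions/site on each terminal branch
#'   (scalar or per-lineage).
#' @param internal_branch expected substitutions/site per internal branch.
#' @param theta_within expected within-lineage segregating sites per bp.
#' @param theta_ancestral expected ancestral polymorphic sites per bp.
#' @param drift_copies granularity of the binomial drift steps (smaller =
#'   stronger drift); the default gives subspecies-scale differentiation
#'   (a sizeable share of ancestral polymorphisms sorts to fixation),
#'   consistent with lineages that carry fixed differences.
#' @param tetraploid integer pair `c(i, j)`: the allotetraploid's parental
#'   lineages, or NULL for none.
#' @param hexaploid integer `k`: allohexaploid = tetraploid x lineage k,
#'   or NULL.
#' @param poly_divergence expected post-formation private mutations/bp per
#'   polyploid sample.
#' @param introgression NULL or `list(donor =, recipient =, fraction =)`
#'   (lineage indices and the fraction of polymorphic sites whose
#'   recipient frequency is replaced by the donor's).
#' @param samples_per_lineage diploid individuals sampled per lineage.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param error_rate per-read base error rate.
#' @param seed RNG seed (mandatory).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000, n_chrom = 5, n_lineages = 4,
                       divergence = 0.008, internal_branch = 0.004,
                       theta_within = 0.005, theta_ancestral = 0.005,
                       drift_copies = 8, tetraploid = c(1, 2),
                       hexaploid = 3, poly_divergence = 0.002,
                       introgression = NULL, samples_per_lineage = 2,
                       mean_depth = 30, error_rate = 0.002, seed = NULL) {
  if (is.null(seed)) stop2("sim_config: seed is mandatory")
  stopifnot(genome_length >= n_chrom, n_lineages >= 2,
            mean_depth > 0, error_rate >= 0, error_rate < 0.5,
            samples_per_lineage >= 1)
  divergence <- rep_len(divergence, n_lineages)
  if (!is.null(tetraploid)) {
    stopifnot(length(tetraploid) == 2)
    if (any(tetraploid < 1 | tetraploid > n_lineages))
      stop2("config error: tetraploid parent lineage undefined")
  }
  if (!is.null(hexaploid)) {
    if (is.null(tetraploid))
      stop2("config error: hexaploid requires a tetraploid")
    if (hexaploid < 1 || hexaploid > n_lineages)
      stop2("config error: hexaploid parent lineage undefined")
  }
  if (!is.null(introgression)) {
    stopifnot(all(c("donor", "recipient", "fraction") %in%
                    names(introgression)))
    if (introgression$fraction < 0 || introgression$fraction > 1)
      stop2("introgression fraction must lie in [0, 1]")
    if (any(c(introgression$donor, introgression$recipient) > n_lineages))
      stop2("config error: introgression lineage undefined")
  }
  structure(as.list(environment()), class = "sim_config")
}

# ladder tree newick over lineages L1..Ln with terminal/internal lengths
lineage_tree_newick <- function(n, divergence, internal_branch) {
  lab <- paste0("L", seq_len(n))
  nwk <- sprintf("%s:%g", lab[1], divergence[1])
  for (i in 2:n) {
    nwk <- sprintf("(%s,%s:%g):%g", nwk, lab[i], divergence[i],
                   if (i < n) internal_branch else 0)
  }
  paste0(nwk, ";")
}

#' Simulate a mixed-ploidy species complex with known truth
#'
#' Generates the full standard-format bundle the pipeline consumes — a
#' reference genome, a multi-sample VCF with GT/AD/DP and passing INFO
#' annotations, and a sample sheet — together with a ground-truth record
#' (lineage allele frequencies, the lineage tree, hybrid parentage, the
#' introgressed site set, every sample's true dosage) for recovery tests.
#'
#' Diploid genotypes are Hardy-Weinberg draws from their lineage's allele
#' frequency. The allotetraploid founder genotype is a diploid draw from
#' parent i plus a diploid draw from parent j (4 copies); the allohexaploid
#' is the tetraploid founder plus a diploid draw from lineage k (6 copies).
#' Allele depths are `depth ~ Poisson(mean_depth)` (zero resampled to 1)
#' with `alt ~ Binomial(depth, dosage/ploidy)` plus symmetric read error.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_complex`: `variants` ([variant_set]),
#'   `reference` (DNAStringSet), `sheet` (sample sheet), `truth`, `config`.
#' @export
simulate_complex <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    L <- cf$genome_length
    n <- cf$n_lineages

    # --- per-class mutation sites and lineage allele frequencies ---------
    freqs <- list(); classes <- character(0)
    add_sites <- function(fmat, cls) {
      if (nrow(fmat) == 0) return()
      freqs[[length(freqs) + 1L]] <<- fmat
      classes <<- c(classes, rep(cls, nrow(fmat)))
    }
    # internal branches of the ladder: clade {L1..Lc}, c = 2..n-1
    if (n >= 3) {
      for (cl in 2:(n - 1)) {
        m <- rpois(1, cf$internal_branch * L)
        if (m > 0) {
          f <- matrix(0, m, n)
          f[, 1:cl] <- 1
          add_sites(f, sprintf("clade_%d", cl))
        }
      }
    }
    # lineage-private fixed differences
    for (i in seq_len(n)) {
      m <- rpois(1, cf$divergence[i] * L)
      if (m > 0) {
        f <- matrix(0, m, n)
        f[, i] <- 1
        add_sites(f, sprintf("private_L%d", i))
      }
    }
    # within-lineage segregating sites
    for (i in seq_len(n)) {
      m <- rpois(1, cf$theta_within * L)
      if (m > 0) {
        f <- matrix(0, m, n)
        f[, i] <- runif(m, 0.1, 0.9)
        add_sites(f, sprintf("segregating_L%d", i))
      }
    }
    # ancestral polymorphism with hierarchical binomial drift down the
    # ladder: the root splits (L1..L(n-1)) vs Ln, then peels off lineages
    m_anc <- rpois(1, cf$theta_ancestral * L)
    if (m_anc > 0) {
      drift <- function(p) rbinom(length(p), cf$drift_copies, p) /
        cf$drift_copies
      f <- matrix(0, m_anc, n)
      q <- runif(m_anc, 0.1, 0.9)
      node <- q
      for (i in n:2) {
        f[, i] <- drift(node)   # terminal edge to Li
        node <- drift(node)     # internal edge continuing toward L1
      }
      f[, 1] <- drift(node)
      add_sites(f, "ancestral_poly")
    }
    freq <- do.call(rbind, freqs)
    m <- nrow(freq)
    if (is.null(freq)) { freq <- matrix(0, 0, n); m <- 0L }

    # --- introgression: recipient frequency replaced by donor's ----------
    introgressed <- integer(0)
    if (!is.null(cf$introgression) && m > 0 &&
        cf$introgression$fraction > 0) {
      k <- round(cf$introgression$fraction * m)
      introgressed <- sort(sample.int(m, min(k, m)))
      freq[introgressed, cf$introgression$recipient] <-
        freq[introgressed, cf$introgression$donor]
    }

    # --- samples and true genotype dosages -------------------------------
    sample_names <- character(0); sample_group <- character(0)
    sample_ploidy <- integer(0)
    dosage <- NULL
    add_sample <- function(name, group, ploidy, dos) {
      sample_names <<- c(sample_names, name)
      sample_group <<- c(sample_group, group)
      sample_ploidy <<- c(sample_ploidy, ploidy)
      dosage <<- cbind(dosage, dos)
    }
    for (i in seq_len(n)) {
      for (s in seq_len(cf$samples_per_lineage)) {
        add_sample(sprintf("L%d_%d", i, s), paste0("L", i), 2L,
                   rbinom(m, 2, freq[, i]))
      }
    }
    truth_parents <- list()
    tet_founder <- NULL
    if (!is.null(cf$tetraploid)) {
      g1 <- rbinom(m, 2, freq[, cf$tetraploid[1]])
      g2 <- rbinom(m, 2, freq[, cf$tetraploid[2]])
      tet_founder <- g1 + g2
      add_sample("tet_1", "tetraploid", 4L, tet_founder)
      truth_parents$tetraploid <- paste0("L", cf$tetraploid)
    }
    if (!is.null(cf$hexaploid)) {
      g3 <- rbinom(m, 2, freq[, cf$hexaploid])
      add_sample("hex_1", "hexaploid", 6L, tet_founder + g3)
      truth_parents$hexaploid <- c("tetraploid", paste0("L", cf$hexaploid))
    }
    n_samp <- length(sample_names)

    # post-formation private mutations (dosage 1) per polyploid sample
    if (cf$poly_divergence > 0) {
      for (j in which(sample_ploidy > 2L)) {
        mp <- rpois(1, cf$poly_divergence * L)
        if (mp > 0) {
          freq <- rbind(freq, matrix(0, mp, n))
          classes <- c(classes, rep(paste0("private_", sample_names[j]), mp))
          extra <- matrix(0L, mp, n_samp)
          extra[, j] <- 1L
          dosage <- rbind(dosage, extra)
          if (length(introgressed)) introgressed <- introgressed  # unchanged
        }
      }
      m <- nrow(freq)
    }

    # drop sites never observed as alternate in any sample
    seen <- rowSums(dosage) > 0
    freq <- freq[seen, , drop = FALSE]
    dosage <- dosage[seen, , drop = FALSE]
    classes <- classes[seen]
    introgressed <- match(introgressed, which(seen))
    introgressed <- introgressed[!is.na(introgressed)]
    m <- nrow(freq)

    # interleave mutation classes along the genome: sites of every class
    # must be spread over all chromosomes, not stacked by generation order
    ord <- sample.int(m)
    freq <- freq[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    classes <- classes[ord]
    introgressed <- sort(match(introgressed, ord))

    # --- genome coordinates and reference --------------------------------
    chrom_len <- rep(L %/% cf$n_chrom, cf$n_chrom)
    chrom_len[cf$n_chrom] <- L - sum(chrom_len[-cf$n_chrom])
    chrom_names <- sprintf("chr%d", seq_len(cf$n_chrom))
    gpos <- sort(sample.int(L, m))
    chrom_of <- findInterval(gpos - 1, cumsum(c(0, chrom_len))[1:cf$n_chrom])
    chrom <- chrom_names[chrom_of]
    pos <- gpos - cumsum(c(0, chrom_len))[chrom_of]
    ref_seqs <- Biostrings::DNAStringSet(vapply(chrom_len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1)))
    names(ref_seqs) <- chrom_names
    ref_chars <- as.character(ref_seqs)
    ref_allele <- substring(ref_chars[chrom_of], pos, pos)
    bases <- c("A", "C", "G", "T")
    other <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
    alt_allele <- other[cbind(match(ref_allele, bases),
                              sample.int(3, m, replace = TRUE))]

    # --- reads: AD and GT strings ----------------------------------------
    gt <- matrix(NA_character_, m, n_samp)
    ad <- matrix(NA_character_, m, n_samp)
    depth_site <- integer(m)
    for (j in seq_len(n_samp)) {
      k <- sample_ploidy[j]
      d <- dosage[, j]
      depth <- rpois(m, cf$mean_depth)
      depth[depth == 0] <- 1L
      p_alt <- (d / k) * (1 - cf$error_rate) + (1 - d / k) * cf$error_rate
      alt_reads <- rbinom(m, depth, p_alt)
      ad[, j] <- paste(depth - alt_reads, alt_reads, sep = ",")
      gt_by_dosage <- vapply(0:k, function(di)
        paste(c(rep("0", k - di), rep("1", di)), collapse = "/"),
        character(1))
      gt[, j] <- gt_by_dosage[d + 1L]
      depth_site <- depth_site + depth
    }

    info <- data.frame(MQ = rep(60, m), QD = rep(25, m), FS = rep(1, m),
                       MQRankSum = rep(0.2, m),
                       ReadPosRankSum = rep(0.5, m), SOR = rep(1, m),
                       DP = depth_site)
    variants <- variant_set(chrom = chrom, pos = pos, ref = ref_allele,
                            alt = alt_allele, gt = gt, ad = ad,
                            qual = 1000, info = info,
                            samples = sample_names)
    sheet <- data.frame(sample = sample_names, group = sample_group,
                        ploidy = sample_ploidy, compartment = "nuclear",
                        stringsAsFactors = FALSE)
    tree <- ape::read.tree(text = lineage_tree_newick(
      n, cf$divergence, cf$internal_branch))
    truth <- list(
      lineage_freq = freq, site_class = classes,
      dosage = dosage, tree = tree,
      parents = truth_parents,
      introgressed_sites = introgressed,
      ploidy = setNames(sample_ploidy, sample_names),
      chrom_lengths = setNames(chrom_len, chrom_names))
    structure(list(variants = variants, reference = ref_seqs, sheet = sheet,
                   truth = truth, config = cf), class = "sim_complex")
  })
}

#' @export
print.sim_complex <- function(x, ...) {
  cat(sprintf("sim_complex: %d lineages, %d samples, %d variant sites, seed %d\n",
              x$config$n_lineages, length(x$variants$samples),
              n_sites(x$variants), x$config$seed))
  invisible(x)
}

#' Write the simulated bundle to standard-format files
#'
#' Emits `ref.fa`, `sim.vcf`, `samples.tsv` and `truth.json` (plus
#' `repeats.bed` / `genes.gff3` when annotation fractions are requested)
#' under `out_dir`.
#'
#' @param sim a [simulate_complex()] result.
#' @param out_dir output directory.
#' @param repeat_fraction,gene_fraction optional annotation coverage
#'   fractions forwarded to [make_annotations()].
#' @return named character vector of written paths.
#' @export
write_sim_bundle <- function(sim, out_dir, repeat_fraction = NULL,
                             gene_fraction = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(out_dir, "ref.fa"),
    vcf = file.path(out_dir, "sim.vcf"),
    sheet = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(sim$reference, paths["reference"])
  write_vcf(sim$variants, paths["vcf"],
            contig_lengths = sim$truth$chrom_lengths)
  write_sample_sheet(sim$sheet, paths["sheet"])
  truth_json <- list(
    parents = sim$truth$parents,
    tree = ape::write.tree(sim$truth$tree),
    ploidy = as.list(sim$truth$ploidy),
    n_sites = n_sites(sim$variants),
    introgressed_sites = sim$truth$introgressed_sites,
    seed = sim$config$seed)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE)
  if (!is.null(repeat_fraction) || !is.null(gene_fraction)) {
    ann <- make_annotations(sum(sim$truth$chrom_lengths),
                            repeat_fraction %||% 0, gene_fraction %||% 0,
                            seed = sim$config$seed + 1L,
                            n_chrom = length(sim$truth$chrom_lengths))
    paths["repeats"] <- file.path(out_dir, "repeats.bed")
    paths["genes"] <- file.path(out_dir, "genes.gff3")
    write_intervals(ann$repeats, paths["repeats"], "bed")
    write_intervals(ann$genes, paths["genes"], "gff3")
  }
  paths
}

#' Simulate an allele-balance profile for a k-ploid sample
#'
#' The generative counterpart of the ploidy-estimation model: per
#' heterozygous site the alternate-allele dosage is uniform on 1..k-1,
#' depth is Poisson (zeros resampled to 1), alternate reads are
#' `Binomial(depth, dosage/k)`, and sites whose draw lands at 0 or full
#' depth are excluded (they would not be called heterozygous).
#'
#' @param k ploidy in `{2, 4, 6}`.
#' @param n_sites number of heterozygous sites to draw.
#' @param depth_mean mean depth.
#' @param seed RNG seed.
#' @return data.frame (`chrom`, `pos`, `ab`) as from
#'   [allele_balance_profile()].
#' @export
simulate_allele_balance <- function(k, n_sites, depth_mean = 30,
                                    seed = NULL) {
  if (!k %in% c(2, 4, 6)) stop2("k must be one of 2, 4, 6")
  stopifnot(is_count(n_sites))
  with_seed(seed, {
    dosage <- sample(seq_len(k - 1), n_sites, replace = TRUE)
    depth <- rpois(n_sites, depth_mean)
    depth[depth == 0] <- 1L
    alt <- rbinom(n_sites, depth, dosage / k)
    keep <- alt > 0 & alt < depth
    out <- data.frame(chrom = "sim", pos = seq_len(sum(keep)),
                      ab = alt[keep] / depth[keep],
                      stringsAsFactors = FALSE)
    attr(out, "sample") <- sprintf("sim_%dx", k)
    out
  })
}

#' Generate random repeat and gene annotation tracks
#'
#' Places fixed-length, non-adjacent intervals at random offsets inside
#' regularly spaced slots, so the covered fraction approximates the request
#' while intervals never touch. Deterministic under `seed`.
#'
#' @param genome_length total genome length (split into `n_chrom` equal
#'   chromosomes named `chr1..`).
#' @param repeat_fraction,gene_fraction target covered fractions in
#'   `[0, 1]`; a sum above 1 is allowed (tracks are independent and may
#'   overlap) but warned about.
#' @param seed RNG seed.
#' @param n_chrom chromosomes.
#' @param interval_length interval size in bp.
#' @return list of `GRanges`: `repeats` and `genes`.
#' @export
make_annotations <- function(genome_length, repeat_fraction, gene_fraction,
                             seed = NULL, n_chrom = 1,
                             interval_length = 1000) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1,
            gene_fraction >= 0, gene_fraction <= 1)
  if (repeat_fraction + gene_fraction > 1)
    warning("repeat + gene fractions exceed 1; tracks will overlap heavily")
  chrom_len <- rep(genome_length %/% n_chrom, n_chrom)
  chrom_len[n_chrom] <- genome_length - sum(chrom_len[-n_chrom])
  one_track <- function(fraction, prefix) {
    if (fraction == 0) {
      gr0 <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr0)$feature_id <- character(0)
      S4Vectors::mcols(gr0)$category <- character(0)
      return(gr0)
    }
    slot <- max(ceiling(interval_length / fraction), interval_length + 2)
    chroms <- character(0); starts <- integer(0)
    for (ci in seq_len(n_chrom)) {
      n_slots <- chrom_len[ci] %/% slot
      if (n_slots == 0) next
      offset <- sample.int(slot - interval_length - 1, n_slots,
                           replace = TRUE)
      chroms <- c(chroms, rep(sprintf("chr%d", ci), n_slots))
      starts <- c(starts, (seq_len(n_slots) - 1L) * slot + offset)
    }
    gr <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(start = starts, width = interval_length))
    S4Vectors::mcols(gr)$feature_id <- sprintf("%s_%04d", prefix,
                                               seq_along(gr))
    S4Vectors::mcols(gr)$category <- prefix
    gr
  }
  with_seed(seed, {
    reps <- one_track(repeat_fraction, "repeat")
    genes <- one_track(gene_fraction, "gene")
    list(repeats = reps, genes = genes)
  })
}
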