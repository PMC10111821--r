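ref10 <- Biostrings::DNAStringSet(c(chr1 = "AACGATTACA"))

test_that("pseudo-alignment substitutes homozygous alternates", {
  gt <- cbind(s1 = c("1/1", "0/0"), s2 = c("0/0", "1/1"))
  x <- make_vs(gt, pos = c(5, 8), ref = c("A", "A"), alt = c("T", "G"))
  aln <- build_pseudoalignment(x, ref10)
  expect_equal(ncol(aln$seq), 2)
  expect_equal(unname(aln$seq["s1", ]), c("T", "A"))
  expect_equal(unname(aln$seq["s2", ]), c("A", "G"))
  expect_equal(aln$provenance$pos, c(5, 8))
  # reference row on request
  aln <- build_pseudoalignment(x, ref10, include_reference = TRUE)
  expect_equal(unname(aln$seq["reference", ]), c("A", "A"))
})

test_that("nuclear mode drops (or masks) heterozygous sites", {
  gt <- cbind(s1 = c("1/1", "0/1"), s2 = c("0/0", "0/0"))
  x <- make_vs(gt, pos = c(5, 8), ref = c("A", "A"), alt = c("T", "G"))
  aln <- build_pseudoalignment(x, ref10)
  # site 2 is het in s1 -> column absent for ALL samples
  expect_equal(ncol(aln$seq), 1)
  expect_equal(aln$provenance$pos, 5)
  masked <- build_pseudoalignment(x, ref10, het_policy = "mask")
  expect_equal(ncol(masked$seq), 2)
  expect_equal(unname(masked$seq["s1", 2]), "N")
  expect_equal(unname(masked$seq["s2", 2]), "A")
})

test_that("organelle mode is haploid with a heterozygosity warning", {
  gt <- cbind(s1 = c("1/1", "1/0"), s2 = c("0/0", "0/0"))
  x <- make_vs(gt, pos = c(5, 8), ref = c("A", "A"), alt = c("T", "G"))
  expect_warning(aln <- build_pseudoalignment(x, ref10, mode = "organelle"),
                 "first allele")
  expect_equal(unname(aln$seq["s1", ]), c("T", "G"))
})

test_that("REF alleles are validated against the reference sequence", {
  gt <- cbind(s1 = "1/1", s2 = "0/0")
  x <- make_vs(gt, pos = 5, ref = "G", alt = "T")  # reference has A at 5
  expect_error(build_pseudoalignment(x, ref10), "mismatch at chr1:5")
  x2 <- make_vs(gt, pos = 50, ref = "A", alt = "T")
  expect_error(build_pseudoalignment(x2, ref10), "beyond")
})

test_that("trimming keeps exactly the variable columns and is idempotent", {
  aln <- structure(list(
    seq = rbind(a = strsplit("AAAACGTGGA", "")[[1]],
                b = strsplit("AAATCGTGGA", "")[[1]],
                c = strsplit("ANAACGAGGA", "")[[1]]),
    labels = c("a", "b", "c"),
    provenance = data.frame(chrom = "chr1", pos = 1:10),
    compartment = "nuclear"), class = "pseudo_alignment")
  tr <- trim_alignment(aln)
  expect_equal(tr$provenance$pos, c(4, 7))   # the two variable columns
  expect_equal(trim_alignment(tr)$seq, tr$seq)
  same <- aln
  same$seq <- rbind(a = rep("A", 10), b = rep("A", 10))
  expect_warning(tr0 <- trim_alignment(same), "zero")
  expect_equal(ncol(tr0$seq), 0)
})

test_that("trimmed column sets equal a brute-force scan on fuzz alignments", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      seqm <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 200, TRUE,
                            prob = c(rep(0.23, 4), 0.08)), 6, 200,
                     dimnames = list(paste0("t", 1:6), NULL))
      aln <- structure(list(seq = seqm, labels = rownames(seqm),
                            provenance = data.frame(chrom = "c",
                                                    pos = 1:200),
                            compartment = "nuclear"),
                       class = "pseudo_alignment")
      tr <- trim_alignment(aln)
      expect_equal(tr$provenance$pos, which(oracle_trim_keep(seqm)))
    }
  })
})

test_that("p-distances equal a brute-force recount with pairwise deletion", {
  aln <- structure(list(
    seq = rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "T")),
    labels = c("a", "b"),
    provenance = data.frame(chrom = "c", pos = 1:4),
    compartment = "nuclear"), class = "pseudo_alignment")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))
  withr::with_seed(23, {
    seqm <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 200, TRUE,
                          prob = c(rep(0.24, 4), 0.04)), 6, 200,
                   dimnames = list(paste0("t", 1:6), NULL))
    aln$seq <- seqm
    aln$provenance <- data.frame(chrom = "c", pos = 1:200)
    d <- p_distance_matrix(aln)
    expect_equal(unname(d), unname(oracle_p_distance(seqm)),
                 tolerance = 1e-12)
    expect_true(isSymmetric(d))
  })
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  len <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(len[["A"]], 0.5)
  expect_equal(len[["B"]], 1.5)
  expect_equal(len[["C"]], 2.5)
  d_bad <- d; d_bad[1, 2] <- 5
  expect_error(nj_tree(d_bad), "not symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      src <- ape::rtree(8, br = function(n) runif(n, 0.05, 1))
      d <- ape::cophenetic.phylo(src)
      rec <- nj_tree(d[src$tip.label, src$tip.label])
      expect_equal(bipartitions(rec), bipartitions(src))
      # branch lengths recovered too: patristic distances match
      expect_equal(ape::cophenetic.phylo(rec)[src$tip.label, src$tip.label],
                   d, tolerance = 1e-8)
    }
  })
})

test_that("bootstrap gives full support to a clean split and is seeded", {
  withr::with_seed(41, {
    base1 <- sample(c("A", "C"), 120, TRUE)
    base2 <- sample(c("G", "T"), 120, TRUE)
    flip <- function(b, p) ifelse(runif(length(b)) < p, "A", b)
    seqm <- rbind(t1 = flip(base1, 0.02), t2 = flip(base1, 0.02),
                  t3 = flip(base1, 0.02), t4 = flip(base2, 0.02),
                  t5 = flip(base2, 0.02), t6 = flip(base2, 0.02))
  })
  aln <- structure(list(seq = seqm, labels = rownames(seqm),
                        provenance = data.frame(chrom = "c", pos = 1:120),
                        compartment = "nuclear"),
                   class = "pseudo_alignment")
  tree <- bootstrap_support(aln, n_reps = 100, seed = 3)
  support <- as.integer(tree$node.label[tree$node.label != ""])
  expect_true(100 %in% support)   # the t1-3 | t4-6 split
  tree2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(tree$node.label, tree2$node.label)
})

test_that("column count equals a direct recount of the homozygosity rule", {
  sim <- simulate_complex(sim_config(seed = 31, genome_length = 50000))
  x <- sim$variants
  aln <- build_pseudoalignment(x, sim$reference)
  dos <- gt_dosage(x)
  pl <- gt_ploidy(x)
  het_any <- rowSums(!is.na(dos) & dos > 0 & dos < pl) > 0
  expect_equal(ncol(aln$seq), sum(!het_any))
})
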