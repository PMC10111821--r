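two_dip <- function(gt1, gt2) {
  matrix(c(gt1, gt2), 1, 2, dimnames = list(NULL, c("s1", "s2")))
}

test_that("SNV thresholds follow the printed comparisons exactly", {
  pass_info <- data.frame(MQ = 60, QD = 20, FS = 1, MQRankSum = 0,
                          ReadPosRankSum = 0, SOR = 1, DP = 30)
  ok <- make_vs(two_dip("0/1", "0/0"), info = pass_info)
  st <- snv_filter_status(ok)
  expect_true(st$pass)
  expect_length(st$reasons[[1]], 0)

  # MQ = 39 fails with reason MQ; MQ = 40 also fails (strict >)
  for (mq in c(39, 40)) {
    x <- make_vs(two_dip("0/1", "0/0"),
                 info = transform(pass_info, MQ = mq))
    st <- snv_filter_status(x)
    expect_false(st$pass)
    expect_equal(st$reasons[[1]], "MQ")
  }
  # DP is the one >= comparison: 10 passes, 9 fails
  expect_true(snv_filter_status(
    make_vs(two_dip("0/1", "0/0"), info = transform(pass_info, DP = 10)))$pass)
  st <- snv_filter_status(
    make_vs(two_dip("0/1", "0/0"), info = transform(pass_info, DP = 9)))
  expect_equal(st$reasons[[1]], "DP")

  # more than two alleles
  multi <- make_vs(two_dip("0/1", "0/2"), alt = "T,G", info = pass_info)
  st <- snv_filter_status(multi)
  expect_false(st$pass)
  expect_true("multiallelic" %in% st$reasons[[1]])

  # any missing genotype drops the site
  miss <- make_vs(two_dip("./.", "0/0"), info = pass_info)
  st <- snv_filter_status(miss)
  expect_equal(st$reasons[[1]], "missing")

  # absent annotation fails by default, passes under the lenient policy
  na_info <- transform(pass_info, SOR = NA_real_)
  st <- snv_filter_status(make_vs(two_dip("0/1", "0/0"), info = na_info))
  expect_equal(st$reasons[[1]], "missing_annotation:SOR")
  st <- snv_filter_status(make_vs(two_dip("0/1", "0/0"), info = na_info),
                          filter_thresholds(missing_annotation = "pass"))
  expect_true(st$pass)
})

test_that("indel filters: QUAL, singleton support and type checking", {
  mk_indel <- function(qual, gt1 = "0/1", gt2 = "0/1", qd = 10, fs = 5) {
    make_vs(two_dip(gt1, gt2), ref = "A", alt = "ATTT", qual = qual,
            info = data.frame(MQ = 60, QD = qd, FS = fs, MQRankSum = 0,
                              ReadPosRankSum = 0, SOR = 1, DP = 30))
  }
  st <- indel_filter_status(mk_indel(29))
  expect_false(st$pass)
  expect_equal(st$reasons[[1]], "QUAL")
  expect_false(indel_filter_status(mk_indel(30))$pass)  # strict > 30.0

  st <- indel_filter_status(mk_indel(100, gt2 = "0/0"))
  expect_equal(st$reasons[[1]], "singleton")
  expect_equal(st$support, 1)

  expect_true(indel_filter_status(mk_indel(100))$pass)
  not_indel <- make_vs(two_dip("0/1", "0/0"))
  expect_error(indel_filter_status(not_indel), "not_an_indel")
})

test_that("fuzz decisions equal an independent rule-by-rule check", {
  x <- random_vs(1000, seed = 42)
  snv_idx <- which(is_snv(x))
  snv <- x[snv_idx, ]
  st <- snv_filter_status(snv)
  want <- vapply(seq_len(n_sites(snv)), function(i) oracle_snv_pass(snv, i),
                 logical(1))
  expect_equal(st$pass, want)
  # failing records carry >= 1 reason, passing none
  expect_true(all(lengths(st$reasons[!st$pass]) >= 1))
  expect_true(all(lengths(st$reasons[st$pass]) == 0))
})

test_that("relaxing any single threshold never loses passing records", {
  x <- random_vs(600, seed = 7)
  snv <- x[which(is_snv(x)), ]
  base_n <- sum(snv_filter_status(snv)$pass)
  relaxed <- list(list(MQ_min = 20), list(QD_min = 0), list(FS_max = 1e3),
                  list(MQRankSum_min = -1e3), list(ReadPosRankSum_min = -1e3),
                  list(SOR_max = 1e3), list(DP_min = 0))
  for (r in relaxed) {
    n <- sum(snv_filter_status(snv, filter_thresholds(snv = r))$pass)
    expect_gte(n, base_n)
  }
})

test_that("indel summary counts zygosity, length classes and genic overlap", {
  gt <- matrix(c("0/1", "1/1", "0/0",
                 "0/1", "0/1", "1/1",
                 "0/0", "0/1", "0/0"), nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  long_alt <- paste(rep("T", 102), collapse = "")   # length diff 101
  edge_alt <- paste(rep("T", 101), collapse = "")   # length diff 100
  x <- variant_set(chrom = "chr1", pos = c(50, 150, 250), ref = "T",
                   alt = c(long_alt, edge_alt, "TAA"), gt = gt,
                   qual = 100)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  s <- summarize_indels(x, genes)
  s1 <- s$per_sample[s$per_sample$sample == "s1", ]
  expect_equal(s1$heterozygous, 2)   # sites 1 and 2
  expect_equal(s1$homozygous, 0)
  expect_equal(s1$large, 1)          # 101 > 100 but 100 is not large
  expect_equal(s1$genic, 1)          # site 2 at pos 150
  s2 <- s$per_sample[s$per_sample$sample == "s2", ]
  expect_equal(s2$homozygous, 1)     # 1/1 at site 1
  expect_equal(s2$total, 3)
  expect_equal(s$min_length, 2)
  expect_equal(s$max_length, 101)
})

test_that("genic indel counts equal a brute-force overlap scan", {
  withr::with_seed(21, {
    n <- 20
    gt <- matrix(sample(c("0/1", "1/1", "0/0"), n * 2, TRUE), n, 2,
                 dimnames = list(NULL, c("s1", "s2")))
    pos <- sort(sample(1:2000, n))
    x <- variant_set(chrom = "chr1", pos = pos, ref = "T",
                     alt = "TAG", gt = gt, qual = 100)
    iv <- data.frame(chrom = "chr1", start1 = c(10, 300, 700, 1200, 1800))
    iv$end1 <- iv$start1 + c(100, 50, 200, 150, 100)
    genes <- GenomicRanges::GRanges(iv$chrom,
                                    IRanges::IRanges(iv$start1, iv$end1))
    s <- summarize_indels(x, genes)
    for (smp in c("s1", "s2")) {
      carriers <- grepl("1", gt[, smp])
      want <- sum(vapply(which(carriers), function(i)
        oracle_point_in("chr1", pos[i], iv), logical(1)))
      expect_equal(s$per_sample$genic[s$per_sample$sample == smp], want)
    }
  })
})

test_that("SNV density scales counts by genome length per zygosity class", {
  gt <- cbind(s1 = rep("1/1", 1000), s2 = rep("0/0", 1000),
              s3 = rep("0/0/1/1", 1000))
  x <- make_vs(gt, pos = 1:1000)
  d <- snv_density(x, 1e6)
  expect_equal(d$hom_per_kb[d$sample == "s1"], 1.0)   # 1000 / 1000 kb
  expect_equal(d$het_per_kb[d$sample == "s1"], 0.0)
  expect_equal(d$hom_per_kb[d$sample == "s2"], 0.0)   # all hom-ref
  expect_equal(d$het_per_kb[d$sample == "s2"], 0.0)
  # tetraploid 0/0/1/1 is heterozygous
  expect_equal(d$het_per_kb[d$sample == "s3"], 1.0)
  expect_equal(d$hom_per_kb[d$sample == "s3"], 0.0)
  expect_error(snv_density(x, 0), "> 0")
})
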