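# Toy panel builder: diploid groups G1 = {d1, d2}, G2 = {d3, d4}, one
# tetraploid "tet". ref = T, alt = A throughout, so allele index 1 is "A".
toy_panel <- function(gt_rows) {
  gt <- do.call(rbind, gt_rows)
  colnames(gt) <- c("d1", "d2", "d3", "d4", "tet")
  make_vs(gt, ref = "T", alt = "A")
}

test_that("exclusive SNVs follow the hom-only / includes-het definition", {
  x <- toy_panel(list(
    c("1/1", "1/1", "0/0", "0/0", "0/0/1/1"),  # exclusive to G1, hom only
    c("1/1", "0/1", "0/0", "0/0", "0/0/0/0"),  # exclusive to G1, incl. het
    c("1/1", "1/1", "0/1", "0/0", "0/0/0/0"),  # d3 carries A -> not exclusive
    c("1/1", "0/0", "0/0", "0/0", "0/0/0/0"),  # d2 lacks A -> not exclusive
    c("0/1", "0/1", "0/0", "0/0", "0/0/0/0"),  # all-het focal: included
    c("0/0", "0/0", "1/1", "1/1", "0/0/1/1"))) # exclusive to G2 instead
  excl <- find_exclusive_snvs(x, c("d1", "d2"), c("d3", "d4"))
  expect_equal(excl$site, c(1L, 2L, 5L))
  expect_equal(excl$class, c("homozygous_only", "includes_heterozygous",
                             "includes_heterozygous"))
  expect_equal(excl$allele, c(1L, 1L, 1L))
  expect_equal(attr(excl, "n_all_het"), 1L)

  # only the variant allele can be exclusive: a fixed difference is an
  # exclusive SNV of the alternate-carrying group, not of the other one
  x2 <- toy_panel(list(c("0/0", "0/0", "1/1", "1/1", "0/0/1/1")))
  expect_equal(nrow(find_exclusive_snvs(x2, c("d1", "d2"), c("d3", "d4"))),
               0)
  expect_equal(nrow(find_exclusive_snvs(x2, c("d3", "d4"), c("d1", "d2"))),
               1)
})

test_that("polyploid samples are rejected from the diploid-only step", {
  x <- toy_panel(list(c("1/1", "1/1", "0/0", "0/0", "0/0/1/1")))
  expect_error(find_exclusive_snvs(x, c("d1", "tet"), c("d3", "d4")),
               "configuration error")
})

test_that("a site can be exclusive to at most one diploid group", {
  x <- random_vs(800, samples = c("d1", "d2", "d3", "d4"), seed = 13)
  x <- x[which(is_snv(x) & n_alt(x) == 1L), ]
  e1 <- find_exclusive_snvs(x, c("d1", "d2"), c("d3", "d4"))
  e2 <- find_exclusive_snvs(x, c("d3", "d4"), c("d1", "d2"))
  expect_length(intersect(e1$site, e2$site), 0)
})

test_that("sharing requires >= 1 copy of the exclusive allele", {
  x <- toy_panel(list(
    c("1/1", "1/1", "0/0", "0/0", "0/0/1/1"),  # tet carries A (het)
    c("1/1", "1/1", "0/0", "0/0", "0/0/0/0"),  # tet lacks A
    c("1/1", "1/1", "0/0", "0/0", "1/1/1/1"))) # tet hom for A
  excl <- find_exclusive_snvs(x, c("d1", "d2"), c("d3", "d4"))
  expect_equal(nrow(excl), 3)
  row <- shared_with_polyploid(excl, x, "tet",
                               totals = list(hom = 10, het = 20))
  expect_equal(row$shared_hom, 1)   # site 3, tet homozygous-alt
  expect_equal(row$shared_het, 1)   # site 1, tet heterozygous
  expect_equal(row$pct_hom, 10)
  expect_equal(row$pct_het, 5)
  expect_error(shared_with_polyploid(excl, x, "tet",
                                     totals = list(hom = 0, het = 5)),
               "positive")
})

test_that("the full matrix equals exhaustive hand enumeration on 8 sites", {
  x <- toy_panel(list(
    c("1/1", "1/1", "0/0", "0/0", "0/0/1/1"),  # G1-excl, tet het  -> shared
    c("1/1", "0/1", "0/0", "0/0", "1/1/1/1"),  # G1-excl, tet hom  -> shared
    c("1/1", "1/1", "0/0", "0/0", "0/0/0/0"),  # G1-excl, not in tet
    c("0/0", "0/0", "1/1", "1/1", "0/1/1/1"),  # G2-excl, tet het  -> shared
    c("0/0", "0/0", "0/1", "0/1", "0/0/0/0"),  # G2-excl (all het), not in tet
    c("1/1", "1/1", "1/1", "1/1", "1/1/1/1"),  # fixed everywhere: no group
    c("0/1", "0/0", "0/0", "0/0", "0/0/1/1"),  # d2 lacks A -> no group
    c("0/0", "0/0", "0/0", "1/1", "0/0/1/1"))) # d3 lacks A -> no group
  sm <- sharing_matrix(x, list(G1 = c("d1", "d2"), G2 = c("d3", "d4")),
                       "tet")
  # tet's own totals: hom sites {2, 6}, het sites {1, 4, 7, 8}
  expect_equal(unname(sm$denominators[, "tet"]), c(2, 4))
  expect_equal(unname(sm$shared["G1:homozygous", "tet"]), 1)
  expect_equal(unname(sm$shared["G1:heterozygous", "tet"]), 1)
  expect_equal(unname(sm$shared["G2:homozygous", "tet"]), 0)
  expect_equal(unname(sm$shared["G2:heterozygous", "tet"]), 1)
  expect_equal(unname(sm$pct["G1:homozygous", "tet"]), 50)
  expect_equal(unname(sm$pct["G1:heterozygous", "tet"]), 25)
  expect_equal(unname(sm$pct["G2:heterozygous", "tet"]), 25)
  expect_true(all(sm$pct >= 0 & sm$pct <= 100))
})

test_that("sample order in the variant set does not change the matrix", {
  x <- random_vs(500, samples = c("d1", "d2", "d3", "d4", "p"), seed = 9)
  # make p a tetraploid with well-defined genotypes
  x$gt[, "p"] <- withr::with_seed(2, paste(
    sample(0:1, n_sites(x), TRUE), sample(0:1, n_sites(x), TRUE),
    sample(0:1, n_sites(x), TRUE), sample(0:1, n_sites(x), TRUE), sep = "/"))
  x <- x[which(is_snv(x) & n_alt(x) == 1L), ]
  groups <- list(G1 = c("d1", "d2"), G2 = c("d3", "d4"))
  sm1 <- sharing_matrix(x, groups, "p")
  perm <- x[, c("p", "d3", "d1", "d4", "d2")]
  sm2 <- sharing_matrix(perm, groups, "p")
  expect_equal(sm1$pct, sm2$pct)
  expect_equal(sm1$shared, sm2$shared)
})

test_that("shared counts grow monotonically as exclusive sites accrue", {
  x <- toy_panel(list(
    c("1/1", "1/1", "0/0", "0/0", "0/0/1/1"),
    c("1/1", "1/1", "0/0", "0/0", "1/1/1/1"),
    c("1/1", "0/1", "0/0", "0/0", "0/1/1/1")))
  excl <- find_exclusive_snvs(x, c("d1", "d2"), c("d3", "d4"))
  tots <- list(hom = 5, het = 5)
  prev <- 0
  for (k in seq_len(nrow(excl))) {
    row <- shared_with_polyploid(excl[seq_len(k), ], x, "tet", totals = tots)
    tot_shared <- row$shared_hom + row$shared_het
    expect_gte(tot_shared, prev)
    prev <- tot_shared
  }
})

test_that("true parents of a simulated allotetraploid rank top-2", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_complex(sim_config(seed = 600 + s, hexaploid = NULL))
    dip <- default_diploid_groups(sim$sheet)
    sm <- sharing_matrix(sim$variants, dip, "tet_1")
    top2 <- rank_parents(sm, "tet_1")[1:2]
    hits <- hits + setequal(top2, sim$truth$parents$tetraploid)
  }
  expect_gte(hits, 4)
})

test_that("a focal group with zero exclusive sites yields a zero row", {
  x <- toy_panel(list(
    c("0/1", "0/1", "0/1", "0/1", "0/0/1/1"),
    c("1/1", "1/1", "0/0", "0/0", "0/0/1/1"),
    c("1/1", "1/1", "1/1", "1/1", "1/1/1/1")))
  sm <- sharing_matrix(x, list(G1 = c("d1", "d2"), G2 = c("d3", "d4")),
                       "tet")
  expect_equal(unname(sm$pct["G2:homozygous", "tet"]), 0)
  expect_equal(unname(sm$pct["G2:heterozygous", "tet"]), 0)
  expect_equal(unname(sm$exclusive_set_sizes["G2"]), 0L)
})
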