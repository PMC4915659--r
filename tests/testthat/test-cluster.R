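test_that("end tolerances are inclusive at 100 bp (5') and 5 bp (3')", {
  join5 <- clusterEnds(mkAssignments(e5 = c(0L, 100L), e3 = c(2000L, 2000L)))
  expect_equal(nrow(join5), 1L)
  split5 <- clusterEnds(mkAssignments(e5 = c(0L, 101L), e3 = c(2000L, 2000L)))
  expect_equal(nrow(split5), 2L)
  join3 <- clusterEnds(mkAssignments(e5 = c(0L, 0L), e3 = c(2000L, 2005L)))
  expect_equal(nrow(join3), 1L)
  split3 <- clusterEnds(mkAssignments(e5 = c(0L, 0L), e3 = c(2000L, 2006L)))
  expect_equal(nrow(split3), 2L)
  expect_error(clusterEnds(mkAssignments(0L, 100L), tol5 = -1), "non-negative")
})

test_that("single linkage chains reads across more than one tolerance width", {
  cl <- clusterEnds(mkAssignments(e5 = c(0L, 100L, 200L),
    e3 = c(2000L, 2000L, 2000L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
})

test_that("clusters equal the connected components of the tolerance graph", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(2:40, 1)
    e5 <- sample(0:400, n, replace = TRUE)
    e3 <- 2000L + sample(0:15, n, replace = TRUE)
    cl <- clusterEnds(mkAssignments(e5 = e5, e3 = e3))
    comp <- componentsOracle(e5, e3, 100, 5)
    expect_equal(nrow(cl), length(unique(comp)))
    asg <- mkAssignments(e5 = e5, e3 = e3)
    oracle_members <- sort(unname(vapply(split(asg$read_id, comp), function(m)
      paste(sort(m), collapse = ","), character(1))), method = "radix")
    expect_equal(sort(clusterPartition(cl), method = "radix"), oracle_members)
  }
})

test_that("cluster count is order-invariant and monotone in the tolerances", {
  set.seed(42)
  e5 <- sample(0:500, 30, replace = TRUE)
  e3 <- 2000L + sample(0:12, 30, replace = TRUE)
  asg <- mkAssignments(e5 = e5, e3 = e3)
  base <- clusterEnds(asg)
  for (i in 1:5) {
    sh <- asg[sample(nrow(asg)), ]
    expect_equal(nrow(clusterEnds(sh)), nrow(base))
    expect_equal(sort(clusterPartition(clusterEnds(sh)), method = "radix"),
      sort(clusterPartition(base), method = "radix"))
  }
  grid5 <- c(0, 25, 50, 100, 200)
  grid3 <- c(0, 2, 5, 10)
  prev <- Inf
  for (t5 in grid5) {
    nc <- nrow(clusterEnds(asg, tol5 = t5, tol3 = 5))
    expect_lte(nc, prev); prev <- nc
  }
  prev <- Inf
  for (t3 in grid3) {
    nc <- nrow(clusterEnds(asg, tol5 = 100, tol3 = t3))
    expect_lte(nc, prev); prev <- nc
  }
  # zero tolerance on all-distinct ends: no redundancy at all
  dist <- mkAssignments(e5 = seq(0L, 290L, by = 10L),
    e3 = seq(2000L, 2290L, by = 10L))
  expect_equal(redundancyFraction(clusterEnds(dist, tol5 = 0, tol3 = 0)), 0)
})

test_that("redundancy percentage is exact on constructed duplicate sets", {
  # 10 reads, 10 singletons
  cl0 <- clusterEnds(mkAssignments(e5 = seq(0L, 9000L, by = 1000L),
    e3 = seq(20000L, 29000L, by = 1000L)))
  expect_equal(redundancyFraction(cl0), 0)
  # k exact duplicates of one molecule among n reads: 100 * (k - 1) / n
  for (k in c(2L, 5L)) {
    n <- 20L
    e5 <- c(rep(0L, k), seq(5000L, by = 1000L, length.out = n - k))
    e3 <- e5 + 1500L
    cl <- clusterEnds(mkAssignments(e5 = e5, e3 = e3))
    expect_equal(redundancyFraction(cl), 100 * (k - 1) / n)
  }
  # 10 reads in 9 clusters -> 10%
  cl9 <- clusterEnds(mkAssignments(
    e5 = c(0L, 0L, seq(5000L, by = 1000L, length.out = 8L)),
    e3 = c(1500L, 1500L, seq(6500L, by = 1000L, length.out = 8L))))
  expect_equal(redundancyFraction(cl9), 10)
  expect_error(redundancyFraction(cl9[0, ]), "no reads")
})

test_that("minus-strand loci cluster by transcript-oriented ends", {
  # same genomic geometry mirrored: e5/e3 encode orientation, so tolerances
  # behave identically on both strands
  plus <- clusterEnds(mkAssignments(e5 = c(1000L, 1100L), e3 = c(3000L, 3004L)))
  minus <- clusterEnds(mkAssignments(e5 = -c(3000L, 3004L) * 0L - c(9000L, 9100L),
    e3 = -c(7000L, 7004L), strand = "-"))
  expect_equal(nrow(plus), 1L)
  expect_equal(nrow(minus), 1L)
})

test_that("unassigned unique reads cluster within genomic overlap groups", {
  asg <- rbind(
    mkAssignments(e5 = c(0L, 10L), e3 = c(1500L, 1500L)),
    within(mkAssignments(e5 = c(50000L, 50010L), e3 = c(51500L, 51500L)), {
      gene_id <- NA_character_
      read_id <- c("u001", "u002")
      read_left <- e5; read_right <- e3
    }))
  cl <- clusterEnds(asg)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$n_members), c(2L, 2L))
  expect_true(any(is.na(cl$gene_id)))
})
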