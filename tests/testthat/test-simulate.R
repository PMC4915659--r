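test_that("simConfig validates probabilities, ranges and seed", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(p_truncated = 1.2), "probabilities")
  expect_error(simConfig(spliced_length_range = c(500, 100)), "range")
  expect_error(simConfig(n_homeolog_triplets = 10, n_genes = 5), "exceed")
  expect_error(simConfig(bogus = 1), "unknown")
})

test_that("annotation generation is seed-deterministic and respects config", {
  cfg <- simConfig(n_genes = 20, n_homeolog_triplets = 5, seed = 1)
  g1 <- generateAnnotation(cfg)
  g2 <- generateAnnotation(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeGFF3Genes(g1$annotation, p1)
  writeGFF3Genes(g2$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))

  an <- geneInfo(g1$annotation)
  expect_true(all(an$spliced_length >= cfg@spliced_length_range[1] &
    an$spliced_length <= cfg@spliced_length_range[2]))
  expect_setequal(unique(an$strand), c("+", "-"))
  expect_gte(length(unique(an$chrom)), 2L)
  # triplets: one table row per member, three members per group
  expect_equal(nrow(g1$homeologs), 15L)
  expect_true(all(table(g1$homeologs$group_id) == 3L))
  # homeolog copies live on distinct chromosomes
  for (g in unique(g1$homeologs$group_id)) {
    mem <- g1$homeologs$gene_id[g1$homeologs$group_id == g]
    expect_equal(length(unique(an$chrom[an$gene_id %in% mem])), 3L)
  }
  # genes never overlap on a chromosome
  for (ch in unique(an$chrom)) {
    x <- an[an$chrom == ch, ]
    x <- x[order(x$span_start), ]
    if (nrow(x) > 1L)
      expect_true(all(x$span_start[-1L] > x$span_end[-nrow(x)]))
  }
})

test_that("molecule truncation follows the configured rate", {
  ann <- generateAnnotation(simConfig(n_genes = 10, seed = 2))$annotation
  m0 <- simulateMolecules(ann, simConfig(n_genes = 10, p_truncated = 0, seed = 2),
    n = 500)
  expect_true(all(m0$capped))
  expect_true(all(m0$bases_lost_5p == 0L))
  m1 <- simulateMolecules(ann, simConfig(n_genes = 10, p_truncated = 1, seed = 2),
    n = 500)
  expect_false(any(m1$capped))
  expect_true(all(m1$bases_lost_5p >= 1L))
  # binomial sampling check at p = 0.4, n = 10000
  m <- simulateMolecules(ann, simConfig(n_genes = 10, p_truncated = 0.4, seed = 2),
    n = 10000)
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(mean(!m$capped) - 0.4), 3 * se)
})

test_that("capture rules are enforced at the protocol limits", {
  cfg <- simConfig(n_genes = 10, n_reads_per_protocol = 200, p_truncated = 0.5,
    cap_capture = 1, cap_leakage = 0, seed = 4)
  gen <- generateAnnotation(cfg)
  mol <- simulateMolecules(gen$annotation, cfg)
  lib <- simulateLibrary(mol, "cap_dependent", gen$annotation, cfg, gen$homeologs)
  expect_true(all(lib$truth$capped))
  expect_true(all(lib$truth$bases_lost_5p == 0L))

  cfg2 <- simConfig(n_genes = 10, n_reads_per_protocol = 200, p_truncated = 0,
    p_incomplete_synthesis = 0, three_prime_jitter_sd = 0, seed = 4)
  gen2 <- generateAnnotation(cfg2)
  mol2 <- simulateMolecules(gen2$annotation, cfg2)
  lib2 <- simulateLibrary(mol2, "template_switch", gen2$annotation, cfg2,
    gen2$homeologs)
  expect_true(all(lib2$truth$read_length == lib2$truth$spliced_length))
})

test_that("read length bookkeeping is exact for every simulated read", {
  sim <- simulateExperiment(simConfig(n_genes = 15, n_reads_per_protocol = 300,
    n_homeolog_triplets = 3, seed = 6))
  for (p in names(sim$libraries)) {
    tr <- sim$libraries[[p]]$truth
    expect_equal(tr$read_length,
      tr$spliced_length - tr$bases_lost_5p - tr$bases_lost_3p + tr$three_prime_ext)
    expect_true(all(tr$bases_lost_5p[tr$capped & tr$protocol == "cap_dependent"] == 0L))
    # emitted primary alignment widths agree with the read length minus the
    # 3' extension beyond the annotation plus it (blocks cover the read)
    info <- alignmentInfo(sim$libraries[[p]]$alignments)
    bl <- alignmentBlocks(sim$libraries[[p]]$alignments)
    prim <- which(info$is_primary)
    w <- vapply(prim, function(i) sum(IRanges::width(bl[[i]])), integer(1))
    expect_equal(w, info$read_length[prim])
  }
})

test_that("cap selection shifts the 5' loss distribution down", {
  cfg <- simConfig(n_genes = 20, n_reads_per_protocol = 2000, seed = 8)
  sim <- simulateExperiment(cfg)
  expect_lt(mean(sim$libraries$cap_dependent$truth$bases_lost_5p),
    mean(sim$libraries$template_switch$truth$bases_lost_5p))
})

test_that("a fixed config reproduces byte-identical simulation outputs", {
  cfg <- simConfig(n_genes = 10, n_reads_per_protocol = 80,
    n_homeolog_triplets = 2, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateExperiment(cfg), d1)
  writeSimulation(simulateExperiment(cfg), d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f)
})
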