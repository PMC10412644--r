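# Data model, EIGENSTRAT I/O and panel-construction filters.

test_that("eigenstrat read transcribes geno characters and flags errors", {
  d <- withr::local_tempdir()
  writeLines(c("029", "110"), file.path(d, "toy.geno"))
  writeLines(c("rs1\t1\t0\t100\tA\tC", "rs2\t1\t0\t200\tG\tT"),
             file.path(d, "toy.snp"))
  writeLines(c("a\tM\tpop1", "b\tF\tpop1", "c\tU\tpop2"),
             file.path(d, "toy.ind"))
  ds <- read_eigenstrat(file.path(d, "toy.geno"), file.path(d, "toy.snp"),
                        file.path(d, "toy.ind"))
  expect_identical(unname(ds$geno$calls),
                   matrix(c(0L, 2L, NA, 1L, 1L, 0L), nrow = 3))
  expect_identical(ds$meta$sex, c("XY", "XX", "UNKNOWN"))

  # dimension mismatch names the offending line
  writeLines(c("02", "110"), file.path(d, "bad.geno"))
  expect_error(read_eigenstrat(file.path(d, "bad.geno"),
                               file.path(d, "toy.snp"),
                               file.path(d, "toy.ind")),
               "width")
  # invalid character reported with coordinates
  writeLines(c("029", "1x0"), file.path(d, "bad2.geno"))
  expect_error(read_eigenstrat(file.path(d, "bad2.geno"),
                               file.path(d, "toy.snp"),
                               file.path(d, "toy.ind")),
               "line 2")
})

test_that("snp panel invariants are enforced", {
  expect_error(snp_panel("s1", "1", 100, "A", "A"), "allele1")
  expect_error(
    snp_panel(c("s1", "s2"), c("1", "1"), c(100, 100),
              c("A", "A"), c("C", "G")),
    "duplicate")
  expect_error(
    snp_panel(c("s1", "s2"), c("1", "1"), c(200, 100),
              c("A", "A"), c("C", "C")),
    "sorted")
  expect_error(snp_panel("s1", "1", 100, "A", "C", ancestral = "G"),
               "ancestral")
})

test_that("eigenstrat round-trip is the identity on a random fixture", {
  ds <- random_dataset(n_ind = 5, n_sites = 50, seed = 11)
  d <- withr::local_tempdir()
  write_eigenstrat(ds$panel, ds$geno, ds$meta, file.path(d, "rt"))
  back <- read_eigenstrat(file.path(d, "rt.geno"), file.path(d, "rt.snp"),
                          file.path(d, "rt.ind"))
  expect_identical(back$geno$calls, ds$geno$calls)
  expect_equal(back$panel$pos, ds$panel$pos)
  expect_equal(back$panel$allele1, ds$panel$allele1)
  expect_identical(back$geno$ids, ds$geno$ids)
})

test_that("writing an empty dataset errors; single-cell body is '1'", {
  panel <- snp_panel("s1", "1", 100, "A", "C")
  g1 <- genotype_matrix(matrix(1L, 1, 1), 2L, ids = "x")
  meta <- individual_meta("x", "pop")
  d <- withr::local_tempdir()
  paths <- write_eigenstrat(panel, g1, meta, file.path(d, "one"))
  expect_identical(readLines(paths[["geno"]]), "1")
  g0 <- structure(list(calls = matrix(integer(0), 0, 1), ploidy = integer(0),
                       ids = character(0)), class = "genotype_matrix")
  expect_error(write_eigenstrat(panel, g0, meta[0, ], file.path(d, "none")),
               "no individuals")
})

test_that("pseudohaploid sampling is deterministic, maps homozygotes, and is unbiased", {
  # homozygotes deterministic
  g <- genotype_matrix(matrix(c(0L, 2L, 2L, 0L), 1), 2L, ids = "a")
  expect_identical(unname(sample_pseudohaploid(g, 1)$calls),
                   matrix(c(0L, 1L, 1L, 0L), 1))
  # same seed, same draw; different seed differs somewhere
  het <- genotype_matrix(matrix(1L, 1, 10000), 2L, ids = "a")
  s1 <- sample_pseudohaploid(het, 7)
  s2 <- sample_pseudohaploid(het, 7)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$ploidy, 1L)
  # binomial 99% bound on the heterozygote draw
  k <- sum(s1$calls)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # diploid-only precondition
  expect_error(sample_pseudohaploid(s1, 1), "diploid")
})

test_that("panel filters match a per-site brute-force re-check", {
  withr::with_seed(5, {
    n <- 200
    alle <- rbind(
      c("A", "C"), c("A", "G"), c("C", "T"), c("T", "A"), c("G", "C")
    )[sample.int(5, n, replace = TRUE), ]
    panel <- snp_panel(paste0("s", 1:n), "1", sort(sample.int(1e6, n)),
                       alle[, 1], alle[, 2])
    nref <- 10
    calls <- matrix(sample(c(0:2, NA), (nref + 2) * n, replace = TRUE),
                    nrow = nref + 2)
    ids <- c(paste0("yri", 1:nref), "anc1", "anc2")
    geno <- genotype_matrix(calls, 2L, ids = ids)
    meta <- individual_meta(
      id = ids, group = c(rep("YRI", nref), "ancient", "ancient"),
      treatment = c(rep("UDG", nref), "non-UDG", "UDG"))
    out <- apply_panel_filters(panel, geno, meta, freq_group = "YRI",
                               maf_min = 0.1, transversions_only = FALSE,
                               treatment_rules = TRUE)
    # brute-force per-site oracle
    keep_oracle <- logical(n)
    for (s in seq_len(n)) {
      yc <- calls[1:nref, s]
      tot <- 2 * sum(!is.na(yc))
      f <- if (tot > 0) sum(yc, na.rm = TRUE) / tot else NA
      keep_oracle[s] <- !is.na(f) && min(f, 1 - f) >= 0.1
    }
    expect_equal(nrow(out$panel), sum(keep_oracle))
    expect_equal(out$panel$pos, panel$pos[keep_oracle])
    # non-UDG individual has transitions masked, UDG keeps them
    trans <- paste0(out$panel$allele1, out$panel$allele2) %in%
      c("AG", "GA", "CT", "TC")
    expect_true(all(is.na(out$geno$calls["anc1", trans])))
    expect_identical(out$geno$calls["anc2", ],
                     geno$calls["anc2", keep_oracle])
    # idempotence
    again <- apply_panel_filters(out$panel, out$geno, meta,
                                 freq_group = "YRI", maf_min = 0.1,
                                 treatment_rules = TRUE)
    expect_equal(again$panel, out$panel)
    # transversions_only drops A/G and C/T sites entirely
    tv <- apply_panel_filters(panel, geno, transversions_only = TRUE)
    expect_false(any(paste0(tv$panel$allele1, tv$panel$allele2) %in%
                       c("AG", "GA", "CT", "TC")))
  })
})

test_that("filters catch unknown frequency group and boundary MAF", {
  panel <- snp_panel(c("s1", "s2"), c("1", "1"), c(100, 200), "A", "C")
  geno <- genotype_matrix(matrix(c(0L, 1L, 0L, 2L), 2), 2L,
                          ids = c("a", "b"))
  meta <- individual_meta(c("a", "b"), "pop")
  expect_error(apply_panel_filters(panel, geno, meta, freq_group = "nope",
                                   maf_min = 0.1), "unknown group")
  # freqs {0.25, 0.5}: site 1 f=0.25 passes 0.1; craft 0.05 case
  g2 <- genotype_matrix(matrix(c(rep(0L, 9), 1L, rep(1L, 10)), 10), 2L,
                        ids = paste0("i", 1:10))
  m2 <- individual_meta(paste0("i", 1:10), "P")
  out <- apply_panel_filters(panel, g2, m2, freq_group = "P", maf_min = 0.1)
  expect_equal(out$panel$site_id, "s2")  # site 1 MAF 0.05 < 0.1 dropped
})

test_that("merge reconciles swapped/flipped alleles and drops triallelic", {
  p1 <- snp_panel(c("s1", "s2", "s3"), "1", c(100, 200, 300),
                  c("A", "A", "A"), c("C", "C", "C"))
  g1 <- genotype_matrix(matrix(c(0L, 1L, 2L), 1), 2L, ids = "x")
  # s1 swapped (C/A), s2 triallelic (A/G), s3 strand-flipped (T/G == A/C)
  p2 <- snp_panel(c("t1", "t2", "t3"), "1", c(100, 200, 300),
                  c("C", "A", "T"), c("A", "G", "G"))
  g2 <- genotype_matrix(matrix(c(2L, 0L, 1L), 1), 2L, ids = "y")
  out <- merge_datasets(list(list(panel = p1, geno = g1),
                             list(panel = p2, geno = g2)))
  expect_equal(out$panel$pos, c(100L, 300L))
  expect_equal(unname(out$report["dropped_triallelic"]), 1L)
  # swapped site recoded 2 -> 0; flipped (not swapped) kept as-is
  expect_identical(unname(out$geno$calls["y", ]), c(0L, 1L))
  # ambiguous A/T site that needs a flip is dropped, counted separately
  p3 <- snp_panel("u1", "1", 100, "A", "T")
  g3 <- genotype_matrix(matrix(0L, 1), 2L, ids = "z")
  p4 <- snp_panel("u2", "1", 100, "C", "G")
  g4 <- genotype_matrix(matrix(0L, 1), 2L, ids = "w")
  out2 <- merge_datasets(list(list(panel = p3, geno = g3),
                              list(panel = p4, geno = g4)))
  expect_equal(nrow(out2$panel), 0L)
  expect_equal(unname(out2$report["dropped_ambiguous"]), 1L)
})

test_that("merge equals a naive per-site reconciliation oracle", {
  withr::with_seed(9, {
    n <- 500
    pos <- sort(sample.int(1e6, n))
    pairs <- rbind(c("A", "C"), c("G", "T"), c("A", "G"))
    pick <- sample.int(3, n, replace = TRUE)
    p1 <- snp_panel(paste0("s", 1:n), "1", pos, pairs[pick, 1],
                    pairs[pick, 2])
    g1 <- genotype_matrix(matrix(sample(0:2, n, TRUE), 1), 2L, ids = "x")
    # second set: random subset, sometimes swapped
    keep2 <- sort(sample.int(n, 300))
    swap <- runif(300) < 0.5
    a1 <- ifelse(swap, pairs[pick[keep2], 2], pairs[pick[keep2], 1])
    a2 <- ifelse(swap, pairs[pick[keep2], 1], pairs[pick[keep2], 2])
    p2 <- snp_panel(paste0("t", seq_along(keep2)), "1", pos[keep2], a1, a2)
    calls2 <- sample(0:2, 300, TRUE)
    g2 <- genotype_matrix(matrix(as.integer(calls2), 1), 2L, ids = "y")
    out <- merge_datasets(list(list(panel = p1, geno = g1),
                               list(panel = p2, geno = g2)))
    expect_equal(out$panel$pos, pos[keep2])
    oracle <- ifelse(swap, 2L - calls2, calls2)
    expect_identical(unname(out$geno$calls["y", ]), as.integer(oracle))
  })
})

test_that("polarize recodes to derived counts", {
  panel <- snp_panel(c("s1", "s2"), "1", c(100, 200), c("A", "A"),
                     c("C", "C"), ancestral = c("A", "C"))
  geno <- genotype_matrix(matrix(c(2L, 1L, 0L, 2L), 2), 2L,
                          ids = c("a", "b"))
  out <- polarize(panel, geno)
  # site 1 ancestral = allele1: unchanged; site 2 ancestral = allele2: flip
  expect_identical(unname(out$geno$calls[, 1L]), c(2L, 1L))
  expect_identical(unname(out$geno$calls[, 2L]), c(2L, 0L))
  expect_true(all(out$panel$ancestral == out$panel$allele1))
  # outgroup-individual source
  panel2 <- snp_panel(c("s1", "s2"), "1", c(100, 200), "A", "C")
  g2 <- genotype_matrix(rbind(c(0L, 2L), c(1L, 1L)), 2L,
                        ids = c("chimp", "x"))
  out2 <- polarize(panel2, g2, ancestral_source = "chimp")
  expect_identical(unname(out2$geno$calls["x", ]), c(1L, 1L))
  expect_error(polarize(panel2, g2, ancestral_source = "missing_id"),
               "not found")
})

test_that("group frequencies match direct counting and combine across merges", {
  ds <- random_dataset(n_ind = 20, n_sites = 40, seed = 3)
  grp <- rep(c("g1", "g2"), each = 10)
  fr <- group_frequencies(ds$geno, grouping = grp)
  for (s in c(1, 17, 40)) {
    sub <- ds$geno$calls[grp == "g1", s]
    expect_equal(unname(fr$count["g1", s]), sum(sub, na.rm = TRUE))
    expect_equal(unname(fr$total["g1", s]), 2 * sum(!is.na(sub)))
  }
  # one pseudohaploid with call 1 -> freq 1, total 1
  g <- genotype_matrix(matrix(1L, 1, 1), 1L, ids = "ph")
  f1 <- group_frequencies(g, grouping = "solo")
  expect_equal(unname(f1$freq["solo", 1]), 1)
  expect_equal(unname(f1$total["solo", 1]), 1)
  # diploids {2, NA} -> freq 1, total 2
  g2 <- genotype_matrix(matrix(c(2L, NA), 2, 1), 2L, ids = c("a", "b"))
  f2g <- group_frequencies(g2, grouping = c("p", "p"))
  expect_equal(unname(f2g$freq["p", 1]), 1)
  expect_equal(unname(f2g$total["p", 1]), 2)
  expect_error(group_frequencies(g2, grouping = character(0)), "align")
})
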