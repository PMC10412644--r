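# f-statistics, blocks and jackknife.

test_that("block assignment follows genetic length with a new block per chromosome", {
  p1 <- snp_panel(paste0("s", 1:3), "1", c(100, 200, 300),
                  "A", "C", genetic_pos = c(0, 0.02, 0.049))
  expect_equal(make_blocks(p1)$n_blocks, 1L)
  p2 <- snp_panel(paste0("s", 1:2), "1", c(100, 200), "A", "C",
                  genetic_pos = c(0, 0.06))
  expect_equal(make_blocks(p2)$n_blocks, 2L)
  # random panel vs an independent linear scan
  withr::with_seed(2, {
    gp <- sort(runif(300, 0, 1.2))
    chrom <- rep(c("1", "2"), c(150, 150))
    panel <- snp_panel(paste0("s", 1:300), chrom,
                       rep(seq_len(150) * 10L, 2), "A", "C",
                       genetic_pos = gp)
    bl <- make_blocks(panel, 0.05)
    # oracle: walk sites, cut when length exceeded or chromosome changes
    oracle <- integer(300); b <- 0L; start <- -Inf; last_chr <- ""
    for (i in 1:300) {
      if (chrom[i] != last_chr || gp[i] - start > 0.05) {
        b <- b + 1L; start <- gp[i]; last_chr <- chrom[i]
      }
      oracle[i] <- b
    }
    expect_identical(bl$block, oracle)
    expect_equal(sum(bl$m), 300L)
  })
})

test_that("f2/f3/f4 match brute-force per-site oracles to 1e-12", {
  withr::with_seed(17, {
    n <- 100
    fm <- matrix(runif(5 * n), 5, n,
                 dimnames = list(c("A", "B", "C", "D", "O"), NULL))
    fr <- freqs_from_matrix(fm)
    bl <- simple_blocks(n, 4L)
    f4_val <- f4(fr, "A", "B", "C", "D", bl)$estimate
    f3_val <- f3_outgroup(fr, "O", "A", "B", bl)$estimate
    f2_val <- f2(fr, "A", "B", bl)$estimate
    expect_equal(f4_val,
                 brute_fstat(fr, c("A", "B", "C", "D"),
                             function(p) (p[1] - p[2]) * (p[3] - p[4])),
                 tolerance = 1e-12)
    expect_equal(f3_val,
                 brute_fstat(fr, c("O", "A", "B"),
                             function(p) (p[1] - p[2]) * (p[1] - p[3])),
                 tolerance = 1e-12)
    expect_equal(f2_val,
                 brute_fstat(fr, c("A", "B"), function(p) (p[1] - p[2])^2),
                 tolerance = 1e-12)
  })
})

test_that("f4 identities: antisymmetry, additivity, zero for identical groups", {
  withr::with_seed(23, {
    n <- 60
    fm <- matrix(runif(5 * n), 5, n,
                 dimnames = list(c("A", "B", "C", "D", "E"), NULL))
    fr <- freqs_from_matrix(fm)
    bl <- simple_blocks(n, 3L)
    ab <- f4(fr, "A", "B", "C", "D", bl)$estimate
    expect_equal(f4(fr, "B", "A", "C", "D", bl)$estimate, -ab)
    expect_equal(f4(fr, "A", "B", "D", "C", bl)$estimate, -ab)
    expect_equal(ab,
                 f4(fr, "A", "B", "C", "E", bl)$estimate +
                   f4(fr, "A", "B", "E", "D", bl)$estimate)
    # identical frequency vectors -> exactly 0
    fm2 <- rbind(fm, X = fm["A", ])
    fr2 <- freqs_from_matrix(fm2)
    expect_equal(f4(fr2, "A", "X", "C", "D", bl)$estimate, 0)
    # hand computation: A=(1,1), B=(0,0), C=(1,0), D=(0,1)
    frh <- freqs_from_matrix(rbind(A = c(1, 1), B = c(0, 0),
                                   C = c(1, 0), D = c(0, 1)))
    expect_equal(f4(frh, "A", "B", "C", "D", simple_blocks(2))$estimate, 0)
    # f3 with A = B is a mean square, >= 0
    expect_gte(f3_outgroup(fr2, "A", "C", "C", bl)$estimate, 0)
    # f2 endpoints
    frf <- freqs_from_matrix(rbind(A = c(1, 0), B = c(0, 1)))
    expect_equal(f2(frf, "A", "B", simple_blocks(2))$estimate, 1)
  })
})

test_that("sites are used per-statistic when some groups are unobserved", {
  fm <- rbind(A = c(0.2, 0.4, 0.9), B = c(0.1, 0.5, 0.2),
              C = c(0.7, 0.3, 0.5), D = c(0.3, 0.8, 0.1))
  fr <- freqs_from_matrix(fm)
  fr$total["D", 2] <- 0  # D unobserved at site 2
  bl <- simple_blocks(3)
  fs <- f4(fr, "A", "B", "C", "D", bl)
  expect_equal(fs$n_snps_used, 2L)
  expect_equal(fs$estimate,
               mean(((fm["A", ] - fm["B", ]) *
                       (fm["C", ] - fm["D", ]))[c(1, 3)]))
  # f2 on the same freqs still uses all 3 sites
  expect_equal(f2(fr, "A", "B", bl)$n_snps_used, 3L)
  fr$total["A", ] <- 0
  expect_error(f4(fr, "A", "B", "C", "D", bl), "undefined")
})

test_that("weighted jackknife reduces to the classic formula for equal blocks", {
  withr::with_seed(31, {
    g <- 10; m <- 50
    sums <- rnorm(g, mean = 2)
    counts <- rep(m, g)
    jk <- block_jackknife(sums, counts)
    theta <- sum(sums) / sum(counts)
    loo <- (sum(sums) - sums) / (sum(counts) - m)
    se_classic <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
    expect_equal(jk$se, se_classic, tolerance = 1e-12)
    # identical leave-one-out estimates -> SE 0
    jk0 <- block_jackknife(rep(3, 5), rep(10, 5))
    expect_equal(jk0$se, 0)
    expect_error(block_jackknife(1, 10), "2 non-empty blocks")
  })
})

test_that("jackknife CIs have near-nominal coverage for a true-zero f4", {
  # clade structure: A and B are samples of the same leaf, so f4 = 0
  graph <- graph_spec("root", data.frame(
    parent = c("root", "root", "anc", "anc"),
    child = c("C", "anc", "AB", "D"),
    F = c(0.05, 0.02, 0.05, 0.05)))
  hits <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    fq <- simulate_graph_freqs(graph, 10000, seed = 1000 + r)
    fq <- rbind(fq, A = fq["AB", ], B = fq["AB", ])
    plan <- data.frame(node = c("A", "B", "C", "D"), n = 3, ploidy = 1,
                       missing = 0, error = 0)
    ds <- sample_individuals(fq, plan, seed = 2000 + r)
    fr <- group_frequencies(ds$geno, ds$meta, "group")
    fs <- f4(fr, "A", "B", "C", "D", make_blocks(ds$panel))
    if (abs(fs$estimate) <= 1.96 * fs$se) hits <- hits + 1L
  }
  # binomial 99.9% bound around 0.95 for 60 replicates
  expect_gte(hits / n_rep, 0.85)
})

test_that("f4_ratio endpoints are exact and recovery brackets the truth", {
  withr::with_seed(41, {
    fq <- simulate_graph_freqs(ratio_graph(0.3), 20000, seed = 5)
    sf <- sampled_freqs(fq, c("O", "A", "B", "C", "X"), n = 4, seed = 6)
    est <- f4_ratio(sf$freqs, "X", "A", "B", "C", "O", sf$blocks)
    expect_lt(abs(est$alpha - 0.3), 2.5 * est$se)
    expect_equal(sum(est$weights), 1)
    expect_true(est$ci[1] <= est$alpha && est$alpha <= est$ci[2])
    # endpoints: X = B gives alpha exactly 1; X = C exactly 0
    fr2 <- sf$freqs
    fr2$freq <- rbind(fr2$freq, XB = fr2$freq["B", ], XC = fr2$freq["C", ])
    fr2$count <- rbind(fr2$count, XB = fr2$count["B", ], XC = fr2$count["C", ])
    fr2$total <- rbind(fr2$total, XB = fr2$total["B", ], XC = fr2$total["C", ])
    fr2$groups <- rownames(fr2$freq)
    expect_equal(f4_ratio(fr2, "XB", "A", "B", "C", "O", sf$blocks)$alpha, 1)
    expect_equal(f4_ratio(fr2, "XC", "A", "B", "C", "O", sf$blocks)$alpha, 0)
  })
})

test_that("admixture weights recover a two-source mixture and agree with f4_ratio", {
  # extend the ratio graph with a second outgroup so rights and outgroup
  # stay disjoint
  graph <- graph_spec(
    "root",
    edges = data.frame(
      parent = c("root", "root", "top", "top", "anc", "anc", "inner",
                 "inner", "Xanc", "anc2"),
      child = c("O", "top", "O2", "anc", "C", "anc2", "B", "A", "X",
                "inner"),
      F = c(0.1, 0.01, 0.08, 0.02, 0.02, 0.02, 0.02, 0.02, 0.005, 0.02)),
    admixtures = data.frame(child = "Xanc", parent1 = "B", parent2 = "C",
                            alpha = 0.7))
  fq <- simulate_graph_freqs(graph, 30000, seed = 11)
  sf <- sampled_freqs(fq, c("O", "O2", "A", "B", "C", "X", "inner", "anc2"),
                      n = 4, seed = 12)
  w <- admixture_weights(sf$freqs, "X", c("B", "C"),
                         rights = c("O2", "A", "inner", "anc2"),
                         outgroup = "O", blocks = sf$blocks)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  expect_lt(abs(w$weights[1] - 0.7), 3 * w$weight_se[1])
  # permuting the non-base rights leaves weights unchanged (same system,
  # different equation order)
  w2 <- admixture_weights(sf$freqs, "X", c("B", "C"),
                          rights = c("O2", "inner", "anc2", "A"),
                          outgroup = "O", blocks = sf$blocks)
  expect_equal(w$weights, w2$weights, tolerance = 1e-10)
  # single source: weight 1 by construction, fit measures cladality
  w1 <- admixture_weights(sf$freqs, "X", "B",
                          rights = c("O2", "A", "inner", "anc2"),
                          outgroup = "O", blocks = sf$blocks)
  expect_equal(w1$weights, 1)
  expect_true(is.finite(w1$chi2))
  # f4_ratio agreement within 2 joint SE on the same data
  fr_est <- f4_ratio(sf$freqs, "X", "A", "B", "C", "O", sf$blocks)
  expect_lt(abs(fr_est$alpha - w$weights[1]),
            2 * sqrt(fr_est$se^2 + w$weight_se[1]^2))
})

test_that("continuity scan flags turnover individuals and filters thin data", {
  # deep divergence between the local line and the incoming line, of the
  # order seen between European forager and farmer gene pools
  graph <- graph_spec("root", data.frame(
    parent = c("root", "root", "anc", "anc"),
    child = c("O", "anc", "lineA", "lineB"),
    F = c(0.1, 0.02, 0.1, 0.1)))
  fq <- simulate_graph_freqs(graph, 20000, seed = 21)
  plan <- data.frame(
    node = c(rep("lineA", 4), rep("lineB", 3), "lineA", "O"),
    group = c(paste0("pre", 1:4), paste0("post", 1:3), "anchor", "O"),
    n = 1, ploidy = 1, missing = 0, error = 0)
  ds <- sample_individuals(fq, plan, seed = 22)
  fr <- group_frequencies(ds$geno, ds$meta, "group")
  bl <- make_blocks(ds$panel)
  ages <- c(pre1 = 9000, pre2 = 8500, pre3 = 8000, pre4 = 7500,
            post1 = 7000, post2 = 6500, post3 = 6000)
  res <- continuity_scan(fr, names(ages), anchor = "anchor",
                         outgroup = "O", blocks = bl, ages = ages)
  expect_false(any(res$discontinuous[grepl("pre", res$id)]))
  expect_true(all(res$discontinuous[grepl("post", res$id)]))
  # a resample of the anchor's own population is never flagged
  expect_false(res$discontinuous[res$id == "pre1"])
  # site-threshold exclusion is reported
  res2 <- continuity_scan(fr, names(ages), anchor = "anchor",
                          outgroup = "O", blocks = bl, ages = ages,
                          min_sites = 1e6)
  expect_true(all(res2$excluded))
  expect_error(continuity_scan(fr, names(ages), anchor = "nope",
                               outgroup = "O", blocks = bl, ages = ages),
               "anchor")
})
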