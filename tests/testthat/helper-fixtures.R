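# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A small random panel + diploid genotype matrix with missingness.
random_dataset <- function(n_ind = 6, n_sites = 50, seed = 42,
                           missing = 0.1, ploidy = 2L) {
  withr::with_seed(seed, {
    panel <- snp_panel(
      site_id = paste0("rs", seq_len(n_sites)),
      chrom = rep("1", n_sites),
      pos = sort(sample.int(n_sites * 100L, n_sites)),
      allele1 = "A", allele2 = "C"
    )
    calls <- matrix(sample(0:ploidy, n_ind * n_sites, replace = TRUE),
                    nrow = n_ind)
    calls[runif(length(calls)) < missing] <- NA_integer_
    geno <- genotype_matrix(calls, ploidy,
                            ids = paste0("ind", seq_len(n_ind)))
    meta <- individual_meta(id = geno$ids, group = "pop1")
    list(panel = panel, geno = geno, meta = meta)
  })
}

# group_freqs built directly from a frequency matrix: "counts" from a large
# notional sample so freq == the given values exactly.
freqs_from_matrix <- function(freq_mat) {
  total <- matrix(1, nrow = nrow(freq_mat), ncol = ncol(freq_mat),
                  dimnames = dimnames(freq_mat))
  structure(list(count = freq_mat, total = total, freq = freq_mat,
                 groups = rownames(freq_mat)),
            class = "group_freqs")
}

# single-block spec for n sites (for exact brute-force comparisons we often
# want >= 2 blocks, so default 2)
simple_blocks <- function(n_sites, n_blocks = 2L) {
  block <- rep(seq_len(n_blocks), length.out = n_sites)
  block <- sort(block)
  structure(list(block = block, m = tabulate(block, n_blocks),
                 n_blocks = n_blocks), class = "block_spec")
}

# Brute-force per-site f-statistic oracle: plain loop over sites, no
# blocking, sites used only when all groups observed.
brute_fstat <- function(freqs, pops, combine) {
  vals <- c()
  for (s in seq_len(ncol(freqs$freq))) {
    p <- freqs$freq[pops, s]
    tot <- freqs$total[pops, s]
    if (all(tot > 0) && !anyNA(p)) vals <- c(vals, combine(p))
  }
  mean(vals)
}

# An f4-ratio test graph: outgroup O, far source C, near source B with
# sister A, admixed target X = alpha*B + (1-alpha)*C.
ratio_graph <- function(alpha, F = 0.02) {
  graph_spec(
    "root",
    edges = data.frame(
      parent = c("root", "root", "anc", "anc", "inner", "inner", "Xanc"),
      child = c("O", "anc", "C", "inner", "B", "A", "X"),
      F = c(0.1, 0.02, F, F, F, F, 0.005)),
    admixtures = data.frame(child = "Xanc", parent1 = "B", parent2 = "C",
                            alpha = alpha)
  )
}

# Sample pseudohaploid group panels from node frequencies for the groups
# named in `plan_nodes` (n individuals each), and return group_freqs +
# blocks.
sampled_freqs <- function(freqs, nodes, n = 4, seed = 1,
                          n_chrom = 1L) {
  plan <- data.frame(node = nodes, n = n, ploidy = 1, missing = 0,
                     error = 0)
  ds <- sample_individuals(freqs, plan, seed)
  fr <- group_frequencies(ds$geno, ds$meta, "group")
  list(freqs = fr, blocks = make_blocks(ds$panel), ds = ds)
}
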