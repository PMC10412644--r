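# Conditional nucleotide diversity on pseudohaploid pairs with temporal
# pairing, and the anchor-individual continuity statistic.

#' Build CND pairs in descending temporal order
#'
#' Individuals of a group passing the depth filter are sorted oldest-first
#' by cal BP midpoint and paired consecutively. A pairing that would join
#' known kin is repaired by swapping the second member with the next
#' individual in temporal order. With an odd roster the oldest unpaired
#' individual is dropped and reported.
#'
#' @param meta an `individual_meta`.
#' @param group group label to pair within.
#' @param min_depth minimum mean genome depth (X); default 0.1.
#' @param kin_exclusions list of length-2 character vectors of known kin
#'   pairs that must not be paired together.
#' @return List with `pairs` (two-column id matrix) and `unpaired` ids.
#' @export
build_cnd_pairs <- function(meta, group, min_depth = 0.1,
                            kin_exclusions = list()) {
  cand <- meta[meta$group == group &
                 (is.na(meta$mean_depth) | meta$mean_depth >= min_depth), ]
  if (nrow(cand) < 2L) stop("fewer than 2 eligible individuals in ", group)
  cand <- cand[order(-cand$cal_bp_mid), ]
  ids <- cand$id
  is_kin <- function(a, b) {
    any(vapply(kin_exclusions, function(k) all(c(a, b) %in% k), TRUE))
  }
  pairs <- list()
  queue <- ids
  while (length(queue) >= 2L) {
    a <- queue[1L]
    partner_idx <- 2L
    while (partner_idx <= length(queue) && is_kin(a, queue[partner_idx])) {
      partner_idx <- partner_idx + 1L
    }
    if (partner_idx > length(queue)) {  # only kin left for a
      queue <- queue[-1L]
      next
    }
    pairs[[length(pairs) + 1L]] <- c(a, queue[partner_idx])
    queue <- queue[-c(1L, partner_idx)]
  }
  pair_mat <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(character(0), ncol = 2L)
  colnames(pair_mat) <- c("id1", "id2")
  list(pairs = pair_mat,
       unpaired = setdiff(ids, as.vector(pair_mat)))
}

#' Conditional nucleotide diversity for one pseudohaploid pair
#'
#' The per-site mismatch rate between two pseudohaploid genomes over their
#' overlapping (both non-missing) ascertained sites; under the assumption
#' that the two haploid genomes are drawn from unrelated members of one
#' population this reflects within-population diversity. The standard error
#' is a weighted block jackknife over sites.
#'
#' @param geno a `genotype_matrix` (both individuals ploidy 1).
#' @param pair length-2 character vector of ids.
#' @param blocks a `block_spec`.
#' @return List of class `cnd_estimate`: ids, `n_overlap`, `mismatch`,
#'   `se`, `ci` (95\%), per-block sums/counts.
#' @export
cnd <- function(geno, pair, blocks) {
  i <- match(pair, geno$ids)
  if (anyNA(i)) stop("individual not found: ", pair[which(is.na(i))[1L]])
  if (any(geno$ploidy[i] != 1L)) {
    stop("cnd requires pseudohaploid individuals; run sample_pseudohaploid() first")
  }
  a <- geno$calls[i[1L], ]; b <- geno$calls[i[2L], ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no overlapping sites for pair ",
                     paste(pair, collapse = ", "))
  diff <- as.numeric(a[ok] != b[ok])
  bl <- blocks$block[ok]
  sums <- numeric(blocks$n_blocks); counts <- numeric(blocks$n_blocks)
  rs <- rowsum(diff, bl)
  ids_b <- as.integer(rownames(rs))
  sums[ids_b] <- rs[, 1L]
  counts[ids_b] <- tabulate(bl, nbins = blocks$n_blocks)
  jk <- block_jackknife(sums, counts)
  structure(list(id1 = pair[1L], id2 = pair[2L], n_overlap = sum(ok),
                 mismatch = jk$estimate, se = jk$se,
                 ci = jk$estimate + c(-1, 1) * 1.96 * jk$se,
                 block_sums = sums, block_counts = counts),
            class = "cnd_estimate")
}

#' Group-level CND with pooled estimate
#'
#' Per-pair CND estimates plus a pooled group estimate: the site-count
#' weighted mean across pairs, with a block jackknife over the summed block
#' contributions. Pooling across pairs is an extension of the per-pair
#' display and labeled as such in the output.
#'
#' @param geno a `genotype_matrix`.
#' @param pairs two-column id matrix (from [build_cnd_pairs()]).
#' @param blocks a `block_spec`.
#' @return List with `pairs` (data.frame of per-pair estimates) and
#'   `pooled` (estimate, se, ci, n).
#' @export
group_cnd <- function(geno, pairs, blocks) {
  pairs <- as.matrix(pairs)
  stopifnot(nrow(pairs) >= 1L)
  ests <- lapply(seq_len(nrow(pairs)), function(r)
    cnd(geno, pairs[r, ], blocks))
  tab <- do.call(rbind, lapply(ests, function(e)
    data.frame(id1 = e$id1, id2 = e$id2, n_overlap = e$n_overlap,
               mismatch = e$mismatch, se = e$se,
               ci_lo = e$ci[1L], ci_hi = e$ci[2L],
               stringsAsFactors = FALSE)))
  sums <- Reduce(`+`, lapply(ests, `[[`, "block_sums"))
  counts <- Reduce(`+`, lapply(ests, `[[`, "block_counts"))
  jk <- block_jackknife(sums, counts)
  list(pairs = tab,
       pooled = list(estimate = jk$estimate, se = jk$se,
                     ci = jk$estimate + c(-1, 1) * 1.96 * jk$se,
                     n = sum(counts), n_pairs = nrow(pairs)))
}

#' Sites heterozygous in a diploid anchor individual
#'
#' The anchor-method conditioning step: the returned site set is where the
#' anchor's diploid call is heterozygous (one ancestral, one derived
#' allele). Requires a polarized panel and a diploid anchor; heterozygosity
#' is unobservable in pseudohaploid data.
#'
#' @param geno a `genotype_matrix`.
#' @param anchor_id id of the (diploid) anchor.
#' @return Integer vector of site indices; warns when empty.
#' @export
anchor_condition <- function(geno, anchor_id) {
  i <- match(anchor_id, geno$ids)
  if (is.na(i)) stop("anchor not found: ", anchor_id)
  if (geno$ploidy[i] != 2L) {
    stop("anchor must be diploid: heterozygosity is unobservable in ",
         "pseudohaploid data")
  }
  sites <- which(!is.na(geno$calls[i, ]) & geno$calls[i, ] == 1L)
  if (!length(sites)) warning("anchor has no heterozygous sites")
  sites
}

#' Derived-allele proportion at anchor-conditioned sites
#'
#' For each test individual, the proportion of derived alleles over the
#' conditioned sites it covers, with block-jackknife SE. Along a continuous
#' lineage this proportion stays at the anchor's calibration value of 0.5
#' forwards in time and falls below it for individuals predating the
#' anchor's ancestry. Individuals with zero overlap are flagged, not fatal.
#'
#' @param geno a `genotype_matrix`.
#' @param sites conditioned site indices from [anchor_condition()].
#' @param test_ids individuals to score.
#' @param blocks a `block_spec`.
#' @return A `data.frame`: id, n_sites, proportion, se, ci bounds,
#'   `no_overlap` flag.
#' @export
anchor_proportion <- function(geno, sites, test_ids, blocks) {
  if (!length(sites)) stop("empty conditioned site set")
  rows <- lapply(test_ids, function(id) {
    i <- match(id, geno$ids)
    if (is.na(i)) stop("individual not found: ", id)
    calls <- geno$calls[i, sites]
    pl <- geno$ploidy[i]
    ok <- !is.na(calls)
    if (!any(ok)) {
      return(data.frame(id = id, n_sites = 0L, proportion = NA_real_,
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        no_overlap = TRUE, stringsAsFactors = FALSE))
    }
    der <- calls[ok] / pl   # derived dosage per site in [0, 1]
    bl <- blocks$block[sites][ok]
    sums <- numeric(blocks$n_blocks); counts <- numeric(blocks$n_blocks)
    rs <- rowsum(der, bl)
    ids_b <- as.integer(rownames(rs))
    sums[ids_b] <- rs[, 1L]
    counts[ids_b] <- tabulate(bl, nbins = blocks$n_blocks)
    if (sum(counts > 0) >= 2L) {
      jk <- block_jackknife(sums, counts)
      est <- jk$estimate; se <- jk$se
    } else {
      est <- sum(sums) / sum(counts); se <- NA_real_
    }
    data.frame(id = id, n_sites = sum(ok), proportion = est, se = se,
               ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
               no_overlap = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
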