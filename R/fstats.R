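# f2/f3/f4 estimators with weighted block jackknife, the f4-ratio admixture
# estimator, a constrained least-squares admixture-weight solver, and the
# regional continuity scan.

#' Assign SNPs to contiguous jackknife blocks
#'
#' Greedy contiguous blocking: a block grows while its genetic length stays
#' within `block_size_morgans` (physical length within `fallback_bp` when
#' genetic positions are absent on a chromosome); a new chromosome always
#' starts a new block.
#'
#' @param panel an `snp_panel`, sorted by (chrom, pos).
#' @param block_size_morgans maximum genetic block length (Morgans).
#' @param fallback_bp maximum physical block length when genetic positions
#'   are missing.
#' @return A list of class `block_spec`: `block` (per-site block index),
#'   `m` (per-block site counts), `n_blocks`.
#' @export
make_blocks <- function(panel, block_size_morgans = 0.05, fallback_bp = 5e6) {
  n <- nrow(panel)
  block <- integer(n)
  bid <- 0L
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    gpos <- panel$genetic_pos[idx]
    if (anyNA(gpos)) {
      coord <- as.numeric(panel$pos[idx]); size <- fallback_bp
    } else {
      coord <- gpos; size <- block_size_morgans
    }
    bid <- bid + 1L
    start <- coord[1L]
    for (k in seq_along(idx)) {
      if (coord[k] - start > size) {
        bid <- bid + 1L
        start <- coord[k]
      }
      block[idx[k]] <- bid
    }
  }
  m <- tabulate(block, nbins = bid)
  structure(list(block = block, m = m, n_blocks = bid), class = "block_spec")
}

#' Weighted delete-one-block jackknife
#'
#' Busing-style weighted jackknife for an estimate that is a ratio
#' `sum(block_sums) / sum(block_counts)` over unequal blocks; with equal
#' block sizes it reduces to the classic delete-one jackknife.
#'
#' @param block_sums per-block numerator sums.
#' @param block_counts per-block site counts (weights).
#' @return List with `estimate`, `se`, `z`, `loo` (leave-one-out estimates).
#' @export
block_jackknife <- function(block_sums, block_counts) {
  keep <- block_counts > 0
  s <- block_sums[keep]; m <- block_counts[keep]
  g <- length(s)
  if (g < 2L) stop("need at least 2 non-empty blocks for the jackknife")
  n <- sum(m); S <- sum(s)
  theta <- S / n
  loo <- (S - s) / (n - m)
  se <- weighted_jackknife_se(theta, loo, m)$se
  list(estimate = theta, se = se,
       z = if (se > 0) theta / se else sign(theta) * Inf, loo = loo)
}

# Weighted jackknife SE from a point estimate, leave-one-out estimates and
# per-block weights (site counts). Returns the bias-corrected estimate too.
weighted_jackknife_se <- function(theta, loo, m) {
  g <- length(loo)
  n <- sum(m)
  h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  list(estimate_bc = theta_j, se = sqrt(var_j))
}

# Shared core: per-site products, masked to sites observed in all groups,
# summed within blocks.
fstat_core <- function(kind, freqs, pops, blocks, term_fun) {
  missing_pop <- setdiff(pops, freqs$groups)
  if (length(missing_pop)) stop("unknown group(s): ",
                                paste(missing_pop, collapse = ", "))
  p <- freqs$freq[pops, , drop = FALSE]
  tot <- freqs$total[pops, , drop = FALSE]
  used <- colSums(tot > 0) == length(pops)
  n_used <- sum(used)
  if (n_used == 0L) stop("undefined statistic: no site observed in all groups")
  term <- term_fun(p)[used]
  bl <- blocks$block[used]
  block_sums <- rowsum(term, bl)
  ids <- as.integer(rownames(block_sums))
  sums <- numeric(blocks$n_blocks); counts <- numeric(blocks$n_blocks)
  sums[ids] <- block_sums[, 1L]
  counts[ids] <- tabulate(bl, nbins = blocks$n_blocks)
  jk <- block_jackknife(sums, counts)
  structure(list(kind = kind, pops = pops, estimate = jk$estimate,
                 block_sums = sums, block_counts = counts,
                 n_snps_used = n_used, se = jk$se, z = jk$z,
                 n_blocks = sum(counts > 0)),
            class = "f_stat")
}

#' @export
print.f_stat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f  (n = %d SNPs, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate, x$se, x$z,
              x$n_snps_used, x$n_blocks))
  invisible(x)
}

#' f4 statistic
#'
#' Mean over sites of `(p_A - p_B)(p_C - p_D)`; zero in expectation when
#' ((A,B),(C,D)) is a clade structure, nonzero under gene flow. Each site is
#' used only when all four groups have at least one non-missing allele.
#'
#' @param freqs a `group_freqs`.
#' @param A,B,C,D group labels.
#' @param blocks a `block_spec` for the jackknife.
#' @return An `f_stat`.
#' @export
f4 <- function(freqs, A, B, C, D, blocks) {
  fstat_core("f4", freqs, c(A, B, C, D), blocks,
             function(p) (p[1L, ] - p[2L, ]) * (p[3L, ] - p[4L, ]))
}

#' Outgroup f3 statistic
#'
#' `f3(O; A, B)`: mean of `(p_O - p_A)(p_O - p_B)`, the shared genetic drift
#' of A and B since their divergence from the outgroup O. No small-sample or
#' inbreeding correction is applied: on pseudohaploid data within-individual
#' heterozygosity is unobservable, so the uncorrected estimator is used for
#' every comparison (a deliberate divergence from some AdmixTools modes).
#'
#' @inheritParams f4
#' @param O outgroup label.
#' @param A,B test group labels.
#' @export
f3_outgroup <- function(freqs, O, A, B, blocks) {
  fstat_core("f3", freqs, c(O, A, B), blocks,
             function(p) (p[1L, ] - p[2L, ]) * (p[1L, ] - p[3L, ]))
}

#' f2 statistic
#'
#' Mean squared frequency difference `(p_A - p_B)^2`; uncorrected.
#' @inheritParams f4
#' @export
f2 <- function(freqs, A, B, blocks) {
  fstat_core("f2", freqs, c(A, B), blocks,
             function(p) (p[1L, ] - p[2L, ])^2)
}

# Leave-one-out estimates of an f_stat for each block in the spec.
fstat_loo <- function(fs) {
  S <- sum(fs$block_sums); n <- sum(fs$block_counts)
  (S - fs$block_sums) / (n - fs$block_counts)
}

#' f4-ratio admixture-proportion estimate
#'
#' Estimates `alpha = f4(A, O; X, C) / f4(A, O; B, C)`, the B-related
#' ancestry proportion in X under the standard f4-ratio tree (A a sister of
#' B, C the other source's relative, O an outgroup). The standard error
#' comes from leave-one-block-out recomputation of the full ratio, which is
#' robust near small denominators.
#'
#' @param freqs a `group_freqs`.
#' @param X target group.
#' @param A,B,C,O reference groups as above.
#' @param blocks a `block_spec`.
#' @param denom_z_min flag the estimate when the denominator f4 has
#'   `|Z|` below this threshold.
#' @return List of class `admixture_estimate` with `alpha`, `se`, `ci`
#'   (95\%), `z`, `weak_denominator`, component `f_stat`s.
#' @export
f4_ratio <- function(freqs, X, A, B, C, O, blocks, denom_z_min = 3) {
  num <- f4(freqs, A, O, X, C, blocks)
  den <- f4(freqs, A, O, B, C, blocks)
  if (den$estimate == 0) stop("zero denominator f4")
  alpha <- num$estimate / den$estimate
  loo <- fstat_loo(num) / fstat_loo(den)
  m <- num$block_counts + den$block_counts
  keep <- m > 0
  se <- weighted_jackknife_se(alpha, loo[keep], m[keep])$se
  structure(list(
    target = X, sources = c(B, C), alpha = alpha,
    weights = c(alpha, 1 - alpha), se = se,
    ci = alpha + c(-1, 1) * 1.96 * se,
    z = if (se > 0) alpha / se else Inf,
    weak_denominator = abs(den$z) < denom_z_min,
    n_snps = num$n_snps_used, num = num, den = den
  ), class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat("admixture estimate for", x$target, "\n")
  if (!is.null(x$alpha)) {
    cat(sprintf("  alpha(%s) = %.4f  SE = %.4f  95%% CI [%.4f, %.4f]\n",
                x$sources[1L], x$alpha, x$se, x$ci[1L], x$ci[2L]))
    if (isTRUE(x$weak_denominator)) cat("  warning: weak denominator f4\n")
  } else {
    for (j in seq_along(x$sources)) {
      cat(sprintf("  %-12s w = %.4f", x$sources[j], x$weights[j]))
      if (!is.null(x$weight_se)) cat(sprintf("  SE = %.4f", x$weight_se[j]))
      cat("\n")
    }
  }
  if (!is.null(x$chi2)) {
    cat(sprintf("  fit: chi2 = %.3f, df = %d, tail p = %.3g\n",
                x$chi2, x$df, x$tail_prob))
  }
  invisible(x)
}

# Solve min (y - A w)' W (y - A w) s.t. sum(w) = 1 by eliminating the last
# weight. W is a positive-definite weight matrix (identity for OLS).
solve_constrained_ls <- function(y, A, W) {
  k <- ncol(A)
  if (k == 1L) return(1)
  B <- A[, -k, drop = FALSE] - A[, k]
  t0 <- y - A[, k]
  if (qr(B)$rank < k - 1L) {
    stop("rank-deficient design: sources are collinear (",
         paste(colnames(A), collapse = ", "), ")")
  }
  u <- solve(crossprod(B, W %*% B), crossprod(B, W %*% t0))
  c(u, 1 - sum(u))
}

#' Admixture weights by constrained least squares over an f4 system
#'
#' A simplified qpAdm-style estimator: for right (reference) populations
#' `R_0..R_m`, solves the system `f4(R_0, R_i; X, O) = sum_j w_j f4(R_0,
#' R_i; S_j, O)` for weights summing to one, by least squares weighted with
#' the block-jackknife covariance of the residual f4 vector. The fit
#' statistic is the residual quadratic form referred to a chi-square with
#' `m - k + 1` degrees of freedom; per-weight standard errors come from
#' leave-one-block-out re-solves. Not numerically identical to qpAdm; it is
#' validated by parameter recovery on simulated admixture graphs.
#'
#' @param freqs a `group_freqs`.
#' @param target target group X.
#' @param sources source groups `S_1..S_k`.
#' @param rights reference groups; the first is the fixed base `R_0`,
#'   requiring `length(rights) - 1 >= length(sources)`.
#' @param outgroup outgroup O.
#' @param blocks a `block_spec`.
#' @return An `admixture_estimate` with weights, SEs, 95\% CIs, chi-square
#'   fit statistic and tail probability.
#' @export
admixture_weights <- function(freqs, target, sources, rights, outgroup,
                              blocks) {
  k <- length(sources)
  m <- length(rights) - 1L
  stopifnot(k >= 1L, m >= k)
  r0 <- rights[1L]; ri <- rights[-1L]
  all_pops <- c(target, sources, rights, outgroup)
  if (anyDuplicated(all_pops)) stop("target, sources, rights and outgroup must be disjoint")
  y_stats <- lapply(ri, function(r) f4(freqs, r0, r, target, outgroup, blocks))
  A_stats <- lapply(ri, function(r) lapply(sources, function(s)
    f4(freqs, r0, r, s, outgroup, blocks)))
  y <- vapply(y_stats, function(f) f$estimate, 0)
  A <- matrix(vapply(unlist(A_stats, recursive = FALSE),
                     function(f) f$estimate, 0),
              nrow = m, ncol = k, byrow = TRUE,
              dimnames = list(ri, sources))
  # leave-one-block-out versions of y and A
  y_loo <- vapply(y_stats, fstat_loo, numeric(blocks$n_blocks))  # g x m
  A_loo <- array(0, dim = c(blocks$n_blocks, m, k))
  for (i in seq_len(m)) for (j in seq_len(k)) {
    A_loo[, i, j] <- fstat_loo(A_stats[[i]][[j]])
  }
  w0 <- solve_constrained_ls(y, A, diag(m))
  # jackknife covariance of the residual vector at w0
  g <- blocks$n_blocks
  mj <- blocks$m
  v_hat <- as.numeric(y - A %*% w0)
  Q <- matrix(0, m, m)
  n <- sum(mj)
  tau <- matrix(0, g, m)
  for (b in seq_len(g)) {
    vb <- y_loo[b, ] - matrix(A_loo[b, , ], m, k) %*% w0
    h <- n / mj[b]
    tau[b, ] <- h * v_hat - (h - 1) * vb
  }
  v_j <- colMeans(tau)
  for (b in seq_len(g)) {
    d <- tau[b, ] - v_j
    Q <- Q + (d %*% t(d)) / (n / mj[b] - 1)
  }
  Q <- Q / g^2   # covariance of the mean residual vector
  Qi <- tryCatch(solve(Q), error = function(e)
    solve(Q + diag(1e-12 * mean(diag(Q)), m)))
  w <- solve_constrained_ls(y, A, Qi)
  resid <- as.numeric(y - A %*% w)
  chi2 <- as.numeric(t(resid) %*% Qi %*% resid)
  df <- m - k + 1L
  # per-weight jackknife SE: re-solve with each block removed, fixed Qi
  w_loo <- matrix(0, g, k)
  for (b in seq_len(g)) {
    w_loo[b, ] <- solve_constrained_ls(y_loo[b, ],
                                       matrix(A_loo[b, , ], m, k), Qi)
  }
  wse <- vapply(seq_len(k), function(j)
    weighted_jackknife_se(w[j], w_loo[, j], mj)$se, 0)
  structure(list(
    target = target, sources = sources, weights = as.numeric(w),
    weight_se = wse,
    weight_ci = cbind(lo = w - 1.96 * wse, hi = w + 1.96 * wse),
    chi2 = chi2, df = df,
    tail_prob = stats::pchisq(chi2, df, lower.tail = FALSE),
    n_snps = y_stats[[1L]]$n_snps_used, rights = rights
  ), class = "admixture_estimate")
}

#' Regional continuity scan with outgroup f3
#'
#' For each test individual X (each its own frequency group), computes
#' `f3(O; X, anchor)` — shared drift with the regional anchor, normally the
#' highest-coverage local Mesolithic individual — with a 95\% jackknife CI.
#' The decision line is the lower CI bound of the oldest individual's
#' statistic: an individual is flagged discontinuous when its upper CI bound
#' falls below that line. Individuals with fewer overlapping sites than
#' `min_sites` are excluded and listed.
#'
#' @param freqs a `group_freqs` in which every test individual (and the
#'   anchor and outgroup) is a group.
#' @param test_ids test individual/group labels.
#' @param anchor anchor label.
#' @param outgroup outgroup label.
#' @param blocks a `block_spec`.
#' @param ages named vector of cal BP midpoints for `test_ids` (larger =
#'   older).
#' @param min_sites minimum overlapping site count (default 500 for
#'   f3-based scans).
#' @return A `data.frame`: id, age, estimate, se, ci bounds, n_snps,
#'   excluded, discontinuous.
#' @export
continuity_scan <- function(freqs, test_ids, anchor, outgroup, blocks,
                            ages, min_sites = 500) {
  if (!anchor %in% freqs$groups) stop("anchor group not found: ", anchor)
  if (anyNA(ages[test_ids])) stop("every test individual needs an age")
  rows <- lapply(test_ids, function(id) {
    fs <- f3_outgroup(freqs, outgroup, id, anchor, blocks)
    data.frame(id = id, age = unname(ages[id]), estimate = fs$estimate,
               se = fs$se, lo = fs$estimate - 1.96 * fs$se,
               hi = fs$estimate + 1.96 * fs$se,
               n_snps = fs$n_snps_used, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$excluded <- res$n_snps < min_sites
  eligible <- !res$excluded
  res$discontinuous <- FALSE
  if (any(eligible)) {
    oldest <- which.max(ifelse(eligible, res$age, -Inf))
    ref_lo <- res$lo[oldest]
    res$discontinuous <- eligible & res$hi < ref_lo
  }
  attr(res, "excluded_ids") <- res$id[res$excluded]
  res
}
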