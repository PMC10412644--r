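# READ-style pairwise-mismatch kinship classification: windowed P0,
# cohort-median normalization, degree assignment with the Z > 1.96
# confidence rule, and the cohort screen.

# Expected normalized P0 is 1 - phi (kinship coefficient): 1 unrelated,
# 0.875 second degree, 0.75 first degree, 0.5 identical/duplicate. Class
# cutoffs sit at the midpoints; kept in one place so they can be
# reconfigured.
KIN_CUTOFFS <- c(identical = 0.625, first = 0.8125, second = 0.9375)
KIN_CLASSES <- c("identical/duplicate", "first degree", "second degree",
                 "unrelated")

#' Windowed pairwise mismatch (P0) for one pair
#'
#' Splits the genome into non-overlapping physical windows (1 Mb by
#' default, the READ convention) and computes, per window with any overlap,
#' the proportion of overlapping sites at which the two pseudohaploid calls
#' differ. Windows with zero overlap are dropped.
#'
#' @param geno a `genotype_matrix` (both individuals ploidy 1).
#' @param panel the matching `snp_panel` (for window coordinates).
#' @param id1,id2 individual ids.
#' @param window_bp window size in bp (default 1e6).
#' @return A `data.frame`: chrom, window, n sites, p0.
#' @export
pairwise_p0 <- function(geno, panel, id1, id2, window_bp = 1e6) {
  i <- match(c(id1, id2), geno$ids)
  if (anyNA(i)) stop("individual not found: ", c(id1, id2)[which(is.na(i))[1L]])
  if (any(geno$ploidy[i] != 1L)) stop("pairwise_p0 requires pseudohaploid calls")
  a <- geno$calls[i[1L], ]; b <- geno$calls[i[2L], ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("zero overlapping sites for pair ", id1, ", ", id2)
  win <- paste(panel$chrom, (panel$pos - 1L) %/% window_bp)
  diff <- as.numeric(a[ok] != b[ok])
  wf <- factor(win[ok], levels = unique(win[ok]))
  n <- as.vector(table(wf))
  mism <- as.vector(rowsum(diff, wf, reorder = FALSE))
  key <- strsplit(levels(wf), " ", fixed = TRUE)
  data.frame(chrom = vapply(key, `[`, "", 1L),
             window = as.integer(vapply(key, `[`, "", 2L)),
             n = n, p0 = mism / n, stringsAsFactors = FALSE)
}

# Mean P0 across windows and its window-based SE (as in READ: the windows
# are the resampling unit).
p0_summary <- function(p0_windows) {
  x <- p0_windows$p0
  k <- length(x)
  list(mean = mean(x),
       se = if (k > 1L) stats::sd(x) / sqrt(k) else NA_real_,
       n_windows = k, n_overlap = sum(p0_windows$n))
}

#' Normalize mean P0 scores across a cohort
#'
#' Divides each pair's mean P0 (and its SE) by the cohort median of the
#' mean P0 values — READ's default normalizer, valid when most pairs are
#' unrelated — or by an explicitly supplied external value.
#'
#' @param pair_table `data.frame` with columns `mean_p0`, `se_p0` (one row
#'   per pair).
#' @param external optional external normalization value replacing the
#'   cohort median.
#' @return The table with `norm_p0`, `norm_se` and the `normalizer` used
#'   (as an attribute).
#' @export
normalize_p0 <- function(pair_table, external = NULL) {
  if (is.null(external)) {
    if (nrow(pair_table) < 2L) {
      stop("a single pair cannot be median-normalized; supply `external`")
    }
    norm <- stats::median(pair_table$mean_p0)
  } else {
    norm <- external
  }
  if (!is.finite(norm) || norm <= 0) stop("invalid normalizer: ", norm)
  pair_table$norm_p0 <- pair_table$mean_p0 / norm
  pair_table$norm_se <- pair_table$se_p0 / norm
  attr(pair_table, "normalizer") <- norm
  pair_table
}

#' Classify kinship degree from normalized P0
#'
#' Classes are bounded by cutoffs at the midpoints of the expected
#' normalized P0 values (1 - phi): 0.625, 0.8125 and 0.9375. A value
#' exactly on a cutoff resolves toward the lower-relatedness side.
#' `z_adjacent` is the minimum standard-error-scaled distance to the
#' class's bounding cutoffs; a pair is reported confident when
#' `z_adjacent > 1.96`.
#'
#' @param norm_p0 normalized mean P0.
#' @param se normalized SE (> 0).
#' @param cutoffs named cutoff vector (identical/first/second upper bounds).
#' @return List: `class`, `z_adjacent`, `confident`.
#' @export
classify_degree <- function(norm_p0, se, cutoffs = KIN_CUTOFFS) {
  stopifnot(se >= 0)
  # a value exactly on a cutoff falls in the upper (less related) class
  cls <- KIN_CLASSES[findInterval(norm_p0, cutoffs) + 1L]
  bounds <- switch(cls,
    "identical/duplicate" = cutoffs[1L],
    "first degree" = cutoffs[1:2],
    "second degree" = cutoffs[2:3],
    "unrelated" = cutoffs[3L])
  gap <- min(abs(norm_p0 - bounds))
  z <- if (se > 0) gap / se else if (gap > 0) Inf else 0
  list(class = cls, z_adjacent = z, confident = z > 1.96)
}

#' Screen a cohort for close kin
#'
#' Runs all within-cell pairs of a partition through windowed P0,
#' cohort-median normalization and degree classification; a second pass
#' excluding individuals below the depth threshold recomputes the
#' normalizer, mirroring the confirmation rerun applied to low-coverage
#' cohorts. Because median normalization assumes an unstructured,
#' mostly-unrelated cohort, a bimodality diagnostic on the mean P0
#' distribution raises a warning when the cohort looks structured.
#'
#' @param geno a pseudohaploid `genotype_matrix`.
#' @param panel the matching `snp_panel`.
#' @param meta an `individual_meta`.
#' @param partition meta column name defining the analysis cells (default
#'   `"group"`); cells with fewer than two members are skipped with a
#'   notice.
#' @param min_depth depth threshold (X) for the confirmation pass.
#' @param window_bp P0 window size.
#' @return A `data.frame` of class `kin_pair_table`: ids, cell, n_overlap,
#'   mean/normalized P0, SE, class, z_adjacent, confident, pass.
#' @export
kin_screen <- function(geno, panel, meta, partition = "group",
                       min_depth = 0.1, window_bp = 1e6) {
  cells <- split(meta$id, meta[[partition]])
  out <- list()
  for (cell in names(cells)) {
    ids <- intersect(cells[[cell]], geno$ids)
    passes <- list(all = ids)
    deep <- ids[is.na(meta$mean_depth[match(ids, meta$id)]) |
                  meta$mean_depth[match(ids, meta$id)] >= min_depth]
    if (!identical(sort(deep), sort(ids)) && length(deep) >= 2L) {
      passes$depth_filtered <- deep
    }
    for (pass in names(passes)) {
      pids <- passes[[pass]]
      if (length(pids) < 2L) {
        message("partition cell '", cell, "' has fewer than 2 individuals; skipped")
        next
      }
      combos <- utils::combn(pids, 2L)
      tab <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
        pw <- pairwise_p0(geno, panel, combos[1L, k], combos[2L, k],
                          window_bp)
        s <- p0_summary(pw)
        data.frame(id1 = combos[1L, k], id2 = combos[2L, k], cell = cell,
                   n_overlap = s$n_overlap, n_windows = s$n_windows,
                   mean_p0 = s$mean, se_p0 = s$se, stringsAsFactors = FALSE)
      }))
      tab <- normalize_p0(tab)
      cl <- lapply(seq_len(nrow(tab)), function(r)
        classify_degree(tab$norm_p0[r], tab$norm_se[r]))
      tab$class <- vapply(cl, `[[`, "", "class")
      tab$z_adjacent <- vapply(cl, `[[`, 0, "z_adjacent")
      tab$confident <- vapply(cl, `[[`, TRUE, "confident")
      tab$pass <- pass
      if (nrow(tab) >= 6L && is_bimodal(tab$mean_p0)) {
        warning("mean P0 distribution in cell '", cell,
                "' looks bimodal: the cohort may be structured, which ",
                "violates the normalization assumption")
      }
      out[[paste(cell, pass)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("kin_pair_table", "data.frame")
  res
}

# Crude bimodality diagnostic: large gap in the sorted values relative to
# the overall spread.
is_bimodal <- function(x) {
  x <- sort(x)
  gaps <- diff(x)
  spread <- diff(range(x))
  spread > 0 && max(gaps) > 0.6 * spread && which.max(gaps) > 1 &&
    which.max(gaps) < length(gaps)
}
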