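# Data model and I/O for ascertained SNP panels and (pseudo)haploid/diploid
# genotype matrices, plus the panel-construction filters applied to ancient
# pseudohaploid datasets.

MISSING <- NA_integer_

TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")
AMBIGUOUS_PAIRS <- c("AT", "TA", "CG", "GC")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct an ascertained SNP panel
#'
#' A SNP panel is the ordered list of biallelic sites over which all
#' statistics in the package are computed. Sites must be sorted by
#' (chromosome, position) and unique on that key.
#'
#' @param site_id character vector of site labels.
#' @param chrom chromosome labels.
#' @param pos integer physical positions, 1-based.
#' @param allele1,allele2 single-character alleles; must differ per site.
#' @param genetic_pos optional genetic positions in Morgans (`NA` if unknown).
#' @param ancestral ancestral allele per site, `NA` when unknown; when present
#'   it must equal `allele1` or `allele2`.
#' @return A `data.frame` of class `snp_panel`.
#' @export
snp_panel <- function(site_id, chrom, pos, allele1, allele2,
                      genetic_pos = NA_real_, ancestral = NA_character_) {
  panel <- data.frame(
    site_id = as.character(site_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    genetic_pos = as.numeric(genetic_pos),
    allele1 = toupper(as.character(allele1)),
    allele2 = toupper(as.character(allele2)),
    ancestral = toupper(as.character(ancestral)),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  if (nrow(panel) == 0L) return(panel)
  if (any(panel$allele1 == panel$allele2)) {
    bad <- which(panel$allele1 == panel$allele2)[1L]
    stop("allele1 == allele2 at site ", panel$site_id[bad])
  }
  key <- paste(panel$chrom, panel$pos)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos): ", key[duplicated(key)][1L])
  }
  ord <- order(panel$chrom, panel$pos)
  if (!identical(ord, seq_len(nrow(panel)))) {
    stop("panel sites must be sorted by (chrom, pos)")
  }
  bad_anc <- !is.na(panel$ancestral) &
    panel$ancestral != panel$allele1 & panel$ancestral != panel$allele2
  if (any(bad_anc)) {
    stop("ancestral allele not in {allele1, allele2} at site ",
         panel$site_id[which(bad_anc)[1L]])
  }
  if (any(!is.na(panel$genetic_pos) & panel$genetic_pos < 0)) {
    stop("negative genetic position")
  }
  panel
}

#' Construct a genotype matrix
#'
#' Calls are stored individual-by-site as the count of `allele2` (or of the
#' derived allele once a panel has been polarized), in `0..ploidy`, with
#' `NA` as the missing sentinel. Pseudohaploid individuals are represented
#' natively with ploidy 1 rather than as forced-homozygous diploids.
#'
#' @param calls integer matrix, individuals in rows, sites in columns.
#' @param ploidy integer vector (1 = pseudohaploid, 2 = diploid), one per
#'   individual.
#' @param ids individual identifiers (defaults to rownames of `calls`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ploidy, ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(calls)))
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, nrow(calls))
  stopifnot(length(ploidy) == nrow(calls), all(ploidy %in% c(1L, 2L)),
            length(ids) == nrow(calls), !anyDuplicated(ids))
  rownames(calls) <- ids
  bad <- sweep(calls, 1L, ploidy, ">") | calls < 0L
  if (any(bad, na.rm = TRUE)) {
    idx <- which(bad)[1L]
    stop("call out of 0..ploidy range at individual ",
         ids[(idx - 1L) %% nrow(calls) + 1L], ", column ",
         (idx - 1L) %/% nrow(calls) + 1L)
  }
  structure(list(calls = calls, ploidy = ploidy, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x",
      ncol(x$calls), "sites;",
      sum(x$ploidy == 1L), "pseudohaploid,",
      sum(x$ploidy == 2L), "diploid\n")
  invisible(x)
}

#' Construct an individual metadata table
#'
#' @param id unique individual identifiers.
#' @param group population/group label.
#' @param sex `"XX"`, `"XY"` or `"UNKNOWN"`.
#' @param treatment library treatment: `"non-UDG"`, `"UDG"` or `"half-UDG"`.
#' @param assay `"shotgun"` or `"capture"`.
#' @param cal_bp_mid calibrated age midpoint in years BP (optional).
#' @param lat,lon coordinates in degrees (optional).
#' @param mt_hg,y_hg uniparental haplogroup labels (optional; `y_hg` only
#'   for XY individuals).
#' @param mean_depth mean genome depth in X coverage (optional).
#' @return A `data.frame` of class `individual_meta`.
#' @export
individual_meta <- function(id, group, sex = "UNKNOWN", treatment = "UDG",
                            assay = "shotgun", cal_bp_mid = NA_real_,
                            lat = NA_real_, lon = NA_real_,
                            mt_hg = NA_character_, y_hg = NA_character_,
                            mean_depth = NA_real_) {
  meta <- data.frame(
    id = as.character(id), group = as.character(group),
    sex = as.character(sex), treatment = as.character(treatment),
    assay = as.character(assay), cal_bp_mid = as.numeric(cal_bp_mid),
    lat = as.numeric(lat), lon = as.numeric(lon),
    mt_hg = as.character(mt_hg), y_hg = as.character(y_hg),
    mean_depth = as.numeric(mean_depth), stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$id)) stop("duplicate individual id")
  stopifnot(all(meta$sex %in% c("XX", "XY", "UNKNOWN")))
  if (any(!is.na(meta$y_hg) & meta$sex != "XY")) {
    stop("y_hg present for a non-XY individual")
  }
  class(meta) <- c("individual_meta", "data.frame")
  meta
}

#' Read EIGENSTRAT genotype files (unpacked text dialect)
#'
#' Reads the `.geno`/`.snp`/`.ind` triplet. Geno rows are sites, columns
#' individuals, characters in `{0,1,2,9}`; `9` maps to the missing sentinel.
#' All individuals are diploid unless their group label in the `.ind` file
#' matches `pseudohaploid_marker`, in which case they are read as ploidy 1
#' (and a call of 2 is a format error).
#'
#' @param geno_path,snp_path,ind_path file paths.
#' @param pseudohaploid_marker optional regular expression applied to the
#'   group label to mark ploidy-1 individuals.
#' @return A list with components `panel`, `geno`, `meta`.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            pseudohaploid_marker = NULL) {
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("site_id", "chrom", "genetic_pos",
                                         "pos", "allele1", "allele2"))
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  geno_lines <- readLines(geno_path)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(snp)) {
    stop("geno row count (", length(geno_lines),
         ") != snp row count (", nrow(snp), ")")
  }
  widths <- nchar(geno_lines)
  if (any(widths != nrow(ind))) {
    bad <- which(widths != nrow(ind))[1L]
    stop("geno line ", bad, " has width ", widths[bad],
         " but ind file lists ", nrow(ind), " individuals")
  }
  chars <- matrix(unlist(strsplit(geno_lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(geno_lines), byrow = TRUE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    row <- (idx - 1L) %% nrow(chars) + 1L
    col <- (idx - 1L) %/% nrow(chars) + 1L
    stop("invalid genotype character '", chars[idx], "' at geno line ", row,
         ", individual column ", col)
  }
  vals <- matrix(match(chars, c("0", "1", "2")) - 1L, nrow = nrow(chars))
  calls <- t(vals)  # individual-major
  ploidy <- rep(2L, nrow(ind))
  if (!is.null(pseudohaploid_marker)) {
    ploidy[grepl(pseudohaploid_marker, ind$group)] <- 1L
  }
  if (any(calls == 2L & ploidy == 1L, na.rm = TRUE)) {
    stop("call value 2 for a pseudohaploid-marked individual")
  }
  panel <- snp_panel(site_id = snp$site_id, chrom = snp$chrom, pos = snp$pos,
                     genetic_pos = ifelse(snp$genetic_pos == 0, NA_real_,
                                          snp$genetic_pos),
                     allele1 = snp$allele1, allele2 = snp$allele2)
  sex <- ifelse(ind$sex == "F", "XX", ifelse(ind$sex == "M", "XY", "UNKNOWN"))
  meta <- individual_meta(id = ind$id, group = ind$group, sex = sex)
  list(panel = panel,
       geno = genotype_matrix(calls, ploidy, ids = ind$id),
       meta = meta)
}

#' Write EIGENSTRAT genotype files (unpacked text dialect)
#'
#' @param panel an `snp_panel`.
#' @param geno a `genotype_matrix` column-aligned with `panel`.
#' @param meta an `individual_meta` row-aligned with `geno`.
#' @param out_prefix path prefix; writes `<prefix>.geno/.snp/.ind`.
#' @param haploid_as_diploid if `TRUE`, ploidy-1 calls are exported as
#'   homozygous diploid (0/2) for interoperability with tools that do not
#'   understand native haploid coding.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_eigenstrat <- function(panel, geno, meta, out_prefix,
                             haploid_as_diploid = FALSE) {
  if (length(geno$ids) == 0L) stop("no individuals to write")
  if (nrow(panel) != ncol(geno$calls)) {
    stop("panel/genotype site-count mismatch")
  }
  calls <- geno$calls
  if (haploid_as_diploid) {
    hap <- geno$ploidy == 1L
    calls[hap, ] <- 2L * calls[hap, ]
  }
  chars <- matrix("9", nrow = nrow(calls), ncol = ncol(calls))
  chars[!is.na(calls)] <- as.character(calls[!is.na(calls)])
  geno_lines <- apply(chars, 2L, paste, collapse = "")  # site-major rows
  paths <- paste0(out_prefix, c(".geno", ".snp", ".ind"))
  writeLines(geno_lines, paths[1L])
  snp_out <- data.frame(panel$site_id, panel$chrom,
                        ifelse(is.na(panel$genetic_pos), 0,
                               panel$genetic_pos),
                        panel$pos, panel$allele1, panel$allele2)
  utils::write.table(snp_out, paths[2L], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sex_code <- c(XX = "F", XY = "M", UNKNOWN = "U")[meta$sex]
  utils::write.table(data.frame(meta$id, sex_code, meta$group), paths[3L],
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(stats::setNames(paths, c("geno", "snp", "ind")))
}

#' Write an individual metadata table as TSV
#' @param meta an `individual_meta`.
#' @param path output file.
#' @export
write_meta <- function(meta, path) {
  utils::write.table(meta, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an individual metadata TSV written by [write_meta()]
#' @param path input file.
#' @export
read_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  do.call(individual_meta, df)
}

#' Randomly draw one allele per site (pseudohaploid sampling)
#'
#' Converts diploid genotypes to pseudohaploid calls by drawing a single
#' allele per site: homozygotes map deterministically (0 to 0, 2 to 1) and
#' heterozygotes go to 0 or 1 with probability one half each.
#'
#' @param geno a diploid `genotype_matrix`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A ploidy-1 `genotype_matrix`.
#' @export
sample_pseudohaploid <- function(geno, seed) {
  if (any(geno$ploidy != 2L)) stop("input individuals must be diploid")
  calls <- geno$calls
  out <- calls
  out[calls == 2L] <- 1L
  het <- which(calls == 1L)
  if (length(het)) {
    with_seed(seed, {
      out[het] <- as.integer(stats::rbinom(length(het), 1L, 0.5))
    })
  }
  genotype_matrix(out, ploidy = 1L, ids = geno$ids)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

is_transition_site <- function(panel) {
  paste0(panel$allele1, panel$allele2) %in% TRANSITION_PAIRS
}

#' Apply panel-construction filters
#'
#' Applies, in order: a minor-allele-frequency filter in a reference group,
#' removal of transition (C/T and G/A) sites, and per-individual treatment
#' masking in which non-UDG individuals have transition-site calls set to
#' missing while UDG and half-UDG individuals keep them.
#'
#' @param panel an `snp_panel`.
#' @param geno a `genotype_matrix`.
#' @param meta an `individual_meta` (required for `freq_group` or
#'   `treatment_rules`).
#' @param freq_group group in which the MAF is computed (e.g. Yoruba).
#' @param maf_min minimum minor allele frequency (0 disables).
#' @param transversions_only drop transition sites entirely.
#' @param treatment_rules apply the per-individual non-UDG transition mask.
#' @return List with filtered `panel`, `geno`, and a `report` of removed-site
#'   counts.
#' @export
apply_panel_filters <- function(panel, geno, meta = NULL, freq_group = NULL,
                                maf_min = 0, transversions_only = FALSE,
                                treatment_rules = FALSE) {
  keep <- rep(TRUE, nrow(panel))
  n_maf <- 0L
  if (maf_min > 0) {
    if (is.null(freq_group) || is.null(meta)) {
      stop("freq_group and meta required when maf_min > 0")
    }
    if (!freq_group %in% meta$group) stop("unknown group: ", freq_group)
    fr <- group_frequencies(geno, meta, meta$group)
    f <- fr$freq[freq_group, ]
    maf <- pmin(f, 1 - f)
    drop_maf <- is.na(maf) | maf < maf_min
    n_maf <- sum(drop_maf & keep)
    keep <- keep & !drop_maf
  }
  transition <- is_transition_site(panel)
  n_trans <- 0L
  if (transversions_only) {
    n_trans <- sum(transition & keep)
    keep <- keep & !transition
  }
  calls <- geno$calls[, keep, drop = FALSE]
  n_masked <- 0L
  if (treatment_rules) {
    if (is.null(meta)) stop("meta required for treatment rules")
    non_udg <- geno$ids %in% meta$id[meta$treatment == "non-UDG"]
    trans_kept <- transition[keep]
    if (any(non_udg) && any(trans_kept)) {
      n_masked <- sum(!is.na(calls[non_udg, trans_kept, drop = FALSE]))
      calls[non_udg, trans_kept] <- MISSING
    }
  }
  out_panel <- panel[keep, , drop = FALSE]
  rownames(out_panel) <- NULL
  list(panel = out_panel,
       geno = genotype_matrix(calls, geno$ploidy, ids = geno$ids),
       report = c(removed_maf = n_maf, removed_transition = n_trans,
                  masked_calls = n_masked))
}

# Reconcile one site's allele pair in `other` against the reference pair.
# Returns "same", "swap", "flip", "flipswap", or NA when irreconcilable.
reconcile_alleles <- function(a1, a2, b1, b2, allow_flip) {
  if (b1 == a1 && b2 == a2) return("same")
  if (b1 == a2 && b2 == a1) return("swap")
  if (allow_flip) {
    fb1 <- COMPLEMENT[[b1]]; fb2 <- COMPLEMENT[[b2]]
    if (fb1 == a1 && fb2 == a2) return("flip")
    if (fb1 == a2 && fb2 == a1) return("flipswap")
  }
  NA_character_
}

#' Merge genotype datasets on shared sites
#'
#' Intersects panels on (chrom, pos) and reconciles allele coding: identical
#' or swapped allele pairs are recoded, strand complement flips are attempted
#' only at transversion sites, strand-ambiguous A/T and C/G sites that do not
#' match directly are dropped, and sites whose allele union exceeds two are
#' dropped and counted as triallelic.
#'
#' @param datasets list of `list(panel=, geno=)` pairs.
#' @return List with merged `panel`, `geno` (individuals stacked in input
#'   order), and a `report` of dropped-site counters.
#' @export
merge_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  ref <- datasets[[1L]]
  report <- c(dropped_triallelic = 0L, dropped_ambiguous = 0L,
              dropped_irreconcilable = 0L)
  for (k in seq_along(datasets)[-1L]) {
    nxt <- datasets[[k]]
    rkey <- paste(ref$panel$chrom, ref$panel$pos)
    nkey <- paste(nxt$panel$chrom, nxt$panel$pos)
    common <- intersect(rkey, nkey)
    ri <- match(common, rkey)
    ni <- match(common, nkey)
    a1 <- ref$panel$allele1[ri]; a2 <- ref$panel$allele2[ri]
    b1 <- nxt$panel$allele1[ni]; b2 <- nxt$panel$allele2[ni]
    ambiguous <- paste0(a1, a2) %in% AMBIGUOUS_PAIRS |
      paste0(b1, b2) %in% AMBIGUOUS_PAIRS
    action <- character(length(common))
    for (s in seq_along(common)) {
      action[s] <- reconcile_alleles(a1[s], a2[s], b1[s], b2[s],
                                     allow_flip = !ambiguous[s])
    }
    failed <- is.na(action)
    if (any(failed)) {
      n_alleles <- mapply(function(x1, x2, y1, y2)
        length(unique(c(x1, x2, y1, y2))),
        a1[failed], a2[failed], b1[failed], b2[failed])
      report["dropped_triallelic"] <-
        report["dropped_triallelic"] + sum(n_alleles > 2L & !ambiguous[failed])
      report["dropped_ambiguous"] <-
        report["dropped_ambiguous"] + sum(ambiguous[failed])
      report["dropped_irreconcilable"] <-
        report["dropped_irreconcilable"] + sum(n_alleles <= 2L &
                                                 !ambiguous[failed])
    }
    keep <- !failed
    ri <- ri[keep]; ni <- ni[keep]; action <- action[keep]
    ncalls <- nxt$geno$calls[, ni, drop = FALSE]
    swap_cols <- action %in% c("swap", "flipswap")
    if (any(swap_cols)) {
      sub <- ncalls[, swap_cols, drop = FALSE]
      ncalls[, swap_cols] <- rep(nxt$geno$ploidy, sum(swap_cols)) - sub
    }
    merged_panel <- ref$panel[ri, , drop = FALSE]
    rownames(merged_panel) <- NULL
    ref <- list(
      panel = merged_panel,
      geno = genotype_matrix(
        rbind(ref$geno$calls[, ri, drop = FALSE], ncalls),
        c(ref$geno$ploidy, nxt$geno$ploidy),
        ids = c(ref$geno$ids, nxt$geno$ids)
      )
    )
  }
  c(ref, list(report = report))
}

#' Recode calls to derived-allele counts
#'
#' Polarizes a dataset so that call values count the derived allele. The
#' ancestral state comes either from the panel's `ancestral` column or from
#' a designated outgroup individual whose (haploid or homozygous) call
#' defines the ancestral allele. Sites with no usable ancestral state are
#' removed.
#'
#' @param panel an `snp_panel`.
#' @param geno a `genotype_matrix`.
#' @param ancestral_source `"panel"` or an individual id present in `geno`.
#' @return List of polarized `panel` and `geno` (outgroup retained).
#' @export
polarize <- function(panel, geno, ancestral_source = "panel") {
  if (identical(ancestral_source, "panel")) {
    anc <- panel$ancestral
  } else {
    i <- match(ancestral_source, geno$ids)
    if (is.na(i)) stop("ancestral_source individual not found: ",
                       ancestral_source)
    call <- geno$calls[i, ]
    pl <- geno$ploidy[i]
    anc <- ifelse(is.na(call), NA_character_,
                  ifelse(call == 0L, panel$allele1,
                         ifelse(call == pl, panel$allele2, NA_character_)))
  }
  if (all(is.na(anc))) stop("no ancestral information available")
  keep <- !is.na(anc) & (anc == panel$allele1 | anc == panel$allele2)
  calls <- geno$calls[, keep, drop = FALSE]
  flip <- anc[keep] == panel$allele2[keep]
  if (any(flip)) {
    sub <- calls[, flip, drop = FALSE]
    calls[, flip] <- rep(geno$ploidy, sum(flip)) - sub
  }
  out_panel <- panel[keep, , drop = FALSE]
  # After recoding, allele2 is the derived allele by construction.
  swap_sites <- flip
  tmp <- out_panel$allele1[swap_sites]
  out_panel$allele1[swap_sites] <- out_panel$allele2[swap_sites]
  out_panel$allele2[swap_sites] <- tmp
  out_panel$ancestral <- out_panel$allele1
  rownames(out_panel) <- NULL
  list(panel = out_panel,
       geno = genotype_matrix(calls, geno$ploidy, ids = geno$ids))
}

#' Per-group allele frequencies
#'
#' Computes, per group and site, the allele-2 (derived, if polarized) count,
#' the total number of non-missing alleles, and their ratio. These are the
#' frequency estimates consumed by every f-statistic.
#'
#' @param geno a `genotype_matrix`.
#' @param meta an `individual_meta` (used to map ids to groups when
#'   `grouping` is a column name).
#' @param grouping either a vector of group labels aligned with `geno$ids`,
#'   or the name of a `meta` column.
#' @return A list of class `group_freqs` with matrices `count`, `total`,
#'   `freq` (groups x sites).
#' @export
group_frequencies <- function(geno, meta = NULL, grouping = "group") {
  if (length(grouping) == 1L && !is.null(meta) && grouping %in% names(meta)) {
    grouping <- meta[[grouping]][match(geno$ids, meta$id)]
  }
  if (length(grouping) != length(geno$ids)) {
    stop("grouping must align with individuals")
  }
  if (length(grouping) == 0L) stop("empty grouping")
  groups <- unique(grouping)
  nS <- ncol(geno$calls)
  count <- matrix(0, nrow = length(groups), ncol = nS,
                  dimnames = list(groups, NULL))
  total <- count
  for (g in seq_along(groups)) {
    rows <- which(grouping == groups[g])
    sub <- geno$calls[rows, , drop = FALSE]
    count[g, ] <- colSums(sub, na.rm = TRUE)
    total[g, ] <- colSums((!is.na(sub)) * geno$ploidy[rows])
  }
  freq <- count / total
  freq[total == 0] <- NA_real_
  structure(list(count = count, total = total, freq = freq, groups = groups),
            class = "group_freqs")
}
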