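# Configuration-driven orchestration: simulate the synthetic bundle, run
# the analysis stages in dependency order, and write per-stage TSV/JSON
# results plus a manifest recording seeds, versions and every exclusion.

PIPELINE_KEYS <- list(
  top = c("seed", "out_dir", "block_size_morgans", "simulate", "analyses"),
  simulate = c("scenario", "K", "n_sites", "n_per_deme", "missing", "error"),
  analyses = c("fstat", "cnd", "kinship", "geodist", "cline"),
  fstat = c("min_sites_f4", "min_sites_f3"),
  cnd = c("min_depth"),
  kinship = c("window_mb", "min_depth", "n_unrelated"),
  geodist = c("vrma", "cellsize"),
  cline = c("min_sites", "distance", "cooks_rule")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) under ", where, ": ",
         paste(unknown, collapse = ", "))
  }
}

#' Run the end-to-end synthetic pipeline
#'
#' Reads a YAML config (or takes an equivalent list), simulates the
#' spatial-cline bundle, then runs the requested stages in dependency
#' order: per-individual f4 allele-sharing scan, conditional nucleotide
#' diversity per deme, a kinship screen on a pedigree cohort, least-cost
#' distances over a synthetic cost surface, and the isolation-by-distance
#' cline regression. All stage outputs are TSV/JSON under `out_dir`, and
#' `manifest.json` records the package version, seeds, thresholds and every
#' excluded individual with its reason; re-running with the same config and
#' seed reproduces all outputs byte-identically.
#'
#' @param config path to a YAML file or a config list.
#' @param quiet suppress console logging.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  check_keys(config, PIPELINE_KEYS$top, "top level")
  check_keys(config$simulate, PIPELINE_KEYS$simulate, "simulate")
  check_keys(config$analyses, PIPELINE_KEYS$analyses, "analyses")
  for (k in names(config$analyses)) {
    check_keys(config$analyses[[k]], PIPELINE_KEYS[[k]], k)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "paleocline_results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  unlink(log_path)
  manifest <- list(package = "paleocline",
                   version = as.character(utils::packageVersion("paleocline")),
                   seed = seed, config = config, exclusions = list(),
                   outputs = character(0))
  stage <- function(name, expr) {
    logf("[", name, "] start")
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, file)
  }

  sim_cfg <- config$simulate %||% list()
  if (!is.null(sim_cfg$scenario) && sim_cfg$scenario != "cline") {
    stop("unsupported simulate scenario: ", sim_cfg$scenario)
  }
  K <- sim_cfg$K %||% 8L
  ds <- stage("simulate", simulate_cline(
    K = K, n_sites = sim_cfg$n_sites %||% 20000L,
    n_per_deme = sim_cfg$n_per_deme %||% 2L,
    missing = sim_cfg$missing %||% 0.05,
    error = sim_cfg$error %||% 0.002, seed = seed))
  blocks <- make_blocks(ds$panel,
                        config$block_size_morgans %||% 0.05)
  demes <- paste0("deme", seq_len(K))
  an <- config$analyses %||% list()

  fstat_tab <- NULL
  if (!is.null(an$fstat) || is.null(config$analyses)) {
    fstat_tab <- stage("fstat", {
      fr <- group_frequencies(ds$geno, grouping = ds$geno$ids)  # per individual
      fr_grp <- group_frequencies(ds$geno, ds$meta, "group")
      deme_inds <- ds$meta$id[ds$meta$group %in% demes]
      rows <- lapply(deme_inds, function(id) {
        fs <- tryCatch(
          f4_indiv(fr, fr_grp, id, blocks), error = function(e) NULL)
        if (is.null(fs)) return(NULL)
        data.frame(id = id, response = fs$estimate, se = fs$se, z = fs$z,
                   n_sites = fs$n_snps_used, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      emit(tab, "fstat_scan.tsv")
      tab
    })
  }

  if (!is.null(an$cnd)) {
    stage("cnd", {
      min_depth <- an$cnd$min_depth %||% 0.1
      rows <- list()
      skipped <- character(0)
      for (d in demes) {
        pr <- tryCatch(build_cnd_pairs(ds$meta, d, min_depth),
                       error = function(e) NULL)
        if (is.null(pr) || nrow(pr$pairs) == 0L) { skipped <- c(skipped, d); next }
        gc_res <- group_cnd(ds$geno, pr$pairs, blocks)
        tab <- gc_res$pairs
        tab$group <- d
        tab$pooled <- gc_res$pooled$estimate
        rows[[d]] <- tab
      }
      manifest$exclusions$cnd_skipped_groups <- skipped
      emit(do.call(rbind, rows), "cnd.tsv")
    })
  }

  if (!is.null(an$kinship)) {
    stage("kinship", {
      n_unrel <- an$kinship$n_unrelated %||% 8L
      p_near <- ds$freqs_true["Near", ]
      ped <- simulate_pedigree("parent-offspring", p_near, seed + 101L)
      cohort_calls <- with_seed(seed + 102L, {
        unrel <- t(vapply(seq_len(n_unrel), function(i)
          as.integer(stats::rbinom(length(p_near), 1L, p_near)),
          integer(length(p_near))))
        ph <- sample_pseudohaploid(ped$geno, seed + 103L)
        rbind(ph$calls, unrel)
      })
      ids <- c("po_parent", "po_child", paste0("unrel", seq_len(n_unrel)))
      rownames(cohort_calls) <- ids
      cohort <- genotype_matrix(cohort_calls, 1L, ids = ids)
      cmeta <- individual_meta(id = ids, group = "cohort")
      kt <- kin_screen(cohort, ped$panel, cmeta, partition = "group",
                       min_depth = an$kinship$min_depth %||% 0.1,
                       window_bp = (an$kinship$window_mb %||% 1) * 1e6)
      emit(kt, "kinship.tsv")
    })
  }

  dist_tab <- NULL
  if (!is.null(an$geodist) || !is.null(an$cline)) {
    dist_tab <- stage("geodist", {
      cs <- an$geodist$cellsize %||% 1
      # uniform-cost square covering the sampling region, one cell of
      # padding around the deme scatter
      ncols <- K + 2L
      water <- raster_grid(matrix(0, ncols, ncols), xllcorner = -1.5,
                           yllcorner = -1.5, cellsize = cs)
      cost <- reclassify_water(water)
      deme_cells <- cell_from_xy(cost, ds$truth$deme_lon,
                                 ds$truth$deme_lat)
      # the two source core regions flank the region to the south-west
      # and south-east, off the sampled scatter
      near_cell <- rbind(c(ncols, 1L))
      far_cell <- rbind(c(ncols, ncols))
      summ <- multi_source_summary(
        cost, NULL, list(whg = near_cell, ag3 = far_cell),
        deme_cells, vrma_cut = an$geodist$vrma %||% 5)
      d_whg <- summ$dist_min[summ$set == "whg"]
      d_ag3 <- summ$dist_min[summ$set == "ag3"]
      deme_of <- match(ds$meta$group, demes)
      tab <- data.frame(id = ds$meta$id[!is.na(deme_of)],
                        dist_whg = d_whg[deme_of[!is.na(deme_of)]],
                        dist_ag3 = d_ag3[deme_of[!is.na(deme_of)]],
                        stringsAsFactors = FALSE)
      emit(tab, "distances.tsv")
      tab
    })
  }

  if (!is.null(an$cline)) {
    stage("cline", {
      if (is.null(fstat_tab)) stop("cline stage requires the fstat stage")
      obs <- assemble_observations(fstat_tab, dist_tab, ds$meta,
                                   min_sites = an$cline$min_sites %||% 5000,
                                   distance_kind = an$cline$distance %||% "min")
      manifest$exclusions$cline <- obs$id[!obs$included]
      model <- fit_cline(obs)
      lr <- leverage_refit(model)
      manifest$exclusions$cline_leverage <- lr$flagged
      coefs <- model$coefficients
      coefs$term <- rownames(coefs)
      emit(coefs[, c("term", "estimate", "se", "t_value", "p_value")],
           "cline_coefficients.tsv")
      report <- list(
        formula = deparse(model$formula),
        n = nrow(model$data), r_squared = model$r_squared,
        coefficients = coefs,
        leverage_flagged = lr$flagged,
        refit_coefficients = if (length(lr$flagged)) {
          rc <- lr$refit$coefficients; rc$term <- rownames(rc); rc
        } else NULL)
      jsonlite::write_json(report, file.path(out_dir, "cline_model.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      manifest$outputs <- c(manifest$outputs, "cline_model.json")
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("[done] outputs in ", out_dir)
  invisible(manifest)
}

# f4(Outgroup, X; Far, Near) for one individual against the group panels:
# the allele-sharing response used by the cline regression.
f4_indiv <- function(freq_ind, freq_grp, id, blocks) {
  combined <- list(
    count = rbind(freq_ind$count[id, , drop = FALSE],
                  freq_grp$count[c("Outgroup", "Far", "Near"), ]),
    total = rbind(freq_ind$total[id, , drop = FALSE],
                  freq_grp$total[c("Outgroup", "Far", "Near"), ]),
    freq = rbind(freq_ind$freq[id, , drop = FALSE],
                 freq_grp$freq[c("Outgroup", "Far", "Near"), ]),
    groups = c(id, "Outgroup", "Far", "Near")
  )
  class(combined) <- "group_freqs"
  f4(combined, "Outgroup", id, "Far", "Near", blocks)
}
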