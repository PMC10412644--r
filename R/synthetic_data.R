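# Synthetic-data generators with known ground truth for every pipeline
# stage: admixture-graph allele frequencies under Balding-Nichols drift,
# (pseudo)haploid genotype sampling, spatial admixture clines, pedigrees
# with Mendelian transmission, and raster fixtures with known least-cost
# answers.

#' Specify an admixture graph
#'
#' Nodes are connected by drift branches (Balding-Nichols parameter `F`) and
#' optional two-parent admixture events with mixing weight `alpha` (the
#' proportion contributed by `parent1`).
#'
#' @param root root node name.
#' @param edges `data.frame(parent, child, F)` drift branches, `F` in
#'   `[0, 0.5]`.
#' @param admixtures optional `data.frame(child, parent1, parent2, alpha)`.
#' @return A validated list of class `graph_spec` with nodes in topological
#'   order.
#' @export
graph_spec <- function(root, edges, admixtures = NULL) {
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(edges$F < 0 | edges$F > 0.5)) stop("drift F out of [0, 0.5]")
  if (!is.null(admixtures)) {
    stopifnot(all(admixtures$alpha >= 0 & admixtures$alpha <= 1))
    admixtures$child <- as.character(admixtures$child)
    admixtures$parent1 <- as.character(admixtures$parent1)
    admixtures$parent2 <- as.character(admixtures$parent2)
  }
  children <- c(edges$child, admixtures$child)
  if (anyDuplicated(children)) stop("a node has more than one incoming event")
  if (root %in% children) stop("root cannot have a parent")
  nodes <- unique(c(root, edges$parent, edges$child,
                    admixtures$parent1, admixtures$parent2,
                    admixtures$child))
  # topological sort (Kahn); also detects cycles
  parents_of <- function(n) {
    c(edges$parent[edges$child == n],
      if (!is.null(admixtures)) {
        i <- which(admixtures$child == n)
        c(admixtures$parent1[i], admixtures$parent2[i])
      })
  }
  ordered <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n)
      all(parents_of(n) %in% ordered), TRUE)]
    if (!length(ready)) stop("graph contains a cycle")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  orphan <- setdiff(ordered, c(root, children))
  if (length(orphan)) stop("node(s) with no path from root: ",
                           paste(orphan, collapse = ", "))
  structure(list(root = root, edges = edges, admixtures = admixtures,
                 nodes = ordered), class = "graph_spec")
}

#' Simulate allele frequencies along an admixture graph
#'
#' Root frequencies are Uniform(0.05, 0.95) per site (mimicking a
#' common-SNP ascertained panel); a child at drift `F` from its parent draws
#' from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (Balding-Nichols, so
#' `Var = F p(1-p)`); an admixture node is the deterministic mixture
#' `alpha p_1 + (1-alpha) p_2`.
#'
#' With `root_dist = "sfs"` the root derived-allele frequencies instead
#' follow a neutral-spectrum-like density proportional to `1/p` on
#' `[0.01, 0.99]`, so derived alleles are mostly rare at the root and tend
#' to be younger than ancestral ones — the asymmetry the anchor continuity
#' test relies on. The uniform default is appropriate for f-statistics on
#' common-SNP panels, where ascertainment has removed that skew.
#'
#' @param graph a `graph_spec`.
#' @param n_sites number of sites.
#' @param seed integer seed (draws are deterministic given the seed).
#' @param root_dist `"uniform"` (ascertained-panel mimic) or `"sfs"`.
#' @return Matrix of frequencies, nodes x sites.
#' @export
simulate_graph_freqs <- function(graph, n_sites, seed,
                                 root_dist = c("uniform", "sfs")) {
  root_dist <- match.arg(root_dist)
  with_seed(seed, {
    p <- matrix(NA_real_, nrow = length(graph$nodes), ncol = n_sites,
                dimnames = list(graph$nodes, NULL))
    p[graph$root, ] <- if (root_dist == "uniform") {
      stats::runif(n_sites, 0.05, 0.95)
    } else {
      0.01 * (0.99 / 0.01)^stats::runif(n_sites)  # density ~ 1/p
    }
    for (node in graph$nodes) {
      if (node == graph$root) next
      ei <- which(graph$edges$child == node)
      if (length(ei)) {
        par <- p[graph$edges$parent[ei], ]
        Fd <- graph$edges$F[ei]
        p[node, ] <- if (Fd == 0) par else
          stats::rbeta(n_sites, par * (1 - Fd) / Fd,
                       (1 - par) * (1 - Fd) / Fd)
      } else {
        ai <- which(graph$admixtures$child == node)
        p[node, ] <- graph$admixtures$alpha[ai] * p[graph$admixtures$parent1[ai], ] +
          (1 - graph$admixtures$alpha[ai]) * p[graph$admixtures$parent2[ai], ]
      }
    }
    p
  })
}

#' Sample individuals from per-node allele frequencies
#'
#' Diploid calls are Binomial(2, p) and pseudohaploid calls Bernoulli(p)
#' draws; entries are then set missing independently at the plan's
#' missingness rate and flipped symmetrically (each allele independently) at
#' the error rate.
#'
#' @param freqs node x site frequency matrix from [simulate_graph_freqs()].
#' @param plan `data.frame(node, n, ploidy, missing, error)` with optional
#'   `age` (cal BP midpoint, recycled within node) and `group` (defaults to
#'   the node name).
#' @param seed integer seed.
#' @return List with `panel` (synthetic, polarized: allele2 = derived),
#'   `geno`, `meta`.
#' @export
sample_individuals <- function(freqs, plan, seed) {
  stopifnot(all(plan$node %in% rownames(freqs)))
  if (is.null(plan$group)) plan$group <- plan$node
  if (is.null(plan$age)) plan$age <- NA_real_
  n_sites <- ncol(freqs)
  with_seed(seed, {
    calls <- list(); ploidy <- integer(0); ids <- character(0)
    groups <- character(0); ages <- numeric(0)
    for (r in seq_len(nrow(plan))) {
      p <- freqs[plan$node[r], ]
      pl <- plan$ploidy[r]
      for (i in seq_len(plan$n[r])) {
        g <- stats::rbinom(n_sites, pl, p)
        if (plan$error[r] > 0) {
          down <- stats::rbinom(n_sites, g, plan$error[r])
          up <- stats::rbinom(n_sites, pl - g, plan$error[r])
          g <- g - down + up
        }
        if (plan$missing[r] > 0) {
          g[stats::runif(n_sites) < plan$missing[r]] <- NA_integer_
        }
        calls[[length(calls) + 1L]] <- g
        ploidy <- c(ploidy, pl)
        ids <- c(ids, sprintf("%s_%d", plan$group[r], i))
        groups <- c(groups, plan$group[r])
        ages <- c(ages, plan$age[r])
      }
    }
    mat <- do.call(rbind, calls)
    list(panel = synth_panel(n_sites),
         geno = genotype_matrix(mat, ploidy, ids = ids),
         meta = individual_meta(id = ids, group = groups,
                                cal_bp_mid = ages))
  })
}

#' Synthetic ascertained SNP panel
#'
#' A/C sites (transversions) on `n_chrom` chromosomes with evenly spaced
#' physical positions and genetic positions spanning `morgans_per_chrom`
#' Morgans per chromosome, already polarized (allele1 ancestral).
#'
#' @param n_sites total site count.
#' @param n_chrom number of chromosomes.
#' @param morgans_per_chrom genetic length per chromosome; the default 5
#'   yields 100 jackknife blocks at the 0.05 Morgan block size.
#' @export
synth_panel <- function(n_sites, n_chrom = 1L, morgans_per_chrom = 5) {
  per <- ceiling(n_sites / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per)[seq_len(n_sites)]
  within <- unlist(lapply(split(seq_len(n_sites), chrom), seq_along),
                   use.names = FALSE)
  n_on <- tabulate(chrom)[chrom]
  snp_panel(site_id = paste0("rs", seq_len(n_sites)),
            chrom = as.character(chrom),
            pos = within * 1000L,
            genetic_pos = (within - 1L) / n_on * morgans_per_chrom,
            allele1 = "A", allele2 = "C", ancestral = "A")
}

#' Simulate a 1-D spatial admixture cline
#'
#' K demes on a line between two diverged sources: deme d has ancestry
#' proportion `alpha_d` from the near source, declining linearly from 1 to 0
#' across the line (K = 3 gives 1, 0.5, 0). The emitted dataset carries the
#' near source (`"Near"`), far source (`"Far"`), a sister of the near source
#' (`"NearSister"`, for f4-ratio reference use) and an outgroup
#' (`"Outgroup"`), plus per-deme coordinates for the distance stages.
#'
#' @param K number of demes (>= 3).
#' @param n_sites sites per individual.
#' @param n_per_deme pseudohaploid individuals sampled per deme.
#' @param drift_source drift F on the branches separating the sources.
#' @param drift_deme drift F after admixture within each deme.
#' @param missing,error per-call missingness and error rates.
#' @param seed integer seed.
#' @return List with `panel`, `geno`, `meta` (deme longitudes increase with
#'   distance from the near source), `freqs_true` (node frequencies) and
#'   `truth` (`alpha` per deme, coordinates, parameters, seed).
#' @export
simulate_cline <- function(K = 20, n_sites = 50000, n_per_deme = 2,
                           drift_source = 0.02, drift_deme = 0.005,
                           missing = 0.05, error = 0.002, seed = 1) {
  stopifnot(K >= 3)
  alpha <- 1 - (seq_len(K) - 1) / (K - 1)
  demes <- paste0("deme", seq_len(K))
  edges <- data.frame(
    parent = c("root", "root", "anc", "anc", "inner", "inner"),
    child = c("Outgroup", "anc", "Far", "inner", "Near", "NearSister"),
    F = c(0.1, 0.02, drift_source, drift_source, drift_source, drift_source)
  )
  adm <- data.frame(child = paste0(demes, "_anc"), parent1 = "Near",
                    parent2 = "Far", alpha = alpha)
  edges <- rbind(edges, data.frame(parent = paste0(demes, "_anc"),
                                   child = demes, F = drift_deme))
  graph <- graph_spec("root", edges, adm)
  freqs <- simulate_graph_freqs(graph, n_sites, seed)
  plan <- rbind(
    data.frame(node = demes, n = n_per_deme, ploidy = 1,
               missing = missing, error = error,
               age = 9000 - 100 * seq_len(K)),
    data.frame(node = c("Near", "Far", "NearSister", "Outgroup"),
               n = c(4, 4, 4, 4), ploidy = 1, missing = 0, error = 0,
               age = NA_real_)
  )
  ds <- sample_individuals(freqs, plan, seed + 1L)
  # deme coordinates: the ancestry cline runs west-east (lon tracks the
  # deme index), while sites scatter over a latitudinal band as wide as
  # the cline is long — the geometry of a continental sampling transect.
  # Without that 2-D scatter the least-cost distances from the two source
  # regions are affinely dependent and the two-distance regression is
  # unidentifiable.
  deme_lon <- (seq_len(K) - 1) * 1.0
  deme_lat <- rep(seq(0, K - 1, length.out = 5), length.out = K)
  idx <- match(ds$meta$group, demes)
  ds$meta$lon <- ifelse(is.na(idx), NA_real_, deme_lon[idx])
  ds$meta$lat <- ifelse(is.na(idx), NA_real_, deme_lat[idx])
  list(panel = ds$panel, geno = ds$geno, meta = ds$meta,
       freqs_true = freqs,
       truth = list(alpha = stats::setNames(alpha, demes),
                    deme_lon = deme_lon, deme_lat = deme_lat, K = K,
                    n_sites = n_sites, drift_source = drift_source,
                    drift_deme = drift_deme, seed = seed))
}

# Founder allele matrix: 2 x n_sites of 0/1 derived indicators.
founder_alleles <- function(p) {
  rbind(stats::rbinom(length(p), 1, p), stats::rbinom(length(p), 1, p))
}

# Mendelian transmission: one random allele from each parent.
mate <- function(g1, g2) {
  n <- ncol(g1)
  rbind(g1[cbind(sample.int(2L, n, replace = TRUE), seq_len(n))],
        g2[cbind(sample.int(2L, n, replace = TRUE), seq_len(n))])
}

PEDIGREE_PHI <- c("identical" = 1 / 2, "parent-offspring" = 1 / 4,
                  "full-sibs" = 1 / 4, "half-sibs" = 1 / 8,
                  "grandparent-grandchild" = 1 / 8, "avuncular" = 1 / 8,
                  "double-first-cousins" = 1 / 8, "unrelated" = 0)

#' Simulate a pedigree pair with Mendelian transmission
#'
#' Founders draw both alleles from the population frequencies; descendants
#' receive one random allele from each parent per site. The focal pair is
#' returned as diploid genotypes (pseudohaploid sampling is applied last by
#' the caller) along with the true kinship coefficient.
#'
#' @param relationship one of `"identical"`, `"parent-offspring"`,
#'   `"full-sibs"`, `"half-sibs"`, `"grandparent-grandchild"`,
#'   `"avuncular"`, `"double-first-cousins"`, `"unrelated"`.
#' @param p population derived-allele frequencies (one per site).
#' @param seed integer seed.
#' @return List with `geno` (diploid `genotype_matrix` of the focal pair,
#'   ids `id1`/`id2`), `panel`, `truth` (`phi`, `relationship`, `seed`).
#' @export
simulate_pedigree <- function(relationship, p, seed) {
  relationship <- match.arg(relationship, names(PEDIGREE_PHI))
  with_seed(seed, {
    F1 <- founder_alleles(p); F2 <- founder_alleles(p)
    F3 <- founder_alleles(p); F4 <- founder_alleles(p)
    pair <- switch(relationship,
      "identical" = { a <- mate(F1, F2); list(a, a) },
      "parent-offspring" = list(F1, mate(F1, F2)),
      "full-sibs" = list(mate(F1, F2), mate(F1, F2)),
      "half-sibs" = list(mate(F1, F2), mate(F1, F3)),
      "grandparent-grandchild" = {
        c1 <- mate(F1, F2)
        list(F1, mate(c1, F3))
      },
      "avuncular" = {
        c1 <- mate(F1, F2); c2 <- mate(F1, F2)
        list(c1, mate(c2, F3))
      },
      "double-first-cousins" = {
        s1a <- mate(F1, F2); s1b <- mate(F1, F2)
        s2a <- mate(F3, F4); s2b <- mate(F3, F4)
        list(mate(s1a, s2a), mate(s1b, s2b))
      },
      "unrelated" = list(mate(F1, F2), mate(F3, F4))
    )
    calls <- rbind(colSums(pair[[1L]]), colSums(pair[[2L]]))
    list(geno = genotype_matrix(calls, ploidy = 2L, ids = c("id1", "id2")),
         panel = synth_panel(length(p)),
         truth = list(phi = unname(PEDIGREE_PHI[relationship]),
                      relationship = relationship, seed = seed))
  })
}

#' Raster fixtures with known least-cost answers
#'
#' Small water/ice/elevation grids whose least-cost structure is known
#' analytically (`uniform`: octile distances) or by exhaustive enumeration
#' over all simple paths (`wall`, `ice_corridor`, `downhill_valley`,
#' `random_small`). The enumeration in `truth` is computed by a depth-first
#' search over simple paths, independent of the Dijkstra implementation.
#'
#' @param scenario one of `"uniform"`, `"wall"`, `"ice_corridor"`,
#'   `"downhill_valley"`, `"random_small"`.
#' @param seed integer seed (used by `random_small`).
#' @return List with `water`, `ice`, `elev` `raster_grid`s, `cost` (final
#'   combined cost raster), `source`, and `truth` (known accumulated costs:
#'   full matrix for `uniform`, named destinations otherwise).
#' @export
make_raster_fixture <- function(scenario = c("uniform", "wall",
                                             "ice_corridor",
                                             "downhill_valley",
                                             "random_small"),
                                seed = 1) {
  scenario <- match.arg(scenario)
  flat <- function(nr, nc) raster_grid(matrix(0, nr, nc))
  zeros <- function(nr, nc) raster_grid(matrix(0, nr, nc))
  out <- switch(scenario,
    uniform = {
      nr <- 5L; nc <- 5L
      water <- raster_grid(matrix(0, nr, nc))
      src <- c(3L, 3L)
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      dr <- abs(rows - src[1L]); dc <- abs(cols - src[2L])
      octile <- pmax(dr, dc) + (sqrt(2) - 1) * pmin(dr, dc)
      list(water = water, ice = zeros(nr, nc), elev = flat(nr, nc),
           source = src, truth = list(accumulated = octile))
    },
    wall = {
      nr <- 4L; nc <- 4L
      w <- matrix(0, nr, nc)
      w[1:3, 3] <- 100  # high-cost wall with a gap at the bottom
      water <- raster_grid(w)
      src <- c(1L, 1L)
      list(water = water, ice = zeros(nr, nc), elev = flat(nr, nc),
           source = src, dest = c(1L, 4L))
    },
    ice_corridor = {
      nr <- 4L; nc <- 5L
      water <- raster_grid(matrix(0, nr, nc))
      ice <- matrix(0, nr, nc)
      ice[2, 2:4] <- 1  # iced corridor row; open detour below
      src <- c(2L, 1L)
      list(water = water, ice = raster_grid(ice), elev = flat(nr, nc),
           source = src, dest = c(2L, 5L))
    },
    downhill_valley = {
      nr <- 3L; nc <- 4L
      water <- raster_grid(matrix(0, nr, nc))
      # gentle slope descending eastward: ~2 degrees over cellsize 1000 m
      elev <- raster_grid(matrix(rep(seq(0, by = -35, length.out = nc),
                                     each = nr), nr, nc))
      src <- c(2L, 1L)
      list(water = water, ice = zeros(nr, nc), elev = elev,
           source = src, dest = c(2L, 4L), cellsize = 1000)
    },
    random_small = {
      nr <- 4L; nc <- 4L
      w <- with_seed(seed, matrix(sample(c(0, 10, 30, 55, 90), nr * nc,
                                         replace = TRUE), nr, nc))
      water <- raster_grid(w)
      src <- c(1L, 1L)
      list(water = water, ice = zeros(nr, nc), elev = flat(nr, nc),
           source = src, dest = c(4L, 4L))
    }
  )
  cs <- if (is.null(out$cellsize)) 1 else out$cellsize
  for (nm in c("water", "ice", "elev")) {
    out[[nm]]$cellsize <- cs
  }
  cost <- add_ice(reclassify_water(out$water), out$ice)
  out$cost <- cost
  if (is.null(out$truth)) {
    dests <- list(out$dest)
    costs <- vapply(dests, function(d)
      enumerate_min_path_cost(cost, out$elev, out$source, d), 0)
    out$truth <- list(dest = out$dest, min_cost = costs[[1L]])
  } else if (scenario == "uniform") {
    out$truth$accumulated <- out$truth$accumulated * cs
  }
  out
}

# Exhaustive minimum path cost by depth-first search over simple paths
# (branch-and-bound pruned against the best complete path found so far).
# Used only to generate fixture truth; independent of path_distance().
enumerate_min_path_cost <- function(cost, elev, src, dst, vrma_cut = 5,
                                    slope_param = 1 / 45, vf_floor = 0.05) {
  nr <- cost$nrows; nc <- cost$ncols
  cm <- cost$data; em <- if (is.null(elev)) NULL else elev$data
  cs <- cost$cellsize
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  edge_cost <- function(r1, c1, r2, c2) {
    d <- cs * sqrt((r1 - r2)^2 + (c1 - c2)^2)
    w <- d * (cm[r1, c1] + cm[r2, c2]) / 2
    if (!is.null(em)) {
      w <- w * vertical_factor(em[r1, c1], em[r2, c2], d, vrma_cut,
                               slope_param, vf_floor)
    }
    w
  }
  recurse <- function(r, c, acc) {
    if (acc >= best) return(invisible(NULL))
    if (r == dst[1L] && c == dst[2L]) {
      best <<- acc
      return(invisible(NULL))
    }
    visited[r, c] <<- TRUE
    for (dir in 1:8) {
      r2 <- r + NEIGHBOR_OFFSETS[dir, 1L]
      c2 <- c + NEIGHBOR_OFFSETS[dir, 2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      if (visited[r2, c2] || is.na(cm[r2, c2])) next
      w <- edge_cost(r, c, r2, c2)
      if (is.finite(w)) recurse(r2, c2, acc + w)
    }
    visited[r, c] <<- FALSE
    invisible(NULL)
  }
  recurse(src[1L], src[2L], 0)
  best
}
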