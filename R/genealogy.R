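# Enumeration of trio genealogies consistent with observed pairwise kinship
# degrees, sexes, uniparental haplogroups and age order. Candidate models
# assign a catalog relationship (with orientation and maternal/paternal
# line) to each pair; every candidate is then actually constructed as a
# small pedigree with latent parents/grandparents, and survives only if the
# construction is internally consistent and the realized kinship
# coefficients match the observed degrees.

DEGREE_PHI <- c(first = 1 / 4, second = 1 / 8, unrelated = 0)

# ---- pedigree construction state ------------------------------------------
# Individuals are focal ids or generated latents. Slots (mother/father) hold
# ids; identities are merged through a union-find so that, e.g., "the mother
# of A" introduced by one relationship can later be identified with a focal
# individual or with "the mother of B".

ped_new <- function(ids, sexes) {
  env <- new.env(parent = emptyenv())
  env$uf <- stats::setNames(ids, ids)           # union-find parent pointers
  env$sex <- stats::setNames(sexes, ids)        # "XX", "XY", "UNKNOWN"
  env$mother <- stats::setNames(rep(NA_character_, length(ids)), ids)
  env$father <- stats::setNames(rep(NA_character_, length(ids)), ids)
  env$focal <- ids
  env$diseq <- list()                           # pairs that must stay distinct
  env$unrelated <- list()                       # pairs with no shared ancestor
  env$counter <- 0L
  env$failed <- FALSE
  env
}

ped_find <- function(env, id) {
  force(id)  # argument expressions may register new ids in env$uf
  while (env$uf[[id]] != id) id <- env$uf[[id]]
  id
}

ped_add <- function(env, sex) {
  env$counter <- env$counter + 1L
  id <- paste0(".L", env$counter)
  env$uf[[id]] <- id
  env$sex[[id]] <- sex
  env$mother[[id]] <- NA_character_
  env$father[[id]] <- NA_character_
  id
}

sex_merge <- function(a, b) {
  if (a == "UNKNOWN") return(b)
  if (b == "UNKNOWN" || a == b) return(a)
  NA_character_  # conflict
}

ped_union <- function(env, a, b) {
  force(a); force(b)
  if (env$failed) return(invisible(FALSE))
  a <- ped_find(env, a); b <- ped_find(env, b)
  if (a == b) return(invisible(TRUE))
  a_focal <- a %in% env$focal; b_focal <- b %in% env$focal
  if (a_focal && b_focal) { env$failed <- TRUE; return(invisible(FALSE)) }
  # keep the focal (or first) id as representative
  if (b_focal) { tmp <- a; a <- b; b <- tmp }
  s <- sex_merge(env$sex[[a]], env$sex[[b]])
  if (is.na(s)) { env$failed <- TRUE; return(invisible(FALSE)) }
  env$sex[[a]] <- s
  env$uf[[b]] <- a
  # reconcile parent slots of the merged identity
  for (slot in c("mother", "father")) {
    pa <- env[[slot]][[a]]; pb <- env[[slot]][[b]]
    if (!is.na(pb)) {
      if (is.na(pa)) env[[slot]][[a]] <- pb
      else ped_union(env, pa, pb)
    }
  }
  invisible(!env$failed)
}

ped_get_parent <- function(env, id, slot) {
  id <- ped_find(env, id)
  p <- env[[slot]][[id]]
  if (is.na(p)) NA_character_ else ped_find(env, p)
}

ped_ensure_parent <- function(env, id, slot) {
  p <- ped_get_parent(env, id, slot)
  if (!is.na(p)) return(p)
  id <- ped_find(env, id)
  latent <- ped_add(env, if (slot == "mother") "XX" else "XY")
  env[[slot]][[id]] <- latent
  latent
}

ped_set_parent <- function(env, child, parent, slot) {
  force(child); force(parent)
  if (env$failed) return(invisible(FALSE))
  want <- if (slot == "mother") "XX" else "XY"
  parent <- ped_find(env, parent)
  s <- sex_merge(env$sex[[parent]], want)
  if (is.na(s)) { env$failed <- TRUE; return(invisible(FALSE)) }
  env$sex[[parent]] <- s
  cur <- ped_get_parent(env, child, slot)
  child <- ped_find(env, child)
  if (is.na(cur)) env[[slot]][[child]] <- parent
  else ped_union(env, cur, parent)
  invisible(!env$failed)
}

ped_ancestors <- function(env, id, depth = 12L) {
  out <- character(0)
  frontier <- ped_find(env, id)
  while (length(frontier) && depth > 0L) {
    nxt <- character(0)
    for (x in frontier) {
      for (slot in c("mother", "father")) {
        p <- ped_get_parent(env, x, slot)
        if (!is.na(p) && !(p %in% out)) { out <- c(out, p); nxt <- c(nxt, p) }
      }
    }
    frontier <- nxt
    depth <- depth - 1L
  }
  out
}

# Kinship coefficient on the realized pedigree; unknown parents are unique
# unrelated founders (contribute zero).
ped_phi <- function(env, x, y) {
  x <- ped_find(env, x); y <- ped_find(env, y)
  if (x == y) {
    m <- ped_get_parent(env, x, "mother"); f <- ped_get_parent(env, x, "father")
    inb <- if (is.na(m) || is.na(f)) 0 else ped_phi(env, m, f)
    return((1 + inb) / 2)
  }
  # recurse through the parents of whichever individual is not an ancestor
  # of the other
  through <- if (x %in% ped_ancestors(env, y)) y else x
  other <- if (through == x) y else x
  m <- ped_get_parent(env, through, "mother")
  f <- ped_get_parent(env, through, "father")
  pm <- if (is.na(m)) 0 else ped_phi(env, m, other)
  pf <- if (is.na(f)) 0 else ped_phi(env, f, other)
  (pm + pf) / 2
}

ped_ok <- function(env) {
  if (env$failed) return(FALSE)
  # acyclic: nobody (focal or latent) is their own ancestor
  reps <- unique(vapply(names(env$uf), function(i) ped_find(env, i), ""))
  for (id in reps) {
    if (id %in% ped_ancestors(env, id)) return(FALSE)
  }
  # disequality constraints (e.g. the unshared parents of half sibs)
  for (pr in env$diseq) {
    if (ped_find(env, pr[1L]) == ped_find(env, pr[2L])) return(FALSE)
  }
  # declared-unrelated pairs share no ancestor and neither is an ancestor
  # of the other
  for (pr in env$unrelated) {
    a <- ped_find(env, pr[1L]); b <- ped_find(env, pr[2L])
    anc_a <- c(a, ped_ancestors(env, a)); anc_b <- c(b, ped_ancestors(env, b))
    if (length(intersect(anc_a, anc_b))) return(FALSE)
  }
  TRUE
}

# maternal-line chain of (resolved) individuals starting at id
maternal_chain <- function(env, id) {
  out <- ped_find(env, id)
  repeat {
    m <- ped_get_parent(env, out[length(out)], "mother")
    if (is.na(m) || m %in% out) break
    out <- c(out, m)
  }
  out
}

paternal_chain <- function(env, id) {
  out <- ped_find(env, id)
  repeat {
    f <- ped_get_parent(env, out[length(out)], "father")
    if (is.na(f) || f %in% out) break
    out <- c(out, f)
  }
  out
}

# ---- candidate relationship moves -----------------------------------------
# Each candidate is a list(label, desc, apply(env)). Orientation pairs are
# (a, b); lines are "mother"/"father".

candidates_for_pair <- function(a, b, degree, sexes) {
  role_of <- function(p) switch(sexes[[p]], XX = "mother", XY = "father", NA)
  mk <- function(label, desc, fn) list(label = label, desc = desc, apply = fn)
  out <- list()
  if (degree == "first") {
    for (ori in list(c(a, b), c(b, a))) {
      p <- ori[1L]; ch <- ori[2L]
      roles <- if (is.na(role_of(p))) c("mother", "father") else role_of(p)
      for (rl in roles) {
        out[[length(out) + 1L]] <- mk(
          "parent-offspring",
          sprintf("%s %s of %s", p, if (rl == "mother") "mother" else "father", ch),
          local({p <- p; ch <- ch; rl <- rl
            function(env) ped_set_parent(env, ch, p, rl)}))
      }
    }
    out[[length(out) + 1L]] <- mk(
      "full-sibs", sprintf("%s and %s full sibs", a, b),
      function(env) {
        ped_union(env, ped_ensure_parent(env, a, "mother"),
                  ped_ensure_parent(env, b, "mother"))
        ped_union(env, ped_ensure_parent(env, a, "father"),
                  ped_ensure_parent(env, b, "father"))
      })
  } else if (degree == "second") {
    for (line in c("mother", "father")) {
      other <- setdiff(c("mother", "father"), line)
      out[[length(out) + 1L]] <- mk(
        "half-sibs",
        sprintf("%s and %s %s half sibs", a, b,
                if (line == "mother") "maternal" else "paternal"),
        local({line <- line; other <- other
          function(env) {
            ped_union(env, ped_ensure_parent(env, a, line),
                      ped_ensure_parent(env, b, line))
            env$diseq[[length(env$diseq) + 1L]] <-
              c(ped_ensure_parent(env, a, other),
                ped_ensure_parent(env, b, other))
            invisible(TRUE)
          }}))
    }
    for (ori in list(c(a, b), c(b, a))) {
      gp <- ori[1L]; gc <- ori[2L]
      for (line in c("mother", "father")) {
        roles <- switch(sexes[[gp]], XX = "mother", XY = "father",
                        c("mother", "father"))
        for (rl in roles) {
          out[[length(out) + 1L]] <- mk(
            "grandparent-grandchild",
            sprintf("%s grandparent of %s (via %s's %s)", gp, gc, gc, line),
            local({gp <- gp; gc <- gc; line <- line; rl <- rl
              function(env) {
                p <- ped_ensure_parent(env, gc, line)
                ped_set_parent(env, p, gp, rl)
              }}))
        }
        out[[length(out) + 1L]] <- mk(
          "avuncular",
          sprintf("%s sibling of %s's %s", gp, gc, line),
          local({av <- gp; gc <- gc; line <- line
            function(env) {
              p <- ped_ensure_parent(env, gc, line)
              ped_union(env, ped_ensure_parent(env, av, "mother"),
                        ped_ensure_parent(env, p, "mother"))
              ped_union(env, ped_ensure_parent(env, av, "father"),
                        ped_ensure_parent(env, p, "father"))
            }}))
      }
    }
    for (mode in c("parallel", "cross")) {
      out[[length(out) + 1L]] <- mk(
        "double-first-cousins",
        sprintf("%s and %s double first cousins (%s)", a, b, mode),
        local({mode <- mode
          function(env) {
            ma <- ped_ensure_parent(env, a, "mother")
            fa <- ped_ensure_parent(env, a, "father")
            mb <- ped_ensure_parent(env, b, "mother")
            fb <- ped_ensure_parent(env, b, "father")
            sib <- function(x, y) {
              ped_union(env, ped_ensure_parent(env, x, "mother"),
                        ped_ensure_parent(env, y, "mother"))
              ped_union(env, ped_ensure_parent(env, x, "father"),
                        ped_ensure_parent(env, y, "father"))
            }
            if (mode == "parallel") { sib(ma, mb); sib(fa, fb) }
            else { sib(ma, fb); sib(fa, mb) }
            env$diseq[[length(env$diseq) + 1L]] <- c(ma, mb)
            env$diseq[[length(env$diseq) + 1L]] <- c(fa, fb)
            invisible(TRUE)
          }}))
    }
  } else {  # unrelated
    out[[length(out) + 1L]] <- mk(
      "unrelated", sprintf("%s and %s unrelated", a, b),
      function(env) {
        env$unrelated[[length(env$unrelated) + 1L]] <- c(a, b)
        invisible(TRUE)
      })
  }
  out
}

hg_compatible <- function(h1, h2) {
  if (is.na(h1) || is.na(h2)) return(TRUE)
  startsWith(h1, h2) || startsWith(h2, h1)
}

#' Enumerate trio genealogies consistent with kinship and uniparental data
#'
#' Given pairwise kinship degrees for three individuals, exhaustively
#' assigns catalog relationships (parent-offspring, full sibs for first
#' degree; half sibs, grandparent-grandchild, avuncular, double first
#' cousins for second degree; unrelated) with all orientations and
#' maternal/paternal line choices to the three pairs, constructs each
#' candidate as an explicit pedigree with latent relatives, and retains the
#' models that are (i) structurally consistent, with realized kinship
#' coefficients matching the observed degrees, (ii) sex-consistent (mothers
#' XX, fathers XY), (iii) consistent with mtDNA — any forced shared
#' maternal line requires identical mt haplogroups, (iv) consistent with
#' Y haplogroups along forced shared paternal lines among XY members, where
#' a truncated haplogroup is compatible with any refinement of itself
#' (prefix rule), and (v) consistent with age order — an ancestor's
#' calibrated interval may not lie entirely later than its descendant's.
#'
#' @param ids character vector of three individual ids.
#' @param degrees named character vector of pairwise degrees, names
#'   `"id1-id2"` style for the three pairs (order-free); values `"first"`,
#'   `"second"` or `"unrelated"`.
#' @param sexes named vector (`"XX"`, `"XY"`, `"UNKNOWN"`).
#' @param mt_hg,y_hg named vectors of haplogroup labels (`NA` = no data).
#' @param age_ranges optional named list of `c(min_bp, max_bp)` calibrated
#'   intervals.
#' @param assume_uniparental when `TRUE`, a shared uniparental haplogroup is
#'   taken to indicate direct matri-/patrilineality: a related pair with
#'   identical mt haplogroups must be connected through a purely maternal
#'   line (and an XY pair with compatible Y haplogroups through a paternal
#'   line), discarding, e.g., paternal half-sib models for mt-identical
#'   individuals.
#' @return A list of surviving models, each with `relationships` (a
#'   `data.frame` of pair, label, description) and `phi` (realized kinship
#'   coefficients per pair).
#' @export
enumerate_trio_genealogies <- function(ids, degrees, sexes, mt_hg = NULL,
                                       y_hg = NULL, age_ranges = NULL,
                                       assume_uniparental = FALSE) {
  stopifnot(length(ids) == 3L)
  prs <- list(c(ids[1L], ids[2L]), c(ids[1L], ids[3L]), c(ids[2L], ids[3L]))
  deg_of <- function(pr) {
    k1 <- paste(pr, collapse = "-"); k2 <- paste(rev(pr), collapse = "-")
    k <- c(k1, k2)[c(k1, k2) %in% names(degrees)]
    if (!length(k)) stop("missing degree for pair ", k1)
    match.arg(degrees[[k[1L]]], c("first", "second", "unrelated"))
  }
  if (is.null(mt_hg)) mt_hg <- stats::setNames(rep(NA_character_, 3L), ids)
  if (is.null(y_hg)) y_hg <- stats::setNames(rep(NA_character_, 3L), ids)
  cand <- lapply(prs, function(pr)
    candidates_for_pair(pr[1L], pr[2L], deg_of(pr), sexes))
  models <- list()
  seen <- character(0)
  for (c1 in cand[[1L]]) for (c2 in cand[[2L]]) for (c3 in cand[[3L]]) {
    env <- ped_new(ids, sexes[ids])
    c1$apply(env); if (env$failed) next
    c2$apply(env); if (env$failed) next
    c3$apply(env); if (env$failed) next
    if (!ped_ok(env)) next
    # realized kinship must match the observed degree for every pair
    phi <- vapply(prs, function(pr) ped_phi(env, pr[1L], pr[2L]), 0)
    want <- vapply(prs, function(pr) DEGREE_PHI[[deg_of(pr)]], 0)
    if (any(abs(phi - want) > 1e-9)) next
    # uniparental consistency over forced shared lines
    bad <- FALSE
    for (pr in prs) {
      mc1 <- maternal_chain(env, pr[1L]); mc2 <- maternal_chain(env, pr[2L])
      if (length(intersect(mc1, mc2)) &&
          !is.na(mt_hg[[pr[1L]]]) && !is.na(mt_hg[[pr[2L]]]) &&
          mt_hg[[pr[1L]]] != mt_hg[[pr[2L]]]) { bad <- TRUE; break }
      if (all(sexes[pr] == "XY")) {
        pc1 <- paternal_chain(env, pr[1L]); pc2 <- paternal_chain(env, pr[2L])
        if (length(intersect(pc1, pc2)) &&
            !hg_compatible(y_hg[[pr[1L]]], y_hg[[pr[2L]]])) { bad <- TRUE; break }
      }
      if (assume_uniparental && deg_of(pr) != "unrelated") {
        if (!is.na(mt_hg[[pr[1L]]]) && !is.na(mt_hg[[pr[2L]]]) &&
            mt_hg[[pr[1L]]] == mt_hg[[pr[2L]]] &&
            !length(intersect(mc1, mc2))) { bad <- TRUE; break }
        if (all(sexes[pr] == "XY") &&
            !is.na(y_hg[[pr[1L]]]) && !is.na(y_hg[[pr[2L]]]) &&
            hg_compatible(y_hg[[pr[1L]]], y_hg[[pr[2L]]])) {
          pc1 <- paternal_chain(env, pr[1L])
          pc2 <- paternal_chain(env, pr[2L])
          if (!length(intersect(pc1, pc2))) { bad <- TRUE; break }
        }
      }
    }
    if (bad) next
    # age order along focal ancestor links
    if (!is.null(age_ranges)) {
      for (x in ids) for (y in ids) {
        if (x == y) next
        if (ped_find(env, x) %in% ped_ancestors(env, y) &&
            !is.null(age_ranges[[x]]) && !is.null(age_ranges[[y]])) {
          if (max(age_ranges[[x]]) < min(age_ranges[[y]])) { bad <- TRUE }
        }
      }
    }
    if (bad) next
    key <- paste(c1$desc, c2$desc, c3$desc, sep = " | ")
    if (key %in% seen) next
    seen <- c(seen, key)
    models[[length(models) + 1L]] <- list(
      relationships = data.frame(
        pair = vapply(prs, paste, "", collapse = "-"),
        label = c(c1$label, c2$label, c3$label),
        description = c(c1$desc, c2$desc, c3$desc),
        stringsAsFactors = FALSE),
      phi = stats::setNames(phi, vapply(prs, paste, "", collapse = "-"))
    )
  }
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a
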