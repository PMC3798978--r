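#' Dock a protein onto a DNA site by reference pose
#'
#' Superposes the protein's interface landmarks onto target positions defined
#' by a reference pose: a mapping from landmark labels to (base-pair offset,
#' offset vector in that base-pair frame), evaluated on the actual site
#' frames of the duplex.
#'
#' @param protein an [atom_set()] carrying the pose's landmarks.
#' @param dna a `duplex_model`.
#' @param site 1-based inclusive bp interval `c(start, end)` on the duplex.
#' @param reference_pose named list of `list(bp = , off = )` entries as in
#'   the packaged Fis pose; `bp` is relative to the site center.
#' @return the docked (transformed) protein with `$dock` holding the
#'   transform and rmsd.
#' @export
dock_on_site <- function(protein, dna, site, reference_pose) {
  stopifnot(inherits(protein, "atom_set"), inherits(dna, "duplex_model"))
  n <- length(dna$frames)
  site <- as.integer(site)
  if (length(site) != 2L || site[1] < 1L || site[2] > n || site[1] >= site[2]) {
    stop("site interval out of range for this duplex")
  }
  center <- (site[1] + site[2]) %/% 2L
  usable <- names(reference_pose)[vapply(reference_pose, function(p) {
    center + p$bp >= 1L && center + p$bp <= n
  }, logical(1))]
  usable <- intersect(usable, names(protein$landmarks))
  if (length(usable) < 3L) stop("need at least 3 landmark/frame correspondences")
  targets <- .pose_targets(dna, center, reference_pose[usable])
  moving <- t(vapply(usable, function(l) landmark_xyz(protein, l), numeric(3)))
  fit <- superpose(moving, targets)
  out <- apply_transform(protein, fit$transform)
  out$dock <- fit
  out
}

#' Assembly configuration
#'
#' Bundles the components of one invertasome: the Fis-bound enhancer model,
#' two hix duplexes, two Fis dimers and four Hin subunits, the landmark
#' contact cutoff, and the substrate loop spacings.
#'
#' @param components output of [make_toy_components()].
#' @param substrate a [substrate_geometry()] carrying the DNA-path topology
#'   of the assembly.
#' @param contact_cutoff landmark contact cutoff (Angstrom).
#' @return an `assembly_config`.
#' @export
assembly_config <- function(components, substrate = NULL, contact_cutoff = 6) {
  need <- c("fis", "hin", "enhancer", "hix", "layout", "pose", "frame")
  if (!all(need %in% names(components))) stop("incomplete component set")
  if (is.null(substrate)) substrate <- make_substrate_geometry(components$spec)
  structure(list(components = components, substrate = substrate,
                 contact_cutoff = contact_cutoff,
                 half_sites = c("hix1L", "hix1R", "hix2L", "hix2R")),
            class = "assembly_config")
}

.transform_duplex <- function(model, tr) {
  model$frames <- lapply(model$frames, function(f) {
    list(origin = as.numeric(tr$rotation %*% f$origin) + tr$translation,
         axes = tr$rotation %*% f$axes)
  })
  model$backbone <- lapply(model$backbone, function(b) {
    t(tr$rotation %*% t(b) + tr$translation)
  })
  model
}

# rotation mapping unit vector a onto unit vector b
.rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  k <- .cross3(a, b); s <- sqrt(sum(k^2)); c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- .cross3(a, p); k <- k / sqrt(sum(k^2))
    return(2 * outer(k, k) - diag(3))
  }
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

#' Assemble an invertasome state
#'
#' Places both Fis dimers on their enhancer sites by reference-pose docking,
#' places the four Hin subunits on the tetramer frame derived from the docked
#' Fis arms (with the two enhancer-proximal subunits on half-sites hix1L and
#' hix2R), threads the two hix duplexes through the corresponding DNA-binding
#' domains, and verifies the assembly contract: Fis-arm/DBD proximity for the
#' hix1L/hix2R pair only, helix-B enhancer contact in the cleaved state, no
#' steric overlap, and two negative hix-over-enhancer nodes on the attached
#' substrate path.
#'
#' @param cfg an [assembly_config()].
#' @param state assembly state (must match the component set's state).
#' @param verify run the contract checks (disable only for perturbation
#'   experiments).
#' @return an `assembly`.
#' @export
assemble_invertasome <- function(cfg, state = cfg$components$state,
                                 verify = TRUE) {
  stopifnot(inherits(cfg, "assembly_config"))
  comp <- cfg$components
  if (!identical(state, comp$state)) {
    stop("component set was generated for state '", comp$state, "'")
  }
  layout <- comp$layout
  enh <- comp$enhancer
  half <- (layout$core_bp - 1L) %/% 2L
  site1 <- c(layout$site1_center - half, layout$site1_center + half)
  site2 <- c(layout$site2_center - half, layout$site2_center + half)
  fis1 <- dock_on_site(comp$fis, enh, site1, comp$pose)
  fis2 <- dock_on_site(comp$fis, enh, site2, comp$pose)

  fr <- comp$frame
  hin <- list()
  for (hs in cfg$half_sites) {
    fit <- superpose(comp$hin$xyz, fr$targets[[hs]])
    hin[[hs]] <- apply_transform(comp$hin, fit$transform)
  }

  dbd_centroid <- function(sub) {
    labs <- c("146", "147", "150", "151", "154", "155", "158", "160")
    colMeans(t(vapply(labs, function(l) landmark_xyz(sub, l), numeric(3))))
  }
  place_hix <- function(subA, subB) {
    a <- dbd_centroid(subA); b <- dbd_centroid(subB)
    d <- (b - a) / sqrt(sum((b - a)^2))
    mid <- (a + b) / 2
    out_dir <- mid - fr$center
    out_dir <- out_dir - sum(out_dir * d) * d
    out_dir <- out_dir / sqrt(sum(out_dir^2))
    ctr <- mid + 6 * out_dir
    R <- .rot_between(c(0, 0, 1), d)
    start <- ctr - d * (25 * 3.4 / 2)
    .transform_duplex(comp$hix, rigid_transform(R, start))
  }
  hix1 <- place_hix(hin$hix1L, hin$hix1R)
  hix2 <- place_hix(hin$hix2L, hin$hix2R)

  a <- structure(list(state = state, fis1 = fis1, fis2 = fis2, hin = hin,
                      hix1 = hix1, hix2 = hix2, enhancer = enh,
                      layout = layout, substrate = cfg$substrate,
                      contact_cutoff = cfg$contact_cutoff,
                      frame = fr),
                 class = "assembly")
  if (verify) {
    viol <- check_assembly(a)
    if (length(viol)) {
      stop("assembly constraints violated:\n  ", paste(viol, collapse = "\n  "))
    }
  }
  a
}

#' @export
print.assembly <- function(x, ...) {
  cat("invertasome assembly (", x$state, "): 2 Fis dimers, 4 Hin subunits, ",
      nchar(x$enhancer$sequence), "-bp enhancer\n", sep = "")
  invisible(x)
}

#' All landmark coordinates of an assembly
#'
#' Landmarks are addressed as `"Fis1:A:21"`, `"Fis2:B:98"`,
#' `"Hin:hix1L:155"`, and so on.
#'
#' @param a an `assembly`.
#' @return named list of 3-vectors.
#' @export
assembly_landmarks <- function(a) {
  out <- list()
  grab <- function(set, prefix) {
    for (l in names(set$landmarks)) out[[paste0(prefix, ":", l)]] <<- landmark_xyz(set, l)
  }
  grab(a$fis1, "Fis1"); grab(a$fis2, "Fis2")
  for (hs in names(a$hin)) {
    s <- a$hin[[hs]]
    for (l in names(s$landmarks)) {
      out[[paste0("Hin:", hs, ":", sub("^.*:", "", l))]] <- landmark_xyz(s, l)
    }
  }
  out
}

# minimum distance between two point clouds
.min_dist <- function(p, q) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
  sqrt(max(0, min(d2)))
}

#' Verify the assembly contract
#'
#' @param a an `assembly`.
#' @return character vector of violated constraints (empty when valid).
#' @export
check_assembly <- function(a) {
  viol <- character(0)
  cutoff <- a$contact_cutoff
  lm <- assembly_landmarks(a)
  prox <- function(arm, hs) {
    min(vapply(c("151", "154", "155"), function(r) {
      sqrt(sum((lm[[arm]] - lm[[paste0("Hin:", hs, ":", r)]])^2))
    }, numeric(1)))
  }
  arm1 <- "Fis1:B:21"; arm2 <- "Fis2:A:21"
  if (prox(arm1, "hix1L") > cutoff) viol <- c(viol, "Fis1 arm not in contact with hix1L DBD")
  if (prox(arm2, "hix2R") > cutoff) viol <- c(viol, "Fis2 arm not in contact with hix2R DBD")
  if (prox(arm1, "hix1R") <= cutoff || prox(arm2, "hix2L") <= cutoff) {
    viol <- c(viol, "rotating-pair DBD within Fis-arm cutoff")
  }
  # Fis dimers seated on their sites
  prox_bp <- rbind(a$enhancer$backbone$top, a$enhancer$backbone$bottom)
  for (f in c("Fis1", "Fis2")) {
    d98 <- min(vapply(c(":A:98", ":B:98"), function(s) {
      .min_dist(matrix(lm[[paste0(f, s)]], 1), prox_bp)
    }, numeric(1)))
    if (d98 > cutoff) viol <- c(viol, paste(f, "not seated on its binding site"))
  }
  if (a$state == "cleaved") {
    hb <- t(vapply(paste0("Hin:hix1L:", c(47, 48, 51)), function(l) lm[[l]], numeric(3)))
    if (.min_dist(hb, prox_bp) > cutoff) {
      viol <- c(viol, "helix-B not contacting enhancer backbone in cleaved state")
    }
  }
  clouds <- c(list(fis1 = a$fis1$xyz, fis2 = a$fis2$xyz),
              lapply(a$hin, `[[`, "xyz"))
  nm <- names(clouds)
  for (i in seq_along(clouds)) {
    for (j in seq_along(clouds)) {
      if (i < j && .min_dist(clouds[[i]], clouds[[j]]) <= 0.5) {
        viol <- c(viol, paste("steric overlap:", nm[i], "vs", nm[j]))
      }
    }
  }
  nodes <- count_nodes(a$substrate$curve, c("hix1", "hix2"), "enhancer")
  if (nrow(nodes) != 2L || any(nodes$sign != -1)) {
    viol <- c(viol, "substrate path does not form 2 negative hix/enhancer nodes")
  }
  viol
}

#' Refine an assembly against distance constraints
#'
#' Seeded random-restart hill climbing over rigid-body perturbations of the
#' protein components, minimising the total positive violation of a
#' crosslink constraint set.  The returned score never exceeds the input
#' score, and identical seeds give identical trajectories.
#'
#' @param a an `assembly`.
#' @param constraints a crosslink constraint table (see
#'   [crosslink_constraints()]).
#' @param max_iter iteration budget.
#' @param step_trans,step_rot perturbation scales (Angstrom / radians).
#' @param seed RNG seed.
#' @param tolerance crosslink distance tolerance.
#' @return list with the refined `assembly` and final `score`.
#' @export
refine_by_constraints <- function(a, constraints, max_iter = 200,
                                  step_trans = 0.5, step_rot = 0.02,
                                  seed = 1L, tolerance = 3) {
  score_of <- function(x) crosslink_score(x, constraints, tolerance)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  movable <- c("fis1", "fis2", names(a$hin))
  best <- a
  best_score <- score_of(a)
  if (best_score == 0) return(list(assembly = a, score = 0))
  for (it in seq_len(max_iter)) {
    who <- sample(movable, 1L)
    ang <- stats::rnorm(2, 0, step_rot)
    R <- .rot_z(ang[1]) %*% .rot_y(ang[2])
    tr <- rigid_transform(R, stats::rnorm(3, 0, step_trans))
    cand <- best
    if (who %in% c("fis1", "fis2")) {
      ctr <- colMeans(cand[[who]]$xyz)
      cand[[who]] <- apply_transform(cand[[who]],
        compose_transform(rigid_transform(diag(3), ctr),
                          compose_transform(tr, rigid_transform(diag(3), -ctr))))
    } else {
      ctr <- colMeans(cand$hin[[who]]$xyz)
      cand$hin[[who]] <- apply_transform(cand$hin[[who]],
        compose_transform(rigid_transform(diag(3), ctr),
                          compose_transform(tr, rigid_transform(diag(3), -ctr))))
    }
    sc <- score_of(cand)
    if (sc < best_score) {
      best <- cand
      best_score <- sc
      if (best_score == 0) break
    }
  }
  list(assembly = best, score = best_score)
}
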