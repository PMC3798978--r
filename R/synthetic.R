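#' Fixture specification for the synthetic data generators
#'
#' Collects every knob of the packaged synthetic system: the Fis-induced bend
#' per site, the enhancer layout, substrate spacings, and the scale of the
#' coarse-grained protein domains.  Identical specs produce byte-identical
#' fixtures; the generators are pure functions of the spec.
#'
#' @param seed integer seed recorded with the fixture (the generators are
#'   deterministic; the seed is consumed only by stochastic refinement).
#' @param fis_bend bend angle per Fis site in degrees (the crystal-derived
#'   bend is not tabulated in print; 65 degrees is the packaged default and
#'   is treated as configuration, not as a literature value).
#' @param layout an [enhancer_layout()].
#' @param loop99_bp,invertible_bp,plasmid_bp substrate spacings in bp.
#' @param domain_scale overall scale factor of the toy protein domains.
#' @param contact_cutoff landmark contact cutoff in Angstrom.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, fis_bend = 65, layout = enhancer_layout(),
                         loop99_bp = 99, invertible_bp = 1000,
                         plasmid_bp = 3000, domain_scale = 1,
                         contact_cutoff = 6) {
  if (fis_bend >= 180) stop("per-site bend must be below 180 degrees")
  if (fis_bend < 0) stop("bend must be non-negative")
  if (domain_scale <= 0 || contact_cutoff <= 0) {
    stop("geometric parameters must be positive")
  }
  structure(list(seed = as.integer(seed), fis_bend = fis_bend, layout = layout,
                 loop99_bp = loop99_bp, invertible_bp = invertible_bp,
                 plasmid_bp = plasmid_bp, domain_scale = domain_scale,
                 contact_cutoff = contact_cutoff),
            class = "fixture_spec")
}

#' Step parameters of a Fis-bent binding site
#'
#' Generates the 20 dinucleotide steps of a 21-bp Fis site whose built duplex
#' deflects the helix axis by `fis_bend` degrees, with the bend distributed
#' as roll/tilt components that stay in one bending plane as the helix
#' twists.  The amplitude is calibrated numerically against the measured
#' entry/exit tangent deflection of the built duplex.
#'
#' @param spec a [fixture_spec()] (only `fis_bend` and the layout's block
#'   width are used).
#' @return a [step_params()] table with `site_block_bp - 1` rows.
#' @export
make_fis_site_params <- function(spec = fixture_spec()) {
  n_steps <- spec$layout$site_block_bp - 1L
  bend <- spec$fis_bend
  if (bend == 0) {
    out <- step_params()[rep(1L, n_steps), ]
    rownames(out) <- NULL
    return(out)
  }
  block_for <- function(B) {
    tw <- 34.2 * pi / 180
    ph <- (seq_len(n_steps) - 0.5) * tw      # helical phase at each mid-step
    step_params(shift = 0, slide = 0, rise = 3.4,
                tilt = -B * sin(ph), roll = B * cos(ph), twist = 34.2)
  }
  deflection <- function(B) {
    m <- build_duplex(strrep("N", n_steps + 1L), block_for(B))
    ax <- axis_curve(m)
    t_in <- ax[2, ] - ax[1, ]
    t_out <- ax[nrow(ax), ] - ax[nrow(ax) - 1L, ]
    acos(max(-1, min(1, sum(t_in * t_out) /
                       sqrt(sum(t_in^2) * sum(t_out^2))))) * 180 / pi
  }
  f <- function(B) deflection(B) - bend
  B <- stats::uniroot(f, c(1e-4, 85), tol = 1e-6)$root
  block_for(B)
}

# reference pose of a Fis dimer on its 15-bp core site: landmark ->
# (bp offset from the site center, offset vector in that bp frame).
# Arm tips protrude along +x (major-groove face), which after docking points
# toward the synapse.
.fis_reference_pose <- function(scale = 1) {
  o <- function(bp, x, y, z) list(bp = bp, off = scale * c(x, y, z))
  list(
    "A:98" = o(-4L, 3.0, 13.0, 0), "B:98" = o(4L, 3.0, -13.0, 0),
    "A:71" = o(-2L, 13, 6, 0),     "B:71" = o(2L, 13, -6, 0),
    "A:16" = o(-6L, 24, 4, 1),     "B:16" = o(6L, 24, -4, -1),
    "A:19" = o(-6L, 26, 2.5, 0),   "B:19" = o(6L, 26, -2.5, 0),
    "A:20" = o(-6L, 27, 1.5, 1),   "B:20" = o(6L, 27, -1.5, -1),
    "A:21" = o(-6L, 28, 0, 0),     "B:21" = o(6L, 28, 0, 0),
    "A:22" = o(-6L, 26.5, -1.5, 1), "B:22" = o(6L, 26.5, 1.5, -1)
  )
}

# target coordinates of a reference pose on a built duplex site
.pose_targets <- function(model, center_bp, pose) {
  t(vapply(pose, function(p) {
    f <- model$frames[[center_bp + p$bp]]
    f$origin + as.numeric(f$axes %*% p$off)
  }, numeric(3)))
}

#' Toy protein components with landmark residues
#'
#' Generates coarse-grained (one point per represented residue) models of the
#' two Fis dimers and the four Hin subunits of a given assembly state.  The
#' internal geometry is constructed to be consistent with the reference poses
#' used by [dock_on_site()] and [assemble_invertasome()], so that the default
#' fixtures satisfy the assembly contracts of the docking module.
#'
#' @param spec a [fixture_spec()].
#' @param state one of `"dimer_docked"`, `"pre_cleaved"`, `"cleaved"`.
#' @return list with `fis` (an [atom_set()] dimer template), `hin` (an
#'   [atom_set()] subunit template for the state), the `enhancer`
#'   `duplex_model`, two straight `hix` duplex templates, and the reference
#'   pose / assembly frame data used by the docking module.
#' @export
make_toy_components <- function(spec = fixture_spec(),
                                state = c("cleaved", "pre_cleaved", "dimer_docked")) {
  state <- match.arg(state)
  layout <- spec$layout
  steps <- compose_enhancer_params(make_fis_site_params(spec), step_params(),
                                   layout)
  enh <- build_duplex(strrep("N", layout$total_bp), steps)
  pose <- .fis_reference_pose(spec$domain_scale)

  # Fis dimer template: pose applied to site 1 of the built enhancer, so
  # docking back onto either (congruent) site is exact
  fis_xyz <- .pose_targets(enh, layout$site1_center, pose)
  fis_xyz <- sweep(fis_xyz, 2, colMeans(fis_xyz))
  labs <- names(pose)
  fis <- atom_set(chain = sub(":.*", "", labs),
                  resno = as.integer(sub(".*:", "", labs)),
                  resname = "GLY", atom = "CA", xyz = fis_xyz,
                  landmarks = stats::setNames(seq_along(labs), labs))

  frame <- .assembly_frame(enh, layout, pose, spec, state)
  hin_xyz <- frame$subunit_local
  hlabs <- rownames(hin_xyz)
  hin <- atom_set(chain = "H", resno = as.integer(hlabs), resname = "GLY",
                  atom = "CA", xyz = hin_xyz,
                  landmarks = stats::setNames(seq_along(hlabs), hlabs))

  hix <- build_duplex(strrep("N", 26L), step_params()[rep(1L, 25L), ])
  list(fis = fis, hin = hin, enhancer = enh, hix = hix, layout = layout,
       pose = pose, frame = frame, state = state, spec = spec)
}

# Assembly frame: docks the Fis dimers, derives the tetramer frame from the
# docked arms, and lays out per-subunit target coordinates.  The two
# enhancer-proximal subunits (half-sites hix1L, hix2R) are each anchored to
# their own Fis arm and their own stretch of enhancer backbone; the distal
# (rotating-pair) subunits are related by the tetramer two-folds.
.assembly_frame <- function(enh, layout, pose, spec, state) {
  ax <- axis_curve(enh)
  targets1 <- .pose_targets(enh, layout$site1_center, pose)
  targets2 <- .pose_targets(enh, layout$site2_center, pose)
  P1 <- ax[layout$site1_center, ]; P2 <- ax[layout$site2_center, ]
  dna_mid <- (P1 + P2) / 2
  arm1 <- targets1[which(names(pose) == "B:21"), ]   # arms facing the middle
  arm2 <- targets2[which(names(pose) == "A:21"), ]
  mid <- (arm1 + arm2) / 2
  chat <- (arm2 - arm1) / sqrt(sum((arm2 - arm1)^2))
  v <- mid - dna_mid
  v <- v - sum(v * chat) * chat
  nhat <- v / sqrt(sum(v^2))
  ahat <- .cross3(chat, nhat)
  h_state <- c(cleaved = 12, pre_cleaved = 16, dimer_docked = 22)[[state]]
  Ctr <- mid + h_state * nhat
  helixB_dist <- c(cleaved = 4, pre_cleaved = 9, dimer_docked = 16)[[state]]

  mk_frame <- function(arm, aref) {
    e1 <- Ctr - arm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- aref - sum(aref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    cbind(e1, e2, .cross3(e1, e2))
  }
  B1 <- mk_frame(arm1, ahat); B2 <- mk_frame(arm2, -ahat)
  L <- sqrt(sum((Ctr - arm1)^2))

  # one subunit's targets, anchored at its arm and its own backbone stretch
  subunit_targets <- function(arm, Bf, hb_bps) {
    qs <- t(vapply(hb_bps, function(bp) {
      qt <- enh$backbone$top[bp, ]; qb <- enh$backbone$bottom[bp, ]
      if (sum((qt - Ctr)^2) <= sum((qb - Ctr)^2)) qt else qb
    }, numeric(3)))
    hb <- function(i, d) {
      r <- qs[i, ] - ax[hb_bps[i], ]
      qs[i, ] + d * r / sqrt(sum(r^2))
    }
    loc <- rbind(
      "146" = c(6.2, 1.2, 0), "147" = c(4.5, 2.2, 0), "150" = c(4.5, 0, 2.5),
      "151" = c(6.0, 0, 0), "154" = c(5.5, -1.2, 0), "155" = c(4.5, 0, 0),
      "158" = c(4.5, 2.0, 3.0), "160" = c(4.5, 0, 4.0),
      "28" = c(L - 2, 4, 0), "101" = c(L - 1, 6, 1), "107" = c(L - 3, 5, -2))
    glob <- t(apply(loc, 1L, function(p) arm + as.numeric(Bf %*% p)))
    rbind(glob,
          "47" = hb(1L, helixB_dist), "48" = hb(2L, helixB_dist),
          "51" = hb(3L, helixB_dist + 0.5), "54" = hb(4L, helixB_dist + 4))
  }
  bpB1 <- layout$site1_center + 18:21
  bpB2 <- layout$site2_center - (18:21)
  T1L <- subunit_targets(arm1, B1, bpB1)
  T2R <- subunit_targets(arm2, B2, bpB2)

  # toy subunit shape: average of the two proximal target sets in their
  # arm-local frames (each then docks with sub-Angstrom residual)
  loc1 <- t(t(B1) %*% t(sweep(T1L, 2, arm1)))
  loc2 <- t(t(B2) %*% t(sweep(T2R, 2, arm2)))
  loc_avg <- (loc1 + loc2) / 2
  rownames(loc_avg) <- rownames(T1L)
  ideal_1L <- sweep(t(B1 %*% t(loc_avg)), 2, arm1, "+")
  rownames(ideal_1L) <- rownames(T1L)

  rot_about <- function(axis) {
    function(p) {
      d <- p - Ctr
      Ctr + 2 * sum(d * axis) * axis - d
    }
  }
  T1R <- t(apply(ideal_1L, 1L, rot_about(chat)))
  T2L <- t(apply(ideal_1L, 1L, rot_about(ahat)))
  targets <- list(hix1L = T1L, hix2R = T2R, hix1R = T1R, hix2L = T2L)

  subunit_local <- sweep(loc_avg, 2, colMeans(loc_avg))
  rownames(subunit_local) <- rownames(T1L)
  list(enhancer_axis = ax, mid = mid, chat = chat, nhat = nhat, ahat = ahat,
       center = Ctr, targets = targets, subunit_local = subunit_local,
       arm_sym = arm1, helixB_dist = helixB_dist)
}

#' Branched substrate fixture
#'
#' Convenience wrapper building the [substrate_geometry()] from a fixture
#' spec.  The default arrangement carries the native 99-bp enhancer-to-hix
#' spacing and produces two negative hix-over-enhancer nodes.
#'
#' @param spec a [fixture_spec()].
#' @return a [substrate_geometry()].
#' @export
make_substrate_geometry <- function(spec = fixture_spec()) {
  substrate_geometry(loop99_bp = spec$loop99_bp,
                     invertible_bp = spec$invertible_bp,
                     plasmid_bp = spec$plasmid_bp)
}
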