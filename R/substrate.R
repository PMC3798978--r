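#' @title Branched invertasome substrate geometry and subunit rotation
#' @name substrate
#' @description
#' The substrate model is a closed, labeled 3D polyline representing the DNA
#' axis of a negatively supercoiled inversion plasmid folded into the
#' invertasome branch: the enhancer segment at the base of the branch, the two
#' hix duplexes paired side-by-side at the synapse (cleavage points facing),
#' the short enhancer-to-hix loops, and the remaining vector DNA as an
#' explicitly interwound plectoneme.  The two hix segments cross the enhancer
#' with two negative nodes, the signature of a branch on (-) supercoiled DNA.
#'
#' Strand exchange is modeled as the subunit-rotation mechanism: both hix
#' sites are cleaved at their centers and the upper half-site pair is rotated
#' in steps of 180 degrees about the synapse axis.  A product after n
#' half-turns is built directly in its relaxed form: the two synapse-proximal
#' strands carry an interwound collar of n half-turns, and for odd n the
#' connectivity is resealed in the recombinant (inverted) orientation.
NULL

.ivs_path <- function(wps, step = 3) {
  out <- NULL
  for (k in seq_len(nrow(wps) - 1L)) {
    a <- wps[k, ]; b <- wps[k + 1L, ]
    L <- sqrt(sum((b - a)^2)); n <- max(1L, ceiling(L / step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                            a[3] + t * (b[3] - a[3])))
  }
  out
}

.ivs_xh1 <- function(y) -4 + 0.15 * y
.ivs_xh2 <- function(y) 4 + 0.15 * y

# synapse collar thread: from a cut point (phase phi0 at y = 0) winding
# sense*n half-turns about the synapse axis over y in [0, 11]
.ivs_thread <- function(phi0, n, sense, npts = NULL) {
  if (is.null(npts)) npts <- max(30L, 40L * max(1L, n))
  y <- seq(0, 11, length.out = npts)
  r <- 4 - 0.115 * y
  phi <- phi0 + sense * n * pi * (y / 11)
  cbind(r * cos(phi), y, r * sin(phi))
}

# Build the full invertasome curve for n half-turns of subunit rotation.
# n = 0 is the substrate.  Geometry is in model units (roughly AA / 5).
.build_invertasome_curve <- function(n = 0L, sense = -1L, p_plect = 4L,
                                     step = 2.5) {
  ys <- function(a, b, st = step) {
    k <- max(2L, ceiling(abs(b - a) / st)); seq(a, b, length.out = k)
  }
  rev_m <- function(m) m[nrow(m):1L, , drop = FALSE]

  A1 <- c(.ivs_xh1(13), 13, 1.3)    # upper attachment points of the half-sites
  A2 <- c(.ivs_xh2(13), 13, -1.3)

  y1 <- ys(-44, 0, 2);  h1s <- cbind(.ivs_xh1(y1), y1, 0.1 * y1)
  y2 <- ys(0, -44, 2);  h2s <- cbind(.ivs_xh2(y2), y2, -0.1 * y2)
  y3 <- ys(13, 44, 2);  h1u <- cbind(.ivs_xh1(y3), y3, 0.1 * y3)
  y4 <- ys(44, 13, 2);  h2u <- cbind(.ivs_xh2(y4), y4, -0.1 * y4)

  # apex of the vector loop, carrying the plectonemic superhelix
  lv1 <- .ivs_path(rbind(c(2.6, 44, 4.4), c(2, 49, 4), c(3, 54, 3)), step)
  tt <- seq(0, 1, length.out = 24L * p_plect)
  base <- (p_plect - 1) * pi * tt
  yy <- 58 + 36 * tt
  ps <- -1                                   # left-handed interwinding: (-) nodes
  sA <- cbind(3.5 + 2.5 * cos(ps * base), yy, 1.5 + 2.5 * sin(ps * base))
  aa <- pi * seq(0, 1, length.out = 9L)[2:8]
  sT <- cbind(3.5 + 2.5 * cos(ps * ((p_plect - 1) * pi + aa)), 94 + 3 * sin(aa),
              1.5 + 2.5 * sin(ps * ((p_plect - 1) * pi + aa)))
  sB <- cbind(3.5 + 2.5 * cos(ps * (rev(base) + pi)), rev(yy),
              1.5 + 2.5 * sin(ps * (rev(base) + pi)))
  plec <- rbind(c(3.2, 56, 2.2), sA, sT, sB)
  lv3 <- .ivs_path(rbind(c(5.5, 54, 0.5), c(9, 49, -1), c(11.5, 45.5, -3),
                         c(10.6, 44, -4.4)), step)

  loop_h2 <- .ivs_path(rbind(c(-2.6, -44, 4.4), c(-20, -48, 0), c(-24, -20, -6),
                             c(-24, 30, -10), c(-16, 36, -14)), step)
  # enhancer: crosses under hix1 (hix over, negative node), then over the
  # hix2 upper arm (enhancer over, negative node) - the alternation of a
  # plectonemic branch, which topologically traps the synapse
  enh <- .ivs_path(rbind(c(-16, 36, -14), c(4, 36, -14), c(6, 37, 2),
                         c(8, 37.6, 2), c(11.5, 40, 0), c(15, 42, -6)), 1.6)
  loop99 <- .ivs_path(rbind(c(15, 42, -6), c(14, 55, -5), c(10, 58, -5),
                            c(8, 100, -4), c(-20, 100, -4), c(-26, 20, -5),
                            c(-26, -20, -5), c(-14, -40, -4.5),
                            c(-10.6, -44, -4.4)), step)

  thrB <- .ivs_thread(pi, n, sense)
  thrA <- .ivs_thread(0, n, sense)
  odd <- n %% 2L == 1L
  mk_blend <- function(from, to_A2) {
    .ivs_path(rbind(from, if (to_A2) A2 else A1), 1)[-1L, , drop = FALSE]
  }
  blB <- mk_blend(thrB[nrow(thrB), ], to_A2 = odd)
  blA <- mk_blend(thrA[nrow(thrA), ], to_A2 = !odd)

  pc <- list(); lb <- character(0)
  put <- function(m, lab) {
    pc[[length(pc) + 1L]] <<- m
    lb <<- c(lb, rep(lab, nrow(m)))
  }
  put(h1s, "hix1")
  if (!odd) {
    put(rbind(thrB, blB), "hix1"); put(h1u, "hix1")
    put(lv1, "loopV"); put(plec, "plectoneme"); put(lv3, "loopV")
    put(h2u, "hix2"); put(rev_m(rbind(thrA, blA)), "hix2")
  } else {
    put(rbind(thrB, blB), "hix1")
    put(rev_m(h2u), "hix2")
    put(rev_m(lv3), "loopV"); put(rev_m(plec), "plectoneme"); put(rev_m(lv1), "loopV")
    put(rev_m(h1u), "hix1")
    put(rev_m(rbind(thrA, blA)), "hix2")
  }
  put(h2s, "hix2")
  put(loop_h2, "loopI")
  put(enh, "enhancer")
  put(loop99, "loop99")

  pts <- do.call(rbind, pc)
  keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-12)
  pts <- pts[keep, , drop = FALSE]; lb <- lb[keep]
  # refine near the synapse so crossings and integrals are well resolved
  .refine_curve(closed_curve(pts, labels = lb),
                rad = 18, maxlen = min(0.6, 1.6 / max(1L, n)))
}

.refine_curve <- function(cv, rad = 18, maxlen = 0.6) {
  pts <- cv$points; n <- nrow(pts); nxt <- c(2:n, 1L)
  out_p <- vector("list", n); out_l <- vector("list", n)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[nxt[i], ]
    d <- min(sqrt(sum(a^2)), sqrt(sum(b^2)))
    L <- sqrt(sum((b - a)^2))
    k <- if (d < rad && L > maxlen) ceiling(L / maxlen) else 1L
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out_p[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                        a[3] + t * (b[3] - a[3]))
    out_l[[i]] <- rep(cv$labels[i], k)
  }
  closed_curve(do.call(rbind, out_p), labels = unlist(out_l))
}

#' Construct a branched invertasome substrate
#'
#' Builds the labeled closed curve of the assembled invertasome substrate
#' together with its base-pair accounting.  The hix cleavage points sit at the
#' synapse (model coordinates (-4, 0, 0) and (4, 0, 0)); the rotor side is the
#' upper half-site pair.
#'
#' @param loop99_bp spacing in bp between the enhancer and the nearest hix
#'   site (99 for the native arrangement; 696 for the long-spacer substrate).
#' @param invertible_bp length of the invertible segment between the hix
#'   cleavage points (about 1 kb in the native system).
#' @param plasmid_bp total plasmid size.
#' @param plectoneme_turns number of interwound superhelical turns drawn
#'   explicitly in the vector domain.
#' @param rotation_sense +1 or -1; the packaged default (-1) is the rotation
#'   sense driven by negative supercoiling, which releases supercoils on the
#'   first exchange.
#' @return a `substrate_geometry` object.
#' @export
substrate_geometry <- function(loop99_bp = 99, invertible_bp = 1000,
                               plasmid_bp = 3000, plectoneme_turns = 4,
                               rotation_sense = -1) {
  if (loop99_bp <= 0 || invertible_bp <= 0 || plasmid_bp <= 0) {
    stop("loop lengths and plasmid size must be positive")
  }
  hix_bp <- 26
  enh_bp <- 65
  loopI_bp <- invertible_bp - loop99_bp - enh_bp - hix_bp
  loopV_bp <- plasmid_bp - invertible_bp - 2 * hix_bp + hix_bp
  if (loopI_bp <= 0) stop("invertible segment too short for enhancer plus spacer")
  if (loopV_bp <= 0) stop("loop lengths exceed plasmid size")
  if (!rotation_sense %in% c(-1, 1)) stop("rotation_sense must be +1 or -1")
  curve <- .build_invertasome_curve(0L, sense = as.integer(rotation_sense),
                                    p_plect = as.integer(plectoneme_turns))
  structure(list(
    curve = curve,
    segments_bp = c(hix1 = hix_bp, loop99 = loop99_bp, enhancer = enh_bp,
                    loopI = loopI_bp, hix2 = hix_bp, loopV = loopV_bp),
    plasmid_bp = plasmid_bp,
    cut_points = rbind(hix1 = c(-4, 0, 0), hix2 = c(4, 0, 0)),
    plectoneme_turns = as.integer(plectoneme_turns),
    rotation_sense = as.integer(rotation_sense),
    branch_node_target = -2L
  ), class = "substrate_geometry")
}

#' @export
print.substrate_geometry <- function(x, ...) {
  cat("invertasome substrate:", x$plasmid_bp, "bp plasmid;",
      x$segments_bp[["loop99"]], "bp enhancer-hix spacer;",
      nrow(x$curve$points), "curve vertices\n")
  invisible(x)
}

#' Simulate processive subunit rotation
#'
#' Cleaves both hix sites at their centers and applies `n` successive 180
#' degree rotations of the upper half-site pair about the synapse axis,
#' resealing the DNA after the last half-turn.  The relaxed product curve
#' carries the accumulated interwinding as an explicit collar; odd `n` reseals
#' in the recombinant (inverted) orientation, even `n` in the parental one.
#'
#' @param s a [substrate_geometry()].
#' @param n number of 180-degree rotation steps (non-negative integer).
#' @return a `rotation_product` with the product curve, `n_half_turns`, and
#'   `orientation` (`"parental"` or `"inverted"`).
#' @export
simulate_rotation <- function(s, n) {
  stopifnot(inherits(s, "substrate_geometry"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  curve <- .build_invertasome_curve(n, sense = s$rotation_sense,
                                    p_plect = s$plectoneme_turns)
  gaps <- sqrt(rowSums((curve$points -
                          curve$points[c(2:nrow(curve$points), 1L), ])^2))
  if (max(gaps) > 8) stop("product curve failed to reseal (resolution error)")
  structure(list(
    curve = curve,
    n_half_turns = n,
    orientation = if (n %% 2L == 1L) "inverted" else "parental",
    substrate = s
  ), class = "rotation_product")
}

#' @export
print.rotation_product <- function(x, ...) {
  cat("rotation product: n =", x$n_half_turns, "half-turns;",
      x$orientation, "orientation\n")
  invisible(x)
}

#' Linking-number change of a recombination product
#'
#' Computes the change in duplex linking number between a substrate and a
#' rotation product as the change in the self-linking number of the modeled
#' axis (writhe plus parallel-transport closure twist; see [self_linking()]).
#' Under the rigid-axis approximation the duplex twist is unchanged, so this
#' integer equals the topological Delta-Lk recorded by the reaction.  The
#' sign convention is positive for a loss of negative supercoils.
#'
#' @param s the [substrate_geometry()] the product came from.
#' @param p a [simulate_rotation()] product of `s`.
#' @param max_residual largest tolerated deviation of either self-linking
#'   number from an integer.
#' @return integer linking-number change.
#' @export
delta_linking <- function(s, p, max_residual = 0.2) {
  stopifnot(inherits(s, "substrate_geometry"), inherits(p, "rotation_product"))
  if (!identical(p$substrate$rotation_sense, s$rotation_sense) ||
      !identical(p$substrate$plectoneme_turns, s$plectoneme_turns)) {
    stop("product does not belong to this substrate")
  }
  sl_s <- self_linking(s$curve)
  sl_p <- self_linking(p$curve)
  for (v in c(sl_s$sl, sl_p$sl)) {
    if (abs(v - round(v)) > max_residual) {
      stop(sprintf("self-linking %.3f not close to an integer; refine curves", v))
    }
  }
  as.integer(round(sl_p$sl) - round(sl_s$sl))
}
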