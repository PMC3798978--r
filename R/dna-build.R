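#' Base-pair step parameters
#'
#' Creates a validated table of the six rigid-body parameters relating
#' successive base-pair frames: shift, slide, rise (Angstrom) and tilt, roll,
#' twist (degrees).
#'
#' @param shift,slide,rise,tilt,roll,twist numeric vectors (recycled to a
#'   common length).
#' @return a data frame of class `step_params`.
#' @export
step_params <- function(shift = 0, slide = 0, rise = 3.4,
                        tilt = 0, roll = 0, twist = 34.2) {
  df <- data.frame(shift = shift, slide = slide, rise = rise,
                   tilt = tilt, roll = roll, twist = twist)
  validate_step_params(df)
  class(df) <- c("step_params", "data.frame")
  df
}

#' @rdname step_params
#' @param x object to validate.
#' @export
validate_step_params <- function(x) {
  need <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  if (!all(need %in% names(x))) {
    stop("step parameters need columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(x[need])))) stop("non-finite step parameter")
  if (any(x$rise <= 0)) stop("rise must be positive for a physical step")
  if (any(abs(x$twist) >= 180)) stop("|twist| must be below 180 degrees")
  if (any(abs(x$roll) >= 90) || any(abs(x$tilt) >= 90)) {
    stop("|roll| and |tilt| must be below 90 degrees")
  }
  invisible(x)
}

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Rigid transform of one base-pair step
#'
#' The standard mid-step-triad composition used by DNA rebuild tools: the
#' bend angle Gamma = sqrt(tilt^2 + roll^2) is applied about the roll-tilt
#' hinge at mid-step, with half the twist on either side; translations
#' (shift, slide, rise) are applied in the mid-step frame.
#'
#' @param step a single-row [step_params()] (or list with the six fields).
#' @return a [rigid_transform()] mapping base-pair frame i onto frame i+1
#'   (rotation applied in the local frame, translation in local coordinates).
#' @export
step_transform <- function(step) {
  validate_step_params(as.data.frame(step)[1, , drop = FALSE])
  d2r <- pi / 180
  tl <- step$tilt[1] * d2r; rl <- step$roll[1] * d2r; tw <- step$twist[1] * d2r
  gamma <- sqrt(tl^2 + rl^2)
  phi <- atan2(tl, rl)
  R <- .rot_z(tw / 2 - phi) %*% .rot_y(gamma) %*% .rot_z(tw / 2 + phi)
  Tm <- .rot_z(tw / 2 - phi) %*% .rot_y(gamma / 2) %*% .rot_z(phi)
  d <- as.numeric(Tm %*% c(step$shift[1], step$slide[1], step$rise[1]))
  rigid_transform(R, d)
}

# invert step_transform: recover the six parameters from frames i, i+1
.step_from_frames <- function(Ai, oi, Aj, oj) {
  R <- t(Ai) %*% Aj
  r2d <- 180 / pi
  c33 <- max(-1, min(1, R[3, 3]))
  gamma <- acos(c33)
  if (abs(sin(gamma)) < 1e-9) {
    tw <- atan2(R[2, 1], R[1, 1])
    phi <- 0; gamma <- 0
  } else {
    a <- atan2(R[2, 3], R[1, 3])
    b <- atan2(R[3, 2], -R[3, 1])
    tw <- a + b
    phi <- (b - a) / 2
  }
  # canonicalise to |twist| < 180 degrees; a 2*pi shift of the twist moves
  # the bend phase by pi (same rotation, conjugate parameterisation)
  if (tw > pi) { tw <- tw - 2 * pi; phi <- phi - pi }
  if (tw < -pi) { tw <- tw + 2 * pi; phi <- phi + pi }
  Tm <- .rot_z(tw / 2 - phi) %*% .rot_y(gamma / 2) %*% .rot_z(phi)
  v <- as.numeric(t(Tm) %*% t(Ai) %*% (oj - oi))
  data.frame(shift = v[1], slide = v[2], rise = v[3],
             tilt = gamma * sin(phi) * r2d, roll = gamma * cos(phi) * r2d,
             twist = tw * r2d)
}

# backbone pseudo-phosphate offsets, cylindrical: radius 8.9 A at +-77 degrees
# from the base-pair x axis (one per strand)
.backbone_offsets <- function(radius = 8.9, phase_deg = 77) {
  ph <- phase_deg * pi / 180
  rbind(top = radius * c(cos(ph), sin(ph), 0),
        bottom = radius * c(cos(-ph), sin(-ph), 0))
}

#' Build a 3D duplex model from step parameters
#'
#' Frames are obtained by sequential composition of [step_transform()]s from
#' a canonical first base-pair frame (identity orientation at the origin,
#' helix advancing along +z).  A pseudo-phosphate backbone proxy is placed for
#' each strand at fixed cylindrical offsets in every base-pair frame.
#'
#' @param sequence nucleotide string (A/C/G/T/N), one character per base pair.
#' @param steps a [step_params()] table with `nchar(sequence) - 1` rows.
#' @param origin,orientation frame of the first base pair.
#' @return a `duplex_model` with fields `sequence`, `frames` (list of
#'   `origin`/`axes`), and `backbone` (two N x 3 matrices, `top` and
#'   `bottom`).
#' @export
build_duplex <- function(sequence, steps, origin = c(0, 0, 0),
                         orientation = diag(3)) {
  sequence <- toupper(as.character(sequence)[1])
  nt <- strsplit(sequence, "")[[1]]
  if (!all(nt %in% c("A", "C", "G", "T", "N"))) {
    stop("invalid nucleotide characters in sequence")
  }
  n <- length(nt)
  steps <- as.data.frame(steps)
  if (nrow(steps) != n - 1L) {
    stop("need exactly length(sequence) - 1 steps (got ", nrow(steps), ")")
  }
  validate_step_params(steps)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-9 ||
      det(orientation) < 0) {
    stop("orientation must be a proper rotation matrix")
  }
  frames <- vector("list", n)
  A <- orientation; o <- as.numeric(origin)
  frames[[1]] <- list(origin = o, axes = A)
  for (i in seq_len(n - 1L)) {
    tr <- step_transform(steps[i, , drop = FALSE])
    o <- o + as.numeric(A %*% tr$translation)
    A <- A %*% tr$rotation
    frames[[i + 1L]] <- list(origin = o, axes = A)
  }
  off <- .backbone_offsets()
  top <- t(vapply(frames, function(f) f$origin + as.numeric(f$axes %*% off["top", ]),
                  numeric(3)))
  bottom <- t(vapply(frames, function(f) f$origin + as.numeric(f$axes %*% off["bottom", ]),
                     numeric(3)))
  structure(list(sequence = sequence, frames = frames,
                 backbone = list(top = top, bottom = bottom)),
            class = "duplex_model")
}

#' @export
print.duplex_model <- function(x, ...) {
  cat("duplex_model:", nchar(x$sequence), "bp\n")
  invisible(x)
}

#' Recover step parameters from a duplex model
#'
#' The inverse of [build_duplex()]: extracts the six rigid-body parameters of
#' every dinucleotide step from consecutive base-pair frames, such that
#' rebuilding from the result reproduces the frame origins.
#'
#' @param model a `duplex_model` with at least two frames.
#' @return a [step_params()] table.
#' @export
analyze_duplex <- function(model) {
  stopifnot(inherits(model, "duplex_model"))
  n <- length(model$frames)
  if (n < 2L) stop("need at least 2 base-pair frames")
  out <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    fi <- model$frames[[i]]; fj <- model$frames[[i + 1L]]
    .step_from_frames(fi$axes, fi$origin, fj$axes, fj$origin)
  }))
  class(out) <- c("step_params", "data.frame")
  out
}

#' Helical axis of a duplex model
#'
#' @param model a `duplex_model`.
#' @return N x 3 matrix of base-pair frame origins (one point per bp, order
#'   preserved).
#' @export
axis_curve <- function(model) {
  stopifnot(inherits(model, "duplex_model"))
  t(vapply(model$frames, `[[`, numeric(3), "origin"))
}

#' Recombinational enhancer layout
#'
#' Coordinates of the two Fis binding sites on the 65-bp enhancer: 15-bp core
#' sites whose centers lie 47 bp apart, with a 21-bp step-parameter block
#' (the crystal-derived segment) around each center.  All positions are
#' 1-based inclusive.
#'
#' @param total_bp enhancer length (65).
#' @param site_block_bp width of the bent parameter block per site (21).
#' @param core_bp width of the core Fis recognition site (15).
#' @param center_separation_bp distance between site centers (47).
#' @param site1_center 1-based position of the first site center.
#' @return an `enhancer_layout` list.
#' @export
enhancer_layout <- function(total_bp = 65, site_block_bp = 21, core_bp = 15,
                            center_separation_bp = 47, site1_center = 10) {
  site2_center <- site1_center + center_separation_bp
  half_core <- (core_bp - 1) %/% 2
  for (ctr in c(site1_center, site2_center)) {
    if (ctr - half_core < 1 || ctr + half_core > total_bp) {
      stop("15-bp core site does not fit inside the enhancer")
    }
  }
  if (site1_center + half_core >= site2_center - half_core) {
    stop("core sites overlap")
  }
  structure(list(total_bp = total_bp, site_block_bp = site_block_bp,
                 core_bp = core_bp, center_separation_bp = center_separation_bp,
                 site1_center = site1_center, site2_center = site2_center),
            class = "enhancer_layout")
}

#' Compose the enhancer step-parameter table
#'
#' Inserts the Fis-bent parameter block at both binding-site positions of the
#' layout and fills the remaining steps with generic parameters.  A block
#' that extends past the duplex ends is clipped there (the bent block is
#' wider than the flanking room at the default site positions).
#'
#' @param fis_block [step_params()] with `site_block_bp - 1` rows.
#' @param generic a single-row [step_params()] used outside the sites.
#' @param layout an [enhancer_layout()].
#' @return [step_params()] with `total_bp - 1` rows.
#' @export
compose_enhancer_params <- function(fis_block, generic, layout = enhancer_layout()) {
  fis_block <- as.data.frame(fis_block); validate_step_params(fis_block)
  generic <- as.data.frame(generic)[1, , drop = FALSE]; validate_step_params(generic)
  if (nrow(fis_block) != layout$site_block_bp - 1L) {
    stop("fis_block must have site_block_bp - 1 steps")
  }
  n_steps <- layout$total_bp - 1L
  out <- generic[rep(1L, n_steps), , drop = FALSE]
  rownames(out) <- NULL
  half <- (layout$site_block_bp - 1L) %/% 2L
  placed <- rep(FALSE, n_steps)
  for (ctr in c(layout$site1_center, layout$site2_center)) {
    # block steps span bp (ctr-half) .. (ctr+half); step k joins bp k,k+1
    for (k in seq_len(nrow(fis_block))) {
      pos <- ctr - half + k - 1L            # 1-based step index
      if (pos >= 1L && pos <= n_steps) {
        if (placed[pos]) stop("Fis site blocks overlap")
        out[pos, ] <- fis_block[k, ]
        placed[pos] <- TRUE
      }
    }
  }
  class(out) <- c("step_params", "data.frame")
  out
}

#' Read / write step-parameter tables
#'
#' Plain text, whitespace-delimited, one step per row, header line with the
#' six column names `shift slide rise tilt roll twist`.
#'
#' @param x a [step_params()] table.
#' @param path file path.
#' @export
write_step_params <- function(x, path) {
  validate_step_params(x)
  utils::write.table(format(as.data.frame(x), digits = 8), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_step_params
#' @export
read_step_params <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  validate_step_params(df)
  class(df) <- c("step_params", "data.frame")
  df
}

#' Read a DNA sequence from FASTA
#'
#' Thin wrapper around `Biostrings::readDNAStringSet`; returns the first
#' record as a plain character string.
#'
#' @param path FASTA file.
#' @return nucleotide string.
#' @export
read_sequence <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readDNAStringSet(path))[[1]])
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, ">")]
  toupper(paste(body, collapse = ""))
}
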