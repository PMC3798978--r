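#' Crosslink constraint sets
#'
#' A constraint is a pair of landmark labels, a crosslinker spacer length,
#' and the observed outcome (`"crosslinked"` or `"not_crosslinked"`).  The
#' packaged spacer lengths are those of the sulfhydryl/amine reagents used
#' to map the Fis-Hin interface: SIA 1.5, AMAS 4.4, GMBS 7.3, EMCS 9.4,
#' SMPH 14.2 and KMUS 16.3 Angstrom, plus the bismaleimide BMOE at 8.
#'
#' @param a,b landmark labels (e.g. `"Fis1:B:21"`, `"Hin:hix1L:146"`).
#' @param spacer spacer length in Angstrom.
#' @param observed `"crosslinked"` or `"not_crosslinked"`.
#' @return data frame of class `crosslink_constraints`.
#' @export
crosslink_constraints <- function(a, b, spacer, observed) {
  observed <- match.arg(observed, c("crosslinked", "not_crosslinked"),
                        several.ok = TRUE)
  if (any(spacer <= 0)) stop("spacer lengths must be positive")
  df <- data.frame(a = as.character(a), b = as.character(b),
                   spacer = as.numeric(spacer),
                   observed = rep_len(observed, length(a)),
                   stringsAsFactors = FALSE)
  class(df) <- c("crosslink_constraints", "data.frame")
  df
}

#' Spacer lengths of the packaged crosslinker panel (Angstrom)
#' @export
crosslinker_spacers <- function() {
  c(SIA = 1.5, AMAS = 4.4, GMBS = 7.3, BMOE = 8.0, EMCS = 9.4,
    SMPH = 14.2, KMUS = 16.3)
}

#' The packaged Fis-Hin crosslink constraint set
#'
#' Encodes the half-site asymmetry of the Fis-Hin contact: the Fis arm
#' crosslinks to residue 146 of the subunits bound to hix1L and hix2R
#' (BMOE, 8 Angstrom, and AMAS, 4.4 Angstrom) and not to the subunits bound
#' to hix1R and hix2L.
#'
#' @return a [crosslink_constraints()] table.
#' @export
default_crosslink_set <- function() {
  sp <- crosslinker_spacers()
  crosslink_constraints(
    a = c("Fis1:B:21", "Fis2:A:21", "Fis1:B:21", "Fis2:A:21",
          "Fis1:B:21", "Fis2:A:21", "Fis1:B:21", "Fis2:A:21"),
    b = c("Hin:hix1L:146", "Hin:hix2R:146", "Hin:hix1L:146", "Hin:hix2R:146",
          "Hin:hix1R:146", "Hin:hix2L:146", "Hin:hix1R:146", "Hin:hix2L:146"),
    spacer = c(sp["BMOE"], sp["BMOE"], sp["AMAS"], sp["AMAS"],
               sp["BMOE"], sp["BMOE"], sp["AMAS"], sp["AMAS"]),
    observed = c(rep("crosslinked", 4), rep("not_crosslinked", 4))
  )
}

#' Evaluate one crosslink constraint on an assembly
#'
#' The distance is the Euclidean separation of the two landmark points; a
#' positive constraint is satisfied when the distance is within spacer +
#' tolerance, a negative constraint when it exceeds it.
#'
#' @param a an `assembly`.
#' @param constraint single-row [crosslink_constraints()].
#' @param tolerance side-chain flexibility allowance (Angstrom).
#' @return list with `distance` and `satisfied`.
#' @export
crosslink_compatibility <- function(a, constraint, tolerance = 3) {
  lm <- assembly_landmarks(a)
  for (l in c(constraint$a[1], constraint$b[1])) {
    if (is.null(lm[[l]])) stop("landmark missing from assembly: ", l)
  }
  d <- sqrt(sum((lm[[constraint$a[1]]] - lm[[constraint$b[1]]])^2))
  ok <- if (constraint$observed[1] == "crosslinked") {
    d <= constraint$spacer[1] + tolerance
  } else {
    d > constraint$spacer[1] + tolerance
  }
  list(distance = d, satisfied = ok)
}

#' Crosslink consistency report
#'
#' @param a an `assembly`.
#' @param constraints a [crosslink_constraints()] table.
#' @param tolerance distance tolerance (Angstrom).
#' @return the constraint table with `distance` and `satisfied` columns.
#' @export
crosslink_report <- function(a, constraints = default_crosslink_set(),
                             tolerance = 3) {
  res <- lapply(seq_len(nrow(constraints)), function(i) {
    crosslink_compatibility(a, constraints[i, , drop = FALSE], tolerance)
  })
  constraints$distance <- vapply(res, `[[`, numeric(1), "distance")
  constraints$satisfied <- vapply(res, `[[`, logical(1), "satisfied")
  constraints
}

# total positive violation (used by the refinement search)
crosslink_score <- function(a, constraints, tolerance = 3) {
  rep <- crosslink_report(a, constraints, tolerance)
  lim <- rep$spacer + tolerance
  sum(pmax(0, rep$distance - lim)[rep$observed == "crosslinked"]) +
    sum(pmax(0, lim - rep$distance)[rep$observed == "not_crosslinked"])
}

#' FeBABE reach model
#'
#' The iron chelate is coupled to an engineered cysteine through a tether of
#' about 12 Angstrom to the Fe center that generates hydroxyl radicals; the
#' radicals diffuse over a short radius before cleaving DNA.  Scission is
#' predicted wherever a backbone position lies within
#' `tether_length + radical_radius` of the tether point.
#'
#' @param tether_length Angstrom from the coupled cysteine to the Fe center.
#' @param radical_radius effective hydroxyl-radical action radius.
#' @return a `febabe_reach`.
#' @export
febabe_reach <- function(tether_length = 12, radical_radius = 10) {
  if (tether_length <= 0 || radical_radius <= 0) stop("lengths must be positive")
  structure(list(tether_length = tether_length,
                 radical_radius = radical_radius,
                 max_reach = tether_length + radical_radius),
            class = "febabe_reach")
}

#' Predict a tethered-nuclease footprint on the enhancer
#'
#' Reports every enhancer backbone position within reach of the tether
#' point, with 1-based bp position, strand, distance, and rank (ranks
#' increase with distance; scission intensity is modeled as inverse distance
#' rank only).
#'
#' @param a an `assembly`.
#' @param tether landmark label carrying the FeBABE (e.g. `"Hin:hix1L:54"`).
#' @param reach a [febabe_reach()].
#' @return data frame of class `footprint_prediction`.
#' @export
predict_febabe_footprint <- function(a, tether, reach = febabe_reach()) {
  lm <- assembly_landmarks(a)
  if (is.null(lm[[tether]])) stop("tether landmark missing: ", tether)
  p <- lm[[tether]]
  res <- do.call(rbind, lapply(c("top", "bottom"), function(strand) {
    b <- a$enhancer$backbone[[strand]]
    d <- sqrt(rowSums(sweep(b, 2, p)^2))
    data.frame(bp = seq_len(nrow(b)), strand = strand, distance = d,
               stringsAsFactors = FALSE)
  }))
  res <- res[res$distance <= reach$max_reach, , drop = FALSE]
  res <- res[order(res$distance), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("footprint_prediction", "data.frame")
  res
}

#' Write footprint predictions as BED
#'
#' 0-based half-open intervals of width 1, with the distance as score.
#'
#' @param fp a [predict_febabe_footprint()] result.
#' @param path output file.
#' @param chrom reference name for the enhancer coordinate system.
#' @export
write_footprint_bed <- function(fp, path, chrom = "enhancer") {
  strand <- ifelse(fp$strand == "top", "+", "-")
  df <- data.frame(chrom = chrom, start = fp$bp - 1L, end = fp$bp,
                   name = paste0("scission_", fp$rank),
                   score = round(fp$distance, 3), strand = strand)
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Basic-patch DNA contacts of a Hin subunit
#'
#' Lists the basic helix-B residues (Lys47, Arg48, Lys51) of a subunit that
#' lie within the cutoff of any backbone position of a duplex, sorted by
#' distance.
#'
#' @param a an `assembly`.
#' @param subunit half-site name (`"hix1L"`, `"hix1R"`, `"hix2L"`,
#'   `"hix2R"`).
#' @param duplex `"enhancer"`, `"hix1"` or `"hix2"`.
#' @param cutoff contact cutoff (Angstrom).
#' @return data frame with `residue` and `distance`.
#' @export
basic_patch_contacts <- function(a, subunit, duplex = "enhancer", cutoff = 6) {
  if (!subunit %in% names(a$hin)) stop("unknown subunit: ", subunit)
  dp <- a[[duplex]]
  if (is.null(dp)) stop("unknown duplex: ", duplex)
  prox <- rbind(dp$backbone$top, dp$backbone$bottom)
  basic <- c("47", "48", "51")
  d <- vapply(basic, function(r) {
    .min_dist(matrix(landmark_xyz(a$hin[[subunit]], r), 1), prox)
  }, numeric(1))
  out <- data.frame(residue = as.integer(basic), distance = d)
  out <- out[out$distance <= cutoff, , drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}
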