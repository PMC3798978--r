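#' Proper rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, determinant +1).
#' @param translation 3-vector.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal")
  }
  if (det(rotation) < 0) stop("improper rotation (reflection) not allowed")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b transforms; `compose_transform(a, b)` applies `b` first.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param tr transform to invert.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Labeled 3D point sets for protein and DNA coordinates
#'
#' An `atom_set` stores one record per atom (chain, residue number, residue
#' name, atom name, element, coordinates) plus an optional landmark index
#' mapping semantic labels such as `"Fis1:A:21"` to records.
#'
#' @param chain,resno,resname,atom,element record fields (vectors).
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param landmarks named integer vector: semantic label -> row index.
#' @return an `atom_set`.
#' @export
atom_set <- function(chain, resno, resname, atom, xyz,
                     element = "C", landmarks = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rec <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = rep_len(as.integer(resno), n),
                    resname = rep_len(as.character(resname), n),
                    atom = rep_len(as.character(atom), n),
                    element = rep_len(as.character(element), n),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(rec$chain, rec$resno, rec$atom)
  if (anyDuplicated(key)) stop("(chain, residue, atom) records must be unique")
  if (!is.null(landmarks)) {
    stopifnot(is.numeric(landmarks), !is.null(names(landmarks)),
              all(landmarks >= 1), all(landmarks <= n))
    landmarks <- vapply(landmarks, as.integer, integer(1))
  }
  structure(list(records = rec, xyz = xyz, landmarks = landmarks),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat("atom_set:", nrow(x$xyz), "atoms,",
      length(unique(x$records$chain)), "chain(s)")
  if (!is.null(x$landmarks)) cat(",", length(x$landmarks), "landmarks")
  cat("\n")
  invisible(x)
}

#' Look up a landmark coordinate
#'
#' @param a an [atom_set()].
#' @param label landmark label.
#' @return 3-vector.
#' @export
landmark_xyz <- function(a, label) {
  if (is.null(a$landmarks) || !label %in% names(a$landmarks)) {
    stop("landmark not found: ", label)
  }
  a$xyz[a$landmarks[[label]], ]
}

#' Read ATOM records from a PDB file
#'
#' Strict fixed-column (v3.3) parser for ATOM/HETATM records: chains and
#' residue numbers are preserved, alternate-location indicators other than
#' blank are rejected, and malformed lines raise an error naming the line
#' number.  (For rich PDB handling use the bio3d package; this reader exists
#' to give the pipeline deterministic, validated round-trips.)
#'
#' @param path PDB file.
#' @return an [atom_set()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  sel <- which(startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  parse_num <- function(s, i, what) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      bad <- i[which(is.na(v))[1]]
      stop(sprintf("malformed %s field at line %d of %s", what, bad, path))
    }
    v
  }
  ln <- lines[sel]
  short <- nchar(ln) < 54
  if (any(short)) {
    stop(sprintf("truncated ATOM record at line %d of %s", sel[short][1], path))
  }
  altloc <- substr(ln, 17, 17)
  if (any(altloc != " ")) {
    stop(sprintf("alternate location indicator at line %d not supported",
                 sel[altloc != " "][1]))
  }
  atom <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resno <- parse_num(trimws(substr(ln, 23, 26)), sel, "residue number")
  x <- parse_num(substr(ln, 31, 38), sel, "x coordinate")
  y <- parse_num(substr(ln, 39, 46), sel, "y coordinate")
  z <- parse_num(substr(ln, 47, 54), sel, "z coordinate")
  element <- trimws(substr(paste0(ln, strrep(" ", 80)), 77, 78))
  element[element == ""] <- substr(atom[element == ""], 1, 1)
  atom_set(chain, as.integer(resno), resname, atom, cbind(x, y, z), element)
}

#' Write an atom set as PDB ATOM records
#'
#' @param a an [atom_set()].
#' @param path output file.
#' @export
write_pdb <- function(a, path) {
  rec <- a$records
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rec))) {
    an <- rec$atom[i]
    an_f <- if (nchar(an) < 4) sprintf(" %-3s", an) else sprintf("%-4s", an)
    writeLines(sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       i %% 100000L, an_f, rec$resname[i], rec$chain[i],
                       rec$resno[i] %% 10000L, a$xyz[i, 1], a$xyz[i, 2],
                       a$xyz[i, 3], 1, 0, rec$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Attach semantic landmarks from a sidecar mapping
#'
#' The mapping is two-column delimited text (`label  chain:resno[:atom]`),
#' so real structure templates and toy fixtures share one constraint
#' vocabulary.
#'
#' @param a an [atom_set()].
#' @param path mapping file, or a data frame with columns `label`, `ref`.
#' @param atom default atom name used when the reference omits one.
#' @return the atom set with landmarks attached.
#' @export
read_landmarks <- function(a, path, atom = "CA") {
  map <- if (is.data.frame(path)) path else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  if (!all(c("label", "ref") %in% names(map))) {
    stop("landmark mapping needs columns 'label' and 'ref'")
  }
  idx <- integer(nrow(map)); names(idx) <- map$label
  for (i in seq_len(nrow(map))) {
    parts <- strsplit(map$ref[i], ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("bad landmark reference: ", map$ref[i])
    at <- if (length(parts) >= 3) parts[3] else atom
    hit <- which(a$records$chain == parts[1] &
                   a$records$resno == as.integer(parts[2]) &
                   a$records$atom == at)
    if (length(hit) != 1L) stop("landmark reference not resolved: ", map$ref[i])
    idx[i] <- hit
  }
  a$landmarks <- idx
  a
}

#' Apply a rigid transform to an atom set
#'
#' Every coordinate is mapped x -> R x + d; records and landmark labels are
#' untouched.
#'
#' @param a an [atom_set()].
#' @param tr a [rigid_transform()].
#' @return the transformed atom set.
#' @export
apply_transform <- function(a, tr) {
  stopifnot(inherits(a, "atom_set"), inherits(tr, "rigid_transform"))
  a$xyz <- t(tr$rotation %*% t(a$xyz) + tr$translation)
  dimnames(a$xyz) <- NULL
  a
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets.  Reflections are never returned: for mirror-image
#' inputs the best proper rotation is used and the residual RMSD is positive.
#'
#' @param moving,target N x 3 matrices with matched rows (N >= 3,
#'   non-collinear).
#' @return list with the optimal [rigid_transform()] (`transform`) and the
#'   minimised `rmsd`.
#' @export
superpose <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (nrow(moving) != nrow(target)) stop("point sets must have equal length")
  if (nrow(moving) < 3L) stop("need at least 3 points")
  cm <- colMeans(moving); ct <- colMeans(target)
  X <- sweep(moving, 2, cm); Y <- sweep(target, 2, ct)
  sv <- svd(crossprod(X, Y))
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2) {
    stop("degenerate (collinear) point set")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cm))
  moved <- t(R %*% t(moving) + tr$translation)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - target)^2))))
}
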