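#' Closed 3D curves for DNA topology
#'
#' A `closed_curve` is an ordered 3D polyline, implicitly closed (the last
#' vertex connects back to the first), optionally carrying a segment label per
#' vertex (e.g. `"hix1"`, `"enhancer"`, `"plectoneme"`).  It is the container
#' on which writhe, linking number, node counts and knot invariants are
#' computed.
#'
#' @param points numeric matrix with 3 columns (x, y, z), one row per vertex.
#' @param labels optional character vector, one label per vertex.
#' @param validate check embedding invariants (at least 4 points, no repeated
#'   consecutive points).
#' @return an object of class `closed_curve`.
#' @export
closed_curve <- function(points, labels = NULL, validate = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("'points' must have three columns")
  storage.mode(points) <- "double"
  if (validate) {
    if (nrow(points) < 4L) stop("a closed curve needs at least 4 points")
    if (any(!is.finite(points))) stop("curve coordinates must be finite")
    gaps <- rowSums((points - points[c(2:nrow(points), 1L), , drop = FALSE])^2)
    if (any(gaps < 1e-18)) stop("repeated consecutive points in curve")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points)) stop("one label per vertex required")
  }
  structure(list(points = points, labels = labels), class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat("closed_curve:", nrow(x$points), "vertices")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(" (", paste0(names(tab), ":", tab, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
.crossm <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# exact solid angle of the Gauss integral for segment pairs (Levitt /
# Klenin-Vologodskii formula), vectorised over an index matrix of pairs
.omega_pairs <- function(S1, E1, S2, E2, idx) {
  p1 <- S1[idx[, 1], , drop = FALSE]; p2 <- E1[idx[, 1], , drop = FALSE]
  p3 <- S2[idx[, 2], , drop = FALSE]; p4 <- E2[idx[, 2], , drop = FALSE]
  r12 <- p2 - p1; r34 <- p4 - p3
  r13 <- p3 - p1; r14 <- p4 - p1; r23 <- p3 - p2; r24 <- p4 - p2
  n1 <- .crossm(r13, r14); n2 <- .crossm(r14, r24)
  n3 <- .crossm(r24, r23); n4 <- .crossm(r23, r13)
  a1 <- sqrt(rowSums(n1^2)); a2 <- sqrt(rowSums(n2^2))
  a3 <- sqrt(rowSums(n3^2)); a4 <- sqrt(rowSums(n4^2))
  ok <- a1 > 1e-12 & a2 > 1e-12 & a3 > 1e-12 & a4 > 1e-12
  n1 <- n1 / a1; n2 <- n2 / a2; n3 <- n3 / a3; n4 <- n4 / a4
  cl <- function(x) pmin(1, pmax(-1, x))
  s <- asin(cl(rowSums(n1 * n2))) + asin(cl(rowSums(n2 * n3))) +
    asin(cl(rowSums(n3 * n4))) + asin(cl(rowSums(n4 * n1)))
  out <- s * sign(rowSums(.crossm(r34, r12) * r13))
  out[!ok] <- 0
  out
}

.curve_pts <- function(x) if (inherits(x, "closed_curve")) x$points else as.matrix(x)

#' Writhe of a closed curve
#'
#' Discretised Gauss double integral over all non-adjacent segment pairs,
#' using the exact per-pair solid-angle formula (so the result is the writhe
#' of the polygon itself, not a quadrature approximation).
#'
#' @param curve a [closed_curve()] (or plain 3-column matrix).
#' @return the writhe (a real number; 0 for planar curves).
#' @export
writhe <- function(curve) {
  pts <- .curve_pts(curve)
  n <- nrow(pts)
  S <- pts; E <- pts[c(2:n, 1L), , drop = FALSE]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- idx[, 2] - idx[, 1] > 1L & !(idx[, 1] == 1L & idx[, 2] == n)
  idx <- idx[keep, , drop = FALSE]
  tot <- 0
  block <- 4e5L
  for (s0 in seq(1L, nrow(idx), by = block)) {
    ii <- idx[s0:min(nrow(idx), s0 + block - 1L), , drop = FALSE]
    tot <- tot + sum(.omega_pairs(S, E, S, E, ii))
  }
  2 * tot / (4 * pi)
}

#' Gauss linking number of two disjoint closed curves
#'
#' @param a,b two [closed_curve()]s (or 3-column matrices).
#' @param max_residual largest tolerated distance of the raw Gauss integral
#'   from the nearest integer; a larger residual signals insufficient
#'   resolution and raises an error.
#' @return an integer linking number.
#' @export
linking_number <- function(a, b, max_residual = 0.1) {
  pa <- .curve_pts(a); pb <- .curve_pts(b)
  na <- nrow(pa); nb <- nrow(pb)
  Sa <- pa; Ea <- pa[c(2:na, 1L), , drop = FALSE]
  Sb <- pb; Eb <- pb[c(2:nb, 1L), , drop = FALSE]
  idx <- as.matrix(expand.grid(seq_len(na), seq_len(nb)))
  tot <- 0
  block <- 4e5L
  for (s0 in seq(1L, nrow(idx), by = block)) {
    ii <- idx[s0:min(nrow(idx), s0 + block - 1L), , drop = FALSE]
    tot <- tot + sum(.omega_pairs(Sa, Ea, Sb, Eb, ii))
  }
  lk <- tot / (4 * pi)
  if (abs(lk - round(lk)) > max_residual) {
    stop(sprintf("linking integral %.4f is not close to an integer; refine the curves", lk))
  }
  as.integer(round(lk))
}

.proj_basis <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- .cross3(v, a); u1 <- u1 / sqrt(sum(u1^2))
  list(u1 = u1, u2 = .cross3(v, u1), v = v)
}

# all transversal crossings of the projected diagram of one closed polyline
.diagram_crossings <- function(pts, v) {
  B <- .proj_basis(v)
  n <- nrow(pts)
  P <- cbind(as.numeric(pts %*% B$u1), as.numeric(pts %*% B$u2))
  H <- as.numeric(pts %*% B$v)
  nx <- c(2:n, 1L)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- idx[, 2] - idx[, 1] > 1L & !(idx[, 1] == 1L & idx[, 2] == n)
  idx <- idx[keep, , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  px <- P[i, 1]; py <- P[i, 2]; rx <- P[nx[i], 1] - px; ry <- P[nx[i], 2] - py
  qx <- P[j, 1]; qy <- P[j, 2]; sx <- P[nx[j], 1] - qx; sy <- P[nx[j], 2] - qy
  den <- rx * sy - ry * sx
  t <- ((qx - px) * sy - (qy - py) * sx) / den
  u <- ((qx - px) * ry - (qy - py) * rx) / den
  ok <- abs(den) > 1e-12 & t > 1e-9 & t < 1 - 1e-9 & u > 1e-9 & u < 1 - 1e-9
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    return(data.frame(seg_i = integer(), seg_j = integer(), ti = numeric(),
                      tj = numeric(), sign = numeric(), i_over = logical(),
                      pos_i = numeric(), pos_j = numeric()))
  }
  i <- i[ok]; j <- j[ok]; t <- t[ok]; u <- u[ok]
  hi <- H[i] + t * (H[nx[i]] - H[i]); hj <- H[j] + u * (H[nx[j]] - H[j])
  Ti <- pts[nx[i], , drop = FALSE] - pts[i, , drop = FALSE]
  Tj <- pts[nx[j], , drop = FALSE] - pts[j, , drop = FALSE]
  cz <- as.numeric(.crossm(Ti, Tj) %*% B$v)
  sgn <- ifelse(hi > hj, sign(cz), -sign(cz))
  data.frame(seg_i = i, seg_j = j, ti = t, tj = u, sign = sgn,
             i_over = hi > hj, pos_i = i + t, pos_j = j + u)
}

#' Signed crossings (nodes) between labeled segments of a DNA path
#'
#' Projects the curve along a viewing direction and reports every transversal
#' crossing between two differently-labeled segment classes, with the
#' right-handed sign convention in which the crossings formed at a branch on
#' negatively supercoiled DNA are negative.
#'
#' @param curve a labeled [closed_curve()].
#' @param labels_a,labels_b character vectors of segment labels; only
#'   crossings with one strand in `labels_a` and the other in `labels_b` are
#'   reported.  With the defaults all crossings are reported.
#' @param projection viewing direction (3-vector); perturbed automatically if
#'   degenerate.
#' @return data frame with one row per crossing: the two labels, the sign
#'   (+1/-1), and which strand passes over.
#' @export
count_nodes <- function(curve, labels_a = NULL, labels_b = NULL,
                        projection = c(0.02, 0.04, 1)) {
  if (is.null(curve$labels)) stop("count_nodes needs a labeled curve")
  cr <- .diagram_crossings(curve$points, projection)
  if (nrow(cr) == 0L) {
    return(data.frame(label_i = character(), label_j = character(),
                      sign = numeric(), over = character()))
  }
  li <- curve$labels[cr$seg_i]; lj <- curve$labels[cr$seg_j]
  out <- data.frame(label_i = li, label_j = lj, sign = cr$sign,
                    over = ifelse(cr$i_over, li, lj),
                    stringsAsFactors = FALSE)
  if (!is.null(labels_a) && !is.null(labels_b)) {
    keep <- (out$label_i %in% labels_a & out$label_j %in% labels_b) |
      (out$label_i %in% labels_b & out$label_j %in% labels_a)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# events of the knot diagram in traversal order
.diagram_events <- function(pts, v) {
  cr <- .diagram_crossings(pts, v)
  nc <- nrow(cr)
  if (nc == 0L) return(NULL)
  ev <- rbind(data.frame(id = seq_len(nc), pos = cr$pos_i, over = cr$i_over),
              data.frame(id = seq_len(nc), pos = cr$pos_j, over = !cr$i_over))
  ev[order(ev$pos), ]
}

#' Knot determinant of a closed curve
#'
#' The determinant |Delta(-1)| of the Alexander polynomial, computed from a
#' generic planar diagram of the curve (1 for the unknot, 3 for a trefoil,
#' 5 for the figure-eight knot).  Several projection directions are tried and
#' must agree, which guards against near-degenerate diagrams.
#'
#' @param curve a [closed_curve()].
#' @param projections matrix of candidate viewing directions (rows).
#' @return a positive odd integer (or 1).
#' @export
knot_determinant <- function(curve, projections = NULL) {
  pts <- .curve_pts(curve)
  if (is.null(projections)) {
    projections <- rbind(c(0.02, 0.04, 1), c(0.3, -0.2, 0.93), c(-0.15, 0.25, 0.95))
  }
  dets <- apply(projections, 1L, function(v) .knot_det_one(pts, v))
  if (length(unique(dets)) != 1L) {
    stop("knot determinant differs between projections (",
         paste(dets, collapse = ", "), "); refine the curve")
  }
  dets[[1L]]
}

.knot_det_one <- function(pts, v) {
  ev <- .diagram_events(pts, v)
  if (is.null(ev)) return(1L)
  nc <- max(ev$id)
  m <- nrow(ev)
  na <- sum(!ev$over)                 # one arc per underpass
  if (na == 0L) return(1L)
  arc_of <- integer(m); j <- 0L
  for (e in seq_len(m)) {
    arc_of[e] <- if (j == 0L) na else j
    if (!ev$over[e]) j <- j + 1L
  }
  # Alexander matrix at t = -1: row per crossing, 2*(over arc) - in - out
  M <- matrix(0, nc, na)
  for (ci in seq_len(nc)) {
    eu <- which(ev$id == ci & !ev$over)
    eo <- which(ev$id == ci & ev$over)
    inc <- arc_of[eu]; outg <- inc %% na + 1L; ov <- arc_of[eo]
    M[ci, inc] <- M[ci, inc] - 1
    M[ci, outg] <- M[ci, outg] - 1
    M[ci, ov] <- M[ci, ov] + 2
  }
  if (na == 1L) return(1L)
  as.integer(round(abs(det(M[-nc, -na, drop = FALSE]))))
}

#' Reduced crossing count of a knot diagram
#'
#' Counts diagram crossings after iteratively removing kinks (Reidemeister I)
#' and cancelling adjacent opposite crossings (Reidemeister II) from the Gauss
#' code, minimised over several projection directions.  This is an upper bound
#' on the crossing number that cleanly separates the knot ladder produced by
#' processive subunit rotation.
#'
#' @param curve a [closed_curve()].
#' @param projections matrix of viewing directions to minimise over.
#' @return integer reduced crossing count (0 for an unknot diagram).
#' @export
reduced_crossing_count <- function(curve, projections = NULL) {
  pts <- .curve_pts(curve)
  if (is.null(projections)) {
    projections <- rbind(c(0.02, 0.04, 1), c(0.3, -0.2, 0.93), c(-0.15, 0.25, 0.95))
  }
  min(apply(projections, 1L, function(v) .reduced_one(pts, v)))
}

.reduced_one <- function(pts, v) {
  ev <- .diagram_events(pts, v)
  if (is.null(ev)) return(0L)
  ids <- ev$id; over <- ev$over
  repeat {
    m <- length(ids)
    if (m == 0L) break
    changed <- FALSE
    for (e in seq_len(m)) {                       # Reidemeister I
      f <- e %% m + 1L
      if (ids[e] == ids[f]) {
        keep <- ids != ids[e]
        ids <- ids[keep]; over <- over[keep]
        changed <- TRUE; break
      }
    }
    if (changed) next
    done <- FALSE
    for (e in seq_len(m)) {                       # Reidemeister II
      f <- e %% m + 1L
      a <- ids[e]; b <- ids[f]
      if (a == b || over[e] != over[f]) next
      for (g in seq_len(m)) {
        h <- g %% m + 1L
        if (g == e) next
        if (((ids[g] == b && ids[h] == a) || (ids[g] == a && ids[h] == b)) &&
            over[g] == over[h] && over[g] != over[e]) {
          keep <- !(ids %in% c(a, b))
          ids <- ids[keep]; over <- over[keep]
          done <- TRUE; break
        }
      }
      if (done) break
    }
    if (!done) break
  }
  length(unique(ids))
}

#' Self-linking number of a closed curve
#'
#' Writhe plus the closure twist of a parallel-transported framing: the
#' linking number of the curve with a push-off along a framing that carries
#' no net material twist.  This integer invariant is the bookkeeping quantity
#' behind [delta_linking()]: under the rigid-axis approximation (duplex twist
#' unchanged), the change in duplex linking number upon recombination equals
#' the change in self-linking of the modeled axis.
#'
#' @param curve a [closed_curve()].
#' @return a list with components `wr` (writhe), `tw` (closure twist) and
#'   `sl` (their sum, an integer up to discretisation error).
#' @export
self_linking <- function(curve) {
  pts <- .curve_pts(curve)
  n <- nrow(pts)
  tg <- pts[c(2:n, 1L), , drop = FALSE] - pts
  tg <- tg / sqrt(rowSums(tg^2))
  u <- c(tg[1, 2], -tg[1, 1], 0)
  u <- u - sum(u * tg[1, ]) * tg[1, ]
  if (sum(u^2) < 1e-12) u <- .cross3(tg[1, ], c(0, 0, 1))
  u <- u / sqrt(sum(u^2))
  u0 <- u; t0 <- tg[1, ]
  rot_step <- function(u, a, b) {
    k <- .cross3(a, b); kk <- sqrt(sum(k^2))
    if (kk > 1e-12) {
      k <- k / kk
      co <- max(-1, min(1, sum(a * b)))
      u <- u * co + .cross3(k, u) * kk + k * sum(k * u) * (1 - co)
    }
    u <- u - sum(u * b) * b
    u / sqrt(sum(u^2))
  }
  for (i in seq_len(n - 1L)) u <- rot_step(u, tg[i, ], tg[i + 1L, ])
  u <- rot_step(u, tg[n, ], tg[1, ])
  v0 <- .cross3(t0, u0)
  alpha <- atan2(sum(u * v0), sum(u * u0))
  wr <- writhe(pts)
  list(wr = wr, tw = -alpha / (2 * pi), sl = wr - alpha / (2 * pi))
}

#' Read / write labeled xyz polylines
#'
#' Curves are exchanged as whitespace-delimited text with columns
#' `x y z label` and a header line.
#'
#' @param curve a [closed_curve()].
#' @param path file path.
#' @return `read_curve` returns a [closed_curve()]; `write_curve` returns
#'   `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(x = curve$points[, 1], y = curve$points[, 2],
                   z = curve$points[, 3],
                   label = if (is.null(curve$labels)) "." else curve$labels)
  utils::write.table(format(df, digits = 10), path, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) stop("curve file needs x y z columns")
  labs <- if ("label" %in% names(df) && !all(df$label == ".")) df$label else NULL
  closed_curve(as.matrix(df[, c("x", "y", "z")]), labels = labs)
}
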