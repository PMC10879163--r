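#' 3D convex hull of a point cloud
#'
#' Incremental (beneath-beyond) convex hull in three dimensions: an initial
#' non-degenerate tetrahedron is grown point by point, replacing the faces
#' visible from each new point with a fan over its horizon edges. Faces are
#' kept outward-oriented, which makes volume (divergence theorem over the
#' triangle fan) and half-space membership tests direct.
#'
#' @param points numeric matrix n x 3 (micrometers), n >= 4, not all
#'   coplanar.
#' @return List of class `hull3d`: `points` (input), `vertices` (indices of
#'   hull vertices), `faces` (f x 3 index matrix, outward orientation),
#'   `volume`, `planes` (list with unit `normals` f x 3 and `offsets` so a
#'   point p is inside iff `normals %*% p <= offsets` for all faces).
#' @export
convex_hull_3d <- function(points) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  if (ncol(P) != 3L) stop("points must be n x 3")
  n <- nrow(P)
  if (n < 4L) stop("zero-volume hull: fewer than 4 points")
  scale <- max(apply(P, 2L, function(v) diff(range(v))), 1e-12)
  eps <- 1e-9 * scale

  # initial simplex from extreme points
  i1 <- which.min(P[, 1L])
  d1 <- rowSums(sweep(P, 2L, P[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) < eps) stop("zero-volume hull: coincident points")
  u <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2L, P[i1, ])
  crossm <- cbind(rel[, 2L] * u[3L] - rel[, 3L] * u[2L],
                  rel[, 3L] * u[1L] - rel[, 1L] * u[3L],
                  rel[, 1L] * u[2L] - rel[, 2L] * u[1L])
  dline <- sqrt(rowSums(crossm^2)) / sqrt(sum(u^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) stop("zero-volume hull: collinear points")
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(rel %*% nrm)
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) stop("zero-volume hull: coplanar points")

  init <- c(i1, i2, i3, i4)
  ctr <- colMeans(P[init, ])
  orient <- function(f) {
    nv <- cross3(P[f[2L], ] - P[f[1L], ], P[f[3L], ] - P[f[1L], ])
    if (sum(nv * (ctr - P[f[1L], ])) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- rbind(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                 orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  face_plane <- function(f) {
    nv <- cross3(P[f[2L], ] - P[f[1L], ], P[f[3L], ] - P[f[1L], ])
    nn <- sqrt(sum(nv^2))
    c(nv / nn, sum(nv / nn * P[f[1L], ]))
  }
  planes <- t(apply(faces, 1L, face_plane))

  for (p in setdiff(seq_len(n), init)) {
    d <- planes[, 1:3, drop = FALSE] %*% P[p, ] - planes[, 4L]
    visible <- which(d > eps)
    if (!length(visible)) next
    vis_faces <- faces[visible, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1L, 2L)], vis_faces[, c(2L, 3L)],
                   vis_faces[, c(3L, 1L)])
    # a directed edge whose reverse also bounds a visible face is interior
    # to the visible region; the rest form the horizon loop
    key <- paste(edges[, 1L], edges[, 2L])
    rev_key <- paste(edges[, 2L], edges[, 1L])
    horizon <- edges[!(rev_key %in% key), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[-visible, , drop = FALSE], new_faces)
    planes <- rbind(planes[-visible, , drop = FALSE],
                    t(apply(new_faces, 1L, face_plane)))
  }

  verts <- sort(unique(as.vector(faces)))
  o <- colMeans(P[verts, , drop = FALSE])
  vol <- 0
  for (f in seq_len(nrow(faces))) {
    a <- P[faces[f, 1L], ] - o
    b <- P[faces[f, 2L], ] - o
    cc <- P[faces[f, 3L], ] - o
    vol <- vol + sum(a * cross3(b, cc)) / 6
  }
  structure(list(points = P, vertices = verts, faces = faces,
                 volume = abs(vol),
                 planes = list(normals = planes[, 1:3, drop = FALSE],
                               offsets = planes[, 4L]),
                 eps = eps),
            class = "hull3d")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Convex hull volume, 0 for degenerate input
#'
#' @param points numeric matrix n x 3.
#' @return Volume in cubic micrometers; 0 when fewer than four points or all
#'   points are coplanar.
#' @export
hull_volume <- function(points) {
  tryCatch(convex_hull_3d(points)$volume,
           error = function(e) {
             if (grepl("zero-volume hull", conditionMessage(e))) 0
             else stop(e)
           })
}

point_in_hull <- function(p, hull, tol = NULL) {
  if (is.null(tol)) tol <- hull$eps
  all(hull$planes$normals %*% p - hull$planes$offsets <= tol)
}

hull_edges <- function(hull) {
  f <- hull$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- t(apply(e, 1L, sort))
  unique(e)
}

# Liang-Barsky clip of segment p->q against a hull's half-spaces; returns the
# clipped endpoints or NULL if the segment misses the hull
clip_segment <- function(p, q, hull, tol = NULL) {
  if (is.null(tol)) tol <- hull$eps
  d <- q - p
  dp <- as.numeric(hull$planes$normals %*% p - hull$planes$offsets)
  dq <- as.numeric(hull$planes$normals %*% q - hull$planes$offsets)
  tmin <- 0; tmax <- 1
  for (i in seq_along(dp)) {
    a <- dp[i]; b <- dq[i] - dp[i]
    if (abs(b) < 1e-300) {
      if (a > tol) return(NULL)
    } else {
      t0 <- -a / b
      if (b > 0) tmax <- min(tmax, t0) else tmin <- max(tmin, t0)
      if (tmin > tmax + 1e-12) return(NULL)
    }
  }
  rbind(p + tmin * d, p + tmax * d)
}

#' Prune convex-hull outliers with the leave-one-out 1/n rule
#'
#' Going through all n points of a class, the hull volume is recomputed
#' without each point; points whose removal changes the volume by more than
#' `1/n` of the original all-points hull volume are outliers and are
#' removed. If that would leave fewer than four somata -- the minimum for a
#' convex hull -- all points are retained instead. Flags are computed
#' against the full-set hull, so the result does not depend on input order.
#'
#' @param points numeric matrix n x 3 of soma coordinates, n >= 4, not all
#'   coplanar.
#' @param class_label optional label carried on the summary.
#' @return List of class `hull_summary`: `kept_points`, `removed_points`,
#'   `volume`, `reverted` (`TRUE` when the fewer-than-four fallback
#'   engaged).
#' @export
prune_hull_outliers <- function(points, class_label = NA_character_) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 points")
  v_all <- convex_hull_3d(P)$volume  # errors on degenerate input
  loo <- vapply(seq_len(n), function(i) {
    hull_volume(P[-i, , drop = FALSE])
  }, numeric(1L))
  outlier <- abs(loo - v_all) > v_all / n
  reverted <- any(outlier) && sum(!outlier) < 4L
  keep <- if (reverted) seq_len(n) else which(!outlier)
  removed <- if (length(keep) == n) P[0L, , drop = FALSE]
             else P[-keep, , drop = FALSE]
  structure(list(class_label = class_label,
                 kept_points = P[keep, , drop = FALSE],
                 removed_points = removed,
                 volume = hull_volume(P[keep, , drop = FALSE]),
                 reverted = reverted),
            class = "hull_summary")
}

#' @export
print.hull_summary <- function(x, ...) {
  cat("<hull_summary>", if (!is.na(x$class_label)) x$class_label else "",
      ": ", nrow(x$kept_points), " kept, ", nrow(x$removed_points),
      " removed, volume ", format(x$volume, digits = 5), " um^3",
      if (x$reverted) " (pruning reverted: <4 survivors)" else "",
      "\n", sep = "")
  invisible(x)
}

hull_of <- function(x) {
  if (inherits(x, "hull3d")) x
  else if (inherits(x, "hull_summary")) convex_hull_3d(x$kept_points)
  else convex_hull_3d(x)
}

#' Overlap ratio of two convex hulls
#'
#' Computes `vol(A intersect B) / vol(A union B)`. The intersection of two
#' convex polytopes is convex; its vertices are the vertices of either hull
#' inside the other plus the points where an edge of one hull crosses the
#' boundary of the other, so the exact volume is the hull volume of that
#' candidate set. The union follows by inclusion-exclusion. A seeded
#' Monte-Carlo estimator (rejection sampling in the overlapping bounding
#' box) is available as a fallback for ill-conditioned geometry and reports
#' its standard error.
#'
#' @param a,b `hull_summary`, `hull3d`, or n x 3 point matrices with
#'   positive hull volume.
#' @param method `"exact"` (default) or `"mc"`.
#' @param mc_samples Monte-Carlo sample count (default 1e5).
#' @param seed optional seed for the Monte-Carlo path.
#' @return List of class `hull_overlap`: `ratio` in `[0, 1]`,
#'   `vol_intersection`, `vol_union`, `vol_a`, `vol_b`, `method`, `se`
#'   (standard error of the ratio, `NA` for exact), `degenerate` (`TRUE`
#'   when no proper intersection volume exists, reported as ratio 0).
#' @export
hull_overlap <- function(a, b, method = c("exact", "mc"),
                         mc_samples = 1e5, seed = NULL) {
  method <- match.arg(method)
  ha <- hull_of(a); hb <- hull_of(b)
  if (ha$volume <= 0 || hb$volume <= 0) stop("zero-volume hull")
  tol <- max(ha$eps, hb$eps)
  if (method == "exact") {
    cand <- list()
    va <- ha$points[ha$vertices, , drop = FALSE]
    vb <- hb$points[hb$vertices, , drop = FALSE]
    ina <- va[apply(va, 1L, point_in_hull, hull = hb, tol = tol), ,
              drop = FALSE]
    inb <- vb[apply(vb, 1L, point_in_hull, hull = ha, tol = tol), ,
              drop = FALSE]
    cand <- rbind(ina, inb)
    for (pair in list(list(ha, hb), list(hb, ha))) {
      h1 <- pair[[1L]]; h2 <- pair[[2L]]
      ed <- hull_edges(h1)
      for (e in seq_len(nrow(ed))) {
        seg <- clip_segment(h1$points[ed[e, 1L], ], h1$points[ed[e, 2L], ],
                            h2, tol = tol)
        if (!is.null(seg)) cand <- rbind(cand, seg)
      }
    }
    vol_int <- if (is.null(cand) || nrow(cand) < 4L) 0 else hull_volume(cand)
    se <- NA_real_
  } else {
    if (!is.null(seed)) set.seed(seed)
    lo <- pmax(apply(ha$points[ha$vertices, , drop = FALSE], 2L, min),
               apply(hb$points[hb$vertices, , drop = FALSE], 2L, min))
    hi <- pmin(apply(ha$points[ha$vertices, , drop = FALSE], 2L, max),
               apply(hb$points[hb$vertices, , drop = FALSE], 2L, max))
    if (any(hi <= lo)) {
      vol_int <- 0; se <- 0
    } else {
      S <- cbind(runif(mc_samples, lo[1L], hi[1L]),
                 runif(mc_samples, lo[2L], hi[2L]),
                 runif(mc_samples, lo[3L], hi[3L]))
      inside <- vapply(seq_len(mc_samples), function(i) {
        point_in_hull(S[i, ], ha, tol) && point_in_hull(S[i, ], hb, tol)
      }, logical(1L))
      box <- prod(hi - lo)
      phat <- mean(inside)
      vol_int <- box * phat
      se <- box * sqrt(phat * (1 - phat) / mc_samples)
    }
  }
  vol_union <- ha$volume + hb$volume - vol_int
  structure(list(ratio = vol_int / vol_union,
                 vol_intersection = vol_int, vol_union = vol_union,
                 vol_a = ha$volume, vol_b = hb$volume,
                 method = method, se = se,
                 degenerate = vol_int <= 0),
            class = "hull_overlap")
}

#' @export
print.hull_overlap <- function(x, ...) {
  cat(sprintf("<hull_overlap> ratio = %.4f (intersection %.4g / union %.4g, %s%s)%s\n",
              x$ratio, x$vol_intersection, x$vol_union, x$method,
              if (!is.na(x$se)) sprintf(", se %.2g", x$se) else "",
              if (x$degenerate) " [degenerate: no overlap volume]" else ""))
  invisible(x)
}

#' Per-class soma layer distribution
#'
#' @param somata data frame with columns `class` and `layer` (one row per
#'   soma); rows with missing layer labels are counted and flagged.
#' @return Data frame `class`, `layer`, `n`, `pct` (percent within class,
#'   summing to 100 over labeled rows); attribute `"unlabeled"` holds the
#'   per-class count of missing labels.
#' @export
layer_distribution <- function(somata) {
  stopifnot(all(c("class", "layer") %in% names(somata)))
  miss <- is.na(somata$layer) | somata$layer == ""
  unl <- table(somata$class[miss])
  ok <- somata[!miss, , drop = FALSE]
  tab <- as.data.frame(table(class = ok$class, layer = ok$layer),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tab <- tab[tab$n > 0 | TRUE, , drop = FALSE]
  tot <- tapply(tab$n, tab$class, sum)
  tab$pct <- 100 * tab$n / as.numeric(tot[tab$class])
  attr(tab, "unlabeled") <- unl
  if (any(miss)) message(sum(miss), " soma(ta) with missing layer label flagged")
  tab
}
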