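segChildren <- function(segments, id) segments$id[segments$parent_id %in% id]

# path of segment ids from the root down to `id` (inclusive)
rootPath <- function(segments, id) {
  path <- id
  cur <- id
  repeat {
    p <- segments$parent_id[segments$id == cur]
    if (is.na(p)) break
    path <- c(p, path)
    cur <- p
  }
  path
}

#' Assign branch orders under the ex vivo or in vivo convention
#'
#' Ex vivo (immunohistochemistry) convention: the penetrating arteriole is
#' branch order 0 throughout; the first vessel branching off it is order 1,
#' incrementing by 1 at each subsequent bifurcation in the capillary bed.
#' In vivo convention: the arteriole carries its own counter, starting at 0
#' at the pial surface and incrementing after each capillary offshoot (so
#' its sections are PA0, PA1, ...); capillary orders are as in the ex vivo
#' convention (the first offshoot is always order 1).
#'
#' @param tree a [VesselTree-class] (validity guarantees a rooted acyclic
#'   graph).
#' @param convention `"ex_vivo"` or `"in_vivo"`.
#' @return The [VesselTree-class] with a `branch_order` column added to its
#'   segments.
#' @export
assignBranchOrders <- function(tree, convention = c("ex_vivo", "in_vivo")) {
  convention <- match.arg(convention)
  seg <- treeSegments(tree)
  orders <- integer(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    path <- rootPath(seg, seg$id[i])
    is_pa_path <- seg$is_pa[match(path, seg$id)]
    if (seg$is_pa[i]) {
      if (convention == "ex_vivo") {
        orders[i] <- 0L
      } else {
        # sections increment after each offshoot encountered above
        above <- path[-length(path)]
        orders[i] <- sum(vapply(above, function(a) {
          kids <- segChildren(seg, a)
          any(!seg$is_pa[match(kids, seg$id)])
        }, logical(1)))
      }
    } else {
      orders[i] <- sum(!is_pa_path)  # capillary segments on the root path
    }
  }
  seg$branch_order <- orders
  methods::initialize(tree, segments = seg)
}

#' Inter-soma distances along one vessel segment
#'
#' For each soma beyond the most proximal one, the straight-line distance
#' (in the measurement plane) to the nearest more-proximal soma on the same
#' segment, scaled to micrometres.
#'
#' @param somata data.frame with columns `x`, `y` (pixel units) and
#'   optionally `pos` giving the proximal-to-distal ordering (defaults to
#'   row order).
#' @param pixel_size_um micrometres per pixel (default 1: coordinates
#'   already in um).
#' @return Numeric vector of ISD values (um), one per non-proximal soma;
#'   empty for a lone soma.
#' @examples
#' measureISD(data.frame(x = c(0, 3), y = c(0, 4)))  # 5
#' @export
measureISD <- function(somata, pixel_size_um = 1) {
  n <- nrow(somata)
  if (is.null(n) || n < 2) return(numeric(0))
  ord <- if ("pos" %in% names(somata)) order(somata$pos) else seq_len(n)
  x <- somata$x[ord]; y <- somata$y[ord]
  vapply(2:n, function(i) {
    min(sqrt((x[i] - x[seq_len(i - 1)])^2 +
             (y[i] - y[seq_len(i - 1)])^2)) * pixel_size_um
  }, numeric(1))
}

segmentISDs <- function(tree, segment_id) {
  so <- treeSomata(tree)
  so <- so[so$segment_id == segment_id, , drop = FALSE]
  if (nrow(so) < 2) return(numeric(0))
  measureISD(data.frame(x = so$x_um, y = so$y_um, pos = so$pos_um))
}

#' Vessel diameter at a position along a segment
#'
#' Returns the wall-to-wall diameter at `position_um` along the segment's
#' path. If the segment carries a linear taper (`diameter0_um`,
#' `diameter1_um` columns) the diameter is interpolated; otherwise the
#' segment diameter is constant. A position coinciding with a branch point
#' at either end of the segment returns that branch point's locally
#' measured diameter.
#'
#' @param tree a [VesselTree-class].
#' @param segment_id segment identifier.
#' @param position_um distance from the segment's proximal end, um.
#' @param tol_um tolerance for matching a branch-point position (default
#'   1e-6).
#' @return Diameter in micrometres.
#' @export
measureDiameter <- function(tree, segment_id, position_um, tol_um = 1e-6) {
  seg <- treeSegments(tree)
  i <- match(segment_id, seg$id)
  if (is.na(i)) stop("unknown segment: ", segment_id)
  len <- seg$length_um[i]
  if (position_um < 0 || position_um > len)
    stop("position ", position_um, " um outside segment of length ", len)
  bp <- treeBranchPoints(tree)
  if (nrow(bp)) {
    at_distal <- abs(position_um - len) <= tol_um & bp$parent_segment == segment_id
    kids_lists <- strsplit(bp$child_segments, ",", fixed = TRUE)
    at_proximal <- abs(position_um) <= tol_um &
      vapply(kids_lists, function(k) segment_id %in% k, logical(1))
    hit <- which(at_distal | at_proximal)
    if (length(hit)) return(bp$local_diameter_um[hit[1]])
  }
  if (all(c("diameter0_um", "diameter1_um") %in% names(seg))) {
    d0 <- seg$diameter0_um[i]; d1 <- seg$diameter1_um[i]
    if (!is.na(d0) && !is.na(d1))
      return(d0 + (d1 - d0) * position_um / len)
  }
  seg$diameter_um[i]
}

# Marker-presence threshold: background mean + 2 SD (configurable upstream).
markerThreshold <- function(tree) {
  bg <- tree@backgroundIntensity
  unname(bg["mean"] + 2 * bg["sd"])
}

# Main analysis path from the root toward the capillary bed: at each
# junction prefer capillary children (marker-positive ones first), only
# descending the arteriole when no capillary child exists.
mainLabeledPath <- function(tree, positive) {
  seg <- treeSegments(tree)
  root <- seg$id[is.na(seg$parent_id)]
  path <- root
  cur <- root
  repeat {
    kids <- segChildren(seg, cur)
    if (!length(kids)) break
    is_cap <- !seg$is_pa[match(kids, seg$id)]
    pool <- if (any(is_cap)) kids[is_cap] else kids
    pos <- pool[positive[match(pool, seg$id)]]
    nxt <- if (length(pos)) pos[1] else pool[1]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Marker termination point and the surrounding ISD profile
#'
#' Walks distally from the root along the main path toward the capillary
#' bed and finds the most distal position at which the marker signal is
#' above threshold; reports the branch order (ex vivo convention), vessel
#' diameter and inter-soma distance there, plus the ISDs at soma offsets
#' -2..+2 around the termination normalized to the ISD at the termination
#' (offset 0), so the profile at offset 0 is exactly 1.
#'
#' @param tree a [VesselTree-class].
#' @param marker marker name present in the tree's annotations.
#' @param threshold presence threshold on the marker intensity; defaults to
#'   the tree's background mean + 2 background SD.
#' @return A list with `status` (`"ok"`, `"no_termination"` when the marker
#'   is present to the end of the field, `"absent"` when present nowhere),
#'   `termination` (data.frame: `marker`, `branch_order`, `diameter_um`,
#'   `isd_um`) and `offsets` (data.frame: `offset`, `isd_um`, `isd_norm`;
#'   offsets beyond the data are omitted).
#' @export
terminationProfile <- function(tree, marker, threshold = NULL) {
  mk <- markerAnnotations(tree)
  mk <- mk[mk$marker == marker, , drop = FALSE]
  if (!nrow(mk)) stop("marker '", marker, "' not annotated on this tree")
  if (is.null(threshold)) threshold <- markerThreshold(tree)
  seg <- treeSegments(tree)
  positive <- mk$intensity[match(seg$id, mk$segment_id)] > threshold
  if (!any(positive)) return(list(status = "absent", termination = NULL,
                                  offsets = NULL))
  path <- mainLabeledPath(tree, positive)
  pos_on_path <- positive[match(path, seg$id)]
  if (!pos_on_path[1])
    return(list(status = "absent", termination = NULL, offsets = NULL))
  k <- max(which(pos_on_path))
  if (k == length(path) || all(pos_on_path))
    return(list(status = "no_termination", termination = NULL,
                offsets = NULL))

  ord_tree <- assignBranchOrders(tree, "ex_vivo")
  orders <- treeSegments(ord_tree)$branch_order
  term_seg <- path[k]
  term_order <- orders[match(term_seg, seg$id)]
  term_diam <- seg$diameter_um[match(term_seg, seg$id)]

  # soma sequence along the path with cumulative positions and ISDs;
  # junction-spanning pairs use the branch point's locally measured ISD
  so <- treeSomata(tree)
  bp <- treeBranchPoints(tree)
  cum <- 0
  soma_pos <- numeric(0); soma_seg <- character(0)
  isd <- numeric(0)  # isd[j]: distance from soma j to its proximal neighbor
  for (j in seq_along(path)) {
    s <- so[so$segment_id == path[j], , drop = FALSE]
    s <- s[order(s$pos_um), , drop = FALSE]
    if (nrow(s)) {
      d_within <- if (nrow(s) > 1)
        sqrt(diff(s$x_um)^2 + diff(s$y_um)^2) else numeric(0)
      if (length(soma_pos)) {
        # spanning ISD at the junction between path[j-1] and path[j]
        hit <- which(bp$parent_segment == path[j - 1] &
                     vapply(strsplit(bp$child_segments, ",", fixed = TRUE),
                            function(kk) path[j] %in% kk, logical(1)))
        span <- if (length(hit)) bp$local_isd_um[hit[1]] else NA_real_
        isd <- c(isd, span, d_within)
      } else {
        isd <- c(isd, NA_real_, d_within)  # first soma has no proximal pair
      }
      soma_pos <- c(soma_pos, cum + s$pos_um)
      soma_seg <- c(soma_seg, rep(path[j], nrow(s)))
    }
    cum <- cum + seg$length_um[match(path[j], seg$id)]
  }
  term_cum <- sum(seg$length_um[match(path[seq_len(k)], seg$id)])
  # ISD "at" the termination: the soma pair spanning the termination point,
  # i.e. the first soma distal to it paired with its closest proximal soma
  i0 <- which(soma_pos > term_cum + 1e-9)[1]
  if (is.na(i0)) i0 <- which.min(abs(soma_pos - term_cum))
  if (is.na(isd[i0]) || isd[i0] == 0)
    return(list(status = "ok",
                termination = data.frame(marker = marker,
                                         branch_order = term_order,
                                         diameter_um = term_diam,
                                         isd_um = NA_real_),
                offsets = NULL))
  offs <- -2:2
  idx <- i0 + offs
  ok <- idx >= 1 & idx <= length(isd)
  offsets <- data.frame(offset = offs[ok], isd_um = isd[idx[ok]])
  offsets <- offsets[!is.na(offsets$isd_um), , drop = FALSE]
  offsets$isd_norm <- offsets$isd_um / isd[i0]
  list(status = "ok",
       termination = data.frame(marker = marker, branch_order = term_order,
                                diameter_um = term_diam, isd_um = isd[i0]),
       offsets = offsets)
}

#' Branch-point specialization ratios
#'
#' For every branch point with measurable neighbors on both its parent and
#' at least one daughter: the ratio of the locally measured branch-point
#' diameter to the mean of the adjacent upstream and downstream diameters
#' (downstream values averaged over daughters), and the analogous ratio for
#' the inter-soma distance, where the branch-point ISD is the soma pair
#' spanning the bifurcation and the neighbor ISDs are the mean soma
#' spacings on the parent and daughter segments.
#'
#' @param tree a [VesselTree-class].
#' @return data.frame with one row per measurable branch point:
#'   `branch_point`, `diameter_ratio`, `isd_ratio`, `local_diameter_um`,
#'   `local_isd_um`. Skipped branch points (missing neighbor measurements)
#'   are recorded in the `"skipped"` attribute with a reason.
#' @export
branchPointRatios <- function(tree) {
  seg <- treeSegments(tree)
  bp <- treeBranchPoints(tree)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(bp))) {
    par <- bp$parent_segment[i]
    kids <- strsplit(bp$child_segments[i], ",", fixed = TRUE)[[1]]
    up_d <- seg$diameter_um[match(par, seg$id)]
    down_d <- mean(seg$diameter_um[match(kids, seg$id)])
    up_isd <- segmentISDs(tree, par)
    kid_isds <- lapply(kids, segmentISDs, tree = tree)
    have_kid <- vapply(kid_isds, function(x) length(x) > 0, logical(1))
    if (!length(up_isd)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        branch_point = bp$id[i], reason = "no ISD measurable upstream")
      next
    }
    if (!any(have_kid)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        branch_point = bp$id[i], reason = "no ISD measurable downstream")
      next
    }
    down_isd <- mean(vapply(kid_isds[have_kid], mean, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      branch_point = bp$id[i],
      diameter_ratio = bp$local_diameter_um[i] / ((up_d + down_d) / 2),
      isd_ratio = bp$local_isd_um[i] / ((mean(up_isd) + down_isd) / 2),
      local_diameter_um = bp$local_diameter_um[i],
      local_isd_um = bp$local_isd_um[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch_point = character(), diameter_ratio = numeric(),
               isd_ratio = numeric(), local_diameter_um = numeric(),
               local_isd_um = numeric())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(branch_point = character(), reason = character())
  out
}

#' Perivascular intensity profile around labeled vessels
#'
#' Measures the mean image intensity in annular shells at increasing
#' distances from each labeled vessel and normalizes every value to the
#' at-vessel (distance 0) intensity of the order-0 vessel (the penetrating
#' arteriole), as used to quantify perivascular marker expression by branch
#' order.
#'
#' @param image numeric matrix of intensities.
#' @param mask integer matrix of the same size: `NA` outside vessels,
#'   branch order (0, 1, 2, ...) on vessel pixels.
#' @param distances_um numeric distances of the shell centres from the
#'   vessel boundary (must include 0, the at-vessel shell).
#' @param pixel_size_um micrometres per pixel.
#' @param shell_width_um annulus width; defaults to the spacing of
#'   `distances_um` (or one pixel for a single distance).
#' @return data.frame: `branch_order`, `distance_um`, `intensity`,
#'   `intensity_norm`. Empty shells are omitted.
#' @export
perivascularIntensityProfile <- function(image, mask, distances_um,
                                         pixel_size_um = 1,
                                         shell_width_um = NULL) {
  stopifnot(all(dim(image) == dim(mask)))
  if (!0 %in% distances_um)
    stop("distances_um must include 0 (the at-vessel shell)")
  if (is.null(shell_width_um))
    shell_width_um <- if (length(distances_um) > 1)
      min(diff(sort(distances_um))) else pixel_size_um
  orders <- sort(unique(mask[!is.na(mask)]))
  if (!0 %in% orders) stop("mask must contain an order-0 vessel")
  h <- nrow(image); w <- ncol(image)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  rows <- list()
  for (o in orders) {
    sel <- which(!is.na(mask) & mask == o)
    vx <- xs[sel]; vy <- ys[sel]
    # distance (um) of every pixel to the nearest pixel of this vessel
    dmat <- matrix(Inf, h, w)
    for (j in seq_along(vx)) {
      d <- sqrt((xs - vx[j])^2 + (ys - vy[j])^2)
      dmat <- pmin(dmat, d)
    }
    dmat <- dmat * pixel_size_um
    for (d0 in distances_um) {
      inshell <- dmat >= d0 - shell_width_um / 2 &
                 dmat < d0 + shell_width_um / 2
      if (!any(inshell)) next
      rows[[length(rows) + 1L]] <- data.frame(
        branch_order = o, distance_um = d0,
        intensity = mean(image[inshell]))
    }
  }
  out <- do.call(rbind, rows)
  ref <- out$intensity[out$branch_order == 0 & out$distance_um == 0]
  if (!length(ref) || ref == 0)
    stop("order-0 at-vessel intensity unavailable for normalization")
  out$intensity_norm <- out$intensity / ref
  out
}
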