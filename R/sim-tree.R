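rotate2d <- function(v, angle) {
  c(cos(angle) * v[1] - sin(angle) * v[2],
    sin(angle) * v[1] + cos(angle) * v[2])
}

#' Simulate a vascular tree with mural-cell somata and marker annotations
#'
#' Builds a rooted tree emulating a penetrating arteriole (PA) and its
#' capillary bed: the PA descends as a chain of sections separated by
#' capillary offshoots; each offshoot bifurcates repeatedly up to the
#' configured maximum branch order. Segment diameters follow
#' `diameter_by_order_um` and the spacing of somata on each segment follows
#' `isd_by_order_um` (order 0 = the arteriole). At every branch point the
#' locally measured diameter is `branch_diameter_ratio` times the mean of
#' the adjacent upstream and downstream diameters, and the inter-soma
#' distance of the soma pair spanning the bifurcation is `branch_isd_ratio`
#' times the mean of the adjacent upstream and downstream ISDs (downstream
#' values averaged over daughters). Molecular markers are present on all
#' segments whose immunohistochemistry-convention branch order is at most
#' the configured termination order, at a fixed signal intensity well above
#' the stored background.
#'
#' With `soma_jitter_frac = 0` (the default) the tree is fully
#' deterministic, so configured ratios and spacings are recovered exactly by
#' the morphometry operations.
#'
#' @param p a [treeSimParams()] object.
#' @return A [VesselTree-class]. Segments carry ground-truth columns
#'   `order_cap` (capillary branch order, NA on the arteriole) and
#'   `pa_index` (arteriole section index, NA on capillaries).
#' @examples
#' tree <- makeVesselTree(treeSimParams())
#' nrow(treeBranchPoints(tree))   # 24 with the defaults
#' @export
makeVesselTree <- function(p) {
  stopifnot(inherits(p, "TreeSimParams"))
  isdO <- function(o) p$isd_by_order_um[o + 1]
  diaO <- function(o) p$diameter_by_order_um[o + 1]
  rI <- p$branch_isd_ratio; rD <- p$branch_diameter_ratio
  nsoma <- p$somata_per_segment
  jit <- p$soma_jitter_frac

  env <- new.env()
  env$segments <- list(); env$somata <- list(); env$bps <- list()
  env$cap_id <- 0L; env$soma_id <- 0L; env$bp_id <- 0L

  addSegment <- function(id, parent, is_pa, pa_index, order_cap,
                         start, dir, len, diameter) {
    end <- start + dir * len
    env$segments[[length(env$segments) + 1L]] <- data.frame(
      id = id, parent_id = if (is.null(parent)) NA_character_ else parent,
      is_pa = is_pa, pa_index = pa_index, order_cap = order_cap,
      x0 = start[1], y0 = start[2], x1 = end[1], y1 = end[2],
      length_um = len, diameter_um = diameter, stringsAsFactors = FALSE)
    end
  }
  addSomata <- function(segment_id, start, dir, positions, isd_here, len) {
    if (jit > 0)
      positions <- pmin(pmax(positions +
        stats::runif(length(positions), -jit, jit) * isd_here, 0.1), len - 0.1)
    for (pos in positions) {
      env$soma_id <- env$soma_id + 1L
      xy <- start + dir * pos
      env$somata[[length(env$somata) + 1L]] <- data.frame(
        id = sprintf("s%03d", env$soma_id), segment_id = segment_id,
        pos_um = pos, x_um = xy[1], y_um = xy[2], stringsAsFactors = FALSE)
    }
  }
  addBranchPoint <- function(at, parent_seg, children, local_d, local_isd) {
    env$bp_id <- env$bp_id + 1L
    env$bps[[length(env$bps) + 1L]] <- data.frame(
      id = sprintf("bp%03d", env$bp_id), x_um = at[1], y_um = at[2],
      parent_segment = parent_seg,
      child_segments = paste(children, collapse = ","),
      local_diameter_um = local_d, local_isd_um = local_isd,
      stringsAsFactors = FALSE)
  }

  # local (branch-point) values: ratio x mean(upstream, mean(downstream))
  paJunctionISD <- rI * (isdO(0) + (isdO(0) + isdO(1)) / 2) / 2
  paJunctionD <- rD * (diaO(0) + (diaO(0) + diaO(1)) / 2) / 2
  capBifISD <- function(o) rI * (isdO(o) + isdO(o + 1)) / 2
  capBifD <- function(o) rD * (diaO(o) + diaO(o + 1)) / 2

  buildCap <- function(parent_id, origin, dir, o, proximal_isd) {
    env$cap_id <- env$cap_id + 1L
    id <- sprintf("C%03d", env$cap_id)
    b <- proximal_isd / 2
    bifurcate <- o < p$max_branch_order
    a <- if (bifurcate) capBifISD(o) / 2 else isdO(o) / 2
    len <- b + (nsoma - 1) * isdO(o) + a
    end <- addSegment(id, parent_id, FALSE, NA_integer_, o,
                      origin, dir, len, diaO(o))
    addSomata(id, origin, dir, b + (0:(nsoma - 1)) * isdO(o), isdO(o), len)
    if (bifurcate) {
      kids <- c(buildCap(id, end, rotate2d(dir, 0.6), o + 1, capBifISD(o)),
                buildCap(id, end, rotate2d(dir, -0.6), o + 1, capBifISD(o)))
      addBranchPoint(end, id, kids, capBifD(o), capBifISD(o))
    }
    id
  }

  build <- function() {
    pa_dir <- c(0, -1)
    pos <- c(0, 0)
    prev_id <- NULL
    side <- 1
    for (k in 0:p$n_offshoots) {
      id <- sprintf("PA%d", k)
      b <- if (k == 0) isdO(0) / 2 else paJunctionISD / 2
      a <- if (k < p$n_offshoots) paJunctionISD / 2 else isdO(0) / 2
      len <- b + (nsoma - 1) * isdO(0) + a
      end <- addSegment(id, prev_id, TRUE, k, NA_integer_,
                        pos, pa_dir, len, diaO(0))
      addSomata(id, pos, pa_dir, b + (0:(nsoma - 1)) * isdO(0), isdO(0), len)
      if (k < p$n_offshoots) {
        off_dir <- rotate2d(pa_dir, side * 1.2)
        side <- -side
        off_id <- buildCap(id, end, off_dir, 1L, paJunctionISD)
        next_id <- sprintf("PA%d", k + 1)
        addBranchPoint(end, id, c(next_id, off_id), paJunctionD, paJunctionISD)
      }
      prev_id <- id
      pos <- end
    }
  }
  if (jit > 0) withSeed(p$rng_seed, build()) else build()

  segments <- do.call(rbind, env$segments)
  somata <- do.call(rbind, env$somata)
  bps <- do.call(rbind, env$bps)

  # immunohistochemistry convention: arteriole order 0, capillary order as-is
  ihc_order <- ifelse(segments$is_pa, 0L, segments$order_cap)
  bg_mean <- 10; bg_sd <- 2; signal <- 100
  markers <- do.call(rbind, lapply(names(p$marker_termination_orders),
    function(m) {
      term <- p$marker_termination_orders[[m]]
      data.frame(marker = m, segment_id = segments$id,
                 intensity = ifelse(ihc_order <= term, signal, bg_mean),
                 stringsAsFactors = FALSE)
    }))

  new("VesselTree", segments = segments, somata = somata,
      branchPoints = bps, markers = markers,
      backgroundIntensity = c(mean = bg_mean, sd = bg_sd))
}
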