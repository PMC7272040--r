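#' Detect physical refuges (crevices and overhangs) along a cross-section
#'
#' A refuge is sized to the average herbivorous fish, represented by a disc
#' of `gauge` diameter (10 cm). Crevices are concave notches whose rim
#' opening width lies within `crevice_width`, whose vertical depth is at
#' least `min_feature`, and into which the gauge disc fits without
#' intersecting the terrain. Because single-valued cross-sections cannot
#' capture undercuts, overhangs are proxied by near-vertical surfaces:
#' maximal monotone runs of the profile with local inclination of at least
#' `wall_angle` degrees and vertical extent of at least `min_feature` that
#' are not the walls of a counted crevice.
#'
#' Candidate crevices are sharp local minima: points whose two-sided local
#' prominence (the lower of the highest terrain within `candidate_window` on
#' each side, minus the floor) reaches `min_feature`. For each candidate the
#' notch is delimited by the highest water level at which the flooded region
#' around the floor is still no wider than the maximum crevice width; the
#' opening width is measured at that level (the shallower rim shoulder).
#' This keeps a conforming notch detectable even when it is carved inside a
#' broader natural depression. Two crevices separated by less than the gauge
#' diameter merge into a single candidate, since one disc placement cannot
#' distinguish them.
#'
#' @param profile A [reef_profile()].
#' @param gauge Disc diameter in metres (default 0.10).
#' @param crevice_width Allowed rim opening widths, `c(min, max)` in metres.
#' @param min_feature Minimum crevice depth / overhang height in metres.
#' @param wall_angle Minimum inclination (degrees from horizontal) for a
#'   surface to count as a wall/overhang.
#' @param candidate_window Half-width (m) of the prominence window used to
#'   nominate crevice floors; slightly wider than the widest crevice.
#' @return An object of class `refuge_set`: a list with tibbles `crevices`
#'   (`x`, `width`, `depth`) and `overhangs` (`x`, `height`).
#' @export
#' @examples
#' p <- generate_profile(default_archetypes()$inner_flat, seed = 2)
#' p <- insert_crevice(p, 2, width = 0.15, depth = 0.12)
#' detect_refuges(p)$crevices
detect_refuges <- function(profile, gauge = 0.10,
                           crevice_width = c(0.10, 0.20),
                           min_feature = 0.10, wall_angle = 80,
                           candidate_window = 0.25) {
  x <- profile$x
  z <- profile$z
  n <- length(x)
  res <- attr(profile, "resolution") %||% stats::median(diff(x))
  tol <- 1e-9
  K <- max(2L, ceiling(candidate_window / res))

  # --- crevice candidates: sharp, two-sided prominent local minima ---------
  left_max <- running_extreme(z, K, "left")
  right_max <- running_extreme(z, K, "right")
  prominence <- pmin(left_max, right_max) - z
  cand <- which(prominence >= min_feature - tol)
  crevices <- tibble::tibble(x = numeric(), width = numeric(), depth = numeric(),
                             .i_lo = integer(), .i_hi = integer())
  if (length(cand)) {
    found <- list()
    taken <- matrix(numeric(0), ncol = 2)
    for (i in cand) {
      if (nrow(taken) && any(x[i] >= taken[, 1] & x[i] <= taken[, 2])) next
      notch <- delimit_notch(x, z, i, crevice_width[2], pmin(left_max, right_max)[i])
      if (is.null(notch)) next
      taken <- rbind(taken, c(x[notch$i_lo], x[notch$i_hi]))
      if (notch$width < crevice_width[1] - tol ||
          notch$width > crevice_width[2] + tol) next
      if (notch$depth < min_feature - tol) next
      if (!disc_fits(x, z, notch$i_lo:notch$i_hi, notch$level, gauge)) next
      found[[length(found) + 1L]] <- tibble::tibble(
        x = (x[notch$i_lo] + x[notch$i_hi]) / 2,
        width = notch$width, depth = notch$depth,
        .i_lo = notch$i_lo, .i_hi = notch$i_hi
      )
    }
    if (length(found)) {
      crevices <- dplyr::arrange(dplyr::bind_rows(found), .data$x)
      # merge detections separated by less than the gauge diameter
      if (nrow(crevices) > 1L) {
        gap <- crevices$x[-1] - (crevices$x[-nrow(crevices)] +
                                   crevices$width[-nrow(crevices)] / 2 +
                                   crevices$width[-1] / 2)
        grp <- cumsum(c(1, as.integer(gap >= gauge)))
        crevices <- dplyr::summarise(
          dplyr::group_by(crevices, grp = grp),
          x = mean(.data$x), width = sum(.data$width), depth = max(.data$depth),
          .i_lo = min(.data$.i_lo), .i_hi = max(.data$.i_hi), .groups = "drop"
        )[-1]
        crevices <- crevices[crevices$width >= crevice_width[1] - tol &
                               crevices$width <= crevice_width[2] + tol, ]
      }
    }
  }

  # --- overhangs: near-vertical monotone runs -------------------------------
  slope <- diff(z) / diff(x)
  steep <- abs(slope) >= tan(wall_angle * pi / 180)
  sgn <- sign(slope) * steep
  overhangs <- tibble::tibble(x = numeric(), height = numeric())
  if (any(steep)) {
    runs <- rle(sgn)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    found <- list()
    for (j in which(runs$values != 0)) {
      i0 <- starts[j]
      i1 <- ends[j] + 1L  # run endpoints in sample indices
      extent <- abs(z[i1] - z[i0])
      if (extent < min_feature - tol) next
      if (nrow(crevices) > 0L &&
          any(x[i0] <= x[crevices$.i_hi] + gauge / 2 &
                x[i1] >= x[crevices$.i_lo] - gauge / 2)) next
      found[[length(found) + 1L]] <- tibble::tibble(
        x = (x[i0] + x[i1]) / 2, height = extent
      )
    }
    if (length(found)) overhangs <- dplyr::bind_rows(found)
  }
  crevices <- crevices[setdiff(names(crevices), c(".i_lo", ".i_hi"))]
  structure(list(crevices = crevices, overhangs = overhangs), class = "refuge_set")
}

# Highest terrain within K samples to one side of each point (excluding the
# point itself).
running_extreme <- function(z, K, side) {
  n <- length(z)
  out <- rep(-Inf, n)
  if (side == "left") {
    for (lag in seq_len(min(K, n - 1L))) {
      idx <- (lag + 1L):n
      out[idx] <- pmax(out[idx], z[idx - lag])
    }
  } else {
    for (lag in seq_len(min(K, n - 1L))) {
      idx <- seq_len(n - lag)
      out[idx] <- pmax(out[idx], z[idx + lag])
    }
  }
  out
}

# Delimit the notch around floor index i: the highest level L at which the
# flooded region containing i is still no wider than `width_max`. Returns
# the region, its width at that level, and depth below it.
delimit_notch <- function(x, z, i, width_max, rim_cap) {
  lo <- z[i]
  hi <- min(rim_cap, z[i] + 5)
  if (hi <= lo) return(NULL)
  flood <- function(L) {
    a <- i
    while (a > 1L && z[a - 1L] < L) a <- a - 1L
    b <- i
    n <- length(z)
    while (b < n && z[b + 1L] < L) b <- b + 1L
    c(a, b)
  }
  for (iter in 1:45) {
    mid <- (lo + hi) / 2
    ab <- flood(mid)
    if (x[ab[2]] - x[ab[1]] <= width_max) lo <- mid else hi <- mid
  }
  ab <- flood(lo)
  width <- x[ab[2]] - x[ab[1]]
  if (width <= 0) return(NULL)
  list(i_lo = ab[1], i_hi = ab[2], level = lo, width = width,
       depth = lo - min(z[ab[1]:ab[2]]))
}

# Can a disc of diameter `gauge` sit inside the notch `idx` below the level
# `level` without intersecting terrain? Checked over candidate centres at
# every sample of the notch.
disc_fits <- function(x, z, idx, level, gauge) {
  r <- gauge / 2
  for (ci in idx) {
    cx <- x[ci]
    win <- which(abs(x - cx) <= r)
    dx <- x[win] - cx
    need <- z[win] + sqrt(pmax(0, r^2 - dx^2))
    cz <- max(need)
    if (cz + r <= level + 1e-9) return(TRUE)
  }
  FALSE
}

#' @export
print.refuge_set <- function(x, ...) {
  cat("<refuge_set> ", nrow(x$crevices), " crevice(s), ",
      nrow(x$overhangs), " overhang(s)\n", sep = "")
  invisible(x)
}
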