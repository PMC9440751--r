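#' Planar wing outline model
#'
#' A rigid flat-plate wing described by 41 planar outline coordinates in the
#' wing-local frame: x spanwise from the hinge (at the local origin) toward
#' the tip, y chordwise. Real wings deform during the stroke; the flat-plate
#' simplification keeps the blade-element geometry tractable.
#'
#' @param outline 41 x 2 matrix of outline coordinates (m); the hinge must lie
#'   at the local origin (the outline must touch (0, 0))
#' @return object of class \code{wing_model} with elements \code{outline},
#'   \code{span} (m), \code{tip} (outline point farthest along the span) and
#'   \code{area} (m^2)
#' @export
wing_model <- function(outline) {
  outline <- rbind(outline)
  if (nrow(outline) != 41 || ncol(outline) != 2)
    stop("a wing model needs exactly 41 planar outline points")
  if (any(!is.finite(outline))) stop("non-finite outline coordinates")
  if (min(sqrt(rowSums(outline^2))) > 1e-9)
    stop("the wing hinge must lie at the local origin")
  span <- max(outline[, 1])
  if (span <= 0) stop("wing span must be positive (tip along +x)")
  tip <- outline[which.max(outline[, 1]), ]
  area <- abs(sum(outline[, 1] * c(outline[-1, 2], outline[1, 2]) -
                  c(outline[-1, 1], outline[1, 1]) * outline[, 2])) / 2
  structure(list(outline = outline, span = span, tip = tip, area = area),
            class = "wing_model")
}

#' @export
print.wing_model <- function(x, ...) {
  cat("Wing model: span", signif(x$span, 4), "m, area",
      signif(x$area * 1e4, 4), "cm^2 (41 outline points)\n")
  invisible(x)
}

#' Generate a synthetic elliptical wing outline
#'
#' Convenience constructor for tests and simulations: a 41-point outline of a
#' (half-)elliptic planform with the hinge at the origin and the tip at
#' (span, 0). With \code{symmetric = TRUE} the chord is centred on the span
#' axis (so blade-element area centroids have zero chordwise offset), which is
#' the convenient geometry for closed-form checks; otherwise the planform is
#' offset toward the trailing edge, loosely resembling a butterfly forewing.
#'
#' @param span hinge-to-tip length (m)
#' @param chord maximum chord (m)
#' @param symmetric logical, see above
#' @return \code{wing_model}
#' @export
synthetic_wing_outline <- function(span = 0.06, chord = 0.04,
                                   symmetric = FALSE) {
  # 41 points: hinge -> tip along the leading edge (22 points, endpoints
  # exactly at (0,0) and (span,0)), then 19 interior trailing-edge points back
  t_up <- seq(0, pi, length.out = 22)
  t_lo <- seq(pi, 2 * pi, length.out = 21)[-c(1, 21)]
  t <- c(t_up, t_lo)
  x <- span / 2 * (1 - cos(t))
  y <- (chord / 2) * sin(t)
  if (!symmetric) y <- y - (chord / 4) * sin(pi * pmin(1, x / span))
  wing_model(cbind(x, y))
}

#' Read a wing outline from a 2-column coordinate text file
#'
#' @param path text file with 41 rows and two columns (x, y in metres),
#'   whitespace- or comma-separated, no header
#' @return \code{wing_model}
#' @export
read_wing_outline <- function(path) {
  first <- readLines(path, n = 1)
  sepc <- if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sepc, header = FALSE))
  wing_model(m)
}

#' Blade-element geometry of a wing model
#'
#' Divides the wing into \code{n_elements} equal spanwise strips and computes
#' each strip's area, area-centroid spanwise position and area-centroid
#' chordwise offset by integrating the chord profile of the outline polygon.
#'
#' @param wing a \code{wing_model}
#' @param n_elements number of spanwise elements (10 is the conventional
#'   choice)
#' @return data.frame with columns \code{element}, \code{r} (spanwise
#'   centroid, m), \code{c} (chordwise centroid offset, m), \code{area} (m^2)
#' @export
blade_elements <- function(wing, n_elements = 10) {
  stopifnot(inherits(wing, "wing_model"), n_elements >= 1)
  P <- wing$outline
  edges <- cbind(P, rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE]))
  chord_at <- function(r) {
    ys <- numeric(0)
    for (i in seq_len(nrow(edges))) {
      x1 <- edges[i, 1]; y1 <- edges[i, 2]; x2 <- edges[i, 3]; y2 <- edges[i, 4]
      if ((x1 - r) * (x2 - r) <= 0 && x1 != x2) {
        tt <- (r - x1) / (x2 - x1)
        ys <- c(ys, y1 + tt * (y2 - y1))
      }
    }
    if (length(ys) < 2) return(c(0, 0))
    c(max(ys) - min(ys), (max(ys) + min(ys)) / 2)
  }
  br <- seq(0, wing$span, length.out = n_elements + 1)
  out <- do.call(rbind, lapply(seq_len(n_elements), function(e) {
    rs <- seq(br[e], br[e + 1], length.out = 21)
    # keep stations strictly inside the strip to avoid edge degeneracies
    rs <- rs + c(1e-9, rep(0, 19), -1e-9) * wing$span
    cw <- t(vapply(rs, chord_at, numeric(2)))
    w <- cw[, 1]
    area <- sum((w[-1] + w[-21]) / 2 * diff(rs))
    if (area <= 0) {
      rc <- mean(rs); cc <- 0
    } else {
      rc <- sum((w[-1] * rs[-1] + w[-21] * rs[-21]) / 2 * diff(rs)) / area
      mid <- cw[, 2]
      cc <- sum((w[-1] * mid[-1] + w[-21] * mid[-21]) / 2 * diff(rs)) / area
    }
    data.frame(element = e, r = rc, c = cc, area = area)
  }))
  rownames(out) <- NULL
  out
}
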