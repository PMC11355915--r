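#' Rotate and rescale a persistence diagram
#'
#' Re-expresses each (birth, death) point as its mean age
#' `m = (birth + death) / 2` and lifetime `l = death - birth` — the rotated
#' and rescaled persistence diagram (RRPD). Requires every death to be
#' finite, i.e. the essential-class convention must already have been
#' applied (see [compute_persistence()]).
#'
#' @param pd A `reva_pd` tibble.
#' @return A tibble of class `reva_rrpd` with columns `dim`, `mean_age`,
#'   `lifetime`.
#' @examples
#' pd <- compute_persistence(matrix(c(0, 2, 1), 1, 3), dim = 0)
#' rrpd(pd)
#' @export
rrpd <- function(pd) {
  if (any(!is.finite(pd$death)))
    abort("diagram contains non-finite deaths; apply the essential-class convention first.")
  out <- tibble(dim = pd$dim,
                mean_age = (pd$birth + pd$death) / 2,
                lifetime = pd$death - pd$birth)
  structure(out, class = c("reva_rrpd", class(tibble())),
            transform = attr(pd, "transform"))
}

#' Accumulative persistence function
#'
#' The APF of an RRPD is the right-continuous non-decreasing step function
#' `APF(m) = sum of lifetimes of points with mean age <= m`. Points sharing a
#' mean age are merged into a single step. The curve is stored as its
#' breakpoints `(m, value)`; before the first breakpoint the value is 0 and
#' at or after the last it equals the total lifetime sum.
#'
#' @param r A `reva_rrpd` tibble (or a `reva_pd`, converted via [rrpd()]).
#' @param side Optional label, `"left"` or `"right"`.
#' @return A tibble of class `reva_apf` with columns `m`, `value` and
#'   attributes `homology_dim`, `side`, `transform`.
#' @examples
#' pd <- compute_persistence(matrix(c(0, 2, 1), 1, 3), dim = 0)
#' apf_curve(rrpd(pd))
#' @export
apf_curve <- function(r, side = NA_character_) {
  if (inherits(r, "reva_pd")) r <- rrpd(r)
  dim <- if (nrow(r)) r$dim[1] else NA_integer_
  steps <- r |>
    dplyr::group_by(m = .data$mean_age) |>
    dplyr::summarise(step = sum(.data$lifetime), .groups = "drop") |>
    dplyr::arrange(.data$m) |>
    dplyr::mutate(value = cumsum(.data$step)) |>
    dplyr::select("m", "value")
  structure(steps, class = c("reva_apf", class(tibble())),
            homology_dim = dim, side = side, transform = attr(r, "transform"))
}

#' Evaluate an APF step curve
#'
#' @param curve A `reva_apf` tibble.
#' @param m Numeric vector of evaluation points.
#' @return `APF(m)` for each `m` (0 below the first breakpoint).
#' @export
apf_eval <- function(curve, m) {
  if (nrow(curve) == 0L) return(rep(0, length(m)))
  idx <- findInterval(m, curve$m)
  ifelse(idx == 0L, 0, curve$value[pmax(idx, 1L)])
}

#' Signed-supremum difference between two APF curves
#'
#' Evaluates `D(m) = APF_R(m) - APF_L(m)` on the union of both curves'
#' breakpoints (where the exact supremum of a piecewise-constant difference
#' is attained), locates the `m` maximising `|D(m)|` (ties resolved toward
#' the smallest `m`), and returns the signed value there. For identical
#' curves the value is exactly 0 at the first breakpoint.
#'
#' @param apf_left,apf_right `reva_apf` curves sharing `dim` and `transform`.
#' @return A list with `value` (signed) and `m_max`.
#' @examples
#' pdl <- compute_persistence(matrix(c(0, 2, 1), 1, 3), dim = 0)
#' a <- apf_curve(rrpd(pdl))
#' reva(a, a)$value  # 0 for identical curves
#' @export
reva <- function(apf_left, apf_right) {
  dl <- attr(apf_left, "homology_dim"); dr <- attr(apf_right, "homology_dim")
  if (!is.na(dl) && !is.na(dr) && dl != dr)
    abort(sprintf("APF dimension mismatch: left %d vs right %d.", dl, dr))
  tl <- attr(apf_left, "transform"); tr <- attr(apf_right, "transform")
  if (!is.na(tl) && !is.na(tr) && !identical(tl, tr))
    abort(sprintf("APF transform mismatch: left '%s' vs right '%s'.", tl, tr))
  grid <- sort(unique(c(apf_left$m, apf_right$m)))
  if (length(grid) == 0L) return(list(value = 0, m_max = NA_real_))
  d <- apf_eval(apf_right, grid) - apf_eval(apf_left, grid)
  i <- which.max(abs(d)) # ties: which.max takes the first, i.e. smallest m
  list(value = d[i], m_max = grid[i])
}

#' Topological asymmetry of a left/right image pair
#'
#' Runs the full chain on a pre-aligned pair: intensity transform,
#' sublevel-set cubical persistence in dimensions 0 and 1, rotation and
#' rescaling, APF summarisation, and the signed-supremum comparison. The
#' right curve is the minuend, so positive values mean more accumulated
#' persistence on the right.
#'
#' @param left,right [greyscale_image()] objects, matrices, or file paths
#'   (read via [read_image()]). Expected pre-aligned; a warning is issued if
#'   dimensions differ.
#' @param transform Intensity transform applied to both images before
#'   filtration: `"unit"` (default) or `"z"`.
#' @return A one-row tibble of class `reva_result`: `reva0`, `reva1`,
#'   `m0_max`, `m1_max`, `transform`, `normalized` (`FALSE`; cohort-level
#'   max-normalization is applied downstream by [normalize_trait()]).
#' @examples
#' img <- make_vessel_image(c(48, 48), seed = 7)
#' compute_reva_pair(img, img)  # identical inputs: both values 0
#' @export
compute_reva_pair <- function(left, right, transform = c("unit", "z")) {
  transform <- match.arg(transform)
  if (is.character(left)) left <- read_image(left)
  if (is.character(right)) right <- read_image(right)
  left <- as_greyscale(left); right <- as_greyscale(right)
  if (!identical(dim(unclass(left)), dim(unclass(right))))
    warn(sprintf("image dimensions differ (%dx%d vs %dx%d); inputs should be pre-aligned.",
                 nrow(left), ncol(left), nrow(right), ncol(right)))
  lt <- apply_transform(left, transform)
  rt <- apply_transform(right, transform)
  one_dim <- function(k) {
    al <- apf_curve(rrpd(compute_persistence(lt, dim = k)), side = "left")
    ar <- apf_curve(rrpd(compute_persistence(rt, dim = k)), side = "right")
    reva(al, ar)
  }
  r0 <- one_dim(0); r1 <- one_dim(1)
  out <- tibble(reva0 = r0$value, reva1 = r1$value,
                m0_max = r0$m_max, m1_max = r1$m_max,
                transform = transform, normalized = FALSE)
  structure(out, class = c("reva_result", class(tibble())))
}

#' Write an APF curve as two-column CSV
#'
#' @param curve A `reva_apf` tibble.
#' @param path CSV path; columns `m,value`.
#' @return `path`, invisibly.
#' @export
write_apf <- function(curve, path) {
  readr::write_csv(curve[, c("m", "value")], path)
  invisible(path)
}
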