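#' Cubical persistent homology of a greyscale image
#'
#' Computes the persistence diagram of the sublevel-set filtration of the
#' image: a pixel enters the complex once the threshold `l` reaches its value,
#' 4-neighbour edges at the maximum of their endpoints, and unit squares at
#' the maximum of their four corners (the vertex construction). As `l`
#' increases this is a nested, non-decreasing family of cubical complexes.
#' Dimension 0 tracks connected components, dimension 1 tracks loops.
#'
#' The single component that never dies (every image has one) is assigned
#' death equal to the maximum pixel value, so every lifetime is finite and the
#' accumulative persistence function is well defined. Zero-lifetime pairs
#' (birth equal to death) carry no persistent information and are dropped by
#' default; they can be kept for bookkeeping with `drop_zero = FALSE`.
#'
#' @param img A [greyscale_image()] or numeric matrix.
#' @param dim Homology dimension, 0 (components) or 1 (loops).
#' @param drop_zero Drop zero-lifetime points? Default `TRUE`.
#' @return A tibble of class `reva_pd` with columns `dim`, `birth`, `death`,
#'   `essential`, and attributes `transform` (inherited from the image) and
#'   `image_max`.
#' @examples
#' img <- matrix(c(0, 2, 1), 1, 3)
#' compute_persistence(img, dim = 0)
#' @export
compute_persistence <- function(img, dim = 0, drop_zero = TRUE) {
  img <- as_greyscale(img)
  if (!dim %in% c(0L, 1L)) abort("`dim` must be 0 or 1.")
  res <- if (dim == 0) .cubical_pers0(unclass(img)) else .cubical_pers1(unclass(img))
  pd <- tibble(dim = as.integer(dim),
               birth = as.numeric(res$birth),
               death = as.numeric(res$death),
               essential = as.logical(res$essential))
  if (drop_zero) pd <- dplyr::filter(pd, .data$death > .data$birth | .data$essential)
  pd <- dplyr::arrange(pd, .data$birth, .data$death)
  new_reva_pd(pd, transform = attr(img, "transform"), image_max = max(img))
}

new_reva_pd <- function(pd, transform, image_max = NA_real_) {
  structure(pd, class = c("reva_pd", class(tibble())),
            transform = transform, image_max = image_max)
}

#' Betti numbers of one sublevel complex, by brute force
#'
#' An independent oracle for validating the persistence computation: the
#' sublevel cubical complex at threshold `level` is materialised explicitly,
#' its components are counted by flood fill, and the first Betti number is
#' recovered from the Euler characteristic
#' (`b1 = b0 - (V - E + F)`, exact because a planar complex has no 2-cycles).
#' Intentionally simple and restricted to small images.
#'
#' @param img A [greyscale_image()] or numeric matrix with at most 10,000
#'   pixels.
#' @param level Filtration threshold; cells with value `<= level` are
#'   included.
#' @return Named integer vector `c(b0 = ..., b1 = ...)`.
#' @examples
#' oracle_betti(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3), level = 0)
#' @export
oracle_betti <- function(img, level) {
  img <- as_greyscale(img)
  N <- nrow(img); M <- ncol(img)
  if (N * M > 10000L)
    abort("oracle_betti is brute-force and refuses images larger than 10,000 pixels.")
  z <- unclass(img)
  inc <- z <= level
  nv <- sum(inc)
  if (nv == 0L) return(c(b0 = 0L, b1 = 0L))

  # flood fill over included vertices, 4-connectivity through included edges
  lab <- matrix(0L, N, M)
  b0 <- 0L
  for (j in seq_len(M)) for (i in seq_len(N)) {
    if (!inc[i, j] || lab[i, j] > 0L) next
    b0 <- b0 + 1L
    stack <- list(c(i, j))
    lab[i, j] <- b0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1L && q[1] <= N && q[2] >= 1L && q[2] <= M &&
            inc[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- b0
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }

  ne <- 0L
  if (N > 1L) ne <- ne + sum(inc[-N, ] & inc[-1, ])
  if (M > 1L) ne <- ne + sum(inc[, -M] & inc[, -1])
  nf <- 0L
  if (N > 1L && M > 1L)
    nf <- sum(inc[-N, -M] & inc[-1, -M] & inc[-N, -1] & inc[-1, -1])
  chi <- nv - ne + nf
  c(b0 = b0, b1 = as.integer(b0 - chi))
}

#' Betti counts implied by a persistence diagram at a threshold
#'
#' Counts diagram points alive at threshold `l`: non-essential points with
#' `birth <= l < death` plus essential points with `birth <= l`. Used to
#' cross-check diagrams against [oracle_betti()].
#'
#' @param pd A `reva_pd` tibble.
#' @param level Threshold.
#' @return Integer count.
#' @export
pd_betti_at <- function(pd, level) {
  sum((pd$birth <= level & level < pd$death & !pd$essential) |
        (pd$essential & pd$birth <= level))
}

#' Write or read a persistence diagram as CSV
#'
#' The stable on-disk schema is one row per point with columns
#' `dim,birth,death,essential`.
#'
#' @param pd A `reva_pd` tibble (or any tibble with those columns).
#' @param path CSV path.
#' @return `write_diagram()` returns `path` invisibly; `read_diagram()`
#'   returns a `reva_pd` tibble.
#' @export
write_diagram <- function(pd, path) {
  readr::write_csv(pd[, c("dim", "birth", "death", "essential")], path)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  pd <- readr::read_csv(path, col_types = readr::cols(
    dim = readr::col_integer(), birth = readr::col_double(),
    death = readr::col_double(), essential = readr::col_logical()))
  new_reva_pd(pd, transform = NA_character_)
}
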