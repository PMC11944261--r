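#' Geometry and topology of the Humphrey 24-2 test pattern
#'
#' Builds the 54-point 24-2 grid for one eye. Coordinates are degrees of
#' visual angle on a 6-degree lattice offset 3 degrees from both meridians;
#' x is temporal-positive for a right eye (OD) and the OS grid is the exact
#' x-mirror. Two locations fall on the physiologic blind spot (x = +15 for
#' OD, x = -15 for OS, y = +/-3) and are excluded from all analyses, leaving
#' the 52 test locations that carry deviation values.
#'
#' Locations are numbered row-major, superior to inferior, temporal to
#' nasal. `feature_index` maps each non-blind-spot location to its position
#' 1..52 in deviation vectors (blind spots get `NA`).
#'
#' Edge locations default to the outermost ring of the pattern plus the two
#' locations directly above and below the blind spot, the convention used
#' by Hodapp-style "non-edge point" cluster rules; pass `edge_indices` to
#' override.
#'
#' Sectors follow a position-based map: superior-temporal (ST),
#' superior-nasal (SN), inferior-temporal (IT) and inferior-nasal (IN)
#' quadrants. The labels T, N and central are accepted in user-supplied
#' sector tables but unused by the default 24-2 map.
#'
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param edge_indices Optional integer vector of location indices to treat
#'   as edge locations, overriding the default convention.
#' @return An object of class `vf_grid`: a data frame with one row per
#'   location and columns `index`, `x`, `y`, `is_blind_spot`, `is_edge`,
#'   `hemifield`, `sector`, `feature_index`, plus a `laterality` attribute.
#' @examples
#' g <- vf_grid("OD")
#' sum(!g$is_blind_spot)           # 52 test locations
#' table(g$sector[!g$is_blind_spot])
#' @export
vf_grid <- function(laterality = c("OD", "OS"), edge_indices = NULL) {
  laterality <- match.arg(laterality)

  rows <- list(
    list(y = 21,  x = c(9, 3, -3, -9)),
    list(y = 15,  x = c(15, 9, 3, -3, -9, -15)),
    list(y = 9,   x = c(21, 15, 9, 3, -3, -9, -15, -21)),
    list(y = 3,   x = c(21, 15, 9, 3, -3, -9, -15, -21, -27)),
    list(y = -3,  x = c(21, 15, 9, 3, -3, -9, -15, -21, -27)),
    list(y = -9,  x = c(21, 15, 9, 3, -3, -9, -15, -21)),
    list(y = -15, x = c(15, 9, 3, -3, -9, -15)),
    list(y = -21, x = c(9, 3, -3, -9))
  )
  x <- unlist(lapply(rows, `[[`, "x"))
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$x))))

  # Blind spot sits temporal to fixation: x = +15 (OD frame), y = +/-3.
  blind <- x == 15 & abs(y) == 3

  if (is.null(edge_indices)) {
    edge <- logical(length(x))
    for (yy in unique(y)) {
      in_row <- y == yy
      edge[in_row & (x == max(x[in_row]) | x == min(x[in_row]))] <- TRUE
    }
    edge[abs(y) == 21] <- TRUE
    # nasal-step convention: the pair straddling the blind spot vertically
    edge[x == 15 & abs(y) == 9] <- TRUE
    edge[blind] <- FALSE
  } else {
    stopifnot(all(edge_indices %in% seq_along(x)))
    edge <- seq_along(x) %in% as.integer(edge_indices)
  }

  hemifield <- ifelse(y > 0, "superior", "inferior")
  sector <- ifelse(y > 0,
                   ifelse(x > 0, "ST", "SN"),
                   ifelse(x > 0, "IT", "IN"))
  sector[blind] <- NA_character_

  feature_index <- rep(NA_integer_, length(x))
  feature_index[!blind] <- seq_len(sum(!blind))

  if (laterality == "OS") x <- -x

  g <- data.frame(
    index = seq_along(x), x = x, y = y,
    is_blind_spot = blind, is_edge = edge,
    hemifield = hemifield, sector = sector,
    feature_index = feature_index,
    stringsAsFactors = FALSE
  )
  attr(g, "laterality") <- laterality
  class(g) <- c("vf_grid", "data.frame")
  g
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("24-2 visual field grid (%s): %d locations, %d test points, %d edge\n",
              attr(x, "laterality"), nrow(x), sum(!x$is_blind_spot),
              sum(x$is_edge)))
  invisible(x)
}

#' Mirror a grid between right and left eye frames
#'
#' Negates x coordinates and flips the laterality tag; an involution.
#'
#' @param grid A [vf_grid()] object.
#' @return The mirrored `vf_grid`.
#' @export
vf_mirror_grid <- function(grid) {
  stopifnot(inherits(grid, "vf_grid"))
  grid$x <- -grid$x
  attr(grid, "laterality") <- if (attr(grid, "laterality") == "OD") "OS" else "OD"
  grid
}

#' Neighbouring test locations on the 24-2 lattice
#'
#' Returns the non-blind-spot locations within one lattice step of `index`.
#' Under 8-connectivity (the default, and the usual reading of "contiguous
#' points" in cluster criteria) diagonal neighbours count: both coordinate
#' offsets at most 6 degrees. Under 4-connectivity only one axis may step.
#'
#' @param grid A [vf_grid()] object.
#' @param index Location index (1..54); must not be a blind-spot location.
#' @param connectivity 8 (default) or 4.
#' @return Integer vector of neighbouring location indices.
#' @export
vf_neighbors <- function(grid, index, connectivity = 8) {
  stopifnot(inherits(grid, "vf_grid"))
  if (length(index) != 1L || !index %in% grid$index) {
    stop_vf("location index %s is out of range", paste(index, collapse = ","))
  }
  if (grid$is_blind_spot[index]) {
    stop_vf("location %d is a blind-spot location", index)
  }
  adj <- grid_adjacency(grid, connectivity)
  which(adj[index, ])
}

# Full 54x54 logical adjacency matrix; blind spots have no edges.
grid_adjacency <- function(grid, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_vf("connectivity must be 4 or 8")
  dx <- abs(outer(grid$x, grid$x, "-"))
  dy <- abs(outer(grid$y, grid$y, "-"))
  adj <- if (connectivity == 8) {
    dx <= 6 & dy <= 6 & (dx + dy) > 0
  } else {
    (dx + dy) == 6
  }
  adj[grid$is_blind_spot, ] <- FALSE
  adj[, grid$is_blind_spot] <- FALSE
  diag(adj) <- FALSE
  adj
}

#' Connected clusters of flagged test locations
#'
#' Finds the maximal connected components of flagged locations under the
#' lattice contiguity scheme, the primitive behind every "cluster of
#' contiguous points" field criterion.
#'
#' @param flags Logical vector over the 52 test locations (feature order) or
#'   over all 54 locations (grid order); blind-spot entries are ignored.
#' @param grid A [vf_grid()] object.
#' @param non_edge_only If `TRUE`, edge locations are removed before
#'   component search.
#' @param same_hemifield If `TRUE`, adjacency across the horizontal meridian
#'   is severed so clusters cannot straddle it.
#' @param connectivity 8 (default) or 4.
#' @return List of integer vectors of location indices, sorted by decreasing
#'   size, ties broken by smallest member index.
#' @examples
#' g <- vf_grid("OD")
#' flags <- rep(FALSE, 52)
#' flags[g$feature_index[g$index %in% c(1, 2, 5)]] <- TRUE
#' vf_find_clusters(flags, g)
#' @export
vf_find_clusters <- function(flags, grid, non_edge_only = FALSE,
                             same_hemifield = FALSE, connectivity = 8) {
  stopifnot(inherits(grid, "vf_grid"))
  flags <- expand_flags(flags, grid)

  active <- flags & !grid$is_blind_spot
  if (non_edge_only) active <- active & !grid$is_edge
  idx <- which(active)
  if (length(idx) == 0L) return(list())

  adj <- grid_adjacency(grid, connectivity)
  if (same_hemifield) {
    sup <- grid$y > 0
    adj[sup, !sup] <- FALSE
    adj[!sup, sup] <- FALSE
  }

  seen <- logical(nrow(grid))
  comps <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & active & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  ord <- order(-vapply(comps, length, 1L), vapply(comps, min, 1L))
  comps[ord]
}

# Accept flags of length 52 (feature order) or 54 (grid order).
expand_flags <- function(flags, grid) {
  flags <- as.logical(flags)
  if (length(flags) == nrow(grid)) return(flags)
  n_feat <- sum(!grid$is_blind_spot)
  if (length(flags) == n_feat) {
    full <- logical(nrow(grid))
    full[!grid$is_blind_spot] <- flags[grid$feature_index[!grid$is_blind_spot]]
    return(full)
  }
  stop_vf("flags must have length %d (test locations) or %d (all locations)",
          n_feat, nrow(grid))
}

#' Anatomical sector of a test location
#'
#' @param grid A [vf_grid()] object.
#' @param index Location index; must not be a blind-spot location.
#' @return Sector label (`"ST"`, `"SN"`, `"IT"`, `"IN"`, and for
#'   user-supplied maps possibly `"T"`, `"N"`, `"central"`).
#' @export
vf_sector <- function(grid, index) {
  stopifnot(inherits(grid, "vf_grid"))
  if (any(!index %in% grid$index)) stop_vf("location index out of range")
  if (any(grid$is_blind_spot[index])) {
    stop_vf("blind-spot locations have no sector")
  }
  grid$sector[index]
}

#' Map deviation-vector feature positions to grid locations
#'
#' Feature position k (1..52) is the k-th non-blind-spot location in grid
#' numbering; deviation vectors (`td1..td52`, `pd1..pd52`) are stored in
#' this order.
#'
#' @param grid A [vf_grid()] object.
#' @param feature Integer vector of feature positions in 1..52.
#' @return Integer vector of grid location indices.
#' @export
vf_location_of_feature <- function(grid, feature) {
  stopifnot(inherits(grid, "vf_grid"))
  lut <- grid$index[!grid$is_blind_spot][order(grid$feature_index[!grid$is_blind_spot])]
  if (any(feature < 1 | feature > length(lut))) {
    stop_vf("feature positions must lie in 1..%d", length(lut))
  }
  lut[feature]
}
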