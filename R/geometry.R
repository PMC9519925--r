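#' Build a synthetic two-hemisphere cortical parcellation
#'
#' Generates `2 * n_per_hemisphere` parcels with quasi-uniform centroids on the
#' unit sphere, split into a left (x < 0) and a right (x > 0) hemisphere.
#' Centroids come from a deterministic Fibonacci lattice on the left
#' hemisphere, perturbed by a small seed-controlled tangential jitter; each
#' right-hemisphere parcel is the exact x-mirror image of its left homolog.
#' Volume coordinates (an MNI-like millimeter frame) are the sphere centroids
#' scaled by a nominal 70 mm cortical radius; they serve as the representative
#' parcel loci for microarray sample assignment.
#'
#' @param n_per_hemisphere parcels per hemisphere, at least 4.
#' @param seed integer seed controlling the lattice jitter.
#' @param jitter_sd tangential jitter as a fraction of the typical
#'   inter-centroid spacing.
#' @return A `parcel_geometry` data frame with columns `parcel_id`,
#'   `hemisphere`, `sx`, `sy`, `sz` (unit-sphere centroid), `vx`, `vy`, `vz`
#'   (volume locus, mm) and `homolog_id`.
#' @examples
#' geom <- make_parcellation(10, seed = 1)
#' nrow(geom)  # 20
#' @export
make_parcellation <- function(n_per_hemisphere, seed = 1L, jitter_sd = 0.25) {
  if (!is.numeric(n_per_hemisphere) || length(n_per_hemisphere) != 1L ||
      n_per_hemisphere < 4 || n_per_hemisphere != round(n_per_hemisphere)) {
    stop("n_per_hemisphere must be an integer >= 4")
  }
  n <- as.integer(n_per_hemisphere)
  ## Fibonacci lattice on the hemisphere centred on the -x axis:
  ## polar angle measured from -x, golden-angle azimuth.
  i <- seq_len(n)
  cos_theta <- (i - 0.5) / n          # in (0, 1): stays strictly left
  sin_theta <- sqrt(1 - cos_theta^2)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  left <- cbind(
    x = -cos_theta,
    y = sin_theta * cos(phi),
    z = sin_theta * sin(phi)
  )
  ## Seeded tangential jitter, then renormalize and clamp to the hemisphere.
  spacing <- sqrt(2 * pi / n)
  left <- with_seed(seed, {
    jit <- matrix(stats::rnorm(3L * n, sd = jitter_sd * spacing), ncol = 3L)
    p <- left + jit
    p <- p / sqrt(rowSums(p^2))
    p[, 1L] <- -abs(p[, 1L])
    p / sqrt(rowSums(p^2))
  })
  right <- left
  right[, 1L] <- -right[, 1L]
  wid <- formatC(i, width = max(3L, nchar(n)), flag = "0")
  ids_l <- paste0("L", wid)
  ids_r <- paste0("R", wid)
  sphere <- rbind(left, right)
  geom <- data.frame(
    parcel_id = c(ids_l, ids_r),
    hemisphere = rep(c("L", "R"), each = n),
    sx = sphere[, 1L], sy = sphere[, 2L], sz = sphere[, 3L],
    vx = 70 * sphere[, 1L], vy = 70 * sphere[, 2L], vz = 70 * sphere[, 3L],
    homolog_id = c(ids_r, ids_l),
    stringsAsFactors = FALSE
  )
  class(geom) <- c("parcel_geometry", "data.frame")
  geom
}

## Unit-sphere centroids as a matrix with parcel_id rownames.
sphere_coords <- function(geometry) {
  m <- as.matrix(geometry[, c("sx", "sy", "sz")])
  rownames(m) <- geometry$parcel_id
  m
}

## Volume (mm) loci as a matrix with parcel_id rownames.
volume_coords <- function(geometry) {
  m <- as.matrix(geometry[, c("vx", "vy", "vz")])
  rownames(m) <- geometry$parcel_id
  m
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(sprintf("parcel_geometry: %d parcels (%d per hemisphere)\n",
              nrow(x), sum(x$hemisphere == "L")))
  NextMethod()
}
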