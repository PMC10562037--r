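#' Dose grids and cumulative dose-volume histograms
#'
#' A `dose_grid` is a small 3-D array of absorbed dose (cGy) with a voxel
#' volume and one binary mask per anatomical structure — a desk-scale
#' stand-in for a DICOM-RT dose/structure-set pair. The cumulative DVH of a
#' structure reports, for each dose level d, the fraction of the structure's
#' volume receiving at least d.
#'
#' @param dose numeric 3-D array of doses (finite, non-negative).
#' @param voxel_volume volume of one voxel in cm^3.
#' @param masks named list of logical arrays, same shape as `dose`, one per
#'   structure; each must select at least one voxel.
#' @param dose_units `"cGy"` (the unit used end-to-end) or `"Gy"`, which
#'   is converted to cGy on input.
#' @return an object of class `dose_grid` (doses stored in cGy).
#' @export
dose_grid <- function(dose, voxel_volume = 0.125, masks = list(),
                      dose_units = c("cGy", "Gy")) {
  dose_units <- match.arg(dose_units)
  stopifnot(is.array(dose), length(dim(dose)) == 3L)
  if (dose_units == "Gy") dose <- dose * 100
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  stopifnot(voxel_volume > 0)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), dim(dose)))
      stop("mask '", nm, "' shape differs from dose grid", call. = FALSE)
    if (!any(m)) stop("mask '", nm, "' selects no voxels", call. = FALSE)
  }
  structure(list(dose = dose, voxel_volume = voxel_volume, masks = masks),
            class = "dose_grid")
}

#' Generate a synthetic dose grid
#'
#' Produces a grid with a central high-dose target region (around the
#' requested prescription dose) falling off towards the edges, with a
#' `PTV` mask over the target and an `OAR` mask in the periphery.
#'
#' @param shape integer vector of 3 grid dimensions (default `c(8, 8, 8)`).
#' @param prescription_cgy nominal target dose in cGy.
#' @param seed integer RNG seed.
#' @return a `dose_grid` with `PTV` and `OAR` masks.
#' @export
generate_dose_grid <- function(shape = c(8L, 8L, 8L),
                               prescription_cgy = 6000, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  set.seed(seed)
  ctr <- (shape + 1) / 2
  idx <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
  r <- sqrt(((idx$x - ctr[1]) / shape[1])^2 + ((idx$y - ctr[2]) / shape[2])^2 +
              ((idx$z - ctr[3]) / shape[3])^2)
  base <- prescription_cgy * pmax(0.02, 1.04 - 1.6 * r)
  dose <- array(pmax(0, base * (1 + stats::rnorm(length(base), 0, 0.03))),
                dim = shape)
  ptv <- array(r <= 0.22, dim = shape)
  oar <- array(r > 0.32 & r <= 0.48, dim = shape)
  if (!any(ptv)) ptv[ceiling(ctr[1]), ceiling(ctr[2]), ceiling(ctr[3])] <- TRUE
  if (!any(oar)) oar[1, 1, 1] <- TRUE
  dose_grid(dose, voxel_volume = 0.125, masks = list(PTV = ptv, OAR = oar))
}

#' Compute a cumulative DVH curve
#'
#' For uniform bin edges 0, w, 2w, ... spanning the structure's maximum
#' dose plus one bin, reports the fraction of masked voxels with dose
#' greater than or equal to each edge.
#'
#' @param grid a `dose_grid`.
#' @param structure structure name (must be a mask of `grid`) or a logical
#'   array mask of the same shape.
#' @param bin_width_cgy positive bin width in cGy.
#' @return object of class `dvh_curve`: list with `dose_cgy` (bin edges),
#'   `volume_fraction`, and the masked voxel `doses` (kept for exact mean
#'   and Dx computations).
#' @export
compute_dvh <- function(grid, structure, bin_width_cgy = 50) {
  stopifnot(inherits(grid, "dose_grid"), bin_width_cgy > 0)
  mask <- if (is.character(structure)) {
    if (!structure %in% names(grid$masks))
      stop("undefined structure: ", structure, call. = FALSE)
    grid$masks[[structure]]
  } else structure
  if (!identical(dim(mask), dim(grid$dose)))
    stop("mask shape differs from dose grid", call. = FALSE)
  doses <- grid$dose[mask]
  if (!length(doses)) stop("undefined structure: empty mask", call. = FALSE)
  edges <- seq(0, max(doses) + bin_width_cgy, by = bin_width_cgy)
  frac <- vapply(edges, function(d) mean(doses >= d), numeric(1))
  structure(list(dose_cgy = edges, volume_fraction = frac, doses = doses),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", length(x$dose_cgy), " edges, max dose ",
      max(x$dose_cgy), " cGy\n", sep = "")
  invisible(x)
}

#' DVH summary metrics
#'
#' `"Dx"` (e.g. `"D95"`): minimum dose received by the hottest x percent of
#' the structure volume — computed exactly from the retained voxel doses
#' when available, otherwise by linear inverse interpolation of the
#' cumulative curve (ties take the smallest qualifying dose). The two
#' routes agree to within one bin width. `"Vx"` (e.g. `"V2000"`):
#' percent of the structure volume receiving at least x cGy, linearly
#' interpolated between edges. `"mean"`/`"max"`/`"min"`: from the
#' underlying voxel doses when the curve retains them, otherwise the mean
#' is the trapezoidal integral of the curve.
#'
#' @param curve a `dvh_curve`.
#' @param requests character vector, e.g. `c("D95", "V2000", "mean")`.
#' @return named numeric vector; Dx in cGy, Vx in percent.
#' @export
dvh_metrics <- function(curve, requests) {
  stopifnot(inherits(curve, "dvh_curve"))
  e <- curve$dose_cgy
  f <- curve$volume_fraction
  vapply(requests, function(req) {
    if (req == "mean") {
      if (!is.null(curve$doses)) return(mean(curve$doses))
      # trapezoidal integral of the cumulative curve equals the mean dose
      return(sum(diff(e) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
    }
    if (req == "max") return(if (!is.null(curve$doses)) max(curve$doses)
                             else max(e[f > 0]))
    if (req == "min") return(if (!is.null(curve$doses)) min(curve$doses)
                             else min(e[f < 1], 0))
    m <- regmatches(req, regexec("^([DV])([0-9.]+)$", req))[[1]]
    if (length(m) != 3L) stop("unrecognized DVH metric request: ", req,
                              call. = FALSE)
    x <- as.numeric(m[3])
    if (m[2] == "V") {
      if (x < 0 || x > max(e)) stop("V request outside curve domain: ", req,
                                    call. = FALSE)
      return(100 * stats::approx(e, f, xout = x, ties = "ordered")$y)
    }
    # Dx: smallest dose with fraction <= x/100
    target <- x / 100
    if (target > 1 || target < 0) stop("D request outside [0,100]: ", req,
                                       call. = FALSE)
    if (!is.null(curve$doses)) {
      d <- sort(curve$doses, decreasing = TRUE)
      n <- length(d)
      k <- floor(target * n)
      if (k < 1) return(max(d))
      return(d[min(k, n)])
    }
    below <- which(f <= target)
    if (!length(below)) return(max(e))
    i <- below[1]
    if (i == 1L || f[i - 1] == f[i]) return(e[i])
    e[i - 1] + (f[i - 1] - target) / (f[i - 1] - f[i]) * (e[i] - e[i - 1])
  }, numeric(1))
}

#' Write a DVH curve as two-column TSV
#'
#' @param curve a `dvh_curve`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(curve, path) {
  utils::write.table(
    data.frame(dose_cgy = curve$dose_cgy,
               volume_fraction = curve$volume_fraction),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
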