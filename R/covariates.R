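#' Minimal regular raster grid
#'
#' A light-weight container for the regular 30-m-class grids from which
#' site covariates are extracted: a numeric matrix plus cell geometry.
#' Row 1 is the southern (bottom) row; cell centres sit at
#' `origin + (index - 0.5) * cellsize` in a locally projected metric
#' coordinate system supplied by the user (the package does not reproject).
#'
#' @param values numeric matrix of cell values.
#' @param cellsize cell edge length in metres (> 0).
#' @param origin numeric length-2 `(x, y)` of the grid's lower-left corner.
#' @param nodata value marking missing cells (compared with `is.na` if NA).
#' @return Object of class `raster_grid`.
#' @export
raster_grid <- function(values, cellsize, origin = c(0, 0), nodata = NA_real_) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0,
            length(origin) == 2)
  structure(list(values = values, cellsize = cellsize,
                 origin = as.numeric(origin), nodata = nodata),
            class = "raster_grid")
}

grid_is_nodata <- function(grid, v) {
  if (is.na(grid$nodata)) is.na(v) else (is.na(v) | v == grid$nodata)
}

#' Normalized Difference Vegetation Index
#'
#' Cellwise `(NIR - Red) / (NIR + Red)` over two co-registered grids.
#' Cells where either band is missing, or where `NIR + Red = 0`, become
#' no-data. Values where defined lie in `[-1, 1]`.
#'
#' @param nir,red [raster_grid()]s of identical geometry.
#' @return A `raster_grid` of NDVI values with `NA` as its no-data marker.
#' @export
ndvi <- function(nir, red) {
  stopifnot(inherits(nir, "raster_grid"), inherits(red, "raster_grid"))
  if (!identical(dim(nir$values), dim(red$values)) ||
      nir$cellsize != red$cellsize || !identical(nir$origin, red$origin))
    stop("NIR and Red grids have mismatched geometry")
  a <- nir$values; b <- red$values
  a[grid_is_nodata(nir, a)] <- NA
  b[grid_is_nodata(red, b)] <- NA
  s <- a + b
  out <- (a - b) / s
  out[!is.na(s) & s == 0] <- NA
  raster_grid(out, nir$cellsize, nir$origin, NA_real_)
}

#' Proportion of buffer cells satisfying a predicate
#'
#' The proportion of valid (non-no-data) cells whose centres fall inside a
#' circular buffer and that satisfy `predicate` — e.g. the proportion of
#' cells with NDVI > 0.2 (substantial vegetation cover), or of land-cover
#' cells in a configured greenspace class set. Cell membership is by
#' cell-centre-in-circle.
#'
#' @param grid a [raster_grid()].
#' @param center numeric length-2 `(x, y)` buffer centre, in the grid's
#'   projected coordinates.
#' @param radius_m buffer radius in metres (> 0); typical choices are
#'   species home-range scales such as 500, 1000 or 1500 m.
#' @param predicate vectorized function mapping cell values to logical.
#' @return Proportion in `[0, 1]`.
#' @export
buffer_proportion <- function(grid, center, radius_m, predicate) {
  stopifnot(inherits(grid, "raster_grid"), length(center) == 2, radius_m > 0)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$cellsize
  cy <- grid$origin[2] + (seq_len(nr) - 0.5) * grid$cellsize
  dx2 <- outer(rep(1, nr), (cx - center[1])^2)
  dy2 <- outer((cy - center[2])^2, rep(1, nc))
  inside <- dx2 + dy2 <= radius_m^2
  if (!any(inside)) stop("buffer lies wholly outside the grid")
  v <- grid$values[inside]
  keep <- !grid_is_nodata(grid, v)
  if (!any(keep)) stop("all cells inside the buffer are no-data")
  v <- v[keep]
  mean(predicate(v))
}

#' Group-mean centre and globally scale covariates
#'
#' Prepares model covariates the way multi-city designs require: each
#' covariate is centred on its *city* mean (so coefficients measure
#' within-city gradients and are insensitive to unequal city sample sizes)
#' and divided by its *global* standard deviation across all rows (so a
#' one-unit change is one global SD). Scaling metadata is attached for
#' exact back-transformation.
#'
#' @param data data frame holding the covariates and a city column.
#' @param covariates character vector of covariate column names.
#' @param city name of the city column.
#' @return `data` with the covariate columns replaced by scaled values,
#'   carrying a `"scaling"` attribute: list with `centers` (city x covariate
#'   matrix of city means) and `sd` (named vector of global SDs).
#' @section Errors: a covariate with zero global standard deviation (fewer
#'   than two distinct values) aborts, naming the covariate.
#' @seealso [unscale_covariates()]
#' @export
center_and_scale <- function(data, covariates, city = "city_id") {
  stopifnot(is.data.frame(data), all(covariates %in% names(data)),
            city %in% names(data))
  cities <- sort(unique(as.character(data[[city]])))
  centers <- matrix(NA_real_, length(cities), length(covariates),
                    dimnames = list(cities, covariates))
  sds <- numeric(length(covariates))
  names(sds) <- covariates
  ci <- as.character(data[[city]])
  for (j in covariates) {
    x <- data[[j]]
    sds[j] <- stats::sd(x)
    if (!is.finite(sds[j]) || sds[j] == 0)
      stop("covariate `", j, "` has zero global standard deviation")
    mns <- tapply(x, ci, mean)
    centers[names(mns), j] <- mns
    data[[j]] <- (x - centers[ci, j]) / sds[j]
  }
  attr(data, "scaling") <- list(centers = centers, sd = sds, city = city)
  data
}

#' Back-transform scaled covariates to their original units
#'
#' @param data data frame of scaled covariates produced by
#'   [center_and_scale()] (or any frame carrying the same columns).
#' @param scaling the `"scaling"` attribute of a [center_and_scale()]
#'   result; taken from `data` itself when omitted.
#' @return `data` with covariates on their original scale.
#' @export
unscale_covariates <- function(data, scaling = attr(data, "scaling")) {
  stopifnot(!is.null(scaling))
  ci <- as.character(data[[scaling$city]])
  for (j in colnames(scaling$centers))
    data[[j]] <- data[[j]] * scaling$sd[j] + scaling$centers[ci, j]
  attr(data, "scaling") <- NULL
  data
}
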