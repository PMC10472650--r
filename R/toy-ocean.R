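#' Toy ocean domain for drifter simulation
#'
#' A rectangular lon/lat domain with an analytic surface velocity field, a
#' lateral diffusion coefficient, and a partition of the domain into labelled
#' basins (by longitude bands).  It stands in for real surface-drifter data
#' coverage so that travel-time estimation can be exercised against a current
#' field with known direction and speed.
#'
#' Presets:
#' * `"uniform-zonal"`: constant eastward current of `u0` degrees/day
#'   (default 0.2 deg/day, roughly a typical 0.25 m/s surface current at
#'   mid-latitudes).
#' * `"double-gyre"`: the classic steady double-gyre streamfunction
#'   \eqn{\psi = A \sin(\pi x)\sin(\pi y)} on the unit-normalized domain,
#'   giving two counter-rotating recirculating cells.
#'
#' @param preset velocity field preset, `"uniform-zonal"` or `"double-gyre"`.
#' @param lon_range,lat_range numeric length-2 domain bounds in degrees.
#' @param diffusion lateral diffusion coefficient in deg^2/day; each Euler
#'   step adds an isotropic Gaussian displacement of variance
#'   `2 * diffusion * step`.
#' @param u0 zonal speed (deg/day) for the uniform preset.
#' @param gyre_amplitude streamfunction amplitude (1/day) for the gyre preset.
#' @param basin_breaks increasing longitudes splitting the domain into basins;
#'   defaults to four equal bands.
#' @param basin_names labels of the bands, defaults to
#'   `c("MED", "NAO", "SAO", "SO")`.
#' @return an object of class `toy_ocean`.
#' @export
toy_ocean <- function(preset = c("uniform-zonal", "double-gyre"),
                      lon_range = c(0, 20), lat_range = c(30, 40),
                      diffusion = 0.02, u0 = 0.2, gyre_amplitude = 0.1,
                      basin_breaks = NULL,
                      basin_names = c("MED", "NAO", "SAO", "SO")) {
  preset <- match.arg(preset)
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    stop_param("degenerate domain bounds")
  }
  if (diffusion < 0) stop_param("diffusion must be non-negative")
  if (is.null(basin_breaks)) {
    basin_breaks <- seq(lon_range[1], lon_range[2],
                        length.out = length(basin_names) + 1L)
  }
  if (length(basin_breaks) != length(basin_names) + 1L) {
    stop_param("basin_breaks must bound each basin_names band")
  }
  structure(list(preset = preset, lon_range = lon_range, lat_range = lat_range,
                 diffusion = diffusion, u0 = u0,
                 gyre_amplitude = gyre_amplitude,
                 basin_breaks = basin_breaks, basin_names = basin_names),
            class = "toy_ocean")
}

#' Velocity of the toy ocean at given positions
#'
#' @param ocean a [toy_ocean()].
#' @param lon,lat numeric vectors of positions (degrees).
#' @return list with components `u` and `v` in degrees/day.
#' @export
ocean_velocity <- function(ocean, lon, lat) {
  switch(ocean$preset,
    "uniform-zonal" = list(u = rep(ocean$u0, length(lon)),
                           v = rep(0, length(lon))),
    "double-gyre" = {
      lx <- diff(ocean$lon_range)
      ly <- diff(ocean$lat_range)
      x <- 2 * (lon - ocean$lon_range[1]) / lx   # in [0, 2]
      y <- (lat - ocean$lat_range[1]) / ly       # in [0, 1]
      a <- ocean$gyre_amplitude
      # u = -dpsi/dy, v = dpsi/dx, rescaled back to degree units
      list(u = -pi * a * sin(pi * x) * cos(pi * y) * (lx / 2),
           v =  pi * a * cos(pi * x) * sin(pi * y) * ly)
    })
}

#' Basin label of positions in a toy ocean
#'
#' @inheritParams ocean_velocity
#' @return character vector of basin labels; the bands partition the domain.
#' @export
ocean_basin <- function(ocean, lon, lat = NULL) {
  idx <- findInterval(lon, ocean$basin_breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  ocean$basin_names[idx]
}
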