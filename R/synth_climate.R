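#' @title Synthetic daily climate generator
#' @description
#' Generates an ERA5-Land-like daily climate cube on a regular grid: a
#' latitudinal baseline temperature gradient, a sinusoidal seasonal cycle
#' peaking in mid-July, a linear warming trend, AR(1) day-to-day weather
#' noise, a winter-wet Bernoulli/gamma precipitation model and dewpoint
#' derived from temperature with a non-negative dewpoint depression. The
#' calendar is 365 days (no leap years). All randomness flows from `seed`
#' split into named substreams, so identical calls are bit-identical.
#'
#' @param grid a [grid_spec()]; at least 100 cells.
#' @param years integer vector of consecutive calendar years; must contain at
#'   least `min_window` years so a climatological window fits.
#' @param trend linear warming trend in degrees C per decade.
#' @param seed master seed.
#' @param noise_sd standard deviation (degrees C) of the AR(1) daily
#'   temperature noise; 0 gives exact sinusoids.
#' @param min_window minimum number of years a climatological window needs
#'   (default 31).
#' @return an object of class `climate_cube`: list with `grid`, `years` and
#'   arrays `tmean`, `tmin`, `tmax`, `precip`, `dewpoint` of dimension
#'   `c(n_cells, 365, n_years)`. Temperatures and dewpoint in degrees C,
#'   precipitation in mm/day.
#' @export
generate_climate <- function(grid, years, trend = 0.4, seed = 1,
                             noise_sd = 2, min_window = 31) {
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (length(years) < min_window)
    stop(sprintf("year range too short: %d years given, at least %d needed ",
                 length(years), min_window),
         "for one climatological window")
  if (grid$n_cells < 100) stop("grid must have at least 100 cells")
  nc <- grid$n_cells; ny <- length(years); nd <- 365L
  cc <- cell_centers(grid)

  base <- with_seed(derive_seed(seed, "climate", "base"), {
    24 - 0.7 * (cc$lat - grid$lat_min) + 0.05 * (cc$lon - grid$lon_min) +
      2 * smooth_field(grid, passes = 8)
  })
  amp <- 6 + 0.35 * (cc$lat - grid$lat_min)
  wet_base <- with_seed(derive_seed(seed, "climate", "wet"), {
    pmin(0.9, pmax(0.1, 0.35 + 0.15 * smooth_field(grid, passes = 8)))
  })
  gam_scale <- with_seed(derive_seed(seed, "climate", "gamscale"), {
    pmax(2, 6 + 2 * smooth_field(grid, passes = 8))
  })

  day <- seq_len(nd)
  season <- cos(2 * pi * (day - 196) / 365)        # thermal peak mid July
  wet_season <- cos(2 * pi * (day - 15) / 365)     # precipitation peak mid Jan

  dims <- c(nc, nd, ny)
  tmean <- array(NA_real_, dims); tmin <- array(NA_real_, dims)
  tmax <- array(NA_real_, dims); precip <- array(NA_real_, dims)
  dewpoint <- array(NA_real_, dims)
  rho <- 0.7
  innov_sd <- noise_sd * sqrt(1 - rho^2)

  for (t in seq_len(ny)) {
    yr_off <- trend / 10 * (years[t] - years[1])
    eps <- with_seed(derive_seed(seed, "climate", "eps", years[t]), {
      e <- matrix(0, nc, nd)
      e0 <- rnorm(nc, 0, noise_sd)
      for (d in seq_len(nd)) {
        e0 <- rho * e0 + rnorm(nc, 0, innov_sd)
        e[, d] <- e0
      }
      e
    })
    tm <- outer(base + yr_off, rep(1, nd)) + outer(amp, season) + eps
    dtr <- with_seed(derive_seed(seed, "climate", "dtr", years[t]), {
      pmax(0.2, 8 + 2 * outer(rep(1, nc), season) +
             matrix(rnorm(nc * nd, 0, noise_sd / 2), nc, nd))
    })
    pw <- pmin(0.95, pmax(0.05, outer(wet_base, rep(1, nd)) +
                            0.2 * outer(rep(1, nc), wet_season)))
    pr <- with_seed(derive_seed(seed, "climate", "precip", years[t]), {
      wet <- matrix(runif(nc * nd), nc, nd) < pw
      amt <- matrix(rgamma(nc * nd, shape = 0.8,
                           scale = rep(gam_scale, nd)), nc, nd)
      ifelse(wet, amt, 0)
    })
    dep <- with_seed(derive_seed(seed, "climate", "dew", years[t]), {
      pmax(0, 3 + 6 * (1 - pw) +
             matrix(rnorm(nc * nd, 0, noise_sd / 2), nc, nd))
    })
    tmean[, , t] <- tm
    tmax[, , t] <- tm + dtr / 2
    tmin[, , t] <- tm - dtr / 2
    precip[, , t] <- pr
    dewpoint[, , t] <- tm - dep
  }
  structure(list(grid = grid, years = years, tmean = tmean, tmin = tmin,
                 tmax = tmax, precip = precip, dewpoint = dewpoint),
            class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  cat(sprintf("climate_cube: %d cells, years %d-%d (365-day calendar)\n",
              x$grid$n_cells, min(x$years), max(x$years)))
  invisible(x)
}

# Smooth standardized Gaussian random field via repeated 3x3 box blur.
# Uses the current RNG stream (callers wrap in with_seed()).
smooth_field <- function(grid, passes = 8) {
  m <- matrix(rnorm(grid$n_cells), grid$ny, grid$nx)
  for (i in seq_len(passes)) {
    p <- rbind(m[1, ], m, m[grid$ny, ])
    p <- cbind(p[, 1], p, p[, grid$nx])
    m <- (p[1:grid$ny, 1:grid$nx] + p[1:grid$ny, 2:(grid$nx + 1)] +
          p[1:grid$ny, 3:(grid$nx + 2)] +
          p[2:(grid$ny + 1), 1:grid$nx] + p[2:(grid$ny + 1), 2:(grid$nx + 1)] +
          p[2:(grid$ny + 1), 3:(grid$nx + 2)] +
          p[3:(grid$ny + 2), 1:grid$nx] + p[3:(grid$ny + 2), 2:(grid$nx + 1)] +
          p[3:(grid$ny + 2), 3:(grid$nx + 2)]) / 9
  }
  v <- as.vector(t(m)) # row-major: lat rows, lon within row
  (v - mean(v)) / max(sd(v), 1e-12)
}

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}

#' Fixed random sea mask
#'
#' A smooth random blob covering a given fraction of the domain, constant in
#' time. `TRUE` marks sea cells (masked out of all species maps).
#'
#' @param grid a [grid_spec()].
#' @param seed master seed.
#' @param fraction fraction of the domain covered by sea, in `[0.1, 0.3]`.
#' @return logical vector of length `n_cells`.
#' @export
sea_mask <- function(grid, seed = 1, fraction = 0.2) {
  stopifnot(fraction >= 0.1, fraction <= 0.3)
  f <- with_seed(derive_seed(seed, "sea"), smooth_field(grid, passes = 12))
  f <= quantile(f, fraction)
}
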