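#' Growth-curve fitting configuration
#'
#' @param window_points number of consecutive readings per fitting window
#'   (default 5, i.e. one hour at 15-minute sampling).
#' @param min_od detection floor; readings at or below it (after blank
#'   subtraction) are excluded and negatives are clipped here (default 0.01).
#' @param min_r2 minimum R-squared for a window to qualify (default 0.99).
#' @param blank_policy how blanks are subtracted: "per-plate-mean" (default)
#'   or "per-well".
#' @return object of class `growth_fit_config`.
#' @export
growth_fit_config <- function(window_points = 5, min_od = 0.01,
                              min_r2 = 0.99,
                              blank_policy = c("per-plate-mean", "per-well")) {
  stopifnot(window_points >= 3, min_r2 > 0, min_r2 <= 1, min_od > 0)
  structure(list(window_points = as.integer(window_points), min_od = min_od,
                 min_r2 = min_r2, blank_policy = match.arg(blank_policy)),
            class = "growth_fit_config")
}

# rolling least-squares slope and r^2 of y on t over windows of w points
# inside one contiguous run; returns data.frame(start, slope, r2)
rolling_fit <- function(t, y, w) {
  n <- length(t)
  if (n < w) return(data.frame(start = integer(0), slope = numeric(0),
                               r2 = numeric(0)))
  cs <- function(z) { c0 <- cumsum(z); c0[w:n] - c(0, c0)[seq_len(n - w + 1)] }
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y); Syy <- cs(y * y)
  sxx <- Stt - St^2 / w
  sxy <- Sty - St * Sy / w
  syy <- Syy - Sy^2 / w
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)
  data.frame(start = seq_len(n - w + 1), slope = slope, r2 = r2)
}

#' Maximum exponential growth rate from an OD600 time series
#'
#' Fits straight lines to log OD600 versus time over every contiguous window
#' of `window_points` readings above the detection floor, and reports the
#' steepest qualifying slope (R-squared at least `min_r2`) as the maximum
#' growth rate. The estimate is invariant to uniform scaling of the readings,
#' since scaling only shifts the log intercept.
#'
#' @param times reading times in minutes, strictly increasing.
#' @param od600 blank-subtracted OD600 readings, same length as `times`;
#'   values below the detection floor are clipped to it and excluded from
#'   fitting windows.
#' @param config a [growth_fit_config()].
#' @return Object of class `growth_fit`: `rate` (per hour), `r2`,
#'   `window_start_min`, `n_windows` (number of qualifying windows).
#'   Errors with "no growth" if fewer than `window_points` readings rise
#'   above the floor, and with a quality error (carrying the best window's
#'   diagnostics) if no window meets `min_r2`.
#' @examples
#' t <- seq(0, 600, by = 15)
#' fit_max_growth_rate(t, 0.01 * exp(0.8 * t / 60))$rate  # 0.8 per hour
#' @export
fit_max_growth_rate <- function(times, od600, config = growth_fit_config()) {
  stopifnot(inherits(config, "growth_fit_config"),
            length(times) == length(od600))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  od <- pmax(od600, config$min_od)
  above <- which(od > config$min_od)
  if (length(above) < config$window_points) {
    stop("no growth: fewer than ", config$window_points,
         " readings above the detection floor")
  }
  t_h <- times / 60
  y <- log(od)
  # fit only within contiguous runs of above-floor readings
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  fits <- do.call(rbind, lapply(runs, function(idx) {
    f <- rolling_fit(t_h[idx], y[idx], config$window_points)
    f$start <- idx[f$start]
    f
  }))
  if (is.null(fits) || nrow(fits) == 0) {
    stop("no growth: no fitting window available")
  }
  ok <- fits$r2 >= config$min_r2 & is.finite(fits$slope)
  if (!any(ok)) {
    best <- fits[which.max(fits$r2), ]
    stop(sprintf(
      "fit quality: no window reached R2 >= %.3f (best R2 %.4f, slope %.3f/h at t = %.0f min)",
      config$min_r2, best$r2, best$slope, times[best$start]))
  }
  fits <- fits[ok, , drop = FALSE]
  i <- which.max(fits$slope)
  structure(list(rate = fits$slope[i], r2 = fits$r2[i],
                 window_start_min = times[fits$start[i]],
                 n_windows = nrow(fits)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "max growth rate %.4f per hour (R2 %.4f, window at t = %.0f min, %d qualifying windows)\n",
    x$rate, x$r2, x$window_start_min, x$n_windows))
  invisible(x)
}

#' Relative fitness and selection coefficient of an evolved clone
#'
#' Relative fitness is the mean maximum growth rate over technical replicates
#' divided by the rate of the matched ancestor measured on the same plate;
#' the selection coefficient is s = relative fitness - 1.
#'
#' @param evolved_rates growth rates (per hour) of the technical replicates;
#'   three are expected and a warning is raised otherwise (the mean of those
#'   available is used).
#' @param ancestor_rate growth rate of the ancestor (per hour), must be > 0.
#' @param clone_id,environment optional labels carried through.
#' @return one-row data.frame: `clone_id`, `environment`, `growth_rate`,
#'   `ancestor_rate`, `relative_fitness`, `s`.
#' @export
relative_fitness <- function(evolved_rates, ancestor_rate,
                             clone_id = NA_character_,
                             environment = NA_character_) {
  if (!is.finite(ancestor_rate) || ancestor_rate <= 0) {
    stop("ancestor_rate must be positive")
  }
  evolved_rates <- evolved_rates[is.finite(evolved_rates)]
  if (length(evolved_rates) == 0) stop("no evolved replicate rates supplied")
  if (length(evolved_rates) != 3) {
    warning("expected 3 technical replicates, got ", length(evolved_rates),
            "; using the mean of those available")
  }
  rel <- mean(evolved_rates) / ancestor_rate
  data.frame(clone_id = clone_id, environment = environment,
             growth_rate = mean(evolved_rates), ancestor_rate = ancestor_rate,
             relative_fitness = rel, s = rel - 1, stringsAsFactors = FALSE)
}

# blank-subtract a long-format plate data.frame in place
subtract_blanks <- function(data, config) {
  blanks <- data[data$role == "blank", ]
  if (nrow(blanks) == 0) return(data)
  if (config$blank_policy == "per-plate-mean") {
    data$od600 <- data$od600 - mean(blanks$od600)
  } else {
    bw <- tapply(blanks$od600, blanks$well, mean)
    adj <- bw[data$well]
    adj[is.na(adj)] <- mean(blanks$od600)
    data$od600 <- data$od600 - adj
  }
  data
}

#' Fit every well of a plate and compute per-clone fitness
#'
#' The standard per-plate pipeline: subtract blanks, fit the maximum growth
#' rate of every non-blank well, average technical replicates of each evolved
#' clone, and divide by its matched ancestor's rate on the same plate.
#'
#' @param data long-format plate data.frame with columns `plate`, `well`,
#'   `clone`, `role` (evolved/ancestor/reference/blank), `environment`,
#'   `time_min`, `od600`, `replicate`.
#' @param config a [growth_fit_config()].
#' @param ancestor_of named character vector mapping evolved clone ids to the
#'   ancestor clone id on the same plate; a single unnamed value applies to
#'   all evolved clones.
#' @return data.frame of per-clone fitness records (see
#'   [relative_fitness()]), plus a `rates` attribute with every well fit.
#' @export
plate_fitness <- function(data, config = growth_fit_config(),
                          ancestor_of = NULL) {
  data <- subtract_blanks(data, config)
  wells <- unique(data[data$role != "blank",
                       c("plate", "well", "clone", "role", "environment",
                         "replicate")])
  wells$rate <- vapply(seq_len(nrow(wells)), function(i) {
    d <- data[data$plate == wells$plate[i] & data$well == wells$well[i], ]
    d <- d[order(d$time_min), ]
    tryCatch(fit_max_growth_rate(d$time_min, d$od600, config)$rate,
             error = function(e) NA_real_)
  }, numeric(1))
  anc <- wells[wells$role == "ancestor", ]
  anc_rate <- tapply(anc$rate, anc$clone, mean, na.rm = TRUE)
  evolved <- wells[wells$role == "evolved", ]
  out <- lapply(unique(evolved$clone), function(cl) {
    a_id <- if (is.null(ancestor_of)) {
      names(anc_rate)[1]
    } else if (is.null(names(ancestor_of)) && length(ancestor_of) == 1) {
      ancestor_of
    } else {
      unname(ancestor_of[cl])
    }
    rates <- evolved$rate[evolved$clone == cl]
    rates <- rates[is.finite(rates)]
    if (length(rates) == 0 || is.na(a_id) || !(a_id %in% names(anc_rate))) {
      return(NULL)
    }
    suppressWarnings(
      relative_fitness(rates, anc_rate[[a_id]], clone_id = cl,
                       environment = evolved$environment[
                         evolved$clone == cl][1]))
  })
  res <- do.call(rbind, out)
  attr(res, "rates") <- wells
  res
}

#' Quality control of one plate run
#'
#' Flags contaminated blanks (blank readings rising above the detection
#' floor), reports the reference-strain rate and its deviation from a
#' supplied cross-plate mean, and lists evolved clones lacking a matched
#' ancestor well on the plate.
#'
#' @param data long-format plate data.frame (see [plate_fitness()]).
#' @param config a [growth_fit_config()].
#' @param reference_mean,reference_sd optional cross-plate mean and sd of the
#'   reference-strain rate; when given, the plate passes if its reference
#'   rate lies within 2 sd of the mean.
#' @return list with `has_blank`, `has_reference`, `blank_contaminated`,
#'   `reference_rate`, `reference_ok` (NA if no cross-plate stats given),
#'   `unmatched_clones`, and overall `qc_failed`.
#' @export
plate_qc <- function(data, config = growth_fit_config(),
                     reference_mean = NULL, reference_sd = NULL) {
  blanks <- data[data$role == "blank", ]
  refs <- data[data$role == "reference", ]
  has_blank <- nrow(blanks) > 0
  has_ref <- nrow(refs) > 0
  contaminated <- FALSE
  if (has_blank) {
    # a contaminated blank drifts upward well past the floor
    rng <- tapply(blanks$od600, blanks$well,
                  function(z) max(z) - stats::median(z[seq_len(min(5, length(z)))]))
    contaminated <- any(rng > config$min_od * 2)
  }
  ref_rate <- NA_real_
  ref_ok <- NA
  if (has_ref) {
    d <- subtract_blanks(data, config)
    rr <- vapply(unique(refs$well), function(w) {
      dd <- d[d$well == w & d$role == "reference", ]
      dd <- dd[order(dd$time_min), ]
      tryCatch(fit_max_growth_rate(dd$time_min, dd$od600, config)$rate,
               error = function(e) NA_real_)
    }, numeric(1))
    ref_rate <- mean(rr, na.rm = TRUE)
    if (!is.null(reference_mean) && !is.null(reference_sd)) {
      ref_ok <- abs(ref_rate - reference_mean) <= 2 * reference_sd
    }
  }
  evolved <- unique(data$clone[data$role == "evolved"])
  ancestors <- unique(data$clone[data$role == "ancestor"])
  unmatched <- if (length(ancestors) == 0) evolved else character(0)
  list(has_blank = has_blank, has_reference = has_ref,
       blank_contaminated = contaminated, reference_rate = ref_rate,
       reference_ok = ref_ok, unmatched_clones = unmatched,
       qc_failed = !has_blank || !has_ref || contaminated)
}

#' Read long-format plate-reader CSV
#'
#' Expected columns: plate, well, clone, role, environment, time_min, od600,
#' replicate.
#'
#' @param path CSV file path.
#' @return data.frame of readings.
#' @export
read_growth_curves <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read wide-format plate-reader CSV with a plate-map sidecar
#'
#' The wide file has a `time_min` column and one column per well; the map CSV
#' has columns well, clone, role, environment, replicate (and optionally
#' plate).
#'
#' @param path wide-format CSV path.
#' @param map_path plate-map CSV path.
#' @return long-format data.frame as produced by [read_growth_curves()].
#' @export
read_plate_wide <- function(path, map_path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  wells <- setdiff(names(wide), "time_min")
  missing <- setdiff(wells, map$well)
  if (length(missing) > 0) {
    stop("wells absent from plate map: ", paste(missing, collapse = ", "))
  }
  long <- do.call(rbind, lapply(wells, function(w) {
    m <- map[map$well == w, ][1, ]
    data.frame(plate = if ("plate" %in% names(map)) m$plate else "plate1",
               well = w, clone = m$clone, role = m$role,
               environment = m$environment, time_min = wide$time_min,
               od600 = wide[[w]],
               replicate = if ("replicate" %in% names(map)) m$replicate else 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
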