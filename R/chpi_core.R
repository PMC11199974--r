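#' Switching-function contact parameters
#'
#' Parameters of the rational switching function used for the CH-pi
#' coordination number: cutoff `r0` (nm) and integer exponents `n < m`.
#' Defaults are r0 = 0.3 nm, n = 6, m = 12.
#'
#' @param r0 cutoff distance in nm
#' @param n numerator exponent
#' @param m denominator exponent
#' @return object of class `contact_params`
#' @export
contact_params <- function(r0 = 0.3, n = 6L, m = 12L) {
  stopifnot(is.numeric(r0), length(r0) == 1L, r0 > 0,
            n > 0, m > n, n == as.integer(n), m == as.integer(m))
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m)),
            class = "contact_params")
}

#' Switching-function value for an H-to-ring-center distance
#'
#' Computes c(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m), the smooth contact
#' indicator: ~1 when the hydrogen sits on the ring center, decaying past
#' r0. The removable singularity at r = r0 has limit n/m. For the default
#' exponents (m = 2n) the closed form 1/(1 + (r/r0)^n) is used, which is
#' exact everywhere including r = r0.
#'
#' @param rij distance(s) in nm, >= 0 (vectorized)
#' @param params a [contact_params()] object
#' @return value(s) in (0, 1]
#' @export
switching_value <- function(rij, params = contact_params()) {
  if (any(rij < 0)) stop("distance must be non-negative", call. = FALSE)
  x <- rij / params$r0
  if (params$m == 2L * params$n) {
    return(1 / (1 + x^params$n))
  }
  out <- (1 - x^params$n) / (1 - x^params$m)
  at_limit <- abs(rij - params$r0) < 1e-9
  out[at_limit] <- params$n / params$m
  out
}

#' CH-pi coordination number of one residue in one frame
#'
#' Sum of switching-function values over all (donor hydrogen, ring center)
#' pairs. For Trp both rings contribute to the sum.
#'
#' @param frame_coords atoms x 3 coordinate matrix (nm)
#' @param rings list of rings (all belonging to one residue)
#' @param donors list of C-H donors from [infer_ch_donors()]
#' @param params a [contact_params()] object
#' @return non-negative coordination number
#' @export
coordination_number <- function(frame_coords, rings, donors,
                                params = contact_params()) {
  if (length(rings) == 0L) {
    stop("coordination number undefined: residue has no aromatic ring",
         call. = FALSE)
  }
  if (length(donors) == 0L) return(0)
  centers <- t(vapply(rings, ring_center, numeric(3), frame_coords = frame_coords))
  h_idx <- vapply(donors, `[[`, integer(1), "hydrogen_index")
  hpos <- frame_coords[h_idx, , drop = FALSE]
  total <- 0
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(rowSums((hpos - matrix(centers[k, ], nrow = nrow(hpos),
                                     ncol = 3L, byrow = TRUE))^2))
    total <- total + sum(switching_value(d, params))
  }
  total
}

#' Per-frame CH-pi contact time series for one residue
#'
#' @param trajectory a `glyco_trajectory`
#' @param residue_key chain-qualified residue id (`"A:28"`) or a residue key
#'   list as produced by the detection functions
#' @param donors list of C-H donors; defaults to [infer_ch_donors()] on the
#'   trajectory
#' @param params a [contact_params()] object
#' @param stride keep every `stride`-th frame
#' @return object of class `contact_series` with `residue_key`, `values`,
#'   `time_step_ns`
#' @export
contact_timeseries <- function(trajectory, residue_key, donors = NULL,
                               params = contact_params(), stride = 1L) {
  if (is.list(residue_key)) {
    sel <- paste0(residue_key$chain_id, ":", residue_key$residue_number,
                  ifelse(nzchar(residue_key$insertion_code),
                         residue_key$insertion_code, ""))
  } else {
    sel <- residue_key
  }
  rings <- detect_aromatic_rings(trajectory, residue_selection = sel)
  if (length(rings) == 0L) {
    stop("residue ", sel, " has no aromatic ring; contact statistic undefined",
         call. = FALSE)
  }
  if (is.null(donors)) donors <- infer_ch_donors(trajectory)
  if (length(donors) == 0L) {
    stop("no C-H donors selected; contact statistic undefined", call. = FALSE)
  }
  frames <- seq(1L, n_frames(trajectory), by = stride)
  values <- vapply(frames, function(f) {
    coordination_number(frame_coords(trajectory, f), rings, donors, params)
  }, numeric(1))
  structure(list(residue_key = rings[[1L]]$residue_key, values = values,
                 time_step_ns = trajectory$time_step_ns * stride),
            class = "contact_series")
}

#' Mean contact number after burn-in
#'
#' @param series a `contact_series`
#' @param burn_in_frames frames to discard from the start
#' @return arithmetic mean of the remaining values
#' @export
mean_contacts <- function(series, burn_in_frames = 0L) {
  v <- series$values
  if (burn_in_frames >= length(v)) {
    stop("burn-in leaves no frames", call. = FALSE)
  }
  mean(v[(burn_in_frames + 1L):length(v)])
}

#' Contact-number distribution
#'
#' Histograms the series into half-open bins [k*w, (k+1)*w) and also rounds
#' each value to the nearest integer (ties to even) to give integer contact
#' counts per frame.
#'
#' @param series a `contact_series`
#' @param bin_width histogram bin width (dimensionless contacts)
#' @return object of class `contact_distribution` with `bin_edges`,
#'   `counts`, `densities`, `integer_counts` (named vector)
#' @export
contact_distribution <- function(series, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  v <- series$values
  k <- floor(v / bin_width)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  edges <- seq(0, (kmax + 1L) * bin_width, by = bin_width)
  ints <- round(v)
  tab <- table(factor(ints, levels = seq(min(ints), max(ints))))
  structure(list(
    bin_edges = edges,
    counts = counts,
    densities = counts / (sum(counts) * bin_width),
    integer_counts = setNames(as.integer(tab), names(tab))
  ), class = "contact_distribution")
}

#' Write a contact series to CSV
#'
#' Columns: frame, time_ns (NA when the time step is unknown), value.
#'
#' @param series a `contact_series`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_contact_series <- function(series, path) {
  n <- length(series$values)
  ts <- series$time_step_ns
  df <- data.frame(frame = seq_len(n) - 1L,
                   time_ns = if (is.na(ts)) NA_real_ else (seq_len(n) - 1L) * ts,
                   value = series$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
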