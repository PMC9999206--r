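#' Poisson probability of k cells in a droplet
#'
#' Random encapsulation loads cells into droplets independently, so the
#' number of cells per droplet follows a Poisson distribution with mean
#' \eqn{\lambda} (the expected number of cells per droplet volume).
#'
#' @param k Non-negative integer cell count (vectorised).
#' @param lam Poisson mean \eqn{\lambda \ge 0}.
#' @return Probability \eqn{P(X = k) = \lambda^k e^{-\lambda}/k!}.
#' @examples
#' poisson_pmf(1, 1)      # peak single-cell probability, ~0.368
#' poisson_pmf(0:4, 0.5)
#' @export
poisson_pmf <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(lam < 0)) stop("lam must be >= 0")
  stats::dpois(k, lam)
}

#' Probability of a single-cell droplet
#'
#' @inheritParams poisson_pmf
#' @return \eqn{P(X = 1)}, maximal at \eqn{\lambda = 1}.
#' @export
single_cell_probability <- function(lam) poisson_pmf(1L, lam)

#' Probability of a multi-cell droplet
#'
#' @inheritParams poisson_pmf
#' @return \eqn{P(X \ge 2) = 1 - P(0) - P(1)}; monotone increasing in
#'   \eqn{\lambda}.
#' @examples
#' multi_cell_probability(1)     # ~0.264
#' multi_cell_probability(0.05)  # ~0.0012, "below 0.5%" regime
#' @export
multi_cell_probability <- function(lam) {
  if (any(lam < 0)) stop("lam must be >= 0")
  stats::ppois(1L, lam, lower.tail = FALSE)
}

#' Theoretical single-cell purity without multi-cell removal
#'
#' Among droplets that contain at least one cell, the fraction containing
#' exactly one: \eqn{P(1)/P(>0)}. This is the best achievable single-cell
#' purity when only empty droplets are rejected.
#'
#' @param lam Poisson mean \eqn{\lambda > 0}.
#' @return Fraction in (0, 1]; tends to 1 as \eqn{\lambda \to 0^+} and is
#'   monotone decreasing (below 60\% already at \eqn{\lambda = 1}).
#' @export
theoretical_purity <- function(lam) {
  if (any(lam <= 0)) stop("theoretical_purity undefined at lam <= 0")
  single_cell_probability(lam) / (1 - poisson_pmf(0L, lam))
}

#' Mean cells per droplet from suspension concentration
#'
#' Computes \eqn{\lambda} as the expected number of cells in one droplet
#' volume: \eqn{\lambda = C \cdot (\pi/6) d^3}. This is an approximation of
#' the loading of a flow-focusing generator from a well-mixed suspension;
#' printed concentration-to-\eqn{\lambda} calibrations of real devices can
#' differ (see [encapsulation_presets()]).
#'
#' @param concentration_per_ml Cell concentration in cells/ml.
#' @param diameter_um Droplet diameter in micrometres.
#' @return Dimensionless \eqn{\lambda}.
#' @examples
#' lambda_from_suspension(1e7, 40)  # ~0.335
#' @export
lambda_from_suspension <- function(concentration_per_ml, diameter_um) {
  if (any(concentration_per_ml < 0)) stop("concentration must be >= 0")
  if (any(diameter_um <= 0)) stop("diameter must be > 0")
  vol_ml <- (pi / 6) * (diameter_um * 1e-4)^3 # um -> cm, 1 cm^3 = 1 ml
  concentration_per_ml * vol_ml
}

#' Theoretical sorted single-cell throughput
#'
#' With a sorter capped at `max_sort_rate_hz` droplet interrogations per
#' second, the sustained rate of collected single-cell droplets is the cap
#' times the single-cell probability.
#'
#' @inheritParams poisson_pmf
#' @param max_sort_rate_hz Maximum droplet rate the sorter sustains (Hz).
#' @return Single-cell droplets per second.
#' @examples
#' theoretical_sorted_throughput(0.05, 200)  # < 10 per second
#' theoretical_sorted_throughput(0.5, 200)
#' @export
theoretical_sorted_throughput <- function(lam, max_sort_rate_hz) {
  if (any(lam < 0)) stop("lam must be >= 0")
  if (any(max_sort_rate_hz <= 0)) stop("max_sort_rate_hz must be > 0")
  max_sort_rate_hz * single_cell_probability(lam)
}

#' Encapsulation parameters
#'
#' Bundles the settings of the droplet generator. Either `lam` or
#' `cell_concentration` must be given; if both, `lam` takes precedence.
#'
#' @param lam Mean cells per droplet (dimensionless, >= 0).
#' @param cell_concentration Cells per ml; converted with
#'   [lambda_from_suspension()] when `lam` is missing.
#' @param droplet_diameter_um Mean droplet diameter (default 40).
#' @param generation_rate_hz Droplet generation rate (default 200).
#' @param diameter_cv Coefficient of variation of droplet diameter
#'   (default 0.03, near-monodisperse flow focusing; up to 0.3 allowed).
#' @param arrival `"poisson"` (exponential gaps) or `"regular"`
#'   (quasi-periodic, as flow focusing tends to produce).
#' @param permeabilized_fraction Fraction of cells with a permeabilized
#'   membrane (non-viable; electrically transparent at high frequency).
#' @return An object of class `encapsulation_params`.
#' @export
encapsulation_params <- function(lam = NULL, cell_concentration = NULL,
                                 droplet_diameter_um = 40,
                                 generation_rate_hz = 200,
                                 diameter_cv = 0.03,
                                 arrival = c("poisson", "regular"),
                                 permeabilized_fraction = 0) {
  arrival <- match.arg(arrival)
  if (is.null(lam)) {
    if (is.null(cell_concentration))
      stop("give either lam or cell_concentration")
    lam <- lambda_from_suspension(cell_concentration, droplet_diameter_um)
  }
  stopifnot(lam >= 0, droplet_diameter_um > 0, generation_rate_hz > 0,
            diameter_cv >= 0, diameter_cv <= 0.3,
            permeabilized_fraction >= 0, permeabilized_fraction <= 1)
  structure(list(lam = lam,
                 droplet_diameter_um = droplet_diameter_um,
                 generation_rate_hz = generation_rate_hz,
                 diameter_cv = diameter_cv,
                 arrival = arrival,
                 permeabilized_fraction = permeabilized_fraction),
            class = "encapsulation_params")
}

#' Named encapsulation presets
#'
#' The two operating points used throughout the analyses: a conventional
#' low-loading condition (1e5 cells/ml, \eqn{\lambda = 0.05}) and a
#' high-loading condition (1e7 cells/ml, \eqn{\lambda = 0.5}). The
#' (concentration, \eqn{\lambda}) pairings are the published device
#' calibrations and are not consistent with [lambda_from_suspension()]'s
#' volume arithmetic; both routes are deliberately exposed.
#'
#' @param name One of `"paper_low"`, `"paper_high"`.
#' @return An `encapsulation_params` object.
#' @export
encapsulation_presets <- function(name = c("paper_high", "paper_low")) {
  name <- match.arg(name)
  switch(name,
    paper_low  = encapsulation_params(lam = 0.05),
    paper_high = encapsulation_params(lam = 0.5))
}

#' Simulate a ground-truth droplet stream
#'
#' Draws `n` droplets with i.i.d. Poisson(\eqn{\lambda}) cell counts,
#' normally distributed diameters, uniform fractional cell positions along
#' the droplet axis, Bernoulli viability flags, and arrival times from the
#' configured arrival process.
#'
#' @param params An [encapsulation_params()] object.
#' @param n Number of droplets (> 0).
#' @param seed Integer seed; the stream is reproducible per seed.
#' @return A data.frame of class `droplet_stream` with columns
#'   `droplet_id`, `arrival_time_s`, `velocity_um_s`, `diameter_um`,
#'   `cell_count`, and list columns `cell_positions` (fractions in `[0,1]`)
#'   and `viable_flags`.
#' @export
sample_stream <- function(params, n, seed) {
  stopifnot(inherits(params, "encapsulation_params"), n > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  counts <- stats::rpois(n, params$lam)
  diam <- stats::rnorm(n, params$droplet_diameter_um,
                       params$diameter_cv * params$droplet_diameter_um)
  diam <- pmax(diam, 0.2 * params$droplet_diameter_um)
  gaps <- if (params$arrival == "poisson") {
    stats::rexp(n, rate = params$generation_rate_hz)
  } else {
    rep(1 / params$generation_rate_hz, n)
  }
  arrival <- cumsum(gaps)
  positions <- lapply(counts, function(k) stats::runif(k))
  viable <- lapply(counts, function(k) {
    stats::runif(k) >= params$permeabilized_fraction
  })
  out <- data.frame(droplet_id = seq_len(n),
                    arrival_time_s = arrival,
                    velocity_um_s = 40000, # nominal transport velocity
                    diameter_um = diam,
                    cell_count = counts)
  out$cell_positions <- positions
  out$viable_flags <- viable
  class(out) <- c("droplet_stream", "data.frame")
  out
}

#' Write / read a droplet stream as CSV
#'
#' List columns are serialized as semicolon-separated values so the file is
#' plain text and round-trips exactly.
#'
#' @param stream A `droplet_stream` data.frame.
#' @param path File path.
#' @return `read_stream()` returns a `droplet_stream`; `write_stream()`
#'   returns `path` invisibly.
#' @export
write_stream <- function(stream, path) {
  flat <- data.frame(
    droplet_id = stream$droplet_id,
    arrival_time_s = stream$arrival_time_s,
    velocity_um_s = stream$velocity_um_s,
    diameter_um = stream$diameter_um,
    cell_count = stream$cell_count,
    cell_positions = vapply(stream$cell_positions,
                            function(p) paste(format(p, digits = 17),
                                              collapse = ";"), ""),
    viable_flags = vapply(stream$viable_flags,
                          function(v) paste(as.integer(v), collapse = ";"),
                          ""))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(cell_positions = "character",
                                         viable_flags = "character"))
  flat$cell_positions <- lapply(strsplit(flat$cell_positions, ";"),
                                function(s) as.numeric(s[nzchar(s)]))
  flat$viable_flags <- lapply(strsplit(flat$viable_flags, ";"),
                              function(s) as.integer(s[nzchar(s)]) == 1L)
  class(flat) <- c("droplet_stream", "data.frame")
  flat
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
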