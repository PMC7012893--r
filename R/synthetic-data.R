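#' Generate a synthetic two-species point pattern
#'
#' Emulates the particle placements digitized from electron micrographs
#' of nanoparticle assemblies, in three regimes:
#'
#' * `"beh_lattice"` — anchors of species A on a jittered square grid at
#'   `anchor_density_per_cm2`, each with exactly one species-B partner at
#'   a distance drawn from Normal(`pair_distance_mean_nm`,
#'   `pair_distance_sd_nm`) truncated positive (by resampling) at a
#'   uniform angle. This is the scaffold-controlled regime in which the
#'   heterotype nearest-neighbour distance recovers the pair-distance
#'   setpoint.
#' * `"csr"` — complete spatial randomness: each species is an
#'   independent homogeneous Poisson pattern with intensity
#'   `intensity_per_nm2`.
#' * `"tethered"` — Poisson anchors (density as in `"csr"` semantics but
#'   using `anchor_density_per_cm2`) with one partner each, drawn as in
#'   `"beh_lattice"`; intended for loosely tethered partners, typically
#'   with a larger `pair_distance_sd_nm`.
#'
#' Partner points are re-drawn (new angle) until they land inside the
#' region, which preserves the pair-distance distribution exactly.
#'
#' @param mode Generation regime (see above).
#' @param region Rectangle `c(x_min, y_min, x_max, y_max)` in nm; default
#'   a 300 x 300 nm field.
#' @param anchor_density_per_cm2 Species-A anchor density for the paired
#'   regimes (default 1.1e11 cm^-2, about 100 anchors per 300 x 300 nm
#'   field).
#' @param intensity_per_nm2 Per-species Poisson intensity for `"csr"`
#'   (default 1e-3 nm^-2).
#' @param pair_distance_mean_nm,pair_distance_sd_nm Setpoints of the A-B
#'   pair distance distribution (defaults 9.1 and 2.8 nm).
#' @param jitter_sd_nm Gaussian jitter of the lattice anchors
#'   (`"beh_lattice"` only; default 2 nm).
#' @param species Two labels, A (anchor) first (default `c("A", "B")`).
#' @param seed Optional integer seed; generation is deterministic per
#'   seed.
#'
#' @return A `point_pattern` tibble (`x_nm`, `y_nm`, `species`).
#' @examples
#' pat <- make_point_pattern("beh_lattice", seed = 1)
#' nn <- heterotype_nn_distances(pat)
#' distance_summary(nn)
#' @export
make_point_pattern <- function(mode = c("beh_lattice", "csr", "tethered"),
                               region = c(0, 0, 300, 300),
                               anchor_density_per_cm2 = 1.1e11,
                               intensity_per_nm2 = 1e-3,
                               pair_distance_mean_nm = 9.1,
                               pair_distance_sd_nm = 2.8,
                               jitter_sd_nm = 2,
                               species = c("A", "B"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (length(region) != 4L || region[3] <= region[1] || region[4] <= region[2]) {
    stop_bad_arg("`region` must be c(x_min, y_min, x_max, y_max) with positive extent.")
  }
  if (pair_distance_sd_nm < 0 || jitter_sd_nm < 0) {
    stop_bad_arg("standard deviations must be nonnegative.")
  }
  if (length(species) != 2L) stop_bad_arg("`species` must give two labels.")
  if (!is.null(seed)) set.seed(seed)
  width <- region[3] - region[1]
  height <- region[4] - region[2]

  if (mode == "csr") {
    check_positive_scalar(intensity_per_nm2, "intensity_per_nm2")
    n_a <- rpois(1, intensity_per_nm2 * width * height)
    n_b <- rpois(1, intensity_per_nm2 * width * height)
    if (n_a < 1L || n_b < 1L) {
      stop_bad_arg("region too small for at least one point of each species.")
    }
    pts <- tibble(
      x_nm = c(runif(n_a, region[1], region[3]), runif(n_b, region[1], region[3])),
      y_nm = c(runif(n_a, region[2], region[4]), runif(n_b, region[2], region[4])),
      species = rep(species, c(n_a, n_b))
    )
    return(point_pattern(pts, region))
  }

  check_positive_scalar(anchor_density_per_cm2, "anchor_density_per_cm2")
  density_nm2 <- anchor_density_per_cm2 / NM_PER_CM^2
  if (mode == "beh_lattice") {
    pitch <- 1 / sqrt(density_nm2)
    if (region[1] + pitch / 2 > region[3] || region[2] + pitch / 2 > region[4]) {
      stop_bad_arg("region too small for at least one anchor at this density.")
    }
    gx <- seq(region[1] + pitch / 2, region[3], by = pitch)
    gy <- seq(region[2] + pitch / 2, region[4], by = pitch)
    anchors <- tidyr::expand_grid(x_nm = gx, y_nm = gy)
    n_a <- nrow(anchors)
    ax <- pmin(pmax(anchors$x_nm + rnorm(n_a, 0, jitter_sd_nm), region[1]), region[3])
    ay <- pmin(pmax(anchors$y_nm + rnorm(n_a, 0, jitter_sd_nm), region[2]), region[4])
  } else { # tethered
    n_a <- rpois(1, density_nm2 * width * height)
    if (n_a < 1L) {
      stop_bad_arg("region too small for at least one anchor at this density.")
    }
    ax <- runif(n_a, region[1], region[3])
    ay <- runif(n_a, region[2], region[4])
  }

  d <- rnorm(n_a, pair_distance_mean_nm, pair_distance_sd_nm)
  while (any(bad <- d <= 0)) {
    d[bad] <- rnorm(sum(bad), pair_distance_mean_nm, pair_distance_sd_nm)
  }
  bx <- rep(NA_real_, n_a)
  by <- rep(NA_real_, n_a)
  pending <- seq_len(n_a)
  tries <- 0L
  while (length(pending) && tries < 1000L) {
    theta <- runif(length(pending), 0, 2 * pi)
    px <- ax[pending] + d[pending] * cos(theta)
    py <- ay[pending] + d[pending] * sin(theta)
    ok <- px >= region[1] & px <= region[3] & py >= region[2] & py <= region[4]
    bx[pending[ok]] <- px[ok]
    by[pending[ok]] <- py[ok]
    pending <- pending[!ok]
    tries <- tries + 1L
  }
  if (length(pending)) {
    stop_bad_arg("could not place partner points inside the region; enlarge it.")
  }
  pts <- tibble(
    x_nm = c(ax, bx),
    y_nm = c(ay, by),
    species = rep(species, c(n_a, n_a))
  )
  point_pattern(pts, region)
}

#' Generate a synthetic biomarker cohort
#'
#' Draws per-sample marker levels from group-specific lognormal
#' distributions linked across markers by a Gaussian copula with
#' exchangeable correlation. Lognormal marginals are used because serum
#' metabolite and protein levels are positive and right-skewed. The
#' default marker setpoints give a sarcosine normal-vs-cancer separation
#' with analytic AUC `pnorm(delta / (sdlog * sqrt(2))) = 0.98` and a PSA
#' marker that is elevated in both benign hyperplasia and cancer and so
#' discriminates the two poorly — the structure the combination analysis
#' assumes. Inter-marker correlation defaults to 0 (the markers carry
#' near-orthogonal information).
#'
#' @param n_per_group Named integer vector of group sizes (default 45
#'   each for `normal`, `BPH`, `PCa`).
#' @param markers Named list; each element is
#'   `list(meanlog = <named vector by group>, sdlog = <scalar>)`. The
#'   default defines `sarcosine_molar` and `psa`.
#' @param correlation Copula correlation between markers, in (-1, 1)
#'   (default 0).
#' @param seed Optional integer seed.
#'
#' @return Tibble: `sample_id`, `group`, one column per marker.
#' @examples
#' co <- make_cohort(seed = 7)
#' dplyr::count(co, group)
#' @export
make_cohort <- function(n_per_group = c(normal = 45, BPH = 45, PCa = 45),
                        markers = default_cohort_markers(),
                        correlation = 0,
                        seed = NULL) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop_bad_arg("`n_per_group` must be a named vector of group sizes.")
  }
  if (any(n_per_group < 2)) stop_bad_arg("every group needs at least 2 samples.")
  if (!is.numeric(correlation) || correlation <= -1 || correlation >= 1) {
    stop_bad_arg("`correlation` must lie in (-1, 1).")
  }
  k <- length(markers)
  if (k < 1L) stop_bad_arg("at least one marker must be specified.")
  for (m in markers) {
    if (any(m$sdlog <= 0)) stop_bad_arg("marker sdlog must be positive.")
    if (!all(names(n_per_group) %in% names(m$meanlog))) {
      stop_bad_arg("every marker needs a meanlog for every group.")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  # exchangeable Gaussian copula across markers
  sigma <- matrix(correlation, k, k)
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop_bad_arg("`correlation` does not give a valid copula for this many markers.")
  })
  z <- matrix(rnorm(n * k), n, k) %*% ch
  out <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = groups
  )
  for (j in seq_len(k)) {
    m <- markers[[j]]
    out[[names(markers)[j]]] <- exp(m$meanlog[groups] + m$sdlog * z[, j])
  }
  out
}

#' @describeIn make_cohort Default marker setpoints (lognormal meanlog per
#'   group and sdlog) for sarcosine (molar) and PSA (arbitrary units).
#' @export
default_cohort_markers <- function() {
  sdlog_sarc <- 0.5
  # normal-vs-PCa shift for analytic AUC 0.98; BPH sits where PCa-vs-BPH
  # AUC is 0.75: delta = qnorm(auc) * sdlog * sqrt(2)
  d_pca <- qnorm(0.98) * sdlog_sarc * sqrt(2)
  d_bph <- d_pca - qnorm(0.75) * sdlog_sarc * sqrt(2)
  list(
    sarcosine_molar = list(
      meanlog = c(
        normal = log(2e-6),
        BPH = log(2e-6) + d_bph,
        PCa = log(2e-6) + d_pca
      ),
      sdlog = sdlog_sarc
    ),
    psa = list(
      meanlog = c(normal = 0, BPH = 1.2, PCa = 1.4),
      sdlog = 0.7
    )
  )
}

#' Generate a synthetic calibration dataset
#'
#' Emulates an electrochemical titration: replicate signals
#' `slope * log10(c) + intercept + Normal(0, noise_sd)` at each
#' concentration level, plus blank replicates at zero analyte drawn as
#' `Normal(blank_mean, noise_sd)`. The default `blank_mean` is
#' constructed so that the 3-delta threshold `blank_mean + 3 * noise_sd`
#' maps exactly to the lowest calibrated level — with the default grid,
#' a detection limit of 50 nM. Blanks are returned as rows with
#' `concentration_m = 0`, the convention [fit_log_linear()] expects.
#'
#' @param slope,intercept Dose-response parameters (signal in A versus
#'   log10 molar); defaults 2e-6 and 1.6e-5.
#' @param noise_sd Gaussian signal noise sd in A (default 5e-8).
#' @param levels Concentration levels in molar, at least 3, all positive;
#'   default seven levels spanning 5e-8 to 1e-2 M (5.3 decades).
#' @param n_replicates Replicates per level (default 3).
#' @param n_blanks Blank replicates (default 10).
#' @param blank_mean Mean blank signal; default
#'   `slope * log10(min(levels)) + intercept - 3 * noise_sd`.
#' @param seed Optional integer seed.
#'
#' @return Tibble: `concentration_m`, `signal_a`, `replicate`.
#' @examples
#' cal <- make_calibration_dataset(noise_sd = 0, seed = 1)
#' lod_3delta(fit_log_linear(cal)) # exactly the lowest level
#' @export
make_calibration_dataset <- function(slope = 2e-6,
                                     intercept = 1.6e-5,
                                     noise_sd = 5e-8,
                                     levels = c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                                     n_replicates = 3,
                                     n_blanks = 10,
                                     blank_mean = NULL,
                                     seed = NULL) {
  if (length(levels) < 3L || any(levels <= 0)) {
    stop_bad_arg("`levels` must be at least 3 positive concentrations.")
  }
  if (noise_sd < 0) stop_bad_arg("`noise_sd` must be nonnegative.")
  check_positive_scalar(n_replicates, "n_replicates")
  check_positive_scalar(n_blanks, "n_blanks")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(blank_mean)) {
    blank_mean <- slope * log10(min(levels)) + intercept - 3 * noise_sd
  }
  conc <- rep(sort(levels), each = n_replicates)
  signals <- slope * log10(conc) + intercept + rnorm(length(conc), 0, noise_sd)
  blanks <- rnorm(n_blanks, blank_mean, noise_sd)
  dplyr::bind_rows(
    tibble(
      concentration_m = conc, signal_a = signals,
      replicate = rep(seq_len(n_replicates), times = length(levels))
    ),
    tibble(
      concentration_m = 0, signal_a = blanks,
      replicate = seq_len(as.integer(n_blanks))
    )
  )
}
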