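#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of the planted-effect cohort:
#' controls with one session, patients with a pre- and a post-treatment
#' session. The generator plants (i) a latent one-dimensional
#' sensorimotor-to-association axis that shapes the ROI correlation
#' structure, (ii) a contraction of that axis in patients (narrower
#' functional gradient span), (iii) a network-graded shift of vertex
#' surface-area scale in patients (wider structural gradient span), and
#' (iv) a post-treatment partial restoration of both effects whose
#' per-subject magnitude drives a planted motor-score improvement.
#'
#' @param n_controls,n_patients subject counts (patients have two sessions).
#' @param n_roi number of ROIs (default 100; scalable to 400).
#' @param n_networks number of canonical networks (default 7).
#' @param n_timepoints time points per session (default 240).
#' @param rho_within within-network correlation in \code{[0, 1)}.
#' @param rho_decay positive rate of correlation decay with axis distance:
#'   between-ROI correlation is
#'   \code{rho_within * exp(-rho_decay * |axis_i - axis_j|)}.
#' @param axis_positions per-network coordinates on the latent axis
#'   (length \code{n_networks}, arbitrary units, low = primary cortex).
#' @param span_shrink fraction in \code{[0, 1]} by which patient axis
#'   positions contract toward the mean (functional effect).
#' @param area_shift structural effect. A scalar is applied as a graded
#'   per-network multiplier \code{area_shift^u} with \code{u} the centered
#'   network axis scaled to \code{[-1, 1]} (a common scale factor would be
#'   invisible to a divergence of densities); a length-\code{n_networks}
#'   vector gives per-network multipliers directly. 1 = no effect.
#' @param restoration mean fraction of each planted effect reversed after
#'   treatment; each patient draws their own fraction from a normal with
#'   this mean and \code{restoration_sd}, truncated to \code{[0, 1]}.
#' @param restoration_sd between-patient spread of the restoration fraction.
#' @param clinical_noise_sd SD of the noise on the planted motor-score
#'   change. \code{NULL} (default) calibrates it so the correlation between
#'   the per-subject restoration magnitude and the planted score change is
#'   \code{clinical_target_r}.
#' @param clinical_target_r planted restoration-score correlation used for
#'   the default calibration (default 0.3).
#' @param clinical_slope motor-score points of improvement per unit
#'   restoration (default 6, on a UPDRS-III-like 0-108 scale).
#' @param vertices_per_roi vertex surface-area samples per ROI (default 50).
#' @param axis_jitter_sd SD of the ROI-level jitter added to the network
#'   axis position, so ROIs inherit the network value with small scatter.
#' @param area_base,area_sdlog,area_axis_slope log-normal vertex-area model:
#'   median area \code{area_base} mm^2, log-SD \code{area_sdlog}, and a
#'   linear trend \code{area_axis_slope} of log-median area along the
#'   centered axis (this trend is what the structural gradient recovers).
#' @param network_labels canonical network names (default the 7-network
#'   scheme VIS, SMN, DAN, VAN, LIB, FPN, DMN).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return a validated \code{cohort_config} list.
#' @export
cohort_config <- function(n_controls = 30L, n_patients = 76L, n_roi = 100L,
                          n_networks = 7L, n_timepoints = 240L,
                          rho_within = 0.4, rho_decay = 1,
                          axis_positions = NULL,
                          span_shrink = 0.4, area_shift = 1.3,
                          restoration = 0.5, restoration_sd = 0.2,
                          clinical_noise_sd = NULL, clinical_target_r = 0.3,
                          clinical_slope = 6,
                          vertices_per_roi = 50L, axis_jitter_sd = 0.12,
                          area_base = 0.5, area_sdlog = 0.35,
                          area_axis_slope = 0.5,
                          network_labels = NULL, seed = 1L) {
  if (is.null(axis_positions)) {
    axis_positions <- default_axis_positions(n_networks)
  }
  if (is.null(network_labels)) {
    network_labels <- default_network_labels(n_networks)
  }
  cfg <- list(n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              n_roi = as.integer(n_roi), n_networks = as.integer(n_networks),
              n_timepoints = as.integer(n_timepoints),
              rho_within = rho_within, rho_decay = rho_decay,
              axis_positions = axis_positions, span_shrink = span_shrink,
              area_shift = area_shift, restoration = restoration,
              restoration_sd = restoration_sd,
              clinical_noise_sd = clinical_noise_sd,
              clinical_target_r = clinical_target_r,
              clinical_slope = clinical_slope,
              vertices_per_roi = as.integer(vertices_per_roi),
              axis_jitter_sd = axis_jitter_sd,
              area_base = area_base, area_sdlog = area_sdlog,
              area_axis_slope = area_axis_slope,
              network_labels = network_labels, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_controls < 2L || n_patients < 2L || n_roi < 2L || n_networks < 2L ||
        n_timepoints < 2L || vertices_per_roi < 2L) {
      stop("all counts must be >= 2")
    }
    if (rho_within < 0 || rho_within >= 1) stop("rho_within must be in [0, 1)")
    if (rho_decay < 0) stop("rho_decay must be nonnegative")
    if (span_shrink < 0 || span_shrink > 1) stop("span_shrink must be in [0, 1]")
    if (restoration < 0 || restoration > 1) stop("restoration must be in [0, 1]")
    if (restoration_sd < 0) stop("restoration_sd must be nonnegative")
    if (length(axis_positions) != n_networks) {
      stop("axis_positions must have exactly n_networks entries")
    }
    if (length(network_labels) != n_networks) {
      stop("network_labels must have exactly n_networks entries")
    }
    if (!(length(area_shift) %in% c(1L, n_networks)) || any(area_shift <= 0)) {
      stop("area_shift must be a positive scalar or length-n_networks vector")
    }
    if (n_roi < n_networks) stop("n_roi must be >= n_networks")
  })
  invisible(cfg)
}

default_axis_positions <- function(n_networks) {
  # evenly spaced along the primary-to-association hierarchy; ROI-level
  # jitter then makes the axis continuous across network boundaries, as the
  # empirical principal gradient is
  seq(0, 1, length.out = n_networks)
}

default_network_labels <- function(n_networks) {
  base <- c("VIS", "SMN", "DAN", "VAN", "LIB", "FPN", "DMN")
  if (n_networks <= 7L) base[seq_len(n_networks)]
  else c(base, paste0("NET", seq_len(n_networks - 7L)))
}

#' Generate a synthetic cohort with planted gradient effects
#'
#' Draws, deterministically given the configuration seed, a cohort of
#' control subjects (one session each) and patients (pre- and
#' post-treatment sessions). Time series are zero-mean Gaussian with ROI
#' covariance \code{C[i,j] = rho_within * exp(-rho_decay * |a_i - a_j|)}
#' (unit diagonal), where \code{a} is the latent axis — contracted toward
#' its mean by \code{span_shrink} for patient-pre sessions and by
#' \code{span_shrink * (1 - restoration_j)} post treatment. Vertex areas
#' are log-normal per ROI with a log-median trend along the axis; patient
#' sessions apply the (graded) \code{area_shift} multiplier, partially
#' restored post treatment. The planted motor-score change is a linear
#' function of the subject's restoration fraction plus Gaussian noise.
#'
#' Each subject consumes their own seeded generator substream, so a
#' subject's data do not depend on cohort composition and pre/post sessions
#' differ only through the planted effects plus fresh session noise.
#'
#' @param config a \code{cohort_config}.
#' @return a \code{synthetic_cohort}: list with \code{subjects}
#'   (data.frame: subject_id, group, age, sex, updrs3_pre, updrs3_post),
#'   \code{timeseries} and \code{vertex_areas} (named by
#'   \code{subject_session()} key), \code{partition} (roi_id, network) and
#'   \code{truth} (planted axis, per-group contracted axes and spans,
#'   per-subject restoration, clinical model coefficients).
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config
         else do.call(cohort_config, config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)

  set.seed(cfg$seed)
  net <- sort(rep_len(seq_len(cfg$n_networks), cfg$n_roi))
  roi_ids <- sprintf("ROI%03d", seq_len(cfg$n_roi))
  axis <- cfg$axis_positions[net] + stats::rnorm(cfg$n_roi, 0, cfg$axis_jitter_sd)
  partition <- data.frame(roi_id = roi_ids,
                          network = cfg$network_labels[net],
                          stringsAsFactors = FALSE)

  # demographics (group-matched; magnitudes follow a typical PD cohort)
  n_sub <- cfg$n_controls + cfg$n_patients
  group <- c(rep("control", cfg$n_controls), rep("patient", cfg$n_patients))
  subject_id <- c(sprintf("C%03d", seq_len(cfg$n_controls)),
                  sprintf("P%03d", seq_len(cfg$n_patients)))
  age <- round(pmin(pmax(stats::rnorm(n_sub, 59, 11), 35), 85), 1)
  sex <- stats::rbinom(n_sub, 1L, 0.5)

  # per-patient restoration fraction and planted clinical change
  resto <- truncnorm(cfg$n_patients, cfg$restoration, cfg$restoration_sd, 0, 1)
  noise_sd <- cfg$clinical_noise_sd
  if (is.null(noise_sd)) {
    s <- cfg$clinical_slope * truncnorm_sd(cfg$restoration,
                                           cfg$restoration_sd, 0, 1)
    noise_sd <- if (cfg$clinical_target_r > 0 && s > 0) {
      s * sqrt(1 / cfg$clinical_target_r^2 - 1)
    } else 1
  }
  b1 <- cfg$clinical_slope
  b0 <- 2.5 - b1 * cfg$restoration        # mean improvement ~2.5 points
  updrs_pre <- round(pmin(pmax(stats::rnorm(cfg$n_patients, 31.3, 12.1), 5),
                          108), 1)
  delta <- b0 + b1 * resto + stats::rnorm(cfg$n_patients, 0, noise_sd)
  updrs_post <- round(updrs_pre - delta, 1)

  subjects <- data.frame(subject_id = subject_id, group = group,
                         age = age, sex = sex,
                         updrs3_pre = c(rep(NA_real_, cfg$n_controls), updrs_pre),
                         updrs3_post = c(rep(NA_real_, cfg$n_controls), updrs_post),
                         stringsAsFactors = FALSE)

  # covariance factors per planted contraction level
  chol_cache <- new.env(parent = emptyenv())
  chol_for <- function(contraction) {
    key <- format(contraction, digits = 15)
    if (!is.null(chol_cache[[key]])) return(chol_cache[[key]])
    a <- mean(axis) + (1 - contraction) * (axis - mean(axis))
    C <- cfg$rho_within * exp(-cfg$rho_decay * abs(outer(a, a, "-")))
    diag(C) <- 1
    U <- tryCatch(chol(C), error = function(e) {
      stop("covariance not positive definite (rho_within=", cfg$rho_within,
           ", rho_decay=", cfg$rho_decay, ", contraction=", contraction, ")")
    })
    chol_cache[[key]] <- U
    U
  }

  # per-network structural multiplier exponent (graded along the axis)
  net_axis <- cfg$axis_positions
  u <- net_axis - mean(net_axis)
  u <- if (max(abs(u)) > 0) u / max(abs(u)) else u
  log_shift_net <- if (length(cfg$area_shift) == 1L) {
    u * log(cfg$area_shift)
  } else {
    log(cfg$area_shift)
  }
  log_shift_roi <- log_shift_net[net]
  meanlog_base <- log(cfg$area_base) +
    cfg$area_axis_slope * (axis - mean(axis))

  draw_session <- function(contraction, shift_scale) {
    U <- chol_for(contraction)
    Z <- matrix(stats::rnorm(cfg$n_timepoints * cfg$n_roi),
                cfg$n_timepoints, cfg$n_roi)
    ts <- Z %*% U
    colnames(ts) <- roi_ids
    meanlog <- meanlog_base + shift_scale * log_shift_roi
    areas <- lapply(seq_len(cfg$n_roi), function(i) {
      stats::rlnorm(cfg$vertices_per_roi, meanlog[i], cfg$area_sdlog)
    })
    names(areas) <- roi_ids
    list(ts = ts, areas = areas)
  }

  timeseries <- list()
  vertex_areas <- list()
  for (j in seq_len(n_sub)) {
    set.seed(subject_seed(cfg$seed, j))
    if (group[j] == "control") {
      s <- draw_session(0, 0)
      key <- subject_session(subject_id[j], "control")
      timeseries[[key]] <- s$ts
      vertex_areas[[key]] <- s$areas
    } else {
      r_j <- resto[j - cfg$n_controls]
      pre <- draw_session(cfg$span_shrink, 1)
      post <- draw_session(cfg$span_shrink * (1 - r_j), 1 - r_j)
      kp <- subject_session(subject_id[j], "pre")
      ko <- subject_session(subject_id[j], "post")
      timeseries[[kp]] <- pre$ts
      vertex_areas[[kp]] <- pre$areas
      timeseries[[ko]] <- post$ts
      vertex_areas[[ko]] <- post$areas
    }
  }

  contract <- function(contraction) {
    mean(axis) + (1 - contraction) * (axis - mean(axis))
  }
  truth <- list(
    axis = stats::setNames(axis, roi_ids),
    axis_pre = stats::setNames(contract(cfg$span_shrink), roi_ids),
    network = stats::setNames(cfg$network_labels[net], roi_ids),
    span_control = max(axis) - min(axis),
    span_pre = (1 - cfg$span_shrink) * (max(axis) - min(axis)),
    restoration = stats::setNames(resto, subject_id[group == "patient"]),
    clinical = list(b0 = b0, b1 = b1, noise_sd = noise_sd),
    log_shift_network = stats::setNames(log_shift_net, cfg$network_labels)
  )

  structure(list(subjects = subjects, timeseries = timeseries,
                 vertex_areas = vertex_areas, partition = partition,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Session key for a subject-session pair
#' @param subject_id subject identifier.
#' @param session one of \code{"control"}, \code{"pre"}, \code{"post"}.
#' @return character key used to index cohort time series and vertex areas.
#' @export
subject_session <- function(subject_id, session) {
  paste(subject_id, session, sep = "_")
}

# deterministic, collision-free per-subject substream seed (kept < 2^31)
subject_seed <- function(seed, j) {
  (as.numeric(seed) * 48271 + j * 9973) %% 2147483629
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

truncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# SD of a normal(mean, sd) truncated to [lo, hi]
truncnorm_sd <- function(mean, sd, lo, hi) {
  if (sd == 0) return(0)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  v <- 1 + (a * da - b * db) / Z - ((da - db) / Z)^2
  sd * sqrt(v)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d controls, %d patients (pre+post), %d ROIs, T=%d\n",
    x$config$n_controls, x$config$n_patients, x$config$n_roi,
    x$config$n_timepoints))
  invisible(x)
}
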