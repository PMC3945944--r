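#' Simulation configuration
#'
#' Describes a ground-truthed synthetic foraging trip: night-active dive
#' bouts of trapezoidal dives with injected transit steps, bottom steps and
#' wiggles; pressure-transducer surface-offset drift; Gaussian depth noise;
#' a 16-Hz jaw-acceleration channel with one high-amplitude transient per
#' true prey-capture attempt; and per-dive attempt counts drawn from a
#' Poisson log-link model on the standardized dive covariates with an
#' individual random intercept.
#'
#' Defaults emulate a breeding-season Antarctic fur seal trip: roughly nine
#' foraging nights, some fifty deep dives per night organised in bouts of
#' ~20 dives, maximum depths around 45 m with a tail of shallow (< 15 m)
#' dives, depth noise of 0.1 m (the depth sensor's resolution), and
#' dive-scale generative coefficients equal to the averaged dive-scale model
#' reported for that system.
#'
#' @param n_individuals Number of individuals in a simulated dataset.
#' @param n_nights Foraging nights per individual.
#' @param night_window Start/end of the nightly foraging window, seconds
#'   within a 24-h day (end may exceed 86400 to cross midnight).
#' @param bout_structure List: `mean_dives` per bout, `surface_mean_s`
#'   within-bout post-dive interval mean, `gap_mean_s` between-bout gap mean.
#' @param dive_shape List: `max_depth_mean`/`max_depth_sd` (m) of the
#'   bottom-arrival depth, `descent_speed`/`ascent_speed` (m/s, must exceed
#'   the 0.4 m/s phase threshold), `bottom_mean_s` target bottom duration,
#'   `shallow_prob` probability of a shallow (< 15 m) V-dive, which the
#'   deep-dive filters must exclude downstream.
#' @param feature_rates Poisson means per deep dive of injected features:
#'   `steps_descent`, `steps_ascent`, lone `steps_descending_bottom`
#'   (a staircase), lone `steps_ascending_bottom`, and `wiggles` (each wiggle
#'   contributes one ascending and one descending bottom step).
#' @param drift List: surface-offset `amplitude_m` over the trip and `shape`
#'   (`"linear"` or `"sine"`).
#' @param depth_noise_sd Additive depth noise sd (m).
#' @param accel List: `rate_hz`, `baseline_sd`, `event_amp` (transient
#'   amplitude as a multiple of the baseline sd, must exceed 1),
#'   `event_dur_s` and `event_freq_hz` (each mouth-opening is a short
#'   fixed-amplitude oscillation at this in-band frequency, random phase),
#'   `body_amp` and `body_freq_hz` for the low-frequency body-motion
#'   component the high-pass filter must remove.
#' @param glmm_truth List: `intercept`, named coefficient vector `beta` on
#'   the standardized dive predictors, random-intercept `sd`.
#' @param seed Integer seed; fixes the full output.
#'
#' @return A list of class `fs_sim_config`.
#' @export
sim_config <- function(n_individuals = 11,
                       n_nights = 9,
                       night_window = c(start = 79200, end = 100800),
                       bout_structure = list(mean_dives = 20,
                                             surface_mean_s = 45,
                                             gap_mean_s = 3600),
                       dive_shape = list(max_depth_mean = 45,
                                         max_depth_sd = 12,
                                         descent_speed = 1.2,
                                         ascent_speed = 1.1,
                                         bottom_mean_s = 40,
                                         shallow_prob = 0.08),
                       feature_rates = list(steps_descent = 0.7,
                                            steps_ascent = 0.5,
                                            steps_descending_bottom = 0.8,
                                            steps_ascending_bottom = 0.4,
                                            wiggles = 0.4),
                       drift = list(amplitude_m = 0.8, shape = "linear"),
                       depth_noise_sd = 0.1,
                       accel = list(rate_hz = 16, baseline_sd = 1,
                                    event_amp = 10, event_dur_s = 0.3,
                                    event_freq_hz = 6,
                                    body_amp = 3, body_freq_hz = 0.4),
                       glmm_truth = list(
                         intercept = 0.058,
                         beta = c(descent_rate = 0.240,
                                  bottom_duration = 0.025,
                                  ascent_rate = 0.194,
                                  max_depth = 0.091,
                                  surface_duration = 0.162,
                                  steps_descending_bottom = 0.143,
                                  steps_ascending_bottom = 0.004,
                                  steps_ascent = 0.065,
                                  steps_descent = 0.075,
                                  depth_variation_bottom = 0.074,
                                  wiggles = 0.004),
                         sd = 0.5),
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_nights = as.integer(n_nights),
              night_window = unname(night_window),
              bout_structure = bout_structure,
              dive_shape = dive_shape,
              feature_rates = feature_rates,
              drift = drift,
              depth_noise_sd = depth_noise_sd,
              accel = accel,
              glmm_truth = glmm_truth,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "fs_sim_config")
}

validate_sim_config <- function(cfg) {
  nw <- cfg$night_window
  if (length(nw) != 2L || nw[2] <= nw[1])
    stopf("night window has zero (or negative) length")
  if (nw[2] - nw[1] > 86400) stopf("night window longer than one day")
  ds <- cfg$dive_shape
  if (ds$descent_speed <= 0.4 || ds$ascent_speed <= 0.4)
    stopf("descent/ascent speeds must exceed 0.4 m/s so phases are detectable")
  if (any(unlist(cfg$feature_rates) < 0)) stopf("feature rates must be >= 0")
  if (cfg$depth_noise_sd < 0 || cfg$drift$amplitude_m < 0)
    stopf("noise sd and drift amplitude must be >= 0")
  if (cfg$accel$event_amp <= 1)
    stopf("event amplitude must exceed 1 baseline sd")
  if (cfg$glmm_truth$sd < 0) stopf("random-intercept sd must be >= 0")
  if (cfg$bout_structure$mean_dives < 0) stopf("mean dives per bout must be >= 0")
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Dive profile construction. All breakpoint times are integers so that 1-Hz
# sampling reproduces the piecewise-linear profile exactly and the phase /
# feature truth is recoverable to the sampling grid on noise-free data.

# Append a linear segment of `dur` seconds ending at depth `to`.
seg_add <- function(prof, dur, to) {
  prof$t <- c(prof$t, prof$t[length(prof$t)] + dur)
  prof$d <- c(prof$d, to)
  prof
}

# Plateau depths for transit steps: below `frac` of the eventual maximum
# depth, at least 3.5 m apart, between 6 m and `lim`.
transit_plateaus <- function(n, lim) {
  if (n <= 0 || lim < 6) return(numeric())
  cand <- seq(6, lim, by = 3.5)
  sort(sample(cand, min(n, length(cand))))
}

# Build one deep dive. d0 is the bottom-arrival depth; descending bottom
# steps form a terminal staircase so the maximum depth is reached late in the
# bottom phase and the bottom depth-variation index equals the staircase
# drop.
build_deep_dive <- function(d0, cfg) {
  ds <- cfg$dive_shape; fr <- cfg$feature_rates
  n_sd_lone <- rpois(1, fr$steps_descending_bottom)
  n_sa_lone <- rpois(1, fr$steps_ascending_bottom)
  n_w <- rpois(1, fr$wiggles)
  n_desc <- rpois(1, fr$steps_descent)
  n_asc <- rpois(1, fr$steps_ascent)

  amp <- function() {
    dur <- sample(2:3, 1)
    list(dur = dur, amp = dur * runif(1, 1.0, 1.3))
  }
  stair <- if (n_sd_lone > 0) replicate(n_sd_lone, amp(), simplify = FALSE) else list()
  # keep the staircase drop small enough that the bottom stays deeper than
  # 60 % of the maximum depth (so tolerated-step logic cannot misfire)
  repeat {
    drop <- sum(vapply(stair, `[[`, 0, "amp"))
    if (drop <= 0.55 * d0 || length(stair) == 0L) break
    stair <- stair[-length(stair)]
  }
  n_sd_lone <- length(stair)
  max_depth <- d0 + sum(vapply(stair, `[[`, 0, "amp"))

  prof <- list(t = 0L, d = 0)
  # descent with tolerated plateaus
  pls <- transit_plateaus(n_desc, min(0.55 * max_depth, d0 - 4))
  n_desc <- length(pls)
  cur <- 0
  for (pd in pls) {
    dur <- max(2L, as.integer(round((pd - cur) / ds$descent_speed)))
    prof <- seg_add(prof, dur, pd)
    prof <- seg_add(prof, sample(3:5, 1), pd)   # plateau
    cur <- pd
  }
  dur <- max(2L, as.integer(round((d0 - cur) / ds$descent_speed)))
  prof <- seg_add(prof, dur, d0)
  descent_end <- prof$t[length(prof$t)]

  # bottom: opening flat, wiggle / lone-ascending blocks, terminal staircase,
  # closing flat. Flats of >= 8 s open and close the bottom so segmentation
  # terminates exactly at the true boundaries.
  prof <- seg_add(prof, 8L + sample(0:4, 1), d0)
  blocks <- sample(c(rep("w", n_w), rep("a", n_sa_lone)))
  for (b in blocks) {
    a <- amp()
    if (b == "w") {
      prof <- seg_add(prof, a$dur, d0 - a$amp)       # ascending step
      prof <- seg_add(prof, 1L, d0 - a$amp)          # < 3 s gap
      prof <- seg_add(prof, a$dur, d0)               # descending step
    } else {
      prof <- seg_add(prof, a$dur, d0 - a$amp)       # lone ascending step
      prof <- seg_add(prof, 4L, d0 - a$amp)
      slow <- max(8L, as.integer(round(a$amp / 0.1)))
      prof <- seg_add(prof, slow, d0)                # slow (sub-rate) return
    }
    prof <- seg_add(prof, sample(4:6, 1), d0)
  }
  cur <- d0
  for (s in stair) {
    prof <- seg_add(prof, s$dur, cur + s$amp)
    cur <- cur + s$amp
    prof <- seg_add(prof, sample(4:6, 1), cur)
  }
  target <- max(20, round(rnorm(1, ds$bottom_mean_s, 15)))
  sofar <- prof$t[length(prof$t)] - descent_end
  prof <- seg_add(prof, max(8L, target - sofar), cur)
  ascent_start <- prof$t[length(prof$t)]
  d_end <- cur

  # ascent with tolerated plateaus
  pls <- rev(transit_plateaus(n_asc, min(0.55 * max_depth, d_end - 4)))
  n_asc <- length(pls)
  cur <- d_end
  for (pd in pls) {
    dur <- max(2L, as.integer(round((cur - pd) / ds$ascent_speed)))
    prof <- seg_add(prof, dur, pd)
    prof <- seg_add(prof, sample(3:5, 1), pd)
    cur <- pd
  }
  dur <- max(2L, as.integer(round(cur / ds$ascent_speed)))
  prof <- seg_add(prof, dur, 0)
  total <- prof$t[length(prof$t)]

  list(bp_t = prof$t, bp_d = prof$d,
       duration = total,
       descent_end = descent_end, ascent_start = ascent_start,
       descent_duration = descent_end,
       bottom_duration = ascent_start - descent_end,
       ascent_duration = total - ascent_start,
       max_depth = max_depth,
       depth_bottom_start = d0, depth_bottom_end = d_end,
       depth_variation_bottom = max_depth - d0,
       steps_descent = n_desc, steps_ascent = n_asc,
       steps_descending_bottom = n_sd_lone + n_w,
       steps_ascending_bottom = n_sa_lone + n_w,
       wiggles = n_w, deep = TRUE)
}

# Shallow (< 15 m) V-dive: detected but excluded from modeling downstream.
build_shallow_dive <- function(dmax) {
  dur <- max(2L, as.integer(round(dmax / 1.0)))
  list(bp_t = c(0L, dur, 2L * dur), bp_d = c(0, dmax, 0),
       duration = 2L * dur,
       descent_end = NA_real_, ascent_start = NA_real_,
       descent_duration = NA_real_, bottom_duration = NA_real_,
       ascent_duration = NA_real_,
       max_depth = dmax,
       depth_bottom_start = NA_real_, depth_bottom_end = NA_real_,
       depth_variation_bottom = NA_real_,
       steps_descent = 0L, steps_ascent = 0L,
       steps_descending_bottom = 0L, steps_ascending_bottom = 0L,
       wiggles = 0L, deep = FALSE)
}

# ---------------------------------------------------------------------------

#' Simulate one foraging trip
#'
#' Generates the 1-Hz depth series, the 16-Hz jaw-acceleration series and a
#' complete ground-truth record (phase boundaries, feature counts, bout
#' labels, event times, per-dive attempt counts, the individual's random
#' intercept) for one individual.
#'
#' @param config An [sim_config()] object.
#' @param individual_id Identifier stored in the outputs.
#' @param seed Optional integer overriding the stream derived from
#'   `config$seed` (used by [simulate_dataset()] to give each individual an
#'   independent stream).
#'
#' @return A list of class `fs_trip` with elements `depth` (tibble
#'   `time_s, depth_m`), `accel` (tibble `time_s, ax, ay`) and `truth`
#'   (list: `dives`, `events`, `nights`, `random_intercept`).
#' @export
simulate_trip <- function(config, individual_id = "ind01", seed = NULL) {
  validate_sim_config(config)
  set.seed(seed %||% derive_seed(config$seed, 1L))
  bs <- config$bout_structure
  nw <- config$night_window
  n_nights <- config$n_nights

  nights <- tibble::tibble(
    night_id = seq_len(n_nights),
    start_s = (seq_len(n_nights) - 1) * 86400 + nw[1],
    end_s = (seq_len(n_nights) - 1) * 86400 + nw[2],
    complete = TRUE)
  t0 <- nights$start_s[1] - 600
  t_end <- nights$end_s[n_nights] + 600

  dives <- list(); profiles <- list()
  bout_counter <- 0L
  if (bs$mean_dives > 0) {
    for (ni in seq_len(n_nights)) {
      t <- nights$start_s[ni] + 30
      night_end <- nights$end_s[ni] - 30
      repeat {
        bout_counter <- bout_counter + 1L
        nd <- 1L + rpois(1, max(0, bs$mean_dives - 1))
        ended <- FALSE
        for (d in seq_len(nd)) {
          d0 <- max(16, rnorm(1, config$dive_shape$max_depth_mean,
                              config$dive_shape$max_depth_sd))
          shallow <- runif(1) < (config$dive_shape$shallow_prob %||% 0)
          prof <- if (shallow) build_shallow_dive(runif(1, 5, 14))
                  else build_deep_dive(d0, config)
          if (t + prof$duration > night_end) { ended <- TRUE; break }
          dives[[length(dives) + 1L]] <- tibble::tibble(
            night_id = ni, bout_id_true = bout_counter, start_s = t,
            end_s = t + prof$duration,
            descent_end_s = t + prof$descent_end,
            ascent_start_s = t + prof$ascent_start,
            descent_duration = prof$descent_duration,
            bottom_duration = prof$bottom_duration,
            ascent_duration = prof$ascent_duration,
            dive_duration = prof$duration,
            max_depth = prof$max_depth,
            depth_bottom_start = prof$depth_bottom_start,
            depth_bottom_end = prof$depth_bottom_end,
            depth_variation_bottom = prof$depth_variation_bottom,
            steps_descent = prof$steps_descent,
            steps_ascent = prof$steps_ascent,
            steps_descending_bottom = prof$steps_descending_bottom,
            steps_ascending_bottom = prof$steps_ascending_bottom,
            wiggles = prof$wiggles, deep = prof$deep)
          profiles[[length(profiles) + 1L]] <- prof
          t <- t + prof$duration
          iv <- if (d < nd) 10 + round(rexp(1, 1 / max(1, bs$surface_mean_s - 10)))
                else 600 + round(rexp(1, 1 / max(1, bs$gap_mean_s - 600)))
          t <- t + iv
          if (t > night_end - 60) { ended <- TRUE; break }
        }
        if (ended || t > night_end - 60) break
      }
    }
  }

  truth <- if (length(dives)) dplyr::bind_rows(dives) else
    tibble::tibble(night_id = integer(), bout_id_true = integer(),
                   start_s = numeric(), end_s = numeric())
  if (nrow(truth)) {
    truth$dive_id <- seq_len(nrow(truth))
    truth$individual_id <- individual_id
    truth$post_dive_interval <- c(diff(truth$start_s) -
                                    truth$dive_duration[-nrow(truth)], NA)
  }

  # depth series: profiles + drift + noise
  time_s <- seq(t0, t_end)
  depth <- numeric(length(time_s))
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      p <- profiles[[i]]
      idx <- (truth$start_s[i] - t0 + 1L):(truth$end_s[i] - t0 + 1L)
      depth[idx] <- approx(p$bp_t, p$bp_d, xout = seq(0L, p$duration))$y
    }
  }
  s <- (time_s - t0) / (t_end - t0)
  drift <- switch(config$drift$shape,
                  linear = config$drift$amplitude_m * s,
                  sine = config$drift$amplitude_m * sin(pi * s),
                  stopf("unknown drift shape '%s'", config$drift$shape))
  depth_obs <- depth + drift +
    if (config$depth_noise_sd > 0) rnorm(length(depth), 0, config$depth_noise_sd) else 0

  # per-dive prey-capture-attempt counts from the generative mixed model
  b_i <- rnorm(1, 0, config$glmm_truth$sd)
  if (nrow(truth)) {
    truth$surface_duration <- truth$post_dive_interval
    deep <- truth$deep
    truth$descent_rate <- truth$depth_bottom_start / truth$descent_duration
    truth$ascent_rate <- truth$depth_bottom_end / truth$ascent_duration
    truth$pca_count <- 0L
    if (any(deep)) {
      tab <- truth[deep, c("max_depth", "surface_duration", "descent_rate",
                           "ascent_rate", "bottom_duration",
                           "depth_variation_bottom", "steps_descent",
                           "steps_ascent", "steps_descending_bottom",
                           "steps_ascending_bottom", "wiggles")]
      tab$surface_duration[is.na(tab$surface_duration)] <-
        mean(tab$surface_duration, na.rm = TRUE)
      z <- vapply(tab, function(x) {
        s <- sd(x)
        if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
      }, numeric(nrow(tab)))
      beta <- config$glmm_truth$beta
      lp <- config$glmm_truth$intercept +
        as.vector(z[, names(beta), drop = FALSE] %*% beta) + b_i
      if (any(!is.finite(lp))) stopf("non-finite linear predictor in simulation")
      truth$pca_count[deep] <- rpois(sum(deep), exp(lp))
    }
  }

  # event times: spread inside the bottom phase, separated by at least two
  # variance-window widths so detections stay resolvable
  events <- list()
  sep <- 3.5
  if (nrow(truth)) {
    for (i in which(truth$pca_count > 0)) {
      k <- truth$pca_count[i]
      lo <- if (truth$deep[i]) truth$descent_end_s[i] + 1 else truth$start_s[i] + 1
      hi <- if (truth$deep[i]) truth$ascent_start_s[i] - 1 else truth$end_s[i] - 1
      if (hi - lo >= sep * (k + 1)) {
        u <- sort(runif(k, 0, (hi - lo) - sep * (k - 1)))
        tt <- lo + u + sep * (seq_len(k) - 1)
      } else {
        tt <- seq(lo, hi, length.out = k + 2)[seq_len(k) + 1]
      }
      events[[length(events) + 1L]] <- tibble::tibble(time_s = tt, dive_id = i)
    }
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(time_s = numeric(), dive_id = integer())

  # 16-Hz acceleration: baseline noise + low-frequency body motion + bursts
  ac <- config$accel
  n16 <- as.integer((t_end - t0) * ac$rate_hz) + 1L
  at <- t0 + (seq_len(n16) - 1L) / ac$rate_hz
  phase <- runif(1, 0, 2 * pi)
  ax <- rnorm(n16, 0, ac$baseline_sd) +
    ac$body_amp * ac$baseline_sd * sin(2 * pi * ac$body_freq_hz * at + phase)
  ay <- rnorm(n16, 0, ac$baseline_sd)
  half <- ac$event_dur_s / 2
  fe <- ac$event_freq_hz %||% 6
  for (te in events$time_s) {
    i1 <- max(1L, as.integer(floor((te - half - t0) * ac$rate_hz)) + 1L)
    i2 <- min(n16, as.integer(ceiling((te + half - t0) * ac$rate_hz)) + 1L)
    tt <- at[i1:i2] - te
    ax[i1:i2] <- ax[i1:i2] + ac$event_amp * ac$baseline_sd *
      sin(2 * pi * fe * tt + runif(1, 0, 2 * pi))
  }

  structure(list(
    depth = tibble::tibble(time_s = time_s, depth_m = depth_obs),
    accel = tibble::tibble(time_s = at, ax = ax, ay = ay),
    truth = list(dives = truth, events = events, nights = nights,
                 random_intercept = b_i, drift = drift,
                 individual_id = individual_id)
  ), class = "fs_trip")
}

#' Simulate a multi-individual dataset
#'
#' @param config An [sim_config()] object; `config$n_individuals` trips are
#'   generated, each from an independent stream derived from `config$seed`.
#' @return A named list of `fs_trip` objects.
#' @export
simulate_dataset <- function(config) {
  ids <- sprintf("ind%02d", seq_len(config$n_individuals))
  out <- lapply(seq_along(ids), function(i)
    simulate_trip(config, ids[i], seed = derive_seed(config$seed, i)))
  names(out) <- ids
  out
}

#' Draw prey-capture-attempt counts from the generative mixed model
#'
#' Counts are `Poisson(exp(intercept + x'beta + b))` with one Gaussian random
#' intercept `b` per individual. Used both inside [simulate_trip()] and to
#' build bare model-recovery benchmarks.
#'
#' @param dive_table Tibble with standardized predictor columns (all names
#'   of `glmm_truth$beta`) and an `individual_id` column (a single shared
#'   intercept is used if absent).
#' @param glmm_truth List with `intercept`, named `beta`, `sd`.
#' @param seed Optional seed.
#' @return Integer vector of counts, one per row, with the per-individual
#'   intercepts attached as attribute `"random_intercepts"`.
#' @export
simulate_pca_counts <- function(dive_table, glmm_truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- glmm_truth$beta
  miss <- setdiff(names(beta), names(dive_table))
  if (length(miss))
    stopf("dive_table lacks predictor column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(dive_table[names(beta)])
  id <- if ("individual_id" %in% names(dive_table))
    as.character(dive_table$individual_id) else rep("all", nrow(dive_table))
  uid <- unique(id)
  b <- setNames(rnorm(length(uid), 0, glmm_truth$sd), uid)
  lp <- glmm_truth$intercept + as.vector(X %*% beta) + b[id]
  if (any(!is.finite(lp))) stopf("non-finite linear predictor")
  out <- rpois(length(lp), exp(lp))
  attr(out, "random_intercepts") <- b
  out
}

#' Write a simulated trip to disk
#'
#' Depth and acceleration as CSV, truth as a JSON sidecar.
#'
#' @param trip An `fs_trip`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trip <- function(trip, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- trip$truth$individual_id
  readr::write_csv(trip$depth, file.path(dir, paste0(id, "_depth.csv")))
  readr::write_csv(trip$accel, file.path(dir, paste0(id, "_accel.csv")))
  jsonlite::write_json(
    list(dives = trip$truth$dives, events = trip$truth$events,
         nights = trip$truth$nights,
         random_intercept = trip$truth$random_intercept),
    file.path(dir, paste0(id, "_truth.json")),
    dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
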