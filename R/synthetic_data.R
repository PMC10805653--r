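#' @include AllClasses.R
NULL

## Seeded generators for every input the pipeline consumes, each returning a
## ground-truth table so recovery tests never re-derive truth. Each generator
## draws from its own PRNG stream (seed + fixed offset) so adding one block
## never perturbs another.

.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Waking-hours microsampling schedule
#'
#' Sampling times emulating a self-sampling protocol: roughly hourly during
#' waking hours (06:00-23:00) with +/- 15 min jitter, nothing overnight, so
#' the between-day gap always exceeds 4 h.
#'
#' @param days number of study days.
#' @param seed integer seed.
#' @param interval_min mean within-day sampling interval (minutes).
#' @param jitter_min uniform jitter half-width (minutes).
#' @return Sorted numeric vector of timestamps (minutes since study start).
#' @export
simSamplingTimes <- function(days = 7L, seed = 1L, interval_min = 60,
                             jitter_min = 15) {
    .with_seed(seed + 11L, {
        unlist(lapply(seq_len(days) - 1L, function(d) {
            base <- seq(360, 1380, by = interval_min)
            t <- d * 1440 + base + stats::runif(length(base), -jitter_min, jitter_min)
            sort(t)
        }))
    })
}

.gamma_kernel <- function(dt, peak_min, shape = 3) {
    ## gamma-density shaped meal-response kernel, scaled to peak at 1
    rate <- (shape - 1) / peak_min
    k <- ifelse(dt > 0, dt^(shape - 1) * exp(-rate * dt), 0)
    k / ((peak_min)^(shape - 1) * exp(-(shape - 1)))
}

#' Simulate wearable streams (heart rate, step count, CGM glucose)
#'
#' Steps are a bursty 1-min series (Markov walking bouts during waking hours,
#' ~100 steps/min while walking). HR at 1-min resolution is
#' \code{baseline + circadian + coupling * steps(t - hr_lag_min) + noise}.
#' CGM is a 5-min series with gamma-kernel meal excursions at the dose times.
#'
#' @param days study days.
#' @param seed integer seed.
#' @param hr_baseline,hr_amplitude,hr_noise_sd resting HR, circadian amplitude
#'   and measurement noise (bpm).
#' @param step_coupling bpm gained per (step/min); \code{hr_lag_min} is the
#'   physiological lag of HR behind steps (minutes; default 1).
#' @param hr_lag_min lag of HR behind step count, minutes.
#' @param cgm_baseline,cgm_meal_mag,cgm_noise_sd fasting glucose, meal
#'   excursion magnitude and sensor noise (mg/dl).
#' @param meal_times_min within-day meal times (minutes after midnight).
#' @return List with elements \code{HR}, \code{steps}, \code{CGM}
#'   ([WearableStream-class]) and \code{truth} (the parameters used).
#' @export
simWearables <- function(days = 7L, seed = 1L,
                         hr_baseline = 65, hr_amplitude = 3, hr_noise_sd = 2,
                         step_coupling = 0.4, hr_lag_min = 1L,
                         cgm_baseline = 95, cgm_meal_mag = 40,
                         cgm_noise_sd = 4,
                         meal_times_min = c(8, 13, 19) * 60) {
    total <- days * 1440L
    t1 <- seq_len(total) - 1L
    steps <- .with_seed(seed + 101L, {
        tod <- t1 %% 1440
        awake <- tod >= 360 & tod < 1380
        ## two-state Markov chain: enter a walking bout w.p. 0.02/min, leave
        ## w.p. 0.12/min (mean bout ~8 min, ~14% of waking time walking)
        state <- logical(total)
        u <- stats::runif(total)
        for (i in 2:total)
            state[i] <- if (state[i - 1L]) u[i] > 0.12 else u[i] < 0.02
        state[!awake] <- FALSE
        val <- ifelse(state, stats::runif(total, 60, 120), 0)
        ## incidental movement registers small counts in ~1/3 of idle waking
        ## minutes, as minute-level actigraphy does
        idle <- awake & !state & stats::runif(total) < 0.35
        val[idle] <- stats::runif(sum(idle), 1, 20)
        round(val)
    })
    hr <- .with_seed(seed + 102L, {
        lag_steps <- c(rep(0, hr_lag_min), steps)[seq_len(total)]
        v <- hr_baseline +
            hr_amplitude * sin(2 * pi * (t1 - 840) / 1440) +
            step_coupling * lag_steps +
            stats::rnorm(total, 0, hr_noise_sd)
        pmax(v, 40)
    })
    t5 <- seq(0, total - 1L, by = 5L)
    cgm <- .with_seed(seed + 103L, {
        bump <- rep(0, length(t5))
        for (d in seq_len(days) - 1L) for (m in meal_times_min) {
            dt <- t5 - (d * 1440 + m)
            bump <- bump + cgm_meal_mag * .gamma_kernel(dt, peak_min = 45)
        }
        pmax(cgm_baseline + bump + stats::rnorm(length(t5), 0, cgm_noise_sd), 40)
    })
    list(HR = WearableStream("HR", t1, hr),
         steps = WearableStream("steps", t1, steps),
         CGM = WearableStream("CGM", t5, cgm),
         truth = list(hr_lag_min = hr_lag_min, step_coupling = step_coupling,
                      hr_amplitude = hr_amplitude, meal_times_min = meal_times_min))
}

#' One analyte block for [simOmics247()]
#'
#' @param mechanism one of \code{"circadian"}, \code{"meal"}, \code{"pk"},
#'   \code{"lagged"}, \code{"noise"}.
#' @param count analytes in the block.
#' @param class analyte class label.
#' @param noise_sd log2-scale noise sd.
#' @param ... mechanism parameters: circadian \code{amplitude}, \code{phase}
#'   (min), \code{period} (default 1440); meal \code{peak_min},
#'   \code{magnitude}; pk \code{ka_halflife_min}, \code{ke_halflife_min},
#'   \code{dose_times_min}; lagged \code{driver} ("HR"/"steps"/"CGM"),
#'   \code{lag_min}, \code{coupling}, \code{integration_min} (width of the
#'   centred driver-integration window, default 30).
#' @return A block spec list.
#' @export
omicsBlock <- function(mechanism, count, class = "metabolite",
                       noise_sd = 0.25, ...) {
    stopifnot(mechanism %in% c("circadian", "meal", "pk", "lagged", "noise"),
              count >= 0)
    c(list(mechanism = mechanism, count = as.integer(count), class = class,
           noise_sd = noise_sd), list(...))
}

.stream_at <- function(stream, times, smooth_min = 10) {
    ## centred-window mean of a wearable stream, so a lagged analyte's
    ## effective lag equals the planted lag exactly
    vapply(times, function(t) {
        sel <- abs(stream@timestamps - t) <= smooth_min / 2
        if (!any(sel)) NA_real_ else mean(stream@values[sel])
    }, numeric(1))
}

#' Simulate the dense single-participant multi-omics time course
#'
#' Analytes are sampled at an irregular waking-hours schedule and generated on
#' the log2 scale from one of five mechanisms (circadian sinusoid, meal
#' kernel, one-compartment pharmacokinetics, wearable-driven with a known lag,
#' or pure noise), then exponentiated to positive intensities.
#'
#' @param wearables output of [simWearables()] (needed for lagged blocks).
#' @param blocks list of [omicsBlock()] specs.
#' @param days,seed schedule parameters (see [simSamplingTimes()]).
#' @param sample_times optional explicit timestamps, overriding the schedule.
#' @return List: \code{omics} ([OmicsTimeCourse-class]) and \code{truth}
#'   (data.frame: analyte, mechanism, and the per-analyte parameters).
#' @export
simOmics247 <- function(wearables = NULL, blocks = list(
                            omicsBlock("circadian", 10, amplitude = 1, phase = 0),
                            omicsBlock("noise", 10)),
                        days = 7L, seed = 1L, sample_times = NULL) {
    if (is.null(sample_times))
        sample_times <- simSamplingTimes(days = days, seed = seed)
    n_s <- length(sample_times)
    rows <- list(); truth <- list(); idx <- 0L
    for (b in seq_along(blocks)) {
        blk <- blocks[[b]]
        if (blk$count == 0L) next
        sig <- .with_seed(seed + 1000L + b, {
            lapply(seq_len(blk$count), function(a) {
                switch(blk$mechanism,
                    circadian = {
                        per <- blk$period %||% 1440
                        blk$amplitude * sin(2 * pi * (sample_times - blk$phase) / per)
                    },
                    meal = {
                        mt <- blk$dose_times_min %||% (c(8, 13, 19) * 60)
                        s <- rep(0, n_s)
                        for (d in seq_len(days) - 1L) for (m in mt)
                            s <- s + .gamma_kernel(sample_times - (d * 1440 + m),
                                                   blk$peak_min %||% 60)
                        (blk$magnitude %||% 1) * s
                    },
                    pk = {
                        ka <- log(2) / (blk$ka_halflife_min %||% 30)
                        ke <- log(2) / (blk$ke_halflife_min %||% 300)
                        mt <- blk$dose_times_min %||% (9 * 60)
                        s <- rep(0, n_s)
                        for (d in seq_len(days) - 1L) for (m in mt) {
                            dt <- sample_times - (d * 1440 + m)
                            s <- s + ifelse(dt > 0,
                                ka / (ka - ke) * (exp(-ke * dt) - exp(-ka * dt)), 0)
                        }
                        peak <- max(s); if (peak > 0) s <- s / peak
                        (blk$magnitude %||% 1) * s
                    },
                    lagged = {
                        if (is.null(wearables))
                            stop("lagged block requires wearables")
                        drv <- wearables[[blk$driver %||% "HR"]]
                        lag <- blk$lag_min %||% 10
                        ## blood analytes integrate the driver over a
                        ## physiological window centred at t - lag
                        v <- .stream_at(drv, sample_times - lag,
                                        smooth_min = blk$integration_min %||% 30)
                        v[is.na(v)] <- mean(v, na.rm = TRUE)
                        z <- (v - mean(v)) / max(stats::sd(v), 1e-12)
                        (blk$coupling %||% 1) * z
                    },
                    noise = rep(0, n_s))
            })
        })
        noise <- .with_seed(seed + 5000L + b,
            matrix(stats::rnorm(blk$count * n_s, 0, blk$noise_sd), blk$count))
        for (a in seq_len(blk$count)) {
            idx <- idx + 1L
            rows[[idx]] <- 2^(8 + sig[[a]] + noise[a, ])
            truth[[idx]] <- data.frame(
                analyte = sprintf("%s_%02d_%03d", blk$mechanism, b, a),
                mechanism = blk$mechanism, class = blk$class,
                noise_sd = blk$noise_sd,
                amplitude = blk$amplitude %||% NA_real_,
                lag_min = blk$lag_min %||% NA_real_,
                driver = blk$driver %||% NA_character_,
                coupling = blk$coupling %||% NA_real_)
        }
    }
    truth <- do.call(rbind, truth)
    m <- do.call(rbind, rows)
    dimnames(m) <- list(truth$analyte, sprintf("s%03d", seq_len(n_s)))
    omics <- OmicsTimeCourse(m, analyte_class = truth$class,
                             participant = "P1",
                             timestamp_min = sample_times)
    list(omics = omics, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.SHAKE_TIMEPOINTS <- c(0, 30, 60, 120, 240)

.shake_template <- function(archetype, speed = 1) {
    ## value at t = 0 is 0 by construction (baseline-subtracted shapes)
    tp <- .SHAKE_TIMEPOINTS
    shapes <- list(
        `1` = c(0, 0.70, 1.00, 0.35, 0.00),   # sharp peak ~60 min, back by 240
        `2` = c(0, 0.25, 0.70, 1.00, 0.60),   # gradual, peak 60-120 min
        `3` = c(0, -1.00, -0.80, -0.35, 0.00) # dip then recovery
    )
    base <- shapes[[as.character(archetype)]]
    ## kinetic speed warps time: fast (>1) reaches the template shape earlier
    stats::approx(tp, base, xout = pmin(tp * speed, max(tp)), rule = 2)$y
}

#' Simulate the 28-participant meal-challenge cohort
#'
#' Five samples per participant at 0/30/60/120/240 min. Responsive analytes
#' follow one of three kinetic archetypes (sharp peak returning to baseline,
#' gradual late peak, dip-and-recover) scaled by a per-participant responder
#' magnitude; participants split into fast and slow kinetic groups via a time
#' warp of the templates. Non-responsive analytes are pure noise.
#'
#' @param n_participants cohort size (default 28).
#' @param n_per_archetype responsive analytes per archetype.
#' @param n_noise non-responsive analytes.
#' @param magnitude log2-scale response magnitude (0 = null cohort).
#' @param noise_sd log2-scale noise sd (default 0.25 of the unit signal).
#' @param kinetic_speeds named c(fast=, slow=) time-warp factors.
#' @param seed integer seed.
#' @return List: \code{omics} ([OmicsTimeCourse-class], \code{timepoint} set),
#'   \code{truth} (analyte, archetype, magnitude), \code{participant_truth}
#'   (participant, kinetic_group, responder_scale).
#' @export
simShakeCohort <- function(n_participants = 28L, n_per_archetype = 20L,
                           n_noise = 40L, magnitude = 1, noise_sd = 0.25,
                           kinetic_speeds = c(fast = 1.4, slow = 0.7),
                           seed = 1L) {
    tp <- .SHAKE_TIMEPOINTS
    n_resp <- 3L * n_per_archetype
    n_a <- n_resp + n_noise
    analytes <- c(sprintf("resp_%d_%02d", rep(1:3, each = n_per_archetype),
                          rep(seq_len(n_per_archetype), 3)),
                  sprintf("noise_%02d", seq_len(max(n_noise, 1))[seq_len(n_noise)]))
    archetype <- c(rep(1:3, each = n_per_archetype), rep(NA_integer_, n_noise))
    pid <- sprintf("S%02d", seq_len(n_participants))
    grp <- rep(c("fast", "slow"), length.out = n_participants)
    resp_scale <- .with_seed(seed + 201L,
        stats::runif(n_participants, 0.6, 1.4))
    vals <- .with_seed(seed + 202L, {
        m <- matrix(NA_real_, n_a, n_participants * 5L)
        col <- 0L
        for (j in seq_len(n_participants)) {
            speed <- kinetic_speeds[[grp[j]]]
            for (k in seq_along(tp)) {
                col <- col + 1L
                sig <- numeric(n_a)
                for (arc in 1:3) {
                    tmpl <- .shake_template(arc, speed)
                    rows <- which(archetype == arc)
                    sig[rows] <- magnitude * resp_scale[j] * tmpl[k]
                }
                m[, col] <- 2^(8 + sig + stats::rnorm(n_a, 0, noise_sd))
            }
        }
        m
    })
    dimnames(vals) <- list(analytes,
                           paste0(rep(pid, each = 5L), "_t", rep(tp, n_participants)))
    cls <- c(rep("metabolite", n_resp), rep("metabolite", n_noise))
    omics <- OmicsTimeCourse(vals, analyte_class = cls,
                             participant = rep(pid, each = 5L),
                             timestamp_min = rep(tp, n_participants),
                             timepoint = as.character(rep(tp, n_participants)))
    list(omics = omics,
         truth = data.frame(analyte = analytes, archetype = archetype,
                            magnitude = ifelse(is.na(archetype), 0, magnitude)),
         participant_truth = data.frame(participant = pid, kinetic_group = grp,
                                        responder_scale = resp_scale))
}

#' Simulate the storage-stability design
#'
#' Two participants, three storage temperatures (4, 25, 37 C), durations
#' 0/3/6/24/72/120 h, duplicate samples per cell. Each analyte's level is
#' \code{baseline + b_d*duration + b_t*temperature + b_dt*duration*temperature
#' + participant offset + noise}; duration-0 samples were never exposed to
#' storage, so all storage terms vanish there.
#'
#' @param n_analytes number of analytes.
#' @param effects optional n_analytes x 3 matrix of coefficients
#'   (columns \code{b_d}, \code{b_t}, \code{b_dt}); default draws a sparse mix
#'   (10\% of analytes per term affected).
#' @param noise_sd residual sd.
#' @param participant_offset additive offset of the second participant.
#' @param seed integer seed.
#' @return List: \code{matrix} (analyte x sample), \code{design} (data.frame:
#'   sample_id, participant, duration_h, temperature_c), \code{truth}
#'   (per-analyte coefficients).
#' @export
simStabilityDesign <- function(n_analytes = 100L, effects = NULL,
                               noise_sd = 0.5, participant_offset = 1,
                               seed = 1L) {
    durations <- c(0, 3, 6, 24, 72, 120)
    temps <- c(4, 25, 37)
    design <- expand.grid(replicate = 1:2, temperature_c = temps,
                          duration_h = durations, participant = c("P1", "P2"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$sample_id <- sprintf("st%03d", seq_len(nrow(design)))
    if (is.null(effects)) {
        effects <- .with_seed(seed + 301L, {
            e <- matrix(0, n_analytes, 3)
            pick <- function() sample(n_analytes, max(1, round(0.1 * n_analytes)))
            e[pick(), 1] <- 0.010 * sample(c(-1, 1), max(1, round(0.1 * n_analytes)), TRUE)
            e[pick(), 2] <- 0.040 * sample(c(-1, 1), max(1, round(0.1 * n_analytes)), TRUE)
            e[pick(), 3] <- 5e-4 * sample(c(-1, 1), max(1, round(0.1 * n_analytes)), TRUE)
            e
        })
    }
    effects <- as.matrix(effects)
    colnames(effects) <- c("b_d", "b_t", "b_dt")
    rownames(effects) <- sprintf("an%03d", seq_len(n_analytes))
    m <- .with_seed(seed + 302L, {
        stored <- design$duration_h > 0
        dd <- ifelse(stored, design$duration_h, 0)
        tt <- ifelse(stored, design$temperature_c, 0)
        po <- ifelse(design$participant == "P2", participant_offset, 0)
        t(vapply(seq_len(n_analytes), function(i) {
            10 + effects[i, 1] * dd + effects[i, 2] * tt +
                effects[i, 3] * dd * tt + po +
                stats::rnorm(nrow(design), 0, noise_sd)
        }, numeric(nrow(design))))
    })
    dimnames(m) <- list(rownames(effects), design$sample_id)
    list(matrix = m,
         design = design[, c("sample_id", "participant", "duration_h",
                             "temperature_c")],
         truth = effects)
}
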