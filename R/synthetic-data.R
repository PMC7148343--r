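# Synthetic-data generators with known ground truth.
#
# Three generators mirror the three data modalities of a smoke-exposure ALI
# study: high-speed cilia videos, longitudinal endpoint tables (TEER, qPCR
# delta-Ct) from a paired air/smoke design, and a pair of expression cohorts
# (in vitro cultures vs in vivo brushings) sharing a deregulated signature but
# separated by a platform shift. All randomness is Gaussian and every
# generator takes an explicit seed; identical seeds give identical output.

#' Specify a synthetic cilia video
#'
#' Beating is modelled as an additive sinusoid per pixel: within a region the
#' trace is `background + amplitude * sin(2*pi*f*t/fps + phase)` plus
#' Gaussian noise, where each pixel's phase is drawn once from
#' `N(0, phase_jitter_sd)` (imperfect metachrony as spatial phase
#' decoherence). Outside all regions there is no periodic component.
#'
#' @param height,width image size in pixels.
#' @param n_frames number of frames (>= 64).
#' @param fps frame rate in Hz; every region frequency must lie strictly
#'   below the Nyquist limit `fps / 2`.
#' @param regions list of regions, each a list with `mask` (`H x W` logical),
#'   `frequency` (Hz), `amplitude` (intensity units) and optionally
#'   `phase_jitter_sd` (radians, default 0).
#' @param background_level,noise_sd mean intensity and Gaussian noise SD.
#' @param seed integer seed.
#' @return an object of class `"cilia_video_spec"`.
#' @export
cilia_video_spec <- function(height = 100L, width = 100L, n_frames = 512L,
                             fps = 30, regions = list(),
                             background_level = 100, noise_sd = 0, seed = 1L) {
  check_number(height, "height", lower = 1); check_number(width, "width", lower = 1)
  check_number(n_frames, "n_frames", lower = 64)
  check_number(fps, "fps", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    stop_if(is.null(r$mask) || !is.logical(r$mask) ||
              !identical(dim(r$mask), c(as.integer(height), as.integer(width))),
            sprintf("region %d: 'mask' must be a %d x %d logical matrix",
                    i, height, width))
    stop_if(!is.numeric(r$frequency) || r$frequency <= 0,
            sprintf("region %d: 'frequency' must be a positive number", i))
    stop_if(r$frequency >= fps / 2,
            sprintf(paste("region %d: frequency %g Hz is at or above the",
                          "Nyquist limit fps/2 = %g Hz"),
                    i, r$frequency, fps / 2))
    stop_if(!is.numeric(r$amplitude) || r$amplitude < 0,
            sprintf("region %d: 'amplitude' must be non-negative", i))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), fps = fps, regions = regions,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cilia_video_spec")
}

#' Rectangular region helper for [cilia_video_spec()]
#'
#' @param height,width full image size.
#' @param rows,cols integer ranges of the rectangle.
#' @param frequency beat frequency in Hz.
#' @param amplitude sinusoid amplitude in intensity units.
#' @param phase_jitter_sd SD of the per-pixel phase (radians).
#' @return a region list usable in `regions = list(...)`.
#' @export
rect_region <- function(height, width, rows, cols, frequency, amplitude = 20,
                        phase_jitter_sd = 0) {
  mask <- matrix(FALSE, height, width)
  mask[rows, cols] <- TRUE
  list(mask = mask, frequency = frequency, amplitude = amplitude,
       phase_jitter_sd = phase_jitter_sd)
}

#' Generate a synthetic cilia video with ground truth
#'
#' @param spec a [cilia_video_spec()].
#' @return list with `stack` (a [video_stack()]) and `truth` (`H x W` matrix
#'   of true frequencies in Hz, `NA` where no periodic component was
#'   simulated).
#' @export
generate_cilia_video <- function(spec) {
  stop_if(!inherits(spec, "cilia_video_spec"), "'spec' must be a cilia_video_spec")
  set.seed(spec$seed)
  d <- c(spec$n_frames, spec$height, spec$width)
  frames <- array(spec$background_level, dim = d)
  if (spec$noise_sd > 0)
    frames <- frames + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
  truth <- matrix(NA_real_, spec$height, spec$width)
  tt <- seq_len(spec$n_frames) - 1L
  for (r in spec$regions) {
    idx <- which(r$mask)                       # column-major pixel indices
    jit <- r$phase_jitter_sd %||% 0
    phases <- if (jit > 0) rnorm(length(idx), sd = jit) else rep(0, length(idx))
    # T x n_region sinusoids, one phase per pixel
    waves <- r$amplitude *
      sin(outer(2 * pi * r$frequency * tt / spec$fps, phases, "+"))
    tr <- matrix(frames, nrow = d[1])
    tr[, idx] <- tr[, idx] + waves
    frames <- array(tr, dim = d)
    truth[idx] <- r$frequency
  }
  list(stack = video_stack(frames, spec$fps), truth = truth)
}

#' Video spec emulating a typical healthy differentiated culture
#'
#' Convenience preset: a handful of irregular ciliated patches covering
#' roughly a tenth of the field, beating in the 7-10 Hz physiological range
#' with moderate phase jitter and camera noise. Useful as a plausibility
#' fixture: its analysis should report an active area in the 5-20% range and
#' a mean CBF between 7 and 10 Hz.
#'
#' @param height,width,n_frames,fps as in [cilia_video_spec()].
#' @param seed integer seed.
#' @return a [cilia_video_spec()].
#' @export
healthy_culture_video_spec <- function(height = 80L, width = 80L,
                                       n_frames = 512L, fps = 30, seed = 1L) {
  set.seed(seed)
  n_patches <- sample(3:5, 1)
  regions <- vector("list", n_patches)
  target <- runif(1, 0.07, 0.16) * height * width   # total active pixels
  for (i in seq_len(n_patches)) {
    side <- max(4L, round(sqrt(target / n_patches)))
    r0 <- sample(seq_len(height - side), 1)
    c0 <- sample(seq_len(width - side), 1)
    regions[[i]] <- rect_region(height, width, r0:(r0 + side - 1L),
                                c0:(c0 + side - 1L),
                                frequency = runif(1, 7.2, 9.8),
                                amplitude = 20, phase_jitter_sd = 0.6)
  }
  cilia_video_spec(height = height, width = width, n_frames = n_frames,
                   fps = fps, regions = regions, background_level = 100,
                   noise_sd = 4, seed = seed + 1L)
}

#' Specify a synthetic longitudinal endpoint experiment
#'
#' Emulates the paired exposure design: both treatments (smoke and air) are
#' applied to cultures from each donor, and the endpoint is measured on a
#' common day grid. Residuals across days are equicorrelated (compound
#' symmetry); a donor-level random intercept shared by both treatment arms
#' induces the pairing.
#'
#' @param n_subjects_per_group donors per group.
#' @param groups,treatments factor levels (defaults `HC`/`COPD`, `Air`/`CS`).
#' @param days strictly increasing measurement days.
#' @param subject_sd SD of the donor random intercept (endpoint units).
#' @param residual_sd SD of the within-series residual (endpoint units).
#' @param within_subject_correlation equicorrelation of residuals between any
#'   two days of one series, in `[0, 1)`.
#' @param mean_curves named list `"<group>.<treatment>"` -> per-day mean
#'   vector (length `length(days)`); missing cells default to zero.
#' @param endpoint endpoint name recorded in the output table.
#' @param seed integer seed.
#' @return an object of class `"longitudinal_spec"`.
#' @export
longitudinal_spec <- function(n_subjects_per_group = 3L,
                              groups = c("HC", "COPD"),
                              treatments = c("Air", "CS"),
                              days = c(7, 14, 21, 28),
                              subject_sd = 1, residual_sd = 1,
                              within_subject_correlation = 0.5,
                              mean_curves = list(),
                              endpoint = "endpoint", seed = 1L) {
  check_number(n_subjects_per_group, "n_subjects_per_group", lower = 1)
  stop_if(length(days) < 1, "'days' must be non-empty")
  stop_if(any(diff(days) <= 0), "'days' must be strictly increasing")
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(residual_sd, "residual_sd", lower = 0)
  check_number(within_subject_correlation, "within_subject_correlation",
               lower = 0, upper = 1 - 1e-12)
  stop_if(length(treatments) != 2L, "exactly two treatments are required")
  for (nm in names(mean_curves))
    stop_if(length(mean_curves[[nm]]) != length(days),
            sprintf("mean_curves[['%s']] must have one value per day", nm))
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups, treatments = treatments, days = days,
                 subject_sd = subject_sd, residual_sd = residual_sd,
                 within_subject_correlation = within_subject_correlation,
                 mean_curves = mean_curves, endpoint = endpoint,
                 seed = as.integer(seed)),
            class = "longitudinal_spec")
}

#' Generate a tidy longitudinal endpoint table
#'
#' @param spec a [longitudinal_spec()].
#' @return data.frame with columns `subject`, `group`, `treatment`,
#'   `endpoint`, `day`, `value`; one row per (subject, treatment, day), every
#'   subject contributing both treatment arms.
#' @export
generate_longitudinal <- function(spec) {
  stop_if(!inherits(spec, "longitudinal_spec"), "'spec' must be a longitudinal_spec")
  set.seed(spec$seed)
  nd <- length(spec$days)
  rho <- spec$within_subject_correlation
  n_series <- length(spec$groups) * spec$n_subjects_per_group *
    length(spec$treatments)
  subject <- group <- treatment <- character(n_series * nd)
  value <- numeric(n_series * nd)
  k <- 0L
  for (g in spec$groups) {
    for (i in seq_len(spec$n_subjects_per_group)) {
      subj <- sprintf("%s_%02d", g, i)
      u <- rnorm(1, sd = spec$subject_sd)            # donor intercept (paired)
      for (tr in spec$treatments) {
        mu <- spec$mean_curves[[paste(g, tr, sep = ".")]] %||% rep(0, nd)
        # equicorrelated residuals: sqrt(rho)*shared + sqrt(1-rho)*independent
        eps <- spec$residual_sd *
          (sqrt(rho) * rnorm(1) + sqrt(1 - rho) * rnorm(nd))
        idx <- k + seq_len(nd)
        subject[idx] <- subj; group[idx] <- g; treatment[idx] <- tr
        value[idx] <- mu + u + eps
        k <- k + nd
      }
    }
  }
  data.frame(subject = subject, group = group, treatment = treatment,
             endpoint = spec$endpoint, day = rep(spec$days, n_series),
             value = value)
}

#' Specify a synthetic two-cohort expression experiment
#'
#' Emulates the transfer setting of an in vitro signature to an in vivo
#' cohort: a paired air/smoke culture cohort and an unpaired
#' smoker/non-smoker cohort share `n_signature` deregulated transcripts
#' (shift `effect_size` in exposed samples, random sign per transcript). A
#' `discordant_fraction` of the signature flips its direction in the in vivo
#' cohort, and a per-transcript constant platform offset (SD
#' `platform_shift_sd`) separates the cohorts — removable by per-dataset
#' min-max normalization, which is what makes independent normalization of
#' the joined datasets consequential.
#'
#' @param n_transcripts,n_signature total and deregulated transcript counts.
#' @param effect_size exposure shift in log2-expression units.
#' @param invitro_donors paired donors in vitro (one air + one smoke sample
#'   each).
#' @param invivo_smokers,invivo_nonsmokers in vivo group sizes.
#' @param platform_shift_sd SD of the per-transcript cohort offset.
#' @param noise_sd residual SD (both cohorts).
#' @param donor_sd SD of the in vitro donor effect.
#' @param discordant_fraction fraction of signature transcripts whose in vivo
#'   direction is flipped, in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `"two_cohort_spec"`.
#' @export
two_cohort_spec <- function(n_transcripts = 500L, n_signature = 50L,
                            effect_size = 2, invitro_donors = 3L,
                            invivo_smokers = 20L, invivo_nonsmokers = 20L,
                            platform_shift_sd = 2, noise_sd = 0.5,
                            donor_sd = 0.5, discordant_fraction = 0,
                            seed = 1L) {
  check_number(n_transcripts, "n_transcripts", lower = 1)
  check_number(n_signature, "n_signature", lower = 0, upper = n_transcripts)
  check_number(discordant_fraction, "discordant_fraction", lower = 0, upper = 1)
  check_number(invitro_donors, "invitro_donors", lower = 2)
  check_number(invivo_smokers, "invivo_smokers", lower = 2)
  check_number(invivo_nonsmokers, "invivo_nonsmokers", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(platform_shift_sd, "platform_shift_sd", lower = 0)
  check_number(donor_sd, "donor_sd", lower = 0)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 n_signature = as.integer(n_signature),
                 effect_size = effect_size,
                 invitro_donors = as.integer(invitro_donors),
                 invivo_smokers = as.integer(invivo_smokers),
                 invivo_nonsmokers = as.integer(invivo_nonsmokers),
                 platform_shift_sd = platform_shift_sd, noise_sd = noise_sd,
                 donor_sd = donor_sd,
                 discordant_fraction = discordant_fraction,
                 seed = as.integer(seed)),
            class = "two_cohort_spec")
}

#' Generate paired two-cohort expression matrices with a truth table
#'
#' @param spec a [two_cohort_spec()].
#' @return list with `invitro` and `invivo` (each a list of `values`
#'   transcripts x samples matrix and `metadata` data.frame with `sample`,
#'   `cohort`, `condition`, `donor`), and `truth` (data.frame per transcript:
#'   `transcript`, `is_signature`, `direction_invitro`, `direction_invivo`
#'   in \{-1, 0, 1\}).
#' @export
generate_two_cohort_expression <- function(spec) {
  stop_if(!inherits(spec, "two_cohort_spec"), "'spec' must be a two_cohort_spec")
  set.seed(spec$seed)
  m <- spec$n_transcripts
  ids <- sprintf("TX%04d", seq_len(m))
  base <- rnorm(m, mean = 8, sd = 1.5)            # shared baseline (log2 scale)
  shift <- rnorm(m, sd = spec$platform_shift_sd)  # per-transcript cohort offset

  dir_a <- integer(m)
  sig <- seq_len(spec$n_signature)
  dir_a[sig] <- sample(c(-1L, 1L), spec$n_signature, replace = TRUE)
  dir_b <- dir_a
  n_flip <- round(spec$discordant_fraction * spec$n_signature)
  if (n_flip > 0) {
    flip <- sample(sig, n_flip)
    dir_b[flip] <- -dir_b[flip]
  }

  # -- in vitro: paired air/smoke per donor ----------------------------------
  nd <- spec$invitro_donors
  meta_a <- data.frame(
    sample = sprintf("ALI_%02d_%s", rep(seq_len(nd), each = 2), c("air", "smoke")),
    cohort = "invitro",
    condition = rep(c("air", "smoke"), nd),
    donor = sprintf("D%02d", rep(seq_len(nd), each = 2)))
  donor_eff <- matrix(rnorm(m * nd, sd = spec$donor_sd), m, nd)
  va <- base + donor_eff[, rep(seq_len(nd), each = 2)] +
    outer(dir_a * spec$effect_size, as.numeric(meta_a$condition == "smoke")) +
    matrix(rnorm(m * nrow(meta_a), sd = spec$noise_sd), m)
  dimnames(va) <- list(ids, meta_a$sample)

  # -- in vivo: unpaired smokers / non-smokers with platform offset ----------
  ns <- spec$invivo_smokers; nn <- spec$invivo_nonsmokers
  meta_b <- data.frame(
    sample = c(sprintf("SAE_NS_%02d", seq_len(nn)), sprintf("SAE_SM_%02d", seq_len(ns))),
    cohort = "invivo",
    condition = c(rep("nonsmoker", nn), rep("smoker", ns)),
    donor = NA_character_)
  vb <- base + shift +
    outer(dir_b * spec$effect_size, as.numeric(meta_b$condition == "smoker")) +
    matrix(rnorm(m * nrow(meta_b), sd = spec$noise_sd), m)
  dimnames(vb) <- list(ids, meta_b$sample)

  list(invitro = list(values = va, metadata = meta_a),
       invivo = list(values = vb, metadata = meta_b),
       truth = data.frame(transcript = ids,
                          is_signature = seq_len(m) %in% sig,
                          direction_invitro = dir_a,
                          direction_invivo = dir_b))
}
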