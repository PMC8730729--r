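## Seeded generators with known ground truth for every downstream stage:
## spectral-count evidence, single-molecule traces, ROI measurements, and
## tubule tracks. Identical config + seed gives byte-identical output.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Configuration for the spectral-count generator
#'
#' Defaults emulate the 4-replicate bait versus 4-replicate cytoplasmic
#' control BioID design with a handful of strongly enriched planted
#' interactors on a large unenriched background.
#'
#' @param n_background_proteins background (unenriched) proteins.
#' @param n_true_interactors planted interactors enriched in the bait.
#' @param n_replicates_bait,n_replicates_control technical replicates.
#' @param baseline_count_mean expected spectral counts per protein of
#'   average length per replicate.
#' @param enrichment_factor multiplicative abundance boost of true
#'   interactors in the bait (>= 1; 1 gives a null simulation).
#' @param shared_peptide_fraction fraction of peptides mapped to 2 proteins.
#' @param dropout_prob probability a true interactor yields zero counts in
#'   a given bait replicate.
#' @param protein_length_range amino-acid length bounds (uniform).
#' @param seed RNG seed.
#' @return named list of class \code{proteomeSimConfig}.
#' @export
proteomeSimConfig <- function(n_background_proteins = 500,
                              n_true_interactors = 20,
                              n_replicates_bait = 4,
                              n_replicates_control = 4,
                              baseline_count_mean = 10,
                              enrichment_factor = 5,
                              shared_peptide_fraction = 0.1,
                              dropout_prob = 0.1,
                              protein_length_range = c(200, 1000),
                              seed = 1) {
  if (n_background_proteins < 1 || n_true_interactors < 0 ||
      n_replicates_bait < 1 || n_replicates_control < 1)
    stop("nonpositive simulation dimensions")
  if (baseline_count_mean <= 0) stop("baseline_count_mean must be > 0")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (shared_peptide_fraction < 0 || shared_peptide_fraction >= 1)
    stop("shared_peptide_fraction must be in [0, 1)")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (length(protein_length_range) != 2 ||
      protein_length_range[1] < 1 ||
      diff(protein_length_range) < 0)
    stop("invalid protein_length_range")
  structure(as.list(environment()), class = "proteomeSimConfig")
}

#' Simulate peptide-level spectral counts with planted interactors
#'
#' Peptide counts are Poisson with a protein-level rate proportional to
#' abundance times length; every protein carries roughly one peptide per
#' 60 amino acids (at least two). A \code{shared_peptide_fraction} of
#' peptides is additionally mapped to a second random protein and draws
#' counts from the summed rate of both. True interactors have their bait
#' abundance multiplied by \code{enrichment_factor}, with per-replicate
#' dropout at \code{dropout_prob}.
#'
#' @param config a [proteomeSimConfig()].
#' @return list with \code{peptides} (columns \code{peptide_id},
#'   \code{protein_ids}, then \code{bait_1..} and \code{control_1..}
#'   counts), \code{proteins} (\code{protein_id}, \code{length_aa}), and
#'   \code{truth} (character vector of planted interactor ids).
#' @export
simulateSpectralCounts <- function(config) {
  stopifnot(inherits(config, "proteomeSimConfig"))
  .with_seed(config$seed, {
    n_bg <- config$n_background_proteins
    n_int <- config$n_true_interactors
    ids <- c(sprintf("BG%04d", seq_len(n_bg)),
             if (n_int > 0) sprintf("INT%03d", seq_len(n_int)))
    n_prot <- length(ids)
    L <- sample(seq(config$protein_length_range[1],
                    config$protein_length_range[2]),
                n_prot, replace = TRUE)
    is_int <- grepl("^INT", ids)

    n_pep <- pmax(2L, as.integer(round(L / 60)))
    pep_prot <- rep(seq_len(n_prot), n_pep)
    n_pep_tot <- length(pep_prot)
    # second mapping for the shared fraction
    second <- rep(NA_integer_, n_pep_tot)
    n_shared <- round(config$shared_peptide_fraction * n_pep_tot)
    if (n_shared > 0 && n_prot > 1) {
      sh <- sample(n_pep_tot, n_shared)
      second[sh] <- vapply(pep_prot[sh], function(k)
        sample(setdiff(seq_len(n_prot), k), 1L), integer(1))
    }

    # per-protein per-peptide Poisson rates, scaled so a protein of mean
    # length expects baseline_count_mean counts per replicate
    rate_prot <- config$baseline_count_mean * L / mean(L)
    rate_pep <- rate_prot[pep_prot] / n_pep[pep_prot]
    rate_pep2 <- ifelse(is.na(second), 0,
                        rate_prot[ifelse(is.na(second), 1, second)] /
                          n_pep[ifelse(is.na(second), 1, second)])

    draw_cond <- function(n_rep, bait) {
      boost <- function(prot_idx) {
        b <- rep(1, length(prot_idx))
        if (bait) b[is_int[prot_idx]] <- config$enrichment_factor
        b
      }
      m <- matrix(0L, nrow = n_pep_tot, ncol = n_rep)
      for (r in seq_len(n_rep)) {
        lam <- rate_pep * boost(pep_prot) +
          ifelse(is.na(second), 0, rate_pep2 * boost(
            ifelse(is.na(second), 1, second)))
        cnt <- stats::rpois(n_pep_tot, lam)
        if (bait && config$dropout_prob > 0 && n_int > 0) {
          drop <- is_int & stats::runif(n_prot) < config$dropout_prob
          cnt[drop[pep_prot]] <- 0L
        }
        m[, r] <- cnt
      }
      m
    }
    bait_m <- draw_cond(config$n_replicates_bait, bait = TRUE)
    ctrl_m <- draw_cond(config$n_replicates_control, bait = FALSE)
    colnames(bait_m) <- sprintf("bait_%d", seq_len(ncol(bait_m)))
    colnames(ctrl_m) <- sprintf("control_%d", seq_len(ncol(ctrl_m)))

    prot_ids <- ifelse(is.na(second), ids[pep_prot],
                       paste(ids[pep_prot],
                             ids[ifelse(is.na(second), 1, second)],
                             sep = ";"))
    peptides <- data.frame(peptide_id = sprintf("pep%05d",
                                                seq_len(n_pep_tot)),
                           protein_ids = prot_ids,
                           stringsAsFactors = FALSE)
    peptides <- cbind(peptides, as.data.frame(bait_m),
                      as.data.frame(ctrl_m))
    list(peptides = peptides,
         proteins = data.frame(protein_id = ids, length_aa = L,
                               stringsAsFactors = FALSE),
         truth = ids[is_int])
  })
}

#' Configuration for the single-molecule trace generator
#'
#' Defaults describe an in vitro reconstitution movie: frames every 0.4 s
#' for 3 min, processive runs at 0.8 um/s with occasional pauses, and
#' landings arriving as a Poisson process along the filament. Purely
#' diffusive or static landings are off by default (the activated
#' motor regime) and can be switched on via the fractions.
#'
#' @param n_movies number of movies.
#' @param movie_duration s per movie (default 180).
#' @param frame_interval s between frames (default 0.4).
#' @param mt_length um of microtubule per movie.
#' @param landing_rate_true events per um per s.
#' @param velocity_mean,velocity_sd um/s of processive runs.
#' @param run_length_mean,run_length_min um; run lengths are
#'   \code{run_length_min} plus an exponential with the remaining mean.
#' @param pause_rate_true pauses per um of run (must be below 1; pause
#'   sites keep a 1 um minimum spacing so distinct stops stay resolvable
#'   at imaging resolution, at exactly this long-run rate).
#' @param pause_duration_mean s; pause durations are Gamma (shape 6) with
#'   this mean so pauses are resolvable at the frame interval.
#' @param diffusive_fraction,static_fraction fractions of landings that
#'   are diffusive or static (sum <= 1; remainder processive).
#' @param localization_noise_sd um of per-frame localization error.
#' @param colocalization_prob probability a processive event carries the
#'   second channel on part of its span.
#' @param seed RNG seed.
#' @return named list of class \code{motilitySimConfig}.
#' @export
motilitySimConfig <- function(n_movies = 50,
                              movie_duration = 180,
                              frame_interval = 0.4,
                              mt_length = 12,
                              landing_rate_true = 0.003,
                              velocity_mean = 0.8,
                              velocity_sd = 0.08,
                              run_length_mean = 4,
                              run_length_min = 1,
                              pause_rate_true = 0.2,
                              pause_duration_mean = 4,
                              diffusive_fraction = 0,
                              static_fraction = 0,
                              localization_noise_sd = 0.02,
                              colocalization_prob = 0.5,
                              seed = 1) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (frame_interval >= movie_duration)
    stop("frame_interval must be smaller than movie_duration")
  if (n_movies < 1 || mt_length <= 0) stop("nonpositive dimensions")
  if (landing_rate_true < 0) stop("landing_rate_true must be >= 0")
  if (velocity_mean <= 0) stop("velocity_mean must be > 0")
  if (diffusive_fraction < 0 || static_fraction < 0 ||
      diffusive_fraction + static_fraction > 1)
    stop("class fractions must be in [0,1] and sum to at most 1")
  if (run_length_min <= 0 || run_length_mean < run_length_min)
    stop("need 0 < run_length_min <= run_length_mean")
  if (pause_rate_true < 0 || pause_rate_true >= 1)
    stop("pause_rate_true must be in [0, 1) pauses per um")
  structure(as.list(environment()), class = "motilitySimConfig")
}

# pause sites along a run: stationary hard-core renewal process with the
# requested rate per um and a minimum spacing, so that distinct stops are
# resolvable as separate pauses at imaging resolution (two stops closer
# than the spacing are one pause to any frame-level analyzer); the
# negative-side burn-in makes the process stationary, hence the rate exact
.pause_positions <- function(run, rate, spacing = 1) {
  if (rate <= 0 || run <= 0) return(numeric(0))
  mu <- 1 / rate - spacing
  x <- -10 * (spacing + mu)
  out <- numeric(0)
  repeat {
    x <- x + spacing + stats::rexp(1, 1 / mu)
    if (x >= run) break
    if (x > 0) out <- c(out, x)
  }
  out
}

# piecewise-linear path of a processive run with pauses; offsets from the
# landing point, time from the landing instant
.processive_path <- function(run, v, pause_rate, pause_mean) {
  pd <- .pause_positions(run, pause_rate)
  n_p <- length(pd)
  pt <- stats::rgamma(n_p, shape = 6, rate = 6 / pause_mean)
  bt <- 0; bx <- 0; tcur <- 0; dprev <- 0
  for (i in seq_len(n_p)) {
    tcur <- tcur + (pd[i] - dprev) / v
    bt <- c(bt, tcur); bx <- c(bx, pd[i])
    tcur <- tcur + pt[i]
    bt <- c(bt, tcur); bx <- c(bx, pd[i])
    dprev <- pd[i]
  }
  tcur <- tcur + (run - dprev) / v
  bt <- c(bt, tcur); bx <- c(bx, run)
  list(t = bt, x = bx, duration = tcur, n_pauses = n_p)
}

#' Simulate single-molecule traces with a ground-truth event log
#'
#' Events land along each microtubule as a Poisson process with rate
#' \code{landing_rate_true * mt_length} per second. Processive events are
#' piecewise-constant-velocity walks (velocity drawn per event, zero
#' during pauses) whose landing position is drawn so the run fits on the
#' filament; diffusive events are reflected random walks making large
#' bidirectional excursions; static events hold position. Gaussian
#' localization noise is added per frame and positions are clipped to the
#' filament. Events visible for fewer than two frames are discarded from
#' both the trace table and the log, so the log and table always contain
#' the same events.
#'
#' @param config a [motilitySimConfig()].
#' @return list with \code{traces} (columns \code{movie}, \code{event_id},
#'   \code{frame}, \code{time_s}, \code{position_um},
#'   \code{channel2_present}), \code{events} (the ground-truth log:
#'   \code{event_id}, \code{movie}, \code{class}, \code{t_land},
#'   \code{velocity}, \code{run_length}, \code{n_pauses},
#'   \code{duration}, \code{colocalized}), and \code{movies}
#'   (\code{movie}, \code{frame_interval}, \code{n_frames},
#'   \code{mt_length}, \code{duration}).
#' @export
simulateTraces <- function(config) {
  stopifnot(inherits(config, "motilitySimConfig"))
  .with_seed(config$seed, {
    dt <- config$frame_interval
    n_frames <- floor(config$movie_duration / dt)
    frame_times <- (seq_len(n_frames) - 1) * dt
    tr_list <- list(); ev_list <- list()
    for (m in seq_len(config$n_movies)) {
      n_ev <- stats::rpois(1, config$landing_rate_true *
                             config$mt_length * config$movie_duration)
      if (n_ev == 0) next
      t_land <- sort(stats::runif(n_ev, 0, config$movie_duration))
      u <- stats::runif(n_ev)
      cls <- ifelse(u < config$diffusive_fraction, "diffusive",
                    ifelse(u < config$diffusive_fraction +
                             config$static_fraction, "static",
                           "processive"))
      for (i in seq_len(n_ev)) {
        id <- sprintf("m%03d_e%04d", m, i)
        if (cls[i] == "processive") {
          v <- max(stats::rnorm(1, config$velocity_mean,
                                config$velocity_sd),
                   0.1 * config$velocity_mean)
          run <- min(config$run_length_min +
                       stats::rexp(1, 1 / (config$run_length_mean -
                                             config$run_length_min +
                                             1e-12)),
                     config$mt_length)
          x0 <- stats::runif(1, 0, config$mt_length - run)
          path <- .processive_path(run, v, config$pause_rate_true,
                                   config$pause_duration_mean)
          ft <- frame_times[frame_times >= t_land[i] &
                              frame_times <= t_land[i] + path$duration]
          if (length(ft) < 2) next
          pos <- x0 + stats::approx(path$t, path$x,
                                    xout = ft - t_land[i])$y
          truth_v <- v; truth_run <- run; truth_np <- path$n_pauses
          dur <- path$duration
        } else if (cls[i] == "static") {
          dur <- stats::rexp(1, 1 / 20)
          ft <- frame_times[frame_times >= t_land[i] &
                              frame_times <= t_land[i] + dur]
          if (length(ft) < 2) next
          pos <- rep(stats::runif(1, 0, config$mt_length), length(ft))
          truth_v <- NA_real_; truth_run <- 0; truth_np <- 0L
        } else {
          # diffusive landings explore the filament vigorously enough to
          # make the defining >0.6 um excursions in both directions
          dur <- 8 + stats::rexp(1, 1 / 15)
          ft <- frame_times[frame_times >= t_land[i] &
                              frame_times <= t_land[i] + dur]
          if (length(ft) < 2) next
          steps <- stats::rnorm(length(ft) - 1, 0, 0.25)
          raw <- cumsum(c(stats::runif(1, 0.2, 0.8) * config$mt_length,
                          steps))
          # reflect into the filament
          pos <- abs(raw %% (2 * config$mt_length))
          pos <- ifelse(pos > config$mt_length,
                        2 * config$mt_length - pos, pos)
          truth_v <- NA_real_; truth_run <- 0; truth_np <- 0L
        }
        if (config$localization_noise_sd > 0)
          pos <- pos + stats::rnorm(length(pos), 0,
                                    config$localization_noise_sd)
        pos <- pmin(pmax(pos, 0), config$mt_length)
        ch2 <- rep(FALSE, length(pos))
        coloc <- FALSE
        if (cls[i] == "processive" &&
            stats::runif(1) < config$colocalization_prob) {
          coloc <- TRUE
          n <- length(pos)
          len <- max(1L, ceiling(stats::runif(1, 0.5, 1) * n))
          s <- sample.int(n - len + 1L, 1L)
          ch2[s:(s + len - 1L)] <- TRUE
        }
        frames <- as.integer(round(ft / dt))
        tr_list[[id]] <- data.frame(movie = m, event_id = id,
                                    frame = frames, time_s = ft,
                                    position_um = pos,
                                    channel2_present = ch2,
                                    stringsAsFactors = FALSE)
        ev_list[[id]] <- data.frame(event_id = id, movie = m,
                                    class = cls[i], t_land = t_land[i],
                                    velocity = truth_v,
                                    run_length = truth_run,
                                    n_pauses = truth_np, duration = dur,
                                    colocalized = coloc,
                                    stringsAsFactors = FALSE)
      }
    }
    traces <- if (length(tr_list) > 0)
      do.call(rbind, c(tr_list, list(make.row.names = FALSE)))
    else data.frame(movie = integer(0), event_id = character(0),
                    frame = integer(0), time_s = numeric(0),
                    position_um = numeric(0),
                    channel2_present = logical(0))
    events <- if (length(ev_list) > 0)
      do.call(rbind, c(ev_list, list(make.row.names = FALSE)))
    else data.frame(event_id = character(0), movie = integer(0),
                    class = character(0), t_land = numeric(0),
                    velocity = numeric(0), run_length = numeric(0),
                    n_pauses = integer(0), duration = numeric(0),
                    colocalized = logical(0))
    movies <- data.frame(movie = seq_len(config$n_movies),
                         frame_interval = dt, n_frames = n_frames,
                         mt_length = config$mt_length,
                         duration = config$movie_duration)
    list(traces = traces, events = events, movies = movies)
  })
}

#' Configuration for the ROI-measurement generator
#'
#' @param n_cells_per_group cells per condition group.
#' @param centrosome_area_fraction fraction of the whole-cell ROI area
#'   occupied by the centrosome ROI (in (0, 1)).
#' @param accumulation_true ground-truth area-normalized enrichment ratio
#'   (1 = uniform fluorescence). \code{accumulation_true *
#'   centrosome_area_fraction} must not exceed 1 (the centrosome cannot
#'   hold more than all the fluorescence).
#' @param intensity_noise_cv coefficient of variation of multiplicative
#'   lognormal noise on the centrosome intensity (mean exactly 1).
#' @param seed RNG seed.
#' @return named list of class \code{roiSimConfig}.
#' @export
roiSimConfig <- function(n_cells_per_group = 80,
                         centrosome_area_fraction = 0.05,
                         accumulation_true = 3,
                         intensity_noise_cv = 0.2,
                         seed = 1) {
  if (n_cells_per_group < 1) stop("nonpositive dimensions")
  if (centrosome_area_fraction <= 0 || centrosome_area_fraction >= 1)
    stop("centrosome_area_fraction must be in (0, 1)")
  if (accumulation_true <= 0) stop("accumulation_true must be > 0")
  if (accumulation_true * centrosome_area_fraction > 1)
    stop("impossible geometry: accumulation_true * area fraction > 1")
  if (intensity_noise_cv < 0) stop("intensity_noise_cv must be >= 0")
  structure(as.list(environment()), class = "roiSimConfig")
}

#' Simulate paired centrosome / whole-cell ROI measurements
#'
#' Each cell gets a lognormal whole-cell area and intensity; the
#' centrosome ROI occupies \code{centrosome_area_fraction} of the area and
#' \code{accumulation_true * centrosome_area_fraction} of the intensity,
#' times mean-one lognormal noise, clipped to the whole-cell intensity.
#' With zero noise every cell's normalized ratio is exactly
#' \code{accumulation_true}.
#'
#' @param config a [roiSimConfig()].
#' @param group label stored in the \code{group} column (default
#'   \code{"group1"}).
#' @return data.frame with \code{cell_id}, \code{group},
#'   \code{centrosome_intensity}, \code{whole_cell_intensity},
#'   \code{centrosome_area}, \code{whole_cell_area}.
#' @export
simulateRoiMeasurements <- function(config, group = "group1") {
  stopifnot(inherits(config, "roiSimConfig"))
  .with_seed(config$seed, {
    n <- config$n_cells_per_group
    wa <- stats::rlnorm(n, log(2e4), 0.2)
    wi <- stats::rlnorm(n, log(1e6), 0.3)
    cv <- config$intensity_noise_cv
    noise <- if (cv > 0) {
      s2 <- log(1 + cv^2)
      stats::rlnorm(n, -s2 / 2, sqrt(s2))
    } else rep(1, n)
    ci <- pmin(config$accumulation_true *
                 config$centrosome_area_fraction * wi * noise, wi)
    data.frame(cell_id = sprintf("%s_c%03d", group, seq_len(n)),
               group = group,
               centrosome_intensity = ci,
               whole_cell_intensity = wi,
               centrosome_area = config$centrosome_area_fraction * wa,
               whole_cell_area = wa,
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-cell tubule tracks
#'
#' Companion generator for the motile-tubule counting rules: each cell
#' receives a Poisson number of tracked tubules; each tubule independently
#' moved from its origin with probability \code{motile_prob} and has a
#' lognormal maximum length.
#'
#' @param n_cells number of cells.
#' @param tubules_per_cell expected tracked tubules per cell.
#' @param motile_prob probability a tubule moved from its origin.
#' @param length_meanlog,length_sdlog lognormal parameters of the maximum
#'   tubule length in um (defaults give a median of 2 um).
#' @param seed RNG seed.
#' @return data.frame with \code{cell_id}, \code{tubule_id},
#'   \code{max_length}, \code{moved_from_origin}.
#' @export
simulateTubuleTracks <- function(n_cells = 55, tubules_per_cell = 8,
                                 motile_prob = 0.7,
                                 length_meanlog = log(2),
                                 length_sdlog = 0.5, seed = 1) {
  if (n_cells < 1 || tubules_per_cell <= 0)
    stop("nonpositive dimensions")
  .with_seed(seed, {
    n_t <- stats::rpois(n_cells, tubules_per_cell)
    cell <- rep(sprintf("cell%03d", seq_len(n_cells)), n_t)
    total <- sum(n_t)
    data.frame(cell_id = cell,
               tubule_id = sprintf("t%05d", seq_len(total)),
               max_length = stats::rlnorm(total, length_meanlog,
                                          length_sdlog),
               moved_from_origin = stats::runif(total) < motile_prob,
               stringsAsFactors = FALSE)
  })
}
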