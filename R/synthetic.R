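#' Configuration for the inhomogeneous-Poisson population simulator
#'
#' Describes a population of independently firing neurons whose rate on a
#' presentation of image \eqn{i} is
#' \deqn{\lambda_{ni}(t) = \max(0,\; b_n + 1[t \ge L_n](g_n + s_n c_i p_n(t)
#'   + \epsilon_{ni}))}
#' with baseline \eqn{b_n}, response latency \eqn{L_n}, visual response gain
#' \eqn{g_n}, category signal \eqn{s_n \in \{0, \pm\kappa\}} (zero for
#' non-selective neurons, \eqn{\kappa} = `category_contrast * training_gain`
#' otherwise, sign random), category code \eqn{c_i = +1/2} for dog and
#' \eqn{-1/2} for cat, within-trial contrast profile \eqn{p_n(t)} and a
#' per-(neuron, image) idiosyncratic rate offset
#' \eqn{\epsilon_{ni} \sim N(0, \sigma_\epsilon^2)} that makes images within
#' a category similar but not identical.
#'
#' `profile = "step"` holds the category contrast constant after the
#' latency (the temporally flat representation typical of area TEO);
#' `profile = "ramp"` grows it linearly from the latency to `ramp_end`
#' (the within-trial growth typical of area TE). `training_gain` scales the
#' contrast multiplicatively and models the post-training strengthening of
#' category signals in TE.
#'
#' Defaults emulate the recorded sessions: 260 images per category, mean
#' firing rates of a few spikes/s, response latencies well under 100 ms,
#' and per-image trial counts in the 5-19 range (10 by default).
#'
#' @param n_neurons number of units.
#' @param images_per_category stimuli per category (cat and dog alike).
#' @param trials_per_image presentations of each image.
#' @param baseline_rate_mean,baseline_rate_sd pre-onset rate distribution
#'   across neurons (spikes/s; draws truncated at 0).
#' @param latency_mean,latency_sd response-onset latency distribution (ms;
#'   truncated at 0).
#' @param response_gain_mean,response_gain_sd category-independent visual
#'   response gain (spikes/s; truncated at 0).
#' @param category_contrast mean absolute dog-minus-cat rate difference for
#'   a selective neuron once its profile is fully expressed (spikes/s).
#' @param selective_fraction probability that a neuron carries category
#'   signal.
#' @param profile `"step"` or `"ramp"`.
#' @param ramp_end time (ms) at which the ramp profile saturates.
#' @param training_gain multiplier on `category_contrast`.
#' @param image_idiosyncrasy_sd sd of the per-(neuron, image) rate offset
#'   (spikes/s).
#' @param area,session,monkey_id metadata stamped on generated datasets.
#' @param analysis_window simulated epoch, ms relative to onset.
#' @param presentation_duration range (ms) from which each trial's
#'   presentation duration is drawn uniformly.
#' @param seed integer seed; identical configs generate identical datasets.
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_neurons = 100,
                             images_per_category = 260,
                             trials_per_image = 10,
                             baseline_rate_mean = 5, baseline_rate_sd = 2,
                             latency_mean = 60, latency_sd = 20,
                             response_gain_mean = 10, response_gain_sd = 5,
                             category_contrast = 5,
                             selective_fraction = 0.5,
                             profile = c("step", "ramp"),
                             ramp_end = 350,
                             training_gain = 1,
                             image_idiosyncrasy_sd = 2,
                             area = c("TEO", "TE"),
                             session = c("pre", "post"),
                             monkey_id = "sim",
                             analysis_window = c(-300, 400),
                             presentation_duration = c(350, 400),
                             seed = 1L) {
  profile <- match.arg(profile)
  area <- match.arg(area)
  session <- match.arg(session)
  if (n_neurons < 1 || images_per_category < 1 || trials_per_image < 1)
    stop("config error: n_neurons, images_per_category and trials_per_image ",
         "must be positive counts")
  if (selective_fraction < 0 || selective_fraction > 1)
    stop("config error: selective_fraction must be in [0, 1]")
  if (training_gain <= 0) stop("config error: training_gain must be > 0")
  if (any(c(baseline_rate_mean, baseline_rate_sd, latency_sd,
            response_gain_mean, response_gain_sd, category_contrast,
            image_idiosyncrasy_sd) < 0))
    stop("config error: rates, sds and contrasts must be >= 0")
  structure(
    list(n_neurons = as.integer(n_neurons),
         images_per_category = as.integer(images_per_category),
         trials_per_image = as.integer(trials_per_image),
         baseline_rate_mean = baseline_rate_mean,
         baseline_rate_sd = baseline_rate_sd,
         latency_mean = latency_mean, latency_sd = latency_sd,
         response_gain_mean = response_gain_mean,
         response_gain_sd = response_gain_sd,
         category_contrast = category_contrast,
         selective_fraction = selective_fraction,
         profile = profile, ramp_end = ramp_end,
         training_gain = training_gain,
         image_idiosyncrasy_sd = image_idiosyncrasy_sd,
         area = area, session = session, monkey_id = monkey_id,
         analysis_window = as.numeric(analysis_window),
         presentation_duration = as.numeric(presentation_duration),
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# run code with a private, seeded RNG stream; caller's stream untouched
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic spike dataset
#'
#' Draws per-neuron parameters, per-(neuron, image) idiosyncratic offsets
#' and then inhomogeneous-Poisson spike trains for every (trial, neuron)
#' pair by thinning: candidate events from a homogeneous process at the
#' per-(neuron, image) rate ceiling are accepted with probability
#' \eqn{\lambda(t)/\lambda_{max}}. Fully vectorised and, given
#' `config$seed`, deterministic: the same config always yields the same
#' spike times.
#'
#' @param config a [synthetic_config()]
#' @return a `spike_dataset`
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  N <- cfg$n_neurons
  n_img <- 2L * cfg$images_per_category
  ntr <- cfg$trials_per_image
  win <- cfg$analysis_window
  epoch_s <- diff(win) / 1000

  # per-neuron parameters (rates truncated at 0, latency at 0)
  b <- pmax(0, rnorm(N, cfg$baseline_rate_mean, cfg$baseline_rate_sd))
  L <- pmax(0, rnorm(N, cfg$latency_mean, cfg$latency_sd))
  g <- pmax(0, rnorm(N, cfg$response_gain_mean, cfg$response_gain_sd))
  sel <- runif(N) < cfg$selective_fraction
  s <- ifelse(sel, sample(c(-1, 1), N, replace = TRUE), 0) *
    cfg$category_contrast * cfg$training_gain

  # stimuli: cats first, then dogs; c_i = -1/2 (cat), +1/2 (dog)
  image_id <- c(sprintf("cat%03d", seq_len(cfg$images_per_category)),
                sprintf("dog%03d", seq_len(cfg$images_per_category)))
  category <- rep(c("cat", "dog"), each = cfg$images_per_category)
  ci <- rep(c(-0.5, 0.5), each = cfg$images_per_category)

  # idiosyncratic per-(neuron, image) offsets, fixed across trials
  eps <- matrix(rnorm(N * n_img, 0, cfg$image_idiosyncrasy_sd),
                nrow = N, ncol = n_img)

  # trials: grouped by image
  n_trial <- n_img * ntr
  trial_img <- rep(seq_len(n_img), each = ntr)
  trial_id <- sprintf("t%06d", seq_len(n_trial))
  dur <- runif(n_trial, cfg$presentation_duration[1],
               cfg$presentation_duration[2])

  # rate ceiling per (neuron, image): lambda(t) is piecewise linear between
  # b (pre-latency), b+g+eps (latency) and b+g+eps+s*c (profile saturated)
  post0 <- pmax(0, b + g + eps)                       # N x n_img
  post1 <- pmax(0, b + g + eps + outer(s, ci))        # N x n_img
  lam_max <- matrix(pmax(b, pmax(post0, post1)), nrow = N, ncol = n_img)

  # one train per (trial, neuron); homogeneous candidates then thinning
  tr_idx <- rep(seq_len(n_trial), times = N)
  nr_idx <- rep(seq_len(N), each = n_trial)
  im_idx <- trial_img[tr_idx]
  lmax_train <- lam_max[cbind(nr_idx, im_idx)]
  m <- rpois(length(lmax_train), lmax_train * epoch_s)
  tot <- sum(m)
  if (tot == 0L) {
    spikes <- data.frame(trial_id = character(0), neuron_id = character(0),
                         spike_time_ms = numeric(0))
  } else {
    ctr <- rep.int(tr_idx, m)
    cnr <- rep.int(nr_idx, m)
    cim <- rep.int(im_idx, m)
    clmax <- rep.int(lmax_train, m)
    tt <- runif(tot, win[1], win[2])
    lam <- .lambda_at(tt, b[cnr], L[cnr], g[cnr], s[cnr], ci[cim],
                      eps[cbind(cnr, cim)], cfg$profile, cfg$ramp_end)
    keep <- runif(tot) < lam / clmax
    neuron_id_all <- sprintf("n%03d", seq_len(N))
    spikes <- data.frame(trial_id = trial_id[ctr[keep]],
                         neuron_id = neuron_id_all[cnr[keep]],
                         spike_time_ms = tt[keep])
  }

  spike_dataset(
    stimuli = data.frame(image_id = image_id, category = category),
    trials = data.frame(trial_id = trial_id, image_id = image_id[trial_img],
                        presentation_duration_ms = dur),
    spikes = spikes,
    neuron_ids = sprintf("n%03d", seq_len(N)),
    area = cfg$area, session = cfg$session, monkey_id = cfg$monkey_id,
    analysis_window = win)
}

# instantaneous rate of the generative model (vectorised over events)
.lambda_at <- function(t, b, L, g, s, ci, eps, profile, ramp_end) {
  p <- if (profile == "step") {
    1
  } else {
    span <- pmax(ramp_end - L, .Machine$double.eps)
    pmin(1, pmax(0, (t - L) / span))
  }
  post <- t >= L
  pmax(0, b + post * (g + s * ci * p + eps))
}

# mean of the profile indicator 1[t >= L] over [a, b)
.frac_past <- function(a, b, L) pmin(1, pmax(0, (b - pmax(a, L)) / (b - a)))

# mean of 1[t >= L] p(t) over [a, b) for the ramp profile
.ramp_mean <- function(a, b, L, R) {
  if (R <= L) return(.frac_past(a, b, L))
  Fi <- function(t) {  # antiderivative of the clamped ramp, F(L) = 0
    t <- pmax(t, L)
    ifelse(t <= R, (t - L)^2 / (2 * (R - L)), (R - L) / 2 + (t - R))
  }
  (Fi(b) - Fi(a)) / (b - a)
}

#' Expected Mahalanobis category separation in a window
#'
#' Closed-form large-trial expectation of the Mahalanobis distance D that
#' [separation_timecourse()] estimates from data generated under `config`,
#' evaluated at the population-mean parameter values (exact when the
#' between-neuron sds are zero). Per selective neuron the dog-minus-cat
#' mean-rate difference is \eqn{\delta = \kappa \bar p} (profile mean
#' \eqn{\bar p} over the window) and the within-class variance of the
#' trial-averaged rate is Poisson counting noise plus the idiosyncratic
#' image-to-image variance:
#' \eqn{\sigma^2 = \bar\lambda / (n_{tr} \Delta t) + (\sigma_\epsilon q)^2}
#' with \eqn{q} the fraction of the window past the latency. Because the
#' empirical D is built from the within-class *scatter* matrix (not the
#' covariance), the squared distance carries a \eqn{1/(n_{img} - 2)}
#' factor:
#' \deqn{D = \sqrt{\frac{f N \delta^2 / \sigma^2}{n_{img} - 2}}}
#' with selective fraction \eqn{f}. Rate truncation at zero is ignored;
#' use parameters where truncation is negligible.
#'
#' @param config a [synthetic_config()]
#' @param window numeric `c(start, end)` in ms, inside the analysis window.
#' @return expected D (non-negative scalar; 0 if the window precedes the
#'   latency or the config carries no category signal).
#' @export
expected_window_separation <- function(config, window) {
  stopifnot(inherits(config, "synthetic_config"), length(window) == 2L)
  a <- window[1]; bnd <- window[2]
  if (bnd <= a) stop("window must satisfy end > start")
  if (a < config$analysis_window[1] || bnd > config$analysis_window[2])
    stop("window outside the analysis window")
  L <- config$latency_mean
  q <- .frac_past(a, bnd, L)
  if (q <= 0) return(0)
  pbar <- if (config$profile == "step") q else
    .ramp_mean(a, bnd, L, config$ramp_end)
  delta <- config$category_contrast * config$training_gain * pbar
  width_s <- (bnd - a) / 1000
  lambda_bar <- config$baseline_rate_mean + q * config$response_gain_mean
  sigma2 <- lambda_bar / (config$trials_per_image * width_s) +
    (config$image_idiosyncrasy_sd * q)^2
  n_img <- 2 * config$images_per_category
  if (n_img <= 2) stop("need more than 2 images for a scatter-based D")
  signal <- config$selective_fraction * config$n_neurons * delta^2 / sigma2
  sqrt(signal / (n_img - 2))
}
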