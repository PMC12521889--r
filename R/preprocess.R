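# Per-cell/bin standardization to [-1, 1], train/test splitting, and
# synthetic-trial augmentation.  All scaling statistics come from the
# training trials only; held-out values are clipped into [-1, 1].

#' Random train/test split of trials
#'
#' Sizes use round-half-up, so 20% of a 630-trial session gives 126
#' training trials.
#'
#' @param n_trials total trials.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed; the same `(n_trials, fraction, seed)` always gives
#'   the same split.
#' @return object of class `split_spec`: `train`, `test` index vectors,
#'   `fraction`, `seed`.
#' @export
split_trials <- function(n_trials, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_train <- floor(fraction * n_trials + 0.5)     # round half up
  if (n_train < 1 || n_train >= n_trials)
    stop("split leaves an empty training or test set")
  train <- with_seed(seed, sort(sample(n_trials, n_train)))
  structure(list(train = train, test = setdiff(seq_len(n_trials), train),
                 fraction = fraction, seed = seed),
            class = "split_spec")
}

#' Fit the per-(cell, bin) scaler on training trials and apply it
#'
#' Each (cell, bin) feature is z-scored with training mean/sd, then the
#' training z-range `[min, max]` is mapped affinely onto `[-1, 1]`.
#' Held-out values are clipped to `[-1, 1]`.  Degenerate features
#' (`sd = 0` or constant z-range) map to 0.
#'
#' @param session a `session_data`, or a plain `trials x cells x bins` array.
#' @param split a `split_spec` (or a vector of training indices).
#' @return list: `scaled` (`trials x cells x bins`, all trials),
#'   `stats` (per-feature `mean`, `sd`, `zmin`, `zmax`), `split`.
#' @export
fit_apply_scaler <- function(session, split) {
  x <- if (inherits(session, "session_data")) session$spikes else session
  train <- if (inherits(split, "split_spec")) split$train else split
  if (length(train) < 1) stop("empty training set")
  d <- dim(x)
  xt <- x[train, , , drop = FALSE]
  mu <- apply(xt, c(2, 3), mean)
  sdv <- apply(xt, c(2, 3), sd)
  if (length(train) == 1) sdv[] <- 0
  stats <- list(mean = mu, sd = sdv)
  z <- sweep(x, c(2, 3), mu, "-")
  safe_sd <- ifelse(sdv > 0, sdv, 1)
  z <- sweep(z, c(2, 3), safe_sd, "/")
  zt <- z[train, , , drop = FALSE]
  zmin <- apply(zt, c(2, 3), min)
  zmax <- apply(zt, c(2, 3), max)
  stats$zmin <- zmin; stats$zmax <- zmax
  rng <- zmax - zmin
  safe_rng <- ifelse(rng > 0, rng, 1)
  y <- sweep(sweep(z, c(2, 3), zmin, "-"), c(2, 3), safe_rng, "/") * 2 - 1
  dead <- (sdv == 0) | (rng == 0)
  if (any(dead)) {
    deadm <- array(rep(dead, each = d[1]), d)
    y[deadm] <- 0
  }
  y <- pmin(pmax(y, -1), 1)
  list(scaled = y, stats = stats,
       split = if (inherits(split, "split_spec")) split else NULL)
}

#' Apply a previously fitted scaler to new data
#' @param x `trials x cells x bins` array.
#' @param stats the `stats` element returned by [fit_apply_scaler()].
#' @return scaled array clipped to `[-1, 1]`.
#' @export
apply_scaler <- function(x, stats) {
  d <- dim(x)
  z <- sweep(x, c(2, 3), stats$mean, "-")
  z <- sweep(z, c(2, 3), ifelse(stats$sd > 0, stats$sd, 1), "/")
  rng <- stats$zmax - stats$zmin
  y <- sweep(sweep(z, c(2, 3), stats$zmin, "-"), c(2, 3),
             ifelse(rng > 0, rng, 1), "/") * 2 - 1
  dead <- (stats$sd == 0) | (rng == 0)
  if (any(dead)) y[array(rep(dead, each = d[1]), d)] <- 0
  pmin(pmax(y, -1), 1)
}

#' Create synthetic training trials by bounded uniform jitter
#'
#' Adds i.i.d. `Uniform(-noise_bound, +noise_bound)` to every (cell, bin)
#' entry of each scaled training trial and clips back into `[-1, 1]`.
#' Labels are copied unchanged, so label marginals are preserved exactly.
#'
#' @param scaled `trials x cells x bins` array in `[-1, 1]`.
#' @param noise_bound uniform half-width, in `[0, 0.2]`.
#' @param multiplier synthetic copies per real trial.
#' @param seed RNG seed.
#' @return list: `x` (augmented array, `multiplier * n` trials), `source`
#'   (index of the originating real trial for each synthetic one).
#' @export
augment_trials <- function(scaled, noise_bound = 0.1, multiplier = 1,
                           seed = 1) {
  if (noise_bound < 0) stop("noise_bound must be >= 0")
  if (noise_bound > 0.2) stop("noise_bound must be <= 0.2")
  d <- dim(scaled)
  src <- rep(seq_len(d[1]), times = multiplier)
  x <- scaled[src, , , drop = FALSE]
  if (noise_bound > 0) {
    noise <- with_seed(seed,
      array(runif(length(x), -noise_bound, noise_bound), dim(x)))
    x <- pmin(pmax(x + noise, -1), 1)
  }
  list(x = x, source = src)
}
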