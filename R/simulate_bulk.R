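# Synthetic bulk RNA-seq series with planted cell-type fraction
# trajectories: diurnal sinusoids, developmental monotone trends, or
# constant weights, with replicate noise applied on the weight scale so
# that fractions stay on the simplex.

#' Trajectory primitives for planted cell-type fraction time courses
#'
#' `traj_sinusoid()` peaks at `phase_hours` and repeats every `period`
#' hours; `traj_monotone()` interpolates linearly from `start_weight` at
#' the first sampled time to `end_weight` at the last; `traj_constant()`
#' is flat.  Weights are relative: at every timepoint the per-type weights
#' are normalized to sum to one to give the true fractions.
#'
#' @param amplitude,phase_hours,period,baseline sinusoid parameters
#'   (hours); the weight is `baseline + amplitude * cos(2*pi*(t - phase) /
#'   period)` and must stay non-negative on the sampled grid.
#' @param start_weight,end_weight endpoints of the monotone trend.
#' @param weight constant weight.
#' @return a trajectory object evaluated internally on the time grid.
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_sinusoid <- function(amplitude, phase_hours, period = 24, baseline) {
  structure(list(kind = "sinusoid", amplitude = amplitude,
                 phase = phase_hours, period = period, baseline = baseline),
            class = "celldecon_traj")
}

#' @rdname trajectories
#' @export
traj_monotone <- function(start_weight, end_weight) {
  structure(list(kind = "monotone", start = start_weight, end = end_weight),
            class = "celldecon_traj")
}

#' @rdname trajectories
#' @export
traj_constant <- function(weight) {
  structure(list(kind = "constant", weight = weight),
            class = "celldecon_traj")
}

eval_traj <- function(traj, t) {
  rng <- range(t)
  span <- if (diff(rng) > 0) diff(rng) else 1
  switch(traj$kind,
         sinusoid = traj$baseline +
           traj$amplitude * cos(2 * pi * (t - traj$phase) / traj$period),
         monotone = traj$start + (traj$end - traj$start) * (t - rng[1L]) / span,
         constant = rep(traj$weight, length(t)),
         stop("unknown trajectory kind: ", traj$kind, call. = FALSE))
}

#' Bundle per-type trajectories with replicate structure
#'
#' @param types named list of trajectory objects (one per cell type; names
#'   must match the reference profile columns).
#' @param replicate_noise_sd standard deviation of the additive weight
#'   perturbation per replicate (weights are clamped at zero and
#'   re-normalized, keeping fractions on the simplex).
#' @param n_replicates biological replicates per timepoint.
#' @return a `trajectory_spec` list.
#' @export
trajectory_spec <- function(types, replicate_noise_sd = 0.02,
                            n_replicates = 4L) {
  stopifnot(length(types) >= 1L, !is.null(names(types)),
            replicate_noise_sd >= 0, n_replicates >= 1L)
  ok <- vapply(types, inherits, TRUE, what = "celldecon_traj")
  if (!all(ok)) stop("all trajectory entries must be traj_* objects",
                     call. = FALSE)
  structure(list(types = types, replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "trajectory_spec")
}

#' Simulate a bulk RNA-seq series with planted fraction trajectories
#'
#' At each timepoint and replicate the true cell-type fractions are the
#' normalized trajectory weights, perturbed by replicate noise on the
#' weight scale and re-normalized.  The expected bulk expression is the
#' fraction-weighted mix of the reference profiles, scaled to the requested
#' sequencing depth; observed counts are Poisson around that expectation.
#'
#' @param profiles genes x types expected-expression matrix (e.g.
#'   `true_profiles` of a [simulate_reference()] result).
#' @param trajectory a [trajectory_spec()] covering exactly the profile
#'   columns.
#' @param timepoints numeric vector of sampled times (hours or days).
#' @param depth total expected counts per sample.
#' @param axis `"time"` (diurnal, hours) or `"age"` (developmental, days);
#'   with `axis = "age"` the metadata carries monotone-plus-noise traits
#'   (pseudotime, biomass, leaf area).
#' @param seed integer seed.
#' @return a `synthetic_bulk_series` list: `counts` (genes x samples),
#'   `metadata` (one row per sample), `true_fractions` (samples x types).
#' @export
simulate_bulk_series <- function(profiles, trajectory, timepoints,
                                 depth = 2e6, axis = c("time", "age"),
                                 seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(inherits(trajectory, "trajectory_spec"),
            is.matrix(profiles), length(timepoints) >= 1L, depth > 0)
  types <- colnames(profiles)
  if (is.null(types) || !setequal(types, names(trajectory$types)))
    stop("trajectory types must match profile columns exactly",
         call. = FALSE)
  W <- vapply(types, function(ty) eval_traj(trajectory$types[[ty]],
                                            timepoints),
              numeric(length(timepoints)))
  W <- matrix(W, nrow = length(timepoints),
              dimnames = list(NULL, types))
  if (any(W < 0))
    stop("negative trajectory weight at a sampled time", call. = FALSE)
  if (any(rowSums(W) == 0))
    stop("all-zero trajectory weights at a sampled time", call. = FALSE)

  nrep <- trajectory$n_replicates
  n_samples <- length(timepoints) * nrep
  out <- with_seed(seed, {
    fr <- matrix(0, n_samples, length(types),
                 dimnames = list(NULL, types))
    meta <- vector("list", n_samples)
    counts <- matrix(0L, nrow(profiles), n_samples)
    s <- 0L
    for (i in seq_along(timepoints)) {
      for (r in seq_len(nrep)) {
        s <- s + 1L
        w <- W[i, ] + stats::rnorm(length(types),
                                   sd = trajectory$replicate_noise_sd)
        w <- pmax(w, 0)
        if (sum(w) == 0) w <- W[i, ]  # degenerate perturbation: keep truth
        f <- w / sum(w)
        fr[s, ] <- f
        ex <- as.numeric(profiles %*% f)
        ex <- ex * depth / sum(ex)
        counts[, s] <- stats::rpois(length(ex), ex)
        meta[[s]] <- data.frame(t = timepoints[i],
                                replicate = paste0("rep", r),
                                stringsAsFactors = FALSE)
      }
    }
    list(fr = fr, counts = counts, meta = do.call(rbind, meta))
  })

  meta <- out$meta
  names(meta)[1L] <- if (axis == "time") "time_hours" else "age_days"
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  meta <- cbind(sample = sample_ids, meta, stringsAsFactors = FALSE)
  if (axis == "age") {
    rng <- range(timepoints)
    span <- if (diff(rng) > 0) diff(rng) else 1
    a <- (meta$age_days - rng[1L]) / span
    meta$pseudotime <- with_seed(seed + 1L,
                                 a + stats::rnorm(n_samples, sd = 0.02))
    meta$biomass <- with_seed(seed + 2L,
                              2 + 8 * a + stats::rnorm(n_samples, sd = 0.2))
    meta$leaf_area <- with_seed(seed + 3L,
                                1 + 9 * a + stats::rnorm(n_samples, sd = 0.2))
  }
  dimnames(out$counts) <- list(rownames(profiles), sample_ids)
  rownames(out$fr) <- sample_ids
  structure(list(counts = out$counts, metadata = meta,
                 true_fractions = out$fr),
            class = "synthetic_bulk_series")
}

#' @exportS3Method base::print
print.synthetic_bulk_series <- function(x, ...) {
  cat("Synthetic bulk series:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples,", ncol(x$true_fractions), "cell types\n")
  invisible(x)
}
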