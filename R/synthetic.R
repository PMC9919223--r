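# Synthetic QCM-D adsorption experiments: exact forward model plus the noise
# structure of real overtone data -- per-crystal constant offsets (irregular
# between crystals, constant in time) and statistical (white) noise.

#' Noise model for synthetic experiments
#'
#' Two independent components: a constant per-crystal offset on every channel
#' (drawn once per overtone per channel from a zero-mean uniform distribution
#' of half-width `offset_scale`, then held fixed for the whole time series --
#' averaging does not reduce it), and white noise added per sample.
#'
#' @param offset_scale Half-width of the constant offsets in Hz (default
#'   0.1 Hz, the magnitude of typical crystal-to-crystal irregularities).
#' @param white_scale Standard deviation of the statistical noise in Hz per
#'   sample (default 0.02 Hz, a realistic post-averaging floor).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(offset_scale = 0.1, white_scale = 0.02) {
  stopifnot(offset_scale >= 0, white_scale >= 0)
  structure(list(offset_scale = offset_scale, white_scale = white_scale),
            class = "noise_model")
}

#' Synthetic adsorption experiment design
#'
#' @param res A [resonator()].
#' @param bulk A [bulk_medium()] (the ambient during adsorption).
#' @param material The film [power_law_material()].
#' @param growth Thickness trajectory `d_f(t)`: a list with `type` one of
#'   `"step"` (`d_max` for `t >= t0`), `"langmuir"`
#'   (`d_max * (1 - exp(-(t - t0)/tau))`, the saturating adsorption shape) or
#'   `"linear"` (`rate * (t - t0)` capped at `d_max`), plus the named
#'   parameters; `t0` defaults to 0.
#' @param n_list Odd overtone orders (default `c(3, 5, 7, 9, 11)`).
#' @param times Sampling time grid in s.
#' @param noise A [noise_model()].
#' @param seed Integer seed; a fixed seed reproduces the series exactly,
#'   including the offsets.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(res, bulk, material,
                              growth = list(type = "langmuir", d_max = 10e-9,
                                            tau = 50),
                              n_list = c(3, 5, 7, 9, 11),
                              times = seq(0, 300, by = 2),
                              noise = noise_model(), seed = 1L) {
  stopifnot(inherits(res, "resonator"), inherits(bulk, "bulk_medium"),
            inherits(material, "power_law_material"),
            is.list(growth), growth$type %in% c("step", "langmuir", "linear"),
            all(n_list %% 2 == 1), !is.unsorted(n_list, strictly = TRUE),
            is.numeric(times), !is.unsorted(times),
            inherits(noise, "noise_model"))
  d <- growth_thickness(growth, times)
  if (any(d < 0) || is.unsorted(d)) stop("d_f(t) must be non-negative and non-decreasing")
  structure(list(res = res, bulk = bulk, material = material, growth = growth,
                 n_list = n_list, times = times, noise = noise,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

growth_thickness <- function(growth, t) {
  t0 <- if (is.null(growth$t0)) 0 else growth$t0
  switch(growth$type,
    step = ifelse(t >= t0, growth$d_max, 0),
    langmuir = pmax(0, growth$d_max * (1 - exp(-pmax(t - t0, 0) / growth$tau))),
    linear = pmin(pmax(0, growth$rate * (t - t0)), growth$d_max))
}

#' Generate a synthetic overtone time series
#'
#' Evaluates the exact film model at every time point (referenced to the
#' bulk-loaded baseline, as adsorption experiments are), then adds the
#' constant per-crystal offsets and the white noise. Deterministic under the
#' design's seed.
#'
#' @param design An [experiment_design()].
#' @return A `qcm_series`: a data.frame with columns `time`, `n`,
#'   `df_over_n`, `dG_over_n`, plus attributes `design`, `model` (the
#'   noiseless model values), `offsets` (the per-crystal constants) and
#'   `d_true` (the thickness trajectory).
#' @export
generate_timeseries <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n_list <- design$n_list
  times <- design$times
  d_t <- growth_thickness(design$growth, times)

  # exact model at each distinct thickness (adsorption plateaus repeat values)
  d_unique <- unique(d_t)
  pred <- vapply(d_unique, function(d) {
    predict_film(design$res, layer(design$material, d), design$bulk,
                 n_list, reference = "bulk") / n_list
  }, complex(length(n_list)))
  pred <- matrix(pred, nrow = length(n_list))
  model <- pred[, match(d_t, d_unique), drop = FALSE]  # n x time

  noise <- design$noise
  no <- withr::with_seed(design$seed, {
    off_f <- stats::runif(length(n_list), -noise$offset_scale, noise$offset_scale)
    off_G <- stats::runif(length(n_list), -noise$offset_scale, noise$offset_scale)
    wf <- matrix(stats::rnorm(length(model), 0, noise$white_scale),
                 nrow = length(n_list))
    wG <- matrix(stats::rnorm(length(model), 0, noise$white_scale),
                 nrow = length(n_list))
    list(off_f = off_f, off_G = off_G, wf = wf, wG = wG)
  })
  df <- Re(model) + no$off_f + no$wf
  dG <- Im(model) + no$off_G + no$wG

  out <- data.frame(time = rep(times, each = length(n_list)),
                    n = rep(n_list, length(times)),
                    df_over_n = as.numeric(df),
                    dG_over_n = as.numeric(dG))
  structure(out,
            design = design, model = model,
            offsets = list(df = no$off_f, dG = no$off_G),
            d_true = d_t,
            n_list = n_list, f0 = design$res$f0, Zq = design$res$Zq,
            reference = "bulk",
            class = c("qcm_series", "data.frame"))
}

#' Extract one time point of a series as an overtone shift set
#'
#' @param series A `qcm_series` (from [generate_timeseries()] or
#'   [read_overtone_csv()]).
#' @param time Requested time in s (nearest sample is used).
#' @param sigma_f,sigma_G Optional noise scales to attach.
#' @return An [overtone_shifts()] object.
#' @export
shifts_at <- function(series, time, sigma_f = NULL, sigma_G = NULL) {
  stopifnot(inherits(series, "qcm_series"))
  tt <- unique(series$time)
  t_sel <- tt[which.min(abs(tt - time))]
  sub <- series[series$time == t_sel, ]
  sub <- sub[order(sub$n), ]
  ref <- attr(series, "reference")
  overtone_shifts(sub$n, sub$df_over_n, sub$dG_over_n,
                  sigma_f = sigma_f, sigma_G = sigma_G,
                  reference = if (identical(ref, "bare")) "bare" else "bulk")
}

#' Block-average a time series
#'
#' Non-overlapping `k`-point block means per overtone channel, emulating the
#' pre-averaging of raw instrument data. White-noise variance shrinks by about
#' `k`; the constant per-crystal offsets are unchanged (averaging does not
#' reduce them).
#'
#' @param series A `qcm_series`.
#' @param k Block length (>= 1).
#' @return A `qcm_series` with `floor(N/k)` time points.
#' @export
pre_average <- function(series, k) {
  stopifnot(inherits(series, "qcm_series"), k >= 1, k == round(k))
  tt <- unique(series$time)
  if (k > length(tt)) stop("block length exceeds series length")
  if (k == 1) return(series)
  nb <- floor(length(tt) / k)
  block <- rep(seq_len(nb), each = k)
  keep_t <- tt[seq_len(nb * k)]
  avg <- function(v) as.numeric(tapply(v, block, mean))
  out_list <- lapply(split(series[series$time %in% keep_t, ],
                           series$n[series$time %in% keep_t]),
                     function(sub) {
                       sub <- sub[order(sub$time), ]
                       data.frame(time = avg(sub$time), n = sub$n[1],
                                  df_over_n = avg(sub$df_over_n),
                                  dG_over_n = avg(sub$dG_over_n))
                     })
  out <- do.call(rbind, out_list)
  out <- out[order(out$time, out$n), ]
  rownames(out) <- NULL
  keep_attrs(series, out)
}

#' Subtract a baseline window
#'
#' Subtracts the per-overtone, per-channel mean over a time window from the
#' whole series (standard referencing against a pre-adsorption baseline).
#'
#' @param series A `qcm_series`.
#' @param window Length-2 numeric: time interval `[t1, t2]` of the baseline.
#' @return The referenced `qcm_series`.
#' @export
baseline_subtract <- function(series, window) {
  stopifnot(inherits(series, "qcm_series"), is.numeric(window),
            length(window) == 2, window[2] >= window[1])
  in_win <- series$time >= window[1] & series$time <= window[2]
  if (!any(in_win)) stop("empty baseline window")
  out <- series
  for (nn in unique(series$n)) {
    sel <- series$n == nn
    out$df_over_n[sel] <- series$df_over_n[sel] -
      mean(series$df_over_n[sel & in_win])
    out$dG_over_n[sel] <- series$dG_over_n[sel] -
      mean(series$dG_over_n[sel & in_win])
  }
  keep_attrs(series, out)
}

keep_attrs <- function(template, out) {
  for (a in c("design", "model", "offsets", "d_true", "n_list", "f0", "Zq",
              "reference")) {
    if (a %in% c("model", "d_true")) next  # no longer aligned after reshaping
    attr(out, a) <- attr(template, a)
  }
  class(out) <- c("qcm_series", "data.frame")
  out
}

#' @export
plot.qcm_series <- function(x, channel = c("df_over_n", "dG_over_n"), ...) {
  channel <- match.arg(channel)
  ns <- sort(unique(x$n))
  cols <- grDevices::hcl.colors(length(ns), "Dark 2")
  graphics::plot(range(x$time), range(x[[channel]]), type = "n",
                 xlab = "time (s)", ylab = paste(channel, "(Hz)"), ...)
  for (i in seq_along(ns)) {
    sub <- x[x$n == ns[i], ]
    graphics::lines(sub$time, sub[[channel]], col = cols[i])
  }
  graphics::legend("topright", legend = paste0("n=", ns), col = cols,
                   lty = 1, cex = 0.8)
  invisible(x)
}
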