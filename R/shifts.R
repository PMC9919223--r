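#' Per-overtone complex shift set
#'
#' Container for one measurement: overtone-normalized frequency and
#' half-bandwidth shifts on a set of odd overtones, with optional per-overtone
#' noise scales and a reference tag stating whether the shifts are relative to
#' the bare resonator or to the bulk-loaded (pure liquid) baseline.
#'
#' @param n Strictly increasing vector of odd overtone orders (>= 1).
#' @param df_over_n Overtone-normalized frequency shifts `df/n` in Hz.
#' @param dG_over_n Overtone-normalized half-bandwidth shifts `dGamma/n` in Hz.
#' @param sigma_f,sigma_G Optional per-overtone noise scales in Hz (recycled if
#'   scalar).
#' @param reference `"bare"` or `"bulk"`.
#' @return An object of class `overtone_shifts`.
#' @export
overtone_shifts <- function(n, df_over_n, dG_over_n,
                            sigma_f = NULL, sigma_G = NULL,
                            reference = c("bare", "bulk")) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(n), length(n) >= 1, all(n >= 1), all(n %% 2 == 1),
            !is.unsorted(n, strictly = TRUE),
            length(df_over_n) == length(n), length(dG_over_n) == length(n))
  if (any(dG_over_n < -1e-6 * pmax(1, abs(df_over_n))))
    warning("negative dGamma/n: non-passive sample or artifact")
  if (!is.null(sigma_f)) sigma_f <- rep_len(sigma_f, length(n))
  if (!is.null(sigma_G)) sigma_G <- rep_len(sigma_G, length(n))
  structure(list(n = as.numeric(n), df_over_n = as.numeric(df_over_n),
                 dG_over_n = as.numeric(dG_over_n),
                 sigma_f = sigma_f, sigma_G = sigma_G, reference = reference),
            class = "overtone_shifts")
}

#' Build an overtone shift set from a complex model prediction
#'
#' @param n Overtone orders.
#' @param shift Complex `df + i dGamma` (total shift, Hz) as returned by
#'   [predict_film()].
#' @inheritParams overtone_shifts
#' @return An `overtone_shifts` object with per-n-normalized channels.
#' @export
shifts_from_complex <- function(n, shift, sigma_f = NULL, sigma_G = NULL,
                                reference = c("bare", "bulk")) {
  overtone_shifts(n, Re(shift) / n, Im(shift) / n,
                  sigma_f = sigma_f, sigma_G = sigma_G, reference = reference)
}

#' @export
print.overtone_shifts <- function(x, ...) {
  cat(sprintf("<overtone_shifts> reference: %s\n", x$reference))
  df <- data.frame(n = x$n, df_over_n = x$df_over_n, dG_over_n = x$dG_over_n)
  if (!is.null(x$sigma_f)) df$sigma_f <- x$sigma_f
  if (!is.null(x$sigma_G)) df$sigma_G <- x$sigma_G
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.overtone_shifts <- function(x, ...) {
  data.frame(n = x$n, df_over_n = x$df_over_n, dG_over_n = x$dG_over_n)
}

#' Acoustic ratio
#'
#' The dimensionless ratio `dGamma/(-df)` per overtone: the dissipative
#' relative to the inertial response. It is 0 for a Sauerbrey film in air, 1
#' for a semi-infinite Newtonian liquid (Kanazawa-Gordon symmetry), and equals
#' `omega * eta_bulk * J'` for a thin stiff film in a Newtonian liquid.
#' Overtones with `df = 0` yield `NA` (undefined ratio), not an error.
#'
#' @param shifts An [overtone_shifts()] object.
#' @return Named numeric vector of ratios, one per overtone.
#' @export
acoustic_ratio <- function(shifts) {
  stopifnot(inherits(shifts, "overtone_shifts"))
  r <- ifelse(shifts$df_over_n == 0, NA_real_,
              shifts$dG_over_n / (-shifts$df_over_n))
  names(r) <- paste0("n", shifts$n)
  r
}
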