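# CSV I/O for overtone time series.
#
# Dialect: wide UTF-8 CSV with `#`-prefixed metadata lines before the header.
# Frequency columns match `f<n>` and dissipation columns `gamma<n>` (Hz) or
# `D<n>` (dissipation factor). Mandatory metadata: f0, Zq, units_f, units_diss,
# normalized, reference. Example:
#
#   # qcmvisc overtone series
#   # f0 = 5e+06
#   # Zq = 8.8e+06
#   # units_f = Hz
#   # units_diss = Hz        (or: ppm)
#   # normalized = true      (columns already divided by n)
#   # reference = bulk
#   time,f3,f5,gamma3,gamma5
#   0,-1.23,-1.25,0.04,0.05

#' Write an overtone time series to CSV
#'
#' Writes the documented wide CSV dialect (per-n-normalized Hz for both
#' channels, metadata in `#` comment lines). The round trip through
#' [read_overtone_csv()] is lossless at the written precision.
#'
#' @param series A `qcm_series`.
#' @param path Output file path.
#' @param digits Significant digits (default 12).
#' @return `path`, invisibly.
#' @export
write_overtone_csv <- function(series, path, digits = 12) {
  stopifnot(inherits(series, "qcm_series"))
  ns <- sort(unique(series$n))
  tt <- unique(series$time)
  wide <- data.frame(time = tt)
  for (nn in ns) {
    sub <- series[series$n == nn, ]
    sub <- sub[match(tt, sub$time), ]
    wide[[paste0("f", nn)]] <- sub$df_over_n
  }
  for (nn in ns) {
    sub <- series[series$n == nn, ]
    sub <- sub[match(tt, sub$time), ]
    wide[[paste0("gamma", nn)]] <- sub$dG_over_n
  }
  f0 <- attr(series, "f0"); Zq <- attr(series, "Zq")
  ref <- attr(series, "reference")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# qcmvisc overtone series",
               sprintf("# f0 = %.10g", if (is.null(f0)) 5e6 else f0),
               sprintf("# Zq = %.10g", if (is.null(Zq)) 8.8e6 else Zq),
               "# units_f = Hz",
               "# units_diss = Hz",
               "# normalized = true",
               sprintf("# reference = %s", if (is.null(ref)) "bulk" else ref)),
             con)
  fmt <- paste0("%.", digits, "g")
  lines <- apply(wide, 1, function(r) paste(sprintf(fmt, r), collapse = ","))
  writeLines(c(paste(names(wide), collapse = ","), lines), con)
  invisible(path)
}

parse_metadata <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Read an overtone time series from CSV
#'
#' Parses the documented dialect: `f<n>` columns for the frequency channel and
#' `gamma<n>` (Hz) or `D<n>` (dissipation factor) columns for the dissipation
#' channel. Unit declarations are mandatory -- there is no silent default for
#' dissipation versus bandwidth. Dissipation columns are converted to
#' `dGamma/n` via `dGamma/n = dD f0/2`; raw (non-normalized) columns are
#' divided by the overtone order. The internal representation is always
#' per-n-normalized Hz.
#'
#' @param path CSV file path.
#' @return A `qcm_series` data.frame with attributes `f0`, `Zq`, `n_list`,
#'   `reference`.
#' @export
read_overtone_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  all_lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", all_lines)
  meta <- parse_metadata(all_lines[is_meta])
  for (req in c("f0", "units_f", "units_diss", "normalized"))
    if (is.null(meta[[req]]))
      stop("missing mandatory metadata key: ", req)
  f0 <- as.numeric(meta$f0)
  Zq <- if (is.null(meta$Zq)) 8.8e6 else as.numeric(meta$Zq)
  res <- resonator(f0, Zq)
  if (!meta$units_f %in% "Hz") stop("ambiguous frequency units: ", meta$units_f)
  if (!meta$units_diss %in% c("Hz", "ppm", "absolute"))
    stop("ambiguous dissipation units: ", meta$units_diss)
  normalized <- tolower(meta$normalized) %in% c("true", "yes", "1")
  reference <- if (is.null(meta$reference)) "bulk" else meta$reference

  tab <- utils::read.csv(text = paste(all_lines[!is_meta], collapse = "\n"),
                         check.names = FALSE)
  nm <- names(tab)
  tcol <- nm[tolower(nm) %in% c("t", "time", "time_s")]
  if (length(tcol) != 1) stop("no unambiguous time column")
  fcols <- grep("^f[0-9]+$", nm, value = TRUE)
  gcols <- grep("^(gamma|D)[0-9]+$", nm, value = TRUE)
  unknown <- setdiff(nm, c(tcol, fcols, gcols))
  if (length(unknown)) stop("unknown columns: ", paste(unknown, collapse = ", "))
  if (!length(fcols)) stop("no frequency columns (f<n>) found")
  n_f <- as.integer(sub("^f", "", fcols))
  n_g <- as.integer(sub("^(gamma|D)", "", gcols))
  if (!setequal(n_f, n_g))
    stop("frequency and dissipation columns cover different overtones")
  diss_is_D <- grepl("^D", gcols)
  if (any(diss_is_D) && meta$units_diss == "Hz")
    stop("D<n> columns require units_diss = ppm or absolute")
  if (!any(diss_is_D) && meta$units_diss != "Hz")
    stop("gamma<n> columns must be in Hz")

  tt <- tab[[tcol]]
  if (is.unsorted(tt, strictly = FALSE) || anyNA(tt)) stop("non-monotone time column")
  ord <- order(n_f)
  n_list <- n_f[ord]
  long <- do.call(rbind, lapply(seq_along(n_list), function(i) {
    nn <- n_list[i]
    fv <- tab[[paste0("f", nn)]]
    if (!normalized) fv <- fv / nn
    gcol <- gcols[match(nn, n_g)]
    gv <- tab[[gcol]]
    if (grepl("^D", gcol)) {
      gv <- dissipation_to_bandwidth(gv, res,
              unit = if (meta$units_diss == "ppm") "ppm" else "absolute")
    } else if (!normalized) gv <- gv / nn
    data.frame(time = tt, n = nn, df_over_n = fv, dG_over_n = gv)
  }))
  long <- long[order(long$time, long$n), ]
  rownames(long) <- NULL
  structure(long, n_list = n_list, f0 = f0, Zq = Zq, reference = reference,
            class = c("qcm_series", "data.frame"))
}
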