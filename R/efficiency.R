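#' Construct a dilution series for efficiency calibration
#'
#' @param gene Gene (primer pair) identifier.
#' @param dilution Relative input amount per measurement (dimensionless,
#'   e.g. 1, 1/2, 1/4, ...); at least 3 distinct values are required for a
#'   standard curve.
#' @param ct Ct values, in cycles.
#' @param replicate Optional technical replicate index.
#' @return An object of class `dilution_series` (a data frame).
#' @export
dilution_series <- function(gene, dilution, ct, replicate = NULL) {
  if (is.null(replicate)) replicate <- stats::ave(dilution, dilution,
                                                  FUN = seq_along)
  df <- data.frame(gene = as.character(gene), dilution = as.numeric(dilution),
                   replicate = as.integer(replicate), ct = as.numeric(ct),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$dilution) | df$dilution <= 0)) {
    stop("dilutions must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(df$ct) | df$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  class(df) <- c("dilution_series", "data.frame")
  df
}

#' Read dilution-series Ct data from CSV
#'
#' Expects columns `gene`, `dilution`, `replicate`, `ct`.
#'
#' @param path CSV path.
#' @return A `dilution_series`, possibly covering several genes (fit each
#'   with [fit_standard_curve()] after subsetting, or use
#'   [fit_standard_curves()]).
#' @export
read_dilution_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("gene", "dilution", "ct"), names(raw))
  if (length(need)) {
    stop("missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dilution_series(raw$gene, raw$dilution, raw$ct, raw$replicate)
}

#' Fit an amplification-efficiency standard curve
#'
#' Ordinary least squares of mean Ct on log10(relative input amount). The
#' amplification efficiency follows from the slope as
#' `E = (10^(-1/slope) - 1) * 100` (percent; 100 = perfect doubling per
#' cycle). A slope of -3.3219 corresponds to E = 100.
#'
#' @param series A [dilution_series] for a single primer pair.
#' @param collapse Average technical replicates within each dilution point
#'   before regression (default); set `FALSE` to fit on raw replicates.
#' @param window Efficiency acceptance window in percent, closed interval.
#' @return An `efficiency_fit`: list with `gene`, `slope` (cycles per
#'   log10 input), `intercept` (cycles), `efficiency` (percent), `r_squared`,
#'   `pass`, `reason`, `n_points`.
#' @export
fit_standard_curve <- function(series, collapse = TRUE, window = c(90, 110)) {
  stopifnot(inherits(series, "dilution_series") || is.data.frame(series))
  genes <- unique(series$gene)
  if (length(genes) > 1) {
    stop("series covers several genes (", paste(genes, collapse = ", "),
         "); fit one at a time or use fit_standard_curves()", call. = FALSE)
  }
  pts <- if (collapse) {
    stats::aggregate(ct ~ dilution, data = series, FUN = mean)
  } else {
    series[c("dilution", "ct")]
  }
  if (length(unique(pts$dilution)) < 3) {
    stop("at least 3 distinct dilution points are required", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10(dilution), data = pts)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid standard curve: Ct does not decrease with input amount ",
         "(slope = ", format(slope), ")", call. = FALSE)
  }
  efficiency <- (10^(-1 / slope) - 1) * 100
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((pts$ct - mean(pts$ct))^2)
  r_squared <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  out <- structure(list(gene = genes, slope = slope, intercept = intercept,
                        efficiency = efficiency, r_squared = r_squared,
                        n_points = length(unique(pts$dilution)),
                        window = window),
                   class = "efficiency_fit")
  cls <- classify_efficiency(out, window)
  out$pass <- cls$pass
  out$reason <- cls$reason
  out
}

#' Fit standard curves for every gene in a series
#' @param series A [dilution_series] covering one or more genes.
#' @inheritParams fit_standard_curve
#' @return A named list of `efficiency_fit` objects.
#' @export
fit_standard_curves <- function(series, collapse = TRUE, window = c(90, 110)) {
  fits <- lapply(split(series, series$gene), function(d) {
    d <- dilution_series(d$gene, d$dilution, d$ct, d$replicate)
    fit_standard_curve(d, collapse = collapse, window = window)
  })
  fits[order(names(fits))]
}

#' Classify an efficiency against the acceptance window
#'
#' The window is a closed interval: boundary values pass. The conventional
#' requirement for quantitative work is 90-110 percent.
#'
#' @param fit An `efficiency_fit`, or a bare efficiency in percent.
#' @param window `(low, high)` in percent.
#' @return A list with `pass` (logical) and `reason` (`"within window"`,
#'   `"below window"` or `"above window"`).
#' @export
classify_efficiency <- function(fit, window = c(90, 110)) {
  e <- if (inherits(fit, "efficiency_fit")) fit$efficiency else as.numeric(fit)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (e < window[1]) {
    list(pass = FALSE, reason = "below window")
  } else if (e > window[2]) {
    list(pass = FALSE, reason = "above window")
  } else {
    list(pass = TRUE, reason = "within window")
  }
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("Standard curve [%s]: slope %.4f, E = %.1f%%, R2 = %.4f (%s)\n",
              x$gene, x$slope, x$efficiency, x$r_squared,
              if (isTRUE(x$pass)) "pass" else paste0("fail: ", x$reason)))
  invisible(x)
}

#' Serialize efficiency fits
#' @param fits An `efficiency_fit` or list of them.
#' @param csv,json Optional output paths.
#' @return Invisibly, a data frame with one row per fit.
#' @export
write_efficiency_fits <- function(fits, csv = NULL, json = NULL) {
  if (inherits(fits, "efficiency_fit")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(gene = f$gene, slope = f$slope, intercept = f$intercept,
               efficiency = f$efficiency, r_squared = f$r_squared,
               pass = f$pass, reason = f$reason,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(df, json, auto_unbox = TRUE,
                                           digits = NA)
  invisible(df)
}
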