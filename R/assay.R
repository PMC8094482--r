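#' Enzyme assay and fermentation metric arithmetic
#'
#' Measurement calculations for engineered-strain characterization:
#' DTNB-based phosphotransacetylase specific activity (free CoA forms a
#' mercaptide ion read at 412 nm), ferric-hydroxamate phosphoketolase
#' readout at 540 nm normalized to extract protein, fold change over a
#' parent strain, Bodipy lipid stain fluorescence per OD600, and batch
#' fermentation metrics (whole-batch lipid yield, lipid content, lipid-free
#' dry cell weight, windowed cell-specific productivity).
#'
#' @name assay_metrics
NULL

#' Absorbance kinetics trace
#'
#' @param time_min reading times in minutes (>= 2, strictly increasing).
#' @param absorbance absorbance readings (AU).
#' @param wavelength_nm wavelength (412 for the DTNB assay).
#' @param path_length_cm cuvette/plate path length.
#' @param reaction_volume_ml assay reaction volume.
#' @param extract_volume_ul cell-free extract volume added.
#' @param protein_mg_per_ml protein concentration of the extract.
#' @return object of class `absorbance_kinetics`.
#' @export
absorbance_kinetics <- function(time_min, absorbance, wavelength_nm = 412,
                                path_length_cm = 1, reaction_volume_ml = 1,
                                extract_volume_ul = 10, protein_mg_per_ml = 1) {
  if (length(time_min) < 2L) stop("need at least two readings")
  if (length(time_min) != length(absorbance))
    stop("time and absorbance lengths differ")
  if (any(diff(time_min) <= 0)) stop("reading times must be strictly increasing")
  for (v in c(path_length_cm, reaction_volume_ml, extract_volume_ul,
              protein_mg_per_ml))
    if (!is.finite(v) || v <= 0) stop("volumes, path length and protein must be positive")
  structure(list(time_min = as.numeric(time_min),
                 absorbance = as.numeric(absorbance),
                 wavelength_nm = wavelength_nm,
                 path_length_cm = path_length_cm,
                 reaction_volume_ml = reaction_volume_ml,
                 extract_volume_ul = extract_volume_ul,
                 protein_mg_per_ml = protein_mg_per_ml),
            class = "absorbance_kinetics")
}

#' Phosphotransacetylase specific activity from a DTNB trace
#'
#' Least-squares slope of absorbance vs time, converted by Beer-Lambert:
#' slope / (epsilon x path) gives mM/min in the reaction; times reaction
#' volume gives umol/min; divided by mg extract protein gives specific
#' activity. Readings above `saturation_cutoff` AU are dropped before the
#' fit (detector saturation guard). A non-positive slope yields activity 0
#' with `flag = "nonpositive_slope"` rather than an error, since extracts
#' without the enzyme read at background.
#'
#' @param k an [absorbance_kinetics()].
#' @param epsilon extinction coefficient in mM^-1 cm^-1 (13.5 for the
#'   DTNB/CoA mercaptide ion).
#' @param saturation_cutoff drop readings above this absorbance.
#' @return object of class `specific_activity`: `value`
#'   (umol min^-1 mg^-1), `slope`, `r_squared`, `n_used`, `truncated`,
#'   `flag`.
#' @examples
#' k <- absorbance_kinetics(0:5, 0.135 * 0:5)
#' pta_specific_activity(k)$value # 1.0
#' @export
pta_specific_activity <- function(k, epsilon = 13.5, saturation_cutoff = 2.0) {
  stopifnot(inherits(k, "absorbance_kinetics"))
  use <- k$absorbance <= saturation_cutoff
  truncated <- !all(use)
  if (sum(use) < 2L) stop("fewer than two readings below the saturation cutoff")
  tt <- k$time_min[use]; aa <- k$absorbance[use]
  slope <- sum((tt - mean(tt)) * (aa - mean(aa))) / sum((tt - mean(tt))^2)
  sst <- sum((aa - mean(aa))^2)
  ssr <- sum((aa - (mean(aa) + slope * (tt - mean(tt))))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  flag <- NULL
  if (slope <= 0) {
    value <- 0
    flag <- "nonpositive_slope"
  } else {
    protein_mg <- k$extract_volume_ul * k$protein_mg_per_ml / 1000
    value <- slope / (epsilon * k$path_length_cm) * k$reaction_volume_ml /
      protein_mg
  }
  structure(list(value = value, slope = slope, r_squared = r2,
                 n_used = sum(use), truncated = truncated, flag = flag),
            class = "specific_activity")
}

#' @export
print.specific_activity <- function(x, ...) {
  cat("<specific activity> ", signif(x$value, 4), " umol/min/mg (slope ",
      signif(x$slope, 4), " A/min, R2 ", round(x$r_squared, 4), ")",
      if (!is.null(x$flag)) paste0(" [", x$flag, "]"), "\n", sep = "")
  invisible(x)
}

#' Phosphoketolase readout normalized to extract protein
#'
#' Endpoint ferric-hydroxamate absorbance at 540 nm divided by total
#' protein; when `reaction_time_min` is supplied, also per minute.
#'
#' @param a540 absorbance at 540 nm (AU).
#' @param total_protein_mg total protein in the extract aliquot (> 0).
#' @param reaction_time_min optional reaction time for the time-resolved
#'   rate.
#' @return AU per mg protein (with attribute `per_min` when time given).
#' @export
xpk_normalized_absorbance <- function(a540, total_protein_mg,
                                      reaction_time_min = NULL) {
  if (any(!is.finite(total_protein_mg)) || any(total_protein_mg <= 0))
    stop("total protein must be positive")
  out <- a540 / total_protein_mg
  if (!is.null(reaction_time_min)) {
    if (any(reaction_time_min <= 0)) stop("reaction time must be positive")
    attr(out, "per_min") <- out / reaction_time_min
  }
  out
}

#' Fold change over a parent strain
#'
#' Each sample divided by the mean of the parent values; no background
#' subtraction is performed.
#'
#' @param sample_values numeric sample measurements.
#' @param parent_values numeric parent-strain measurements (mean > 0).
#' @return per-sample fold change.
#' @export
fold_change <- function(sample_values, parent_values) {
  pm <- mean(parent_values)
  if (!is.finite(pm) || pm <= 0) stop("parent mean must be positive")
  sample_values / pm
}

#' Bodipy lipid fluorescence normalized to OD600
#'
#' @param fluorescence fluorescence units (AU).
#' @param od600 optical density at 600 nm (> 0).
#' @return Fl/OD ratio.
#' @export
bodipy_fl_od <- function(fluorescence, od600) {
  if (any(!is.finite(od600)) || any(od600 <= 0)) stop("od600 must be positive")
  fluorescence / od600
}

## ---- fermentation time courses -------------------------------------------

#' Batch fermentation time course
#'
#' @param time_d sampling times in days.
#' @param glucose_gL residual glucose (g/L), non-increasing within
#'   `glucose_tol` relative tolerance.
#' @param dcw_gL total dry cell weight (g/L), never below the lipid titer.
#' @param lipid_gL lipid titer (g/L).
#' @param extra optional data.frame of additional broth metabolite columns
#'   (e.g. `citrate_gL`).
#' @param glucose_tol allowed relative increase between consecutive glucose
#'   samples (measurement noise allowance).
#' @return object of class `fermentation_time_course` (a data.frame).
#' @export
fermentation_time_course <- function(time_d, glucose_gL, dcw_gL, lipid_gL,
                                     extra = NULL, glucose_tol = 0.02) {
  n <- length(time_d)
  if (!all(lengths(list(glucose_gL, dcw_gL, lipid_gL)) == n))
    stop("all series must have equal length")
  if (any(diff(time_d) <= 0)) stop("sampling times must be strictly increasing")
  if (any(glucose_gL < 0) || any(dcw_gL < 0) || any(lipid_gL < 0))
    stop("concentrations must be non-negative")
  rises <- diff(glucose_gL) > glucose_tol * pmax(glucose_gL[-n], 1)
  if (any(rises))
    stop("glucose must be non-increasing (within tolerance); rise after day ",
         paste(time_d[which(rises)], collapse = ", "))
  if (any(dcw_gL < lipid_gL))
    stop("dry cell weight below lipid titer at day ",
         paste(time_d[dcw_gL < lipid_gL], collapse = ", "))
  df <- data.frame(time_d = time_d, glucose_gL = glucose_gL, dcw_gL = dcw_gL,
                   lipid_gL = lipid_gL)
  if (!is.null(extra)) df <- cbind(df, extra)
  class(df) <- c("fermentation_time_course", "data.frame")
  df
}

#' Read / write the fermentation time-course TSV dialect
#'
#' Tab-separated with header columns `time_d`, `glucose_gL`, `dcw_gL`,
#' `lipid_gL` and optional extra metabolite columns.
#'
#' @param path file path.
#' @param glucose_tol passed to [fermentation_time_course()].
#' @return a [fermentation_time_course()].
#' @export
read_time_course <- function(path, glucose_tol = 0.02) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_d", "glucose_gL", "dcw_gL", "lipid_gL")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("time-course TSV missing column(s): ", paste(missing, collapse = ", "))
  extra <- df[setdiff(names(df), need)]
  fermentation_time_course(df$time_d, df$glucose_gL, df$dcw_gL, df$lipid_gL,
                           extra = if (ncol(extra)) extra else NULL,
                           glucose_tol = glucose_tol)
}

#' @rdname read_time_course
#' @param tc a [fermentation_time_course()].
#' @export
write_time_course <- function(tc, path) {
  utils::write.table(as.data.frame(tc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fermentation performance metrics
#'
#' Whole-batch metrics plus a windowed cell-specific productivity:
#' * lipid-free dry cell weight LFDCW(t) = DCW(t) - lipid(t);
#' * lipid yield = lipid formed / glucose consumed over the whole batch;
#' * lipid content = final lipid / final DCW;
#' * cell-specific productivity (CSP) over `csp_window` = lipid formed in
#'   the window / (mean LFDCW over the window x window length), with the
#'   mean taken trapezoidally over all samples in the window (default) or
#'   as the endpoint mean.
#'
#' The CSP window defaults to days 2-5, the phase after growth has slowed
#' and lipogenesis is underway.
#'
#' @param tc a [fermentation_time_course()].
#' @param csp_window two sampling days (must be present in `tc$time_d`).
#' @param csp_mean `"trapezoid"` or `"endpoint"` LFDCW averaging.
#' @return object of class `fermentation_metrics`: `lipid_yield_g_per_g`,
#'   `lipid_content`, `lfdcw_gL` (series), `csp_g_per_g_per_day`, window
#'   bookkeeping.
#' @examples
#' tc <- fermentation_time_course(c(0, 2, 5), c(150, 100, 10),
#'                                c(5, 20, 58), c(0, 10, 28))
#' fermentation_metrics(tc)$lipid_yield_g_per_g # 0.2
#' @export
fermentation_metrics <- function(tc, csp_window = c(2, 5),
                                 csp_mean = c("trapezoid", "endpoint")) {
  stopifnot(inherits(tc, "fermentation_time_course"))
  csp_mean <- match.arg(csp_mean)
  t <- tc$time_d
  n <- length(t)
  consumed <- tc$glucose_gL[1] - tc$glucose_gL[n]
  if (consumed <= 0) stop("no glucose consumed: lipid yield undefined")
  lfdcw <- tc$dcw_gL - tc$lipid_gL
  lipid_yield <- (tc$lipid_gL[n] - tc$lipid_gL[1]) / consumed
  lipid_content <- tc$lipid_gL[n] / tc$dcw_gL[n]
  i0 <- match(csp_window[1], t); i1 <- match(csp_window[2], t)
  if (is.na(i0) || is.na(i1) || i1 <= i0)
    stop("csp_window endpoints must be sampling days in increasing order")
  span <- t[i1] - t[i0]
  lf_mean <- if (csp_mean == "endpoint") {
    mean(lfdcw[c(i0, i1)])
  } else {
    idx <- i0:i1
    sum(diff(t[idx]) * (utils::head(lfdcw[idx], -1) + utils::tail(lfdcw[idx], -1)) / 2) / span
  }
  csp <- (tc$lipid_gL[i1] - tc$lipid_gL[i0]) / (lf_mean * span)
  structure(list(lipid_yield_g_per_g = lipid_yield,
                 lipid_content = lipid_content,
                 lfdcw_gL = lfdcw,
                 csp_g_per_g_per_day = csp,
                 csp_window = csp_window, csp_mean = csp_mean,
                 glucose_consumed_gL = consumed),
            class = "fermentation_metrics")
}

#' @export
print.fermentation_metrics <- function(x, ...) {
  cat("<fermentation metrics>\n")
  cat("  lipid yield:   ", round(x$lipid_yield_g_per_g, 4), " g/g glucose\n", sep = "")
  cat("  lipid content: ", round(100 * x$lipid_content, 2), " % of DCW\n", sep = "")
  cat("  CSP (day ", x$csp_window[1], "-", x$csp_window[2], ", ", x$csp_mean,
      "): ", round(x$csp_g_per_g_per_day, 4), " g/g LFDCW/day\n", sep = "")
  invisible(x)
}
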