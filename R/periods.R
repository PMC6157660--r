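#' Named climate periods
#'
#' `period()` builds one period; `default_periods()` returns the two
#' standard late-Holocene periods used for aggregation: the Medieval
#' Warm Period (850-1200 AD) and the Little Ice Age (1400-1850 AD).
#' Intervals are closed at both ends; periods in a set must not overlap.
#'
#' @param name Period name.
#' @param start_AD,end_AD Closed interval bounds in years AD.
#' @return Data frame with columns `name`, `start_AD`, `end_AD`.
#' @export
#' @examples
#' default_periods()
period <- function(name, start_AD, end_AD) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(start_AD), is.numeric(end_AD))
  if (start_AD > end_AD)
    stop("period '", name, "': start_AD must be <= end_AD", call. = FALSE)
  data.frame(name = name, start_AD = start_AD, end_AD = end_AD,
             stringsAsFactors = FALSE)
}

#' @rdname period
#' @export
default_periods <- function() {
  rbind(period("MWP", 850, 1200), period("LIA", 1400, 1850))
}

as_periods <- function(periods) {
  if (is.data.frame(periods)) p <- periods
  else p <- do.call(rbind, periods)
  stopifnot(all(c("name", "start_AD", "end_AD") %in% names(p)))
  if (any(p$start_AD > p$end_AD))
    stop("each period needs start_AD <= end_AD", call. = FALSE)
  n <- nrow(p)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (p$start_AD[i] <= p$end_AD[j] && p$start_AD[j] <= p$end_AD[i])
        stop("periods '", p$name[i], "' and '", p$name[j], "' overlap",
             call. = FALSE)
    }
  }
  p
}

#' Assign ages to climate periods
#'
#' Each age maps to the unique period whose closed interval contains it,
#' or to `"unassigned"`. Overlapping period sets are a configuration
#' error.
#'
#' @param age_AD Numeric vector of calendar ages (years AD).
#' @param periods Period set as returned by [default_periods()] (or a
#'   list of [period()] rows).
#' @return Character vector of period names / `"unassigned"` (`NA` ages
#'   give `NA`).
#' @export
#' @examples
#' assign_period(c(1082, 1680, 1341))
assign_period <- function(age_AD, periods = default_periods()) {
  p <- as_periods(periods)
  vapply(age_AD, function(a) {
    if (is.na(a)) return(NA_character_)
    hit <- which(p$start_AD <= a & a <= p$end_AD)
    if (length(hit)) p$name[hit] else "unassigned"
  }, character(1))
}

#' Per-period trophic-position summaries
#'
#' Estimates every specimen's TP with the chosen Glu/Phe model, assigns
#' dated specimens to periods, and summarises each occupied period plus
#' an `"all"` row spanning every dated specimen (the whole record,
#' which overlaps the named periods and is therefore reported
#' separately, not as a third period). Undated specimens are excluded
#' with a warning.
#'
#' @param specimens List of [specimen()] objects.
#' @param periods Period set (see [assign_period()]).
#' @param method `"single"` or `"multi"` Glu/Phe estimator.
#' @param model A [tdf_model()].
#' @param sd_convention `"sample"` or `"population"`.
#' @param include_all Add the `"all"` whole-record row?
#' @return Data frame with columns `period`, `n`, `mean_tp`, `sd_tp`
#'   (`NA` when `n = 1`), `method`.
#' @export
period_summary <- function(specimens, periods = default_periods(),
                           method = c("single", "multi"),
                           model = tdf_model(),
                           sd_convention = c("sample", "population"),
                           include_all = TRUE) {
  method <- match.arg(method)
  sd_convention <- match.arg(sd_convention)
  p <- as_periods(periods)
  est <- estimate_tp(specimens, method, model)
  undated <- is.na(est$age_AD)
  if (any(undated))
    warning(sum(undated), " undated specimen(s) excluded from period summary: ",
            paste(est$specimen_id[undated], collapse = ", "), call. = FALSE)
  est <- est[!undated, , drop = FALSE]
  if (nrow(est) == 0) {
    warning("no dated specimens fall in any period", call. = FALSE)
    return(data.frame(period = character(), n = integer(),
                      mean_tp = numeric(), sd_tp = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  }
  est$period <- assign_period(est$age_AD, p)
  summarise <- function(label, tps) {
    data.frame(period = label, n = length(tps), mean_tp = mean(tps),
               sd_tp = if (length(tps) >= 2) dispersion(tps, sd_convention)
                       else NA_real_,
               method = paste0(method, "_tdf"), stringsAsFactors = FALSE)
  }
  rows <- lapply(p$name, function(nm) {
    tps <- est$tp[est$period == nm]
    if (!length(tps)) NULL else summarise(nm, tps)
  })
  out <- do.call(rbind, rows)
  if (include_all) out <- rbind(out, summarise("all", est$tp))
  if (is.null(out) || nrow(out) == 0)
    warning("no dated specimens fall in any period", call. = FALSE)
  out
}

#' Trophic position time series
#'
#' Orders dated specimens by age and returns their TP (chosen
#' estimator) next to the bulk delta15N of their primary tissue, ready
#' for co-plotting the two trophic signals. Undated specimens are
#' excluded with a warning.
#'
#' @inheritParams period_summary
#' @return Data frame with columns `specimen_id`, `age_AD`, `tp`,
#'   `bulk_d15N`, sorted by ascending age.
#' @export
tp_timeseries <- function(specimens, method = c("multi", "single"),
                          model = tdf_model()) {
  method <- match.arg(method)
  if (!length(specimens))
    return(data.frame(specimen_id = character(), age_AD = numeric(),
                      tp = numeric(), bulk_d15N = numeric(),
                      stringsAsFactors = FALSE))
  est <- estimate_tp(specimens, method, model)
  est$bulk_d15N <- vapply(specimens, function(s) s$bulk_d15N, numeric(1))
  undated <- is.na(est$age_AD)
  if (any(undated))
    warning(sum(undated), " undated specimen(s) excluded from time series: ",
            paste(est$specimen_id[undated], collapse = ", "), call. = FALSE)
  est <- est[!undated, c("specimen_id", "age_AD", "tp", "bulk_d15N")]
  est[order(est$age_AD), , drop = FALSE]
}
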