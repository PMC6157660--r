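#' Trophic discrimination model
#'
#' Collects every isotope-propagation constant used by the estimators.
#' Defaults are the values established for marine food webs ending in a
#' bird: `beta` is the Glu-Phe delta15N spacing of aquatic primary
#' producers (3.4 per mil); `tdf_plankton` the per-step increase of that
#' spacing through plankton-type consumers (7.6 per mil); `tdf_bird` the
#' avian-specific per-step increase (3.5 per mil); `bulk_step` the
#' bulk-tissue delta15N enrichment per trophic level (3.4 per mil);
#' `suess_offset` the post-1850 decline in regional delta13C applied
#' when comparing pre-industrial consumers to modern diet (-1.8 per
#' mil). A beta for C3/C4 terrestrial webs may be supplied by the user;
#' no terrestrial default is provided.
#'
#' @param beta,tdf_plankton,tdf_bird,bulk_step,suess_offset Per-mil
#'   constants, see description.
#' @return Object of class `tdf_model`.
#' @export
#' @examples
#' tdf_model()                 # marine defaults
#' tdf_model(tdf_bird = 5.4)   # e.g. muscle-based avian TDF
tdf_model <- function(beta = 3.4, tdf_plankton = 7.6, tdf_bird = 3.5,
                      bulk_step = 3.4, suess_offset = -1.8) {
  stopifnot(is.numeric(beta), is.numeric(tdf_plankton), is.numeric(tdf_bird),
            is.numeric(bulk_step), is.numeric(suess_offset))
  if (tdf_plankton <= 0 || tdf_bird <= 0 || bulk_step <= 0)
    stop("tdf_plankton, tdf_bird and bulk_step must be positive", call. = FALSE)
  structure(list(beta = beta, tdf_plankton = tdf_plankton,
                 tdf_bird = tdf_bird, bulk_step = bulk_step,
                 suess_offset = suess_offset),
            class = "tdf_model")
}

#' @export
print.tdf_model <- function(x, ...) {
  cat("<tdf_model>  beta =", x$beta, " TDF(plankton) =", x$tdf_plankton,
      " TDF(bird) =", x$tdf_bird, "\n")
  cat("             bulk step =", x$bulk_step,
      " Suess offset =", x$suess_offset, "(per mil)\n")
  invisible(x)
}

#' A trophic-position estimate
#'
#' @param tp Numeric trophic position(s); producer = 1.
#' @param sd Optional standard deviation (same length or scalar).
#' @param method One of `"single_tdf"`, `"multi_tdf"`, `"diet"`,
#'   `"bulk_offset"`, `"size_corrected"`.
#' @param inputs List recording provenance (specimen ids, constants).
#' @return Object of class `tp_estimate`.
#' @export
tp_estimate <- function(tp, sd = NA_real_,
                        method = c("single_tdf", "multi_tdf", "diet",
                                   "bulk_offset", "size_corrected"),
                        inputs = list()) {
  method <- match.arg(method)
  if (any(!is.finite(tp))) stop("tp must be finite", call. = FALSE)
  if (any(!is.na(sd) & sd < 0)) stop("sd must be >= 0", call. = FALSE)
  structure(list(tp = tp, sd = sd, method = method, inputs = inputs),
            class = "tp_estimate")
}

#' @export
print.tp_estimate <- function(x, digits = 2, ...) {
  v <- round_half_up(x$tp, digits)
  s <- if (all(is.na(x$sd))) "" else
    paste0(" ± ", round_half_up(x$sd, digits))
  cat("<tp_estimate> TP =", paste(v, collapse = ", "), s,
      " [", x$method, "]\n")
  invisible(x)
}

#' @export
as.numeric.tp_estimate <- function(x, ...) x$tp

glu_phe_of <- function(s) {
  g <- aa_value(s$profile, "Glu", "d15N")
  p <- aa_value(s$profile, "Phe", "d15N")
  if (is.na(g) || is.na(p))
    stop("specimen '", s$id, "' is unusable for Glu/Phe TP estimation: ",
         paste(c(if (is.na(g)) "Glu", if (is.na(p)) "Phe"), collapse = " and "),
         " delta15N missing", call. = FALSE)
  c(glu = g, phe = p)
}

#' Trophic position by the single-TDF Glu/Phe model
#'
#' `TP = 1 + (d15N_Glu - d15N_Phe - beta) / TDF_plankton`. Appropriate
#' for aquatic consumers reached exclusively through plankton-type
#' trophic steps; applying it to birds underestimates their TP (see
#' [tp_multi_tdf()]).
#'
#' @param d15N_glu,d15N_phe Glu and Phe delta15N, per mil (vectorized).
#' @param model A [tdf_model()].
#' @return A [tp_estimate()] with method `"single_tdf"`.
#' @export
#' @examples
#' tp_single_tdf(18.0, 3.0) # flying fish, TP 2.53
tp_single_tdf <- function(d15N_glu, d15N_phe, model = tdf_model()) {
  stopifnot(inherits(model, "tdf_model"),
            all(is.finite(d15N_glu)), all(is.finite(d15N_phe)))
  tp <- 1 + (d15N_glu - d15N_phe - model$beta) / model$tdf_plankton
  tp_estimate(tp, method = "single_tdf",
              inputs = list(model = model, d15N_glu = d15N_glu,
                            d15N_phe = d15N_phe))
}

#' Trophic position by the multi-TDF Glu/Phe model
#'
#' `TP = 2 + (d15N_Glu - d15N_Phe - TDF_plankton - beta) / TDF_bird`.
#' The consumer is assumed to sit at least one plankton-type step above
#' the producer, with the remaining enrichment accumulated at the
#' avian-specific rate. Related to the single-TDF estimate by the exact
#' identity `TP_multi = 2 + (TDF_plankton/TDF_bird) * (TP_single - 2)`.
#'
#' @inheritParams tp_single_tdf
#' @return A [tp_estimate()] with method `"multi_tdf"`.
#' @export
#' @examples
#' tp_multi_tdf(19.2, 4.1) # seabird bone, TP 3.17
tp_multi_tdf <- function(d15N_glu, d15N_phe, model = tdf_model()) {
  stopifnot(inherits(model, "tdf_model"),
            all(is.finite(d15N_glu)), all(is.finite(d15N_phe)))
  tp <- 2 + (d15N_glu - d15N_phe - model$tdf_plankton - model$beta) /
    model$tdf_bird
  tp_estimate(tp, method = "multi_tdf",
              inputs = list(model = model, d15N_glu = d15N_glu,
                            d15N_phe = d15N_phe))
}

#' Correct a trophic position for body-size delta15N bias
#'
#' Shifts a TP estimate by the bulk-delta15N offset between a reference
#' population and the measured sample, at `bulk_step` per mil per
#' trophic level: `TP' = TP + (d15N_reference - d15N_sample) /
#' bulk_step`. Used when the analysed individuals differ in size (hence
#' bulk delta15N) from the population whose TP is wanted.
#'
#' @param tp_sample A [tp_estimate()] (or numeric TP) for the sample.
#' @param d15N_reference Bulk delta15N of the reference population.
#' @param d15N_sample Bulk delta15N of the measured sample.
#' @param model A [tdf_model()].
#' @return A [tp_estimate()] with method `"size_corrected"`; the sd of
#'   `tp_sample` is carried through unchanged (the offset is a constant).
#' @export
size_correct_tp <- function(tp_sample, d15N_reference, d15N_sample,
                            model = tdf_model()) {
  stopifnot(is.finite(d15N_reference), is.finite(d15N_sample))
  base <- if (inherits(tp_sample, "tp_estimate")) tp_sample else
    tp_estimate(tp_sample, method = "single_tdf")
  tp_estimate(base$tp + (d15N_reference - d15N_sample) / model$bulk_step,
              sd = base$sd, method = "size_corrected",
              inputs = list(model = model, base = base,
                            d15N_reference = d15N_reference,
                            d15N_sample = d15N_sample))
}

#' Infer a trophic position from a bulk delta15N offset
#'
#' `TP_target = TP_base + (d15N_target - d15N_base) / bulk_step`: the
#' target's TP is the base organism's TP displaced by their bulk
#' delta15N difference at the standard per-level enrichment. Used e.g.
#' to place squid relative to flying fish from muscle bulk values.
#'
#' @param tp_base A [tp_estimate()] (or numeric TP) of the base organism.
#' @param d15N_target,d15N_base Bulk delta15N values, per mil.
#' @param model A [tdf_model()].
#' @return A [tp_estimate()] with method `"bulk_offset"`.
#' @export
#' @examples
#' size_corrected_fish <- tp_estimate(2.38, method = "size_corrected")
#' tp_from_bulk_offset(size_corrected_fish, 10.2, 9.2) # squid, TP 2.67
tp_from_bulk_offset <- function(tp_base, d15N_target, d15N_base,
                                model = tdf_model()) {
  stopifnot(is.finite(d15N_target), is.finite(d15N_base))
  base <- if (inherits(tp_base, "tp_estimate")) tp_base else
    tp_estimate(tp_base, method = "single_tdf")
  tp_estimate(base$tp + (d15N_target - d15N_base) / model$bulk_step,
              sd = base$sd, method = "bulk_offset",
              inputs = list(model = model, base = base,
                            d15N_target = d15N_target,
                            d15N_base = d15N_base))
}

#' Two-prey diet mass balance
#'
#' Builds the mixing specification for a consumer eating two prey
#' species: `f` is the mass fraction of prey 1.
#'
#' @param f Mass fraction of prey 1 in `[0, 1]`.
#' @param tp_prey1,tp_prey2 Prey trophic positions ([tp_estimate()] or
#'   numeric).
#' @param f_sd Optional standard deviation of `f`.
#' @return Object of class `diet_model`.
#' @export
diet_model <- function(f, tp_prey1, tp_prey2, f_sd = NA_real_) {
  if (!is.finite(f) || f < 0 || f > 1)
    stop("f must lie in [0, 1]", call. = FALSE)
  as_tp <- function(x) if (inherits(x, "tp_estimate")) x else
    tp_estimate(x, method = "diet")
  structure(list(f = f, f_sd = f_sd, tp_prey1 = as_tp(tp_prey1),
                 tp_prey2 = as_tp(tp_prey2)),
            class = "diet_model")
}

#' Consumer trophic position from diet composition
#'
#' `TP = f * TP_prey1 + (1 - f) * TP_prey2 + 1`: the consumer sits one
#' level above the mass-weighted mean of its prey. Affine in `f` with
#' slope `TP_prey1 - TP_prey2`; when `f_sd` is given, the sd is the
#' exact affine propagation `|slope| * f_sd` (prey TPs held fixed).
#'
#' @param diet A [diet_model()].
#' @return A [tp_estimate()] with method `"diet"`.
#' @export
#' @examples
#' tp_diet(diet_model(0.88, 2.38, 2.67)) # 3.41
tp_diet <- function(diet) {
  stopifnot(inherits(diet, "diet_model"))
  t1 <- diet$tp_prey1$tp
  t2 <- diet$tp_prey2$tp
  tp <- diet$f * t1 + (1 - diet$f) * t2 + 1
  sd <- if (is.na(diet$f_sd)) NA_real_ else abs(t1 - t2) * diet$f_sd
  tp_estimate(tp, sd = sd, method = "diet", inputs = list(diet = diet))
}

#' Glu-Phe delta15N spacing across specimens
#'
#' The spacing `d15N_Glu - d15N_Phe` grows along a food chain and is the
#' raw signal behind every Glu/Phe TP estimator; comparing its mean
#' across conspecifics with literature values is a basic plausibility
#' check.
#'
#' @param specimens List of [specimen()] objects (or [aa_profile()]s).
#' @param sd_convention `"sample"` (n-1 divisor, default) or
#'   `"population"`.
#' @return List with `mean`, `sd` (`NA` for a single profile), `n` and
#'   the per-specimen `spacings`.
#' @export
glu_phe_spacing <- function(specimens, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (inherits(specimens, "csia_specimen")) specimens <- list(specimens)
  spac <- vapply(specimens, function(s) {
    if (inherits(s, "aa_profile")) {
      g <- aa_value(s, "Glu"); p <- aa_value(s, "Phe")
      if (is.na(g) || is.na(p))
        stop("a profile lacks Glu or Phe delta15N", call. = FALSE)
      g - p
    } else {
      gp <- glu_phe_of(s)
      gp[["glu"]] - gp[["phe"]]
    }
  }, numeric(1))
  list(mean = mean(spac),
       sd = if (length(spac) >= 2) dispersion(spac, sd_convention) else NA_real_,
       n = length(spac), spacings = spac)
}

#' Per-specimen trophic positions for a set of specimens
#'
#' Applies [tp_single_tdf()] or [tp_multi_tdf()] to every specimen's
#' Glu/Phe pair. Specimens missing either amino acid raise an error
#' naming them (use [qc_specimen()] to screen first).
#'
#' @param specimens List of [specimen()] objects.
#' @param method `"single"` or `"multi"`.
#' @param model A [tdf_model()].
#' @return Data frame with columns `specimen_id`, `age_AD`, `tp`,
#'   `method`.
#' @export
estimate_tp <- function(specimens, method = c("single", "multi"),
                        model = tdf_model()) {
  method <- match.arg(method)
  fn <- if (method == "single") tp_single_tdf else tp_multi_tdf
  rows <- lapply(specimens, function(s) {
    gp <- glu_phe_of(s)
    data.frame(specimen_id = s$id, age_AD = s$age_AD,
               tp = fn(gp[["glu"]], gp[["phe"]], model)$tp,
               method = paste0(method, "_tdf"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Round half away from zero
#'
#' Presentation-level rounding matching how isotope tables are printed
#' (2.625 prints as 2.63). Internal arithmetic is never rounded; use
#' this only when reporting. A small guard absorbs binary floating-point
#' representation error before the tie is broken.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Dispersion under an explicit convention
#'
#' @param x Numeric vector.
#' @param convention `"sample"` (n-1 divisor) or `"population"` (n).
#' @return Standard deviation of `x`.
#' @export
dispersion <- function(x, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (convention == "population") s * sqrt((n - 1) / n) else s
}
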