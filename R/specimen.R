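#' A measured specimen
#'
#' Bundles specimen metadata, bulk-tissue isotope values and the
#' per-amino-acid profile of its primary tissue. A specimen may
#' additionally carry bulk values measured on a secondary tissue
#' (`aux_bulk`), e.g. fish whose amino acids were measured in bone
#' collagen but whose muscle bulk delta15N is also reported.
#'
#' @param id Specimen identifier, unique within a dataset.
#' @param taxon Taxon name (optional).
#' @param tissue Primary tissue, `"bone_collagen"` or `"muscle"`.
#' @param age_AD Calendar age of the specimen in years AD (optional).
#' @param profile_origin Sampling profile / site label (optional).
#' @param bulk_d15N,bulk_d13C Bulk isotope values of the primary tissue,
#'   per mil (optional).
#' @param cn_ratio Atomic C/N ratio of the collagen extract (optional).
#' @param mass_g Body mass in grams (optional).
#' @param standard_length_cm Standard length in cm (optional).
#' @param collection_year Year the sample was collected (optional;
#'   relevant for Suess-effect handling of delta13C).
#' @param profile An [aa_profile()].
#' @param aux_bulk Optional data frame of bulk values on other tissues,
#'   with columns `tissue`, `element` (`"15N"`/`"13C"`), `value_permil`.
#' @return An object of class `csia_specimen`.
#' @export
specimen <- function(id, taxon = NA_character_,
                     tissue = c("bone_collagen", "muscle"),
                     age_AD = NA_real_, profile_origin = NA_character_,
                     bulk_d15N = NA_real_, bulk_d13C = NA_real_,
                     cn_ratio = NA_real_, mass_g = NA_real_,
                     standard_length_cm = NA_real_,
                     collection_year = NA_real_,
                     profile = aa_profile(), aux_bulk = NULL) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("specimen id must be a non-empty string", call. = FALSE)
  tissue <- match.arg(tissue)
  if (!inherits(profile, "aa_profile"))
    stop("profile must be an aa_profile", call. = FALSE)
  if (!is.null(aux_bulk)) {
    stopifnot(is.data.frame(aux_bulk),
              all(c("tissue", "element", "value_permil") %in% names(aux_bulk)))
    if (!all(aux_bulk$element %in% c("15N", "13C")))
      stop("aux_bulk element must be 15N or 13C", call. = FALSE)
  }
  structure(list(
    id = id, taxon = taxon, tissue = tissue, age_AD = age_AD,
    profile_origin = profile_origin, bulk_d15N = bulk_d15N,
    bulk_d13C = bulk_d13C, cn_ratio = cn_ratio, mass_g = mass_g,
    standard_length_cm = standard_length_cm,
    collection_year = collection_year,
    profile = profile, aux_bulk = aux_bulk
  ), class = "csia_specimen")
}

#' @export
print.csia_specimen <- function(x, ...) {
  cat("<csia_specimen>", x$id,
      if (!is.na(x$taxon)) paste0("(", x$taxon, ")"), "\n")
  cat("  tissue:", x$tissue,
      if (!is.na(x$age_AD)) paste0(" age: ", x$age_AD, " AD"), "\n")
  cat("  amino acids measured:", nrow(x$profile), "\n")
  invisible(x)
}

#' Retrieve a bulk isotope value from a specimen
#'
#' @param s A [specimen()].
#' @param element `"15N"` or `"13C"`.
#' @param tissue Tissue to look up; defaults to the specimen's primary
#'   tissue. Secondary tissues are served from `aux_bulk`.
#' @return Per-mil value or `NA`.
#' @export
bulk_value <- function(s, element = c("15N", "13C"), tissue = NULL) {
  element <- match.arg(element)
  if (is.null(tissue) || identical(tissue, s$tissue))
    return(if (element == "15N") s$bulk_d15N else s$bulk_d13C)
  if (is.null(s$aux_bulk)) return(NA_real_)
  hit <- s$aux_bulk$tissue == tissue & s$aux_bulk$element == element
  if (!any(hit)) return(NA_real_)
  s$aux_bulk$value_permil[which(hit)[1]]
}

#' Quality-control report for one specimen
#'
#' Applies the collagen preservation criterion (atomic C/N within a
#' closed interval, by default 2.9-3.6) and records which amino acids
#' are missing and whether the specimen can enter Glu/Phe trophic
#' position estimation (both Glu and Phe delta15N present). Missing
#' fields yield absent flags, never errors: failing specimens are
#' flagged, not dropped.
#'
#' @param s A [specimen()].
#' @param cn_range Closed interval of acceptable C/N ratios.
#' @return An object of class `qc_report`: list with `specimen_id`,
#'   `cn_pass` (logical; `NA` when `cn_ratio` is missing),
#'   `missing_aas`, `usable_for_tp`.
#' @export
#' @examples
#' s <- specimen("f1", profile = aa_profile(d15N = c(Glu = 18, Phe = 3)),
#'               cn_ratio = 3.2)
#' qc_specimen(s)
qc_specimen <- function(s, cn_range = c(2.9, 3.6)) {
  stopifnot(inherits(s, "csia_specimen"), length(cn_range) == 2,
            cn_range[1] <= cn_range[2])
  cn_pass <- if (is.na(s$cn_ratio)) NA else
    s$cn_ratio >= cn_range[1] && s$cn_ratio <= cn_range[2]
  measured <- s$profile$aa[!is.na(s$profile$d15N)]
  usable <- all(c("Glu", "Phe") %in% measured)
  structure(list(
    specimen_id = s$id,
    cn_pass = cn_pass,
    missing_aas = setdiff(aa_codes(), measured),
    usable_for_tp = usable
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$specimen_id, "\n")
  cat("  C/N pass:", if (is.na(x$cn_pass)) "(no C/N ratio)" else x$cn_pass, "\n")
  cat("  usable for Glu/Phe TP:", x$usable_for_tp, "\n")
  if (length(x$missing_aas))
    cat("  missing amino acids:", paste(x$missing_aas, collapse = ", "), "\n")
  invisible(x)
}

#' Delta notation from isotope ratios
#'
#' `delta = (R_sample / R_standard - 1) * 1000`, in per mil. For
#' delta15N the standard ratio is atmospheric N2; for delta13C it is
#' V-PDB. `ratio_from_delta()` is the exact inverse.
#'
#' @param r_sample,r_standard Isotope ratios; `r_standard` must be > 0.
#' @return Per-mil delta value(s).
#' @export
#' @examples
#' delta_from_ratio(1.01, 1) # 10 per mil
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0))
    stop("r_standard must be positive", call. = FALSE)
  (r_sample / r_standard - 1) * 1000
}

#' @rdname delta_from_ratio
#' @param delta Per-mil delta value(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0))
    stop("r_standard must be positive", call. = FALSE)
  (delta / 1000 + 1) * r_standard
}
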