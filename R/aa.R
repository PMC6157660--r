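#' Amino acids measured by the collagen CSIA protocol
#'
#' The eleven amino acids quantified by the methyl-chloroformate
#' GC-IRMS protocol used for bone collagen: alanine, aspartic acid,
#' glutamic acid, glycine, isoleucine, leucine, lysine, methionine,
#' phenylalanine, proline and valine. All profile data are restricted
#' to this vocabulary.
#'
#' @return Character vector of three-letter amino-acid codes.
#' @export
#' @examples
#' aa_codes()
aa_codes <- function() {
  c("Ala", "Asp", "Glu", "Gly", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Val")
}

#' Per-amino-acid isotope profile of one specimen
#'
#' Holds the delta15N (vs atmospheric N2) and optionally delta13C
#' (vs V-PDB) values, in per mil, of individual amino acids from a single
#' specimen and tissue. Any amino acid may be missing (ancient samples
#' often lack methionine); unknown codes and non-finite values are
#' rejected.
#'
#' @param d15N Named numeric vector of delta15N values (names are
#'   three-letter amino-acid codes from [aa_codes()]).
#' @param d13C Named numeric vector of delta13C values, same naming rule.
#' @return An object of class `aa_profile`: a data frame with columns
#'   `aa`, `d15N`, `d13C`.
#' @export
#' @examples
#' aa_profile(d15N = c(Glu = 18.0, Phe = 3.0))
aa_profile <- function(d15N = numeric(), d13C = numeric()) {
  check_named <- function(x, what) {
    if (length(x) == 0) return(invisible(NULL))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("all ", what, " values must be named by amino-acid code", call. = FALSE)
    bad <- setdiff(names(x), aa_codes())
    if (length(bad))
      stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(x)))
      stop("duplicated amino-acid code in ", what, call. = FALSE)
    if (any(!is.finite(x)))
      stop("non-finite ", what, " value for: ",
           paste(names(x)[!is.finite(x)], collapse = ", "), call. = FALSE)
  }
  check_named(d15N, "d15N")
  check_named(d13C, "d13C")
  aas <- intersect(aa_codes(), union(names(d15N), names(d13C)))
  out <- data.frame(
    aa = aas,
    d15N = unname(d15N[match(aas, names(d15N))]),
    d13C = unname(d13C[match(aas, names(d13C))]),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0)
    out <- data.frame(aa = character(), d15N = numeric(), d13C = numeric(),
                      stringsAsFactors = FALSE)
  class(out) <- c("aa_profile", "data.frame")
  out
}

#' Look up one isotope value in a profile
#'
#' @param profile An [aa_profile()].
#' @param aa Three-letter amino-acid code.
#' @param element `"d15N"` or `"d13C"`.
#' @return The value in per mil, or `NA` if not measured.
#' @export
aa_value <- function(profile, aa, element = c("d15N", "d13C")) {
  element <- match.arg(element)
  i <- match(aa, profile$aa)
  if (is.na(i)) return(NA_real_)
  profile[[element]][i]
}

#' Classify amino acids as trophic/source and essential/nonessential
#'
#' Two independent partitions used when interpreting per-amino-acid
#' enrichment: the nitrogen-side split into "trophic" amino acids (whose
#' C-N bond cleaves during transamination, enriching delta15N at each
#' trophic transfer) versus "source" amino acids (which retain the
#' baseline delta15N), and the carbon-side split into essential versus
#' nonessential amino acids. Codes named by neither list of a partition
#' are classified `"other"`.
#'
#' @param codes Character vector of codes from [aa_codes()].
#' @return Data frame with columns `aa`, `trophic_source`
#'   (`"trophic"`, `"source"`, `"other"`) and `essentiality`
#'   (`"essential"`, `"nonessential"`, `"other"`).
#' @export
#' @examples
#' classify_aas(c("Glu", "Phe", "Lys"))
classify_aas <- function(codes) {
  bad <- setdiff(codes, aa_codes())
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  trophic <- c("Ala", "Asp", "Glu", "Leu", "Pro")
  source_ <- c("Gly", "Phe")
  essential <- c("Ile", "Leu", "Phe", "Val")
  nonessential <- c("Ala", "Asp", "Glu", "Gly", "Pro")
  data.frame(
    aa = codes,
    trophic_source = ifelse(codes %in% trophic, "trophic",
                            ifelse(codes %in% source_, "source", "other")),
    essentiality = ifelse(codes %in% essential, "essential",
                          ifelse(codes %in% nonessential, "nonessential", "other")),
    stringsAsFactors = FALSE
  )
}
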