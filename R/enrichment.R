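#' Per-amino-acid trophic enrichment factors between two groups
#'
#' For each amino acid measured in both groups, computes the consumer
#' minus diet offset of group means (unpaired groups; the dispersion of
#' the offset combines the two group dispersions in quadrature). When
#' both groups carry bulk values of the element on their primary tissue,
#' a bulk offset is computed the same way. These are enrichment factors
#' (TEFs) between whatever tissues were measured, not controlled-feeding
#' discrimination factors.
#'
#' @param consumers,diets Lists of [specimen()] objects.
#' @param element `"15N"` or `"13C"`.
#' @param sd_convention `"sample"` or `"population"` group dispersion.
#' @return A `tef_table`: data frame with columns `aa`, `element`,
#'   `mean_offset`, `sd`, `n_consumer`, `n_diet`, `n_pairs`
#'   (`min(n_consumer, n_diet)`), `suess_applied`, and attributes
#'   `bulk_offset`, `bulk_sd` (both `NA` if either group lacks bulk
#'   values) and `element`.
#' @export
tef_per_aa <- function(consumers, diets, element = c("15N", "13C"),
                       sd_convention = c("sample", "population")) {
  element <- match.arg(element)
  sd_convention <- match.arg(sd_convention)
  if (!length(consumers) || !length(diets))
    stop("need at least one specimen per group", call. = FALSE)
  field <- if (element == "15N") "d15N" else "d13C"

  group_values <- function(group, aa)
    Filter(is.finite, vapply(group, function(s) {
      v <- aa_value(s$profile, aa, field)
      if (is.na(v)) NA_real_ else v
    }, numeric(1)))

  rows <- lapply(aa_codes(), function(aa) {
    cv <- group_values(consumers, aa)
    dv <- group_values(diets, aa)
    if (!length(cv) || !length(dv)) return(NULL)
    sdc <- dispersion(cv, sd_convention)
    sdd <- dispersion(dv, sd_convention)
    data.frame(aa = aa, element = element,
               mean_offset = mean(cv) - mean(dv),
               sd = if (is.na(sdc) || is.na(sdd)) NA_real_ else
                 sqrt(sdc^2 + sdd^2),
               n_consumer = length(cv), n_diet = length(dv),
               n_pairs = min(length(cv), length(dv)),
               suess_applied = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  bulk_group <- function(group)
    Filter(is.finite, vapply(group, function(s)
      bulk_value(s, element), numeric(1)))
  bc <- bulk_group(consumers)
  bd <- bulk_group(diets)
  bulk_offset <- if (length(bc) && length(bd)) mean(bc) - mean(bd) else NA_real_
  bulk_sd <- if (length(bc) >= 2 && length(bd) >= 2)
    sqrt(dispersion(bc, sd_convention)^2 + dispersion(bd, sd_convention)^2)
  else NA_real_

  if (is.null(tab) && is.na(bulk_offset))
    stop("element ", element,
         " is absent from both groups for every amino acid", call. = FALSE)
  if (is.null(tab))
    tab <- data.frame(aa = character(), element = character(),
                      mean_offset = numeric(), sd = numeric(),
                      n_consumer = integer(), n_diet = integer(),
                      n_pairs = integer(), suess_applied = logical(),
                      stringsAsFactors = FALSE)
  structure(tab, element = element, bulk_offset = bulk_offset,
            bulk_sd = bulk_sd, suess_applied = FALSE,
            class = c("tef_table", "data.frame"))
}

#' Remove the Suess effect from a delta13C enrichment table
#'
#' Industrial-era fossil-fuel emissions have depleted environmental
#' delta13C since 1850; comparing a pre-industrial consumer with a
#' modern diet therefore inflates every consumer-minus-diet delta13C
#' offset. This adds the (negative) `suess_offset` of the model to every
#' per-amino-acid and bulk offset, once. Only delta13C tables may be
#' adjusted, and only once.
#'
#' @param table A `tef_table` from [tef_per_aa()] with element `"13C"`.
#' @param model A [tdf_model()] supplying `suess_offset`.
#' @return The adjusted `tef_table` with `suess_applied = TRUE`.
#' @export
suess_adjust <- function(table, model = tdf_model()) {
  stopifnot(inherits(table, "tef_table"))
  if (!identical(attr(table, "element"), "13C"))
    stop("Suess adjustment applies to delta13C tables only", call. = FALSE)
  if (isTRUE(attr(table, "suess_applied")))
    stop("Suess adjustment already applied", call. = FALSE)
  table$mean_offset <- table$mean_offset + model$suess_offset
  table$suess_applied <- TRUE
  attr(table, "bulk_offset") <- attr(table, "bulk_offset") + model$suess_offset
  attr(table, "suess_applied") <- TRUE
  table
}

#' @export
print.tef_table <- function(x, ...) {
  cat("<tef_table> element", attr(x, "element"),
      if (isTRUE(attr(x, "suess_applied"))) "(Suess-adjusted)", "\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  bo <- attr(x, "bulk_offset")
  if (!is.na(bo)) cat("bulk offset:", format(bo, digits = 3), "per mil\n")
  invisible(x)
}

#' Student's t comparison of two groups of per-mil values
#'
#' Two-sided Student's t test, paired or two-sample; equal variances are
#' assumed by default (classic Student's test), with Welch's correction
#' available. Degenerate inputs (zero variance) are handled by
#' convention: identical means give `t = 0, p = 1`; different means with
#' zero variance give `|t| = Inf, p = 0`.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @param welch Use Welch's unequal-variance correction (two-sample
#'   only)?
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
compare_groups <- function(a, b, paired = FALSE, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length groups", call. = FALSE)
  tol <- sqrt(.Machine$double.eps) * max(1, abs(mean(a)), abs(mean(b)))
  degenerate <- if (paired) stats::sd(a - b) < tol else
    stats::sd(a) < tol && stats::sd(b) < tol
  if (degenerate) {
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t_statistic = 0, p_value = 1, df = df))
    return(list(t_statistic = sign(mean(a) - mean(b)) * Inf,
                p_value = 0, df = df))
  }
  ht <- stats::t.test(a, b, paired = paired,
                      var.equal = !welch || paired)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
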