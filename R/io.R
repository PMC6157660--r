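#' Read specimens from a long-format isotope CSV
#'
#' The package's CSV dialect is UTF-8, comma-separated, one measurement
#' per row, with a mandatory header. Required columns: `specimen_id`,
#' `tissue`, `aa` (empty for bulk-tissue rows), `element` (`15N` or
#' `13C`) and `value_permil`. Optional metadata columns (`taxon`,
#' `age_AD`, `profile_origin`, `mass_g`, `standard_length_cm`,
#' `cn_ratio`, `collection_year`) are repeated per row; the first
#' non-empty value per specimen wins. Empty cells mean "not measured"
#' and are never coerced to zero. Lines starting with `#` are ignored.
#'
#' Rows of one specimen sharing the primary tissue are folded into its
#' amino-acid profile and primary bulk fields; bulk rows on a different
#' tissue (e.g. muscle bulk values for a collagen-profiled fish) are kept
#' in `aux_bulk`. The primary tissue is the tissue of the amino-acid
#' rows, or of the first bulk row for profile-less specimens.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping the dialect's
#'   column names to the names used in the file, e.g.
#'   `c(specimen_id = "sample")`.
#' @return List of [specimen()] objects, in order of first appearance.
#' @seealso [write_specimens()] for the exact inverse.
#' @export
load_specimens <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", comment.char = "#",
                  check.names = FALSE, na.strings = character())
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      i <- match(col_map[[std]], names(raw))
      if (!is.na(i)) names(raw)[i] <- std
    }
  }
  required <- c("specimen_id", "tissue", "aa", "element", "value_permil")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0) return(list())

  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA, trimws(x))
  for (nm in names(raw)) raw[[nm]] <- blank_to_na(raw[[nm]])

  num_field <- function(x, what, row) {
    if (is.na(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop("non-numeric ", what, " '", x, "' in row ", row, call. = FALSE)
    v
  }

  rows <- seq_len(nrow(raw))
  bad_aa <- which(!is.na(raw$aa) & !(raw$aa %in% aa_codes()))
  if (length(bad_aa))
    stop("unknown amino-acid code '", raw$aa[bad_aa[1]], "' in row ",
         bad_aa[1], call. = FALSE)
  bad_el <- which(is.na(raw$element) | !(raw$element %in% c("15N", "13C")))
  if (length(bad_el))
    stop("element must be 15N or 13C in row ", bad_el[1], call. = FALSE)
  if (any(is.na(raw$specimen_id)))
    stop("empty specimen_id in row ", which(is.na(raw$specimen_id))[1],
         call. = FALSE)
  raw$value_num <- vapply(rows, function(i)
    num_field(raw$value_permil[i], "value_permil", i), numeric(1))
  if (any(is.na(raw$value_num)))
    stop("empty value_permil in row ", which(is.na(raw$value_num))[1],
         call. = FALSE)

  key <- paste(raw$specimen_id, raw$tissue, ifelse(is.na(raw$aa), "", raw$aa),
               raw$element, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate measurement (specimen '", raw$specimen_id[dup[1]],
         "', aa '", ifelse(is.na(raw$aa[dup[1]]), "bulk", raw$aa[dup[1]]),
         "', element ", raw$element[dup[1]], ") in row ", dup[1], call. = FALSE)

  meta_num <- c("age_AD", "mass_g", "standard_length_cm", "cn_ratio",
                "collection_year")
  meta_chr <- c("taxon", "profile_origin")

  ids <- unique(raw$specimen_id)
  lapply(ids, function(id) {
    sub <- raw[raw$specimen_id == id, , drop = FALSE]
    first_meta <- function(col, numeric) {
      if (!col %in% names(sub)) return(if (numeric) NA_real_ else NA_character_)
      v <- sub[[col]][!is.na(sub[[col]])]
      if (!length(v)) return(if (numeric) NA_real_ else NA_character_)
      if (numeric) num_field(v[1], col, which(raw$specimen_id == id)[1]) else v[1]
    }
    aa_rows <- sub[!is.na(sub$aa), , drop = FALSE]
    primary_tissue <- if (nrow(aa_rows)) {
      tis <- unique(aa_rows$tissue)
      if (length(tis) > 1)
        stop("specimen '", id, "' has amino-acid rows on multiple tissues",
             call. = FALSE)
      tis
    } else sub$tissue[1]
    if (!primary_tissue %in% c("bone_collagen", "muscle"))
      stop("specimen '", id, "': tissue must be bone_collagen or muscle",
           call. = FALSE)

    d15N <- with(aa_rows[aa_rows$element == "15N", , drop = FALSE],
                 setNames(value_num, aa))
    d13C <- with(aa_rows[aa_rows$element == "13C", , drop = FALSE],
                 setNames(value_num, aa))
    bulk_rows <- sub[is.na(sub$aa), , drop = FALSE]
    primary_bulk <- bulk_rows[bulk_rows$tissue == primary_tissue, , drop = FALSE]
    aux_rows <- bulk_rows[bulk_rows$tissue != primary_tissue, , drop = FALSE]
    pick_bulk <- function(el) {
      v <- primary_bulk$value_num[primary_bulk$element == el]
      if (length(v)) v[1] else NA_real_
    }
    aux_bulk <- if (nrow(aux_rows)) data.frame(
      tissue = aux_rows$tissue, element = aux_rows$element,
      value_permil = aux_rows$value_num, stringsAsFactors = FALSE
    ) else NULL

    specimen(
      id = id,
      taxon = first_meta("taxon", FALSE),
      tissue = primary_tissue,
      age_AD = first_meta("age_AD", TRUE),
      profile_origin = first_meta("profile_origin", FALSE),
      bulk_d15N = pick_bulk("15N"),
      bulk_d13C = pick_bulk("13C"),
      cn_ratio = first_meta("cn_ratio", TRUE),
      mass_g = first_meta("mass_g", TRUE),
      standard_length_cm = first_meta("standard_length_cm", TRUE),
      collection_year = first_meta("collection_year", TRUE),
      profile = aa_profile(d15N = d15N, d13C = d13C),
      aux_bulk = aux_bulk
    )
  })
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) as.character(v), character(1)))
}

specimens_to_table <- function(specimens) {
  one <- function(s) {
    meta <- data.frame(
      specimen_id = s$id, taxon = ifelse(is.na(s$taxon), "", s$taxon),
      age_AD = fmt_num(s$age_AD),
      profile_origin = ifelse(is.na(s$profile_origin), "", s$profile_origin),
      mass_g = fmt_num(s$mass_g),
      standard_length_cm = fmt_num(s$standard_length_cm),
      cn_ratio = fmt_num(s$cn_ratio),
      collection_year = fmt_num(s$collection_year),
      stringsAsFactors = FALSE
    )
    rows <- list()
    add <- function(tissue, aa, element, value) {
      if (is.na(value)) return()
      rows[[length(rows) + 1]] <<- cbind(
        meta,
        data.frame(tissue = tissue, aa = aa, element = element,
                   value_permil = fmt_num(value), stringsAsFactors = FALSE)
      )
    }
    add(s$tissue, "", "15N", s$bulk_d15N)
    add(s$tissue, "", "13C", s$bulk_d13C)
    if (!is.null(s$aux_bulk))
      for (i in seq_len(nrow(s$aux_bulk)))
        add(s$aux_bulk$tissue[i], "", s$aux_bulk$element[i],
            s$aux_bulk$value_permil[i])
    for (i in seq_len(nrow(s$profile))) {
      add(s$tissue, s$profile$aa[i], "15N", s$profile$d15N[i])
      add(s$tissue, s$profile$aa[i], "13C", s$profile$d13C[i])
    }
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(specimens, one))
  cols <- c("specimen_id", "taxon", "tissue", "age_AD", "profile_origin",
            "mass_g", "standard_length_cm", "cn_ratio", "collection_year",
            "aa", "element", "value_permil")
  out[, cols]
}

#' Write specimens to the long-format isotope CSV
#'
#' Exact inverse of [load_specimens()]: loading the written file
#' reproduces every field. Numeric values are written as their shortest
#' round-tripping decimal text; missing values as empty cells.
#'
#' @param specimens List of [specimen()] objects.
#' @param path Output file path.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written before the header (e.g. provenance / config hash).
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path, header_lines = NULL) {
  tab <- specimens_to_table(specimens)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a packaged example dataset
#'
#' `"table1_fish"`: bone-collagen amino-acid delta15N, bulk collagen and
#' muscle delta15N, mass and standard length of three modern flying fish.
#' `"table2_birds"`: bone-collagen amino-acid and bulk delta15N of seven
#' ancient tropical seabird bones dated 1020-1913 AD.
#' `"table3_diet_fractions"`: published flying-fish mass fractions of the
#' seabird diet per climate period. `"reported_tp_reference"`: the
#' published per-specimen and summary trophic positions used by
#' [reproduce_paper()]'s discrepancy report.
#'
#' @param name Dataset name (see above), without extension.
#' @return Absolute file path.
#' @export
csia_fixture <- function(name = c("table1_fish", "table2_birds",
                                  "table3_diet_fractions",
                                  "reported_tp_reference")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "csiaTP")
  if (!nzchar(path)) stop("packaged dataset not found: ", name, call. = FALSE)
  path
}
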