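#' Default endpoint-to-assay mapping for the cardiotoxicity AOP
#'
#' Three endpoints along the linear adverse outcome pathway: inhibition of
#' mitochondrial complexes (MIE1, 6 assays), increased oxidative stress
#' (KE1, 7 assays), and mitochondrial dysfunction (KE2, 12 assays), using the
#' ICE "Cardiomyocyte/Myocardial Injury" assay names.
#'
#' @return Named list of character vectors (endpoint -> assay names).
#' @export
default_endpoint_map <- function() {
  list(
    MIE1 = c(
      "CCTE Simmons MITO basal resp rate OCR dn",
      "CCTE Simmons MITO basal resp rate OCR up",
      "CCTE Simmons MITO inhib resp rate OCR dn",
      "CCTE Simmons MITO inhib resp rate OCR up",
      "CCTE Simmons MITO max resp rate OCR dn",
      "CCTE Simmons MITO max resp rate OCR up"
    ),
    KE1 = c(
      "APR HepG2 P-H2AX 24 h dn", "APR HepG2 P-H2AX 24 h up",
      "APR HepG2 P-H2AX 72 h dn", "APR HepG2 P-H2AX 72 h up",
      "APR HepG2 StressKinase 24 h dn", "APR HepG2 StressKinase 24 h up",
      "APR HepG2 StressKinase 72 h dn"
    ),
    KE2 = c(
      "APR HepG2 MitoMass 24 h dn", "APR HepG2 MitoMass 24 h up",
      "APR HepG2 MitoMass 72 h dn", "APR HepG2 MitoMass 72 h up",
      "APR HepG2 MitoMembPot 24 h dn", "APR HepG2 MitoMembPot 24 h up",
      "APR HepG2 MitoMembPot 72 h dn", "APR HepG2 MitoMembPot 72 h up",
      "ATG XTT Cytotoxicity up",
      "TOX21 MMP ratio down", "TOX21 MMP ratio up", "TOX21 MMP rhodamine"
    )
  )
}

#' Aggregate assay hit calls into one endpoint label per compound
#'
#' A compound is labelled active for an endpoint when at least one of the
#' endpoint's assays reports an active hit call; it is inactive when every
#' observed call is inactive. Compounds with no observed call among the
#' selected assays are excluded (logged in attribute `"excluded"`).
#'
#' @param calls Wide data frame: one compound column plus one column per
#'   assay with values in `active_values` / `inactive_values`; anything else
#'   (including `NA` and `""`) counts as missing.
#' @param assay_subset Character vector of assay column names defining the
#'   endpoint; must all be present in `calls`.
#' @param endpoint Endpoint name stored on the result.
#' @param compound_col Name of the compound identifier column.
#' @param active_values,inactive_values Accepted call aliases.
#' @return Tibble (`compound`, `active`) with attributes `endpoint`,
#'   `n_assays_used`, and `excluded` (tibble of all-missing compounds).
#' @export
aggregate_hitcalls <- function(calls, assay_subset,
                               endpoint = "endpoint",
                               compound_col = "compound",
                               active_values = c("active", "1", "TRUE"),
                               inactive_values = c("inactive", "0", "FALSE")) {
  stopifnot(is.data.frame(calls))
  if (length(assay_subset) == 0L) {
    stop("aggregate_hitcalls: empty assay subset")
  }
  missing_assays <- setdiff(assay_subset, names(calls))
  if (length(missing_assays)) {
    stop("aggregate_hitcalls: unknown assay(s): ",
         paste(missing_assays, collapse = ", "))
  }
  if (anyDuplicated(assay_subset)) {
    stop("aggregate_hitcalls: duplicated assay names in subset")
  }
  grid <- as.matrix(dplyr::select(calls, dplyr::all_of(assay_subset)))
  grid <- matrix(trimws(tolower(as.character(grid))), nrow = nrow(grid))
  is_active <- matrix(grid %in% tolower(active_values), nrow = nrow(grid))
  is_inactive <- matrix(grid %in% tolower(inactive_values), nrow = nrow(grid))
  observed <- is_active | is_inactive

  any_active <- rowSums(is_active) > 0L
  any_observed <- rowSums(observed) > 0L

  compounds <- as.character(calls[[compound_col]])
  out <- tibble::tibble(
    compound = compounds[any_observed],
    active = any_active[any_observed]
  )
  attr(out, "endpoint") <- endpoint
  attr(out, "n_assays_used") <- length(assay_subset)
  attr(out, "excluded") <- tibble::tibble(
    compound = compounds[!any_observed],
    reason = "all_calls_missing"
  )
  class(out) <- c("endpoint_dataset", class(out))
  out
}

# round half away from zero (matches the integer percentages printed in the
# endpoint summary tables)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise an endpoint dataset
#'
#' Counts and integer percentages of active/inactive compounds (percentages
#' rounded half away from zero, as printed in dataset summary tables).
#'
#' @param ds Tibble with a logical `active` column (see [aggregate_hitcalls()]).
#' @return One-row tibble: `endpoint`, `n`, `n_active`, `n_inactive`,
#'   `pct_active`, `pct_inactive`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(is.data.frame(ds), "active" %in% names(ds), nrow(ds) > 0)
  n <- nrow(ds)
  n_active <- sum(ds$active)
  tibble::tibble(
    endpoint = attr(ds, "endpoint") %||% NA_character_,
    n = n,
    n_active = n_active,
    n_inactive = n - n_active,
    pct_active = round_half_away(100 * n_active / n),
    pct_inactive = round_half_away(100 * (n - n_active) / n)
  )
}

#' Read a wide hit-call matrix from CSV
#'
#' @param path CSV path: one compound column, one column per assay.
#' @param compound_col Compound identifier column name.
#' @return Tibble.
#' @export
read_hitcalls <- function(path, compound_col = "compound") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(compound_col %in% names(df))
  tibble::as_tibble(df)
}

#' Read an endpoint configuration (YAML)
#'
#' Expects `endpoints: {NAME: [assay, ...], ...}`; falls back to
#' [default_endpoint_map()] when the file has no `endpoints` key.
#'
#' @param path YAML file path.
#' @return Named list endpoint -> assay names.
#' @export
read_endpoint_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  eps <- cfg$endpoints %||% cfg
  if (is.null(eps) || !length(eps)) return(default_endpoint_map())
  lapply(eps, as.character)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
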