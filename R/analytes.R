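#' Define an analyte
#'
#' An analyte specification carries the physical constants needed to move
#' between mass and molar concentration scales, the assay's lower limit of
#' quantification (LLOQ), and a potency weight used when summing molar
#' exposures into a total HMG-CoA reductase inhibitory activity.
#'
#' @param name Analyte name (string), e.g. `"atorvastatin"`.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param lloq Assay lower limit of quantification in ng/mL; must be positive.
#' @param potency_weight Non-negative weight applied in activity sums.
#'   Atorvastatin and its metabolites are equipotent (weight 1);
#'   N-desmethyl rosuvastatin is about half as active as its parent (0.5).
#'
#' @return An object of class `analyte_spec`.
#' @examples
#' analyte_spec("atorvastatin", molar_mass = 558.64, lloq = 0.1)
#' @export
analyte_spec <- function(name, molar_mass, lloq, potency_weight = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0) {
    stop("molar_mass must be a positive finite number (g/mol)", call. = FALSE)
  }
  if (!is.numeric(lloq) || length(lloq) != 1L || !is.finite(lloq) || lloq <= 0) {
    stop("lloq must be a positive finite number (ng/mL)", call. = FALSE)
  }
  if (!is.numeric(potency_weight) || length(potency_weight) != 1L ||
      !is.finite(potency_weight) || potency_weight < 0) {
    stop("potency_weight must be a non-negative finite number", call. = FALSE)
  }
  structure(
    list(name = name, molar_mass = molar_mass, lloq = lloq,
         potency_weight = potency_weight),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s: M %.2f g/mol, LLOQ %g ng/mL, weight %g\n",
              x$name, x$molar_mass, x$lloq, x$potency_weight))
  invisible(x)
}

#' Default analyte table
#'
#' Molar masses are standard reference values (average atomic weights);
#' LLOQs are 0.1 ng/mL for the atorvastatin family, 0.05 ng/mL for the
#' rosuvastatin family and 0.001 ng/mL (1 pg/mL) for midazolam.
#' Potency weights: the atorvastatin family is equipotent (1);
#' N-desmethyl rosuvastatin carries weight 0.5.
#'
#' @return Named list of [analyte_spec()] objects.
#' @export
default_analyte_table <- function() {
  specs <- list(
    analyte_spec("atorvastatin",                   558.64, 0.1),
    analyte_spec("atorvastatin_lactone",           540.62, 0.1),
    analyte_spec("2oh_atorvastatin",               574.64, 0.1),
    analyte_spec("2oh_atorvastatin_lactone",       556.62, 0.1),
    analyte_spec("4oh_atorvastatin",               574.64, 0.1),
    analyte_spec("4oh_atorvastatin_lactone",       556.62, 0.1),
    analyte_spec("rosuvastatin",                   481.54, 0.05),
    analyte_spec("n_desmethyl_rosuvastatin",       467.52, 0.05, potency_weight = 0.5),
    analyte_spec("rosuvastatin_lactone",           463.53, 0.05),
    analyte_spec("midazolam",                      325.77, 0.001)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Read an analyte table from a YAML or JSON config file
#'
#' The file holds a list of records with fields `name`, `molar_mass`,
#' `lloq` and optionally `potency_weight`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [analyte_spec()] objects.
#' @export
read_analyte_table <- function(path) {
  if (!file.exists(path)) stop("analyte table not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  specs <- lapply(raw, function(r) {
    analyte_spec(r$name, r$molar_mass, r$lloq,
                 if (is.null(r$potency_weight)) 1 else r$potency_weight)
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
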