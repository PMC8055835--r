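#' Economic inputs for the partitioned survival model
#'
#' \code{default_econ_inputs()} builds the model's full economic ledger:
#' a \emph{parameter table} of every input varied in sensitivity analysis
#' (health-state utilities, unit drug costs, administration, supportive
#' and terminal care costs, adverse-event management costs, risks,
#' disutilities and durations, and the discount rate -- each with its
#' deterministic value, sampling distribution and low/high bounds) plus
#' fixed \emph{constants}: patient characteristics (weight 70 kg, body
#' surface area 1.86 m2, creatinine clearance 70 mL/min), second-line
#' uptake proportions, and regimen definitions. Unit costs are 2019 US$
#' average sale prices per the stated unit size (e.g. atezolizumab per
#' 10 mg); pricing is linear in dose with no vial wastage.
#'
#' @return an object of class \code{"econ_inputs"}: list with
#'   \code{params} (data frame \code{name, group, value, dist, low,
#'   high}) and \code{constants}.
#' @examples
#' inp <- default_econ_inputs()
#' subset(inp$params, group == "utility")
#' @export
default_econ_inputs <- function() {
  p <- function(name, group, value, dist, low, high)
    data.frame(name = name, group = group, value = value, dist = dist,
               low = low, high = high, stringsAsFactors = FALSE)
  ae <- c("neutropenia", "anemia", "neutrophil_count_decreased",
          "thrombocytopenia", "leukopenia")
  params <- rbind(
    p("utility_pf", "utility", 0.840, "beta", 0.672, 0.883),
    p("utility_pp", "utility", 0.473, "beta", 0.166, 0.568),
    p("cost_atezolizumab_per10mg", "unit_cost", 77.46, "gamma", 77.01, 77.76),
    p("cost_etoposide_per10mg", "unit_cost", 0.66, "gamma", 0.56, 0.74),
    p("cost_carboplatin_per50mg", "unit_cost", 3.09, "gamma", 2.89, 3.25),
    p("cost_topotecan_per0.1mg", "unit_cost", 0.94, "gamma", 0.87, 1.01),
    p("cost_cyclophosphamide_per100mg", "unit_cost", 3.91, "gamma", 3.31, 4.54),
    p("cost_doxorubicin_per10mg", "unit_cost", 3.08, "gamma", 2.89, 3.73),
    p("cost_vincristine_per1mg", "unit_cost", 4.88, "gamma", 4.79, 5.00),
    p("cost_supportive_care", "cost", 478, "gamma", 359, 597),
    p("cost_death", "cost", 9433, "gamma", 7075, 11791),
    p("cost_admin_first", "cost", 144.72, "gamma", 115.78, 173.66),
    p("cost_admin_additional", "cost", 31.68, "gamma", 25.34, 38.02),
    p(paste0("cost_ae_", ae), "ae_cost",
      c(17181, 20260, 17181, 22698, 17181), "gamma",
      c(13745, 16208, 13745, 20289, 13745),
      c(20617, 24312, 20617, 25377, 20617)),
    p(paste0("risk_ac_", ae), "ae_risk",
      c(0.23, 0.14, 0.14, 0.10, 0.05), "beta",
      c(0.19, 0.11, 0.11, 0.08, 0.04), c(0.28, 0.17, 0.17, 0.12, 0.06)),
    p(paste0("risk_c_", ae), "ae_risk",
      c(0.25, 0.12, 0.17, 0.08, 0.04), "beta",
      c(0.20, 0.10, 0.13, 0.06, 0.03), c(0.29, 0.15, 0.20, 0.09, 0.05)),
    p("discount_rate", "rate", 0.03, "fixed", 0, 0.05),
    p(paste0("disutility_", ae), "ae_disutility",
      c(-0.09, -0.09, -0.09, -0.108, -0.09), "beta",
      c(-0.122, -0.133, -0.122, -0.128, -0.122),
      c(-0.062, -0.055, -0.062, -0.089, -0.062)),
    p(paste0("duration_", ae), "ae_duration",
      c(2, 21, 4, 24, 2), "normal",
      c(2, 17, 3, 19, 2), c(2, 25, 5, 28, 2))
  )
  constants <- list(
    patient = list(weight_kg = 70, bsa_m2 = 1.86, crcl_ml_min = 70),
    second_line = list(
      uptake = list(
        intervention = c(topotecan = 0.403, cav = 0.154),
        control = c(topotecan = 0.436, cav = 0.228)
      ),
      n_cycles = 4
    ),
    regimens = list(
      chemo_cycles = 4,          # induction carboplatin + etoposide cycles
      etoposide_days = 3,        # dosing days per 21-day cycle
      topotecan_days = 5,
      atezolizumab_mg = 1200,
      carboplatin_auc = 5,
      etoposide_mg_m2 = 100,
      topotecan_mg_m2 = 1.5,
      cyclophosphamide_mg_m2 = 1000,
      doxorubicin_mg_m2 = 45,
      vincristine_mg = 2
    ),
    ae_events = ae
  )
  structure(list(params = params, constants = constants),
            class = "econ_inputs")
}

#' @export
print.econ_inputs <- function(x, ...) {
  cat("Economic inputs:", nrow(x$params), "sensitivity parameters in",
      length(unique(x$params$group)), "groups\n")
  print(utils::head(x$params, 4))
  cat("  ... plus fixed constants (patient, second-line uptake, regimens)\n")
  invisible(x)
}

validate_econ_inputs <- function(inputs) {
  pr <- inputs$params
  stopifnot(all(c("name", "value", "dist", "low", "high") %in% names(pr)))
  if (anyDuplicated(pr$name)) stop("duplicated input names")
  if (any(pr$low > pr$value + 1e-12 | pr$value > pr$high + 1e-12))
    stop("need low <= deterministic <= high for every input")
  ut <- pr[pr$group == "utility", ]
  if (any(ut$value < 0 | ut$value > 1)) stop("utilities must lie in [0,1]")
  if (any(pr$value[grepl("^cost", pr$name)] < 0)) stop("costs must be >= 0")
  invisible(inputs)
}

#' Look up a named input value
#'
#' @param inputs an \code{econ_inputs} object.
#' @param name parameter name.
#' @return the deterministic value.
#' @export
econ_value <- function(inputs, name) {
  i <- match(name, inputs$params$name)
  if (is.na(i)) stop("unknown input '", name, "'")
  inputs$params$value[i]
}

#' Override input values
#'
#' Returns a copy of the inputs with the named deterministic values
#' replaced (used for scenario analysis and the DSA).
#'
#' @param inputs an \code{econ_inputs} object.
#' @param overrides named numeric vector or list of replacements.
#' @export
econ_override <- function(inputs, overrides) {
  if (!length(overrides)) return(inputs)
  nm <- names(overrides)
  idx <- match(nm, inputs$params$name)
  if (anyNA(idx)) stop("unknown override key(s): ",
                       paste(nm[is.na(idx)], collapse = ", "))
  inputs$params$value[idx] <- unlist(overrides)
  inputs
}

#' Read / write the economic-inputs YAML config
#'
#' The YAML mirrors the inputs object: a \code{params} list of
#' \code{name/group/value/dist/low/high} records and a \code{constants}
#' block.
#'
#' @param inputs an \code{econ_inputs} object.
#' @param path file path.
#' @return \code{read_econ_inputs} returns a validated \code{econ_inputs}.
#' @export
write_econ_inputs <- function(inputs, path) {
  validate_econ_inputs(inputs)
  cons <- inputs$constants
  # named vectors must be written as YAML maps, not sequences
  cons$second_line$uptake <- lapply(cons$second_line$uptake, as.list)
  yaml::write_yaml(list(
    params = lapply(seq_len(nrow(inputs$params)), function(i)
      as.list(inputs$params[i, ])),
    constants = cons
  ), path)
  invisible(path)
}

#' @rdname write_econ_inputs
#' @export
read_econ_inputs <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- do.call(rbind, lapply(raw$params, function(r)
    data.frame(name = r$name, group = r$group, value = as.numeric(r$value),
               dist = r$dist, low = as.numeric(r$low),
               high = as.numeric(r$high), stringsAsFactors = FALSE)))
  cons <- raw$constants
  for (arm in names(cons$second_line$uptake))
    cons$second_line$uptake[[arm]] <- unlist(cons$second_line$uptake[[arm]])
  out <- structure(list(params = params, constants = cons),
                   class = "econ_inputs")
  validate_econ_inputs(out)
  out
}
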