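#' Model configuration
#'
#' The whole analysis is driven by a flat parameter list (drug prices,
#' adverse-event incidences, utilities, survival-curve parameters,
#' treatment-cycle caps, ...) plus a handful of structural settings. The
#' default configuration, shipped as a YAML file under
#' `inst/extdata/escc_first_line.yaml`, encodes the base case of the
#' first-line pembrolizumab + cisplatin/5-FU vs chemotherapy comparison in
#' advanced oesophageal squamous cell carcinoma, together with each
#' parameter's sensitivity range and probabilistic-sampling family.
#'
#' @param path Path to a YAML configuration; defaults to the shipped file.
#' @return A `cea_config` object: list with `model` (structural settings)
#'   and `parameters` (named list of
#'   `list(value, low, high, psa, integer)` entries).
#' @examples
#' cfg <- default_config()
#' cfg$parameters$cost_pembrolizumab_mg$value
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model) || is.null(raw$parameters))
    stop("config needs `model` and `parameters` blocks", call. = FALSE)
  validate_config(structure(raw, class = "cea_config"), check_ranges = TRUE)
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "escc_first_line.yaml",
                          package = "pembropsm", mustWork = TRUE))
}

# Range consistency (low <= value <= high) is asserted only on freshly
# loaded configurations; programmatic updates (threshold searches, OWSA)
# may legitimately push a value outside its stored sensitivity range.
validate_config <- function(config, check_ranges = FALSE) {
  stopifnot(inherits(config, "cea_config"))
  for (nm in names(config$parameters)) {
    p <- config$parameters[[nm]]
    if (is.null(p$value) || !is.numeric(p$value))
      stop("parameter `", nm, "` has no numeric value", call. = FALSE)
    if (check_ranges && !is.null(p$low) && !is.null(p$high)) {
      if (!(p$low <= p$value && p$value <= p$high))
        stop("parameter `", nm, "`: need low <= value <= high", call. = FALSE)
    }
  }
  needed <- c("os_shape_pembro", "os_scale_pembro", "os_shape_chemo",
              "os_scale_chemo", "pfs_shape_pembro", "pfs_scale_pembro",
              "pfs_shape_chemo", "pfs_scale_chemo",
              "cost_pembrolizumab_mg", "cost_fluorouracil_mg",
              "cost_cisplatin_mg", "cost_docetaxel_mg", "cost_irinotecan_mg",
              "cost_ae_anemia", "cost_ae_neutropenia",
              "inc_anemia_pembro", "inc_neutropenia_pembro",
              "inc_anemia_chemo", "inc_neutropenia_chemo",
              "utility_pfd", "utility_pd",
              "disutility_anemia", "disutility_neutropenia",
              "followup_cost_per_cycle", "bsa_m2", "annual_discount",
              "wtp_per_qaly", "max_cycles_pembrolizumab",
              "max_cycles_first_line", "max_cycles_cisplatin",
              "second_line_docetaxel_weight")
  missing <- setdiff(needed, names(config$parameters))
  if (length(missing))
    stop("config is missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  config
}

#' Read or replace configuration parameter values
#'
#' @param config A `cea_config`.
#' @param key Parameter name (one entry of `config$parameters`).
#' @param ... For `config_update()`: `name = value` pairs of parameter
#'   values to replace.
#' @return `config_value()` returns the scalar base-case value;
#'   `config_update()` the modified configuration.
#' @export
config_value <- function(config, key) {
  stopifnot(inherits(config, "cea_config"))
  if (!key %in% names(config$parameters))
    stop("unknown configuration parameter: `", key, "`", call. = FALSE)
  config$parameters[[key]]$value
}

#' @rdname config_value
#' @export
config_update <- function(config, ...) {
  stopifnot(inherits(config, "cea_config"))
  upd <- list(...)
  if (length(upd) == 1L && is.list(upd[[1]]) && is.null(names(upd)))
    upd <- upd[[1]]
  for (key in names(upd)) {
    if (!key %in% names(config$parameters))
      stop("unknown configuration parameter: `", key, "`", call. = FALSE)
    v <- upd[[key]]
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
    if (isTRUE(config$parameters[[key]]$integer)) v <- round(v)
    config$parameters[[key]]$value <- v
  }
  config
}

#' Assemble model objects from a configuration
#'
#' Expands the flat parameter list into the structured objects the engine
#' consumes: a [cycle_spec()], an [econ_params()], per-arm
#' [strategy_config()]s and per-arm OS/PFS [surv_model()]s.
#'
#' @param config A `cea_config` (see [default_config()]).
#' @return List with elements `cycle`, `econ`, `strategies`, `curves`,
#'   `intervention`, `comparator`, `wtp`.
#' @export
build_model <- function(config) {
  config <- validate_config(config)
  v <- function(key) config_value(config, key)
  cycle <- cycle_spec(cycle_days = config$model$cycle_days %||% 21,
                      horizon_years = config$model$horizon_years %||% 10)
  econ <- econ_params(
    annual_discount = v("annual_discount"),
    wtp_per_qaly = v("wtp_per_qaly"),
    utility_pfd = v("utility_pfd"),
    utility_pd = v("utility_pd"),
    ae = list(
      anemia = list(cost = v("cost_ae_anemia"),
                    disutility = -abs(v("disutility_anemia"))),
      neutropenia = list(cost = v("cost_ae_neutropenia"),
                         disutility = -abs(v("disutility_neutropenia")))
    ),
    followup_cost_per_cycle = v("followup_cost_per_cycle"),
    bsa_m2 = v("bsa_m2"),
    half_cycle = isTRUE(config$model$half_cycle %||% TRUE),
    disutility_duration_years = (config$model$cycle_days %||% 21) / 365.25
  )
  backbone <- list(
    drug_regimen("fluorouracil", 800, "per_m2_mg", admins_per_cycle = 5,
                 unit_cost = v("cost_fluorouracil_mg"),
                 max_cycles = v("max_cycles_first_line")),
    drug_regimen("cisplatin", 80, "per_m2_mg", admins_per_cycle = 1,
                 unit_cost = v("cost_cisplatin_mg"),
                 max_cycles = v("max_cycles_cisplatin"))
  )
  pembro <- drug_regimen("pembrolizumab", 200, "flat_mg",
                         admins_per_cycle = 1,
                         unit_cost = v("cost_pembrolizumab_mg"),
                         max_cycles = v("max_cycles_pembrolizumab"))
  w_doc <- v("second_line_docetaxel_weight")
  second_line <- list(
    drug_regimen("docetaxel", 75, "per_m2_mg", admins_per_cycle = 1,
                 unit_cost = v("cost_docetaxel_mg"), state = "pd"),
    # q2w drug inside a 21-day cycle: 1.5 administrations per cycle
    drug_regimen("irinotecan", 180, "per_m2_mg", admins_per_cycle = 1.5,
                 unit_cost = v("cost_irinotecan_mg"), state = "pd")
  )
  strategies <- list(
    pembro_chemo = strategy_config(
      "pembro_chemo",
      first_line = c(list(pembro), backbone),
      ae_incidence = c(anemia = v("inc_anemia_pembro"),
                       neutropenia = v("inc_neutropenia_pembro")),
      second_line = second_line,
      second_line_weights = c(w_doc, 1 - w_doc)
    ),
    chemo = strategy_config(
      "chemo",
      first_line = backbone,
      ae_incidence = c(anemia = v("inc_anemia_chemo"),
                       neutropenia = v("inc_neutropenia_chemo")),
      second_line = second_line,
      second_line_weights = c(w_doc, 1 - w_doc)
    )
  )
  curves <- list(
    pembro_chemo = list(
      os = surv_model("loglogistic", v("os_shape_pembro"), v("os_scale_pembro")),
      pfs = surv_model("loglogistic", v("pfs_shape_pembro"), v("pfs_scale_pembro"))
    ),
    chemo = list(
      os = surv_model("loglogistic", v("os_shape_chemo"), v("os_scale_chemo")),
      pfs = surv_model("loglogistic", v("pfs_shape_chemo"), v("pfs_scale_chemo"))
    )
  )
  list(cycle = cycle, econ = econ, strategies = strategies, curves = curves,
       intervention = config$model$intervention %||% "pembro_chemo",
       comparator = config$model$comparator %||% "chemo",
       wtp = v("wtp_per_qaly"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
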