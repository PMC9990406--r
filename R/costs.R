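#' Cost description of one biosecurity intervention
#'
#' One-off implementation costs (equipment purchase and installation) are
#' spread over the item's lifetime as straight-line depreciation; recurring
#' operational costs (maintenance, consumables such as disinfectant refills
#' or hygienogram plates) are charged per year. Costs that depend on
#' production characteristics scale with the farm: `per_animal` items are
#' charged per broiler place and round (e.g. vaccination), `per_round`
#' items once per production round, `per_stable` items per animal house.
#' Negative operational costs can encode foregone revenue (e.g. fewer
#' broilers when depopulating in one step) as a positive yearly expense is
#' what the planner reports.
#'
#' @param feature measure name the item applies to.
#' @param implementation_cost one-off cost in euro (>= 0).
#' @param lifetime_years depreciation horizon in years (>= 1).
#' @param operational_cost recurring cost in euro per year.
#' @param scaling one of `"fixed"`, `"per_animal"`, `"per_round"`,
#'   `"per_stable"`.
#' @param scale_rate euro per scaling unit (ignored for `"fixed"`).
#' @return An object of class `cost_item`.
#' @export
cost_item <- function(feature, implementation_cost = 0, lifetime_years = 1,
                      operational_cost = 0, scaling = "fixed",
                      scale_rate = 0) {
  scaling <- match.arg(scaling,
                       c("fixed", "per_animal", "per_round", "per_stable"))
  stopifnot(implementation_cost >= 0, lifetime_years >= 1)
  structure(list(feature = feature,
                 implementation_cost = as.numeric(implementation_cost),
                 lifetime_years = as.numeric(lifetime_years),
                 operational_cost = as.numeric(operational_cost),
                 scaling = scaling,
                 scale_rate = as.numeric(scale_rate)),
            class = "cost_item")
}

#' Read a cost table from YAML
#'
#' One block per measure with the [cost_item()] fields; omitted fields take
#' the item defaults. An example cost book ships in
#' `inst/extdata/costs_example.yaml`; prices are indicative and meant to be
#' redefined by the user.
#'
#' @param path YAML file path.
#' @return Named list of `cost_item` objects.
#' @export
read_cost_table <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- lapply(names(raw), function(f) {
    do.call(cost_item, c(list(feature = f), raw[[f]]))
  })
  stats::setNames(items, names(raw))
}

#' Yearly cost of one intervention on one farm
#'
#' Depreciation (implementation cost / lifetime) plus operational cost plus
#' the scaling term: `per_animal` multiplies the rate by broilers per round
#' times rounds per year, `per_round` by rounds per year, `per_stable` by
#' the number of stables (defaulting to 2 when the farm table does not
#' record it).
#'
#' @param item a [cost_item()].
#' @param farm one-row farm table (needs `broilers_per_round` and
#'   `rounds_per_year` for the scaled items; optionally `n_stables`).
#' @return Euro per year.
#' @export
yearly_cost <- function(item, farm) {
  stopifnot(inherits(item, "cost_item"))
  base <- item$implementation_cost / item$lifetime_years +
    item$operational_cost
  scale_term <- switch(item$scaling,
    fixed = 0,
    per_animal = {
      if (is.null(farm$broilers_per_round) || is.null(farm$rounds_per_year))
        stop("yearly_cost: per_animal item needs broilers_per_round and rounds_per_year")
      item$scale_rate * farm$broilers_per_round * farm$rounds_per_year
    },
    per_round = {
      if (is.null(farm$rounds_per_year))
        stop("yearly_cost: per_round item needs rounds_per_year")
      item$scale_rate * farm$rounds_per_year
    },
    per_stable = {
      n_stables <- if (!is.null(farm$n_stables) && !is.na(farm$n_stables))
        farm$n_stables else 2
      item$scale_rate * n_stables
    })
  base + scale_term
}

#' Yearly cost of a scenario
#'
#' Sum of [yearly_cost()] over the measures flipped in the scenario.
#' Measures without a cost item are costed 0 with a warning.
#'
#' @param flipped character vector of flipped measures.
#' @param cost_table named list from [read_cost_table()].
#' @param farm one-row farm table.
#' @return Euro per year.
#' @export
scenario_cost <- function(flipped, cost_table, farm) {
  total <- 0
  for (f in flipped) {
    if (!f %in% names(cost_table)) {
      warning("scenario_cost: no cost item for ", f, "; costed 0")
      next
    }
    total <- total + yearly_cost(cost_table[[f]], farm)
  }
  total
}

#' Cost per unit of TIDDDvet change
#'
#' Yearly scenario cost divided by the difference between the scenario's and
#' the baseline predicted TIDDDvet. Reductions give negative values (euro
#' per unit of TIDDDvet reduction); an unchanged prediction leaves the ratio
#' undefined (`NA` with a warning).
#'
#' @param yearly scenario cost in euro per year.
#' @param baseline_ti baseline predicted TIDDDvet.
#' @param scenario_ti scenario predicted TIDDDvet.
#' @return Euro per TIDDDvet unit of change.
#' @export
cost_effectiveness <- function(yearly, baseline_ti, scenario_ti) {
  if (scenario_ti == baseline_ti) {
    warning("cost_effectiveness: no TIDDDvet change; undefined")
    return(NA_real_)
  }
  yearly / (scenario_ti - baseline_ti)
}

#' Attach costs to a plan report
#'
#' Adds `yearly_cost` (euro/year) and `cost_per_ti` (euro per TIDDDvet unit
#' of change) columns to the scenario table of a [evaluate_plan()] report.
#'
#' @param report a `plan_report`.
#' @param cost_table named list from [read_cost_table()].
#' @param farm one-row farm table used for cost scaling.
#' @return The report with costed scenario table.
#' @export
attach_costs <- function(report, cost_table, farm) {
  stopifnot(inherits(report, "plan_report"))
  tab <- report$scenarios
  tab$yearly_cost <- vapply(tab$flipped, function(fl)
    scenario_cost(strsplit(fl, "+", fixed = TRUE)[[1]], cost_table, farm),
    numeric(1))
  tab$cost_per_ti <- mapply(function(cost, ti)
    suppressWarnings(cost_effectiveness(cost, report$baseline_prediction_ti,
                                        ti)),
    tab$yearly_cost, tab$predicted_ti)
  report$scenarios <- tab
  report
}
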