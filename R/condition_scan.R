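#' Define a media condition
#'
#' A media condition is a set of exchange-reaction bounds plus metadata. By
#' the usual exchange convention uptake is a negative exchange flux, so a
#' nutrient is "open" when its exchange lower bound is negative; anaerobic
#' conditions have an O2 exchange lower bound of 0.
#'
#' @param condition_id label.
#' @param exchange_bounds named list, exchange reaction id to `c(lower,
#'   upper)` in mmol/gDW/h.
#' @param aerobic logical.
#' @param element_class which elemental source the condition varies:
#'   `"C"`, `"N"`, `"P"` or `"S"`.
#' @param nutrient_id the varied nutrient.
#' @param sources named character vector giving the base source nutrient for
#'   each element class (used by [make_media()]).
#' @param o2_exchange id of the O2 exchange reaction.
#' @return a list of class `media_condition`.
#' @export
media_condition <- function(condition_id, exchange_bounds, aerobic = TRUE,
                            element_class = "C", nutrient_id = NA_character_,
                            sources = NULL, o2_exchange = NULL) {
  for (b in exchange_bounds) {
    if (b[[1]] > b[[2]]) stop("media bound with lower > upper")
  }
  if (!aerobic && !is.null(o2_exchange) &&
      o2_exchange %in% names(exchange_bounds)) {
    if (exchange_bounds[[o2_exchange]][[1]] < 0) {
      stop("anaerobic condition must have O2 exchange lower bound 0")
    }
  }
  structure(list(condition_id = condition_id,
                 exchange_bounds = exchange_bounds, aerobic = aerobic,
                 element_class = element_class, nutrient_id = nutrient_id,
                 sources = sources, o2_exchange = o2_exchange),
            class = "media_condition")
}

#' Derive a sole-source media condition from a base medium
#'
#' Implements the sole-source swap protocol: the base source of
#' `element_class` is closed and the nutrient's exchange is opened at
#' `uptake` (or the base source's own uptake limit), leaving the other
#' element sources untouched. With `supplement = TRUE` the base source stays
#' open and the nutrient is added on top. Aerobicity toggles the O2
#' exchange lower bound.
#'
#' @param base a [media_condition()] carrying `sources` and `o2_exchange`.
#' @param nutrient_id nutrient to use as the element source.
#' @param element_class one of `"C"`, `"N"`, `"P"`, `"S"`.
#' @param aerobic logical.
#' @param model the [me_model()] (for the nutrient-to-exchange map).
#' @param uptake uptake limit for the swapped nutrient, mmol/gDW/h.
#' @param o2_uptake O2 uptake limit under aerobic conditions.
#' @param supplement add the nutrient instead of replacing the base source.
#' @return a [media_condition()].
#' @export
make_media <- function(base, nutrient_id, element_class, aerobic, model,
                       uptake = 10, o2_uptake = 20, supplement = FALSE) {
  nx <- model$nutrient_exchanges
  if (is.null(nx)) stop("model carries no nutrient_exchanges table")
  hit <- nx$exchange_id[nx$nutrient_id == nutrient_id]
  if (length(hit) != 1L) {
    stop("nutrient ", nutrient_id, " has no (unique) exchange reaction")
  }
  if (is.null(base$sources) || !element_class %in% names(base$sources)) {
    stop("base media does not define a source for element class ",
         element_class)
  }
  bounds <- base$exchange_bounds
  base_nutrient <- base$sources[[element_class]]
  base_ex <- nx$exchange_id[nx$nutrient_id == base_nutrient]
  if (!supplement && length(base_ex) == 1L) {
    bounds[[base_ex]] <- c(0, bounds[[base_ex]][[2]])
  }
  bounds[[hit]] <- c(-abs(uptake), bounds[[hit]][[2]] %||% 1000)
  if (!is.null(base$o2_exchange)) {
    bounds[[base$o2_exchange]] <-
      c(if (aerobic) -abs(o2_uptake) else 0, 1000)
  }
  media_condition(
    condition_id = paste0(nutrient_id, "_", element_class, "_",
                          if (aerobic) "aerobic" else "anaerobic"),
    exchange_bounds = bounds, aerobic = aerobic,
    element_class = element_class, nutrient_id = nutrient_id,
    sources = base$sources, o2_exchange = base$o2_exchange)
}

#' Scan growth and biomass composition across a nutrient panel
#'
#' For every (nutrient, element class) pair and aerobicity, builds the
#' sole-source media, maximizes growth, classifies the condition as growth
#' supporting when \eqn{\mu^* >} `min_growth`, and for growth-supporting
#' conditions computes the protein-biomass-normalized constituent demands.
#' Individual solver failures are recorded and skipped, never aborting the
#' scan; the model is restored between conditions.
#'
#' @param model an [me_model()] (typically with coenzyme coupling applied).
#' @param panel data.frame with columns `nutrient_id`, `element_class`.
#' @param base base [media_condition()] (e.g. [toy_base_media()]).
#' @param coenzymes list of [coenzyme_spec()]; defaults to
#'   `model$coenzymes`.
#' @param aerobicities logical vector of aerobicities to scan.
#' @param tol bisection tolerance.
#' @param min_growth growth-support classification threshold, 1/h.
#' @param uptake uptake bound for the swapped nutrient.
#' @param normalization passed to [constituent_demands()].
#' @return an object of class `me_scan`: list with `growth` (one row per
#'   condition: `condition_id`, `nutrient_id`, `element_class`, `aerobic`,
#'   `growth_rate`, `growth_supporting`, `status`) and `table` (long demand
#'   table for growth-supporting conditions with columns `condition_id`,
#'   `aerobic`, `element_class`, `nutrient_id`, `component_id`,
#'   `component_class`, `demand`, `normalization`).
#' @export
scan_conditions <- function(model, panel, base,
                            coenzymes = model$coenzymes,
                            aerobicities = c(TRUE, FALSE), tol = 1e-6,
                            min_growth = 1e-3, uptake = 10,
                            normalization = "per_protein_biomass") {
  stopifnot(nrow(panel) > 0)
  growth <- list(); demands <- list()
  for (i in seq_len(nrow(panel))) {
    for (aer in aerobicities) {
      media <- make_media(base, panel$nutrient_id[[i]],
                          panel$element_class[[i]], aer, model,
                          uptake = uptake)
      sol <- tryCatch(solve_condition(model, media, tol = tol),
                      error = function(e) e)
      if (inherits(sol, "error")) {
        growth[[length(growth) + 1L]] <- data.frame(
          condition_id = media$condition_id,
          nutrient_id = panel$nutrient_id[[i]],
          element_class = panel$element_class[[i]], aerobic = aer,
          growth_rate = NA_real_, growth_supporting = FALSE,
          status = paste("error:", conditionMessage(sol)))
        next
      }
      mu <- if (is.na(sol$mu_opt)) 0 else sol$mu_opt
      supporting <- mu > min_growth
      growth[[length(growth) + 1L]] <- data.frame(
        condition_id = media$condition_id,
        nutrient_id = panel$nutrient_id[[i]],
        element_class = panel$element_class[[i]], aerobic = aer,
        growth_rate = if (supporting) mu else 0,
        growth_supporting = supporting, status = sol$status)
      if (supporting) {
        cd <- constituent_demands(sol, model, coenzymes,
                                  mode = normalization,
                                  condition_id = media$condition_id,
                                  aerobic = aer,
                                  element_class = panel$element_class[[i]])
        cd <- as.data.frame(cd)
        cd$condition_id <- media$condition_id
        cd$aerobic <- aer
        cd$element_class <- panel$element_class[[i]]
        cd$nutrient_id <- panel$nutrient_id[[i]]
        cd$normalization <- normalization
        demands[[length(demands) + 1L]] <- cd
      }
    }
  }
  growth <- do.call(rbind, growth)
  table <- if (length(demands)) do.call(rbind, demands) else NULL
  rownames(growth) <- NULL
  if (!is.null(table)) rownames(table) <- NULL
  structure(list(growth = growth, table = table), class = "me_scan")
}

#' @export
print.me_scan <- function(x, ...) {
  cat("<me_scan> ", nrow(x$growth), " conditions, ",
      sum(x$growth$growth_supporting), " growth-supporting\n", sep = "")
  invisible(x)
}

#' Pivot a scan's demand table into a condition x component matrix
#'
#' @param scan an `me_scan` (or its long `table`).
#' @return numeric matrix, rows = condition ids, columns = component ids,
#'   with attributes `aerobic` (named logical), `growth_rate` (named
#'   numeric, for growth-supporting conditions) and `component_class`
#'   (named character).
#' @export
composition_matrix <- function(scan) {
  tab <- if (inherits(scan, "me_scan")) scan$table else scan
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("scan has no growth-supporting conditions to tabulate")
  }
  conds <- unique(tab$condition_id)
  comps <- unique(tab$component_id)
  m <- matrix(0, length(conds), length(comps),
              dimnames = list(conds, comps))
  m[cbind(match(tab$condition_id, conds), match(tab$component_id, comps))] <-
    tab$demand
  aer <- tapply(tab$aerobic, tab$condition_id, `[[`, 1)[conds]
  cls <- tapply(tab$component_class, tab$component_id, `[[`, 1)[comps]
  gr <- NULL
  if (inherits(scan, "me_scan")) {
    g <- scan$growth
    gr <- stats::setNames(g$growth_rate, g$condition_id)[conds]
  }
  structure(m, aerobic = aer, component_class = cls, growth_rate = gr)
}
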