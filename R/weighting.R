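# Hierarchical weights over documented cells.
#
# Four sequential steps build the weight of each documented cell:
#   (a) within an ecosystem slice, each indicator starts from its ecosystem
#       membership fraction (an indicator spanning mountains 0.7 / forests
#       0.3 contributes with those base weights in the respective slices);
#   (b) indicators flagged extra-representative jointly take the 50% cap of
#       the slice whenever ordinary indicators coexist; the remainder is
#       split equally among the trophic/functional groups present among the
#       documented ordinary indicators, then proportionally to base weights
#       within each group;
#   (c) all major ecosystems present in a spatial unit (positive area) count
#       equally, so each gets factor 1/E — ecosystems are never ranked by
#       area, and destroying one lowers the index until it is restored;
#   (d) spatial units are averaged proportionally to area.
# Undocumented cells always carry zero weight; any deficit this leaves is
# repaired by explicit renormalization over documented cells (reported as a
# diagnostic), so that weights sum to one for every computed scope and date.

#' Indicator weights within one ecosystem slice
#'
#' Computes step (a)–(b) weights over the documented indicators of one
#' (ecosystem, unit, date) slice. Extra-representative indicators jointly
#' receive exactly the 50% cap when at least one ordinary indicator is
#' documented (the full share when they are alone); the remaining share is
#' divided equally among the groups present among documented ordinary
#' indicators and, within a group, proportionally to ecosystem-membership
#' base weights.
#'
#' @param meta indicator metadata table (or an [ni_dataset()], from which
#'   it is taken).
#' @param ecosystem_id the ecosystem of the slice.
#' @param documented character vector of documented indicator ids in the
#'   slice; must be non-empty.
#' @return data frame `indicator_id`, `base_membership`,
#'   `extra_representative`, `group_id`, `weight`; weights sum to 1.
#' @examples
#' meta <- data.frame(
#'   indicator_id = c("er", "a1", "a2", "b1", "b2", "b3"),
#'   ecosystem_id = "forest", membership = 1,
#'   group_id = c("top_pred", "A", "A", "B", "B", "B"),
#'   extra_representative = c(TRUE, rep(FALSE, 5)))
#' w <- within_ecosystem_weights(meta, "forest", meta$indicator_id)
#' # er: 0.5; a1, a2: 0.125 each; b1..b3: 1/12 each
#' @export
within_ecosystem_weights <- function(meta, ecosystem_id, documented) {
  if (inherits(meta, "ni_dataset")) meta <- meta$meta
  if (!length(documented))
    stop("no documented indicators in this ecosystem slice", call. = FALSE)
  ms <- meta[meta$ecosystem_id == ecosystem_id &
               meta$indicator_id %in% documented & meta$membership > 0, ]
  if (!setequal(ms$indicator_id, documented))
    stop("documented indicator(s) lack membership in ecosystem ",
         ecosystem_id, ": ",
         paste(setdiff(documented, ms$indicator_id), collapse = ", "),
         call. = FALSE)
  base <- ms$membership
  er <- ms$extra_representative
  w <- numeric(nrow(ms))
  er_share <- if (!any(er)) 0 else if (all(er)) 1 else 0.5
  if (any(er)) w[er] <- er_share * base[er] / sum(base[er])
  if (any(!er)) {
    groups <- unique(ms$group_id[!er])
    per_group <- (1 - er_share) / length(groups)
    for (g in groups) {
      sel <- !er & ms$group_id == g
      w[sel] <- per_group * base[sel] / sum(base[sel])
    }
  }
  w <- w / sum(w)
  data.frame(indicator_id = ms$indicator_id, base_membership = base,
             extra_representative = er, group_id = ms$group_id,
             weight = w, row.names = NULL)
}

#' Equal-weight factors across ecosystems of a unit
#'
#' Step (c): each major ecosystem present in the unit (positive area,
#' optionally intersected with a selection) receives the factor 1/E, where E
#' is the number of present ecosystems. Division is by *presence*, not by
#' documentation: an undocumented present ecosystem leaves a weight deficit
#' that surfaces in the renormalization diagnostic rather than silently
#' inflating the documented ones.
#'
#' @param units spatial-unit table (or an `ni_dataset`).
#' @param unit_id the unit.
#' @param ecosystems optional ecosystem selection.
#' @return data frame `ecosystem_id`, `eco_factor`.
#' @export
across_ecosystem_weights <- function(units, unit_id, ecosystems = NULL) {
  if (inherits(units, "ni_dataset")) units <- units$units
  u <- units[units$unit_id == unit_id & units$ecosystem_area > 0, ]
  if (!is.null(ecosystems)) u <- u[u$ecosystem_id %in% ecosystems, ]
  if (!nrow(u))
    stop("no present ecosystems for unit ", unit_id, call. = FALSE)
  data.frame(ecosystem_id = u$ecosystem_id, eco_factor = 1 / nrow(u),
             row.names = NULL)
}

#' Area-proportional factors across spatial units
#'
#' Step (d): each selected unit receives area_k / sum(area) so that values
#' averaged over several units represent the total area. Within a
#' single-ecosystem scope the ecosystem's own area in each unit is used (a
#' unit that is 5% mountain should not dominate a mountain index by its
#' total size); otherwise the unit's total area.
#'
#' @param units spatial-unit table (or an `ni_dataset`).
#' @param unit_ids selection of units; defaults to all.
#' @param ecosystem_id optional single ecosystem defining the scope.
#' @return data frame `unit_id`, `area`, `area_factor` summing to 1.
#' @export
area_weights <- function(units, unit_ids = NULL, ecosystem_id = NULL) {
  if (inherits(units, "ni_dataset")) units <- units$units
  if (is.null(unit_ids)) unit_ids <- unique(units$unit_id)
  miss <- setdiff(unit_ids, units$unit_id)
  if (length(miss))
    stop("unknown spatial unit(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(ecosystem_id) && length(ecosystem_id) == 1) {
    u <- units[units$unit_id %in% unit_ids &
                 units$ecosystem_id == ecosystem_id, ]
    area <- u$ecosystem_area[match(unit_ids, u$unit_id)]
    area[is.na(area)] <- 0
  } else {
    area <- units$total_area[match(unit_ids, units$unit_id)]
  }
  tot <- sum(area)
  if (tot <= 0)
    stop("selected spatial units have zero total area", call. = FALSE)
  data.frame(unit_id = unit_ids, area = area, area_factor = area / tot,
             row.names = NULL)
}

#' Scope descriptor for index computations
#'
#' A scope restricts the cells entering an index: `NULL` components mean
#' "all". The same object doubles as the binary weight overlay of thematic
#' sub-indexes.
#'
#' @param indicators,ecosystems,units optional character vectors of ids.
#' @return list of class `ni_scope`.
#' @export
ni_scope <- function(indicators = NULL, ecosystems = NULL, units = NULL) {
  structure(list(indicators = indicators, ecosystems = ecosystems,
                 units = units), class = "ni_scope")
}

.in_scope <- function(x, sel) is.null(sel) | x %in% sel

#' Build the weight table for one scope and date
#'
#' Assembles the full audit trail of the hierarchical weights for every
#' documented cell in scope at `date`: base membership, within-ecosystem
#' weight (steps a–b), ecosystem factor (step c), area factor (step d), the
#' raw product and the final weight renormalized to sum exactly to one over
#' documented cells. The pre-renormalization deficit — weight lost to
#' present-but-undocumented ecosystems or units — is attached as attribute
#' `deficit`.
#'
#' @param dataset an [ni_dataset()].
#' @param scope an [ni_scope()].
#' @param date single study date.
#' @return data frame of class `ni_weights` with attributes `deficit`,
#'   `scope`, `date`.
#' @export
build_weight_table <- function(dataset, scope = ni_scope(), date) {
  stopifnot(inherits(dataset, "ni_dataset"), length(date) == 1)
  rec <- dataset$records
  rec <- rec[rec$date == date &
               .in_scope(rec$indicator_id, scope$indicators) &
               .in_scope(rec$ecosystem_id, scope$ecosystems) &
               .in_scope(rec$unit_id, scope$units), ]
  if (!nrow(rec))
    stop("no documented indicators in scope at date ", date, call. = FALSE)

  units_sel <- if (is.null(scope$units))
    unique(dataset$units$unit_id) else scope$units
  eco_sel <- scope$ecosystems
  aw <- area_weights(dataset$units, units_sel,
                     if (!is.null(eco_sel) && length(eco_sel) == 1)
                       eco_sel else NULL)
  aw <- aw[aw$area_factor > 0, ]

  out <- NULL
  for (k in unique(rec$unit_id)) {
    af <- aw$area_factor[match(k, aw$unit_id)]
    if (is.na(af)) next  # unit with zero relevant area contributes nothing
    ef <- across_ecosystem_weights(dataset$units, k, eco_sel)
    rk <- rec[rec$unit_id == k, ]
    for (j in unique(rk$ecosystem_id)) {
      fac <- ef$eco_factor[match(j, ef$ecosystem_id)]
      if (is.na(fac)) next  # documented in an ecosystem with zero area
      docs <- rk$indicator_id[rk$ecosystem_id == j]
      ww <- within_ecosystem_weights(dataset$meta, j, docs)
      out <- rbind(out, data.frame(
        indicator_id = ww$indicator_id, ecosystem_id = j, unit_id = k,
        date = date, base_membership = ww$base_membership,
        extra_representative = ww$extra_representative,
        group_id = ww$group_id, within_weight = ww$weight,
        eco_factor = fac, area_factor = af,
        weight_raw = ww$weight * fac * af, row.names = NULL))
    }
  }
  if (is.null(out))
    stop("no documented indicators in scope at date ", date, call. = FALSE)
  tot <- sum(out$weight_raw)
  out$weight <- out$weight_raw / tot
  structure(out, deficit = 1 - tot, scope = scope, date = date,
            class = c("ni_weights", "data.frame"))
}

#' Thematic binary weight overlay
#'
#' Restricts an existing weight table to a theme — a selection of
#' indicators, ecosystems and/or units — by zeroing weights outside it and
#' renormalizing within, as thematic sub-indexes use binary weights on top
#' of the standard scheme.
#'
#' @param weights an `ni_weights` table from [build_weight_table()].
#' @param theme an [ni_scope()] describing the theme.
#' @return a renormalized `ni_weights` table containing only themed cells.
#' @export
thematic_mask <- function(weights, theme) {
  stopifnot(inherits(weights, "ni_weights"), inherits(theme, "ni_scope"))
  keep <- .in_scope(weights$indicator_id, theme$indicators) &
    .in_scope(weights$ecosystem_id, theme$ecosystems) &
    .in_scope(weights$unit_id, theme$units)
  if (!any(keep))
    stop("thematic selection contains no documented cells", call. = FALSE)
  out <- weights[keep, ]
  tot <- sum(out$weight_raw)
  out$weight <- out$weight_raw / tot
  structure(out, deficit = 1 - tot, scope = theme,
            date = attr(weights, "date"),
            class = c("ni_weights", "data.frame"))
}
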