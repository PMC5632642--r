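# Stand-structure analysis: elevation classes, age-height regression,
# height-to-age conversion, ingrowth-time distributions and densities for
# canopy-height tree tables (detection threshold 2.5 m).

#' Assign trees to elevation classes
#'
#' Splits a stand table into three elevation classes using the 25th and 75th
#' percentiles of elevation as class breaks. Trees exactly on a break are
#' assigned to the lower class (deterministic rule).
#'
#' @param table Data frame with at least a numeric `elevation` column (m).
#' @return Factor of length `nrow(table)` with levels `lower25`,
#'   `central50`, `upper25`. Degenerate input (all elevations equal) puts
#'   every tree in one class with a warning.
#' @export
elevation_classes <- function(table) {
  elev <- table$elevation
  if (length(elev) < 4L) stop("need >= 4 trees", call. = FALSE)
  br <- quantile(elev, c(0.25, 0.75), names = FALSE, type = 7)
  if (br[1] == br[2]) {
    warning("degenerate elevation distribution: all trees in one class")
    return(factor(rep("central50", length(elev)),
                  levels = c("lower25", "central50", "upper25")))
  }
  cls <- ifelse(elev <= br[1], "lower25",
                ifelse(elev <= br[2], "central50", "upper25"))
  factor(cls, levels = c("lower25", "central50", "upper25"))
}

#' Site-specific age-height regression
#'
#' Ordinary least-squares fit of `age = b_0 + b_1 * height` on cored trees
#' whose ages come from pith-dated base cores (plus pith offset).
#'
#' @param ages Tree ages in years.
#' @param heights Tree heights in m.
#' @return An object of class `age_height_model` with `b0` (years), `b1`
#'   (years per m), `r_squared`, `p_value`, `n`.
#' @export
fit_age_height <- function(ages, heights) {
  ok <- is.finite(ages) & is.finite(heights)
  ages <- ages[ok]; heights <- heights[ok]
  if (length(ages) < 3L) stop("need >= 3 (age, height) pairs", call. = FALSE)
  if (var(heights) == 0) stop("heights have zero variance", call. = FALSE)
  fit <- lm(ages ~ heights)
  sm <- summary(fit)
  structure(list(b0 = unname(coef(fit)[1L]), b1 = unname(coef(fit)[2L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n = length(ages)),
            class = "age_height_model")
}

#' @export
print.age_height_model <- function(x, ...) {
  cat(sprintf("<age_height_model> age = %.2f + %.2f x height (R2 = %.2f, p = %.2g, n = %d)\n",
              x$b0, x$b1, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Convert tree heights to estimated ages and ingrowth times
#'
#' Applies a site-specific [fit_age_height()] model to a stand table of
#' detected trees, floors predicted ages at 1 year (with a warning when the
#' floor bites), and derives each tree's ingrowth time — the estimated years
#' since establishment, i.e. the tree's age at the survey — together with
#' the estimated establishment year. Per-elevation-class summaries (counts
#' by age bin and skewness) describe the shape of the ingrowth
#' distributions.
#'
#' @param table Stand table with `elevation` and `height` columns (heights
#'   above the 2.5 m detection threshold).
#' @param model An `age_height_model` fitted at the same site.
#' @param survey_year Calendar year of the height survey (default 2015).
#' @param bin_width Histogram bin width in years for the class summaries.
#' @return A list with `trees` (the table plus `age`, `ingrowth_time`,
#'   `establishment_year`, `elev_class`) and `class_summary` (per class:
#'   n, mean/median ingrowth time, skewness, and a `counts` histogram).
#' @export
heights_to_ingrowth <- function(table, model, survey_year = 2015,
                                bin_width = 20) {
  stopifnot(inherits(model, "age_height_model"))
  age <- model$b0 + model$b1 * table$height
  n_floored <- sum(age < 1)
  if (n_floored > 0L) {
    warning(sprintf("%d predicted ages below 1 yr floored at 1", n_floored))
  }
  age <- pmax(age, 1)
  trees <- table
  trees$age <- age
  trees$ingrowth_time <- age
  trees$establishment_year <- survey_year - age
  trees$elev_class <- elevation_classes(table)
  breaks <- seq(0, ceiling(max(age) / bin_width) * bin_width, by = bin_width)
  class_summary <- lapply(split(trees, trees$elev_class), function(d) {
    if (nrow(d) == 0L) {
      return(list(n = 0L, mean_ingrowth = NA_real_, median_ingrowth = NA_real_,
                  skewness = NA_real_, counts = NULL))
    }
    h <- graphics::hist(d$ingrowth_time, breaks = breaks, plot = FALSE)
    list(n = nrow(d), mean_ingrowth = mean(d$ingrowth_time),
         median_ingrowth = median(d$ingrowth_time),
         skewness = skewness(d$ingrowth_time),
         counts = data.frame(bin_start = h$breaks[-length(h$breaks)],
                             bin_end = h$breaks[-1], count = h$counts))
  })
  list(trees = trees, class_summary = class_summary)
}

#' Stand density per elevation class
#'
#' @param table Stand table with `elevation`.
#' @param areas Either a single total area (ha), split across classes in
#'   proportion to an equal elevation-band assumption is NOT attempted —
#'   a named vector `c(lower25 =, central50 =, upper25 =)` of per-class
#'   areas in ha, or one number interpreted as the total area with density
#'   reported overall only.
#' @return A data frame with columns `class`, `n_trees`, `area_ha`,
#'   `density_ha` (trees per hectare); the last row is the overall total.
#' @export
stand_density <- function(table, areas) {
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  cls <- elevation_classes(table)
  counts <- table(cls)
  lv <- levels(cls)
  if (length(areas) == 1L && is.null(names(areas))) {
    out <- data.frame(class = "overall", n_trees = nrow(table),
                      area_ha = unname(areas),
                      density_ha = nrow(table) / unname(areas))
    return(out)
  }
  if (!all(lv %in% names(areas))) {
    stop("`areas` must be named with the three class labels or be a single total",
         call. = FALSE)
  }
  per <- data.frame(class = lv, n_trees = as.integer(counts[lv]),
                    area_ha = as.numeric(areas[lv]),
                    density_ha = as.integer(counts[lv]) / as.numeric(areas[lv]),
                    row.names = NULL)
  total <- data.frame(class = "overall", n_trees = nrow(table),
                      area_ha = sum(per$area_ha),
                      density_ha = nrow(table) / sum(per$area_ha))
  rbind(per, total)
}
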