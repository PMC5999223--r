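#' Registry of slide-level histomorphological variables
#'
#' Returns the canonical registry of the 16 histomorphological variables
#' collected per slide during the standardized thymectomy work-up, one row per
#' variable: its snake_case name, measurement scale, admissible value range,
#' units, and the stainings it is read from.
#'
#' These ranges drive row-level validation in [read_slide_table()]: a value
#' outside `[range_min, range_max]` rejects the row. The nominal narrative
#' variable has no numeric range and is excluded from all numeric operations.
#'
#' @return A data.frame with columns `variable`, `scale`
#'   (`"nominal"`/`"ordinal"`/`"interval"`), `range_min`, `range_max`,
#'   `units`, `stainings` (comma-separated staining codes).
#' @export
#' @examples
#' histo_variables()[, c("variable", "scale", "range_min", "range_max")]
histo_variables <- function() {
  v <- function(variable, scale, range_min, range_max, units, stainings)
    data.frame(variable = variable, scale = scale, range_min = range_min,
               range_max = range_max, units = units, stainings = stainings,
               stringsAsFactors = FALSE)
  rbind(
    v("narrative_follicle_morphology", "nominal", NA, NA, "", "HE,CD23"),
    v("grading_atrophy", "ordinal", 0, 4, "grade", "HE"),
    v("grading_follicle", "ordinal", 0, 4, "grade", "HE,CD23"),
    v("grading_overall_fat", "interval", 0, 100, "%", "HE"),
    v("grading_intrathymic_fat", "interval", 0, 100, "%", "HE"),
    v("area_b_cell_infiltrate", "interval", 0, 100, "%", "CD20"),
    v("n_follicle", "interval", 0, 100, "count", "HE,CD23"),
    v("cortical_area", "interval", 0, 10000, "pixel", "HE"),
    v("medullary_area", "interval", 0, 10000, "pixel", "HE"),
    v("follicle_area", "interval", 0, 10000, "pixel", "HE,CD23,IgD"),
    v("germinal_centre_area", "interval", 0, 10000, "pixel", "HE,CD23,IgD"),
    v("mantle_zone_area", "interval", 0, 10000, "pixel", "HE,CD23,IgD"),
    v("marginal_zone_area", "interval", 0, 10000, "pixel", "HE,CD23,IgD"),
    v("area_thymic_tissue", "interval", 0, 10000, "pixel", "HE"),
    v("n_follicle_gc", "interval", 0, 100, "count", "HE"),
    v("n_follicle_no_gc", "interval", 0, 100, "count", "HE")
  )
}

#' Staining codes accepted in slide tables
#' @return Character vector of valid staining codes.
#' @export
staining_codes <- function() c("HE", "CD23", "CD20", "IgD")

#' Anatomical region vocabulary
#'
#' Default region codes for the standardized specimen work-up: the completely
#' processed central horizontal plane (`"A"`) and the right/left lobe samples
#' above and below it (`"RU"`, `"RL"`, `"LU"`, `"LL"`). Region is carried as
#' slide metadata only; every slide counts as one measurement point regardless
#' of region.
#'
#' @return Character vector of region codes.
#' @export
region_codes <- function() c("A", "RU", "RL", "LU", "LL")

#' Default entropy features
#'
#' The four slide-level features for which per-case entropy is computed by
#' default, each paired with the staining it is read from: CD23 follicle
#' counts, CD23 follicular-hyperplasia grade, HE intrathymic fat percentage
#' and HE atrophy grade.
#'
#' @return data.frame with columns `variable` and `staining`.
#' @export
default_entropy_features <- function() {
  data.frame(
    variable = c("n_follicle", "grading_follicle",
                 "grading_intrathymic_fat", "grading_atrophy"),
    staining = c("CD23", "CD23", "HE", "HE"),
    stringsAsFactors = FALSE
  )
}
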