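#' Regional anthropometric reference table
#'
#' Published average adult weight, height, and BMI for a set of countries,
#' by sex. These literature averages are the kind of prior knowledge a
#' federated pre-study would use to define client-specific target
#' distributions (e.g. a "German clinic" vs a "Japanese clinic" client).
#' Heights are stored in metres as published.
#'
#' @return A tibble with columns `country`, `weight_men_kg`,
#'   `weight_women_kg`, `height_men_m`, `height_women_m`, `bmi_men`,
#'   `bmi_women`.
#' @export
region_presets <- function() {
  path <- system.file("extdata", "region_anthropometrics.csv",
                      package = "biasplit", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Target spec from a regional demographic preset
#'
#' Looks up the published mean weight and height for a country/sex
#' combination and returns a [target_spec()] centred there. Heights are
#' converted from the published metres to the cohort convention of
#' centimetres; the conversion is recorded in the spec's `provenance`
#' attribute. The literature table publishes no standard deviations, so
#' `sd` must be supplied by the caller -- typically from the
#' mixture-feasibility solver [feasible_sigma()].
#'
#' @param region Country name (e.g. `"Germany"`, `"Japan"`).
#' @param sex `"men"` or `"women"`.
#' @param sd Optional per-dimension standard deviations `(weight, height)`.
#' @return A `target_spec` with means in kg and cm.
#' @examples
#' preset_targets("Germany", "men")
#' @export
preset_targets <- function(region, sex = c("men", "women"), sd = NULL) {
  sex <- match.arg(sex)
  tab <- region_presets()
  row <- tab[tab$country == region, ]
  if (nrow(row) != 1) {
    abort(paste0(
      "Unknown region '", region, "'. Available: ",
      paste(tab$country, collapse = ", ")
    ))
  }
  height_m <- row[[paste0("height_", sex, "_m")]]
  spec <- target_spec(
    mean = c(weight = row[[paste0("weight_", sex, "_kg")]],
             height = height_m * 100),
    sd = sd
  )
  attr(spec, "provenance") <- list(
    region = region, sex = sex,
    height_converted = "published metres * 100 -> cm"
  )
  spec
}
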