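#' Catalog of the 33 chronic conditions and risk factors
#'
#' The condition set covers nine body systems; three entries (hypertension,
#' high cholesterol, obesity) are lifestyle-linked risk factors that are
#' clustered like any other condition but can be excluded from the
#' chronic-condition portfolio analysis.
#'
#' @return A data frame with one row per condition and columns `name`
#'   (snake_case column name used in cohort files), `label` (display name),
#'   `category` (body system) and `risk_factor` (logical).
#' @export
#' @examples
#' cat33 <- condition_catalog()
#' nrow(cat33)                      # 33
#' sum(cat33$risk_factor)           # 3
condition_catalog <- function() {
  df <- data.frame(
    name = c(
      "ischemic_heart_disease", "atrial_fibrillation", "heart_failure",
      "peripheral_artery_occlusive_disease", "hypertension", "stroke",
      "high_cholesterol",
      "diabetes_i", "diabetes_ii", "obesity",
      "copd", "allergies",
      "joint_disease", "osteoporosis", "osteoarthritis",
      "cancer_digestive", "cancer_respiratory", "cancer_skin",
      "cancer_breast", "cancer_genital", "cancer_other",
      "epilepsy", "parkinsons_disease", "multiple_sclerosis",
      "dementia", "schizophrenia", "depression", "anxiety",
      "addictive_disorder", "personality_disorder",
      "kidney_disease",
      "liver_disease", "bowel_disease"
    ),
    label = c(
      "Ischemic heart disease", "Atrial fibrillation", "Heart failure",
      "Peripheral artery occlusive disease", "Hypertension", "Stroke",
      "High cholesterol",
      "Diabetes I", "Diabetes II", "Obesity",
      "COPD", "Allergies",
      "Joint disease", "Osteoporosis", "Osteoarthritis",
      "Cancer of digestive organs",
      "Cancer of respiratory and intrathoracic organs", "Skin cancer",
      "Breast cancer", "Cancer of genital organs",
      "Other cancer excluding metastases",
      "Epilepsy", "Parkinson's disease", "Multiple sclerosis",
      "Dementia", "Schizophrenia", "Depression", "Anxiety",
      "Addictive disorder", "Personality disorder",
      "Chronic kidney disease",
      "Chronic liver disease", "Inflammatory bowel disease"
    ),
    category = c(
      rep("Circulatory system", 7),
      rep("Endocrine system", 3),
      rep("Pulmonary system", 2),
      rep("Musculoskeletal system", 3),
      rep("Cancers", 6),
      rep("Neurological system", 3),
      rep("Mental health conditions", 6),
      "Urogenital system",
      rep("Gastrointestinal system", 2)
    ),
    stringsAsFactors = FALSE
  )
  df$risk_factor <- df$name %in% c("hypertension", "high_cholesterol", "obesity")
  stopifnot(nrow(df) == 33L, !anyDuplicated(df$name), sum(df$risk_factor) == 3L)
  df
}

#' Healthcare-utilization variable schema
#'
#' Seven count-valued variables accumulated over one calendar year, in the
#' canonical column order used by cohort files.
#'
#' @return Character vector of the 7 utilization column names.
#' @export
utilization_schema <- function() {
  c("hospitalizations", "bed_days", "medication_usage", "outpatient_visits",
    "gp_visits", "specialist_visits", "psychologist_visits")
}

#' Sociodemographic field names of the cohort schema
#'
#' Categorical descriptors used for cluster profiling only; they never enter
#' the clustering itself. An optional numeric `age` column may accompany
#' them in cohort files to enable the mean-age profile row.
#'
#' @return Character vector of the 7 categorical field names.
#' @export
sociodemo_fields <- function() {
  c("age_band", "sex", "family_type", "region", "employment", "education",
    "income_quartile")
}
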