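# Internal helpers shared across modules.

# Canonical cohort columns. `baseline_columns()` is the default 25-column
# required set for complete-case filtering (all baseline fields); GWW/GWE are
# the outcomes.
cohort_numeric_columns <- function() {
  c("age", "SBP", "DBP", "eGFR", "BNP", "BMI", "LVEF", "LVMI", "RWT",
    "GLS", "PSD", "LAVI", "E_to_e", "GWW", "GWE")
}

cohort_binary_columns <- function() {
  c("sex", "HTN", "DM", "CAD", "RD")
}

#' Default baseline feature set
#'
#' The 25-variable baseline set used for complete-case filtering: all
#' demographic, comorbidity, laboratory and echocardiographic fields of the
#' cohort table except the outcomes (GWW, GWE) and bookkeeping columns. The
#' published analysis never enumerates its baseline list, so this default is
#' user-overridable wherever it is consumed.
#'
#' @return Character vector of column names.
#' @export
baseline_columns <- function() {
  c("age", "sex", "SBP", "DBP", "HTN", "DM", "CAD", "RD", "eGFR", "BNP",
    "BMI", "LVEF", "LVMI", "RWT", "GLS", "PSD", "LAVI", "E_to_e")
}

outcome_columns <- function() c("GWW", "GWE")

cohort_all_columns <- function() {
  c("patient_id", baseline_columns(), outcome_columns(), "cluster")
}

#' Eight clustering variables
#'
#' The a-priori variable set used for k-means subtyping: age, BMI, eGFR, BNP,
#' LVEF, LAVI, E/e' ratio and PSD.
#'
#' @return Character vector of column names.
#' @export
clustering_variables <- function() {
  c("age", "BMI", "eGFR", "BNP", "LVEF", "LAVI", "E_to_e", "PSD")
}

# Derive a stream seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483563L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(x) {
  ux <- unique(x[!is.na(x)])
  length(ux) <= 2 && all(ux %in% c(0, 1))
}

# Column-wise z-score of a numeric matrix with n-1 sd.
scale_matrix <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (any(s <= 0)) {
    stopf("zero-variance column(s): %s",
          paste(colnames(X)[s <= 0], collapse = ", "))
  }
  list(X = sweep(sweep(X, 2, mu, "-"), 2, s, "/"), means = mu, sds = s)
}
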