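# Synthetic HFpEF cohort generator: two latent subtypes over the eight
# clustering variables, a known exposure -> PSD -> outcome mediation path,
# dirty-token missingness, and paired repeat PSD readings.

#' Specify a synthetic HFpEF cohort
#'
#' Builds the full generative recipe for [generate_cohort()]. The defaults
#' are the "table1" preset: two subtypes matching the published cluster
#' profiles — a younger cardiorenal phenotype (severe renal dysfunction,
#' high BNP, PSD around 56 ms) and an older cardiac phenotype (preserved
#' renal function, PSD around 41 ms). eGFR and BNP are right-skewed and are
#' drawn log-normally; for those two variables `cluster_means` holds the
#' per-cluster *median* and `cluster_sds` the log-scale sd. BMI, LAVI and
#' E/e' defaults are package choices (clinically plausible values), not
#' published numbers.
#'
#' The mediation path acts on latent z-scales: the mediator PSD is
#' `a * z_exposure + noise` and each outcome is
#' `c' * z_x + b * z_PSD + gamma * z_PSD^2 + delta * z_x * z_PSD + noise`,
#' mapped affinely onto clinical units (GWE uses the negated path so that
#' efficiency moves opposite to wasted work). When the noise SDs are `NULL`
#' they are solved so the latent mediator and outcome have unit variance in
#' the linear case, i.e. `a`, `b`, `c'` are standardized path coefficients.
#'
#' @param n_patients Number of patients (>= 2).
#' @param cluster_weights Two mixing probabilities summing to 1.
#' @param cluster_means,cluster_sds 2 x 8 matrices (rows = clusters, columns
#'   = `clustering_variables()`); see Details for eGFR/BNP interpretation.
#' @param path_a,path_b,path_c_prime Length-2 numeric: per-cluster
#'   exposure->mediator, mediator->outcome and direct exposure->outcome
#'   coefficients on the latent z scale.
#' @param nonlinear_gamma Coefficient on the squared mediator (0 disables).
#' @param interaction_delta Coefficient on exposure x mediator (0 disables).
#' @param exposure_var Which cohort column carries the exposure
#'   (default "BNP", the headline pathway).
#' @param noise_sd_mediator,noise_sd_outcome Residual SDs on the latent
#'   scale, or `NULL` for the standardized-path solution.
#' @param missing_rate Per-cell probability a dirty-eligible cell is
#'   replaced by a dirty token in [inject_dirty()]. In `[0, 1)` normally;
#'   exactly 1 is accepted so a whole column can be dirtied.
#' @param dirty_tokens Character vector of dirty tokens.
#' @param replicate_sd Re-measurement noise SD (ms) for paired PSD readings;
#'   the default 1.14 ms gives a population ICC of 0.98 at a within-cluster
#'   PSD SD of 8 ms.
#' @param seed Integer seed; the whole cohort is bit-reproducible from it.
#' @return A `synthetic_spec` list, validated.
#' @export
synthetic_spec <- function(n_patients = 150,
                           cluster_weights = c(43, 41) / 84,
                           cluster_means = NULL,
                           cluster_sds = NULL,
                           path_a = c(0.5, 0.5),
                           path_b = c(0.5, 0.5),
                           path_c_prime = c(0.2, 0.2),
                           nonlinear_gamma = 0,
                           interaction_delta = 0,
                           exposure_var = "BNP",
                           noise_sd_mediator = NULL,
                           noise_sd_outcome = NULL,
                           missing_rate = 0,
                           dirty_tokens = c("/", "empty value", "#DIV/0!", ""),
                           replicate_sd = 1.14,
                           seed = 42L) {
  vars <- clustering_variables()
  if (is.null(cluster_means)) {
    cluster_means <- rbind(
      c(age = 58.6, BMI = 27.0, eGFR = 12.8, BNP = 510.0, LVEF = 61.2,
        LAVI = 42.0, E_to_e = 16.0, PSD = 56.0),
      c(age = 71.2, BMI = 25.0, eGFR = 104.0, BNP = 153.0, LVEF = 65.0,
        LAVI = 38.0, E_to_e = 14.0, PSD = 41.0))
  }
  if (is.null(cluster_sds)) {
    # eGFR/BNP entries are log-scale SDs backed out of the published IQRs.
    cluster_sds <- rbind(
      c(age = 13.2, BMI = 4.0, eGFR = 0.597, BNP = 1.200, LVEF = 4.4,
        LAVI = 10.0, E_to_e = 4.0, PSD = 8.0),
      c(age = 9.7, BMI = 3.5, eGFR = 0.351, BNP = 0.812, LVEF = 3.4,
        LAVI = 9.0, E_to_e = 4.0, PSD = 8.0))
  }
  colnames(cluster_means) <- vars
  colnames(cluster_sds) <- vars
  spec <- structure(list(
    n_patients = as.integer(n_patients),
    cluster_weights = cluster_weights,
    cluster_means = cluster_means,
    cluster_sds = cluster_sds,
    path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
    nonlinear_gamma = nonlinear_gamma,
    interaction_delta = interaction_delta,
    exposure_var = exposure_var,
    noise_sd_mediator = noise_sd_mediator,
    noise_sd_outcome = noise_sd_outcome,
    missing_rate = missing_rate,
    dirty_tokens = dirty_tokens,
    replicate_sd = replicate_sd,
    seed = as.integer(seed),
    # Per-cluster parameters outside the 8 clustering variables (Table-1
    # profile): flags are Bernoulli prevalences, the rest Gaussian.
    prevalence = rbind(
      c(sex = 0.628, HTN = 0.930, DM = 0.558, CAD = 0.209),
      c(sex = 0.366, HTN = 0.780, DM = 0.537, CAD = 0.439)),
    extra_means = rbind(
      c(SBP = 161.7, DBP = 80.3, GLS = 15.0, LVMI = 139.1, RWT = 0.5),
      c(SBP = 141.6, DBP = 67.5, GLS = 18.6, LVMI = 106.3, RWT = 0.4)),
    extra_sds = rbind(
      c(SBP = 23.3, DBP = 12.2, GLS = 3.3, LVMI = 31.1, RWT = 0.1),
      c(SBP = 27.1, DBP = 13.5, GLS = 3.9, LVMI = 23.3, RWT = 0.1)),
    outcome_loc = rbind(GWW = c(138, 95), GWE = c(93, 95.5)),
    outcome_scale = rbind(GWW = c(55, 55), GWE = c(2.5, 2.5))
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_patients < 2) stopf("n_patients must be >= 2, got %d", spec$n_patients)
  if (abs(sum(spec$cluster_weights) - 1) > 1e-8)
    stopf("cluster_weights must sum to 1 (got %g)", sum(spec$cluster_weights))
  if (any(spec$cluster_sds <= 0)) stopf("all cluster_sds must be > 0")
  if (spec$missing_rate < 0 || spec$missing_rate > 1)
    stopf("missing_rate must lie in [0, 1]")
  if (!spec$exposure_var %in% clustering_variables())
    stopf("exposure_var must be one of the clustering variables")
  invisible(spec)
}

# Truncated-normal draw by resampling out-of-range values.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  it <- 0L
  while (length(bad) > 0 && it < 1000L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower | x > upper)
    it <- it + 1L
  }
  x[x < lower] <- lower
  x[x > upper] <- upper
  x
}

# Outcome surface on the latent z scale (no noise).
latent_outcome <- function(zx, zm, cp, b, gamma, delta) {
  cp * zx + b * zm + gamma * zm^2 + delta * zx * zm
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws each patient from one of two latent subtypes, generates the eight
#' clustering variables (eGFR/BNP log-normally), comorbidity flags, blood
#' pressures and structural echo parameters, then plants the mediation path
#' exposure -> PSD -> GWW/GWE with the spec's per-cluster coefficients.
#' LVEF is truncated at 50 (the HFpEF inclusion criterion), PSD at 0, and
#' GWE is clipped to \[0, 100\]. The renal dysfunction flag RD is forced
#' consistent with eGFR < 60.
#'
#' The returned ground truth holds the latent labels and per-cluster
#' total/direct/indirect effects. In the nonlinear case the indirect effect
#' is defined as the cohort-average change in model-implied outcome when the
#' mediator moves from its value at exposure `x` to its value at `x + 1` SD
#' (numerically evaluated); in the linear case this reduces exactly to
#' `a * b`, and total = direct + indirect holds exactly by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `cohort` (data.frame, one row per patient, columns
#'   `cohort_all_columns()`) and `truth` (list: `true_labels`,
#'   `true_indirect`, `true_direct`, `true_total`, `latent_exposure`,
#'   `latent_mediator`).
#' @export
generate_cohort <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  k <- sample.int(2L, n, replace = TRUE, prob = spec$cluster_weights)
  vars <- clustering_variables()
  mu <- spec$cluster_means[k, , drop = FALSE]
  sg <- spec$cluster_sds[k, , drop = FALSE]

  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
  lower <- c(age = 18, BMI = 12, LVEF = 50, LAVI = 5, E_to_e = 2)
  for (v in c("age", "BMI", "LVEF", "LAVI", "E_to_e")) {
    cohort[[v]] <- rnorm_trunc(n, mu[, v], sg[, v], lower = lower[[v]])
  }
  for (v in c("eGFR", "BNP")) {
    cohort[[v]] <- rlnorm(n, meanlog = log(mu[, v]), sdlog = sg[, v])
  }

  # Latent exposure z-score (log scale for the skewed labs).
  ev <- spec$exposure_var
  zx <- if (ev %in% c("eGFR", "BNP")) {
    (log(cohort[[ev]]) - log(mu[, ev])) / sg[, ev]
  } else {
    (cohort[[ev]] - mu[, ev]) / sg[, ev]
  }

  a <- spec$path_a[k]; b <- spec$path_b[k]; cp <- spec$path_c_prime[k]
  gam <- spec$nonlinear_gamma; del <- spec$interaction_delta
  sd_m <- spec$noise_sd_mediator
  if (is.null(sd_m)) sd_m <- sqrt(pmax(0.05, 1 - spec$path_a^2))
  sd_y <- spec$noise_sd_outcome
  if (is.null(sd_y)) {
    vpath <- spec$path_c_prime^2 + spec$path_b^2 +
      2 * spec$path_c_prime * spec$path_b * spec$path_a
    sd_y <- sqrt(pmax(0.05, 1 - vpath))
  }
  sd_m <- rep(sd_m, length.out = 2)[k]
  sd_y <- rep(sd_y, length.out = 2)[k]

  zm <- a * zx + rnorm(n, 0, sd_m)
  cohort$PSD <- pmax(0, mu[, "PSD"] + sg[, "PSD"] * zm)

  zy_www <- latent_outcome(zx, zm, cp, b, gam, del) + rnorm(n, 0, sd_y)
  zy_gwe <- latent_outcome(zx, zm, -cp, -b, -gam, -del) + rnorm(n, 0, sd_y)
  cohort$GWW <- pmax(0, spec$outcome_loc["GWW", k] +
                       spec$outcome_scale["GWW", k] * zy_www)
  cohort$GWE <- pmin(100, pmax(0, spec$outcome_loc["GWE", k] +
                                 spec$outcome_scale["GWE", k] * zy_gwe))

  for (v in colnames(spec$prevalence)) {
    cohort[[v]] <- rbinom(n, 1, spec$prevalence[k, v])
  }
  cohort$RD <- as.integer(cohort$eGFR < 60)
  for (v in colnames(spec$extra_means)) {
    lo <- if (v == "RWT") 0.1 else 0
    cohort[[v]] <- rnorm_trunc(n, spec$extra_means[k, v],
                               spec$extra_sds[k, v], lower = lo)
  }
  cohort$cluster <- k - 1L
  cohort <- cohort[, cohort_all_columns()]

  truth <- list(true_labels = k - 1L,
                latent_exposure = zx, latent_mediator = zm)
  eff <- lapply(1:2, function(cl) {
    z <- zx[k == cl]
    if (length(z) == 0) z <- 0
    aa <- spec$path_a[cl]; bb <- spec$path_b[cl]; cc <- spec$path_c_prime[cl]
    g <- function(x, m) latent_outcome(x, m, cc, bb, gam, del)
    indirect <- mean(g(z + 1, aa * (z + 1)) - g(z + 1, aa * z))
    direct <- mean(g(z + 1, aa * z) - g(z, aa * z))
    total <- mean(g(z + 1, aa * (z + 1)) - g(z, aa * z))
    c(indirect = indirect, direct = direct, total = total)
  })
  truth$true_indirect <- vapply(eff, `[[`, numeric(1), "indirect")
  truth$true_direct <- vapply(eff, `[[`, numeric(1), "direct")
  truth$true_total <- vapply(eff, `[[`, numeric(1), "total")
  list(cohort = cohort, truth = truth)
}

#' Inject dirty tokens into a cohort table
#'
#' Serializes a copy of the table in which each dirty-eligible cell is
#' independently replaced, with probability `spec$missing_rate`, by a
#' uniformly chosen dirty token (the tokens real spreadsheets produce:
#' `/`, `empty value`, `#DIV/0!`, the empty string). Replacement positions
#' are recorded so QC round-trips can be checked exactly.
#'
#' @param table A cohort data.frame.
#' @param spec A [synthetic_spec()] (supplies `missing_rate`, `dirty_tokens`
#'   and the seed).
#' @param columns Columns eligible for dirt; default all numeric cohort
#'   columns present in `table`.
#' @return List: `raw` (all-character data.frame), `positions` (data.frame
#'   with `row`, `column`, `token`).
#' @export
inject_dirty <- function(table, spec, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(cohort_numeric_columns()), names(table))
  }
  raw <- as.data.frame(lapply(table, as.character),
                       stringsAsFactors = FALSE)
  names(raw) <- names(table)
  set.seed(derive_seed(spec$seed, 101L))
  pos <- list()
  for (cn in columns) {
    hit <- which(runif(nrow(raw)) < spec$missing_rate)
    if (length(hit) > 0) {
      tok <- sample(spec$dirty_tokens, length(hit), replace = TRUE)
      raw[hit, cn] <- tok
      pos[[cn]] <- data.frame(row = hit, column = cn, token = tok,
                              stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(pos)) do.call(rbind, pos) else
    data.frame(row = integer(0), column = character(0), token = character(0))
  rownames(positions) <- NULL
  list(raw = raw, positions = positions)
}

#' Dirty exactly enough rows to leave a target complete-case count
#'
#' The per-cell Bernoulli injection of [inject_dirty()] leaves a binomial
#' number of complete rows; this helper instead dirties exactly
#' `nrow(table) - n_complete_target` distinct rows (one randomly chosen
#' required cell each), emulating a raw export in which a known number of
#' records are unusable — e.g. 150 collected, 84 complete.
#'
#' @param table Cohort data.frame.
#' @param n_complete_target Number of rows that must stay fully complete.
#' @param columns Required columns a dirty cell may fall in.
#' @param tokens Dirty tokens to draw from.
#' @param seed Integer seed.
#' @return Same shape as [inject_dirty()].
#' @export
dirty_exact_rows <- function(table, n_complete_target,
                             columns = c(baseline_columns(), outcome_columns()),
                             tokens = c("/", "empty value", "#DIV/0!", ""),
                             seed = 1L) {
  n <- nrow(table)
  if (n_complete_target > n) stopf("target exceeds table size")
  columns <- intersect(columns, names(table))
  raw <- as.data.frame(lapply(table, as.character), stringsAsFactors = FALSE)
  names(raw) <- names(table)
  set.seed(seed)
  rows <- sample.int(n, n - n_complete_target)
  cols <- sample(columns, length(rows), replace = TRUE)
  toks <- sample(tokens, length(rows), replace = TRUE)
  for (i in seq_along(rows)) raw[rows[i], cols[i]] <- toks[i]
  list(raw = raw,
       positions = data.frame(row = rows, column = cols, token = toks,
                              stringsAsFactors = FALSE))
}

#' Paired repeat PSD readings for reliability analysis
#'
#' Samples `n_per_cluster` patients without replacement from each cluster
#' and produces two independent re-readings of PSD, each the patient's true
#' PSD plus Gaussian noise with SD `spec$replicate_sd` — the two-sonographer
#' re-measurement design.
#'
#' @param table Cohort with a `cluster` column.
#' @param n_per_cluster Patients to sample per cluster (default 20).
#' @param spec A [synthetic_spec()].
#' @return data.frame: `patient_id`, `cluster`, `reading_1`, `reading_2`.
#' @export
generate_replicates <- function(table, n_per_cluster = 20, spec) {
  if (!"cluster" %in% names(table)) stopf("table lacks a cluster column")
  set.seed(derive_seed(spec$seed, 202L))
  out <- lapply(sort(unique(table$cluster)), function(cl) {
    idx <- which(table$cluster == cl)
    if (n_per_cluster > length(idx))
      stopf("n_per_cluster (%d) exceeds cluster %s size (%d)",
            n_per_cluster, cl, length(idx))
    sel <- sample(idx, n_per_cluster)
    data.frame(patient_id = table$patient_id[sel],
               cluster = cl,
               reading_1 = table$PSD[sel] + rnorm(n_per_cluster, 0, spec$replicate_sd),
               reading_2 = table$PSD[sel] + rnorm(n_per_cluster, 0, spec$replicate_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort as UTF-8 CSV and the ground truth as a JSON sidecar.
#'
#' @param cohort,truth As returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  write.csv(cohort, csv, row.names = FALSE)
  js <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(cohort = csv, truth = js))
}
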