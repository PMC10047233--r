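#' Class-conditional effect configuration for synthetic patient tables
#'
#' Controls how strongly the five diagnostic classes separate in feature
#' space. Continuous features (age and the four perfusion descriptors) are
#' drawn from class-conditional Gaussians whose means are shifted by
#' `separation` standard deviations along a fixed sign pattern that makes
#' all five classes pairwise distinguishable; `separation = 0` removes all
#' label signal. Binary covariates get class-specific rates only when
#' `separation > 0`.
#'
#' @param separation mean shift in units of the feature standard
#'   deviation; 3 (the default) is a strongly separable setting, 0 a
#'   pure-noise null.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(separation = 3) {
  stopifnot(separation >= 0)
  base_mean <- c(Age = 65, `Maximum Intensity` = 120,
                 `Area Under the Curve` = 9000, `Mean Transit Time` = 45,
                 `Time to Peak` = 25)
  base_sd <- c(Age = 10, `Maximum Intensity` = 25,
               `Area Under the Curve` = 2000, `Mean Transit Time` = 12,
               `Time to Peak` = 8)
  # sign pattern, classes x continuous features: every class sits at a
  # vertex of the +-1 hypercube (pairwise Hamming distance >= 2), so all
  # pairs are linearly separable with margin and no class is enclosed by
  # the others
  pattern <- matrix(c( 1,  1,  1, -1, -1,
                       1, -1, -1,  1, -1,
                      -1,  1, -1, -1,  1,
                      -1, -1,  1,  1,  1,
                       1, -1,  1, -1,  1),
                    nrow = 5, byrow = TRUE,
                    dimnames = list(label_names(), names(base_mean)))
  p_female <- c(0.20, 0.35, 0.50, 0.65, 0.80)
  # cirrhosis/hepatitis prevalence falls steeply from HCC to benign classes
  p_cirrhosis <- if (separation > 0) c(0.90, 0.65, 0.40, 0.20, 0.05)
                 else rep(0.40, 5)
  p_hepatitis <- if (separation > 0) c(0.70, 0.50, 0.30, 0.15, 0.05)
                 else rep(0.20, 5)
  structure(list(separation = separation, base_mean = base_mean,
                 base_sd = base_sd, pattern = pattern,
                 p_female = if (separation > 0) p_female else rep(0.4, 5),
                 p_cirrhosis = p_cirrhosis, p_hepatitis = p_hepatitis),
            class = "effect_config")
}

#' Generate a synthetic patient feature table
#'
#' Emits `n` patient records with the 8 feature columns of
#' [feature_names()] (gender coded 1 = male / 2 = female, 0/1 history
#' booleans) and one-hot label columns of [label_names()]. Class
#' assignment is multinomial with the given proportions; the default
#' mirrors a hepatocellular-carcinoma-dominant cohort (40.67% HCC).
#'
#' @param n number of records (>= 5).
#' @param class_proportions 5-vector summing to 1.
#' @param effect an [effect_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return Data frame with 13 columns (8 features, 5 one-hot labels).
#' @export
generate_patient_table <- function(n,
                                   class_proportions = c(0.4067, 0.15,
                                                         0.15, 0.15,
                                                         0.1433),
                                   effect = effect_config(), seed = 1L) {
  stopifnot(n >= 5, length(class_proportions) == 5,
            abs(sum(class_proportions) - 1) < 1e-6,
            inherits(effect, "effect_config"))
  with_seed(seed, {
    cls <- sample.int(5, n, replace = TRUE, prob = class_proportions)
    gender <- 1L + rbinom(n, 1, effect$p_female[cls])
    cirr <- rbinom(n, 1, effect$p_cirrhosis[cls])
    hep <- rbinom(n, 1, effect$p_hepatitis[cls])
    cont <- sapply(names(effect$base_mean), function(f) {
      mu <- effect$base_mean[[f]] +
        effect$separation * effect$base_sd[[f]] * effect$pattern[cls, f]
      rnorm(n, mu, effect$base_sd[[f]])
    })
    cont[, "Age"] <- clamp(round(cont[, "Age"]), 18, 100)
    onehot <- matrix(0L, n, 5, dimnames = list(NULL, label_names()))
    onehot[cbind(seq_len(n), cls)] <- 1L
    out <- data.frame(Gender = gender, Age = cont[, "Age"],
                      `Cirrhosis History` = cirr,
                      `Hepatitis History` = hep,
                      `Maximum Intensity` = cont[, "Maximum Intensity"],
                      `Area Under the Curve` = cont[, "Area Under the Curve"],
                      `Mean Transit Time` = cont[, "Mean Transit Time"],
                      `Time to Peak` = cont[, "Time to Peak"],
                      check.names = FALSE)
    cbind(out, as.data.frame(onehot, check.names = FALSE))
  })
}

#' Write or read a patient table as CSV
#'
#' Uses the exact schema column names; decimal points are always `.`.
#' @param data patient table from [generate_patient_table()] or
#'   [run_build_dataset()].
#' @param path CSV path.
#' @return `read_patient_csv` returns the data frame.
#' @export
write_patient_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  read.csv(path, check.names = FALSE)
}
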