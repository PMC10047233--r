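#' Pipeline configuration
#'
#' Bundles the tunable knobs of the end-to-end run. Defaults mirror the
#' reference protocol: 10 x 10 dilation kernel, 75% probe-lift rejection
#' rule, Savitzky--Golay window 51 / order 3, 1 Hz sampling, and the
#' classifier training defaults of [train_config()].
#'
#' @param regions region coordinates ([default_regions()]).
#' @param kernel_size dilation kernel side in pixels.
#' @param reject_fraction probe-lift validity threshold.
#' @param window,polyorder Savitzky--Golay parameters.
#' @param split_fraction training fraction of [run_train_eval()].
#' @param classifier a [train_config()].
#' @param output_dir where run artifacts (CSVs) are written.
#' @param seed master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(regions = default_regions(), kernel_size = 10,
                            reject_fraction = 0.75, window = 51,
                            polyorder = 3, split_fraction = 0.70,
                            classifier = train_config(),
                            output_dir = tempdir(), seed = 1L) {
  structure(list(regions = regions, kernel_size = kernel_size,
                 reject_fraction = reject_fraction, window = window,
                 polyorder = polyorder, split_fraction = split_fraction,
                 classifier = classifier, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

clinical_fields <- function() feature_names()[1:4]

validate_clinical <- function(record) {
  rec <- as.list(record)
  miss <- setdiff(clinical_fields(), names(rec))
  if (length(miss))
    stop("clinical record is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rec
}

#' Extract a time-intensity curve and its parameters from one video
#'
#' Convenience composition of [sample_tic()], [smooth_tic()] and
#' [extract_params()].
#'
#' @param frames a [frame_sequence()] (or phantom).
#' @param provider a [mask_provider()].
#' @param config a [pipeline_config()].
#' @return `list(curve =, smoothed =, params =)`.
#' @export
extract_tic <- function(frames, provider, config = pipeline_config()) {
  curve <- sample_tic(frames, provider, regions = config$regions,
                      kernel = structuring_element(config$kernel_size),
                      reject_fraction = config$reject_fraction)
  smoothed <- smooth_tic(curve, window = config$window,
                         polyorder = config$polyorder)
  list(curve = curve, smoothed = smoothed,
       params = extract_params(smoothed, "lesion"))
}

#' Predict the lesion class for one investigation
#'
#' Runs the full inference pipeline: masks, TIC extraction, smoothing,
#' parameter extraction, then the classifier over the perfusion
#' descriptors joined with the clinical record. Writes the per-second
#' curve CSV, the parameter CSV and a per-class probability report under
#' `config$output_dir`.
#'
#' @param frames a [frame_sequence()] or directory path for [read_video()].
#' @param clinical named list/row with the fields `Gender`, `Age`,
#'   `Cirrhosis History`, `Hepatitis History`.
#' @param provider a [mask_provider()].
#' @param classifier a fitted `ceus_classifier`.
#' @param config a [pipeline_config()].
#' @return `list(curve, smoothed, params, probabilities, files)`; the
#'   probabilities are a named 5-vector summing to 1.
#' @export
run_predict <- function(frames, clinical, provider, classifier,
                        config = pipeline_config()) {
  if (is.character(frames)) frames <- read_video(frames)
  rec <- validate_clinical(clinical)
  tic <- extract_tic(frames, provider, config)
  feats <- data.frame(
    Gender = rec$Gender, Age = rec$Age,
    `Cirrhosis History` = rec[["Cirrhosis History"]],
    `Hepatitis History` = rec[["Hepatitis History"]],
    `Maximum Intensity` = tic$params$max_intensity,
    `Area Under the Curve` = tic$params$auc,
    `Mean Transit Time` = tic$params$mtt,
    `Time to Peak` = tic$params$ttp, check.names = FALSE)
  probs <- predict(classifier, feats)[1, ]

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(tic = file.path(config$output_dir, "tic.csv"),
             params = file.path(config$output_dir, "tic_params.csv"),
             probs = file.path(config$output_dir, "prediction.csv"))
  write_tic_csv(tic$smoothed, files["tic"], params = tic$params,
                params_path = files["params"])
  write.csv(data.frame(label = names(probs), probability = unname(probs)),
            files["probs"], row.names = FALSE)
  list(curve = tic$curve, smoothed = tic$smoothed, params = tic$params,
       probabilities = probs, files = files)
}

#' Build a feature dataset from several investigations
#'
#' One row per lesion: the 8 feature columns followed by the 5 one-hot
#' label columns. Videos whose curves yield fewer than 3 valid seconds (or
#' that fail any stage) are skipped with a warning and counted in the
#' `skipped` attribute.
#'
#' @param videos list of [frame_sequence()] objects or directory paths.
#' @param records list of clinical records (see [run_predict()]).
#' @param labels character vector of class labels (from [label_names()]).
#' @param providers a single [mask_provider()] or a list, one per video.
#' @param config a [pipeline_config()].
#' @return Data frame with 13 columns in schema order.
#' @export
run_build_dataset <- function(videos, records, labels, providers,
                              config = pipeline_config()) {
  stopifnot(length(videos) >= 1, length(videos) == length(records),
            length(videos) == length(labels),
            all(labels %in% label_names()))
  if (inherits(providers, "mask_provider"))
    providers <- rep(list(providers), length(videos))
  rows <- list()
  skipped <- 0L
  for (i in seq_along(videos)) {
    row <- tryCatch({
      frames <- videos[[i]]
      if (is.character(frames)) frames <- read_video(frames)
      rec <- validate_clinical(records[[i]])
      tic <- extract_tic(frames, providers[[i]], config)
      oh <- as.integer(label_names() == labels[i])
      cbind(data.frame(
        Gender = rec$Gender, Age = rec$Age,
        `Cirrhosis History` = rec[["Cirrhosis History"]],
        `Hepatitis History` = rec[["Hepatitis History"]],
        `Maximum Intensity` = tic$params$max_intensity,
        `Area Under the Curve` = tic$params$auc,
        `Mean Transit Time` = tic$params$mtt,
        `Time to Peak` = tic$params$ttp, check.names = FALSE),
        as.data.frame(as.list(stats::setNames(oh, label_names())),
                      check.names = FALSE))
    }, error = function(e) {
      warning("video ", i, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) skipped <- skipped + 1L else
      rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Train and evaluate the classifier on a feature dataset
#'
#' The reference protocol: stratified 70/30 split, feature z-scoring from
#' the training split, oversampling of the training split only, focal
#' cross-entropy + RMSProp training, then the four multiclass metrics on
#' both splits.
#'
#' @param data feature data frame (13 schema columns).
#' @param config a [pipeline_config()].
#' @return `list(model, report, history, split)`: `report` is a 2-row data
#'   frame (training, validation) with columns `Categorical Accuracy`,
#'   `F1 Micro`, `F1 Macro`, `MCC`.
#' @export
run_train_eval <- function(data, config = pipeline_config()) {
  sp <- split_dataset(data, fraction = config$split_fraction,
                      seed = config$seed)
  model <- train_classifier(sp$train, validation = sp$validation,
                            config = config$classifier)
  eval_split <- function(d) {
    p <- predict(model, d)
    metrics_report(confusion_matrix(dataset_labels(d),
                                    label_names()[max.col(p)],
                                    levels = label_names()))
  }
  report <- as.data.frame(rbind(Training = eval_split(sp$train),
                                Validation = eval_split(sp$validation)),
                          check.names = FALSE)
  list(model = model, report = report, history = model$history, split = sp)
}
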