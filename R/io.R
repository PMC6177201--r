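#' Read a labelled dataset from delimited text
#'
#' Expects a header row and columns `trial_id`, `class`, `subclass`, followed
#' by the feature columns `f1..fd`. The nesting invariant (each subclass
#' belongs to exactly one class) is validated on load.
#'
#' @param file Path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param sep Field separator, default comma.
#' @return A [nested_data()] object.
#' @export
read_dataset <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("trial_id", "class", "subclass")
  if (!all(required %in% names(df)))
    stop("dataset file must have columns trial_id, class, subclass, f1..fd")
  feat_cols <- setdiff(names(df), required)
  if (length(feat_cols) == 0L) stop("no feature columns (f1..fd) found")
  nested_data(
    features = as.matrix(df[, feat_cols, drop = FALSE]),
    class_labels = df$class,
    subclass_labels = df$subclass)
}

#' Write a labelled dataset to delimited text
#'
#' Inverse of [read_dataset()]: columns `trial_id`, `class`, `subclass`,
#' `f1..fd` with a header row.
#'
#' @param data A [nested_data()] object.
#' @param file Output path.
#' @param sep Field separator, default comma.
#' @return `file`, invisibly.
#' @export
write_dataset <- function(data, file, sep = ",") {
  if (!inherits(data, "nested_data")) stop("'data' must be a nested_data object")
  d <- ncol(data$features)
  df <- data.frame(trial_id = seq_len(nrow(data$features)),
                   class = data$class, subclass = data$subclass)
  feats <- as.data.frame(data$features)
  names(feats) <- paste0("f", seq_len(d))
  utils::write.table(cbind(df, feats), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a run configuration file
#'
#' Parses a YAML configuration with flat key-value sections `simulate`,
#' `classify`, `permute` and `sweep`. Only the `simulate` section is
#' interpreted by the package itself (via [sim_params_from_config()]); the
#' other sections are returned verbatim for the command-line drivers.
#'
#' @param file Path to a YAML file.
#' @return Named list of sections.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.list(cfg)) stop("configuration file must contain key-value sections")
  cfg
}

#' Simulation parameters from a configuration section
#'
#' @param config A list as returned by [read_config()], or the `simulate`
#'   section itself.
#' @return A [sim_params()] object.
#' @export
sim_params_from_config <- function(config) {
  sec <- if (!is.null(config$simulate)) config$simulate else config
  args <- sec[intersect(names(sec),
                        c("d", "K", "N", "sigma_C", "sigma_S", "sigma_W", "seed"))]
  do.call(sim_params, args)
}

#' Serialise simulation parameters to a configuration file
#'
#' @param params A [sim_params()] object.
#' @param file Output YAML path.
#' @return `file`, invisibly.
#' @export
write_config <- function(params, file) {
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params object")
  sec <- params[c("d", "K", "N", "sigma_C", "sigma_S", "sigma_W")]
  if (!is.null(params$seed)) sec$seed <- params$seed
  yaml::write_yaml(list(simulate = sec), file)
  invisible(file)
}
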