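#' Read a survival table from delimited text
#'
#' Expects a comma-separated file with a header containing at least the
#' columns `y` (positive observed time) and `delta` (0/1 event indicator);
#' all remaining columns are treated as covariates in file order.
#'
#' @param path file path.
#' @return a [survival_dataset()].
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("y", "delta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  covs <- setdiff(names(df), need)
  X <- as.matrix(df[, covs, drop = FALSE])
  survival_dataset(df$y, df$delta, X, covs)
}

#' @rdname read_survival_table
#' @param data a [survival_dataset()].
#' @export
write_survival_table <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(y = data$y, delta = data$delta, check.names = FALSE)
  if (ncol(data$X) > 0) df <- cbind(df, as.data.frame(data$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.FIT_FORMAT_VERSION <- "copboost-fit-1"

#' Serialize / restore a boosted fit as JSON
#'
#' Lossless round trip of offsets, centering means, update trace, risk paths
#' and the selected stopping iteration; numbers are written at full
#' precision.
#'
#' @param fit a `boost_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "boost_fit"))
  spec_desc <- if (fit$type == "copula") {
    list(margin_T = fit$spec$margin_T$family,
         margin_C = fit$spec$margin_C$family,
         copula = fit$spec$copula$family)
  } else {
    list(margin_T = fit$spec$family)
  }
  obj <- list(format = .FIT_FORMAT_VERSION, type = fit$type,
              spec = spec_desc,
              param_names = fit$param_names,
              offsets = unname(fit$offsets),
              centers = unname(fit$centers),
              covariate_names = fit$covariate_names,
              nu = fit$nu, mstop_max = fit$mstop_max, mstop = fit$mstop,
              trace = fit$trace,
              risk_train = fit$risk_train, risk_val = fit$risk_val)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) .stopf("fit file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, .FIT_FORMAT_VERSION))
    .stopf("unsupported fit file format: %s (expected %s)",
           if (is.null(obj$format)) "<none>" else obj$format,
           .FIT_FORMAT_VERSION)
  spec <- if (obj$type == "copula") {
    model_spec(margin_spec(obj$spec$margin_T), margin_spec(obj$spec$margin_C),
               copula_spec(obj$spec$copula))
  } else {
    margin_spec(obj$spec$margin_T)
  }
  trace <- as.data.frame(obj$trace)
  if (nrow(trace) == 0)
    trace <- data.frame(iteration = integer(), param = integer(),
                        learner = integer(), increment = numeric())
  structure(list(type = obj$type, spec = spec,
                 param_names = obj$param_names,
                 offsets = stats::setNames(obj$offsets, obj$param_names),
                 centers = as.numeric(obj$centers),
                 covariate_names = obj$covariate_names,
                 nu = obj$nu, mstop_max = obj$mstop_max, mstop = obj$mstop,
                 trace = trace,
                 risk_train = obj$risk_train,
                 risk_val = obj$risk_val),
            class = "boost_fit")
}

#' Export the selected coefficients as a delimited table
#'
#' One row per covariate, one column per distribution parameter; covariates
#' never selected for a parameter are left blank.
#'
#' @param fit a `boost_fit`.
#' @param path file path.
#' @param at_iteration iteration at which to extract coefficients.
#' @export
write_coef_table <- function(fit, path, at_iteration = NULL) {
  cf <- coef(fit, at_iteration)
  tab <- rbind(`(Intercept)` = cf$intercepts, cf$beta)
  out <- as.data.frame(ifelse(tab == 0 & row(tab) > 1, NA, tab))
  out <- cbind(term = rownames(tab), out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# truth sidecar: per-row true parameters plus the generating families
write_truth_sidecar <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(format = "copboost-truth-1",
              margin = truth$spec$margin_T$family,
              copula = truth$spec$copula$family,
              params = as.data.frame(truth$params),
              T = truth$T, C = truth$C)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_truth_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "copboost-truth-1"))
    .stopf("unsupported truth sidecar format")
  spec <- model_spec(margin_spec(obj$margin), margin_spec(obj$margin),
                     copula_spec(obj$copula))
  structure(list(T = obj$T, C = obj$C, params = as.matrix(obj$params),
                 spec = spec),
            class = "sim_truth")
}
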