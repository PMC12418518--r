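# Run configuration: one record gathering every knob of a training run.
# Defaults follow the reference hyperparameter table (batch 128, N = 200,
# eta_v = 0.01, eta_theta = 0.01, beta = 1, threshold 1e-7).

#' Training-run configuration
#'
#' @param batch_size Samples per gradient update.
#' @param N Maximum number of inference iterations per batch.
#' @param eta_v Inference-phase (state) step size.
#' @param eta_theta Learning-phase (parameter) step size.
#' @param beta External-energy scale in `[0, 1]`.
#' @param threshold Energy convergence threshold for the inference loop.
#' @param method Learning rule: `"hpc"`, `"bipc_additive"`, `"bipc_combined"`,
#'   `"ep"` or `"backprop"`.
#' @param optimizer `"sgd"`, `"adam"` or `"lalr"`.
#' @param architecture Architecture name for [build_graph()].
#' @param epochs Training epochs.
#' @param seed Master seed: parameter initialization and data order all
#'   derive from it.
#' @param loss_f Output loss kind.
#' @return A `run_config` list.
#' @export
run_config <- function(batch_size = 128L, N = 200L, eta_v = 0.01,
                       eta_theta = 0.01, beta = 1, threshold = 1e-7,
                       method = "bipc_combined", optimizer = "lalr",
                       architecture = "toy_chain", epochs = 5L, seed = 0L,
                       loss_f = "cross_entropy") {
  stopifnot(batch_size >= 1, N >= 1, eta_v > 0, eta_theta > 0,
            beta >= 0, beta <= 1, threshold > 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size), N = as.integer(N),
                 eta_v = eta_v, eta_theta = eta_theta, beta = beta,
                 threshold = threshold, method = method, optimizer = optimizer,
                 architecture = architecture, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss_f = loss_f),
            class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param cfg A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path A YAML file written by [write_run_config()] (unknown keys are
#'   rejected).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
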