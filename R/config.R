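#' Default run configuration
#'
#' All tunables of the end-to-end pipeline in one flat, serialisable list.
#' Every field has a documented default; [write_config()] prints the fully
#' resolved configuration into each output directory for provenance.
#'
#' Fields:
#' \describe{
#'   \item{phantom, size, voxel_size, contrast}{scene settings for
#'     [generate_phantom()].}
#'   \item{counts_target}{total expected true counts the activity is scaled
#'     to (default 1e6, a realistic 2D slice count level).}
#'   \item{scatter_fraction, efficiency}{acquisition factor settings.}
#'   \item{n_views}{view count (`NULL`: one view per image column).}
#'   \item{n_subsets}{angular subsets for all subset algorithms.}
#'   \item{beta, gamma, epsilon_rel, delta_rel}{prior strength, edge
#'     preservation, and the OSEM-relative epsilon/delta factors.}
#'   \item{alpha0, eta}{relaxed step schedule for the reference and the
#'     BSREM challenger.}
#'   \item{svrg_alpha0, svrg_eta, svrg_warmup_epochs}{SVRG challenger step
#'     settings; per-algorithm step tuning is part of the protocol. The
#'     smaller constant step keeps the variance-reduced updates stable.}
#'   \item{osem_epochs}{epochs of the OSEM initialiser.}
#'   \item{reference_max_updates, challenger_max_updates}{update budgets.}
#'   \item{algorithms, runs}{challenger set and repeats per algorithm.}
#'   \item{whole_rmse, background_rmse, voi_aem, persistence, time_cap}{the
#'     convergence thresholds and censoring cap.}
#'   \item{timing}{`"updates"` (deterministic pseudo-clock) or `"wall"`.}
#'   \item{seed}{master seed; all other seeds derive from it.}
#' }
#' @param ... overrides of the defaults by name.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    phantom = "nema_like", size = 64L, voxel_size = 3, contrast = 4,
    counts_target = 1e6, scatter_fraction = 0.1, efficiency = 1,
    n_views = NULL, n_subsets = 8L,
    beta = 1, gamma = 2, epsilon_rel = 1e-4, delta_rel = 1e-6,
    alpha0 = 1, eta = 0.1, osem_epochs = 2L,
    svrg_alpha0 = 0.1, svrg_eta = 0.05, svrg_warmup_epochs = 20L,
    reference_max_updates = 10000L, challenger_max_updates = 3000L,
    algorithms = c("bsrem", "svrg"), runs = 3L,
    whole_rmse = 0.01, background_rmse = 0.01, voi_aem = 0.005,
    persistence = 10L, time_cap = 3600,
    timing = "updates", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$size >= 16, cfg$contrast > 0, cfg$counts_target > 0,
            cfg$beta > 0, cfg$gamma >= 0, cfg$epsilon_rel > 0,
            cfg$delta_rel > 0, cfg$alpha0 > 0, cfg$eta >= 0,
            cfg$svrg_alpha0 > 0, cfg$svrg_eta >= 0,
            cfg$svrg_warmup_epochs >= 0,
            cfg$runs >= 1, cfg$persistence >= 1, cfg$time_cap > 0,
            cfg$timing %in% c("updates", "wall"),
            all(cfg$algorithms %in% c("osem", "bsrem", "svrg")))
  invisible(cfg)
}

#' Write a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the [run_config()] defaults; unknown fields
#' are rejected.
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

# derive a bounded child seed from the master seed and a label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

log_line <- function(logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", sep = "", file = logfile, append = TRUE)
  invisible(msg)
}
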