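#' Write all fit artifacts to a directory
#'
#' Writes the machine-readable outputs of a [fit_wall_orientation()] run:
#' \itemize{
#'   \item `samples.csv` — one row per orientation sample (stack, slice,
#'     depth, normalized depth, angle, eigen ratio, area);
#'   \item `kde.csv` — the density surface in long format
#'     (z_n, alpha_deg, density);
#'   \item `octiles.csv` — the seven octile curves over depth;
#'   \item `dispersion.csv` — per-depth 25/50/75th percentiles of per-stack
#'     circular SDs (when fitted to >= 2 stacks);
#'   \item `density_<stack>.csv` — per-slice cell densities;
#'   \item `report.json` — filter-chain counts per stack and the parameters
#'     used (provenance echo).
#' }
#'
#' @param fit a `wall_orientation` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  kde_long <- data.frame(
    z_n = rep(fit$kde$depth, times = length(fit$kde$angle)),
    alpha_deg = rep(fit$kde$angle, each = length(fit$kde$depth)),
    density = as.vector(fit$kde$density))
  utils::write.csv(kde_long, file.path(dir, "kde.csv"), row.names = FALSE)
  oct <- data.frame(z_n = fit$octiles$depth, mean_deg = fit$octiles$mean_deg,
                    fit$octiles$octiles)
  names(oct)[3:9] <- sprintf("q%d_8", 1:7)
  utils::write.csv(oct, file.path(dir, "octiles.csv"), row.names = FALSE)
  if (!is.null(fit$dispersion))
    utils::write.csv(fit$dispersion, file.path(dir, "dispersion.csv"),
                     row.names = FALSE)
  for (id in names(fit$density)) {
    safe <- gsub("[^A-Za-z0-9._-]+", "_", id)
    utils::write.csv(fit$density[[id]],
                     file.path(dir, sprintf("density_%s.csv", safe)),
                     row.names = FALSE)
  }
  report <- list(
    n_samples = nrow(fit$samples),
    stacks = names(fit$density),
    lm_thickness_um = as.list(fit$lm_thickness_um),
    filter_chain = fit$counts,
    parameters = list(cellness = unclass(fit$cellness),
                      kde = unclass(fit$kde_params),
                      delta_max_um = fit$delta_max,
                      min_ratio = fit$min_ratio,
                      dispersion_depths = fit$dispersion_depths,
                      dispersion_window = fit$dispersion_window),
    version = as.character(utils::packageVersion("tubeorient")))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
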