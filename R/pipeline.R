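#' Run configuration for the spectral pipelines
#'
#' Builds and validates the configuration driving [run_validate_sphere()]
#' and [run_analyze_leadfield()]. Accepts a YAML file path or a named list;
#' unspecified entries take the defaults below, which reproduce the
#' full-scale spherical study (six layouts from 34 to 4000 sensors on a
#' 92 mm sphere, a 7700-source ensemble over 77 shells).
#'
#' @param x `NULL` (all defaults), a YAML file path, or a named list.
#' @param ... individual overrides, e.g. `per_shell = 20`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(x = NULL, ...) {
  defaults <- list(
    layout_sizes = c(34, 104, 232, 462, 938, 4000),
    deviation_layout_sizes = c(34, 104),
    dense_layout_size = 4000,
    radius = 92,
    shell_radii = c(80, 81, 86, 92),
    conductivities = c(0.33, 1.79, 0.0066, 0.33),
    series_tol = 1e-10,
    l_max_cap = 600,
    l_max = 15,
    ensemble_radii = 0:76,
    per_shell = 100,
    spectrum_radii = c(0, 30, 50, 70, 76),
    spectrum_per_shell = 100,
    n_depth_groups = 6,
    n_reference_deepest = 15,
    seed = 1,
    percentiles = c(0.5, 0.9, 0.99, 0.999)
  )
  user <- if (is.null(x)) list()
    else if (is.character(x)) yaml::read_yaml(x)
    else if (is.list(x)) x
    else stop("`x` must be NULL, a file path or a list")
  user <- utils::modifyList(user, list(...))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)

  stopifnot(
    all(cfg$layout_sizes >= 4),
    all(cfg$deviation_layout_sizes %in% cfg$layout_sizes),
    cfg$dense_layout_size %in% cfg$layout_sizes,
    length(cfg$shell_radii) == 4, all(diff(cfg$shell_radii) > 0),
    length(cfg$conductivities) == 4, all(cfg$conductivities > 0),
    cfg$series_tol > 0, cfg$l_max_cap >= 1, cfg$l_max >= 1,
    all(cfg$ensemble_radii < cfg$shell_radii[1]),
    cfg$per_shell >= 1, cfg$spectrum_per_shell >= 1,
    cfg$n_depth_groups >= 1, cfg$seed == round(cfg$seed)
  )
  if (abs(cfg$radius - cfg$shell_radii[4]) > 1e-9)
    stop("`radius` must equal the outer shell radius")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))
}

#' Spherical validation pipeline
#'
#' End-to-end run of the spherical-model analyses: layout generation and
#' Nyquist statistics, depth-dependent energy gain, per-degree term
#' spectra, discrete-sampling energy deviations, and the spherical-harmonic
#' versus Sphara spectral comparison on the densest layout. Writes delimited
#' tables plus a machine-readable `summary.json`, and returns the results
#' invisibly.
#'
#' @param config a [run_config()] (or anything accepted by it).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with elements `layouts`, `energy_gain`,
#'   `term_spectrum`, `deviations`, `deviation_stats`, `sh_spectrum`,
#'   `sphara_spectrum`, `comparison`, `summary`.
#' @export
run_validate_sphere <- function(config = run_config(), out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_resolved_config(cfg, out_dir)
  model <- shell_model(cfg$shell_radii, cfg$conductivities)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  layouts <- stage("layouts", sensor_layouts(cfg$layout_sizes,
                                             radius = cfg$radius,
                                             seed = cfg$seed))
  gain <- stage("energy_gain",
                energy_gain_curve(model, radii = cfg$ensemble_radii,
                                  tol = cfg$series_tol,
                                  l_max_cap = cfg$l_max_cap))
  tspec <- stage("term_spectrum",
                 term_spectrum(model, radii = cfg$spectrum_radii,
                               l_max = cfg$l_max))

  ens <- stage("ensemble",
               dipole_ensemble(radii = cfg$ensemble_radii,
                               per_shell = cfg$per_shell,
                               seed = cfg$seed, model = model))
  dev_layouts <- layouts[layouts$n %in% cfg$deviation_layout_sizes, ]
  devs <- stage("deviations",
                sampled_energy_deviation(dev_layouts, model, ens,
                                         tol = cfg$series_tol,
                                         l_max_cap = cfg$l_max_cap))
  dev_stats <- dplyr::summarise(
    dplyr::group_by(devs, .data$layout_n),
    max_abs_rel_dev_pct = 100 * max(abs(.data$rel_dev)),
    median_underestimation_pct = 100 * stats::median(-.data$rel_dev),
    frac_underestimated = mean(.data$rel_dev <= 0),
    .groups = "drop"
  )

  # spectral comparison on the densest layout
  dense_mesh <- layouts$mesh[[which(layouts$n == cfg$dense_layout_size)]]
  sub_ens <- stage("spectrum_ensemble",
                   dipole_ensemble(radii = cfg$spectrum_radii,
                                   per_shell = cfg$spectrum_per_shell,
                                   seed = cfg$seed, model = model))
  fields <- stage("spectrum_fields",
                  t(pseudo_leadfield(dense_mesh, sub_ens, model,
                                     tol = cfg$series_tol,
                                     l_max_cap = cfg$l_max_cap)))
  shsp <- stage("sh_spectrum", {
    coef <- sh_expand_lsq(dense_mesh$vertices, fields, cfg$l_max)
    e_by_l <- t(rowsum(coef^2, attr(coef, "l"))) * 4 * pi *
      (model$radii[4] * 1e-3)^2
    spectrum_tibble(e_by_l, sub_ens, method = "sh")
  })
  basis <- stage("sphara_basis",
                 sphara_basis(dense_mesh, n_modes = (cfg$l_max + 1)^2))
  spsp <- stage("sphara_spectrum",
                sphara_spectrum(basis, model, sub_ens, l_max = cfg$l_max,
                                fields = fields))
  spsp_mode <- stage("sphara_spectrum_modes",
                     sphara_spectrum(basis, model, sub_ens,
                                     l_max = cfg$l_max, by = "mode",
                                     fields = fields))
  cmp <- stage("comparison",
               compare_spectra(dplyr::filter(shsp, .data$l >= 1), spsp[spsp$l >= 1, ]))

  # within-depth spread of per-degree Sphara contributions
  spread <- dplyr::summarise(
    dplyr::group_by(spsp, .data$radius_mm, .data$orientation_class, .data$l),
    sd_pct = 100 * stats::sd(.data$fraction),
    .groups = "drop"
  )

  dc_sh <- dplyr::filter(shsp, .data$l == 0)

  summary <- list(
    layout_stats = as.data.frame(layouts[, c("n", "n_triangles", "h_mean",
                                             "h_sd", "h_max", "lambda_n",
                                             "omega_n")]),
    radial_gain_76 = with(gain, ratio[radius_mm == max(radius_mm) &
                                        orientation == "radial"]),
    tangential_gain_76 = with(gain, ratio[radius_mm == max(radius_mm) &
                                            orientation == "tangential"]),
    deviation_stats = as.data.frame(dev_stats),
    max_dc_db = max(dc_sh$db),
    sh_vs_sphara_max_diff_pct = cmp$max_abs_diff,
    sh_vs_sphara_median_diff_pct = cmp$median_abs_diff,
    max_within_depth_sd_pct = max(spread$sd_pct, na.rm = TRUE),
    seed = cfg$seed
  )

  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(as.data.frame(layouts[, setdiff(names(layouts), "mesh")]), "layout_stats.tsv")
  wt(gain, "energy_gain.tsv")
  wt(tspec, "term_spectrum.tsv")
  wt(devs, "deviations.tsv")
  wt(dev_stats, "deviation_stats.tsv")
  wt(shsp, "sh_spectrum.tsv")
  wt(spsp, "sphara_spectrum.tsv")
  wt(spread, "sphara_within_depth_sd.tsv")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)

  invisible(list(layouts = layouts, energy_gain = gain, term_spectrum = tspec,
                 deviations = devs, deviation_stats = dev_stats,
                 sh_spectrum = shsp, sphara_spectrum = spsp,
                 sphara_spectrum_modes = spsp_mode,
                 within_depth_spread = spread, comparison = cmp,
                 summary = summary))
}

#' Lead-field spectral analysis pipeline
#'
#' Runs the open-surface route on an imported (or synthetic) lead-field
#' bundle: Sphara basis of the covered surface, per-source spectral
#' decomposition with the median energy of the deepest sources as 0 dB
#' reference, percentile envelopes and depth-group envelopes. Writes
#' delimited tables and `summary.json`.
#'
#' @param bundle a `leadfield_bundle` (see [leadfield_import()],
#'   [open_surface_fixture()]).
#' @param out_dir output directory.
#' @param config a [run_config()] for `l_max`, depth groups, percentiles.
#' @return invisibly, a list with `basis`, `spectra`, `envelopes`,
#'   `depth_envelopes`, `reference_energy`, `summary`.
#' @export
run_analyze_leadfield <- function(bundle, out_dir, config = run_config()) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_resolved_config(cfg, out_dir)
  if (!inherits(bundle, "leadfield_bundle")) stop("`bundle` must be a leadfield_bundle")

  src <- tibble::as_tibble(bundle$sources)
  if (!"depth_mm" %in% names(src))
    src <- source_geometry_metrics(src, outer = cfg$shell_radii[4],
                                   inner = cfg$shell_radii[1])
  if (!"source" %in% names(src)) src$source <- seq_len(nrow(src))

  n_modes <- min((cfg$l_max + 1)^2, nrow(bundle$mesh$vertices))
  basis <- sphara_basis(bundle$mesh, n_modes = n_modes)
  fields <- t(bundle$leadfield)                    # n_vertices x n_sources
  coef <- sphara_analyze(basis, fields)
  e_mode <- coef^2 * 1e-6
  e_tot <- field_energy(fields, basis$B) * 1e-6

  deepest <- utils::head(order(src$depth_mm, decreasing = TRUE),
                         cfg$n_reference_deepest)
  ref <- stats::median(e_tot[deepest])

  ns <- nrow(src)
  spectra <- dplyr::bind_cols(
    src[rep(seq_len(ns), each = n_modes), c("source", "depth_mm")],
    tibble::tibble(mode = rep(seq_len(n_modes), ns),
                   l = rep(mode_degrees(n_modes, cfg$l_max), ns),
                   energy = as.vector(e_mode))
  )
  spectra <- dplyr::mutate(spectra, fraction = .data$energy / ref,
                           db = to_db(.data$fraction))
  attr(spectra, "reference_energy") <- ref
  attr(spectra, "grouping") <- "mode"
  class(spectra) <- c("energy_spectrum", class(spectra))

  env <- percentile_envelopes(spectra, probs = cfg$percentiles)
  denv <- depth_group_envelopes(spectra, n_groups = cfg$n_depth_groups)

  summary <- list(
    n_sources = ns,
    n_vertices = nrow(bundle$mesh$vertices),
    n_modes = n_modes,
    reference_energy = ref,
    reference_source_ids = src$source[deepest],
    max_dc_fraction = max(spectra$fraction[spectra$l == 0]),
    seed = cfg$seed
  )
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(spectra, "sphara_spectrum.tsv")
  wt(env, "percentile_envelopes.tsv")
  wt(denv, "depth_group_envelopes.tsv")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)

  invisible(list(basis = basis, spectra = spectra, envelopes = env,
                 depth_envelopes = denv, reference_energy = ref,
                 summary = summary))
}
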