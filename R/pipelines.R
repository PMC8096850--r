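#' Run the pore-profiling pipeline
#'
#' Wires the pore stages end to end: read (or accept) a model, estimate the
#' channel axis, profile the pore radius, locate constrictions, classify the
#' open/closed state per ion, and render a human-readable report in the dual
#' native(model) residue numbering. With `out_dir` set, the profile,
#' constriction table, state table and report are written as TSV/text with
#' fixed formatting so identical configurations produce byte-identical
#' output.
#'
#' @param config named list: `model` (path or [atomic_model()]), `step`
#'   (A, default 0.5), `z_min`, `z_max`, `r_cap`, `ions` (default
#'   [ion_radii()]), `prominence` (A, default 0.5), `index_map` (default
#'   [index_map()]; `NULL` for single-numbering models), `seed`, `out_dir`.
#' @return List: `axis`, `profile`, `constrictions`, `state`, `report`
#'   (character vector).
#' @export
run_pore_pipeline <- function(config) {
  model <- config$model
  if (is.character(model)) model <- read_model(model)
  if (!inherits(model, "atomic_model") || nrow(model) == 0) {
    abort("config$model must be a non-empty atomic model or a readable file")
  }
  step <- config$step %||% 0.5
  ions <- config$ions %||% ion_radii()
  prominence <- config$prominence %||% 0.5
  imap <- if ("index_map" %in% names(config)) config$index_map else index_map()
  axis <- channel_axis(model)
  profile <- pore_profile(model, axis, z_min = config$z_min,
                          z_max = config$z_max, step = step,
                          r_cap = config$r_cap %||% 30,
                          seed = config$seed %||% 1)
  constr <- find_constrictions(profile, model, ions, prominence)
  state <- classify_state(profile, ions)
  fmt_res <- function(chain, resid) {
    if (is.null(imap)) return(sprintf("%s:%d", chain, resid))
    native <- tryCatch(model_to_native_index(resid, imap),
                       error = function(e) NA_integer_)
    ifelse(is.na(native), sprintf("%s:tag%d", chain, resid),
           sprintf("%s:%s", chain, dual_numbering(native, imap)))
  }
  report <- c(
    sprintf("pore profile: %d planes, z in [%.2f, %.2f] A, step %.2f A",
            nrow(profile), min(profile$z), max(profile$z), step),
    sprintf("minimum pore radius: %.2f A", min(profile$radius)),
    sprintf("constrictions (prominence >= %.2f A): %d", prominence,
            nrow(constr)),
    if (nrow(constr)) sprintf(
      "  z = %+.2f A, radius %.2f A, lined by %s, excludes: %s",
      constr$z, constr$radius,
      fmt_res(constr$chain, constr$resid),
      ifelse(constr$excluded_ions == "", "none", constr$excluded_ions)),
    sprintf("state per ion: %s",
            paste(sprintf("%s %s (margin %+.2f A)", state$ion,
                          ifelse(state$closed, "closed", "open"),
                          state$margin), collapse = "; "))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_tsv(profile, file.path(config$out_dir, "profile.tsv"))
    readr::write_tsv(constr, file.path(config$out_dir, "constrictions.tsv"))
    readr::write_tsv(state, file.path(config$out_dir, "state.tsv"))
    writeLines(report, file.path(config$out_dir, "report.txt"))
  }
  list(axis = axis, profile = profile, constrictions = constr,
       state = state, report = report)
}

write_profile_tsv <- function(profile, path) {
  out <- profile
  out$radius <- sprintf("%.6f", out$radius)
  out$cx <- sprintf("%.6f", out$cx)
  out$cy <- sprintf("%.6f", out$cy)
  readr::write_tsv(out, path)
}

#' Run the synthetic umbrella-sampling / WHAM pipeline
#'
#' Generates the window grid, samples every window from an analytic PMF with
#' the Langevin surrogate, solves WHAM, smooths the profile, optionally
#' re-solves on cumulative trajectory blocks, and reports barriers (mapped
#' to toy-channel residues when a model is supplied).
#'
#' @param config named list: `pmf` (an [analytic_pmf()], default the shipped
#'   double well), `q_start`, `q_end`, `interval`, `replicas`, `force_const`
#'   (window grid; defaults c = 20 kcal/mol/A^2), `n_samples` per window,
#'   `bin_width` (default 0.5 A), `thermo` (default 310 K), `seed`,
#'   `smooth_bins`, `block_ends`, `model`, `out_dir`.
#' @return List: `windows`, `pmf` (`pmf_result`), `barriers`, `convergence`
#'   (or `NULL`).
#' @export
run_pmf_pipeline <- function(config) {
  pmf <- config$pmf %||% analytic_pmf("double_well")
  thermo <- config$thermo %||% thermo_state()
  seed <- config$seed %||% 1
  grid <- make_windows(q_start = config$q_start %||% 12,
                       q_end = config$q_end %||% -12,
                       interval = config$interval %||% 1,
                       replicas = config$replicas %||% 1,
                       force_const = config$force_const %||% 20)
  windows <- sample_windows(pmf, grid,
                            n_samples = config$n_samples %||% 5000,
                            thermo = thermo, seed = seed)
  result <- wham_solve(windows, thermo = thermo,
                       bin_width = config$bin_width %||% 0.5)
  result <- smooth_pmf(result, config$smooth_bins %||% 5)
  barriers <- barrier_report(result, model = config$model,
                             prominence = config$barrier_prominence %||% 1)
  conv <- if (!is.null(config$block_ends)) {
    convergence_profile(windows, config$block_ends, thermo = thermo,
                        bin_width = config$bin_width %||% 0.5)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    bins <- result$bins
    bins$A <- sprintf("%.6f", bins$A)
    bins$P <- sprintf("%.6e", bins$P)
    if ("A_smooth" %in% names(bins)) bins$A_smooth <- sprintf("%.6f", bins$A_smooth)
    readr::write_tsv(bins, file.path(config$out_dir, "pmf.tsv"))
    readr::write_tsv(barriers, file.path(config$out_dir, "barriers.tsv"))
  }
  list(windows = windows, pmf = result, barriers = barriers,
       convergence = conv)
}
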