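#' End-to-end experiment configuration
#'
#' Bundles every stage parameter of a full run: tube construction, helical
#' wrap, binding-energy angle scan, synthetic STM rendering and period /
#' orientation analysis. All randomness used downstream is derived from the
#' single `seed`.
#'
#' @param n,m chiral indices.
#' @param n_units tube repeat units.
#' @param sequence DNA sequence string.
#' @param angle_grid construction angles for the scan (degrees).
#' @param fixed_ends end-constraint mode for the scan.
#' @param params an [ff_params()] object.
#' @param delta,L wrap geometry (nm), see [wrap_config()].
#' @param max_iter minimization iteration cap per scan point.
#' @param stm list of STM render settings: `backbone_radius`, `n_coils`,
#'   `strand_radius`, `tip_radius`, `tip_half_angle`, `noise_rms`, `pixel`,
#'   `size`.
#' @param seed master seed.
#' @param out_dir output directory for artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(n = 6, m = 5, n_units = 3,
                       sequence = "GAGAAGAGAGCAGAAGGAGA",
                       angle_grid = seq(10, 80, by = 10), fixed_ends = TRUE,
                       params = ff_params(), delta = 0.33, L = 0.50,
                       max_iter = 2000L,
                       stm = list(backbone_radius = 1.05, n_coils = 3,
                                  strand_radius = 0.30, tip_radius = 2,
                                  tip_half_angle = 30, noise_rms = 0.02,
                                  pixel = 0.05, size = c(21, 21)),
                       seed = 1L, out_dir = tempfile("cntdna_run_")) {
  if (length(angle_grid) == 0) stop("angle_grid must be non-empty")
  structure(list(n = n, m = m, n_units = n_units, sequence = sequence,
                 angle_grid = angle_grid, fixed_ends = fixed_ends,
                 params = params, delta = delta, L = L,
                 max_iter = as.integer(max_iter), stm = stm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes build -> wrap -> scan -> render -> analyze, writing structures
#' (PDB/XYZ), the scan table (CSV) and summary (JSON), topographies (text
#' grid and TIFF) and the analysis results (JSON), plus a manifest with the
#' configuration and md5 checksums of every artifact. Reruns with the same
#' configuration reproduce every artifact bit for bit.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest` (also written as `manifest.json`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  paths <- character(0)
  note <- function(p) { paths <<- c(paths, p); p }
  stage_times <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[cntdna] stage %-8s %.1f s", name, stage_times[[name]]))
    res
  }
  out <- function(f) file.path(config$out_dir, f)

  spec <- nanotube_spec(config$n, config$m, n_units = config$n_units)
  tube <- tick("build", build_nanotube(spec))
  write_xyz(tube, note(out("tube.xyz")))
  write_pdb(tube, note(out("tube.pdb")))

  hybrids <- tick("wrap", generate_initial_configs(
    config$sequence, tube, config$angle_grid, delta = config$delta,
    L = config$L, seed = config$seed, fixed_ends = config$fixed_ends))
  write_pdb(hybrids[[1]], note(out("hybrid_initial.pdb")))

  scan <- tick("scan", scan_binding_vs_angle(
    config$sequence, tube, config$angle_grid, fixed_ends = config$fixed_ends,
    params = config$params, seed = config$seed, delta = config$delta,
    L = config$L, max_iter = config$max_iter))
  write_scan(scan, note(out("scan.csv")), note(out("scan_summary.json")))
  write_pdb(scan$hybrids[[scan$minimum$index]], note(out("hybrid_optimal.pdb")))

  stm <- config$stm
  hp <- helix_param(tube_radius = tube_dimensions(spec)$radius,
                    backbone_radius = stm$backbone_radius,
                    angle_from_axis = 90 - chiral_angle(spec),
                    n_coils = stm$n_coils, strand_radius = stm$strand_radius)
  topo <- tick("render", {
    t0 <- render_surface(hp, size = stm$size, pixel = stm$pixel)
    t1 <- tip_dilate(t0, tip_model("cone", stm$tip_radius, stm$tip_half_angle))
    add_noise(t1, stm$noise_rms, seed = config$seed)
  })
  write_topography(topo, note(out("topography.txt")), "text")
  write_topography(topo, note(out("topography.tif")), "tiff")
  note(out("topography.tif.json"))

  analysis <- tick("analyze", {
    prof <- ridge_profile(topo)
    spec_p <- dominant_period(prof)
    orient <- strand_orientation(topo)
    list(period_nm = spec_p$period, band90 = spec_p$band90,
         n_periods = spec_p$n_periods,
         angle_from_axis = orient$angle_from_axis,
         true_pitch = topo$meta$true_pitch,
         true_angle_from_axis = topo$meta$true_angle_from_axis)
  })
  jsonlite::write_json(analysis, note(out("stm_analysis.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config = list(n = config$n, m = config$m, n_units = config$n_units,
                  sequence = config$sequence, angle_grid = config$angle_grid,
                  fixed_ends = config$fixed_ends, delta = config$delta,
                  L = config$L, max_iter = config$max_iter, stm = stm,
                  seed = config$seed,
                  ff = config$params[c("scale", "cutoff", "r_on", "k_intra",
                                       "k_link", "tol", "max_iter")]),
    minimum = scan$minimum, barrier_ev = scan$barrier_ev,
    stm_analysis = analysis,
    stage_seconds = stage_times,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    artifacts = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}
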