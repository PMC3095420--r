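#!/usr/bin/env Rscript

# Thin command-line front end over the package API.
#
#   Rscript scripts/cntdna.R build-tube --n 6 --m 5 --units 3 --out tube.xyz
#   Rscript scripts/cntdna.R wrap --sequence CCCC --n 6 --m 5 --units 3 \
#       --alpha 45 --out hybrid.pdb
#   Rscript scripts/cntdna.R scan --sequence C25 --grid 10:80:5 --fix-ends \
#       --seed 1 --out scan.csv
#   Rscript scripts/cntdna.R stm-sim --pitch 3.3 --coils 3 --tip-radius 2 \
#       --noise 0.02 --seed 1 --out topo.txt
#   Rscript scripts/cntdna.R stm-analyze --in topo.txt --out analysis.json
#   Rscript scripts/cntdna.R run-all --out-dir run1 --seed 1

suppressPackageStartupMessages({
  library(cntdna)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: cntdna.R <build-tube|wrap|scan|stm-sim|stm-analyze|run-all> [options]")
cmd <- argv[1]
rest <- argv[-1]

expand_seq <- function(s) {
  # "C25" -> 25 cytosines, otherwise taken literally
  if (grepl("^[ACGT][0-9]+$", s)) strrep(substr(s, 1, 1), as.integer(substring(s, 2))) else s
}
parse_grid <- function(s) {
  p <- as.numeric(strsplit(s, ":")[[1]])
  if (length(p) == 3) seq(p[1], p[2], by = p[3]) else p
}

common <- list(
  make_option("--n", type = "integer", default = 6),
  make_option("--m", type = "integer", default = 5),
  make_option("--units", type = "integer", default = 3),
  make_option("--seed", type = "integer", default = 1),
  make_option("--out", type = "character", default = NULL)
)

if (cmd == "build-tube") {
  o <- parse_args(OptionParser(option_list = common), rest)
  tube <- build_nanotube(nanotube_spec(o$n, o$m, n_units = o$units))
  out <- if (is.null(o$out)) sprintf("tube_%d_%d.xyz", o$n, o$m) else o$out
  if (grepl("\\.pdb$", out)) write_pdb(tube, out) else write_xyz(tube, out)
  print(tube)

} else if (cmd == "wrap") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--sequence", type = "character"),
    make_option("--alpha", type = "character", default = "45"),
    make_option("--delta", type = "double", default = 0.33),
    make_option("--L", type = "double", default = 0.50)
  ))), rest)
  tube <- build_nanotube(nanotube_spec(o$n, o$m, n_units = o$units))
  hyb <- generate_initial_configs(expand_seq(o$sequence), tube,
                                  parse_grid(o$alpha), delta = o$delta,
                                  L = o$L, seed = o$seed)
  out <- if (is.null(o$out)) "hybrid.pdb" else o$out
  if (length(hyb) == 1) write_pdb(hyb[[1]], out)
  else for (nm in names(hyb)) write_pdb(hyb[[nm]], sub("\\.pdb$", paste0("_", nm, ".pdb"), out))
  message(length(hyb), " hybrid(s) written")

} else if (cmd == "scan") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--sequence", type = "character"),
    make_option("--grid", type = "character", default = "10:80:5"),
    make_option("--fix-ends", action = "store_true", default = FALSE,
                dest = "fix_ends"),
    make_option("--max-iter", type = "integer", default = 3000,
                dest = "max_iter")
  ))), rest)
  tube <- build_nanotube(nanotube_spec(o$n, o$m, n_units = o$units))
  scan <- scan_binding_vs_angle(expand_seq(o$sequence), tube,
                                parse_grid(o$grid), fixed_ends = o$fix_ends,
                                seed = o$seed, max_iter = o$max_iter)
  print(scan)
  out <- if (is.null(o$out)) "scan.csv" else o$out
  write_scan(scan, out, sub("\\.csv$", ".json", out))

} else if (cmd == "stm-sim") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--pitch", type = "double", default = NULL),
    make_option("--coils", type = "double", default = 3),
    make_option("--backbone-radius", type = "double", default = 1.05,
                dest = "backbone_radius"),
    make_option("--tip-radius", type = "double", default = 2, dest = "tip_radius"),
    make_option("--noise", type = "double", default = 0.02)
  ))), rest)
  spec <- nanotube_spec(o$n, o$m)
  hp <- helix_param(tube_radius = tube_dimensions(spec)$radius,
                    backbone_radius = o$backbone_radius,
                    pitch = o$pitch,
                    angle_from_axis = if (is.null(o$pitch)) 90 - chiral_angle(spec) else NULL,
                    n_coils = o$coils)
  topo <- render_surface(hp)
  topo <- tip_dilate(topo, tip_model("cone", o$tip_radius, 30))
  topo <- add_noise(topo, o$noise, seed = o$seed)
  out <- if (is.null(o$out)) "topography.txt" else o$out
  write_topography(topo, out, if (grepl("\\.tif+$", out)) "tiff" else "text")
  print(topo)

} else if (cmd == "stm-analyze") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--in", type = "character", dest = "input"),
    make_option("--tip-radius", type = "double", default = 2, dest = "tip_radius")
  ))), rest)
  topo <- read_topography(o$input, if (grepl("\\.tif+$", o$input)) "tiff" else "text")
  prof <- ridge_profile(topo)
  per <- dominant_period(prof)
  orient <- strand_orientation(topo, tip = tip_model("cone", o$tip_radius, 30))
  res <- list(period_nm = per$period, band90_nm = per$band90,
              n_periods = per$n_periods,
              angle_from_axis = orient$angle_from_axis)
  print(per); print(orient)
  if (!is.null(o$out)) jsonlite::write_json(res, o$out, auto_unbox = TRUE, digits = NA)

} else if (cmd == "run-all") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--sequence", type = "character", default = "GAGAAGAGAGCAGAAGGAGA"),
    make_option("--grid", type = "character", default = "10:80:10"),
    make_option("--out-dir", type = "character", default = "cntdna_run",
                dest = "out_dir")
  ))), rest)
  cfg <- run_config(n = o$n, m = o$m, n_units = o$units,
                    sequence = expand_seq(o$sequence),
                    angle_grid = parse_grid(o$grid),
                    seed = o$seed, out_dir = o$out_dir)
  manifest <- run_experiment(cfg)
  message("artifacts in ", o$out_dir)

} else {
  stop("unknown subcommand: ", cmd)
}
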