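#' Run the full design-and-characterization pipeline
#'
#' Orchestrates skeleton design, voxelization, smoothing, morphometry,
#' elastic homogenization, permeability homogenization and the surface
#' strain analysis, writing every stage artifact and a single JSON report.
#'
#' @param config a [design_config()] or a path to a JSON/YAML configuration
#' @param out_dir output directory (created if missing)
#' @param target_phi target porosity
#' @param scale grid scale factor (1 = full 500^3 grid)
#' @param stages character vector choosing the characterization stages,
#'   subset of `c("morpho", "elastic", "perm", "strain")`
#' @param nu Poisson ratio for the mechanical stages
#' @param mil_directions MIL direction count (scaled runs may lower it)
#' @return the run manifest (list, also written to `manifest.json`)
#' @export
run_pipeline <- function(config, out_dir, target_phi = 0.75, scale = 1,
                         stages = c("morpho", "elastic", "perm"),
                         nu = 0.3, mil_directions = 129) {
  if (is.character(config)) config <- read_design_config(config)
  stopifnot(inherits(config, "design_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  report <- list(config = unclass(config), target_phi = target_phi,
                 scale = scale)

  t0 <- tic()
  graph <- design_scaffold_graph(config)
  t_all$design <- tic() - t0
  gs <- graph_stats(graph)
  report$graph <- list(
    candidate_edges = attr(graph, "candidate_count"),
    selected_edges = attr(graph, "n_selected"),
    pruned_edges = attr(graph, "n_pruned"),
    modal_degree = gs$modal_degree,
    modal_inter_trabecular_angle = gs$modal_angle_bin,
    seed_density = config$seed_density
  )
  write_graph_json(graph, file.path(out_dir, "graph.json"))

  t0 <- tic()
  vol <- generate_scaffold(config, target_phi, scale = scale, graph = graph)
  t_all$voxelize <- tic() - t0
  report$volume <- list(grid = dim(vol$occ), pitch_um = vol$pitch,
                        porosity = porosity(vol),
                        thickness_units = attr(vol, "thickness"))
  write_tiff_stack(vol, file.path(out_dir, "scaffold.tif"))

  if ("morpho" %in% stages) {
    t0 <- tic()
    th <- thickness_report(vol)
    fab <- mil_fabric(vol, n_directions = mil_directions)
    mesh <- extract_mesh(vol)
    curv <- gaussian_curvature(mesh)
    t_all$morpho <- tic() - t0
    report$morphometry <- list(
      tb_th_um = unname(th$tb_th["mean"]), tb_th_sd_um = unname(th$tb_th["sd"]),
      tb_sp_um = unname(th$tb_sp["mean"]), tb_sp_sd_um = unname(th$tb_sp["sd"]),
      DA = fab$DA,
      frac_area_nonpositive_K = sum(curv$vertex_area[curv$K <= 0]) /
        sum(curv$vertex_area)
    )
    write_stl(mesh, file.path(out_dir, "scaffold.stl"))
  }
  if ("elastic" %in% stages) {
    t0 <- tic()
    stiff <- homogenize_stiffness(vol, nu = nu)
    az <- anisotropy_az(stiff)
    t_all$elastic <- tic() - t0
    report$elastic <- list(C = stiff$C, Ez = stiff$Ez, AZ = az$AZ,
                           AT = anisotropy_at(stiff))
    write.csv(stiff$C, file.path(out_dir, "stiffness_C.csv"),
              row.names = FALSE)
  }
  if ("perm" %in% stages) {
    t0 <- tic()
    perm <- permeability_tensor(vol)
    t_all$perm <- tic() - t0
    report$permeability <- list(K = perm$K, A_kappa = perm$A_kappa,
                                asymmetry = perm$asymmetry)
    write.csv(perm$K, file.path(out_dir, "permeability_K.csv"),
              row.names = FALSE)
  }
  if ("strain" %in% stages) {
    t0 <- tic()
    sf <- octahedral_strain(vol, "uniaxial", nu = nu)
    t_all$strain <- tic() - t0
    report$octahedral_strain <- list(load = sf$load,
                                     quartiles = unname(sf$summary))
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- list.files(out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    version = as.character(utils::packageVersion("anisovor")),
    config = unclass(config),
    seconds = t_all,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
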