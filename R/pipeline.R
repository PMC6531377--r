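# Config-driven orchestration over one or more receptor states, with
# state-comparison reports. A "state" bundles a topology and a multi-run
# ensemble (a toy fixture directory written by write_toy_fixture(), or any
# directory with the same layout) plus optional work samples for the
# free-energy stage. One YAML config drives everything; defaults equal the
# package-wide conventions (0.5 trailing window, 30 bins, 5 A / 75%
# proximity, 3.5 A / 120 deg hydrogen bonds, 4 A carbon contacts, strict
# >40% sustained rule, 12 A box at 1 A grid).

default_parameters <- function() {
  list(bins = 30, mi_correction = "miller-madow", mi_aggregate = "max",
       proximity_cutoff = 5.0, proximity_occupancy = 0.75,
       hbond_dist = 3.5, hbond_angle = 120, vdw_dist = 4.0,
       volume_spacing = 1.0, volume_box = 12.0, core_radius = 4.0,
       projection_bin = 0.25, window_fraction = 0.5)
}

#' Read and validate a pipeline run configuration
#'
#' The YAML config names the states (each with a fixture directory and
#' optional work-sample TSV), the stages to run, analysis regions, and the
#' stage parameters. Parameters not given fall back to the documented
#' defaults. Validation fails with the offending field's name.
#'
#' @param path YAML file.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  pars <- utils::modifyList(default_parameters(), cfg$parameters %||% list())
  for (fld in c("proximity_cutoff", "hbond_dist", "vdw_dist",
                "volume_spacing", "volume_box", "core_radius",
                "projection_bin", "bins")) {
    if (!is.numeric(pars[[fld]]) || pars[[fld]] <= 0)
      stopf("invalid parameter '%s': must be a positive number", fld)
  }
  if (pars$window_fraction <= 0 || pars$window_fraction > 1)
    stopf("invalid parameter 'window_fraction': must be in (0, 1]")
  if (pars$proximity_occupancy < 0 || pars$proximity_occupancy > 1)
    stopf("invalid parameter 'proximity_occupancy': must be in [0, 1]")
  cfg$parameters <- pars
  cfg$stages <- cfg$stages %||% c("entropy", "mi", "allosteer", "contacts",
                                  "geometry", "bar")
  if (is.null(cfg$states) || !length(cfg$states))
    stopf("invalid field 'states': at least one state required")
  for (s in cfg$states) {
    if (is.null(s$name)) stopf("invalid field 'states': each needs a name")
    fd <- s$fixture_dir
    if (is.null(fd)) stopf("invalid field 'fixture_dir' for state %s", s$name)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

resolve_path <- function(p, base) {
  if (is.null(base) || grepl("^/", p)) p else file.path(base, p)
}

config_regions <- function(cfg) {
  rg <- cfg$regions
  if (is.character(rg) && length(rg) == 1) return(load_region_fixture(rg))
  out <- list()
  for (nm in names(rg)) {
    entries <- rg[[nm]]
    ids <- unlist(lapply(as.character(entries), function(e)
      if (grepl("-", e)) {
        ab <- as.integer(strsplit(e, "-")[[1]]); seq(ab[1], ab[2])
      } else as.integer(e)))
    out[[nm]] <- region_set(nm, ids)
  }
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages for every state and writes per-state TSV/JSON
#' outputs, a machine-readable manifest (inputs, parameters, package
#' version, seed, stage outputs), and a log. Given identical inputs and
#' seed the numeric outputs are byte-identical across reruns. A stage
#' failure aborts with the stage name after writing a partial-results
#' manifest.
#'
#' @param config a [read_run_config()] result (or a config list, which will
#'   be validated).
#' @param output_dir artifact directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- config$parameters
  regions <- config_regions(config)
  log_path <- file.path(output_dir, "run.log")
  logcon <- file(log_path, "w")
  on.exit(close(logcon), add = TRUE)
  logmsg <- function(...) writeLines(sprintf(...), logcon)
  manifest <- list(package = "gpcrdyn",
                   version = as.character(utils::packageVersion("gpcrdyn")),
                   seed = config$seed, parameters = pars, states = list())
  current_stage <- NA_character_
  for (st in config$states) {
    sdir <- file.path(output_dir, st$name)
    dir.create(sdir, showWarnings = FALSE)
    set.seed(config$seed)
    logmsg("state %s: loading fixture", st$name)
    fix <- read_toy_fixture(resolve_path(st$fixture_dir, config$base_dir))
    top <- fix$topology
    ens <- select_analysis_frames(fix$ensemble, pars$window_fraction)
    outputs <- character(0)
    emit <- function(stage, fn, df) {
      path <- file.path(sdir, fn)
      write_tsv(df, path)
      outputs[[stage]] <<- fn
      logmsg("state %s: stage %s -> %s", st$name, stage, fn)
    }
    res <- tryCatch({
      torsions <- NULL
      etab <- NULL
      mi <- NULL
      if (any(c("entropy", "mi", "allosteer") %in% config$stages)) {
        current_stage <- "entropy"
        torsions <- extract_torsions(top, ens)
        etab <- torsion_entropy_table(torsions, bins = pars$bins,
                                      correction = pars$mi_correction)
      }
      if ("entropy" %in% config$stages) {
        current_stage <- "entropy"
        reg_rows <- do.call(rbind, lapply(names(regions), function(nm) {
          rg <- regions[[nm]]
          rg <- region_set(nm, intersect(rg$residues,
                                         etab$residue_id))
          re <- region_entropy(etab, rg)
          data.frame(region = nm, total_S = re$total,
                     n_residues = length(rg$residues))
        }))
        emit("entropy", "entropy_per_torsion.tsv", etab)
        write_tsv(reg_rows, file.path(sdir, "entropy_regions.tsv"))
      }
      if (any(c("mi", "allosteer") %in% config$stages)) {
        current_stage <- "mi"
        mi <- mi_matrix(torsions, bins = pars$bins,
                        aggregate = pars$mi_aggregate,
                        correction = pars$mi_correction)
        if ("mi" %in% config$stages)
          emit("mi", "mi_matrix.tsv", as.data.frame(mi))
      }
      if ("allosteer" %in% config$stages) {
        current_stage <- "allosteer"
        g <- build_residue_graph(top, ens, mi,
                                 proximity_cutoff = pars$proximity_cutoff,
                                 proximity_occupancy = pars$proximity_occupancy)
        pw <- enumerate_pathways(g, regions[[st$sources %||% "sources"]],
                                 regions[[st$sinks %||% "sinks"]],
                                 regions[[st$via %||% "via"]])
        path_df <- if (length(pw$pathways))
          do.call(rbind, lapply(pw$pathways, function(p) data.frame(
            source = p$source, sink = p$sink,
            residues = paste(p$residues, collapse = ","),
            total_mi = p$total_mi, total_cost = p$total_cost)))
          else data.frame(source = integer(0), sink = integer(0),
                          residues = character(0), total_mi = numeric(0),
                          total_cost = numeric(0))
        emit("allosteer", "pathways.tsv", path_df)
        if (length(pw$pathways)) {
          pipes <- assemble_pipelines(pw$pathways)
          pipe_df <- do.call(rbind, lapply(seq_along(pipes), function(k)
            data.frame(pipeline = k, strength = pipes[[k]]$strength,
                       residues = paste(names(pipes[[k]]$hub_counts),
                                        collapse = ","),
                       hub_counts = paste(pipes[[k]]$hub_counts,
                                          collapse = ","))))
          write_tsv(pipe_df, file.path(sdir, "pipelines.tsv"))
        }
      }
      if ("contacts" %in% config$stages) {
        current_stage <- "contacts"
        cres <- st$contact_residues %||% regions$binding_site$residues
        ctab <- contact_table(top, ens, intersect(unlist(cres),
                                                  top$residues$resid),
                              dist_cutoff = pars$hbond_dist,
                              angle_cutoff = pars$hbond_angle)
        emit("contacts", "contacts.tsv", ctab)
      }
      if ("geometry" %in% config$stages) {
        current_stage <- "geometry"
        ca <- atom_select(top, "calpha")
        rmsf <- compute_rmsf(ens, ca)
        gdf <- data.frame(residue_id = top$atoms$resid[ca], rmsf = rmsf,
                          bfactor = rmsf_to_bfactor(rmsf))
        emit("geometry", "rmsf_bfactor.tsv", gdf)
        lig <- atom_select(top, "ligand")
        if (length(lig)) {
          vol <- pocket_volume_series(top, ens, lig,
                                      spacing = pars$volume_spacing,
                                      box = pars$volume_box,
                                      core_radius = pars$core_radius)
          write_tsv(data.frame(mean_volume = vol$mean, sd_volume = vol$sd,
                               n_frames = length(vol$per_frame)),
                    file.path(sdir, "volume.tsv"))
        }
        if (!is.null(st$projection)) {
          pr <- state_projection(top, ens,
                                 unlist(st$projection$pairA),
                                 unlist(st$projection$pairB),
                                 bin_width = pars$projection_bin)
          write_tsv(data.frame(dA = pr$dA, dB = pr$dB),
                    file.path(sdir, "projection.tsv"))
        }
      }
      if ("bar" %in% config$stages && !is.null(st$work_samples)) {
        current_stage <- "bar"
        ws <- read_work_samples(resolve_path(st$work_samples,
                                             config$base_dir))
        fe <- bar_total(ws)
        jsonlite::write_json(list(total_dg = fe$total_dg,
                                  total_se = fe$total_se,
                                  units = fe$units,
                                  per_window = fe$per_window),
                             file.path(sdir, "bar.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs[["bar"]] <- "bar.json"
        logmsg("state %s: stage bar -> bar.json", st$name)
      }
      TRUE
    }, error = function(e) e)
    manifest$states[[st$name]] <- list(
      fixture_dir = st$fixture_dir, outputs = as.list(outputs))
    if (inherits(res, "error")) {
      manifest$states[[st$name]]$failed_stage <- current_stage
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stopf("stage '%s' failed for state %s: %s", current_stage, st$name,
            conditionMessage(res))
    }
  }
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

read_tsv_if <- function(path) {
  if (file.exists(path)) read.table(path, header = TRUE, sep = "\t") else NULL
}

#' Compare analysed states
#'
#' Joins the per-state artifact tables and reports pairwise deltas
#' (`stateB - stateA`): region entropies, contact occupancies and mean
#' distances (contacts present in only one state are flagged), mean pocket
#' volume, per-residue B-factor, and top pipeline strength. States must
#' have been analysed with identical parameters (checked via manifests).
#'
#' @param run_dir artifact directory produced by [run_pipeline()] (a single
#'   run over several states), or a list of two such directories each
#'   holding one state.
#' @param pair character vector of two state names.
#' @return object of class `comparison_report` (list of delta tables).
#' @export
compare_states <- function(run_dir, pair) {
  if (length(pair) != 2) stopf("pair must name exactly two states")
  if (length(run_dir) == 1) {
    dirs <- file.path(run_dir, pair)
    manifests <- rep(file.path(run_dir, "manifest.json"), 2)
  } else {
    dirs <- vapply(seq_len(2), function(k)
      file.path(run_dir[[k]], pair[k]), character(1))
    manifests <- vapply(run_dir, function(d)
      file.path(d, "manifest.json"), character(1))
  }
  for (d in dirs) if (!dir.exists(d)) stopf("no artifacts for state at %s", d)
  m <- lapply(manifests, function(p) jsonlite::read_json(p))
  if (!identical(m[[1]]$parameters, m[[2]]$parameters))
    stopf("states were analysed with different parameters")
  out <- list(pair = pair)
  re <- lapply(dirs, function(d) read_tsv_if(file.path(d, "entropy_regions.tsv")))
  if (!is.null(re[[1]]) && !is.null(re[[2]])) {
    j <- merge(re[[1]], re[[2]], by = "region", suffixes = c("_a", "_b"))
    j$delta_S <- j$total_S_b - j$total_S_a
    out$entropy <- j
  }
  ct <- lapply(dirs, function(d) read_tsv_if(file.path(d, "contacts.tsv")))
  if (!is.null(ct[[1]]) && !is.null(ct[[2]])) {
    j <- merge(ct[[1]], ct[[2]], by = c("residue_id", "kind"),
               suffixes = c("_a", "_b"), all = TRUE)
    j$delta_occupancy <- j$occupancy_b - j$occupancy_a
    j$delta_mean_distance <- j$mean_distance_all_b - j$mean_distance_all_a
    j$only_in <- ifelse(is.na(j$occupancy_a), pair[2],
                        ifelse(is.na(j$occupancy_b), pair[1], ""))
    out$contacts <- j
  }
  vol <- lapply(dirs, function(d) read_tsv_if(file.path(d, "volume.tsv")))
  if (!is.null(vol[[1]]) && !is.null(vol[[2]])) {
    out$volume <- data.frame(
      mean_a = vol[[1]]$mean_volume, mean_b = vol[[2]]$mean_volume,
      delta = vol[[2]]$mean_volume - vol[[1]]$mean_volume)
  }
  bf <- lapply(dirs, function(d) read_tsv_if(file.path(d, "rmsf_bfactor.tsv")))
  if (!is.null(bf[[1]]) && !is.null(bf[[2]])) {
    j <- merge(bf[[1]], bf[[2]], by = "residue_id", suffixes = c("_a", "_b"))
    j$delta_bfactor <- j$bfactor_b - j$bfactor_a
    out$bfactor <- j
  }
  pp <- lapply(dirs, function(d) read_tsv_if(file.path(d, "pipelines.tsv")))
  if (!is.null(pp[[1]]) && !is.null(pp[[2]])) {
    out$pipeline_strength <- data.frame(
      max_a = max(pp[[1]]$strength), max_b = max(pp[[2]]$strength),
      delta = max(pp[[2]]$strength) - max(pp[[1]]$strength))
  }
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s: %s\n", x$pair[1], x$pair[2],
              paste(setdiff(names(x), "pair"), collapse = ", ")))
  invisible(x)
}
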