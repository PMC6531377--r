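# End-to-end pipeline fixture: two toy states differing in a scheduled
# contact distance, plus work samples and a YAML config.

make_pipeline_fixture <- function(root, d_in_vdw = c(5.0, 3.5), seed = 101) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  states <- list()
  for (k in 1:2) {
    spec <- toy_receptor_spec(
      helix_count = 1, residues_per_helix = 12, per_atom_sigma = 0.25,
      n_runs = 2, frames_per_run = 120, seed = seed,  # same seed: states
      contact_schedule = list(                        # differ only by d_in
        list(residue = 3, kind = "hbond", occupancy = 0.6),
        list(residue = 5, kind = "vdw", occupancy = 1.0,
             d_in = d_in_vdw[k])))
    fix <- gen_toy_trajectory(spec)
    sdir <- file.path(root, sprintf("fixture_state%s", LETTERS[k]))
    write_toy_fixture(fix, sdir)
    states[[k]] <- list(name = sprintf("state%s", LETTERS[k]),
                        fixture_dir = basename(sdir),
                        work_samples = "work.tsv",
                        sources = "sources", sinks = "sinks", via = "via",
                        contact_residues = c(3, 5),
                        projection = list(pairA = c(1, 6),
                                          pairB = c(1, 12)))
  }
  ws <- gen_bar_samples(work_sample_spec(n_windows = 3,
                                         samples_per_window = 400,
                                         mu_w = c(1, 0.5, 2), sigma_w = 0.8,
                                         seed = seed))
  write_work_samples(ws, file.path(root, "work.tsv"))
  cfg <- list(seed = seed,
              parameters = list(window_fraction = 0.5,
                                mi_correction = "none"),
              regions = list(sources = "1-2", sinks = "11-12", via = "5-8"),
              states = states)
  path <- file.path(root, "config.yml")
  yaml::write_yaml(cfg, path)
  path
}

# All regular files under a run directory, as relative paths, excluding the
# (timestamped) log.
run_output_files <- function(dir) {
  f <- list.files(dir, recursive = TRUE)
  sort(setdiff(f, "run.log"))
}
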