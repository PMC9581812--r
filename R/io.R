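#' Write frames to an XYZ trajectory
#'
#' Extended-XYZ dialect: per frame, line 1 is the bead count; line 2 is the
#' comment line `box_edge=<nm> time_fs=<fs>`; each following line is
#' `LABEL x y z` in nm with the bead label encoding class and molecule kind
#' (`HL`/`TL` for lipid head/tail, `HP`/`TP` for peptide beads).
#'
#' @param frames A `cooke_trajectory`, a list of `cooke_state`s, or a single
#'   `cooke_state`.
#' @param path Output file.
#' @param topology `cooke_topology` supplying the bead labels.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, topology) {
  if (inherits(frames, "cooke_trajectory")) frames <- frames$frames
  if (inherits(frames, "cooke_state")) frames <- list(frames)
  lab <- paste0(topology$beads$bead_class,
                ifelse(topology$beads$molecule_kind == "lipid", "L", "P"))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$positions)), con)
    writeLines(sprintf("box_edge=%.8g time_fs=%.8g", fr$box_edge,
                       fr$time_fs), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Parses the dialect written by [write_trajectory()]. Malformed frames
#' (bad counts, missing box comment) raise an error citing the line number.
#'
#' @param path XYZ file.
#' @return List of `cooke_state` frames, each with attribute `labels`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln]))
      stop(sprintf("read_trajectory: expected bead count at line %d", ln))
    n <- as.integer(lines[ln])
    if (ln + 1L > length(lines) ||
        !grepl("box_edge=", lines[ln + 1L], fixed = TRUE))
      stop(sprintf("read_trajectory: missing box_edge comment at line %d",
                   ln + 1L))
    cm <- lines[ln + 1L]
    box <- as.numeric(sub(".*box_edge=([0-9.eE+-]+).*", "\\1", cm))
    tfs <- if (grepl("time_fs=", cm, fixed = TRUE))
      as.numeric(sub(".*time_fs=([0-9.eE+-]+).*", "\\1", cm)) else 0
    if (ln + 1L + n > length(lines))
      stop(sprintf("read_trajectory: truncated frame starting at line %d", ln))
    body <- lines[(ln + 2L):(ln + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop(sprintf("read_trajectory: malformed coordinate at line %d",
                   ln + 1L + bad[1]))
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    st <- new_system_state(pos, box, time_fs = tfs)
    attr(st, "labels") <- vapply(parts, `[`, character(1), 1)
    frames[[length(frames) + 1L]] <- st
    ln <- ln + 2L + n
  }
  frames
}

#' Export a topology to JSON
#'
#' Documented schema: `beads` (index, bead_class, molecule_id,
#' molecule_kind, layer), `fene_bonds`, `harmonic_bonds`, `elastic_bonds`,
#' and `reference_coords` (row-major N x 3, nm).
#'
#' @param topology `cooke_topology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(beads = topology$beads,
              fene_bonds = topology$fene_bonds,
              harmonic_bonds = topology$harmonic_bonds,
              elastic_bonds = topology$elastic_bonds,
              reference_coords = unclass(topology$reference_coords))
  jsonlite::write_json(obj, path, digits = NA, dataframe = "columns",
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path JSON file written by [write_topology_json()].
#' @return `cooke_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beads <- as.data.frame(obj$beads, stringsAsFactors = FALSE)
  beads$layer <- as.integer(beads$layer)
  fix_ij <- function(df, with_r0 = FALSE) {
    df <- as.data.frame(df)
    if (!nrow(df)) {
      df <- if (with_r0)
        data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
      else data.frame(i = integer(0), j = integer(0))
    } else {
      df$i <- as.integer(df$i); df$j <- as.integer(df$j)
    }
    df
  }
  new_topology(beads = beads,
               fene_bonds = fix_ij(obj$fene_bonds),
               harmonic_bonds = fix_ij(obj$harmonic_bonds, TRUE),
               elastic_bonds = fix_ij(obj$elastic_bonds, TRUE),
               reference_coords = matrix(unlist(obj$reference_coords),
                                         ncol = 3))
}

#' Export a state to PDB for visualization
#'
#' One residue per molecule; residue names `LIP`/`PEP`; the element column
#' encodes bead class (`N` for hydrophilic, `C` for hydrophobic) so generic
#' viewers color the hydrophobic surface distinctly. Coordinates are written
#' in Angstrom as the format requires.
#'
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(state, topology, path) {
  b <- topology$beads
  xyz <- state$positions * 10  # nm -> Angstrom
  elem <- ifelse(b$bead_class == "T", "C", "N")
  resn <- ifelse(b$molecule_kind == "lipid", "LIP", "PEP")
  lines <- sprintf(
    "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(b)) %% 100000,
    sprintf("%s%d", b$bead_class, seq_len(nrow(b)) %% 1000),
    resn, b$molecule_id %% 10000,
    xyz[, 1], xyz[, 2], xyz[, 3], elem)
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       state$box_edge * 10, state$box_edge * 10,
                       state$box_edge * 10),
               lines, "END"), path)
  invisible(path)
}

#' Run configuration serialization
#'
#' A run configuration bundles the system spec, force-field overrides,
#' engine settings, and analysis settings; it round-trips losslessly
#' through YAML and its defaults reproduce the model's standard parameter
#' values.
#'
#' @param spec `system_spec`.
#' @param ff `cooke_ff`.
#' @param engine `engine_config`.
#' @param analysis Named list of analysis settings (clustering cutoff, Rg
#'   cutoff, minimum aggregate size, equilibrated window).
#' @param n_steps Production step count.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = system_spec(50),
                       ff = ff_params(),
                       engine = engine_config(),
                       analysis = list(cutoff_nm = 0.9, rg_cutoff_nm = 2.5,
                                       min_size = 5, window = c(2/3, 1)),
                       n_steps = 1e6) {
  cfg <- list(spec = unclass(spec), ff = unclass(ff),
              engine = unclass(engine), analysis = analysis,
              n_steps = n_steps)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    spec = do.call(system_spec,
                   raw$spec[c("n_lipids", "n_peptides",
                              "lipid_concentration_mM", "replicas",
                              "base_seed")]),
    ff = do.call(ff_params,
                 raw$ff[setdiff(names(raw$ff), "kB")]),
    engine = do.call(engine_config, raw$engine),
    analysis = raw$analysis,
    n_steps = raw$n_steps
  )
  cfg$analysis$window <- as.numeric(unlist(cfg$analysis$window))
  class(cfg) <- "run_config"
  cfg
}
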