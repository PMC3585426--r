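# Readers and writers: PDB structures (read via bio3d, written by a small
# fixed-width formatter that also emits multi-model files), DCD and
# multi-model PDB trajectories, COLVAR / HILLS whitespace tables with
# "#! FIELDS" headers (the dominant metadynamics file dialect), gridded
# free-energy text files and YAML run configuration.

pdb_to_frame <- function(pdb, xyz_row = NULL) {
  a <- pdb$atom
  keep <- a$type %in% c("ATOM", "HETATM")
  a <- a[keep, , drop = FALSE]
  # altloc policy: keep the highest-occupancy conformer of each atom
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety, a$insert)
    o <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -o)
    a2 <- a[ord, , drop = FALSE]
    dup <- duplicated(paste(a2$chain, a2$resno, a2$elety, a2$insert))
    if (any(dup)) {
      message(sum(dup), " altloc duplicate(s) dropped (highest occupancy kept)")
      a <- a2[!dup, , drop = FALSE]
      a <- a[order(as.integer(rownames(a))), , drop = FALSE]
    }
  }
  if (is.null(xyz_row)) {
    coords <- cbind(a$x, a$y, a$z)
  } else {
    xyz <- matrix(pdb$xyz[xyz_row, ], ncol = 3, byrow = TRUE)
    coords <- xyz[keep, , drop = FALSE][match(rownames(a), rownames(pdb$atom[keep, , drop = FALSE])), , drop = FALSE]
  }
  ch <- a$chain; ch[is.na(ch) | ch == ""] <- "A"
  mdframe(coords, data.frame(chain = ch, resno = a$resno, elety = a$elety,
                             resid = a$resid))
}

#' Read a structure file (PDB)
#'
#' Parses a PDB file into an [mdframe]. For multi-model files one model is
#' selected. Altloc duplicates keep the highest-occupancy conformer (with a
#' message).
#'
#' @param path path to a PDB file.
#' @param model model number for multi-model files (default 1).
#' @return an [mdframe].
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  nm <- nrow(pdb$xyz)
  if (model > nm) stop(sprintf("model %d requested but file has %d", model, nm))
  if (nm > 1L || model > 1L) pdb_to_frame(pdb, xyz_row = model)
  else pdb_to_frame(pdb)
}

#' Read a trajectory
#'
#' Supported formats: multi-model PDB and DCD (topology frame required for
#' DCD). Frames are returned with a constant atom count; an atom-count
#' mismatch with the topology is an error. Frame times (ps) are taken from
#' `times` or default to 0, 1, 2, ...
#'
#' @param path trajectory file (.pdb or .dcd).
#' @param topology an [mdframe] supplying atom metadata (required for DCD).
#' @param times optional per-frame times in ps.
#' @return list of [mdframe]s with attribute `times`.
#' @export
read_trajectory <- function(path, topology = NULL, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    if (is.null(topology)) stop("a topology frame is required for DCD input")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3L * natoms(topology))
      stop(sprintf("atom-count mismatch: DCD has %d atoms, topology %d",
                   ncol(xyz) / 3L, natoms(topology)))
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      set_coords(topology, matrix(xyz[i, ], ncol = 3, byrow = TRUE)))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i)
      pdb_to_frame(pdb, xyz_row = if (nrow(pdb$xyz) > 1L) i else NULL))
    if (!is.null(topology)) {
      if (natoms(frames[[1]]) != natoms(topology))
        stop(sprintf("atom-count mismatch: trajectory has %d atoms, topology %d",
                     natoms(frames[[1]]), natoms(topology)))
    }
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times length does not match the frame count")
  attr(frames, "times") <- times
  frames
}

#' Write frames as a (multi-model) PDB file
#'
#' Fixed-width PDB v3.3 ATOM records, one MODEL block per frame for
#' multi-frame input. Coordinates are written with 3 decimals (the format's
#' precision, 1e-3 Angstrom).
#'
#' @param frames an [mdframe] or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "mdframe")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- fr$atoms
    lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(natoms(fr)),
                     ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
                     a$resid, a$chain, a$resno,
                     fr$coords[, 1], fr$coords[, 2], fr$coords[, 3], 1, 0)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

fnv1a <- function(x) {
  # small content hash for provenance headers (FNV-1a, 32 bit)
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

provenance_header <- function(seed = NA, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("helixcv")),
                  error = function(e) "dev")
  sprintf("# helixcv %s  config %s  seed %s", ver,
          if (is.null(config)) "-" else fnv1a(yaml::as.yaml(config)),
          if (is.na(seed)) "-" else as.character(seed))
}

#' Write a COLVAR-style time series
#'
#' Whitespace-delimited table, one row per frame, with a `#! FIELDS` header
#' naming the columns and a provenance comment (tool version, configuration
#' hash, seed).
#'
#' @param df data.frame; first column should be `time`.
#' @param path output path.
#' @param seed,config optional provenance information.
#' @param digits significant digits (default 10).
#' @return the path, invisibly.
#' @export
write_colvar <- function(df, path, seed = NA, config = NULL, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  writeLines(provenance_header(seed, config), con)
  fmt <- paste0("%.", digits, "g")
  body <- apply(df, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read a COLVAR-style file
#' @param path file written by [write_colvar()] (or a compatible dialect).
#' @return data.frame with the named columns.
#' @export
read_colvar <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#! FIELDS", first)) stop("not a COLVAR file (missing #! FIELDS)")
  cols <- strsplit(sub("^#! FIELDS +", "", first), "[ \t]+")[[1]]
  df <- utils::read.table(path, comment.char = "#", col.names = cols)
  df
}

#' Write a HILLS file
#'
#' Columns `time center... sigma... height biasf` with a `#! FIELDS`
#' header. Values are written with 17 significant digits so that a
#' read-back reproduces the run's doubles exactly (bit-identical replay).
#'
#' @param state a [bias_state].
#' @param path output path.
#' @param seed optional provenance seed.
#' @return the path, invisibly.
#' @export
write_hills <- function(state, path, seed = NA) {
  d <- state$d
  cvn <- paste0("cv", seq_len(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time", paste(cvn, collapse = " "),
                   paste(paste0("sigma_", cvn), collapse = " "),
                   "height biasf"), con)
  writeLines(provenance_header(seed), con)
  h <- state$hills
  m <- cbind(as.matrix(h), state$params$bias_factor)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  if (nrow(h)) writeLines(body, con)
  invisible(path)
}

#' Read a HILLS file into a bias state
#'
#' @param path HILLS file.
#' @param temperature system temperature in K (not stored in the file;
#'   default 298).
#' @param pace,initial_height optional parameters to restore (defaults: the
#'   median deposition interval and the maximum height).
#' @return a [bias_state].
#' @export
read_hills <- function(path, temperature = 298, pace = NULL,
                       initial_height = NULL) {
  df <- read_colvar(path)
  nc <- ncol(df)
  d <- (nc - 3L) / 2L
  if (d < 1 || d != round(d)) stop("unexpected HILLS column layout")
  biasf <- df[[nc]][1]
  hills <- df[, seq_len(nc - 1L), drop = FALSE]
  names(hills) <- c("time", paste0("center.", seq_len(d)),
                    paste0("sigma.", seq_len(d)), "height")
  if (is.null(pace)) pace <- if (nrow(hills) > 1) stats::median(diff(hills$time)) else 1
  if (is.null(initial_height)) initial_height <- max(hills$height)
  params <- wtmetad_params(temperature = temperature, bias_factor = biasf,
                           pace = pace, initial_height = initial_height,
                           widths = as.numeric(hills[1, paste0("sigma.", seq_len(d))]))
  bias_state(hills, params)
}

#' Write a gridded free-energy surface as text
#'
#' One row per grid node: axis coordinates then the value; `#` comment
#' header records the axis edges and units. Masked (NA) bins are written as
#' `nan`.
#'
#' @param surf a `surface_grid`.
#' @param path output path.
#' @param seed optional provenance seed.
#' @return the path, invisibly.
#' @export
write_fes <- function(surf, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- length(surf$mids)
  writeLines(sprintf("# fes %dD units %s", d, surf$kind), con)
  writeLines(provenance_header(seed), con)
  if (d == 1L) {
    writeLines(sprintf("%.10g %.10g", surf$mids[[1]], surf$values), con)
  } else {
    for (i in seq_along(surf$mids[[1]]))
      writeLines(sprintf("%.10g %.10g %.10g", surf$mids[[1]][i],
                         surf$mids[[2]], surf$values[i, ]), con)
  }
  invisible(path)
}

#' Compile helix definitions from a YAML configuration
#'
#' The configuration maps helix labels to chain, residue range and
#' rotational-reference residues, e.g.
#' `helices: {N1: {chain: A, residues: "282-296", rotref: [283,287,291,295]}}`.
#' Residue numbers follow the author numbering of the structure.
#'
#' @param frame the [mdframe] the definitions are compiled against.
#' @param config list (parsed YAML) with a `helices` block and optional
#'   `helical_selection` residue ranges.
#' @return list with `helices`, `bundle` and `ref` as in [build_bundle()].
#' @export
compile_helix_config <- function(frame, config) {
  if (is.null(config$helices)) stop("config lacks a 'helices' block")
  parse_range <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    parts <- strsplit(as.character(x), "-", fixed = TRUE)[[1]]
    seq(as.integer(parts[1]), as.integer(parts[2]))
  }
  helices <- lapply(names(config$helices), function(lab) {
    hc <- config$helices[[lab]]
    helix_definition_from_residues(frame, hc$chain, parse_range(hc$residues),
                                   as.integer(hc$rotref), label = lab)
  })
  names(helices) <- names(config$helices)
  helical_sel <- unlist(lapply(helices, `[[`, "all_ca"), use.names = FALSE)
  reg <- if (!is.null(config$crick_register))
    unlist(config$crick_register) else NULL
  bundle <- bundle_definition(helices, helical_sel,
                              hbond_residues = unique(frame$atoms[, c("chain", "resno")]),
                              crick_register = reg)
  ref <- reference_model(frame, helices, helical_sel)
  list(helices = helices, bundle = bundle, ref = ref)
}

#' Read and validate a run configuration (YAML)
#'
#' Known top-level blocks: `structure`, `trajectory`, `helices`,
#' `helical_selection`, `crick_register`, `analysis`, `metad`, `walls`,
#' `output`, `seed`, `log_level`. Unknown keys are rejected; referenced
#' paths must exist.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("structure", "trajectory", "helices", "helical_selection",
             "crick_register", "analysis", "metad", "walls", "output",
             "seed", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (p in c(cfg$structure, cfg$trajectory))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  if (!is.null(cfg$seed) && cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  cfg
}
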