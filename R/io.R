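# Coordinate and volumetric file IO.
#
# Supported formats: multi-frame XYZ (comment line carries frame index,
# time, box), multi-model PDB (MODEL/ENDMDL; read through bio3d), an
# OpenDX-style regular volumetric grid, and a YAML topology sidecar mapping
# 1-based atom index ranges to molecule ids and molecule specs.

#' Build a topology sidecar description
#'
#' @param specs list of [molecule_spec()] objects
#' @param molecules data.frame with columns `molecule_id`, `spec` (spec
#'   name), `from`, `to` (1-based atom index range within each frame)
#' @return list of class `topology`
#' @export
topology <- function(specs, molecules) {
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  molecules <- as.data.frame(molecules)
  need <- c("molecule_id", "spec", "from", "to")
  if (!all(need %in% names(molecules)))
    stop("topology molecules table needs columns: ",
         paste(need, collapse = ", "))
  if (any(!molecules$spec %in% names(specs)))
    stop("topology error: molecule references unknown spec")
  idx <- unlist(Map(seq, molecules$from, molecules$to))
  if (anyDuplicated(idx))
    stop("topology error: atom index ranges overlap")
  structure(list(specs = specs, molecules = molecules), class = "topology")
}

#' Derive the topology of an (in-memory) ensemble
#' @param ens an [ensemble()]
#' @return a [topology()]
#' @export
ensemble_topology <- function(ens) {
  fr <- ens$frames[[1]]
  specs <- list()
  rows <- list()
  at <- 0L
  for (m in fr$molecules) {
    specs[[m$spec$name]] <- m$spec
    rows[[length(rows) + 1L]] <- data.frame(
      molecule_id = m$molecule_id, spec = m$spec$name,
      from = at + 1L, to = at + nrow(m$xyz))
    at <- at + nrow(m$xyz)
  }
  topology(unname(specs), do.call(rbind, rows))
}

#' Write a topology sidecar (YAML)
#' @param topo a [topology()]
#' @param path output path
#' @export
write_topology <- function(topo, path) {
  yaml::write_yaml(list(
    specs = lapply(unname(topo$specs), function(s) unclass(s)),
    molecules = lapply(seq_len(nrow(topo$molecules)), function(i)
      as.list(topo$molecules[i, ]))), path)
  invisible(path)
}

#' Read a topology sidecar (YAML)
#' @param path input path
#' @return a [topology()]
#' @export
read_topology <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$specs, function(s)
    molecule_spec(s$name, s$role, unlist(s$ring_atoms),
                  unlist(s$reference_atoms),
                  unlist(s$acceptor_atoms) %||% character(),
                  unlist(s$hydrogen_atoms) %||% character()))
  molecules <- do.call(rbind, lapply(raw$molecules, as.data.frame))
  topology(specs, molecules)
}

# Assemble one frame from a flat (natoms x 3) coordinate block + names.
.frame_from_block <- function(xyz, names, topo, frame_index, box = NULL,
                              time = NULL) {
  n_need <- max(topo$molecules$to)
  if (nrow(xyz) < n_need)
    stop("malformed input: frame ", frame_index, " has ", nrow(xyz),
         " atoms but the topology maps up to atom ", n_need,
         " (missing molecule?)")
  mols <- lapply(seq_len(nrow(topo$molecules)), function(i) {
    row <- topo$molecules[i, ]
    blk <- xyz[row$from:row$to, , drop = FALSE]
    rownames(blk) <- names[row$from:row$to]
    planar_molecule(row$molecule_id, topo$specs[[row$spec]], blk)
  })
  md_frame(mols, box = box, frame_index = frame_index, time = time)
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    names <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                  ncol = 3, byrow = TRUE)
    grab <- function(key) {
      m <- regmatches(comment,
                      regexpr(paste0(key, "=[-0-9.eE,]+"), comment))
      if (!length(m)) return(NULL)
      as.numeric(strsplit(sub(paste0(key, "="), "", m), ",")[[1]])
    }
    frames[[length(frames) + 1L]] <- list(
      xyz = xyz, names = names, box = grab("box"),
      frame_index = grab("frame"), time = grab("time"))
    i <- i + 2L + nat
  }
  frames
}

#' Read a coordinate ensemble
#'
#' Multi-frame XYZ (`.xyz`) or multi-model PDB (`.pdb`, parsed with
#' bio3d). Atom-to-molecule mapping comes from the topology sidecar; every
#' named analysis atom must resolve in every frame or reading fails with a
#' topology error naming the atom.
#'
#' @param path coordinate file
#' @param topology_obj a [topology()] or the path of a YAML sidecar
#' @return an [ensemble()]
#' @export
read_ensemble <- function(path, topology_obj) {
  topo <- if (inherits(topology_obj, "topology")) topology_obj
    else read_topology(topology_obj)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    raw <- .read_xyz_frames(path)
    if (!length(raw)) stop("malformed input: no frames in ", path)
    frames <- lapply(seq_along(raw), function(fi) {
      fr <- raw[[fi]]
      .frame_from_block(fr$xyz, fr$names, topo,
                        frame_index = (fr$frame_index %||% (fi - 1L)),
                        box = fr$box, time = fr$time)
    })
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    names <- trimws(pdb$atom$elety)
    nmodel <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nmodel), function(fi) {
      xyz <- matrix(pdb$xyz[fi, ], ncol = 3, byrow = TRUE)
      .frame_from_block(xyz, names, topo, frame_index = fi - 1L)
    })
  } else stop("unsupported coordinate format: .", ext,
              " (use .xyz or .pdb)")
  ensemble(frames, metadata = list(source = path))
}

#' Write a coordinate ensemble
#'
#' Format chosen by extension: `.xyz` (multi-frame, 3-decimal coordinates)
#' or `.pdb` (MODEL/ENDMDL records, CRYST1 when a box is present). A
#' matching topology sidecar is written alongside when `sidecar = TRUE`
#' (same path with extension `.topology.yaml`).
#'
#' @param ens an [ensemble()]
#' @param path output path
#' @param sidecar also write the topology sidecar?
#' @return `path`, invisibly
#' @export
write_ensemble <- function(ens, path, sidecar = FALSE) {
  if (!n_frames(ens)) stop("cannot write an ensemble with no frames")
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "xyz") {
    for (fr in ens$frames) {
      xyz <- do.call(rbind, lapply(fr$molecules, `[[`, "xyz"))
      comment <- sprintf("frame=%d", fr$frame_index)
      if (!is.null(fr$time)) comment <- paste0(comment,
                                               sprintf(" time=%g", fr$time))
      if (!is.null(fr$box))
        comment <- paste0(comment, sprintf(" box=%.4f,%.4f,%.4f",
                                           fr$box[1], fr$box[2], fr$box[3]))
      writeLines(c(as.character(nrow(xyz)), comment), con)
      writeLines(sprintf("%-5s %12.3f %12.3f %12.3f", rownames(xyz),
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else if (ext == "pdb") {
    for (fr in ens$frames) {
      writeLines(sprintf("MODEL     %4d", fr$frame_index + 1L), con)
      if (!is.null(fr$box))
        writeLines(sprintf(
          "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
          fr$box[1], fr$box[2], fr$box[3]), con)
      serial <- 0L
      for (m in fr$molecules) {
        res <- toupper(substr(m$spec$name, 1, 3))
        for (a in seq_len(nrow(m$xyz))) {
          serial <- serial + 1L
          writeLines(sprintf(
            "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, rownames(m$xyz)[a], res, m$molecule_id %% 10000L,
            m$xyz[a, 1], m$xyz[a, 2], m$xyz[a, 3], m$element[a]), con)
        }
      }
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("unsupported coordinate format: .", ext)
  if (sidecar)
    write_topology(ensemble_topology(ens),
                   paste0(sub("\\.[^.]+$", "", path), ".topology.yaml"))
  invisible(path)
}

#' Write an SDF grid as an OpenDX file
#'
#' Regular grids only (single cubic spacing); values are written in the
#' OpenDX scan order (z fastest, x slowest).
#'
#' @param grid an [sdf_grid()]
#' @param path output path
#' @export
write_grid <- function(grid, path) {
  if (!inherits(grid, "sdf_grid"))
    stop("contract violation: write_grid expects an sdf_grid")
  if (length(grid$spacing) != 1L || grid$spacing <= 0)
    stop("contract violation: non-regular grid (spacing must be one ",
         "positive cubic edge)")
  if (length(grid$occupancy) != prod(grid$dims))
    stop("contract violation: dims do not match the number of values")
  d <- grid$dims
  vals <- as.vector(aperm(grid$occupancy, c(3, 2, 1)))  # z fastest
  pad <- c(vals, rep(NA_real_, (3 - length(vals) %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  lines <- apply(rows, 1, function(v)
    paste(sprintf("%.8e", v[!is.na(v)]), collapse = " "))
  header <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d)))
  writeLines(c(header, lines,
               'attribute "dep" string "positions"'), path)
  invisible(path)
}

#' Read an OpenDX grid written by [write_grid()]
#' @param path input path
#' @return an [sdf_grid()] (without reference coordinates)
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  cnt <- regmatches(lines[1], gregexpr("[0-9]+", lines[1]))[[1]]
  d <- as.integer(cnt[(length(cnt) - 2):length(cnt)])
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[2])),
                                "[[:space:]]+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("delta", "", lines[3])),
                                 "[[:space:]]+")[[1]])[1]
  i0 <- grep("data follows", lines)[1]
  tail_at <- grep("^attribute", lines)
  end <- if (length(tail_at)) tail_at[1] - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1L):end]),
                                     "[[:space:]]+")))
  if (length(vals) != prod(d))
    stop("corrupt grid file: expected ", prod(d), " values, found ",
         length(vals))
  occ <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  sdf_grid(origin, spacing, d, occ)
}

#' Export a dimer table as a delimited file
#' @param dimers an [enumerate_dimers()] data frame
#' @param path output path (tab-separated)
#' @export
write_dimer_table <- function(dimers, path) {
  utils::write.table(dimers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
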