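# Readers and writers for the standard structure formats: PDB in (via bio3d),
# PSF + CHARMM-style nonbonded parameter tables in (no installed R reader
# exists for these, so the minimal sections are parsed here), DCD or
# multi-frame XYZ trajectories in, and PDB out with a per-residue metric in
# the B-factor column.

ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38
)

guess_mass <- function(elety, name) {
  el <- toupper(ifelse(is.na(elety) | elety == "", substr(gsub("[0-9]", "", name), 1, 1), elety))
  m <- ELEMENT_MASS[el]
  ifelse(is.na(m), 12.011, m)
}

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records of the first model (waters and other HETATM groups are
#' ignored), preserving author residue numbers and insertion codes verbatim as
#' residue labels. The returned topology is a skeleton: charges and
#' Lennard-Jones parameters are absent (`NA`) until supplied by
#' [read_topology()]; masses are guessed from elements so centre-of-mass
#' networks work directly from a PDB.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier(s) to keep. Structures often carry
#'   several chains and the analysis is per-chain, so selection is explicit.
#' @return A list with elements `topology` (skeleton) and `frame` (coordinates
#'   of the file's first model, Angstrom).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_usage(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)),
                              class = "reinet_parse_error")
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop_validation(sprintf("no protein ATOM records in '%s'%s", path,
                            if (is.null(chain)) "" else sprintf(" for chain %s", paste(chain, collapse = ","))))
  }
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  ch <- ifelse(is.na(at$chain) | at$chain == "", "_", at$chain)
  label <- paste0(at$resno, ins)
  key <- paste(ch, label, sep = ":")

  res_first <- !duplicated(key)
  residues <- tibble(
    index = seq_len(sum(res_first)) - 1L,
    key = key[res_first],
    label = label[res_first],
    name = at$resid[res_first],
    chain = ch[res_first]
  )
  atoms <- tibble(
    atom_id = seq_len(nrow(at)),
    name = at$elety,
    type = NA_character_,
    residue_key = key,
    charge = NA_real_,
    lj_eps = NA_real_,
    lj_rmin_half = NA_real_,
    mass = guess_mass(at$elesy, at$elety)
  )
  topo <- topology(atoms, residues)
  coords <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(coords))) stop_validation("non-finite coordinates in PDB")
  list(topology = topo, frame = new_frame(coords, 0L))
}

new_frame <- function(coords, frame_index = 0L) {
  structure(list(frame_index = as.integer(frame_index), coords = unname(as.matrix(coords))),
            class = "frame")
}

frame_coords <- function(frame) {
  if (inherits(frame, "frame")) frame$coords else unname(as.matrix(frame))
}

# ---- PSF ----

#' Read a PSF topology with CHARMM-style nonbonded parameters
#'
#' Parses the `!NATOM` and `!NBOND` sections of an X-PLOR/CHARMM PSF (the only
#' sections consumed: nonbonded energies need charges, types, masses, and the
#' bond graph for 1-2/1-3 exclusions and 1-4 special pairs) and joins
#' per-atom-type Lennard-Jones parameters from `param_path`.
#'
#' Two parameter dialects are accepted: the CHARMM `NONBONDED` table
#' (`type ignored -eps rmin/2 [ignored -eps14 rmin14/2]`) and a simplified
#' whitespace table (`type eps rmin_half [eps14 rmin_half14]`). Comment lines
#' start with `*`, `!` or `#`.
#'
#' @param psf_path Path to the PSF file.
#' @param param_path Path to the nonbonded parameter table.
#' @return A fully parameterised [topology()].
#' @export
read_topology <- function(psf_path, param_path) {
  if (!file.exists(psf_path)) stop_usage(sprintf("PSF file not found: %s", psf_path))
  if (!file.exists(param_path)) stop_usage(sprintf("parameter file not found: %s", param_path))
  lines <- readLines(psf_path, warn = FALSE)

  natom_line <- grep("!NATOM", lines, fixed = TRUE)
  if (length(natom_line) != 1L) {
    abort(sprintf("no !NATOM section in '%s'", psf_path), class = "reinet_parse_error")
  }
  natom <- as.integer(strsplit(trimws(lines[natom_line]), "\\s+")[[1]][1])
  atom_lines <- lines[(natom_line + 1L):(natom_line + natom)]
  tok <- strsplit(trimws(atom_lines), "\\s+")
  bad <- which(vapply(tok, length, 1L) < 8L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed PSF atom record at line %d of '%s'",
                  natom_line + bad[1], psf_path), class = "reinet_parse_error")
  }
  fld <- function(k) vapply(tok, `[[`, "", k)
  seg <- fld(2); resid <- fld(3); resname <- fld(4)

  key <- paste(seg, resid, sep = ":")
  res_first <- !duplicated(key)
  residues <- tibble(
    index = seq_len(sum(res_first)) - 1L,
    key = key[res_first],
    label = resid[res_first],
    name = resname[res_first],
    chain = seg[res_first]
  )
  params <- read_nb_param_table(param_path)
  type <- fld(6)
  missing_types <- setdiff(unique(type), params$type)
  if (length(missing_types) > 0L) {
    stop_validation(sprintf("atom type(s) missing from parameter table: %s",
                            paste(missing_types, collapse = ", ")))
  }
  prow <- match(type, params$type)
  atoms <- tibble(
    atom_id = as.integer(fld(1)),
    name = fld(5),
    type = type,
    residue_key = key,
    charge = as.numeric(fld(7)),
    lj_eps = params$eps[prow],
    lj_rmin_half = params$rmin_half[prow],
    lj_eps14 = params$eps14[prow],
    lj_rmin_half14 = params$rmin_half14[prow],
    mass = as.numeric(fld(8))
  )

  nbond_line <- grep("!NBOND", lines, fixed = TRUE)
  bonds <- tibble(i = integer(), j = integer())
  if (length(nbond_line) == 1L) {
    nbond <- as.integer(strsplit(trimws(lines[nbond_line]), "\\s+")[[1]][1])
    if (!is.na(nbond) && nbond > 0L) {
      nums <- integer(0)
      k <- nbond_line + 1L
      while (length(nums) < 2L * nbond && k <= length(lines)) {
        nums <- c(nums, as.integer(strsplit(trimws(lines[k]), "\\s+")[[1]]))
        k <- k + 1L
      }
      if (length(nums) < 2L * nbond) {
        abort(sprintf("truncated !NBOND section in '%s'", psf_path), class = "reinet_parse_error")
      }
      nums <- nums[seq_len(2L * nbond)]
      bonds <- tibble(i = nums[c(TRUE, FALSE)], j = nums[c(FALSE, TRUE)])
    }
  }
  topology(atoms, residues, bonds)
}

read_nb_param_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^[*!#]", lines)]
  charmm <- any(grepl("^NONBONDED", lines))
  if (charmm) {
    start <- grep("^NONBONDED", lines)[1]
    lines <- lines[-seq_len(start)]
    stopat <- grep("^(BONDS|ANGLES|DIHEDRALS|IMPROPER|CMAP|NBFIX|HBOND|END)", lines)
    if (length(stopat) > 0L) lines <- lines[seq_len(stopat[1] - 1L)]
    lines <- lines[!grepl("^cutnb|^CUTNB|^ctonnb|^ctofnb", lines)]
  }
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  tok <- strsplit(lines, "\\s+")
  parse_row <- function(t) {
    if (charmm) {
      # type ignored -eps rmin/2 [ignored -eps14 rmin14/2]
      if (length(t) < 4L) return(NULL)
      out <- list(type = t[1], eps = -as.numeric(t[3]), rmin_half = as.numeric(t[4]),
                  eps14 = NA_real_, rmin_half14 = NA_real_)
      if (length(t) >= 7L) {
        out$eps14 <- -as.numeric(t[6]); out$rmin_half14 <- as.numeric(t[7])
      }
    } else {
      if (length(t) < 3L) return(NULL)
      out <- list(type = t[1], eps = as.numeric(t[2]), rmin_half = as.numeric(t[3]),
                  eps14 = NA_real_, rmin_half14 = NA_real_)
      if (length(t) >= 5L) {
        out$eps14 <- as.numeric(t[4]); out$rmin_half14 <- as.numeric(t[5])
      }
    }
    out
  }
  rows <- purrr::compact(lapply(tok, parse_row))
  if (length(rows) == 0L) {
    abort(sprintf("no parameter rows found in '%s'", path), class = "reinet_parse_error")
  }
  dplyr::bind_rows(rows)
}

# ---- trajectories ----

#' Read a trajectory and attach it to a topology
#'
#' DCD files are read through bio3d; plain multi-frame XYZ (repeated
#' `n / comment / name x y z` blocks, Angstrom) is read natively and is the
#' format the synthetic-system generator writes.
#'
#' @param topology A [topology()]; the frame atom count must match.
#' @param path Path to a `.dcd` or `.xyz` trajectory.
#' @param stride Keep every `stride`-th frame, starting at the first (>= 1).
#' @return A `trajectory` object (topology reference, coordinate array
#'   `n_atoms x 3 x n_frames`, retained original frame indices, stride).
#' @export
read_trajectory <- function(topology, path, stride = 1L) {
  if (!file.exists(path)) stop_usage(sprintf("trajectory file not found: %s", path))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop_validation("stride must be a positive integer")
  n_at <- nrow(topology$atoms)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    n_fr <- nrow(xyz)
    if (ncol(xyz) != 3L * n_at) {
      stop_validation(sprintf("trajectory has %d atoms but topology has %d",
                              ncol(xyz) %/% 3L, n_at))
    }
    coords <- array(NA_real_, dim = c(n_at, 3L, n_fr))
    for (f in seq_len(n_fr)) coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  } else {
    coords <- read_xyz_frames(path)
    if (dim(coords)[1] != n_at) {
      stop_validation(sprintf("trajectory has %d atoms but topology has %d",
                              dim(coords)[1], n_at))
    }
  }
  keep <- seq(1L, dim(coords)[3], by = stride)
  new_trajectory(topology, coords[, , keep, drop = FALSE], frame_index = keep - 1L,
                 stride = stride)
}

new_trajectory <- function(topology, coords, frame_index = NULL, stride = 1L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[3] < 1L) stop_validation("trajectory needs at least one frame")
  if (any(!is.finite(coords))) stop_validation("non-finite trajectory coordinates")
  if (is.null(frame_index)) frame_index <- seq_len(dim(coords)[3]) - 1L
  structure(
    list(topology = topology, coords = coords,
         frame_index = as.integer(frame_index), stride = as.integer(stride)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms (stride %d)\n",
              n_frames(x), dim(x$coords)[1], x$stride))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A trajectory from [read_trajectory()] or the generator.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame from a trajectory
#' @param trajectory A trajectory.
#' @param which Frame position (1-based); defaults to the final snapshot.
#' @return A `frame` object.
#' @export
get_frame <- function(trajectory, which = n_frames(trajectory)) {
  stopifnot(which >= 1L, which <= n_frames(trajectory))
  new_frame(trajectory$coords[, , which], trajectory$frame_index[which])
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  k <- 1L
  while (k <= length(lines)) {
    if (trimws(lines[k]) == "") { k <- k + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(n) || n < 1L || k + 1L + n > length(lines)) {
      abort(sprintf("malformed XYZ frame header at line %d of '%s'", k, path),
            class = "reinet_parse_error")
    }
    block <- lines[(k + 2L):(k + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    k <- k + 2L + n
  }
  if (length(frames) == 0L) {
    abort(sprintf("no frames found in '%s'", path), class = "reinet_parse_error")
  }
  n_at <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != n_at)) {
    stop_validation("XYZ frames disagree on atom count")
  }
  array(unlist(frames), dim = c(n_at, 3L, length(frames)))
}

write_xyz_frames <- function(coords, names, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n_at <- dim(coords)[1]
  for (f in seq_len(dim(coords)[3])) {
    writeLines(c(as.character(n_at), sprintf("frame %d", f - 1L)), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", names,
                       coords[, 1, f], coords[, 2, f], coords[, 3, f]), con)
  }
  invisible(path)
}

# ---- profile-annotated PDB output ----

#' Write a structure with a per-residue profile in the B-factor column
#'
#' Every atom's B-factor is set to its residue's profile value so molecular
#' viewers can colour the structure by connectivity. Values are clamped to the
#' fixed-width PDB column (-99.99 to 999.99); non-finite values (isolated
#' residues) become the sentinel 999.99 with a warning.
#'
#' @param frame A `frame` (or plain `n x 3` coordinate matrix).
#' @param topology Matching [topology()].
#' @param profile A [residue_profile][average_shortest_path_profile] (or a
#'   numeric vector of length `N` in residue-ordinal order).
#' @param path Output PDB path.
#' @return The path, invisibly.
#' @export
write_profile_structure <- function(frame, topology, profile, path) {
  vals <- if (is.data.frame(profile)) profile$value else as.numeric(profile)
  if (length(vals) != n_residues(topology)) {
    stop_validation("profile length must equal the residue count")
  }
  if (any(!is.finite(vals))) {
    warn("non-finite profile values written as sentinel 999.99")
    vals[!is.finite(vals)] <- 999.99
  }
  vals <- pmin(pmax(vals, -99.99), 999.99)
  xyz <- frame_coords(frame)
  if (nrow(xyz) != nrow(topology$atoms)) stop_validation("frame does not match topology")

  at <- topology$atoms
  rs <- topology$residues
  ridx <- match(at$residue_key, rs$key)
  resno <- suppressWarnings(as.integer(sub("([0-9]+).*", "\\1", rs$label[ridx])))
  resno[is.na(resno)] <- ridx[is.na(resno)]
  icode <- sub("^[0-9]+", "", rs$label[ridx])
  icode <- ifelse(nchar(icode) == 1L, icode, " ")
  chain <- substr(ifelse(rs$chain[ridx] %in% c("", "_"), "A", rs$chain[ridx]), 1, 1)
  aname <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)

  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    at$atom_id %% 100000L, substr(aname, 1, 4), substr(rs$name[ridx], 1, 3),
    chain, resno %% 10000L, icode, xyz[, 1], xyz[, 2], xyz[, 3], 1.00, vals[ridx]
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a topology's sequence to FASTA
#' @param topology A [topology()].
#' @param path Output FASTA path.
#' @param id Sequence header.
#' @inheritParams extract_sequence
#' @return The path, invisibly.
#' @export
write_sequence_fasta <- function(topology, path, id = "sequence", modified = NULL) {
  seq <- extract_sequence(topology, modified = modified)
  writeLines(c(paste0(">", id), gsub("(.{60})", "\\1\n", seq)), path)
  invisible(path)
}
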