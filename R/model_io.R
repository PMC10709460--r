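#' Construct a topology annotation
#'
#' A topology names the atoms of the system and assigns the roles every
#' downstream analysis needs: the three ordered rim-oxygen rings of the
#' macrocycle (primary hydroxyl rim O6, middle glycosidic rim O1, secondary
#' hydroxyl rim O3), the guest atoms and the guest hydroxyl oxygen, water
#' oxygens, and the donor/hydrogen/acceptor lists for hydrogen-bond
#' detection. Rim rings must be supplied in cyclic order around the
#' macrocycle; the package never infers ring order from coordinates.
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resname}, \code{resid} (one row per atom).
#' @param phr_oxygens,mid_oxygens,shr_oxygens integer vectors of atom indices
#'   forming the three rims, each in cyclic order; equal length n >= 3 and
#'   pairwise disjoint.
#' @param guest_atoms integer vector of guest atom indices (may be empty).
#' @param guest_oxygen single index of the guest hydroxyl oxygen, or
#'   \code{NA}; must be a member of \code{guest_atoms}.
#' @param water_oxygens integer vector of water oxygen indices.
#' @param donors,hydrogens,acceptors integer index vectors for hydrogen-bond
#'   detection. \code{hydrogens} and \code{donors} are parallel: hydrogen
#'   \code{hydrogens[i]} is covalently bound to donor \code{donors[i]}, so a
#'   donor heavy atom with two polar hydrogens appears twice in \code{donors}.
#' @param masses optional numeric per-atom masses (u).
#' @param charges optional numeric per-atom partial charges (e).
#' @return object of class \code{cd_topology}.
#' @export
cd_topology <- function(atoms, phr_oxygens, mid_oxygens, shr_oxygens,
                        guest_atoms = integer(), guest_oxygen = NA_integer_,
                        water_oxygens = integer(),
                        donors = integer(), hydrogens = integer(),
                        acceptors = integer(),
                        masses = NULL, charges = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "resname", "resid") %in% names(atoms)))
  n <- nrow(atoms)
  rims <- list(phr = as.integer(phr_oxygens), mid = as.integer(mid_oxygens),
               shr = as.integer(shr_oxygens))
  len <- lengths(rims)
  if (length(unique(len)) != 1L || len[1] < 3L)
    stopf("the three rim rings must have equal length n >= 3 (got %s)",
          paste(len, collapse = "/"))
  if (anyDuplicated(unlist(rims)))
    stopf("rim rings must be pairwise disjoint")
  idx_ok <- function(i) length(i) == 0L || (all(i >= 1L) && all(i <= n))
  for (v in c(rims, list(guest_atoms, water_oxygens, donors, hydrogens, acceptors)))
    if (!idx_ok(as.integer(v))) stopf("atom index out of range (1..%d)", n)
  if (!is.na(guest_oxygen) && !(guest_oxygen %in% guest_atoms))
    stopf("guest_oxygen must be one of guest_atoms")
  if (length(hydrogens) != length(donors))
    stopf("'hydrogens' and 'donors' must be parallel vectors (every hydrogen assigned to exactly one donor)")
  if (anyDuplicated(hydrogens))
    stopf("each hydrogen may be assigned to exactly one donor")
  if (!is.null(masses) && length(masses) != n) stopf("masses must have one entry per atom")
  if (!is.null(charges) && length(charges) != n) stopf("charges must have one entry per atom")
  structure(list(atoms = atoms, phr_oxygens = rims$phr, mid_oxygens = rims$mid,
                 shr_oxygens = rims$shr,
                 guest_atoms = as.integer(guest_atoms),
                 guest_oxygen = as.integer(guest_oxygen),
                 water_oxygens = as.integer(water_oxygens),
                 donors = as.integer(donors), hydrogens = as.integer(hydrogens),
                 acceptors = as.integer(acceptors),
                 masses = masses, charges = charges),
            class = "cd_topology")
}

#' @export
print.cd_topology <- function(x, ...) {
  cat(sprintf("cd_topology: %d atoms, %d-unit macrocycle", nrow(x$atoms),
              length(x$phr_oxygens)))
  cat(sprintf(", %d guest atoms, %d water oxygens\n",
              length(x$guest_atoms), length(x$water_oxygens)))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Construct a trajectory
#'
#' Ordered coordinate frames with a fixed timestep. Coordinates are always
#' in nm, times in ps, and boxes are orthorhombic (three edge lengths).
#'
#' @param coords 3-D array with dim \code{c(n_atoms, 3, n_frames)}, or a list
#'   of \code{n_atoms x 3} matrices (converted).
#' @param box per-frame box edge lengths (nm): length-3 vector (recycled) or
#'   \code{n_frames x 3} matrix.
#' @param dt frame spacing in ps (> 0).
#' @param t0 time of the first frame in ps.
#' @return object of class \code{cd_trajectory}.
#' @export
cd_trajectory <- function(coords, box, dt = 10, t0 = 0) {
  if (is.list(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3L, length(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (nf < 1L) stopf("a trajectory needs at least one frame")
  assert_scalar_number(dt, "dt")
  if (dt <= 0) stopf("'dt' must be > 0 (ps)")
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3L) stopf("box must be length 3 or n_frames x 3")
  if (any(box <= 0)) stopf("box edge lengths must be > 0")
  structure(list(coords = coords, box = box, dt = dt, t0 = t0),
            class = "cd_trajectory")
}

#' @export
print.cd_trajectory <- function(x, ...) {
  cat(sprintf("cd_trajectory: %d frames x %d atoms, dt = %g ps, t0 = %g ps\n",
              n_frames(x), dim(x$coords)[1], x$dt, x$t0))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a \code{cd_trajectory}.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory a \code{cd_trajectory}.
#' @param i frame index (1-based).
#' @return \code{n_atoms x 3} matrix (nm).
#' @export
frame_coords <- function(trajectory, i) trajectory$coords[, , i, drop = TRUE]

#' Tail analysis window
#'
#' Resolves the contiguous final fraction of a trajectory used for all
#' summary statistics (production tail, e.g. the last 10%). The window
#' always holds \code{ceiling(fraction * N)} frames; frame counts, not time
#' stamps, are used, so the result is deterministic even without \code{t0}.
#'
#' @param trajectory a \code{cd_trajectory}, or a single integer frame count.
#' @param fraction fraction of frames in (0, 1]; default 0.10.
#' @return list with \code{fraction}, \code{start}, \code{end},
#'   \code{frames} (index vector), class \code{tail_window}.
#' @export
tail_window <- function(trajectory, fraction = 0.10) {
  n <- if (inherits(trajectory, "cd_trajectory")) n_frames(trajectory)
       else as.integer(trajectory)
  if (is.na(n) || n < 1L) stopf("need a trajectory or a positive frame count")
  assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) stopf("'fraction' must be in (0, 1]")
  k <- as.integer(ceiling(fraction * n))
  structure(list(fraction = fraction, start = n - k + 1L, end = n,
                 frames = (n - k + 1L):n),
            class = "tail_window")
}

resolve_window <- function(trajectory, window) {
  if (is.null(window)) return(seq_len(n_frames(trajectory)))
  if (inherits(window, "tail_window")) return(window$frames)
  as.integer(window)
}

## ---------------------------------------------------------------- PDB -----

fmt_pdb_atom <- function(serial, name, resname, resid, xyz_ang, element) {
  if (any(abs(xyz_ang) >= 10000 - 5e-4))
    stopf("coordinate %.3f A exceeds the PDB fixed field width", max(abs(xyz_ang)))
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial %% 100000L, substr(nm, 1, 4), substr(resname, 1, 4),
          resid %% 10000L, xyz_ang[1], xyz_ang[2], xyz_ang[3], element)
}

#' Write a trajectory to multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; coordinates converted nm to Angstrom on
#' output; the box is written as a CRYST1 record (orthorhombic, 90 deg
#' angles). Coordinates that would overflow the fixed-width field raise an
#' error rather than being truncated.
#'
#' @param trajectory a \code{cd_trajectory}.
#' @param topology a \code{cd_topology} providing atom names.
#' @param path output file.
#' @param format only \code{"pdb"} is supported for writing.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, topology, path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!inherits(trajectory, "cd_trajectory")) stopf("not a cd_trajectory")
  nf <- n_frames(trajectory)
  if (nf < 1L) stopf("refusing to write an empty trajectory")
  at <- topology$atoms
  if (dim(trajectory$coords)[1] != nrow(at))
    stopf("trajectory has %d atoms but topology has %d",
          dim(trajectory$coords)[1], nrow(at))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("REMARK   generated by cdtraj; dt = %g ps, t0 = %g ps",
                     trajectory$dt, trajectory$t0), con)
  for (f in seq_len(nf)) {
    b <- trajectory$box[f, ] * 10
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       b[1], b[2], b[3]), con)
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- frame_coords(trajectory, f) * 10   # nm -> Angstrom
    lines <- vapply(seq_len(nrow(at)), function(i)
      fmt_pdb_atom(i, at$name[i], at$resname[i], at$resid[i], xyz[i, ],
                   at$element[i]), character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

parse_pdb_coord <- function(line, lineno) {
  x <- suppressWarnings(as.numeric(c(substr(line, 31, 38), substr(line, 39, 46),
                                     substr(line, 47, 54))))
  if (anyNA(x))
    stopf("unparseable ATOM coordinate fields at line %d", lineno)
  x
}

#' Read a coordinate trajectory
#'
#' Reads multi-model PDB (\code{format = "pdb"}; Angstrom converted to nm,
#' factor 0.1) or concatenated GRO frames (\code{format = "gro"};
#' coordinates already in nm). Frames are returned in file order and the
#' per-frame atom count must match the topology.
#'
#' @param path input file.
#' @param format \code{"pdb"} or \code{"gro"}.
#' @param topology \code{cd_topology}; atom counts are validated against it.
#' @param dt,t0 frame spacing / start time (ps) attached to the result.
#' @param default_box fallback box edge lengths (nm) for PDB files without a
#'   CRYST1 record.
#' @return a \code{cd_trajectory}.
#' @export
read_trajectory <- function(path, format = c("pdb", "gro"), topology,
                            dt = 10, t0 = 0, default_box = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  na <- n_atoms(topology)
  if (format == "pdb") {
    frames <- list(); boxes <- list()
    cur <- NULL; cur_n <- 0L; box <- default_box; fi <- 0L
    for (ln in seq_along(lines)) {
      line <- lines[ln]; rec <- substr(line, 1, 6)
      if (rec == "CRYST1") {
        box <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                             substr(line, 16, 24),
                                             substr(line, 25, 33)))) / 10
        if (anyNA(box)) stopf("unparseable CRYST1 record at line %d", ln)
      } else if (rec == "MODEL ") {
        fi <- fi + 1L; cur <- matrix(NA_real_, na, 3L); cur_n <- 0L
      } else if (rec == "ATOM  " || rec == "HETATM") {
        if (is.null(cur)) { fi <- fi + 1L; cur <- matrix(NA_real_, na, 3L); cur_n <- 0L }
        cur_n <- cur_n + 1L
        if (cur_n > na)
          stopf("frame %d has more atoms than the topology (%d)", fi, na)
        cur[cur_n, ] <- parse_pdb_coord(line, ln) / 10   # Angstrom -> nm
      } else if (rec == "ENDMDL" || (rec == "END   " && !is.null(cur)) ||
                 (substr(line, 1, 3) == "END" && nchar(trimws(line)) == 3L && !is.null(cur))) {
        if (cur_n != na)
          stopf("frame %d has %d atoms, topology expects %d", fi, cur_n, na)
        frames[[fi]] <- cur; boxes[[fi]] <- box; cur <- NULL
      }
    }
    if (!is.null(cur)) {  # file without trailing END
      if (cur_n != na) stopf("frame %d has %d atoms, topology expects %d", fi, cur_n, na)
      frames[[fi]] <- cur; boxes[[fi]] <- box
    }
    if (length(frames) == 0L) stopf("no frames found in '%s'", path)
    if (any(vapply(boxes, is.null, logical(1))))
      stopf("no CRYST1 record and no default_box given")
    cd_trajectory(frames, do.call(rbind, boxes), dt = dt, t0 = t0)
  } else {
    frames <- list(); boxes <- list(); i <- 1L; fi <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(nat)) stopf("unparseable atom count at line %d", i + 1L)
      fi <- fi + 1L
      if (nat != na) stopf("frame %d has %d atoms, topology expects %d", fi, nat, na)
      blk <- lines[(i + 2L):(i + 1L + nat)]
      xyz <- matrix(NA_real_, nat, 3L)
      for (k in seq_len(nat)) {
        ln <- blk[k]
        xyz[k, ] <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                                  substr(ln, 29, 36),
                                                  substr(ln, 37, 44))))
        if (anyNA(xyz[k, ])) stopf("unparseable GRO coordinates at line %d", i + 1L + k)
      }
      bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                                 "\\s+")[[1]]))
      if (length(bl) < 3L || anyNA(bl[1:3]))
        stopf("unparseable GRO box line at line %d", i + 2L + nat)
      frames[[fi]] <- xyz; boxes[[fi]] <- bl[1:3]
      i <- i + 3L + nat
    }
    if (fi == 0L) stopf("no frames found in '%s'", path)
    cd_trajectory(frames, do.call(rbind, boxes), dt = dt, t0 = t0)
  }
}

#' Write a trajectory as concatenated GRO frames
#'
#' @inheritParams write_trajectory
#' @return \code{path}, invisibly.
#' @export
write_trajectory_gro <- function(trajectory, topology, path) {
  nf <- n_frames(trajectory)
  if (nf < 1L) stopf("refusing to write an empty trajectory")
  at <- topology$atoms
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nf)) {
    t_ps <- trajectory$t0 + (f - 1L) * trajectory$dt
    writeLines(sprintf("cdtraj frame t= %.3f", t_ps), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    xyz <- frame_coords(trajectory, f)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$resid %% 100000L, substr(at$resname, 1, 5),
                       substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", trajectory$box[f, 1],
                       trajectory$box[f, 2], trajectory$box[f, 3]), con)
  }
  invisible(path)
}

## ------------------------------------------------------- lambda samples ---

#' Construct a lambda-window sample set
#'
#' Per-window samples feeding the TI and BAR estimators: dH/dlambda samples
#' for each lambda point, and forward/reverse potential-energy differences
#' for each adjacent lambda pair. Lambda runs from 0 (full interactions) to
#' 1 (decoupled).
#'
#' @param lambdas ascending numeric vector of lambda values in [0, 1].
#' @param dhdl list (one numeric vector per lambda) of dH/dlambda samples,
#'   kJ/mol; may be \code{NULL} when only BAR is used.
#' @param forward,reverse lists (one numeric vector per adjacent lambda
#'   pair, length \code{length(lambdas) - 1}) of energy differences, kJ/mol;
#'   may be \code{NULL} when only TI is used.
#' @param temperature simulation temperature in K (metadata; kT for BAR is
#'   passed explicitly).
#' @param softcore optional metadata list recording the soft-core schedule
#'   (never used in computation).
#' @return object of class \code{lambda_samples}.
#' @export
lambda_samples <- function(lambdas, dhdl = NULL, forward = NULL, reverse = NULL,
                           temperature = 310, softcore = NULL) {
  lambdas <- as.numeric(lambdas)
  if (any(lambdas < 0 | lambdas > 1)) stopf("lambda values must lie in [0, 1]")
  if (is.unsorted(lambdas, strictly = TRUE)) stopf("lambda values must be strictly ascending")
  k <- length(lambdas)
  if (!is.null(dhdl) && length(dhdl) != k) stopf("need one dhdl vector per lambda")
  if (!is.null(forward) && length(forward) != k - 1L)
    stopf("need one forward-difference vector per adjacent lambda pair")
  if (!is.null(reverse) && length(reverse) != k - 1L)
    stopf("need one reverse-difference vector per adjacent lambda pair")
  structure(list(lambdas = lambdas, dhdl = dhdl, forward = forward,
                 reverse = reverse, temperature = temperature,
                 softcore = softcore),
            class = "lambda_samples")
}

#' Write lambda-window samples as TSV
#'
#' Long format with columns \code{lambda}, \code{sample}, \code{dhdl},
#' \code{du_forward}, \code{du_reverse}. Forward differences for the pair
#' (i, i+1) are stored on rows of lambda_i; reverse differences on rows of
#' lambda_{i+1}. A comment header records the temperature.
#'
#' @param samples a \code{lambda_samples} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lambda_samples <- function(samples, path) {
  k <- length(samples$lambdas)
  rows <- list()
  for (i in seq_len(k)) {
    dh <- if (!is.null(samples$dhdl)) samples$dhdl[[i]] else numeric()
    fw <- if (!is.null(samples$forward) && i < k) samples$forward[[i]] else numeric()
    rv <- if (!is.null(samples$reverse) && i > 1L) samples$reverse[[i - 1L]] else numeric()
    m <- max(length(dh), length(fw), length(rv), 1L)
    pad <- function(v) c(v, rep(NA_real_, m - length(v)))
    rows[[i]] <- data.frame(lambda = samples$lambdas[i], sample = seq_len(m),
                            dhdl = pad(dh), du_forward = pad(fw),
                            du_reverse = pad(rv))
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# temperature_K: %g", samples$temperature), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read lambda-window samples from TSV
#'
#' @param path file written by \code{\link{write_lambda_samples}} or any TSV
#'   with columns \code{lambda}, \code{sample}, \code{dhdl} and optionally
#'   \code{du_forward}, \code{du_reverse}.
#' @return a \code{lambda_samples} object with lambda groups sorted
#'   ascending.
#' @export
read_lambda_samples <- function(path) {
  hdr <- readLines(path, n = 5L)
  temp <- 310
  tl <- grep("^#\\s*temperature_K:", hdr, value = TRUE)
  if (length(tl)) temp <- as.numeric(sub("^#\\s*temperature_K:\\s*", "", tl[1]))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("lambda", "sample", "dhdl") %in% names(df)))
    stopf("lambda sample table needs columns lambda, sample, dhdl")
  if (any(df$lambda < 0 | df$lambda > 1)) stopf("lambda values must lie in [0, 1]")
  lam <- sort(unique(df$lambda))
  k <- length(lam)
  grab <- function(col, i) {
    if (!col %in% names(df)) return(numeric())
    v <- df[[col]][df$lambda == lam[i]]
    v[!is.na(v)]
  }
  dhdl <- lapply(seq_len(k), function(i) grab("dhdl", i))
  fw <- if ("du_forward" %in% names(df) && k > 1L)
    lapply(seq_len(k - 1L), function(i) grab("du_forward", i)) else NULL
  rv <- if ("du_reverse" %in% names(df) && k > 1L)
    lapply(seq_len(k - 1L), function(i) grab("du_reverse", i + 1L)) else NULL
  if (all(lengths(dhdl) == 0L)) dhdl <- NULL
  if (!is.null(fw) && all(lengths(fw) == 0L)) fw <- NULL
  if (!is.null(rv) && all(lengths(rv) == 0L)) rv <- NULL
  lambda_samples(lam, dhdl = dhdl, forward = fw, reverse = rv,
                 temperature = temp)
}

## ------------------------------------------------------------ topology ----

#' Write a topology annotation to YAML
#' @param topology a \code{cd_topology}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_topology <- function(topology, path) {
  x <- unclass(topology)
  x$atoms <- as.list(x$atoms)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a topology annotation from YAML
#' @param path file written by \code{\link{write_topology}}.
#' @return a \code{cd_topology}.
#' @export
read_topology <- function(path) {
  x <- yaml::read_yaml(path)
  cd_topology(as.data.frame(x$atoms), x$phr_oxygens, x$mid_oxygens,
              x$shr_oxygens, x$guest_atoms %||% integer(),
              x$guest_oxygen %||% NA_integer_,
              x$water_oxygens %||% integer(), x$donors %||% integer(),
              x$hydrogens %||% integer(), x$acceptors %||% integer(),
              masses = x$masses, charges = x$charges)
}
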