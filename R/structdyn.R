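# Structure and trajectory statistics: superposition, RMSF with block
# averaging, native contacts, minimum inter-loop distances, B-factor
# profiles. PDB I/O goes through bio3d.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model
#'
#' @param atoms data frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno` and optionally `b` (B-factor).
#' @param xyz numeric vector of coordinates (x1,y1,z1,x2,...), A.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms)
  need <- c("eleno", "elety", "resid", "chain", "resno")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(xyz) != 3 * nrow(atoms))
    stop("xyz length must be 3 * number of atoms", call. = FALSE)
  if (any(!is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (is.null(atoms$b)) atoms$b <- NA_real_
  structure(list(atoms = atoms, xyz = as.numeric(xyz)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d residues, chain(s) %s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology a [structure_model()].
#' @param frames numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param frame_spacing_ns time between frames, ns.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_spacing_ns = 0.05) {
  stopifnot(inherits(topology, "structure_model"))
  frames <- as.matrix(frames)
  if (ncol(frames) != length(topology$xyz))
    stop("every frame must match the topology's atom count", call. = FALSE)
  if (frame_spacing_ns <= 0)
    stop("frame_spacing_ns must be positive", call. = FALSE)
  structure(list(topology = topology, frames = frames,
                 frame_spacing_ns = frame_spacing_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.3g ns/frame (%.3g ns total)\n",
              nrow(x$frames), ncol(x$frames) / 3, x$frame_spacing_ns,
              nrow(x$frames) * x$frame_spacing_ns))
  invisible(x)
}

#' Read a PDB structure
#'
#' @param path PDB file.
#' @return A [structure_model()] (first MODEL if the file has several).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  structure_model(pdb$atom[, c("eleno", "elety", "resid", "chain", "resno",
                               "b")],
                  as.numeric(pdb$xyz[1, ]))
}

#' Read a trajectory from a multi-model PDB or DCD file
#'
#' @param path multi-model PDB, or DCD (requires `topology`).
#' @param topology PDB file providing atom records when `path` is a DCD.
#' @param frame_spacing_ns time between frames, ns.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, frame_spacing_ns = 0.05) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology))
      stop("DCD input requires a PDB topology", call. = FALSE)
    topo <- read_structure(topology)
    frames <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    topo <- structure_model(pdb$atom[, c("eleno", "elety", "resid", "chain",
                                         "resno", "b")],
                            as.numeric(pdb$xyz[1, ]))
    frames <- unclass(pdb$xyz)
  }
  md_trajectory(topo, frames, frame_spacing_ns)
}

#' Write a structure (or trajectory) as (multi-model) PDB
#'
#' @param x a [structure_model()] or [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(x, path) {
  if (inherits(x, "structure_model")) {
    a <- x$atoms
    bio3d::write.pdb(file = path, xyz = x$xyz, resno = a$resno,
                     resid = a$resid, eleno = a$eleno, elety = a$elety,
                     chain = a$chain,
                     b = ifelse(is.na(a$b), 0, a$b))
  } else if (inherits(x, "md_trajectory")) {
    a <- x$topology$atoms
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nrow(x$frames))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      co <- matrix(x$frames[f, ], ncol = 3, byrow = TRUE)
      writeLines(sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        a$eleno, a$elety, a$resid, a$chain, a$resno,
        co[, 1], co[, 2], co[, 3], 1,
        ifelse(is.na(a$b), 0, a$b)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}

#' Define a residue selection
#'
#' @param residues integer vector of residue numbers, or `c(start, end)`
#'   range when `range = TRUE`.
#' @param chain optional chain id.
#' @param name selection label (e.g. "loopB3").
#' @param range interpret `residues` as an inclusive range.
#' @return An object of class `residue_selection`.
#' @examples
#' residue_selection(c(243, 256), name = "loopB3", range = TRUE)
#' @export
residue_selection <- function(residues, chain = NULL, name = "",
                              range = FALSE) {
  if (range) residues <- seq(residues[1], residues[2])
  structure(list(name = name, chain = chain,
                 residues = as.integer(residues)),
            class = "residue_selection")
}

# atom indices for a selection within a topology
selection_atom_idx <- function(topology, sel, heavy_only = TRUE) {
  a <- topology$atoms
  keep <- a$resno %in% sel$residues
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (heavy_only) keep <- keep & !grepl("^H", a$elety)
  which(keep)
}

atom_type_idx <- function(topology, selection) {
  a <- topology$atoms
  idx <- switch(selection,
                all = seq_len(nrow(a)),
                backbone = which(a$elety %in% BACKBONE_ATOMS),
                calpha = which(a$elety == "CA"),
                stop("unknown selection: ", selection, call. = FALSE))
  if (!length(idx)) stop("empty atom selection", call. = FALSE)
  idx
}

#' Superpose all trajectory frames onto a reference
#'
#' Each frame is rigidly transformed (optimal least-squares rotation and
#' translation) to minimize the RMSD of the selected atoms to the
#' reference.
#'
#' @param traj an [md_trajectory()].
#' @param reference frame index (default 1) or a [structure_model()].
#' @param selection "backbone", "calpha" or "all".
#' @return A superposed [md_trajectory()].
#' @export
superpose_trajectory <- function(traj, reference = 1,
                                 selection = "backbone") {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- atom_type_idx(traj$topology, selection)
  if (length(idx) < 3)
    stop("superposition needs at least 3 selected atoms", call. = FALSE)
  fixed <- if (inherits(reference, "structure_model")) reference$xyz
           else traj$frames[reference, ]
  xyz_idx <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = traj$frames,
                           fixed.inds = xyz_idx, mobile.inds = xyz_idx)
  md_trajectory(traj$topology, fitted, traj$frame_spacing_ns)
}

rmsf_atoms <- function(frames) {
  mu <- colMeans(frames)
  dev2 <- sweep(frames, 2, mu)^2
  persite <- colMeans(dev2)
  # sum x,y,z per atom
  sqrt(persite[c(TRUE, FALSE, FALSE)] + persite[c(FALSE, TRUE, FALSE)] +
         persite[c(FALSE, FALSE, TRUE)])
}

#' Per-residue root mean square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` per atom, averaged over each
#' residue's selected atoms. With `block_ns` set, the trajectory is cut into
#' contiguous blocks of that length, the RMSF computed within each block
#' (about the block mean), and the mean and SD across blocks reported.
#' Superposition is assumed to have been applied already.
#'
#' @param traj a superposed [md_trajectory()] with >= 2 frames.
#' @param selection "backbone", "calpha" or "all".
#' @param block_ns optional block length for block averaging, ns (e.g. 2.5).
#' @return Data frame `resno`, `rmsf` (A) and, when blocked, `sd`.
#' @export
rmsf_profile <- function(traj, selection = "calpha", block_ns = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (nrow(traj$frames) < 2) stop("need at least 2 frames", call. = FALSE)
  idx <- atom_type_idx(traj$topology, selection)
  xyz_idx <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  resno <- traj$topology$atoms$resno[idx]
  agg <- function(per_atom)
    tapply(per_atom, resno, mean)[as.character(unique(resno))]
  if (is.null(block_ns)) {
    per_res <- agg(rmsf_atoms(traj$frames[, xyz_idx, drop = FALSE]))
    return(data.frame(resno = unique(resno), rmsf = as.numeric(per_res)))
  }
  bf <- floor(block_ns / traj$frame_spacing_ns)
  nb <- floor(nrow(traj$frames) / bf)
  if (bf < 2 || nb < 1)
    stop("block longer than trajectory (or shorter than 2 frames)",
         call. = FALSE)
  per_block <- vapply(seq_len(nb), function(b) {
    rows <- ((b - 1) * bf + 1):(b * bf)
    as.numeric(agg(rmsf_atoms(traj$frames[rows, xyz_idx, drop = FALSE])))
  }, numeric(length(unique(resno))))
  per_block <- matrix(per_block, ncol = nb)
  data.frame(resno = unique(resno),
             rmsf = rowMeans(per_block),
             sd = apply(per_block, 1, stats::sd))
}

# residue table: CA atom index and side-chain heavy atom indices per residue
residue_table <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain, a$resno, sep = ":")
  res_keys <- unique(key)
  lapply(res_keys, function(k) {
    rows <- which(key == k)
    ca <- rows[a$elety[rows] == "CA"]
    side <- rows[!(a$elety[rows] %in% BACKBONE_ATOMS) &
                   !grepl("^H", a$elety[rows])]
    if (!length(side)) side <- ca  # Gly (or CA-only model): CA as proxy
    list(key = k, chain = a$chain[rows[1]], resno = a$resno[rows[1]],
         ca = ca, side = side)
  })
}

coords_of <- function(xyz, atom_idx) {
  matrix(xyz[as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1,
                             3 * atom_idx))],
         ncol = 3, byrow = TRUE)
}

# per-residue CA coordinates and side-chain centroids for one frame
residue_geometry <- function(res_tab, xyz) {
  ca <- t(vapply(res_tab, function(r)
    colMeans(coords_of(xyz, r$ca)), numeric(3)))
  cen <- t(vapply(res_tab, function(r)
    colMeans(coords_of(xyz, r$side)), numeric(3)))
  list(ca = ca, centroid = cen)
}

#' Native contacts of a reference structure
#'
#' A residue pair (i, j) is a native contact of residue i when the
#' side-chain heavy-atom centroid of j lies within `cutoff` of residue i's
#' CA in the reference structure (the rule is directional). Glycine, which
#' has no side-chain heavy atoms, uses its CA as the side-chain proxy. Only
#' the self-pair is excluded; sequence neighbours count. The total is the
#' sum of all residues' contact counts.
#'
#' @param reference a [structure_model()] with CA atoms.
#' @param cutoff contact distance, A (default 6.5).
#' @return An object of class `native_contact_set`: `pairs` (data frame
#'   `i`, `j` of residue indices), `counts` (per residue), `total`,
#'   `residues`, `cutoff`.
#' @export
native_contacts <- function(reference, cutoff = 6.5) {
  stopifnot(inherits(reference, "structure_model"))
  res_tab <- residue_table(reference)
  no_ca <- vapply(res_tab, function(r) length(r$ca) == 0, logical(1))
  if (any(no_ca)) {
    warning(sum(no_ca), " residue(s) without CA skipped")
    res_tab <- res_tab[!no_ca]
  }
  geo <- residue_geometry(res_tab, reference$xyz)
  nres <- length(res_tab)
  # distance from each residue's CA (rows) to each side-chain centroid (cols)
  d2 <- outer(rowSums(geo$ca^2), rowSums(geo$centroid^2), `+`) -
    2 * geo$ca %*% t(geo$centroid)
  contact <- d2 <= cutoff^2
  diag(contact) <- FALSE
  pairs <- which(contact, arr.ind = TRUE)
  counts <- rowSums(contact)
  names(counts) <- vapply(res_tab, `[[`, character(1), "key")
  structure(list(pairs = data.frame(i = pairs[, 1], j = pairs[, 2]),
                 counts = counts, total = sum(counts),
                 residues = res_tab, cutoff = cutoff),
            class = "native_contact_set")
}

#' @export
print.native_contact_set <- function(x, ...) {
  cat(sprintf("Native contacts: %d total over %d residues (cutoff %.1f A)\n",
              x$total, length(x$counts), x$cutoff))
  invisible(x)
}

#' Per-frame retained native-contact totals
#'
#' Re-evaluates the reference contact rule for every native pair in each
#' frame; a native contact is retained when the rule still holds. Contacts
#' absent from the reference set never count.
#'
#' @param traj an [md_trajectory()] congruent with the reference topology.
#' @param contact_set a [native_contacts()] result.
#' @return Data frame `frame`, `total_contacts`.
#' @export
count_retained <- function(traj, contact_set) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(contact_set, "native_contact_set"))
  res_tab <- contact_set$residues
  pr <- contact_set$pairs
  cutoff2 <- contact_set$cutoff^2
  totals <- vapply(seq_len(nrow(traj$frames)), function(f) {
    geo <- residue_geometry(res_tab, traj$frames[f, ])
    d2 <- rowSums((geo$ca[pr$i, , drop = FALSE] -
                     geo$centroid[pr$j, , drop = FALSE])^2)
    sum(d2 <= cutoff2)
  }, numeric(1))
  data.frame(frame = seq_len(nrow(traj$frames)), total_contacts = totals)
}

#' Per-frame minimum distance between two residue selections
#'
#' The minimum over all heavy-atom pairs (a in A, b in B) of the Euclidean
#' distance, for each frame.
#'
#' @param traj an [md_trajectory()].
#' @param selA,selB [residue_selection()] objects; must be disjoint.
#' @return Data frame `frame`, `min_dist` (A).
#' @export
min_distance_series <- function(traj, selA, selB) {
  stopifnot(inherits(traj, "md_trajectory"))
  ia <- selection_atom_idx(traj$topology, selA)
  ib <- selection_atom_idx(traj$topology, selB)
  if (!length(ia) || !length(ib))
    stop("empty selection", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("selections overlap", call. = FALSE)
  md <- vapply(seq_len(nrow(traj$frames)), function(f) {
    A <- coords_of(traj$frames[f, ], ia)
    B <- coords_of(traj$frames[f, ], ib)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  data.frame(frame = seq_len(nrow(traj$frames)), min_dist = md)
}

#' Histogram of a per-frame distance series
#'
#' @param series data frame from [min_distance_series()] or numeric vector.
#' @param bin_width bin width, A.
#' @return Data frame `bin_left`, `count`; counts sum to the frame count.
#' @export
dist_histogram <- function(series, bin_width = 0.5) {
  x <- if (is.data.frame(series)) series$min_dist else as.numeric(series)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(lo, max(x) + bin_width, by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)], count = h$counts)
}

#' Per-residue B-factor profile
#'
#' One value per residue possessing the named atom, optionally remapped
#' through a residue-number map (e.g. alignment-derived) for cross-protein
#' overlay.
#'
#' @param structure a [structure_model()] with B-factors.
#' @param chain chain id; `NULL` uses all chains.
#' @param atom atom name (default "CA").
#' @param map optional named integer vector: `map[as.character(resno)]`
#'   gives the reference position; residues absent from the map are dropped.
#' @return Data frame `resno` (or `ref_position` when mapped) and `b`.
#' @export
bfactor_profile <- function(structure, chain = NULL, atom = "CA",
                            map = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  if (!is.null(chain)) {
    if (!chain %in% a$chain) stop("chain not present: ", chain, call. = FALSE)
    a <- a[a$chain == chain, , drop = FALSE]
  }
  a <- a[a$elety == atom, , drop = FALSE]
  if (all(is.na(a$b))) stop("no B-factors present", call. = FALSE)
  out <- data.frame(resno = a$resno, b = a$b)
  if (!is.null(map)) {
    pos <- map[as.character(out$resno)]
    keep <- !is.na(pos)
    out <- data.frame(ref_position = as.integer(pos[keep]),
                      b = out$b[keep])
  }
  out
}

#' Default tunnel-loop residue selections
#'
#' Residue ranges for the tunnel-enclosing loops that are anchored in the
#' structures' own numbering: loop A1 (99-101), loop B3 (243-256, delimited
#' by its disulfide anchors) and the A4 region (390-410). Other loops vary
#' between structures and are user-supplied.
#'
#' @return Named list of [residue_selection()] objects.
#' @export
default_loop_selections <- function() {
  list(loopA1 = residue_selection(c(99, 101), name = "loopA1", range = TRUE),
       loopB3 = residue_selection(c(243, 256), name = "loopB3", range = TRUE),
       regionA4 = residue_selection(c(390, 410), name = "regionA4",
                                    range = TRUE))
}
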