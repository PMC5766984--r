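# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes. All generators are pure functions of their
# arguments including the seed: identical calls give bit-identical output.

#' Generate noisy progress curves from known processive parameters
#'
#' Simulates the noise-free curve once and perturbs each replicate with
#' multiplicative Gaussian noise of the given coefficient of variation
#' (negative values clipped at zero).
#'
#' @inheritParams recovery_study
#' @param params generating [processive_params()].
#' @param noise_cv fractional noise level; 0 returns the noise-free curve.
#' @param reps number of replicate curves.
#' @param seed integer seed.
#' @return List of [progress_curve()] objects of length `reps`.
#' @examples
#' p <- processive_params(0.0055, 4, 0.0066, 89)
#' cv <- gen_progress_curves(p, assay_conditions(3.3, 50), reps = 2, seed = 7)
#' @export
gen_progress_curves <- function(params, conditions, noise_cv = 0.025,
                                reps = 1, seed) {
  clean <- simulate_progress_curve(params, conditions)
  set.seed(as.integer(seed))
  lapply(seq_len(reps), function(i) {
    noisy <- if (noise_cv > 0)
      pmax(clean$product * (1 + noise_cv * stats::rnorm(length(clean$product))), 0)
    else clean$product
    progress_curve(clean$times, noisy, conditions,
                   label = sprintf("synthetic rep %d", i))
  })
}

#' Generate a steady-state rate dataset with inhibition
#'
#' Rates are computed with [mm_rate()] over the grid substrate x inhibitor x
#' replicate and perturbed with multiplicative Gaussian noise.
#'
#' @param params generating [mm_params()].
#' @param substrate_levels substrate concentrations, mM (default: the ten
#'   assay levels, [pnp_lac_levels()]).
#' @param inhibitor_levels inhibitor concentrations, uM (default 0 and 100).
#' @param noise_cv fractional noise level.
#' @param reps replicates per grid point.
#' @param seed integer seed.
#' @return A [rate_dataset()] with `10 x 2 x reps` rows under the defaults.
#' @examples
#' d <- gen_mm_dataset(mm_params(0.067, 0.12, 0.9, K_ic = 49),
#'                     noise_cv = 0.02, reps = 2, seed = 3)
#' @export
gen_mm_dataset <- function(params, substrate_levels = pnp_lac_levels(),
                           inhibitor_levels = c(0, 100),
                           noise_cv = 0.02, reps = 1, seed) {
  stopifnot(inherits(params, "mm_params"))
  grid <- expand.grid(replicate = seq_len(reps),
                      inhibitor_uM = inhibitor_levels,
                      substrate_mM = substrate_levels)
  v <- mm_rate(params, grid$substrate_mM, grid$inhibitor_uM)
  set.seed(as.integer(seed))
  if (noise_cv > 0)
    v <- pmax(v * (1 + noise_cv * stats::rnorm(length(v))), 0)
  rate_dataset(grid$substrate_mM, grid$inhibitor_uM, v,
               enzyme_conc = params$enzyme_conc, replicate = grid$replicate)
}

# substitute along one edge: per site, draw the child state from the exact
# Dayhoff transition probabilities P(rate * len) given the parent state
evolve_seq <- function(seq_idx, rates, len) {
  out <- seq_idx
  for (i in seq_along(seq_idx)) {
    P <- dayhoff_prob(rates[i] * len)
    out[i] <- sample.int(20L, 1L, prob = P[seq_idx[i], ])
  }
  out
}

# simulate sequences down a phylo tree under per-site rates (states are
# indices into the Dayhoff alphabet)
simulate_clade <- function(tree, rates, root_idx) {
  tree <- stats::reorder(tree)  # cladewise: parents before children
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1]] <- root_idx
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[[child]] <- evolve_seq(seqs[[par]], rates, tree$edge.length[e])
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

#' Generate a two-clade alignment with a planted divergent window
#'
#' Two clades are simulated along independent random coalescent trees under
#' a Poisson substitution process with per-site gamma-distributed rates
#' (shape `gamma_shape`, mean 1). Inside `hot_window`, the site rates of
#' lineage A are multiplied by `multiplier`; lineage B is left unchanged.
#' This emulates type-1 functional divergence: sites variable in one lineage
#' but conserved in the sister lineage. States evolve under the Dayhoff
#' substitution model (exact per-edge transition probabilities), matching
#' the model family the downstream rate estimation assumes.
#'
#' @param n_taxa_A,n_taxa_B taxa per clade (defaults 11 and 6, the lineage
#'   sizes of the motivating comparison).
#' @param n_columns alignment length (default 430, a GH7 catalytic domain).
#' @param gamma_shape shape of the per-site rate distribution.
#' @param hot_window numeric `c(start, width, multiplier)`; 1-based start
#'   column, window width, and rate multiplier for lineage A.
#' @param tree_depth expected root-to-tip substitutions/site per clade.
#' @param stem_length substitutions/site on each clade's stem branch (the
#'   shared divergence separating the two lineages from their common
#'   ancestor).
#' @param seed integer seed.
#' @return A list with `alignment` (a `lineage_alignment`: character matrix
#'   plus lineage factor) and `truth` (trees, per-site base rates, per-site
#'   lineage rates, window bounds, seed).
#' @examples
#' g <- gen_divergent_alignment(hot_window = c(200, 12, 10), seed = 1,
#'                              n_columns = 120)
#' @export
gen_divergent_alignment <- function(n_taxa_A = 11, n_taxa_B = 6,
                                    n_columns = 430, gamma_shape = 1,
                                    hot_window = c(200, 12, 10),
                                    tree_depth = 0.15, stem_length = 0.1,
                                    seed) {
  start <- hot_window[1]; width <- hot_window[2]; mult <- hot_window[3]
  if (mult <= 0) stop("window multiplier must be positive", call. = FALSE)
  if (start < 1 || start + width - 1 > n_columns)
    stop("hot window must lie inside [1, n_columns]", call. = FALSE)
  set.seed(as.integer(seed))
  aa <- dayhoff_alphabet()
  base_rates <- stats::rgamma(n_columns, shape = gamma_shape,
                              rate = gamma_shape)
  hot <- seq(start, start + width - 1)
  rates_A <- base_rates
  rates_A[hot] <- rates_A[hot] * mult
  rates_B <- base_rates

  scale_depth <- function(tr, depth) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / h
    tr
  }
  tree_A <- scale_depth(ape::rcoal(n_taxa_A,
                                   tip.label = sprintf("A%02d", seq_len(n_taxa_A))),
                        tree_depth)
  tree_B <- scale_depth(ape::rcoal(n_taxa_B,
                                   tip.label = sprintf("B%02d", seq_len(n_taxa_B))),
                        tree_depth)
  root <- sample.int(20L, n_columns, replace = TRUE,
                     prob = dayhoff_model()$bf)
  root_A <- evolve_seq(root, rates_A, stem_length)
  root_B <- evolve_seq(root, rates_B, stem_length)
  seq_A <- simulate_clade(tree_A, rates_A, root_A)
  seq_B <- simulate_clade(tree_B, rates_B, root_B)
  mat <- matrix(aa[rbind(seq_A, seq_B)], nrow = n_taxa_A + n_taxa_B,
                dimnames = list(c(rownames(seq_A), rownames(seq_B)), NULL))
  lineage <- stats::setNames(rep(c("A", "B"), c(n_taxa_A, n_taxa_B)),
                             rownames(mat))
  aln <- lineage_alignment(mat, lineage)
  list(alignment = aln,
       truth = list(tree_A = tree_A, tree_B = tree_B,
                    base_rates = base_rates, rates_A = rates_A,
                    rates_B = rates_B,
                    window = c(start = as.integer(start),
                               end = as.integer(start + width - 1)),
                    multiplier = mult, seed = seed))
}

#' Generate a toy trajectory with known per-residue fluctuation amplitudes
#'
#' The reference backbone is laid out on a regular helical curve (one CA
#' atom per residue, 3.8 A spacing along the axis path) with one side-chain
#' centroid pseudo-atom (CB) per residue offset 1.5 A radially. Each frame
#' displaces every residue's atoms by an isotropic Gaussian with the
#' residue's sigma (per coordinate, A), so the expected RMSF is
#' `sigma * sqrt(3)`.
#'
#' @param n_residues number of residues.
#' @param sigma_profile per-residue displacement SD per coordinate, A
#'   (recycled if length 1).
#' @param n_frames number of frames (must be positive).
#' @param frame_spacing_ns time between frames, ns (default 0.05, i.e.
#'   2000 frames per 100 ns).
#' @param seed integer seed.
#' @return A list with `trajectory` (an `md_trajectory`) and `truth`
#'   (sigma profile and expected RMSF `sigma * sqrt(3)`).
#' @examples
#' g <- gen_trajectory(5, 0.5, n_frames = 10, seed = 2)
#' @export
gen_trajectory <- function(n_residues, sigma_profile, n_frames,
                           frame_spacing_ns = 0.05, seed) {
  if (n_frames <= 0) stop("n_frames must be positive", call. = FALSE)
  sigma <- rep_len(sigma_profile, n_residues)
  if (any(sigma < 0)) stop("sigma_profile must be non-negative", call. = FALSE)
  # reference: gentle helix, ~3.8 A along the path per residue
  th <- seq_len(n_residues) * 0.6
  ca <- cbind(5 * cos(th), 5 * sin(th), 2.5 * th)
  cb <- ca + cbind(1.5 * cos(th), 1.5 * sin(th), 0)
  xyz_ref <- numeric(0)
  atoms <- NULL
  for (i in seq_len(n_residues)) {
    xyz_ref <- c(xyz_ref, ca[i, ], cb[i, ])
    atoms <- rbind(atoms,
                   data.frame(eleno = 2 * i - 1, elety = "CA", resid = "ALA",
                              chain = "A", resno = i, b = 0,
                              stringsAsFactors = FALSE),
                   data.frame(eleno = 2 * i, elety = "CB", resid = "ALA",
                              chain = "A", resno = i, b = 0,
                              stringsAsFactors = FALSE))
  }
  topo <- structure_model(atoms, xyz_ref)
  set.seed(as.integer(seed))
  per_atom_sigma <- rep(sigma, each = 2)          # CA and CB share sigma
  sig3 <- rep(per_atom_sigma, each = 3)           # per coordinate
  frames <- matrix(rep(xyz_ref, n_frames), nrow = n_frames, byrow = TRUE)
  noise <- matrix(stats::rnorm(n_frames * length(xyz_ref)),
                  nrow = n_frames, byrow = TRUE)
  frames <- frames + sweep(noise, 2, sig3, `*`)
  traj <- md_trajectory(topo, frames, frame_spacing_ns = frame_spacing_ns)
  list(trajectory = traj,
       truth = list(sigma = sigma, expected_rmsf = sigma * sqrt(3),
                    seed = seed))
}
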