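# Shared fixtures and independent oracles used across test files.

table2_params <- function(row) {
  tab <- cel7_kinetic_table()
  processive_params(tab$k_on[row], tab$k_cat[row], tab$k_off[row],
                    tab$n[row])
}

std_conditions <- function(dt = 1)
  assay_conditions(3.3, 50, t_end = 200, sampling_interval = dt)

# Independent ODE oracle for the three-state model (adaptive integrator at
# tight tolerance; no code shared with the closed-form solver under test).
ode_progress_oracle <- function(params, conditions, times) {
  rhs <- function(t, y, p) {
    a <- p$k_on * conditions$substrate_load
    b <- p$k_cat / p$n
    list(c(-a * y[1] + p$k_off * y[3],
           a * y[1] - b * y[2],
           b * y[2] - p$k_off * y[3],
           p$k_cat * y[2]))
  }
  out <- deSolve::ode(c(conditions$enzyme_total, 0, 0, 0), times, rhs,
                      params, method = "lsoda", rtol = 1e-11, atol = 1e-9)
  out[, 5]
}

# brute-force additive-tree fixture: random topology + branch lengths,
# patristic distance matrix from the tree itself
random_additive_case <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# simulate one clade on a fixed tree under given per-site rates (Dayhoff)
simulate_on_tree <- function(tree, rates, seed) {
  set.seed(seed)
  bf <- cel7tools:::dayhoff_model()$bf
  root <- sample.int(20L, length(rates), replace = TRUE, prob = bf)
  idx <- cel7tools:::simulate_clade(tree, rates, root)
  matrix(dayhoff_alphabet()[idx], nrow = nrow(idx),
         dimnames = list(rownames(idx), NULL))
}

toy_chain_structure <- function(n = 5, spacing = 3, b = NULL) {
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(eleno = i, elety = "CA", resid = "GLY", chain = "A",
               resno = i, b = if (is.null(b)) 0 else b[i])))
  xyz <- as.numeric(t(cbind(spacing * (seq_len(n) - 1), 0, 0)))
  structure_model(atoms, xyz)
}

rigid_move <- function(xyz, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  as.numeric(t(sweep(m %*% t(R), 2, shift, `+`)))
}
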