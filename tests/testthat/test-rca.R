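test_that("alignment cleaning removes gapped and ambiguous columns with provenance", {
  m <- matrix(c("A","C","D","E","F",
                "A","-","D","E","F",
                "A","C","D","E","Y"), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1","t2","t3"), NULL))
  lin <- c(t1 = "A", t2 = "A", t3 = "B")
  aln <- load_and_clean_alignment(m, lin)
  expect_identical(ncol(aln$mat), 4L)
  expect_identical(aln$column_map, c(1L, 3L, 4L, 5L))
  # gap-free alignment unchanged
  clean <- load_and_clean_alignment(m[, -2, drop = FALSE], lin)
  expect_identical(clean$mat, toupper(m[, -2]))
  # all-gap and mixed columns both removed (brute-force column scan)
  m2 <- m; m2[, 2] <- "-"; m2[1, 4] <- "X"
  ok <- vapply(seq_len(ncol(m2)), function(j)
    all(m2[, j] %in% dayhoff_alphabet()), logical(1))
  aln2 <- load_and_clean_alignment(m2, lin)
  expect_identical(aln2$column_map, which(ok))
  # invalid inputs
  expect_error(load_and_clean_alignment(m, c(t1 = "A", t2 = "A")),
               "unlabeled")
  mdup <- m; rownames(mdup) <- c("t1", "t1", "t3")
  expect_error(load_and_clean_alignment(mdup, lin), "duplicate")
})

test_that("reference numbering maps retained columns to residue numbers", {
  m <- matrix(c("A","-","D","E",
                "A","C","D","E"), nrow = 2, byrow = TRUE,
              dimnames = list(c("r","s"), NULL))
  aln <- load_and_clean_alignment(m, c(r = "A", s = "B"), ref_id = "r")
  # column 2 dropped; reference residues at original columns 1,3,4 are 1,2,3
  expect_identical(aln$ref_numbering, c(1L, 2L, 3L))
})

test_that("pairwise identity counts only comparable columns", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  expect_equal(pairwise_identity("AC-E", "ACDE"), 100)
  expect_error(pairwise_identity("--", "AC"), "no comparable")
})

test_that("Dayhoff distances are symmetric, zero on identity, and inflate
           observed differences (matrix-exponential oracle)", {
  set.seed(1)
  aa <- dayhoff_alphabet()
  s1 <- sample(aa, 300, replace = TRUE)
  d0 <- dayhoff_distance_matrix(rbind(x = s1, y = s1))
  expect_equal(d0["x", "y"], 0, tolerance = 1e-9)
  # 10% observed differences -> corrected distance above 0.10
  s2 <- s1
  idx <- sample(300, 30)
  for (i in idx) s2[i] <- sample(setdiff(aa, s1[i]), 1)
  dm <- dayhoff_distance_matrix(rbind(x = s1, y = s2))
  expect_gt(dm["x", "y"], 0.10)
  expect_equal(dm["x", "y"], dm["y", "x"])
  # independent oracle: maximize the pair likelihood with P(t) from
  # Matrix::expm of the Dayhoff generator
  tmp <- get(".Dayhoff", environment(phangorn::pml))
  bf <- as.numeric(tmp$bf); k <- 20
  R <- matrix(0, k, k); R[lower.tri(R)] <- tmp$Q; R <- R + t(R)
  Q <- R * rep(bf, each = k); diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * bf)
  i1 <- match(s1, aa); i2 <- match(s2, aa)
  negll <- function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    -sum(log(bf[i1] * P[cbind(i1, i2)]))
  }
  t_hat <- stats::optimize(negll, c(1e-4, 3))$minimum
  expect_equal(dm["x", "y"], t_hat, tolerance = 1e-3)
  # symmetry under sequence swap for random pairs
  set.seed(2)
  for (r in 1:5) {
    a <- sample(aa, 50, replace = TRUE); b <- sample(aa, 50, replace = TRUE)
    d1 <- dayhoff_distance_matrix(rbind(p = a, q = b))
    d2 <- dayhoff_distance_matrix(rbind(p = b, q = a))
    expect_equal(d1["p", "q"], d2["p", "q"], tolerance = 1e-9)
  }
})

test_that("neighbor joining solves the worked four-taxon additive case exactly", {
  lbl <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lbl, lbl))
  d["A","B"] <- 0.3;  d["C","D"] <- 0.7
  d["A","C"] <- 0.45; d["A","D"] <- 0.55
  d["B","C"] <- 0.55; d["B","D"] <- 0.65
  d <- d + t(d)
  tr <- nj_from_distance(d)
  # split AB|CD with internal branch exactly 0.05
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 0.05, tolerance = 1e-12)
  leaf_len <- setNames(numeric(4), lbl)
  for (i in 1:4)
    leaf_len[tr$tip.label[i]] <- tr$edge.length[tr$edge[, 2] == i]
  expect_equal(leaf_len, c(A = 0.1, B = 0.2, C = 0.3, D = 0.4),
               tolerance = 1e-12)
  # path lengths reproduce the input matrix (four-point consistency)
  expect_equal(ape::cophenetic.phylo(tr)[lbl, lbl], d, tolerance = 1e-12)
})

test_that("neighbor joining is exact on random additive matrices", {
  for (case in 1:20) {
    cs <- random_additive_case(ntaxa = sample(5:8, 1), seed = 400 + case)
    tr <- nj_from_distance(cs$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(cs$tree), tr)), 0)
    lbl <- rownames(cs$d)
    expect_equal(ape::cophenetic.phylo(tr)[lbl, lbl], cs$d,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap gives full support to a clean two-clade split", {
  g <- gen_divergent_alignment(n_taxa_A = 4, n_taxa_B = 4, n_columns = 200,
                               hot_window = c(50, 10, 1), tree_depth = 0.3,
                               seed = 5)
  tr <- nj_tree_with_bootstrap(g$alignment, reps = 50, seed = 9)
  # the A|B split must exist with 100% support (the stored root is
  # arbitrary, so the split may surface as either lineage's clade)
  clade_a <- rownames(g$alignment$mat)[g$alignment$lineage == "A"]
  clade_b <- rownames(g$alignment$mat)[g$alignment$lineage == "B"]
  ntip <- length(tr$tip.label)
  found <- FALSE
  for (node in (ntip + 2):(ntip + tr$Nnode)) {
    tips <- ape::extract.clade(tr, node)$tip.label
    if (setequal(tips, clade_a) || setequal(tips, clade_b)) {
      found <- TRUE
      expect_equal(as.numeric(tr$node.label[node - ntip]), 100)
    }
  }
  expect_true(found)
  expect_error(nj_tree_with_bootstrap(g$alignment$mat[1:2, ]), "3 taxa")
})

test_that("site-rate profiles are normalized and order conserved sites low", {
  set.seed(42)
  tr <- ape::rcoal(12)
  tr$edge.length <- tr$edge.length * 1.0 / max(ape::node.depth.edgelength(tr))
  rates <- c(rep(1, 30), 0.0001)  # last column effectively invariant
  mat <- simulate_on_tree(tr, rates, seed = 8)
  prof <- site_rates_empirical_bayes(mat, tr)
  expect_equal(mean(prof$profile$S), 0, tolerance = 1e-9)
  expect_equal(stats::sd(prof$profile$S), 1, tolerance = 1e-9)
  expect_lt(prof$profile$S[31], 0)
  expect_error(site_rates_empirical_bayes(mat, {
    t0 <- tr; t0$edge.length <- t0$edge.length * 0; t0
  }), "zero total length")
})

test_that("fast and slow site groups separate completely on an informative tree", {
  set.seed(42)
  tr <- ape::rcoal(17)
  tr$edge.length <- tr$edge.length * 1.5 / max(ape::node.depth.edgelength(tr))
  rates <- rep(c(0.3, 3), each = 20)  # 10x ratio
  mat <- simulate_on_tree(tr, rates, seed = 12)
  prof <- site_rates_empirical_bayes(mat, tr)
  r <- prof$profile$rate
  expect_lt(max(r[1:20]), min(r[21:40]))
})

test_that("posterior-mean rates are rank-faithful to generating gamma rates", {
  set.seed(42)
  tr <- ape::rcoal(17)
  tr$edge.length <- tr$edge.length * 1.5 / max(ape::node.depth.edgelength(tr))
  set.seed(7)
  rates <- stats::rgamma(200, 1, 1)
  mat <- simulate_on_tree(tr, rates, seed = 13)
  prof <- site_rates_empirical_bayes(mat, tr)
  rho <- stats::cor(rates, prof$profile$rate, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("rca_scan window logic matches its definition", {
  mk_prof <- function(S) structure(list(profile = data.frame(
    column = seq_along(S), rate = S, S = S)), class = "site_rate_profile")
  # constant profiles below threshold: no sections
  s0 <- rca_scan(mk_prof(rep(0.5, 30)), mk_prof(rep(0.5, 30)))
  expect_identical(nrow(s0$sections), 0L)
  expect_equal(s0$table$W_A, rep(0.5, 30))
  # identical profiles with W >= 1 somewhere: still no sections (B fails)
  hot <- c(rep(0, 10), rep(2, 10), rep(0, 10))
  s1 <- rca_scan(mk_prof(hot), mk_prof(hot), window = 7, threshold = 1)
  expect_gt(max(s1$table$W_A), 1)
  expect_identical(nrow(s1$sections), 0L)
  # divergent only in A: one section containing the hot run
  s2 <- rca_scan(mk_prof(hot), mk_prof(rep(0, 30)))
  expect_identical(nrow(s2$sections), 1L)
  expect_true(s2$sections$start >= 8 && s2$sections$end <= 23)
  expect_true(all(s2$high_S_residues %in% 11:20))
  # W is equivariant to adding a constant to S
  s3 <- rca_scan(mk_prof(hot + 2), mk_prof(rep(0, 30)))
  expect_equal(s3$table$W_A, s2$table$W_A + 2)
  # idempotent: scanning the same profiles twice gives identical sections
  expect_identical(rca_scan(mk_prof(hot), mk_prof(rep(0, 30)))$sections,
                   s2$sections)
  expect_error(rca_scan(mk_prof(hot), mk_prof(rep(0, 30)), window = 4),
               "odd")
  expect_error(rca_scan(mk_prof(hot), mk_prof(rep(0, 10))), "different")
})

test_that("a planted divergent window is found near its true location", {
  g <- gen_divergent_alignment(hot_window = c(200, 12, 10), seed = 3)
  res <- run_rca_pipeline(g$alignment)
  win <- g$truth$window
  overlap <- res$scan$sections$start <= win["end"] &
    res$scan$sections$end >= win["start"]
  expect_true(any(overlap))
  sec <- res$scan$sections[which(overlap)[1], ]
  expect_lte(abs(sec$start - win["start"]), 3)
  expect_lte(abs(sec$end - win["end"]), 3)
})
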