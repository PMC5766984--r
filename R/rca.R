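# Reverse conservation analysis: alignment handling, Dayhoff distances,
# NJ + bootstrap, empirical-Bayes site rates and lineage divergence scan.

.cel7_cache <- new.env(parent = emptyenv())

# Dayhoff substitution model (exchangeabilities + equilibrium frequencies)
# as shipped with phangorn's ML machinery; rate matrix normalized to one
# expected substitution per site per unit time, eigen-decomposed once.
dayhoff_model <- function() {
  if (!is.null(.cel7_cache$dayhoff)) return(.cel7_cache$dayhoff)
  tmp <- get(".Dayhoff", environment(phangorn::pml))
  bf <- as.numeric(tmp$bf)
  k <- length(bf)
  R <- matrix(0, k, k)
  R[lower.tri(R)] <- tmp$Q
  R <- R + t(R)
  Q <- R * rep(bf, each = k)        # Q_ij = R_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * bf)       # normalize: 1 sub/site/unit time
  # symmetric similarity transform for a stable eigen-decomposition
  sb <- sqrt(bf)
  B <- Q * outer(sb, 1 / sb)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- eg$vectors / sb              # row-scaled: diag(1/sb) %*% U
  Vinv <- t(eg$vectors * sb)        # U^T %*% diag(sb)
  m <- list(bf = bf, Q = Q, values = eg$values, V = V, Vinv = Vinv,
            alphabet = toupper(names(tmp$bf)))
  .cel7_cache$dayhoff <- m
  m
}

#' The 20-letter amino-acid alphabet in Dayhoff model order
#' @return Character vector of one-letter codes.
#' @export
dayhoff_alphabet <- function() dayhoff_model()$alphabet

# transition probability matrix P(t) = exp(Qt)
dayhoff_prob <- function(t) {
  m <- dayhoff_model()
  P <- m$V %*% (exp(m$values * t) * m$Vinv)
  P[P < 0] <- 0
  P
}

#' Construct a lineage-labelled alignment
#'
#' @param mat character matrix, taxa x columns, one-letter amino-acid codes.
#' @param lineage named character vector mapping taxon id to "A" or "B".
#' @param column_map original 1-based column indices (provenance after
#'   cleaning); defaults to `1:ncol(mat)`.
#' @param ref_numbering optional integer vector, per retained column, of the
#'   residue number in a reference sequence.
#' @return An object of class `lineage_alignment`.
#' @export
lineage_alignment <- function(mat, lineage, column_map = seq_len(ncol(mat)),
                              ref_numbering = NULL) {
  if (is.null(rownames(mat))) stop("alignment rows must be named", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate sequence ids", call. = FALSE)
  missing <- setdiff(rownames(mat), names(lineage))
  if (length(missing))
    stop("unlabeled taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  lineage <- lineage[rownames(mat)]
  if (!all(lineage %in% c("A", "B")))
    stop("lineage labels must be 'A' or 'B'", call. = FALSE)
  if (length(column_map) != ncol(mat))
    stop("column_map length must match alignment width", call. = FALSE)
  structure(list(mat = toupper(mat), lineage = lineage,
                 column_map = as.integer(column_map),
                 ref_numbering = ref_numbering),
            class = "lineage_alignment")
}

#' @export
print.lineage_alignment <- function(x, ...) {
  cat(sprintf("Lineage alignment: %d taxa (%d A, %d B) x %d columns\n",
              nrow(x$mat), sum(x$lineage == "A"), sum(x$lineage == "B"),
              ncol(x$mat)))
  invisible(x)
}

#' Load an aligned FASTA and remove gapped/ambiguous columns
#'
#' Every column containing a gap, missing data, or an ambiguous residue code
#' in any sequence is eliminated; the original column indices of the
#' retained columns are kept for reporting. If `ref_id` is given, each
#' retained column is additionally mapped to its residue number in that
#' (ungapped) reference sequence.
#'
#' @param fasta path to an aligned FASTA file, or a character matrix.
#' @param lineage_map named vector id -> "A"/"B", or path to a two-column
#'   TSV (`id<TAB>A|B`, no header).
#' @param ref_id optional reference sequence id for residue numbering.
#' @return A [lineage_alignment()] with clean columns only.
#' @export
load_and_clean_alignment <- function(fasta, lineage_map, ref_id = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && !is.matrix(fasta)) {
    bin <- ape::read.FASTA(fasta, type = "AA")
    lens <- lengths(bin)
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal aligned lengths", call. = FALSE)
    mat <- toupper(as.character(as.matrix(bin)))
  } else {
    mat <- toupper(as.matrix(fasta))
  }
  if (is.character(lineage_map) && length(lineage_map) == 1L &&
      file.exists(lineage_map)) {
    lt <- utils::read.table(lineage_map, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    lineage_map <- stats::setNames(lt[[2]], lt[[1]])
  }
  ok_col <- apply(mat, 2, function(col) all(col %in% dayhoff_alphabet()))
  clean <- mat[, ok_col, drop = FALSE]
  ref_num <- NULL
  if (!is.null(ref_id)) {
    if (!ref_id %in% rownames(mat))
      stop("reference id not in alignment: ", ref_id, call. = FALSE)
    is_res <- mat[ref_id, ] %in% dayhoff_alphabet()
    resno <- cumsum(is_res)             # residue number at each column
    ref_num <- as.integer(resno[ok_col])
  }
  lineage_alignment(clean, lineage_map, column_map = which(ok_col),
                    ref_numbering = ref_num)
}

#' Restrict an alignment to one lineage
#'
#' @param aln a [lineage_alignment()].
#' @param which "A" or "B".
#' @return A [lineage_alignment()] over the same columns.
#' @export
restrict_lineage <- function(aln, which = c("A", "B")) {
  which <- match.arg(which)
  keep <- aln$lineage == which
  lineage_alignment(aln$mat[keep, , drop = FALSE], aln$lineage[keep],
                    column_map = aln$column_map,
                    ref_numbering = aln$ref_numbering)
}

#' Percent pairwise sequence identity
#'
#' Identity over columns where both sequences carry a residue (gaps in
#' either sequence are excluded from the denominator).
#'
#' @param a,b aligned sequences: character vectors of equal length, or
#'   single strings.
#' @return Percent identity (0-100).
#' @examples
#' pairwise_identity("ACDE", "ACDF")  # 75
#' @export
pairwise_identity <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  a <- toupper(a); b <- toupper(b)
  aa <- dayhoff_alphabet()
  comp <- a %in% aa & b %in% aa
  if (!any(comp)) stop("no comparable columns", call. = FALSE)
  100 * sum(a[comp] == b[comp]) / sum(comp)
}

#' Maximum-likelihood Dayhoff distance matrix
#'
#' Pairwise evolutionary distances (expected substitutions/site) under the
#' Dayhoff substitution model, each found by one-dimensional likelihood
#' maximization (via [phangorn::dist.ml()]).
#'
#' @param aln a cleaned [lineage_alignment()] or character matrix.
#' @return Symmetric numeric matrix with taxon labels, zero diagonal.
#' @export
dayhoff_distance_matrix <- function(aln) {
  mat <- if (inherits(aln, "lineage_alignment")) aln$mat else as.matrix(aln)
  pd <- phangorn::phyDat(mat, type = "AA")
  as.matrix(phangorn::dist.ml(pd, model = "Dayhoff"))
}

#' Neighbor-joining tree with column-resampling bootstrap
#'
#' Saitou-Nei neighbor joining on the Dayhoff ML distance matrix. Bootstrap
#' replicates resample alignment columns with replacement, rebuild the NJ
#' tree, and per-edge split frequencies are attached as internal node labels
#' (percent). Negative NJ branch lengths are clamped to zero.
#'
#' @param aln a cleaned [lineage_alignment()] or character matrix.
#' @param reps bootstrap replicate count; 0 omits supports.
#' @param seed integer seed for the bootstrap resampling.
#' @return An `ape::phylo` tree; `node.label` holds bootstrap percentages
#'   when `reps >= 1`.
#' @export
nj_tree_with_bootstrap <- function(aln, reps = 0, seed = 1) {
  mat <- if (inherits(aln, "lineage_alignment")) aln$mat else as.matrix(aln)
  if (nrow(mat) < 3) stop("need at least 3 taxa", call. = FALSE)
  tree <- nj_from_distance(dayhoff_distance_matrix(mat))
  if (reps >= 1) {
    set.seed(as.integer(seed))
    boots <- lapply(seq_len(reps), function(b) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      nj_from_distance(dayhoff_distance_matrix(mat[, idx, drop = FALSE]))
    })
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / reps, 1)
  }
  tree
}

#' Neighbor joining from a distance matrix
#'
#' @param d symmetric distance matrix or `dist` object.
#' @return An `ape::phylo` tree with negative branch lengths clamped to 0.
#' @export
nj_from_distance <- function(d) {
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# per-site likelihoods by Felsenstein pruning: returns nsites x 1 vector
# of site likelihoods for one relative rate
prune_site_lik <- function(idx_mat, tree, rate) {
  m <- dayhoff_model()
  ntip <- nrow(idx_mat)
  nsites <- ncol(idx_mat)
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tr$Nnode
  L <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    Li <- matrix(0, 20, nsites)
    Li[cbind(idx_mat[tr$tip.label[i], ], seq_len(nsites))] <- 1
    L[[i]] <- Li
  }
  # accumulate children into parents in postorder
  acc <- vector("list", nnode)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- dayhoff_prob(rate * tr$edge.length[e])
    contrib <- P %*% if (child <= ntip) L[[child]] else acc[[child]]
    acc[[par]] <- if (is.null(acc[[par]])) contrib else acc[[par]] * contrib
  }
  root <- tr$edge[nrow(tr$edge), 1]
  as.numeric(m$bf %*% acc[[root]])
}

#' Empirical-Bayes site-specific evolutionary rates
#'
#' Per-column relative substitution rates under the Dayhoff model with
#' discrete-gamma rate variation (equal-probability categories). The gamma
#' shape is estimated by maximizing the summed site log-likelihoods over the
#' tree; each site's posterior-mean rate is then computed from the category
#' likelihoods, and normalized into an S score (profile mean 0, SD 1,
#' higher = more variable).
#'
#' @param aln a cleaned [lineage_alignment()] (or character matrix).
#' @param tree `ape::phylo` over the same taxa, with positive total length.
#' @param k number of gamma rate categories (default 16).
#' @param shape_interval search interval for the gamma shape.
#' @return An object of class `site_rate_profile`: data frame `profile`
#'   (`column`, `ref_residue` if available, `rate`, `S`) plus `shape`,
#'   `logLik`.
#' @export
site_rates_empirical_bayes <- function(aln, tree, k = 16,
                                       shape_interval = c(0.05, 20)) {
  mat <- if (inherits(aln, "lineage_alignment")) aln$mat else as.matrix(aln)
  col_map <- if (inherits(aln, "lineage_alignment")) aln$column_map
             else seq_len(ncol(mat))
  ref_num <- if (inherits(aln, "lineage_alignment")) aln$ref_numbering
             else NULL
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree tips and alignment ids differ", call. = FALSE)
  if (sum(tree$edge.length) <= 0)
    stop("tree has zero total length; site rates undefined", call. = FALSE)
  aa <- dayhoff_alphabet()
  idx <- matrix(match(mat, aa), nrow = nrow(mat),
                dimnames = dimnames(mat))
  if (anyNA(idx))
    stop("alignment contains non-standard residues; clean it first",
         call. = FALSE)

  cat_lik <- function(shape) {
    r <- phangorn::discrete.gamma(shape, k)
    vapply(r, function(ri) prune_site_lik(idx, tree, ri),
           numeric(ncol(idx)))                      # nsites x k
  }
  obj <- function(log_shape) {
    lik <- cat_lik(exp(log_shape))
    -sum(log(rowMeans(lik)))
  }
  opt <- stats::optimize(obj, interval = log(shape_interval))
  shape <- exp(opt$minimum)
  lik <- cat_lik(shape)
  r <- phangorn::discrete.gamma(shape, k)
  post_rate <- as.numeric(lik %*% r) / rowSums(lik)
  S <- as.numeric(scale(post_rate))
  prof <- data.frame(column = col_map, rate = post_rate, S = S)
  if (!is.null(ref_num)) prof$ref_residue <- ref_num
  structure(list(profile = prof, shape = shape, logLik = -opt$objective,
                 k = k),
            class = "site_rate_profile")
}

#' @export
print.site_rate_profile <- function(x, ...) {
  cat(sprintf(
    "Site-rate profile: %d columns, gamma shape %.3g (%d categories), logLik %.2f\n",
    nrow(x$profile), x$shape, x$k, x$logLik))
  invisible(x)
}

# centered running mean truncated at the profile ends
window_mean <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Scan two lineage rate profiles for type-1 divergent sections
#'
#' Computes the sliding-window mean W of the S scores (window `window`,
#' truncated at the profile edges) for each lineage, flags columns where
#' `W_A >= threshold` (variable in lineage A) and `W_B <= threshold`
#' (not elevated in lineage B), and merges maximal runs of flagged columns
#' into sections. Residues with `S_A >= 1` inside sections are reported as
#' high-diversity positions.
#'
#' @param profile_A,profile_B [site_rates_empirical_bayes()] results over
#'   the same retained columns (computed on lineage-restricted
#'   sub-alignments of one master alignment).
#' @param window sliding-window width (odd, default 7).
#' @param threshold significance intensity on W (default 1).
#' @return An object of class `rca_result`: data frame `table` (`column`,
#'   `S_A`, `W_A`, `S_B`, `W_B`, `divergent`), `sections` (data frame
#'   `start`, `end` in original column numbering, non-overlapping, sorted)
#'   and `high_S_residues`.
#' @export
rca_scan <- function(profile_A, profile_B, window = 7, threshold = 1) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1", call. = FALSE)
  pa <- profile_A$profile; pb <- profile_B$profile
  if (nrow(pa) != nrow(pb) || !all(pa$column == pb$column))
    stop("profiles cover different columns", call. = FALSE)
  W_A <- window_mean(pa$S, window)
  W_B <- window_mean(pb$S, window)
  div <- W_A >= threshold & W_B <= threshold
  tab <- data.frame(column = pa$column, S_A = pa$S, W_A = W_A,
                    S_B = pb$S, W_B = W_B, divergent = div)
  if ("ref_residue" %in% names(pa)) tab$ref_residue <- pa$ref_residue
  runs <- rle(div)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sect_idx <- which(runs$values)
  sections <- data.frame(start = pa$column[starts[sect_idx]],
                         end = pa$column[ends[sect_idx]])
  high_idx <- div & pa$S >= 1
  structure(list(table = tab, sections = sections,
                 high_S_residues = pa$column[high_idx],
                 window = window, threshold = threshold),
            class = "rca_result")
}

#' @export
print.rca_result <- function(x, ...) {
  cat(sprintf("RCA scan (window %d, threshold %g): %d divergent section(s)\n",
              x$window, x$threshold, nrow(x$sections)))
  if (nrow(x$sections)) print(x$sections)
  invisible(x)
}
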