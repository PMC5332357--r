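GAP_CHARS <- c("-", ".")

as_alignment <- function(set) {
  if (methods::is(set, "AAStringSet") || methods::is(set, "DNAStringSet")) {
    set <- setNames(as.character(set), names(set))
  }
  stopifnot(is.character(set), !is.null(names(set)))
  if (length(unique(nchar(set))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  set
}

#' Pairwise distances on an aligned protein (or nucleotide) set
#'
#' p-distance (mismatches over compared sites) or its Poisson correction
#' `-ln(1 - p)`.  Gap handling: "pairwise" deletion drops gapped sites per
#' pair (the usual default for protein NJ trees); "complete" drops every
#' column containing a gap.
#'
#' @param set named character vector of equal-length aligned sequences
#'   (or an `AAStringSet`).
#' @param model "p" or "poisson".
#' @param gaps "pairwise" or "complete".
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(set, model = c("p", "poisson"),
                              gaps = c("pairwise", "complete")) {
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  set <- as_alignment(set)
  n <- length(set)
  chars <- do.call(rbind, strsplit(set, "", fixed = TRUE))
  is_gap <- matrix(chars %in% GAP_CHARS, nrow = n)
  if (gaps == "complete") {
    keep <- colSums(is_gap) == 0L
    if (!any(keep)) stop("complete deletion leaves no comparable sites")
    chars <- chars[, keep, drop = FALSE]
    is_gap <- is_gap[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(names(set), names(set)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is_gap[i, ] & !is_gap[j, ]
      m <- sum(ok)
      if (m == 0L) {
        stop("no comparable sites between '", names(set)[i], "' and '",
             names(set)[j], "'")
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / m
      d <- if (model == "p") p else {
        if (p >= 1) stop("Poisson correction undefined at p = 1 for '",
                         names(set)[i], "' vs '", names(set)[j], "'")
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Percent-identity matrix
#'
#' `100 * (1 - p)` on pairwise-deleted sites.
#'
#' @inheritParams pairwise_distance
#' @return symmetric matrix of percent identities (diagonal 100).
#' @export
percent_identity <- function(set, gaps = c("pairwise", "complete")) {
  100 * (1 - pairwise_distance(set, model = "p", gaps = gaps))
}

#' Neighbor-joining tree
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion `Q_ij = (m - 2) d_ij - R_i - R_j`, with limb lengths
#' `v_i = d_ij / 2 + (R_i - R_j) / (2 (m - 2))` and reduced distances
#' `d_uk = (d_ik + d_jk - d_ij) / 2`.  Ties are broken deterministically
#' by the first minimal pair in row-scan order.  Negative limb estimates
#' are clamped to zero with the deficit moved to the sibling limb (the
#' pairwise distance is preserved); the number of clamped limbs is
#' recorded in the `clamped` attribute.  Exact on additive matrices.
#'
#' @param D symmetric non-negative distance matrix with dimnames,
#'   n >= 3 taxa.
#' @return an [ape::read.tree()] "phylo" object (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon names")
  if (anyNA(D) || any(D < 0)) stop("distances must be non-negative and ",
                                   "free of NA")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  newick <- labels                 # growing subtree strings per node
  active <- seq_len(n)
  Dm <- D
  clamped <- 0L
  while (length(active) > 2L) {
    m <- length(active)
    R <- rowSums(Dm)
    best <- NULL
    best_q <- Inf
    for (a in seq_len(m - 1L)) {
      for (b in seq(a + 1L, m)) {
        q <- (m - 2) * Dm[a, b] - R[a] - R[b]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(a, b)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    dij <- Dm[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0; clamped <- clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; clamped <- clamped + 1L }
    sub <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], vi, newick[j], vj)
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (Dm[i, keep] + Dm[j, keep] - dij) / 2
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd),
                c(newd, 0))
    newick <- c(newick[keep], sub)
    active <- c(active[keep], 0L)
  }
  # connect the last two nodes by a single branch; represent the unrooted
  # tree with a trifurcating root by folding the lone branch into the
  # children of the last internal node
  s1 <- newick[1L]; s2 <- newick[2L]
  if (grepl("(", s2, fixed = TRUE)) {
    root <- s2; other <- s1
  } else {
    root <- s1; other <- s2
  }
  final <- paste0(substr(root, 1L, nchar(root) - 1L), ",", other,
                  sprintf(":%.10g);", max(Dm[1L, 2L], 0)))
  tree <- ape::read.tree(text = final)
  attr(tree, "clamped") <- clamped
  tree
}

# Leaf-name bipartition induced by each internal edge of an unrooted
# phylo; canonical side = the side not containing the first tip label
# (sorted), used for support matching.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- lapply(parts, function(idx) sort(tree$tip.label[idx]))
  out <- lapply(out, function(side) {
    if (tips[1L] %in% side) sort(setdiff(tips, side)) else side
  })
  # drop trivial splits (all tips or single tip)
  out[vapply(out, function(s)
    length(s) >= 2L && length(s) <= length(tips) - 2L, logical(1))]
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and labels every internal edge of the
#' full-data tree with the percentage of replicates containing the same
#' leaf bipartition.  Reproducible given `seed`.
#'
#' @inheritParams pairwise_distance
#' @param n_reps bootstrap replicates (default 1000); 0 returns the tree
#'   without supports.
#' @param seed RNG seed for column resampling.
#' @return a "phylo" tree whose `node.label` holds bootstrap percentages
#'   (root label empty).
#' @export
bootstrap_support <- function(set, n_reps = 1000L, seed = 1L,
                              model = c("p", "poisson"),
                              gaps = c("pairwise", "complete")) {
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  set <- as_alignment(set)
  tree <- nj_tree(pairwise_distance(set, model, gaps))
  if (n_reps <= 0L) return(tree)
  len <- nchar(set[[1L]])
  chars <- do.call(rbind, strsplit(set, "", fixed = TRUE))
  set.seed(seed)
  boot_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_set <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste,
                              collapse = ""), names(set))
    boot_trees[[b]] <- nj_tree(pairwise_distance(rep_set, model, gaps))
  }
  ref_splits <- tree_bipartitions(tree)
  keys <- vapply(ref_splits, paste, character(1), collapse = "|")
  hits <- setNames(numeric(length(keys)), keys)
  for (bt in boot_trees) {
    bkeys <- vapply(tree_bipartitions(bt), paste, character(1),
                    collapse = "|")
    hits[keys %in% bkeys] <- hits[keys %in% bkeys] + 1
  }
  support <- round(100 * hits / n_reps)
  # map supports back onto internal nodes: prop.part order matches the
  # order used to build ref_splits
  node_lab <- character(tree$Nnode)
  parts <- ape::prop.part(tree)
  tips <- sort(tree$tip.label)
  pi <- 0L
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
    if (length(side) >= 2L && length(side) <= length(tips) - 2L) {
      pi <- pi + 1L
      node_lab[k] <- as.character(support[pi])
    }
  }
  tree$node.label <- node_lab
  tree
}
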