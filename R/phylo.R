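BASES <- c("A", "C", "G", "T")
## Transition partner of A, C, G, T (A<->G, C<->T).
TS_PARTNER <- c(3L, 4L, 1L, 2L)

#' Aligned nucleotide sequences
#'
#' @param x Named character vector of equal-length sequence strings, or
#'   a character matrix (rows = taxa, one column per site).
#' @return A character matrix of class `eco_alignment` with unique row
#'   names; symbols are upper-cased but not restricted to ACGT
#'   (gaps/ambiguity codes are handled pairwise downstream).
#' @export
sequence_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else if (is.matrix(x)) {
    m <- toupper(x)
    if (is.null(rownames(m))) stop("alignment matrix must have row names")
  } else stop("expected a named character vector or matrix")
  if (nrow(m) < 2L) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(rownames(m))) stop("sequence names must be unique")
  structure(m, class = c("eco_alignment", class(m)))
}

#' Read an aligned FASTA file
#'
#' @param path FASTA path (already aligned; equal lengths enforced).
#' @return An `eco_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""),
                 character(1L))
  sequence_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln An `eco_alignment`.
#' @param path Output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", rownames(aln)),
                           apply(unclass(aln), 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Kimura 2-parameter distance between two sequences
#'
#' Sites where either symbol is not one of A, C, G, T are excluded
#' pairwise. With P and Q the transition and transversion proportions
#' over the included sites,
#' d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)).
#'
#' @param s1,s2 Character vectors of single symbols, or single strings,
#'   of equal length.
#' @return The K2P distance (substitutions per site).
#' @export
k2p_distance <- function(s1, s2) {
  if (length(s1) == 1L && nchar(s1[1L]) > 1L) s1 <- strsplit(s1, "")[[1L]]
  if (length(s2) == 1L && nchar(s2[1L]) > 1L) s2 <- strsplit(s2, "")[[1L]]
  if (length(s1) != length(s2)) stop("sequences must have equal length")
  s1 <- toupper(s1); s2 <- toupper(s2)
  use <- s1 %in% BASES & s2 %in% BASES
  n <- sum(use)
  if (n == 0L) stop("no comparable sites (all excluded pairwise)")
  i1 <- match(s1[use], BASES)
  i2 <- match(s2[use], BASES)
  diff <- i1 != i2
  ts <- diff & (i2 == TS_PARTNER[i1])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(sprintf("K2P saturation: 1-2P-Q = %g, 1-2Q = %g", w1, w2))
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' @param aln An `eco_alignment`.
#' @return A symmetric labelled matrix with zero diagonal.
#' @export
k2p_matrix <- function(aln) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- k2p_distance(aln[i, ], aln[j, ])
  D
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D Symmetric labelled distance matrix.
#' @param path Output path.
#' @export
write_phylip_distance <- function(D, path) {
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste0(formatC(rownames(D)[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = " ")),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ with the rate-corrected Q criterion and
#' Studier-Keppler distance updates. Ties in Q are broken toward the
#' pair whose members contain the lowest original taxon indices;
#' negative intermediate branch lengths are clamped to 0 with the
#' deficit moved to the sister edge. The result is an unrooted binary
#' tree (an ape `"phylo"` object, trifurcation at the last join).
#'
#' @param D Symmetric labelled distance matrix, n >= 3, zero diagonal.
#' @return An ape `phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-12)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## active nodes: temporary ids (tips 1..n, internals n+1, n+2, ...)
  ids <- seq_len(n)
  key <- seq_len(n)            # lowest original tip index per node
  next_id <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0L)
  Dm <- unname(D)
  while (length(ids) > 3L) {
    r <- length(ids)
    Ri <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(Ri, Ri, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pk <- cbind(pmin(key[cand[, 1L]], key[cand[, 2L]]),
                pmax(key[cand[, 1L]], key[cand[, 2L]]))
    pick <- order(pk[, 1L], pk[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    bi <- Dm[i, j] / 2 + (Ri[i] - Ri[j]) / (2 * (r - 2))
    bj <- Dm[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, ids[i]), c(u, ids[j]))
    lens <- c(lens, bi, bj)
    du <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    new_key <- min(key[i], key[j])
    ids <- c(ids[keep], u)
    key <- c(key[keep], new_key)
  }
  ## final three-point join
  v <- next_id
  b <- c((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2,
         (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2,
         (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  b <- pmax(b, 0)
  edges <- rbind(edges, cbind(v, ids))
  lens <- c(lens, b)
  ## renumber to ape convention: tips 1..n, root n+1, internals BFS
  n_internal <- n - 2L
  map <- integer(next_id)
  map[seq_len(n)] <- seq_len(n)
  newid <- n + 1L
  queue <- v
  while (length(queue) > 0L) {
    node <- queue[1L]; queue <- queue[-1L]
    map[node] <- newid; newid <- newid + 1L
    kids <- edges[edges[, 1L] == node, 2L]
    queue <- c(queue, kids[kids > n])
  }
  ## orient edges parent->child from the root
  edge <- cbind(map[edges[, 1L]], map[edges[, 2L]])
  o <- order(edge[, 1L], edge[, 2L])
  tree <- structure(list(edge = edge[o, , drop = FALSE],
                         edge.length = lens[o],
                         tip.label = labels,
                         Nnode = n_internal),
                    class = "phylo", order = "cladewise")
  tree
}

## Tip label sets below each node (index by node id). An edge is
## merged into its parent only once the child's own set is complete.
node_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- n + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  pending <- tabulate(edge[, 1L], nbins = nnode)
  complete <- c(rep(TRUE, n), rep(FALSE, tree$Nnode))
  remaining <- seq_len(nrow(edge))
  while (length(remaining) > 0L) {
    keep <- logical(length(remaining))
    for (t in seq_along(remaining)) {
      e <- remaining[t]
      child <- edge[e, 2L]
      parent <- edge[e, 1L]
      if (complete[child]) {
        sets[[parent]] <- c(sets[[parent]], sets[[child]])
        pending[parent] <- pending[parent] - 1L
        if (pending[parent] == 0L) complete[parent] <- TRUE
      } else keep[t] <- TRUE
    }
    if (all(keep)) stop("malformed tree")
    remaining <- remaining[keep]
  }
  sets
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa in two; a split is canonically
#' represented by the sorted side that does not contain the
#' lexicographically smallest tip label, so the key is independent of
#' rooting and of taxon input order.
#'
#' @param tree An ape `phylo` object.
#' @return Character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  sets <- node_tipsets(tree)
  anchor <- all_tips[1L]
  keys <- character(0L)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next
    side <- sort(sets[[child]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining K2P tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' distance matrix and NJ tree per replicate, and scores each internal
#' edge of the full-data tree by the percentage of replicates whose
#' tree contains the same bipartition. Replicates that hit K2P
#' saturation are dropped and counted (support percentages are over
#' the retained replicates).
#'
#' @param aln An `eco_alignment`.
#' @param replicates Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @return The full-data `phylo` tree with internal-node bootstrap
#'   supports in `node.label` (empty at the basal trifurcation node
#'   when its edge is trivial) and attributes `n_dropped`,
#'   `n_retained`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  full <- nj_tree(k2p_matrix(aln))
  n <- length(full$tip.label)
  counts <- stats::setNames(numeric(0L), character(0L))
  full_keys <- tree_bipartitions(full)
  counts[full_keys] <- 0
  set.seed(seed)
  dropped <- 0L
  retained <- 0L
  L <- ncol(aln)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_tree <- tryCatch(nj_tree(k2p_matrix(sequence_alignment(
      unclass(aln)[, cols, drop = FALSE]))), error = function(e) NULL)
    if (is.null(rep_tree)) { dropped <- dropped + 1L; next }
    retained <- retained + 1L
    hit <- intersect(tree_bipartitions(rep_tree), full_keys)
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0L)
    warning(sprintf("%d bootstrap replicate(s) dropped (K2P saturation)", dropped))
  support <- if (retained > 0L) counts / retained * 100 else counts * NA
  ## map supports onto internal nodes via each node's split key
  sets <- node_tipsets(full)
  all_tips <- sort(full$tip.label)
  anchor <- all_tips[1L]
  node.label <- character(full$Nnode)
  for (nd in (n + 1L):(n + full$Nnode)) {
    side <- sort(sets[[nd]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    key <- paste(side, collapse = "|")
    node.label[nd - n] <- if (key %in% names(support))
      sprintf("%g", round(support[[key]], 1)) else ""
  }
  full$node.label <- node.label
  attr(full, "n_dropped") <- dropped
  attr(full, "n_retained") <- retained
  full
}

#' Write a tree (with supports) as Newick
#'
#' @param tree An ape `phylo` object, optionally with `node.label`
#'   supports.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
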